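#' Counts to concentrations
#'
#' Converts molecule counts to concentrations using the fatty-acid count as
#' the cell-size proxy: the cell volume is `vol_per_fa * fa`, so the
#' concentration of species X is `count(X) / (vol_per_fa * fa)`. A direct
#' consequence is that the fatty-acid concentration is constant
#' (`1 / vol_per_fa`) and that scaling every count by the same factor leaves
#' all concentrations unchanged.
#'
#' @param state Named numeric over `c("fa","aa1","aa2","s","e","n")`:
#'   molecule counts; `fa` must be positive.
#' @param p A `"protocell_params"` object.
#' @return Named numeric vector of concentrations, one per species.
#' @export
concentrations <- function(state, p) {
  fa <- state[["fa"]]
  if (!is.finite(fa) || fa <= 0) {
    abort("degenerate cell: fatty-acid count must be > 0 to define volume",
          class = "protoflux_degenerate_error")
  }
  state[SPECIES] / (p$vol_per_fa * fa)
}

cell_volume <- function(state, p) p$vol_per_fa * state[["fa"]]

#' Effective fixation catalysis under the catalysis cost
#'
#' Nucleotide catalysis of CO2 fixation (KCN) is discounted when the same
#' nucleotides also catalyse individual branches, in proportion to the
#' strength of each distinct pathway-catalysis activity:
#' `KCN_eff = KCN * max(0, 1 - alpha * cost)` where
#' `cost = k_in[fa] + max(k_in[aa1], k_in[aa2]) + k_in[s] + k_in[e]`.
#' The two amino-acid branches driven at a shared strength count once: they
#' represent a single catalytic activity on amino-acid synthesis. The factor
#' is clipped at zero because several pathways together can exceed strength 1.
#' With `alpha = 0` the function returns KCN unchanged.
#'
#' @inheritParams concentrations
#' @return The effective fixation-catalysis constant (scalar).
#' @export
effective_fixation_catalysis <- function(p) {
  kin <- p$k_in
  cost <- kin[["fa"]] + max(kin[["aa1"]], kin[["aa2"]]) + kin[["s"]] + kin[["e"]]
  p$k_cn * max(0, 1 - p$alpha * cost)
}

#' Total CO2-fixation flux
#'
#' Fixation is driven by FeS clusters chelated by the first amino-acid pool
#' and is boosted linearly by nucleotide concentration:
#' `flux = k_fix * co2 * [AA1] * (1 + KCN_eff * [N]) * V`, expressed as total
#' C2 units produced per day for the whole cell. Because `[AA1] * V` is the
#' AA1 count, the flux is proportional to the number of FeS-bearing amino
#' acids and is zero when that pool is empty.
#'
#' @inheritParams concentrations
#' @return Total C2 production rate (scalar, C2 units per day).
#' @export
fixation_flux <- function(state, p) {
  if (any(!is.finite(state))) {
    abort("non-finite state in fixation_flux",
          class = "protoflux_numeric_error")
  }
  conc <- concentrations(state, p)
  p$k_fix * p$co2 * conc[["aa1"]] *
    (1 + effective_fixation_catalysis(p) * conc[["n"]]) *
    cell_volume(state, p)
}

#' Carbon allocation fractions at the branch point
#'
#' Fixed carbon is finite, so catalysis of one branch diverts flux from the
#' others: each branch carries a weight
#' `w_i = lambda_i * (1 + k_in[i] * [N] / (k_sat + [N]))` and receives the
#' normalized fraction `w_i / sum(w)`. With no pathway catalysis (or no
#' nucleotides) the fractions equal the baseline `lambda` exactly; they always
#' sum to 1.
#'
#' @inheritParams concentrations
#' @return Named numeric over `c("fa","aa1","aa2","s","e")`, summing to 1.
#' @export
branch_fractions <- function(state, p) {
  n_conc <- concentrations(state, p)[["n"]]
  sat <- if (p$k_sat + n_conc > 0) n_conc / (p$k_sat + n_conc) else 1
  w <- p$lambda * (1 + p$k_in * sat)
  w / sum(w)
}

#' Nucleotide synthesis rate
#'
#' Nucleotides form trimolecularly from the second amino-acid pool, sugars
#' and the energy currency, with a linear autocatalytic boost:
#' `rate = KNE * [AA2] * [S] * [E] * (1 + KNN * [N]) * V` (molecules per
#' day for the whole cell). Each nucleotide consumes exactly one AA2, one S
#' and one E, so the energy currency acts as a substrate: the rate is zero
#' whenever any of the three substrates is absent.
#'
#' @inheritParams concentrations
#' @return N synthesis rate (scalar, molecules per day).
#' @export
nucleotide_rate <- function(state, p) {
  conc <- concentrations(state, p)
  p$k_ne * conc[["aa2"]] * conc[["s"]] * conc[["e"]] *
    (1 + p$k_nn * conc[["n"]]) * cell_volume(state, p)
}

#' Full rate breakdown at one state
#'
#' Collects the fixation flux, branch fractions, per-branch production rates
#' (molecules per day, `flux * fraction / n_c2`), the nucleotide synthesis
#' rate and its substrate consumption. Carbon is conserved by construction:
#' the production rates weighted by their carbon stoichiometries sum to the
#' fixation flux.
#'
#' @inheritParams concentrations
#' @return A list of class `"rate_breakdown"` with elements `fixation_flux`,
#'   `branch_fractions`, `production_rates`, `nucleotide_rate` and
#'   `consumption_rates`.
#' @export
rate_breakdown <- function(state, p) {
  flux <- fixation_flux(state, p)
  frac <- branch_fractions(state, p)
  prod <- flux * frac / p$n_c2
  nrate <- nucleotide_rate(state, p)
  structure(
    list(fixation_flux = flux,
         branch_fractions = frac,
         production_rates = prod,
         nucleotide_rate = nrate,
         consumption_rates = c(aa2 = nrate, s = nrate, e = nrate)),
    class = "rate_breakdown")
}

#' @export
print.rate_breakdown <- function(x, ...) {
  cat("<rate_breakdown>\n")
  cat(sprintf("  fixation flux: %.6g C2/day\n", x$fixation_flux))
  cat("  fractions:     ", paste(sprintf("%s=%.4g", names(x$branch_fractions),
                                         x$branch_fractions), collapse = " "), "\n")
  cat(sprintf("  nucleotide synthesis: %.6g /day\n", x$nucleotide_rate))
  invisible(x)
}

#' @export
tidy.rate_breakdown <- function(x, ...) {
  tibble(
    species = c(BRANCHES, "n"),
    fraction = c(unname(x$branch_fractions), NA_real_),
    production = c(unname(x$production_rates), x$nucleotide_rate),
    consumption = c(0, 0, x$nucleotide_rate, x$nucleotide_rate,
                    x$nucleotide_rate, 0)
  )
}

#' Time derivative of the molecule counts
#'
#' The right-hand side of the protocell ODE between divisions: each branch
#' gains `flux * fraction / n_c2` molecules per day; AA2, S and E each lose
#' one molecule per nucleotide synthesized; nucleotides gain the synthesis
#' rate. Derivatives are homogeneous of degree one in the counts (scaling a
#' state scales its derivative), which is what makes the converged division
#' cycle a doubling.
#'
#' @inheritParams concentrations
#' @return Named numeric over all six species: d(count)/dt in molecules/day.
#' @export
protocell_rhs <- function(state, p) {
  ## Integrators probe marginally negative states near absorbing boundaries;
  ## clamp those for rate evaluation but refuse genuinely negative states.
  if (any(state < -1e-6 * max(1, p$fa_div))) {
    abort(paste0("negative molecule counts in state: ",
                 paste(sprintf("%s=%.6g", SPECIES, state[SPECIES]),
                       collapse = " ")),
          class = "protoflux_numeric_error")
  }
  st <- pmax(state[SPECIES], 0)
  b <- rate_breakdown(st, p)
  d <- setNames(numeric(6), SPECIES)
  d[BRANCHES] <- b$production_rates
  d[c("aa2", "s", "e")] <- d[c("aa2", "s", "e")] - b$nucleotide_rate
  d[["n"]] <- b$nucleotide_rate
  if (any(!is.finite(d))) {
    abort(paste0("non-finite derivative at state: ",
                 paste(sprintf("%s=%.6g", SPECIES, st), collapse = " ")),
          class = "protoflux_numeric_error")
  }
  d
}
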