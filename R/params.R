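#' Model parameters for a protocell
#'
#' Builds and validates the full parameter set of the protocell
#' protometabolism model. Defaults are the standard simulation preset:
#' thermodynamically assigned branch fractions (fatty acids 0.376, each
#' amino-acid pool 0.282, sugars 0.05, energy currency 0.01), nucleotide
#' catalysis of CO2 fixation `k_cn = 1e3`, trimolecular nucleotide synthesis
#' `k_ne = 2` with autocatalysis `k_nn = 2`, and a pathway-catalysis
#' half-saturation constant `k_sat = 1`.
#'
#' Three calibration constants are not part of the standard preset. `fa_div`
#' is ten times the initial fatty-acid count and
#' `k_fix = log(2) / lambda["aa1"]`, so that the null model (no nucleotide
#' catalysis anywhere) divides exactly once per day: the FeS-bearing
#' amino-acid pool grows exponentially at rate `lambda_aa1 * k_fix` and the
#' converged division cycle is a doubling, giving an asymptotic division rate
#' of `lambda_aa1 * k_fix / log(2)` = 1 per day. The count-to-concentration
#' scale `vol_per_fa = 0.1` is chosen so that nucleotide synthesis runs
#' substrate-limited in the energy currency (about 97% of the E supply is
#' consumed at the null steady state): the energy currency genuinely limits
#' nucleotide production, which is what makes catalysis of the E pathway feed
#' through to nucleotide concentration while sugar-pathway catalysis stays
#' neutral until sugars are made costly. With a much larger scale the
#' nucleotide feedbacks degenerate into perturbative corrections.
#'
#' @param lambda Named numeric over `c("fa","aa1","aa2","s","e")`: baseline
#'   branch fractions of the fixed-carbon (C2) flux. Must be non-negative and
#'   sum to 1 (within 1e-12).
#' @param k_fix Base CO2-fixation rate constant (per day, per unit AA1
#'   concentration). Default is the calibrated value `log(2)/0.282`.
#' @param co2 Ambient CO2 availability multiplier (unitless).
#' @param k_cn Nucleotide catalysis of CO2 fixation (KCN, per concentration).
#' @param k_in Pathway-catalysis strengths (KiN): named values in `[0, 1)`
#'   over any subset of `c("fa","aa1","aa2","s","e")`; omitted entries are 0.
#' @param k_sat Half-saturation constant of the nucleotide-concentration
#'   dependence of pathway catalysis (concentration units).
#' @param k_ne Base trimolecular rate constant of nucleotide synthesis from
#'   AA2 + S + E (KNE).
#' @param k_nn Autocatalysis strength of nucleotide synthesis (KNN, per
#'   concentration).
#' @param alpha Cost coupling in `[0, 1]` between pathway catalysis and
#'   fixation catalysis; see [effective_fixation_catalysis()].
#' @param n_c2 Named integer vector: C2 units consumed per molecule produced,
#'   per branch (all 1 by default; raise `n_c2["s"]` for the costly-sugar
#'   variant).
#' @param vol_per_fa Volume contributed per fatty-acid molecule; sets the
#'   count-to-concentration conversion.
#' @param fa_div Fatty-acid count that triggers division; must exceed the
#'   initial fatty-acid count.
#' @param init Named numeric over all six species
#'   `c("fa","aa1","aa2","s","e","n")`: default initial molecule counts. The
#'   default composition sits near the balanced-growth ray
#'   (AA1/FA = lambda_aa1/lambda_fa) so transients are short; steady-state
#'   results do not depend on it. The absolute scale (about `10^3`--`10^4`
#'   fatty acids, a small vesicle's worth of membrane molecules) matters only
#'   for the stochastic division rule, where it sets the granularity of
#'   binomial partitioning; the deterministic dynamics are scale-invariant.
#'
#' @return A validated object of class `"protocell_params"`.
#' @seealso [validate_params()], [set_pathway_catalysis()], [preset()]
#' @examples
#' p <- protocell_params()
#' p$lambda
#' protocell_params(k_cn = 0)$k_cn
#' @export
protocell_params <- function(lambda = c(fa = 0.376, aa1 = 0.282, aa2 = 0.282,
                                        s = 0.05, e = 0.01),
                             k_fix = log(2) / 0.282,
                             co2 = 1,
                             k_cn = 1e3,
                             k_in = c(fa = 0, aa1 = 0, aa2 = 0, s = 0, e = 0),
                             k_sat = 1,
                             k_ne = 2,
                             k_nn = 2,
                             alpha = 0,
                             n_c2 = c(fa = 1, aa1 = 1, aa2 = 1, s = 1, e = 1),
                             vol_per_fa = 0.1,
                             fa_div = 10000,
                             init = c(fa = 1000, aa1 = 750, aa2 = 750,
                                      s = 130, e = 30, n = 0)) {
  k_in <- fill_named(k_in, BRANCHES, 0, "k_in")
  n_c2 <- fill_named(n_c2, BRANCHES, 1, "n_c2")
  p <- structure(
    list(lambda = lambda, k_fix = k_fix, co2 = co2, k_cn = k_cn,
         k_in = k_in, k_sat = k_sat, k_ne = k_ne, k_nn = k_nn,
         alpha = alpha, n_c2 = n_c2, vol_per_fa = vol_per_fa,
         fa_div = fa_div, init = init),
    class = "protocell_params")
  validate_params(p)
}

## Merge a possibly partial named vector into a full template.
fill_named <- function(x, names_full, default, what) {
  out <- setNames(rep(default, length(names_full)), names_full)
  if (is.null(x)) return(out)
  if (is.null(names(x)) && length(x) == length(names_full)) {
    names(x) <- names_full
  }
  bad <- setdiff(names(x), names_full)
  if (length(bad) > 0) {
    abort(sprintf("unknown %s entries: %s", what, paste(bad, collapse = ", ")),
          class = "protoflux_config_error")
  }
  out[names(x)] <- x
  out
}

#' Validate protocell model parameters
#'
#' Checks every structural invariant of the parameter set. Out-of-range
#' values are rejected, never clipped silently (the only documented clip in
#' the model is the cost clip at zero inside
#' [effective_fixation_catalysis()]).
#'
#' @param p A `"protocell_params"` object or a bare list with the same fields.
#' @return `p`, with class `"protocell_params"`, if all invariants hold.
#' @export
validate_params <- function(p) {
  if (!is.list(p)) {
    abort("parameters must be a list", class = "protoflux_config_error")
  }
  class(p) <- "protocell_params"

  lam <- p$lambda
  if (!identical(sort(names(lam)), sort(BRANCHES))) {
    abort("lambda must be named over fa, aa1, aa2, s, e",
          class = "protoflux_config_error")
  }
  p$lambda <- lam[BRANCHES]
  if (any(!is.finite(lam)) || any(lam < 0)) {
    abort("branch fractions lambda must be finite and >= 0",
          class = "protoflux_config_error")
  }
  if (abs(sum(lam) - 1) > 1e-12) {
    abort(sprintf("branch fractions must sum to 1, got %.12g", sum(lam)),
          class = "protoflux_config_error")
  }

  for (nm in c("k_fix", "co2", "k_cn", "k_sat", "k_ne", "k_nn", "vol_per_fa")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0) {
      abort(sprintf("rate constant %s must be a single finite number >= 0", nm),
            class = "protoflux_config_error")
    }
  }
  if (p$vol_per_fa <= 0) {
    abort("vol_per_fa must be > 0", class = "protoflux_config_error")
  }

  kin <- fill_named(p$k_in, BRANCHES, 0, "k_in")
  if (any(!is.finite(kin)) || any(kin < 0) || any(kin >= 1)) {
    abort("pathway catalysis strengths k_in must lie in [0, 1)",
          class = "protoflux_config_error")
  }
  p$k_in <- kin

  if (!is.numeric(p$alpha) || length(p$alpha) != 1 ||
      !is.finite(p$alpha) || p$alpha < 0 || p$alpha > 1) {
    abort("alpha must lie in [0, 1]", class = "protoflux_config_error")
  }

  nc2 <- fill_named(p$n_c2, BRANCHES, 1, "n_c2")
  if (any(!is.finite(nc2)) || any(nc2 < 1) || any(nc2 != round(nc2))) {
    abort("carbon stoichiometries n_c2 must be integers >= 1",
          class = "protoflux_config_error")
  }
  p$n_c2 <- nc2

  init <- p$init
  if (!identical(sort(names(init)), sort(SPECIES))) {
    abort("init must be named over fa, aa1, aa2, s, e, n",
          class = "protoflux_config_error")
  }
  p$init <- init[SPECIES]
  if (any(!is.finite(p$init)) || any(p$init < 0)) {
    abort("initial counts must be finite and >= 0",
          class = "protoflux_config_error")
  }
  if (!is.finite(p$fa_div) || p$fa_div <= p$init[["fa"]]) {
    abort("fa_div must exceed the initial fatty-acid count",
          class = "protoflux_config_error")
  }
  p
}

#' @export
print.protocell_params <- function(x, ...) {
  cat("<protocell_params>\n")
  cat("  lambda:   ", paste(sprintf("%s=%.4g", BRANCHES, x$lambda),
                            collapse = " "), "\n")
  cat(sprintf("  k_fix=%.6g  co2=%.4g  k_cn=%.4g  k_sat=%.4g\n",
              x$k_fix, x$co2, x$k_cn, x$k_sat))
  cat(sprintf("  k_ne=%.4g  k_nn=%.4g  alpha=%.4g\n", x$k_ne, x$k_nn, x$alpha))
  if (any(x$k_in > 0)) {
    cat("  k_in:     ", paste(sprintf("%s=%.4g", BRANCHES, x$k_in),
                              collapse = " "), "\n")
  }
  if (any(x$n_c2 != 1)) {
    cat("  n_c2:     ", paste(sprintf("%s=%d", BRANCHES, as.integer(x$n_c2)),
                              collapse = " "), "\n")
  }
  cat(sprintf("  fa_div=%g  vol_per_fa=%g  init fa=%g\n",
              x$fa_div, x$vol_per_fa, x$init[["fa"]]))
  invisible(x)
}

#' Modify parameters
#'
#' `update_params()` returns a copy of `p` with the named fields replaced and
#' re-validated. `set_pathway_catalysis()` sets the pathway-catalysis strength
#' KiN for one pathway family: `"aa"` drives both amino-acid branches at the
#' shared strength (the default convention), `"fa"`, `"s"`, `"e"` drive one
#' branch, and `"aa1"`/`"aa2"` drive a single amino-acid pool (the
#' one-pool variant).
#'
#' @param p A `"protocell_params"` object.
#' @param ... Named parameter fields to replace (as in [protocell_params()]).
#' @return A validated `"protocell_params"` object.
#' @export
update_params <- function(p, ...) {
  dots <- list(...)
  if (length(dots) == 0) return(validate_params(p))
  bad <- setdiff(names(dots), names(unclass(p)))
  if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
    abort(sprintf("unknown parameter field(s): %s", paste(bad, collapse = ", ")),
          class = "protoflux_config_error")
  }
  q <- unclass(p)
  for (nm in names(dots)) {
    if (nm %in% c("k_in", "n_c2", "lambda", "init") && !is.null(names(dots[[nm]]))) {
      q[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      q[[nm]] <- dots[[nm]]
    }
  }
  validate_params(q)
}

#' @param pathway One of `"aa"`, `"fa"`, `"s"`, `"e"`, `"aa1"`, `"aa2"`.
#' @param strength KiN value in `[0, 1)`.
#' @rdname update_params
#' @export
set_pathway_catalysis <- function(p, pathway, strength) {
  pathway <- as.character(pathway)[1]
  branches <- switch(pathway,
    aa  = c("aa1", "aa2"),
    aa1 = "aa1",
    aa2 = "aa2",
    fa  = "fa",
    s   = "s",
    e   = "e",
    abort(sprintf("unknown pathway '%s' (use aa, aa1, aa2, fa, s or e)", pathway),
          class = "protoflux_config_error")
  )
  kin <- p$k_in
  kin[branches] <- strength
  update_params(p, k_in = kin)
}

#' Named parameter presets
#'
#' `preset("standard")` is the standard parameter set (the package default).
#' `preset("slow_kcn")` and `preset("fast_kcn")` change only the strength of
#' nucleotide catalysis of CO2 fixation, to `10^0.9` and `10^4` respectively:
#' the slow and fast fixation-catalysis regimes used by the pathway-catalysis
#' sweeps. `preset("null")` switches off every nucleotide feedback
#' (`k_cn = k_nn = 0`, all `k_in = 0`), leaving the calibrated base model.
#'
#' @param name Preset name.
#' @return A validated `"protocell_params"` object.
#' @export
preset <- function(name = c("standard", "slow_kcn", "fast_kcn", "null")) {
  name <- match.arg(name)
  p <- protocell_params()
  switch(name,
    standard = p,
    slow_kcn = update_params(p, k_cn = 10^0.9),
    fast_kcn = update_params(p, k_cn = 1e4),
    null = update_params(p, k_cn = 0, k_nn = 0,
                         k_in = c(fa = 0, aa1 = 0, aa2 = 0, s = 0, e = 0))
  )
}
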