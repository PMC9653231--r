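#' Control settings used by the experiment layer
#'
#' The pathway-catalysis effects on the division rate are small fractions of
#' a percent under the default half-saturation constant, so the experiment
#' layer integrates tightly (`rtol = 1e-10`) and demands a tight steady-state
#' criterion (`rel_tol = 1e-7`) to resolve orderings well above numerical
#' noise.
#'
#' @inheritParams sim_control
#' @return A `"sim_control"` list.
#' @export
experiment_control <- function(rtol = 1e-10, atol = 1e-12, t_budget = 500,
                               max_divisions = 400, rel_tol = 1e-7,
                               k_intervals = 5, stoch_window = 20,
                               dense_n = 400) {
  sim_control(rtol = rtol, atol = atol, t_budget = t_budget,
              max_divisions = max_divisions, rel_tol = rel_tol,
              k_intervals = k_intervals, stoch_window = stoch_window,
              dense_n = dense_n)
}

## One steady-state measurement -> one tibble row.
measure_point <- function(p, control, init = NULL) {
  lin <- run_lineage(p, init = init, control = control)
  ss <- steady_state(lin)
  tibble(
    division_rate = ss$division_rate,
    eq_n_conc = unname(ss$eq_concentrations[["n"]]),
    collapsed = ss$collapsed,
    converged = ss$converged,
    cycles = ss$cycles_used,
    convergence_time = ss$convergence_time)
}

new_sweep <- function(tbl, axes, provenance = list()) {
  structure(tbl, class = c("protocell_sweep", class(tbl)),
            axes = axes, provenance = provenance)
}

#' Sweep the fixation-catalysis constant KCN
#'
#' Measures the steady-state division rate along a grid of
#' fixation-catalysis strengths. With default parameters the rate is
#' non-decreasing along the grid: nucleotide catalysis of CO2 fixation is a
#' pure positive feedback on growth.
#'
#' @inheritParams run_lineage
#' @param kcn_grid Numeric grid of KCN values (non-empty).
#' @return A `"protocell_sweep"` tibble with one row per grid point.
#' @export
sweep_kcn <- function(p = protocell_params(), kcn_grid = c(0, 10^(0:4)),
                      control = experiment_control()) {
  if (length(kcn_grid) == 0) {
    abort("kcn_grid must be non-empty", class = "protoflux_config_error")
  }
  rows <- purrr::map(kcn_grid, function(kcn) {
    dplyr::bind_cols(tibble(kcn = kcn),
                     measure_point(update_params(p, k_cn = kcn), control))
  })
  new_sweep(dplyr::bind_rows(rows),
            axes = list(kcn = kcn_grid),
            provenance = list(experiment = "sweep_kcn"))
}

resolve_kcn <- function(kcn) {
  if (is.character(kcn)) {
    switch(kcn[1],
           slow = 10^0.9,
           fast = 1e4,
           abort(sprintf("unknown kcn preset '%s' (use 'slow' or 'fast')", kcn[1]),
                 class = "protoflux_config_error"))
  } else {
    kcn[1]
  }
}

#' Sweep nucleotide catalysis of one synthetic pathway
#'
#' Measures division rate and equilibrium nucleotide concentration over a
#' grid of pathway-catalysis strengths KiN for one pathway family, together
#' with the KiN = 0 reference (catalysis of CO2 fixation alone), reported in
#' the `baseline_rate` / `baseline_eq_n` columns. Pathway `"aa"` drives both
#' amino-acid branches at the shared strength; set `aa_single_branch` to
#' drive only the FeS-chelating pool (`"aa1"`), the one-pool variant.
#'
#' @inheritParams run_lineage
#' @param pathway One of `"aa"`, `"fa"`, `"s"`, `"e"`.
#' @param kin_grid Grid of KiN strengths in `[0, 1)`; the conventional grid
#'   is 0 (none), 0.33 (weak), 0.66 (moderate), 0.99 (strong).
#' @param kcn `"slow"` (`10^0.9`), `"fast"` (`10^4`), a number, or `NULL` to
#'   keep the value in `p`.
#' @param alpha Catalysis cost coupling in `[0, 1]`.
#' @param aa_single_branch Apply the `"aa"` strength to AA1 only.
#' @return A `"protocell_sweep"` tibble, one row per KiN.
#' @export
sweep_pathway <- function(p = protocell_params(),
                          pathway = c("aa", "fa", "s", "e"),
                          kin_grid = c(0, 0.33, 0.66, 0.99),
                          kcn = NULL, alpha = NULL,
                          aa_single_branch = FALSE,
                          control = experiment_control()) {
  pathway <- match.arg(pathway)
  target <- if (pathway == "aa" && aa_single_branch) "aa1" else pathway
  if (!is.null(kcn)) p <- update_params(p, k_cn = resolve_kcn(kcn))
  if (!is.null(alpha)) p <- update_params(p, alpha = alpha)
  rows <- purrr::map(kin_grid, function(kin) {
    pk <- set_pathway_catalysis(p, target, kin)
    dplyr::bind_cols(
      tibble(pathway = pathway, kin = kin, kcn = p$k_cn, alpha = p$alpha),
      measure_point(pk, control))
  })
  tbl <- dplyr::bind_rows(rows)
  base <- dplyr::filter(tbl, .data$kin == 0)
  if (nrow(base) == 1) {
    tbl$baseline_rate <- base$division_rate
    tbl$baseline_eq_n <- base$eq_n_conc
  } else {
    tbl$baseline_rate <- NA_real_
    tbl$baseline_eq_n <- NA_real_
  }
  new_sweep(tbl, axes = list(kin = kin_grid),
            provenance = list(experiment = "sweep_pathway", pathway = pathway,
                              kcn = p$k_cn, alpha = p$alpha,
                              aa_single_branch = aa_single_branch))
}

#' Autocatalysis-by-fixation-catalysis heat map
#'
#' Measures division rate and equilibrium nucleotide concentration over the
#' log-spaced grid KNN x KCN. Along the fixation-catalysis axis the division
#' rate is non-decreasing; nucleotides accumulate most where autocatalysis is
#' strong but fixation catalysis weak (slow division dilutes them least),
#' while the division rate peaks where both are strong.
#'
#' @inheritParams run_lineage
#' @param knn_grid,kcn_grid Numeric grids (length >= 3 each); defaults are 13
#'   log-spaced points spanning `10^-2..10^4` (KNN) and `10^0..10^4` (KCN).
#' @return An object of class `"protocell_heatmap"`: a list with the long
#'   `table` (tibble), matrices `rate` and `eq_n` (rows = KNN, columns =
#'   KCN), and the two grids.
#' @export
heatmap_autocatalysis <- function(p = protocell_params(),
                                  knn_grid = 10^seq(-2, 4, length.out = 13),
                                  kcn_grid = 10^seq(0, 4, length.out = 13),
                                  control = experiment_control()) {
  if (length(knn_grid) < 3 || length(kcn_grid) < 3) {
    abort("heat-map grids need at least 3 points per axis",
          class = "protoflux_config_error")
  }
  grid <- tidyr::expand_grid(knn = knn_grid, kcn = kcn_grid)
  rows <- purrr::pmap(grid, function(knn, kcn) {
    dplyr::bind_cols(tibble(knn = knn, kcn = kcn),
                     measure_point(update_params(p, k_nn = knn, k_cn = kcn),
                                   control))
  })
  tbl <- dplyr::bind_rows(rows)
  rate <- matrix(tbl$division_rate, nrow = length(knn_grid), byrow = TRUE,
                 dimnames = list(signif(knn_grid, 6), signif(kcn_grid, 6)))
  eq_n <- matrix(tbl$eq_n_conc, nrow = length(knn_grid), byrow = TRUE,
                 dimnames = dimnames(rate))
  structure(list(table = tbl, rate = rate, eq_n = eq_n,
                 knn_grid = knn_grid, kcn_grid = kcn_grid),
            class = "protocell_heatmap")
}

#' @export
print.protocell_heatmap <- function(x, ...) {
  cat(sprintf("<protocell_heatmap> %d x %d (KNN x KCN)\n",
              length(x$knn_grid), length(x$kcn_grid)))
  cat(sprintf("  rate range %.4g..%.4g /day, eq [N] range %.4g..%.4g\n",
              min(x$rate), max(x$rate), min(x$eq_n), max(x$eq_n)))
  invisible(x)
}

#' @export
tidy.protocell_heatmap <- function(x, ...) x$table

#' @export
as_tibble.protocell_heatmap <- function(x, ...) x$table

#' Initial-condition independence scan
#'
#' Runs lineages from rescaled and skewed initial states and reports the
#' steady-state division rate, equilibrium concentrations and time to
#' convergence. `scale` multiplies every non-membrane count (a
#' concentration scaling at fixed cell size); `skew` additionally multiplies
#' the two amino-acid pools (a composition skew). Steady-state results are
#' independent of both; dilute starts only take longer to converge.
#'
#' @inheritParams run_lineage
#' @param scale_grid,skew_grid Numeric grids of multipliers (> 0).
#' @return A `"protocell_sweep"` tibble, one row per (scale, skew) pair, with
#'   `eq_*` columns for all six species.
#' @export
initial_condition_scan <- function(p = protocell_params(),
                                   scale_grid = c(0.1, 1, 10),
                                   skew_grid = c(0.25, 1, 4),
                                   control = experiment_control()) {
  grid <- tidyr::expand_grid(scale = scale_grid, skew = skew_grid)
  rows <- purrr::pmap(grid, function(scale, skew) {
    init <- p$init
    init[setdiff(SPECIES, "fa")] <- init[setdiff(SPECIES, "fa")] * scale
    init[c("aa1", "aa2")] <- init[c("aa1", "aa2")] * skew
    lin <- run_lineage(p, init = init, control = control)
    ss <- steady_state(lin)
    dplyr::bind_cols(
      tibble(scale = scale, skew = skew),
      tibble(division_rate = ss$division_rate,
             collapsed = ss$collapsed, converged = ss$converged,
             cycles = ss$cycles_used, convergence_time = ss$convergence_time),
      tibble(!!!setNames(as.list(unname(ss$eq_concentrations[SPECIES])),
                         paste0("eq_", SPECIES))))
  })
  new_sweep(dplyr::bind_rows(rows),
            axes = list(scale = scale_grid, skew = skew_grid),
            provenance = list(experiment = "initial_condition_scan"))
}

#' Stochastic-segregation experiment
#'
#' For each segregation-noise level (the variance multiplier of
#' [divide_cell()]), runs `n_seeds` stochastic lineages and reports the mean
#' and standard error of the division rate and of the equilibrium nucleotide
#' concentration, next to the deterministic reference. Seeds are derived
#' deterministically from `base_seed`, so the table is reproducible.
#'
#' @inheritParams run_lineage
#' @param noise_grid Noise levels in `[0, 1]`.
#' @param n_seeds Number of replicate lineages per noise level (>= 2).
#' @param base_seed Integer seed from which replicate seeds are derived.
#' @return A `"protocell_sweep"` tibble, one row per noise level.
#' @export
stochastic_segregation <- function(p = protocell_params(),
                                   noise_grid = c(0, 0.25, 0.5, 0.75, 1),
                                   n_seeds = 20, base_seed = 1,
                                   control = experiment_control()) {
  if (n_seeds < 2) {
    abort("n_seeds must be >= 2 (no standard error otherwise)",
          class = "protoflux_config_error")
  }
  stoch_control <- sim_control(
    rtol = control$rtol, atol = control$atol, t_budget = control$t_budget,
    max_divisions = max(control$max_divisions, 3 * control$stoch_window),
    rel_tol = control$rel_tol, k_intervals = control$k_intervals,
    stoch_window = control$stoch_window, dense_n = control$dense_n)
  ## Deterministic reference, measured with the same estimator as the
  ## replicates (a noise-0 stochastic-mode run IS deterministic halving), so
  ## the no-noise limit reproduces it exactly.
  det_lin <- run_lineage(p, mode = "stochastic", noise = 0, seed = base_seed,
                         control = stoch_control)
  det_ss <- steady_state(det_lin)
  det <- list(division_rate = det_ss$division_rate,
              eq_n_conc = unname(det_ss$eq_concentrations[["n"]]))
  rows <- purrr::map(noise_grid, function(noise) {
    reps <- purrr::map(seq_len(n_seeds), function(i) {
      seed <- (base_seed * 10000L + i) %% .Machine$integer.max
      lin <- run_lineage(p, mode = "stochastic", noise = noise, seed = seed,
                         control = stoch_control)
      ss <- steady_state(lin)
      c(rate = ss$division_rate, eq_n = unname(ss$eq_concentrations[["n"]]))
    })
    m <- do.call(rbind, reps)
    tibble(noise = noise, n_seeds = n_seeds,
           mean_rate = mean(m[, "rate"]),
           se_rate = sd(m[, "rate"]) / sqrt(n_seeds),
           mean_eq_n = mean(m[, "eq_n"]),
           se_eq_n = sd(m[, "eq_n"]) / sqrt(n_seeds),
           det_rate = det$division_rate,
           det_eq_n = det$eq_n_conc)
  })
  new_sweep(dplyr::bind_rows(rows),
            axes = list(noise = noise_grid),
            provenance = list(experiment = "stochastic_segregation",
                              base_seed = base_seed, n_seeds = n_seeds))
}

#' Costly-sugar variant
#'
#' Repeats the sugar-pathway catalysis sweep at each sugar carbon
#' stoichiometry in `n_c2_s_grid`. At the default stoichiometry (1 C2 per
#' sugar) sugars are produced in excess of nucleotide-synthesis demand, so
#' catalysing their production is neutral or mildly deleterious; when more
#' carbon is needed per sugar, sugar availability begins to limit nucleotide
#' synthesis and strong sugar-pathway catalysis becomes beneficial. The
#' `beneficial_at_strong` column flags whether the strongest KiN beats the
#' KiN = 0 baseline. The default parameter set is the slow
#' fixation-catalysis preset, the regime in which the substrate-limitation
#' mechanism shows most cleanly.
#'
#' @inheritParams sweep_pathway
#' @param n_c2_s_grid Integer grid of C2 units consumed per sugar molecule.
#'   The default contrasts the standard stoichiometry with 8 C2 per sugar,
#'   which moves the limiting substrate of nucleotide synthesis from the
#'   energy currency (supply ratio `lambda_e = 0.01`) to sugars
#'   (`lambda_s / n_c2_s = 0.05/8`).
#' @return A `"protocell_sweep"` tibble, one row per (n_c2_s, KiN) pair.
#' @export
sugar_cost_variant <- function(p = preset("slow_kcn"),
                               n_c2_s_grid = c(1, 8),
                               kin_grid = c(0, 0.33, 0.66, 0.99),
                               control = experiment_control()) {
  rows <- purrr::map(n_c2_s_grid, function(ns) {
    pv <- update_params(p, n_c2 = c(s = ns))
    sw <- sweep_pathway(pv, pathway = "s", kin_grid = kin_grid,
                        control = control)
    class(sw) <- setdiff(class(sw), "protocell_sweep")
    attr(sw, "axes") <- NULL
    attr(sw, "provenance") <- NULL
    strong <- dplyr::filter(sw, .data$kin == max(kin_grid))
    dplyr::mutate(sw,
                  n_c2_s = ns,
                  rel_effect = .data$division_rate / .data$baseline_rate - 1,
                  beneficial_at_strong =
                    strong$division_rate > strong$baseline_rate,
                  .before = 1)
  })
  new_sweep(dplyr::bind_rows(rows),
            axes = list(n_c2_s = n_c2_s_grid, kin = kin_grid),
            provenance = list(experiment = "sugar_cost_variant"))
}

#' CO2 availability scan
#'
#' Division rate along a grid of ambient CO2 multipliers. Fixation flux is
#' proportional to CO2 availability, so the rate is non-decreasing in the
#' multiplier and the cell collapses at zero CO2.
#'
#' @inheritParams run_lineage
#' @param co2_grid Numeric grid of CO2 multipliers (>= 0).
#' @return A `"protocell_sweep"` tibble, one row per grid point.
#' @export
co2_scan <- function(p = protocell_params(), co2_grid = c(0, 0.5, 1, 2),
                     control = experiment_control()) {
  rows <- purrr::map(co2_grid, function(co2) {
    dplyr::bind_cols(tibble(co2 = co2),
                     measure_point(update_params(p, co2 = co2), control))
  })
  new_sweep(dplyr::bind_rows(rows),
            axes = list(co2 = co2_grid),
            provenance = list(experiment = "co2_scan"))
}
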