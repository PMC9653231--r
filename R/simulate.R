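#' Simulation control settings
#'
#' Numerical settings shared by the lineage simulator and the experiment
#' layer. The integrator is `deSolve::lsodar`, which switches automatically
#' between non-stiff and stiff methods and locates the division threshold by
#' root finding; collapse-regime dynamics can be stiff, hence both tolerances
#' are exposed.
#'
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param t_budget Total simulated time budget per lineage (days).
#' @param max_divisions Cap on the number of division events per lineage.
#' @param rel_tol Steady-state criterion: relative spread of the last
#'   `k_intervals` inter-division intervals below which the lineage is
#'   declared converged (deterministic mode).
#' @param k_intervals Number of trailing intervals used by the deterministic
#'   convergence criterion and by the rate estimate.
#' @param stoch_window Window length (intervals) for the stochastic
#'   convergence criterion: the running mean of the last window must agree
#'   with the previous window within two standard errors.
#' @param dense_n Number of sample points used when a cycle trajectory is
#'   re-integrated densely (event timing is unaffected; this only controls
#'   trajectory output and time-averaged concentrations).
#' @return A list of class `"sim_control"`.
#' @export
sim_control <- function(rtol = 1e-8, atol = 1e-10, t_budget = 500,
                        max_divisions = 200, rel_tol = 1e-4,
                        k_intervals = 5, stoch_window = 20, dense_n = 400) {
  structure(list(rtol = rtol, atol = atol, t_budget = t_budget,
                 max_divisions = max_divisions, rel_tol = rel_tol,
                 k_intervals = k_intervals, stoch_window = stoch_window,
                 dense_n = dense_n),
            class = "sim_control")
}

## deSolve plumbing: rhs and the division-threshold root function.
rhs_desolve <- function(t, y, parms) {
  list(unname(protocell_rhs(setNames(y, SPECIES), parms)))
}

root_division <- function(t, y, parms) y[1] - parms$fa_div

#' Integrate one growth cycle up to the division threshold
#'
#' Integrates the protocell ODE from `state` until the fatty-acid count
#' reaches `fa_div` (located by root finding) or until `t_max` elapses.
#'
#' @inheritParams concentrations
#' @param t_max Time budget for this cycle (days).
#' @param control A [sim_control()] list.
#' @param dense If `TRUE`, also return the cycle trajectory sampled at
#'   `control$dense_n + 1` equally spaced times.
#' @return A list with elements `event` (`NULL` on timeout, otherwise a list
#'   with `time` and `mother`, the state at the threshold), `state` (final
#'   state), `time` (elapsed time), `timed_out`, and `trajectory` (a tibble
#'   or `NULL`).
#' @export
step_to_division <- function(state, p, t_max = 500, control = sim_control(),
                             dense = FALSE) {
  state <- state[SPECIES]
  if (state[["fa"]] >= p$fa_div) {
    abort("state is already at or above the division threshold",
          class = "protoflux_config_error")
  }
  out <- try(deSolve::lsodar(
    y = unname(state), times = c(0, t_max), func = rhs_desolve, parms = p,
    rtol = control$rtol, atol = control$atol,
    rootfunc = root_division, maxsteps = 1e5), silent = TRUE)
  if (inherits(out, "try-error")) {
    abort(paste0("integration failure: ", attr(out, "condition")$message),
          class = "protoflux_integration_error")
  }
  troot <- attr(out, "troot")
  last <- out[nrow(out), ]
  final <- setNames(pmax(unname(last[1 + seq_along(SPECIES)]), 0), SPECIES)
  t_end <- unname(last[1])
  has_event <- length(troot) > 0 && is.finite(troot[1])
  traj <- NULL
  if (dense) {
    times <- seq(0, t_end, length.out = control$dense_n + 1)
    dd <- deSolve::lsoda(y = unname(state), times = times, func = rhs_desolve,
                         parms = p, rtol = control$rtol, atol = control$atol,
                         maxsteps = 1e5)
    traj <- as_tibble(as.data.frame(dd))
    names(traj) <- c("time", SPECIES)
  }
  list(
    event = if (has_event) list(time = troot[1], mother = final) else NULL,
    state = final,
    time = t_end,
    timed_out = !has_event,
    trajectory = traj
  )
}

#' Partition a mother cell into a daughter
#'
#' Deterministic mode halves every count exactly, which leaves all
#' concentrations unchanged (the volume, proportional to the fatty-acid
#' count, halves too). Stochastic mode rounds counts to integers
#' (round-half-to-even) and draws each species independently as
#' `Binomial(count, 1/2)`; `noise` interpolates the segregation variance
#' between exact halving (0) and the full binomial variance (1) via
#' `daughter = count/2 + sqrt(noise) * (Binomial(count, 1/2) - count/2)`.
#' At `noise = 0` the deterministic rule is used exactly. Stochastic draws
#' use the R random number generator; seed it (or pass `seed` to
#' [run_lineage()]) for reproducibility.
#'
#' @inheritParams concentrations
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param noise Variance multiplier in `[0, 1]` (stochastic mode only).
#' @return Named numeric vector: the daughter's counts.
#' @export
divide_cell <- function(state, mode = c("deterministic", "stochastic"),
                        noise = 1) {
  mode <- match.arg(mode)
  state <- state[SPECIES]
  if (mode == "deterministic" || noise == 0) {
    return(state / 2)
  }
  if (!is.finite(noise) || noise < 0 || noise > 1) {
    abort("noise must lie in [0, 1]", class = "protoflux_config_error")
  }
  x <- round(state)
  b <- rbinom(length(x), size = x, prob = 0.5)
  daughter <- x / 2 + sqrt(noise) * (b - x / 2)
  pmax(setNames(daughter, SPECIES), 0)
}

#' Simulate a single protocell lineage
#'
#' Alternates [step_to_division()] and [divide_cell()], following one
#' daughter after each division (both daughters are exchangeable under
#' binomial partitioning). The run stops at `max_divisions`, when the time
#' budget is spent, when the steady-state criterion is met
#' (`stop_when_converged`), or at collapse (no division within the budget).
#'
#' @inheritParams step_to_division
#' @param init Initial counts (defaults to `p$init`).
#' @param mode,noise Division rule, as in [divide_cell()].
#' @param seed RNG seed; required in stochastic mode.
#' @param max_divisions,t_budget Budget overrides (default from `control`).
#' @param stop_when_converged Stop as soon as the convergence criterion holds.
#' @return An object of class `"protocell_lineage"`: a list with `events`
#'   (one-row-per-division tibble), `collapsed`, `timed_out`, `converged_at`,
#'   `final_state`, `last_cycle_start`, `last_interval`, and the run inputs.
#' @export
run_lineage <- function(p, init = NULL, mode = c("deterministic", "stochastic"),
                        noise = 1, seed = NULL,
                        max_divisions = NULL, t_budget = NULL,
                        control = sim_control(), stop_when_converged = TRUE) {
  mode <- match.arg(mode)
  p <- validate_params(p)
  if (is.null(init)) init <- p$init
  init <- init[SPECIES]
  if (any(!is.finite(init)) || any(init < 0)) {
    abort("initial counts must be finite and >= 0",
          class = "protoflux_config_error")
  }
  if (mode == "stochastic") {
    if (noise > 0 && is.null(seed)) {
      abort("stochastic mode needs a seed for reproducibility",
            class = "protoflux_config_error")
    }
    if (!is.null(seed)) set.seed(seed)
  }
  if (is.null(max_divisions)) max_divisions <- control$max_divisions
  if (is.null(t_budget)) t_budget <- control$t_budget

  state <- init
  t_abs <- 0
  rows <- vector("list", max_divisions)
  intervals <- numeric(0)
  n_ev <- 0L
  converged_at <- NA_integer_
  timed_out <- FALSE
  last_cycle_start <- init
  last_interval <- NA_real_

  while (n_ev < max_divisions && t_budget - t_abs > 1e-9) {
    cycle_start <- state
    st <- tryCatch(
      step_to_division(state, p, t_max = t_budget - t_abs, control = control),
      protoflux_integration_error = function(e) {
        abort(sprintf("integration error in cycle %d: %s", n_ev + 1L,
                      conditionMessage(e)),
              class = "protoflux_integration_error")
      })
    if (st$timed_out) {
      timed_out <- TRUE
      state <- st$state
      t_abs <- t_abs + st$time
      break
    }
    mother <- st$event$mother
    daughter <- divide_cell(mother, mode, noise)
    n_ev <- n_ev + 1L
    t_abs <- t_abs + st$event$time
    intervals <- c(intervals, st$event$time)
    last_cycle_start <- cycle_start
    last_interval <- st$event$time
    rows[[n_ev]] <- tibble(
      division = n_ev, t_event = t_abs, interval = st$event$time,
      !!!setNames(as.list(mother), paste0("mother_", SPECIES)),
      !!!setNames(as.list(daughter), paste0("daughter_", SPECIES)))
    state <- daughter
    if (is.na(converged_at) &&
        lineage_converged(intervals, mode, control)) {
      converged_at <- n_ev
      if (stop_when_converged) break
    }
  }

  structure(
    list(events = dplyr::bind_rows(rows[seq_len(n_ev)]),
         collapsed = n_ev == 0L,
         timed_out = timed_out,
         converged_at = converged_at,
         n_divisions = n_ev,
         final_state = state,
         last_cycle_start = last_cycle_start,
         last_interval = last_interval,
         init = init, params = p, mode = mode,
         noise = if (mode == "stochastic") noise else 0,
         seed = seed, control = control),
    class = "protocell_lineage")
}

## Convergence test on the inter-division intervals.
lineage_converged <- function(intervals, mode, control) {
  if (mode == "deterministic") {
    k <- control$k_intervals
    if (length(intervals) < k + 1) return(FALSE)
    last <- tail(intervals, k)
    (max(last) - min(last)) / mean(last) < control$rel_tol
  } else {
    m <- control$stoch_window
    if (length(intervals) < 2 * m) return(FALSE)
    a <- tail(intervals, m)
    b <- tail(head(intervals, -m), m)
    se <- sd(a) / sqrt(m)
    if (!is.finite(se) || se == 0) se <- .Machine$double.eps
    abs(mean(a) - mean(b)) < 2 * se
  }
}

#' @export
print.protocell_lineage <- function(x, ...) {
  cat(sprintf("<protocell_lineage> %d division(s), mode=%s%s\n",
              x$n_divisions, x$mode,
              if (x$collapsed) ", COLLAPSED" else ""))
  if (x$n_divisions > 0) {
    cat(sprintf("  last interval %.6g d, converged at division %s\n",
                x$last_interval,
                ifelse(is.na(x$converged_at), "NA", x$converged_at)))
  }
  invisible(x)
}

#' @export
tidy.protocell_lineage <- function(x, ...) x$events

#' Steady-state division rate and equilibrium concentrations
#'
#' Estimates the converged per-day division rate as the reciprocal of the
#' mean of the trailing inter-division intervals (the last `k_intervals` in
#' deterministic mode, the last `stoch_window` in stochastic mode), and the
#' equilibrium concentrations as the time average of the concentrations over
#' the final complete cycle (re-integrated densely). Collapsed lineages
#' return rate 0, `converged = FALSE`, and the concentrations of the final
#' (stalled) state.
#'
#' @param lineage A `"protocell_lineage"`.
#' @param control Optional [sim_control()] override for the dense
#'   re-integration (defaults to the lineage's own control).
#' @return An object of class `"protocell_steady_state"` with fields
#'   `division_rate`, `eq_concentrations`, `converged`, `collapsed`,
#'   `cycles_used`, `convergence_time`.
#' @export
steady_state <- function(lineage, control = NULL) {
  if (is.null(control)) control <- lineage$control
  p <- lineage$params
  if (lineage$collapsed) {
    eq <- tryCatch(concentrations(lineage$final_state, p),
                   protoflux_degenerate_error = function(e)
                     setNames(rep(NA_real_, 6), SPECIES))
    return(structure(list(division_rate = 0, eq_concentrations = eq,
                          converged = FALSE, collapsed = TRUE,
                          cycles_used = 0L, convergence_time = NA_real_),
                     class = "protocell_steady_state"))
  }
  k <- if (lineage$mode == "deterministic") control$k_intervals
       else control$stoch_window
  ints <- lineage$events$interval
  rate <- 1 / mean(tail(ints, min(k, length(ints))))
  ## Time-averaged concentrations over the final complete cycle.
  st <- step_to_division(lineage$last_cycle_start, p,
                         t_max = lineage$last_interval * (1 + 1e-6),
                         control = control, dense = TRUE)
  traj <- st$trajectory
  conc <- t(apply(as.matrix(traj[SPECIES]), 1, function(row)
    row / (p$vol_per_fa * row[1])))
  colnames(conc) <- SPECIES
  tt <- traj$time
  w <- diff(tt)
  eq <- apply(conc, 2, function(v)
    sum((head(v, -1) + tail(v, -1)) / 2 * w) / sum(w))
  conv_time <- if (!is.na(lineage$converged_at)) {
    lineage$events$t_event[lineage$converged_at]
  } else NA_real_
  structure(
    list(division_rate = rate, eq_concentrations = eq,
         converged = !is.na(lineage$converged_at), collapsed = FALSE,
         cycles_used = lineage$n_divisions, convergence_time = conv_time),
    class = "protocell_steady_state")
}

#' @export
print.protocell_steady_state <- function(x, ...) {
  cat(sprintf("<protocell_steady_state> rate %.6g /day (%s, %d cycles)\n",
              x$division_rate,
              if (x$collapsed) "collapsed"
              else if (x$converged) "converged" else "not converged",
              x$cycles_used))
  cat("  eq conc: ", paste(sprintf("%s=%.4g", SPECIES, x$eq_concentrations),
                           collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.protocell_steady_state <- function(x, ...) {
  tibble(species = SPECIES,
         eq_concentration = unname(x$eq_concentrations[SPECIES]))
}

#' @export
glance.protocell_steady_state <- function(x, ...) {
  tibble(division_rate = x$division_rate, converged = x$converged,
         collapsed = x$collapsed, cycles_used = x$cycles_used,
         convergence_time = x$convergence_time)
}

#' Steady-state division rate for a parameter set
#'
#' Convenience wrapper: runs a deterministic lineage from the default initial
#' state and returns the converged division rate (0 for collapsed cells).
#'
#' @inheritParams run_lineage
#' @return Divisions per day (scalar).
#' @export
division_rate <- function(p, control = sim_control(), init = NULL) {
  steady_state(run_lineage(p, init = init, control = control))$division_rate
}
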