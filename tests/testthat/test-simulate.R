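test_that("division events are located precisely at the threshold", {
  p <- preset("null")
  st <- step_to_division(p$init, p, t_max = 10)
  expect_false(st$timed_out)
  expect_lt(abs(st$event$mother[["fa"]] - p$fa_div) / p$fa_div, 1e-6)
  ## null model started on the balanced ray: fa grows as 2^t, so the first
  ## division (a 10x growth) happens at log2(10) days exactly
  expect_equal(st$event$time, log2(10), tolerance = 1e-6)
})

test_that("cycles that cannot finish report timeout, not error", {
  p <- preset("null")
  short <- step_to_division(p$init, p, t_max = 1)
  expect_true(short$timed_out)
  expect_lt(short$state[["fa"]], p$fa_div)
  ## no FeS amino acids: fixation is dead forever
  dead <- p$init; dead[["aa1"]] <- 0
  out <- step_to_division(dead, p, t_max = 50)
  expect_true(out$timed_out)
  expect_equal(out$state[["fa"]], dead[["fa"]], tolerance = 1e-8)
})

test_that("deterministic division halves counts and preserves concentrations", {
  p <- protocell_params()
  mother <- c(fa = 100, aa1 = 50, aa2 = 50, s = 10, e = 2, n = 4)
  daughter <- divide_cell(mother, "deterministic")
  expect_equal(unname(daughter), c(50, 25, 25, 5, 1, 2))
  expect_equal(concentrations(daughter, p), concentrations(mother, p),
               tolerance = 1e-12)
})

test_that("stochastic division is unbiased binomial partitioning", {
  set.seed(2024)
  mother <- c(fa = 100, aa1 = 100, aa2 = 100, s = 100, e = 100, n = 100)
  reps <- replicate(1e4, divide_cell(mother, "stochastic")[["fa"]])
  ## binomial(100, 1/2): mean 50, se of the mean over 1e4 draws = 0.05
  expect_lt(abs(mean(reps) - 50), 3 * 0.05)
  expect_true(all(reps == round(reps)))
  ## nothing to partition stays empty
  zero <- mother; zero[["n"]] <- 0
  expect_equal(divide_cell(zero, "stochastic")[["n"]], 0)
  ## same seed, same outcome
  set.seed(11); a <- divide_cell(mother, "stochastic")
  set.seed(11); b <- divide_cell(mother, "stochastic")
  expect_identical(a, b)
  ## zero noise reproduces exact halving even for odd counts
  odd <- mother; odd[["s"]] <- 13
  expect_equal(divide_cell(odd, "stochastic", noise = 0), odd / 2)
})

test_that("lineages run, record events, and are reproducible under a seed", {
  p <- protocell_params()
  lin <- run_lineage(p, control = sim_control(), stop_when_converged = FALSE,
                     max_divisions = 12)
  expect_s3_class(lin, "protocell_lineage")
  expect_gte(lin$n_divisions, 10)
  expect_true(all(diff(lin$events$t_event) > 0))
  expect_false(lin$collapsed)
  ## mother at threshold, daughter half of it (deterministic)
  expect_equal(lin$events$daughter_fa, lin$events$mother_fa / 2)

  s1 <- run_lineage(p, mode = "stochastic", noise = 1, seed = 42,
                    max_divisions = 15, stop_when_converged = FALSE)
  s2 <- run_lineage(p, mode = "stochastic", noise = 1, seed = 42,
                    max_divisions = 15, stop_when_converged = FALSE)
  expect_identical(s1$events, s2$events)
  expect_error(run_lineage(p, mode = "stochastic", noise = 1),
               class = "protoflux_config_error")
})

test_that("dead initial states give a collapsed lineage with rate zero", {
  p <- protocell_params()
  dead <- p$init; dead[["aa1"]] <- 0; dead[["aa2"]] <- 0
  lin <- run_lineage(p, init = dead, t_budget = 30)
  expect_true(lin$collapsed)
  expect_equal(nrow(lin$events), 0)
  ss <- steady_state(lin)
  expect_equal(ss$division_rate, 0)
  expect_false(ss$converged)
})

test_that("the steady-state rate is the reciprocal mean trailing interval", {
  p <- preset("null")
  ## a perfectly periodic synthetic lineage at 0.5-day intervals
  ev <- tibble::tibble(division = 1:8, t_event = cumsum(rep(0.5, 8)),
                       interval = rep(0.5, 8))
  fake <- structure(
    list(events = ev, collapsed = FALSE, timed_out = FALSE,
         converged_at = 8L, n_divisions = 8L,
         final_state = p$init, last_cycle_start = p$init,
         last_interval = 0.5, init = p$init, params = p,
         mode = "deterministic", noise = 0, seed = NULL,
         control = sim_control()),
    class = "protocell_lineage")
  expect_equal(steady_state(fake)$division_rate, 2)
})

test_that("the null model divides at the calibrated rate of one per day", {
  rate <- division_rate(preset("null"))
  expect_equal(rate, 1, tolerance = 1e-5)
  ## fixation catalysis accelerates division
  expect_gt(division_rate(protocell_params()), rate)
})

test_that("steady-state concentrations are reported per species", {
  lin <- run_lineage(protocell_params(), control = sim_control())
  ss <- steady_state(lin)
  expect_true(ss$converged)
  expect_named(ss$eq_concentrations, c("fa", "aa1", "aa2", "s", "e", "n"))
  ## the membrane concentration is pinned by the volume convention
  expect_equal(ss$eq_concentrations[["fa"]],
               1 / protocell_params()$vol_per_fa, tolerance = 1e-6)
  expect_true(all(ss$eq_concentrations > 0))
})
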