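## A lighter control keeps the unit layer quick; the acceptance suite runs
## the tight experiment_control() defaults.
quick <- sim_control(rtol = 1e-9, atol = 1e-11, rel_tol = 1e-6,
                     max_divisions = 300)

test_that("sweep_kcn covers the grid and responds monotonically", {
  single <- sweep_kcn(kcn_grid = 0, control = quick)
  expect_equal(nrow(single), 1)
  expect_equal(single$division_rate, 1, tolerance = 1e-4)

  sw <- sweep_kcn(kcn_grid = c(0, 1e3), control = quick)
  expect_equal(nrow(sw), 2)
  expect_gte(sw$division_rate[2], sw$division_rate[1])
  expect_error(sweep_kcn(kcn_grid = numeric(0)),
               class = "protoflux_config_error")
})

test_that("sweeps are pure functions of their inputs", {
  a <- sweep_kcn(kcn_grid = c(0, 100), control = quick)
  b <- sweep_kcn(kcn_grid = c(0, 100), control = quick)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("sweep_pathway reports the catalysis-free reference", {
  sw <- sweep_pathway(preset("slow_kcn"), pathway = "fa",
                      kin_grid = c(0, 0.5), control = quick)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$baseline_rate, rep(sw$division_rate[sw$kin == 0], 2))
  expect_lt(sw$division_rate[2], sw$baseline_rate[2])
  expect_error(sweep_pathway(pathway = "lipid"))
})

test_that("the kcn presets resolve and the aa pathway drives both pools", {
  sw <- sweep_pathway(kin_grid = 0, kcn = "fast", control = quick)
  expect_equal(sw$kcn, 1e4)
  expect_error(sweep_pathway(kin_grid = 0, kcn = "medium"),
               class = "protoflux_config_error")
})

test_that("heat maps have matching shapes and KCN-monotone rates", {
  hm <- heatmap_autocatalysis(knn_grid = c(0.01, 1, 100),
                              kcn_grid = c(1, 100, 1e4), control = quick)
  expect_s3_class(hm, "protocell_heatmap")
  expect_equal(dim(hm$rate), c(3, 3))
  expect_equal(dim(hm$eq_n), c(3, 3))
  expect_equal(nrow(hm$table), 9)
  ## at every autocatalysis level, stronger fixation catalysis divides faster
  for (i in 1:3) expect_true(all(diff(hm$rate[i, ]) > 0))
  expect_error(heatmap_autocatalysis(knn_grid = c(1, 2), kcn_grid = c(1, 2, 3)),
               class = "protoflux_config_error")
})

test_that("identical initial conditions give identical scan rows", {
  ic <- initial_condition_scan(scale_grid = c(1, 1), skew_grid = 1,
                               control = quick)
  expect_equal(nrow(ic), 2)
  expect_equal(ic$division_rate[1], ic$division_rate[2])
  expect_equal(ic$eq_n[1], ic$eq_n[2])
})

test_that("the segregation experiment is seeded and guards its inputs", {
  expect_error(stochastic_segregation(n_seeds = 1),
               class = "protoflux_config_error")
  st1 <- stochastic_segregation(noise_grid = c(0, 1), n_seeds = 3,
                                base_seed = 5, control = quick)
  st2 <- stochastic_segregation(noise_grid = c(0, 1), n_seeds = 3,
                                base_seed = 5, control = quick)
  expect_identical(tibble::as_tibble(st1), tibble::as_tibble(st2))
  ## the no-noise limit reproduces the deterministic values exactly
  row0 <- st1[st1$noise == 0, ]
  expect_equal(row0$mean_rate, row0$det_rate)
  expect_equal(row0$se_rate, 0)
  expect_equal(row0$mean_eq_n, row0$det_eq_n)
})

test_that("a single-value sugar-cost grid yields a single stratum", {
  sv <- sugar_cost_variant(n_c2_s_grid = 1, kin_grid = c(0, 0.99),
                           control = quick)
  expect_equal(unique(sv$n_c2_s), 1)
  expect_equal(nrow(sv), 2)
  expect_true(all(c("rel_effect", "beneficial_at_strong") %in% names(sv)))
})

test_that("growth tracks CO2 availability", {
  sc <- co2_scan(co2_grid = c(0, 0.5, 1), control = quick)
  expect_equal(sc$division_rate[1], 0)
  expect_true(sc$collapsed[1])
  expect_true(all(diff(sc$division_rate) >= 0))
  ## the unit multiplier is the plain model, computed identically
  expect_identical(sc$division_rate[3],
                   division_rate(protocell_params(), control = quick))
})
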