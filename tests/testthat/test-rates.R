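test_that("concentrations follow the fatty-acid volume convention", {
  p <- update_params(protocell_params(), vol_per_fa = 1)
  st <- c(fa = 100, aa1 = 30, aa2 = 20, s = 5, e = 2, n = 10)
  conc <- concentrations(st, p)
  expect_equal(conc[["n"]], 0.1)
  expect_equal(conc[["fa"]], 1)
  ## doubling every count leaves concentrations unchanged (volume doubles)
  expect_equal(concentrations(2 * st, p), conc)
  st0 <- st; st0[["fa"]] <- 0
  expect_error(concentrations(st0, p),
               class = "protoflux_degenerate_error")
})

test_that("the catalysis cost discounts fixation catalysis per activity", {
  p0 <- update_params(protocell_params(), alpha = 0, k_cn = 1e3,
                      k_in = c(fa = 0.9, e = 0.9))
  expect_equal(effective_fixation_catalysis(p0), 1e3)
  p1 <- update_params(protocell_params(), alpha = 1, k_cn = 1e4,
                      k_in = c(fa = 0.99))
  expect_equal(effective_fixation_catalysis(p1), 1e4 * 0.01)
  ## two distinct pathways at 0.66 overshoot strength 1 and clip to zero
  p2 <- update_params(protocell_params(), alpha = 1,
                      k_in = c(fa = 0.66, s = 0.66))
  expect_equal(effective_fixation_catalysis(p2), 0)
  ## the amino-acid pair at a shared strength is one catalytic activity
  p3 <- update_params(protocell_params(), alpha = 1, k_cn = 1e4,
                      k_in = c(aa1 = 0.66, aa2 = 0.66))
  expect_equal(effective_fixation_catalysis(p3), 1e4 * (1 - 0.66))
})

test_that("fixation flux is AA1-driven and nucleotide-boosted", {
  p <- protocell_params()
  st <- c(fa = 200, aa1 = 120, aa2 = 80, s = 20, e = 5, n = 0)
  ## without nucleotides the flux is the bare FeS-cluster term
  expect_equal(fixation_flux(st, p), p$k_fix * p$co2 * st[["aa1"]])
  ## no FeS-bearing amino acids, no fixation
  st0 <- st; st0[["aa1"]] <- 0
  expect_equal(fixation_flux(st0, p), 0)
  ## strictly increasing in KCN at fixed positive [N]
  stn <- st; stn[["n"]] <- 50
  fluxes <- vapply(c(0, 10, 1e3), function(kcn)
    fixation_flux(stn, update_params(p, k_cn = kcn)), numeric(1))
  expect_true(all(diff(fluxes) > 0))
})

test_that("branch fractions reduce to the baseline split and renormalize", {
  p <- protocell_params()
  st <- c(fa = 100, aa1 = 75, aa2 = 75, s = 13, e = 3, n = 40)
  ## no pathway catalysis: fractions are exactly the lambda values
  expect_equal(branch_fractions(st, p), p$lambda)
  ## and likewise with catalysis but no nucleotides
  pk <- set_pathway_catalysis(p, "fa", 0.99)
  st0 <- st; st0[["n"]] <- 0
  expect_equal(branch_fractions(st0, pk), p$lambda)
  ## saturated limit of a single boosted branch (frozen hand evaluation)
  stbig <- st; stbig[["n"]] <- 1e12
  expect_equal(branch_fractions(stbig, pk)[["fa"]], 0.5452687, tolerance = 1e-4)
  ## always a distribution
  for (i in 1:25) {
    f <- branch_fractions(random_state(), random_params())
    expect_equal(sum(f), 1, tolerance = 1e-12)
    expect_true(all(f >= 0))
  }
})

test_that("nucleotide synthesis needs all three substrates", {
  p <- update_params(protocell_params(), vol_per_fa = 1)
  base <- c(fa = 10, aa1 = 0, aa2 = 10, s = 10, e = 10, n = 10)
  ## energy currency is a substrate: none, no synthesis
  st <- base; st[["e"]] <- 0
  expect_equal(nucleotide_rate(st, p), 0)
  ## with unit concentrations, rate density = KNE * (1 + KNN) = 6
  expect_equal(nucleotide_rate(base, p), 2 * 1 * 1 * 1 * (1 + 2 * 1) * 10)
  ## no autocatalysis: independent of the nucleotide count
  p0 <- update_params(p, k_nn = 0)
  st2 <- base; st2[["n"]] <- 400
  expect_equal(nucleotide_rate(base, p0), nucleotide_rate(st2, p0))
})

test_that("the rhs equals the independently assembled production/consumption", {
  set.seed(421)
  p <- protocell_params()
  st <- p$init; st[["n"]] <- 5
  expect_equal(protocell_rhs(st, p), oracle_rhs(st, p), tolerance = 1e-12)
  for (i in 1:50) {
    ps <- random_params()
    sts <- random_state()
    expect_equal(protocell_rhs(sts, ps), oracle_rhs(sts, ps),
                 tolerance = 1e-12)
  }
})

test_that("raising the sugar carbon cost halves sugar output, nothing else", {
  p1 <- protocell_params()
  p2 <- update_params(p1, n_c2 = c(s = 2))
  st <- c(fa = 150, aa1 = 90, aa2 = 80, s = 20, e = 6, n = 12)
  b1 <- rate_breakdown(st, p1)
  b2 <- rate_breakdown(st, p2)
  expect_equal(b2$production_rates[["s"]], b1$production_rates[["s"]] / 2)
  expect_equal(b2$fixation_flux, b1$fixation_flux)
  expect_equal(b2$branch_fractions, b1$branch_fractions)
  others <- c("fa", "aa1", "aa2", "e")
  expect_equal(b2$production_rates[others], b1$production_rates[others])
})

test_that("a cell with no FeS amino acids and empty pools is inert", {
  p <- protocell_params()
  st <- c(fa = 500, aa1 = 0, aa2 = 0, s = 0, e = 0, n = 0)
  expect_equal(unname(protocell_rhs(st, p)), rep(0, 6))
})

test_that("carbon conservation and scale invariance hold at random states", {
  set.seed(99)
  for (i in 1:300) {
    ps <- random_params()
    st <- random_state()
    b <- rate_breakdown(st, ps)
    expect_equal(sum(b$production_rates * ps$n_c2), b$fixation_flux,
                 tolerance = 1e-9)
    expect_equal(sum(b$branch_fractions), 1, tolerance = 1e-12)
    ## degree-one homogeneity: scaling counts scales derivatives
    cc <- 3.7
    expect_equal(protocell_rhs(cc * st, ps), cc * protocell_rhs(st, ps),
                 tolerance = 1e-9)
  }
})

test_that("rates respond monotonically to nucleotides and substrates", {
  set.seed(7)
  for (i in 1:50) {
    ps <- random_params()
    st <- random_state()
    up <- st; up[["n"]] <- st[["n"]] * 2 + 1
    expect_gte(fixation_flux(up, ps), fixation_flux(st, ps))
    expect_gte(nucleotide_rate(up, ps), nucleotide_rate(st, ps))
    for (sub in c("aa2", "s", "e")) {
      more <- st; more[[sub]] <- st[[sub]] * 2 + 1
      expect_gte(nucleotide_rate(more, ps), nucleotide_rate(st, ps))
    }
  }
})
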