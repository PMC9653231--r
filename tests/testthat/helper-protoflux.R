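## Shared fixtures: everything is generated in code.

## A random valid state: positive membrane, arbitrary non-negative pools.
random_state <- function() {
  c(fa = runif(1, 10, 2000),
    aa1 = runif(1, 0, 2000),
    aa2 = runif(1, 0, 2000),
    s = runif(1, 0, 500),
    e = runif(1, 0, 100),
    n = runif(1, 0, 500))
}

## A random valid parameter set (independent of the defaults).
random_params <- function() {
  lam <- runif(5, 0.05, 1)
  lam <- lam / sum(lam)
  protocell_params(
    lambda = stats::setNames(lam, c("fa", "aa1", "aa2", "s", "e")),
    k_cn = 10^runif(1, 0, 3),
    k_in = stats::setNames(runif(5, 0, 0.99), c("fa", "aa1", "aa2", "s", "e")),
    k_nn = runif(1, 0, 5),
    k_ne = runif(1, 0, 5),
    alpha = runif(1),
    vol_per_fa = runif(1, 0.05, 2))
}

## Independent straight-line recomputation of the ODE right-hand side,
## assembled term by term without reusing the package's rate functions.
oracle_rhs <- function(state, p) {
  vol <- p$vol_per_fa * state[["fa"]]
  conc <- state / vol
  kin <- p$k_in
  cost <- kin[["fa"]] + max(kin[["aa1"]], kin[["aa2"]]) + kin[["s"]] + kin[["e"]]
  kcn_eff <- p$k_cn * max(0, 1 - p$alpha * cost)
  flux <- p$k_fix * p$co2 * conc[["aa1"]] * (1 + kcn_eff * conc[["n"]]) * vol
  sat <- conc[["n"]] / (p$k_sat + conc[["n"]])
  w <- vapply(c("fa", "aa1", "aa2", "s", "e"), function(i)
    p$lambda[[i]] * (1 + kin[[i]] * sat), numeric(1))
  frac <- w / sum(w)
  nrate <- p$k_ne * conc[["aa2"]] * conc[["s"]] * conc[["e"]] *
    (1 + p$k_nn * conc[["n"]]) * vol
  d <- c(fa = flux * frac[["fa"]] / p$n_c2[["fa"]],
         aa1 = flux * frac[["aa1"]] / p$n_c2[["aa1"]],
         aa2 = flux * frac[["aa2"]] / p$n_c2[["aa2"]] - nrate,
         s = flux * frac[["s"]] / p$n_c2[["s"]] - nrate,
         e = flux * frac[["e"]] / p$n_c2[["e"]] - nrate,
         n = nrate)
  d
}
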