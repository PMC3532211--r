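# Shared fixtures, computed lazily once per test run.
.fx <- new.env(parent = emptyenv())

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- default_params()
  .fx$params
}

# Unfished coexistence equilibrium at omega = 0 (used by several files).
fx_eq0 <- function() {
  if (is.null(.fx$eq0)) .fx$eq0 <- solve_equilibrium(fx_params(), 0, 0)
  .fx$eq0
}

# Unit-effort equilibrium at omega = 0, warm-started from the unfished one.
fx_eq1 <- function() {
  if (is.null(.fx$eq1))
    .fx$eq1 <- solve_equilibrium(fx_params(), 0, 1, init = fx_eq0()$state)
  .fx$eq1
}

# A random non-negative state on realistic scales (resources up to K,
# consumer stages up to a few g/L).
random_state <- function() {
  make_state(R_p = runif(1, 0, 1), R_s = runif(1, 0, 0.3),
             R_sh = runif(1, 0, 0.3),
             J_p = runif(1, 0, 2), LJ_p = runif(1, 0, 5),
             A_p = runif(1, 0, 5), J_s = runif(1, 0, 2),
             LJ_s = runif(1, 0, 5), A_s = runif(1, 0, 5))
}

# Independent re-computation of the per-stage rates used by the
# flow-balance bookkeeping oracle: plain arithmetic, no package rate
# functions.
oracle_species_rates <- function(sp, R_own, R_sh, R_h, E) {
  avail <- R_own + R_sh
  IR <- sp$I_max * avail / (R_h + avail)
  nu <- sp$delta * IR - sp$T_maint
  mu <- c(J = sp$mu, LJ = sp$mu + sp$f[["LJ"]] * E,
          A = sp$mu + sp$f[["A"]] * E)
  gam <- function(v, m, z) {
    if (v <= 0) return(0)
    if (abs(v - m) < 1e-12 * max(v, m)) return(-v / log(z))
    (v - m) / (1 - z^(1 - m / v))
  }
  list(IR = IR, nu = nu, mu = mu,
       gamma = c(J = gam(nu[["J"]], mu[["J"]], sp$z[["J"]]),
                 LJ = gam(nu[["LJ"]], mu[["LJ"]], sp$z[["LJ"]])))
}
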