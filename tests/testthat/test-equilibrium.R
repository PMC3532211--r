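test_that("a consumer-free system settles exactly on the resource maxima", {
  p <- fx_params()
  init <- make_state(R_p = 0.2, R_s = 0.05, R_sh = 0.02)
  eq <- solve_equilibrium(p, omega = 0.3, E = 0, init = init)
  K <- split_resource_maxima(p$resources$K_m, 0.3)
  expect_lt(max(abs(eq$state[1:3] -
                      c(p$resources$K_p, K[["K_sole"]], K[["K_shared"]]))),
            1e-8)
  expect_equal(unname(eq$state[4:9]), rep(0, 6))
  expect_true(all(eq$extinct))
})

test_that("complete resource overlap competitively excludes sole", {
  eq <- solve_equilibrium(fx_params(), omega = 1, E = 0)
  expect_true(eq$extinct[["sole"]])
  expect_false(eq$extinct[["plaice"]])
  expect_equal(unname(eq$state[7:9]), rep(0, 3))
  expect_gt(sum(eq$state[4:6]), 1)
})

test_that("polished equilibria satisfy the residual and non-negativity
           invariants and match long integration", {
  p <- fx_params()
  set.seed(11)
  cases <- data.frame(omega = runif(4, 0, 0.8), E = runif(4, 0, 30))
  for (i in seq_len(nrow(cases))) {
    eq <- solve_equilibrium(p, cases$omega[i], cases$E[i])
    expect_true(eq$converged)
    expect_lt(eq$residual, 1e-9)
    expect_true(all(eq$state >= 0))
    # oracle: endpoint of a plain long integration from the same seed state
    long <- deSolve::ode(
      y = default_init_state(p, cases$omega[i]),
      times = c(0, 1e5, 2e5, 4e5, 8e5),
      func = function(t, y, parms) list(rhs(pmax(y, 0), p, cases$E[i],
                                            cases$omega[i])),
      parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-13)
    end <- pmax(long[nrow(long), -1], 0)
    expect_lt(max(abs(end - eq$state) / (abs(eq$state) + 1e-8)), 1e-6)
  }
})

test_that("without overlap the coupled system decouples into two
           single-species systems", {
  p <- fx_params()
  full <- fx_eq0()
  only <- function(keep) {
    init <- default_init_state(p, 0)
    drop <- setdiff(c("plaice", "sole"), keep)
    idx <- list(plaice = 4:6, sole = 7:9)[[drop]]
    init[idx] <- 0
    solve_equilibrium(p, 0, 0, init = init)
  }
  sole_only <- only("sole")
  plaice_only <- only("plaice")
  expect_lt(max(abs(sole_only$state[7:9] - full$state[7:9])), 1e-8)
  expect_lt(max(abs(plaice_only$state[4:6] - full$state[4:6])), 1e-8)
  expect_lt(abs(sole_only$state[["R_s"]] - full$state[["R_s"]]), 1e-8)
})

test_that("effort sweeps warm-start, record extinction brackets and
           reproduce the single-point solve", {
  p <- fx_params()
  cv1 <- sweep_effort(p, 0, E_grid = 0)
  expect_equal(cv1$records[[1]]$state, fx_eq0()$state, tolerance = 1e-9)
  cv <- sweep_effort(p, 0, E_grid = c(0, 20, 40, 60, 80, 100))
  df <- as.data.frame(cv)
  expect_true(all(diff(df$E) > 0))
  # adult biomass of both species decreases while the species persists
  expect_true(all(diff(df$A_s) < 0))
  alive_p <- !df$extinct_plaice
  expect_true(all(diff(df$A_p[alive_p]) < 0))
  # plaice drops out between 60 and 80 under these parameters
  expect_equal(unname(cv$extinction_brackets$plaice), c(60, 80))
  expect_true(anyNA(cv$extinction_brackets$sole))
  expect_true(all(df$residual < 1e-9))
})

test_that("non-negativity is forward-invariant under integration", {
  p <- fx_params()
  set.seed(3)
  for (i in 1:5) {
    y0 <- random_state()
    sol <- deSolve::ode(y = y0, times = seq(0, 500, by = 100),
                        func = function(t, y, parms)
                          list(rhs(pmax(y, 0), p, 2, 0.5)),
                        parms = NULL, rtol = 1e-8, atol = 1e-12)
    expect_gt(min(sol[, -1]), -1e-10)
  }
})

test_that("extinction thresholds: sentinels, bisection, and agreement with
           a fine sweep", {
  p <- fx_params()
  # unfishable species: threshold at infinity
  p_nofish <- p
  p_nofish$species$sole$f[] <- 0
  expect_identical(find_extinction_effort(p_nofish, 0, "sole"), Inf)
  # species already excluded by competition: sentinel NA
  expect_true(is.na(find_extinction_effort(p, 1, "sole")))
  # bisection vs grid crossing for plaice, omega = 0
  e_star <- find_extinction_effort(p, 0, "plaice", rtol = 1e-3)
  grid <- seq(62, 78, by = 2)
  cv <- sweep_effort(p, 0, grid)
  br <- cv$extinction_brackets$plaice
  expect_gte(e_star, br[["lo"]])
  expect_lte(e_star, br[["hi"]])
  # invasion rate changes sign across the threshold
  resident <- function(E) {
    init <- default_init_state(p, 0); init[4:6] <- 0
    solve_equilibrium(p, 0, E, init = init)$state
  }
  expect_gt(invasion_rate(p, "plaice", resident(e_star * 0.98), e_star * 0.98), 0)
  expect_lt(invasion_rate(p, "plaice", resident(e_star * 1.02), e_star * 1.02), 0)
})

test_that("revenue curve analysis flags maxima, plateaus and empty curves", {
  p <- fx_params()
  # all catchabilities zero: flat zero revenue, no maxima
  p0 <- p
  p0$species$plaice$f[] <- 0
  p0$species$sole$f[] <- 0
  cv0 <- sweep_effort(p0, 0, E_grid = c(0, 1, 2, 3))
  an0 <- analyze_revenue_curve(cv0, refine = FALSE)
  expect_equal(nrow(an0$maxima), 0)
  expect_equal(an0$modality, "none")
  df0 <- as.data.frame(cv0)
  expect_true(all(df0$revenue_total == 0))
  # the flat curves equal the unfished equilibrium everywhere
  expect_equal(unlist(df0[4, names(cv0$records[[1]]$state)]),
               cv0$records[[1]]$state, tolerance = 1e-9,
               ignore_attr = TRUE)
  # a genuine sweep at omega = 0 has a single interior revenue peak
  cv <- sweep_effort(p, 0, c(0, 2, 5, 10, 15, 25, 40, 60, 80))
  an <- analyze_revenue_curve(cv, refine = TRUE)
  expect_equal(an$modality, "unimodal")
  expect_gt(an$global_max$E, 2)
  expect_lt(an$global_max$E, 40)
  expect_equal(cv$records[[1]]$metrics$revenue_total, 0)
})
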