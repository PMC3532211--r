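test_that("length-weight conversion matches the default table and inverts", {
  # adult sole: 24 cm with a = 0.0091, b = 3.077 should land on ~160.7 g
  expect_equal(weight_at_length(24, 0.0091, 3.077), 160.7,
               tolerance = 0.005)
  expect_equal(weight_at_length(0, 0.0091, 3.077), 0)
  # plaice at 10 cm, frozen from hand evaluation of 0.0089 * 10^3.0353
  expect_equal(weight_at_length(10, 0.0089, 3.0353), 9.654,
               tolerance = 1e-4)
  W <- weight_at_length(c(0.85, 5, 17), 0.0091, 3.077)
  expect_equal(length_at_weight(W, 0.0091, 3.077), c(0.85, 5, 17))
  expect_error(weight_at_length(-1, 0.0091, 3.077), "non-negative")
  expect_error(weight_at_length(1, 0, 3.077))
})

test_that("stage average weight is the logarithmic mean", {
  expect_equal(stage_average_weight(1, exp(1)), exp(1) - 1,
               tolerance = 1e-12)
  # degenerate stage: continuous limit
  expect_equal(stage_average_weight(5, 5), 5)
  # sole juvenile bounds reproduce the printed 2.3 g
  W <- weight_at_length(c(0.85, 12), 0.0091, 3.077)
  expect_equal(stage_average_weight(W[1], W[2]), 2.3, tolerance = 0.02)
  expect_error(stage_average_weight(2, 1), ">=")
  expect_error(stage_average_weight(0, 1), "positive")
})

test_that("logarithmic mean matches the quadrature oracle", {
  # biomass-weighted average of W under a 1/W density between the bounds
  set.seed(42)
  for (i in 1:100) {
    w_min <- runif(1, 1e-3, 10)
    w_max <- w_min * exp(runif(1, 0.01, 6))
    num <- integrate(function(w) rep(1, length(w)), w_min, w_max,
                     rel.tol = 1e-10)$value
    den <- integrate(function(w) 1 / w, w_min, w_max,
                     rel.tol = 1e-10)$value
    expect_equal(stage_average_weight(w_min, w_max), num / den,
                 tolerance = 1e-6)
  }
})

test_that("stage mass ratio is independent of the length-weight coefficient", {
  set.seed(7)
  for (a in runif(20, 1e-4, 1)) {
    z <- z_ratio(12, 24, 3.077)
    expect_equal(weight_at_length(12, a, 3.077) /
                   weight_at_length(24, a, 3.077), z, tolerance = 1e-12)
  }
  # printed references: sole 0.118 (LJ->A) and 0.0003 (J->LJ)
  expect_equal(z_ratio(12, 24, 3.077), 0.118, tolerance = 0.005)
  expect_equal(signif(z_ratio(0.85, 12, 3.077), 1), 3e-4)
  expect_equal(z_ratio(5, 5, 3.077), 1)
  expect_error(z_ratio(10, 5, 3.077), "L_entry")
})

test_that("annual survival and benthos conversion reproduce stated values", {
  expect_equal(annual_survival(0.001), 0.694, tolerance = 1e-3)
  expect_equal(annual_survival(0), 1)
  expect_equal(annual_survival(0.01), exp(-3.65), tolerance = 1e-12)
  expect_error(annual_survival(-0.1), "non-negative")
  # 10.1 g/m2 in a 10 cm layer over 1/3 of the bottom -> ~0.3 g/L
  expect_equal(benthos_to_volumetric(10.1, 0.1, 1 / 3), 0.303,
               tolerance = 1e-3)
  expect_equal(benthos_to_volumetric(10.1, 0.1, 1), 0.101)
  expect_equal(benthos_to_volumetric(1, 1, 1), 0.001)
  expect_error(benthos_to_volumetric(1, 0, 1), "positive")
})

test_that("default parameter build validates against printed references", {
  p <- fx_params()
  rep <- derivation_report(p)
  expect_true(all(rep$ok))
  # sole rows match at 2 % or printed precision
  sole <- rep[grepl("^sole", rep$parameter), ]
  expect_true(all(sole$rel_diff < 0.04))  # raw; all within printed precision
  expect_equal(p$resources$K_p / p$resources$K_m, 1 / 0.3,
               tolerance = 1e-12)
  expect_equal(unname(p$species$sole$W_avg[["A"]]), 160.7,
               tolerance = 0.005)
  expect_equal(unname(p$species$sole$z[["LJ"]]), 0.118, tolerance = 0.01)
  # stage ordering invariants enforced by the constructor
  expect_error(species_params("x", L = c(J = 5, LJ = 4, A = 10),
                              lw_a = 0.01, lw_b = 3,
                              I_max = c(J = .1, LJ = .1, A = .1),
                              T_maint = 1e-3, delta = 0.3, mu = 1e-3,
                              price = 1, f_LJ = 0, f_A = 0))
})

test_that("stage boundaries can be replaced with rederived weights", {
  p <- fx_params()
  q <- set_stage_boundaries(p, "sole", c(J = 1.5, LJ = 10, A = 27))
  expect_equal(unname(q$species$sole$z[["LJ"]]), (10 / 27)^3.077,
               tolerance = 1e-12)
  expect_identical(q$species$sole$I_max, p$species$sole$I_max)
  # re-applying a species' own boundaries is a no-op
  same <- set_stage_boundaries(p, "sole", p$species$sole$L)
  expect_equal(same, p)
})
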