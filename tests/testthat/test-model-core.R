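test_that("resource maximum split conserves K_m and honors the endpoints", {
  expect_equal(split_resource_maxima(0.3, 0),
               c(K_sole = 0.3, K_shared = 0))
  expect_equal(split_resource_maxima(0.3, 1),
               c(K_sole = 0, K_shared = 0.3))
  expect_equal(split_resource_maxima(0.3, 0.5),
               c(K_sole = 0.15, K_shared = 0.15))
  set.seed(1)
  for (om in runif(25)) {
    k <- split_resource_maxima(0.3, om)
    expect_identical(sum(k), 0.3)
  }
  expect_error(split_resource_maxima(0.3, 1.2), "omega")
  expect_error(split_resource_maxima(0.3, -0.1), "omega")
})

test_that("two-resource ingestion follows a saturating response with
           density-proportional split", {
  Rh <- 0.01
  expect_equal(ingestion(Rh, 0, 0.05, Rh)[["total"]], 0.05 / 2)
  expect_equal(unname(ingestion(0, 0, 0.05, Rh)),
               c(0, 0, 0))
  # hand arithmetic: 0.05 * 0.02 / 0.03
  got <- ingestion(0.01, 0.01, 0.05, 0.01)
  expect_equal(got[["total"]], 0.05 * 0.02 / 0.03, tolerance = 1e-12)
  expect_equal(got[["frac_own"]], 0.5)
  expect_equal(got[["frac_own"]] + got[["frac_shared"]], 1)
  expect_error(ingestion(-0.1, 0, 0.05, 0.01), "non-negative")
})

test_that("net production is assimilation minus maintenance, any sign", {
  expect_equal(net_production(0.0032 / 0.36, 0.36, 0.0032), 0)
  expect_equal(net_production(0, 0.36, 0.0032), -0.0032)
  expect_equal(net_production(0.02, 0.36, 0.0032), 0.004)
  expect_error(net_production(-1, 0.36, 0.0032), "non-negative")
})

test_that("maturation rate handles starvation, the zero-mortality case and
           the removable singularity", {
  expect_equal(maturation_rate(-0.001, 0.01, 0.5), 0)
  expect_equal(maturation_rate(0, 0.01, 0.5), 0)
  expect_equal(maturation_rate(0.01, 0, 0.5), 0.02)
  # frozen from direct evaluation of the closed form
  expect_equal(maturation_rate(0.01, 0.001, 0.118),
               0.009 / (1 - 0.118^0.9), tolerance = 1e-12)
  expect_equal(maturation_rate(0.01, 0.001, 0.118), 0.010540,
               tolerance = 1e-4)
  expect_error(maturation_rate(0.01, 0.001, 1.2), "z must")
  expect_error(maturation_rate(0.01, 0.001, 0), "z must")
})

test_that("maturation rate is continuous across nu = mu", {
  mu <- 0.0012
  for (z in c(0.0003, 0.048, 0.118, 0.5)) {
    lim <- -mu / log(z)
    for (eps in 10^-(3:9)) {
      expect_equal(maturation_rate(mu * (1 + eps), mu, z), lim,
                   tolerance = 1e-8 / lim + 10 * eps)
      expect_equal(maturation_rate(mu * (1 - eps), mu, z), lim,
                   tolerance = 1e-8 / lim + 10 * eps)
    }
  }
})

test_that("fishing mortality is linear in effort and catchability", {
  expect_equal(fishing_mortality(0.001455, 1), 0.001455)
  expect_equal(fishing_mortality(0.2, 0), 0)
  expect_equal(fishing_mortality(5e-5, 2), 1e-4)
  expect_error(fishing_mortality(-1, 1), "non-negative")
})

test_that("consumer-free resources at their maxima are a fixed point, and
           regrowth drives an empty system", {
  p <- fx_params()
  for (om in c(0, 0.4, 1)) {
    K <- split_resource_maxima(p$resources$K_m, om)
    s <- make_state(R_p = p$resources$K_p, R_s = K[["K_sole"]],
                    R_sh = K[["K_shared"]])
    expect_equal(unname(rhs(s, p, E = 2, omega = om)), rep(0, 9))
  }
  d0 <- rhs(make_state(), p, E = 0, omega = 0.25)
  K <- split_resource_maxima(p$resources$K_m, 0.25)
  expect_equal(unname(d0[1:3]),
               p$resources$r * c(p$resources$K_p, K[["K_sole"]],
                                 K[["K_shared"]]))
  expect_equal(unname(d0[4:9]), rep(0, 6))
  expect_error(rhs(make_state() - 1, p, 0), "non-negative")
})

test_that("every biomass flow in the derivative is accounted for
           (bookkeeping oracle)", {
  p <- fx_params()
  set.seed(99)
  for (i in 1:25) {
    s <- random_state()
    E <- runif(1, 0, 10)
    om <- runif(1)
    d <- rhs(s, p, E, omega = om)
    Rh <- p$resources$R_h
    K <- c(p$resources$K_p, (1 - om) * p$resources$K_m,
           om * p$resources$K_m)
    for (k in 1:2) {
      nm <- c("plaice", "sole")[k]
      sp <- p$species[[nm]]
      B <- s[3 + (k - 1) * 3 + 1:3]
      R_own <- s[[k]]
      rt <- oracle_species_rates(sp, R_own, s[[3]], Rh, E)
      # species biomass balance: growth - mortality - catch, transfers cancel
      gain <- sum(rt$nu * B) - sum(rt$mu * B)
      expect_equal(sum(d[3 + (k - 1) * 3 + 1:3]), gain, tolerance = 1e-12)
      # exclusive resource balance: regrowth minus this species' grazing
      graze_own <- sum(sp$I_max * B) * R_own / (Rh + R_own + s[[3]])
      expect_equal(d[[k]], p$resources$r * (K[k] - R_own) - graze_own,
                   tolerance = 1e-12)
      # grazing on both pools sums to total ingestion
      graze_sh <- sum(sp$I_max * B) * s[[3]] / (Rh + R_own + s[[3]])
      expect_equal(graze_own + graze_sh, sum(rt$IR * B), tolerance = 1e-12)
    }
  }
})

test_that("fishery metrics compute landings, discards and revenue flows", {
  p <- fx_params()
  s <- make_state(R_p = 0.5, R_s = 0.2, J_p = 0.1, LJ_p = 1, A_p = 2,
                  J_s = 0.1, LJ_s = 1, A_s = 1)
  m0 <- fishery_metrics(s, p, E = 0)
  expect_equal(unname(m0$landings), c(0, 0))
  expect_equal(m0$revenue_total, 0)
  expect_true(all(is.na(m0$discard_ratio)))  # no landings: flagged
  # hand arithmetic: 10.06 EUR/kg * (1 g/L / 1000) * 0.001455 * 1
  m1 <- fishery_metrics(s, p, E = 1)
  expect_equal(m1$revenue[["sole"]], 1.4637e-5, tolerance = 1e-4)
  expect_equal(m1$landings[["plaice"]], 0.001272 * 2)
  expect_equal(m1$discard_ratio[["plaice"]],
               (5e-5 * 1) / (0.001272 * 2))
  s2 <- s; s2[["LJ_p"]] <- 0
  expect_equal(fishery_metrics(s2, p, 1)$discard_ratio[["plaice"]], 0)
  expect_error(fishery_metrics(s, p, -1), "non-negative")
})
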