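test_that("growth rate is the log-linear slope and flags degenerate fits", {
  ms <- exp_biomass_measurements(mu = 0.288, X0 = 1.6, days = c(0, 2, 4))
  gr <- estimate_growth_rate(ms, day = 4)
  expect_equal(gr$mu, 0.288, tolerance = 1e-12)
  expect_equal(gr$fit_r2, 1, tolerance = 1e-9)

  flat <- measurement_set(c(0, 2, 4), rep(2.5, 3))
  gf <- estimate_growth_rate(flat, day = 4)
  expect_equal(gf$mu, 0)
  expect_true(is.na(gf$fit_r2))

  expect_error(estimate_growth_rate(ms, day = 4, window = c(4)), "at least 2")
  expect_error(estimate_growth_rate(ms, day = 3), "not a measured timepoint")
  expect_error(measurement_set(c(0, 2), c(1, -1)), "positive")
})

test_that("noisy growth series recovers mu within 10%", {
  set.seed(123)
  mu <- 0.288
  days <- 0:6
  for (k in 1:10) {
    x <- 1.6 * exp(mu * days) * rlnorm(length(days), 0, sqrt(log(1 + 0.05^2)))
    gr <- estimate_growth_rate(measurement_set(days, x), day = 6)
    expect_lt(abs(gr$mu - mu) / mu, 0.10)
  }
})

test_that("accumulation flux converts units and is bilinear", {
  gr <- structure(list(mu = 0.2), class = "vf_growth")
  expect_equal(accumulation_flux(0, "mmol_per_gDW", growth = gr), 0)
  expect_equal(accumulation_flux(0.1, "mmol_per_gDW", growth = gr), 0.02)
  gr288 <- structure(list(mu = 0.288), class = "vf_growth")
  expect_equal(accumulation_flux(4.93, "mg_per_gDW", 493, gr288),
               4.93 / 493 * 0.288, tolerance = 1e-15)
  expect_equal(accumulation_flux(4.93, "mg_per_gDW", 493, gr288), 0.00288,
               tolerance = 1e-12)
  expect_error(accumulation_flux(1, "mg_per_gDW", growth = gr), "molar_mass")

  set.seed(5)
  for (k in 1:20) {
    c0 <- runif(1, 0, 10); mu <- runif(1, 0.05, 0.5); a <- runif(1, 0.1, 3)
    expect_equal(accumulation_flux(a * c0, "mmol_per_gDW", growth = mu),
                 a * accumulation_flux(c0, "mmol_per_gDW", growth = mu),
                 tolerance = 1e-12)
    expect_equal(accumulation_flux(c0, "mmol_per_gDW", growth = a * mu),
                 a * accumulation_flux(c0, "mmol_per_gDW", growth = mu),
                 tolerance = 1e-12)
  }
})

test_that("assemble_problem builds the documented bound structure", {
  net <- build_gt3_network()
  ids <- reaction_ids(net)
  comp <- data.frame(component_id = c("Vac-mal", "Vac-glc"), day = 4,
                     value = c(0.5, 0.3), unit = "mmol_per_gDW",
                     molar_mass = NA_real_, stringsAsFactors = FALSE)
  ms <- exp_biomass_measurements(
    components = comp, capacities = c(Vpk = 3, Vpfp = 3, Vmdh = 2.5),
    atp_synthesis_rate = 3.54, condition = "N")
  pr <- assemble_problem(net, ms, day = 4)
  mu <- attr(pr, "meta")$growth$mu

  j <- function(id) match(id, pr$reaction_ids)
  # irreversible uncapacitated: [0, Inf)
  expect_equal(pr$lb[j("Vhk")], 0)
  expect_equal(pr$ub[j("Vhk")], Inf)
  # reversible uncapacitated: (-Inf, Inf)
  expect_equal(pr$lb[j("Vpgi")], -Inf)
  # capacity on irreversible: [0, cap]
  expect_equal(pr$ub[j("Vpk")], 3)
  expect_equal(pr$lb[j("Vpk")], 0)
  # capacity on reversible: [-cap, cap]
  expect_equal(pr$lb[j("Vpfp")], -3)
  expect_equal(pr$ub[j("Vpfp")], 3)
  expect_equal(pr$lb[j("Vmdh")], -2.5)
  # measured exchanges fixed bit-equal
  expect_identical(pr$lb[j("Vac-mal")], pr$ub[j("Vac-mal")])
  expect_identical(pr$lb[j("Vac-mal")], 0.5 * mu)
  # exactly one respiration coupling row summing Vnrj1 + Vnrj2
  expect_equal(nrow(pr$couplings$A), 1L)
  expect_equal(pr$couplings$lower, 3.54)
  expect_equal(pr$couplings$upper, 3.54)
  expect_equal(which(pr$couplings$A[1, ] != 0), c(j("Vnrj1"), j("Vnrj2")))

  # interval mode widens to mean +/- se
  pr2 <- assemble_problem(net, ms, day = 4, respiration_mode = "interval",
                          respiration_se = 0.18)
  expect_equal(pr2$couplings$lower, 3.54 - 0.18)
  expect_equal(pr2$couplings$upper, 3.54 + 0.18)

  # low-N respiration value
  ms3 <- exp_biomass_measurements(components = comp, atp_synthesis_rate = 2.86,
                                  condition = "N-")
  expect_equal(assemble_problem(net, ms3, day = 4)$couplings$lower, 2.86)

  # unmatched components are listed
  bad <- comp; bad$component_id[1] <- "nonesuch"
  msb <- exp_biomass_measurements(components = bad)
  expect_error(assemble_problem(net, msb, day = 4), "nonesuch")

  # component_map redirects component ids to reactions
  mapped <- comp; mapped$component_id <- c("malate", "glucose_pool")
  msm <- exp_biomass_measurements(components = mapped)
  prm <- assemble_problem(net, msm, day = 4,
                          component_map = c(malate = "Vac-mal",
                                            glucose_pool = "Vac-glc"))
  expect_equal(prm$lb[j("Vac-mal")], 0.5 * attr(prm, "meta")$growth$mu)
})

test_that("assembly is independent of measurement row order", {
  net <- build_gt3_network()
  comp <- data.frame(component_id = c("Vac-mal", "Vac-glc", "Vac-suc"),
                     day = 4, value = c(0.5, 0.3, 0.1),
                     unit = "mmol_per_gDW", molar_mass = NA_real_)
  ms1 <- exp_biomass_measurements(components = comp, atp_synthesis_rate = 3.54)
  ms2 <- exp_biomass_measurements(components = comp[c(3, 1, 2), ],
                                  atp_synthesis_rate = 3.54)
  p1 <- assemble_problem(net, ms1, 4)
  p2 <- assemble_problem(net, ms2, 4)
  expect_identical(p1$lb, p2$lb)
  expect_identical(p1$ub, p2$ub)
  expect_identical(p1$couplings$lower, p2$couplings$lower)
  # and idempotent: assembling twice gives identical problems
  p3 <- assemble_problem(net, ms1, 4)
  expect_identical(p1$lb, p3$lb)
  expect_identical(p1$ub, p3$ub)
})

test_that("biomass coverage sums component masses", {
  ms81 <- exp_biomass_measurements(components = coverage_components(0.81))
  expect_equal(biomass_coverage(ms81, 4), 81, tolerance = 1e-12)
  ms0 <- exp_biomass_measurements()
  expect_equal(biomass_coverage(ms0, 4), 0)
  # molar-based components convert through the molar mass
  comp <- data.frame(component_id = "c1", day = 4, value = 2,
                     unit = "mmol_per_gDW", molar_mass = 150)
  msm <- exp_biomass_measurements(components = comp)
  expect_equal(biomass_coverage(msm, 4), 100 * 2 * 150 / 1000)
})

test_that("the O2-to-ATP helper applies the documented conversion", {
  # 100 nmol O2/min/gFW, 10 gFW/gDW, P/O = 2.5:
  # 100*1440*1e-6 mmol O2/day/gFW * 10 * 2 O/O2 * 2.5
  expect_equal(atp_rate_from_o2(100, 10, 2.5), 100 * 1440 * 1e-6 * 10 * 5)
  expect_error(atp_rate_from_o2(-1, 10, 2.5), "o2_rate")
})
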