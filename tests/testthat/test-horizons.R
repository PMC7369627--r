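test_that("OPD interpolates the 1 uM crossing of the terminal run", {
  p <- solute_profile("O2", c(0, 0.5, 1.0, 1.5, 2.0),
                      c(300, 200, 100, 0.5, 0.2))
  opd <- oxygen_penetration_depth(p)
  # hand oracle: crossing between (1.0, 100) and (1.5, 0.5)
  expect_equal(as.numeric(opd), 1.0 + (1 - 100) / (0.5 - 100) * 0.5)
  expect_gt(as.numeric(opd), 1.0)
  expect_lt(as.numeric(opd), 1.5)
})

test_that("a sub-threshold dip with recovery does not set the OPD (steadily rule)", {
  spiky <- solute_profile("O2", seq(0, 3, 0.5),
                          c(300, 0.5, 150, 80, 0.4, 0.3, 0.2))
  opd <- oxygen_penetration_depth(spiky)
  # the dip at 0.5 mm is ignored; the terminal run starts at 2.0 mm
  expect_gt(as.numeric(opd), 1.5)
  expect_lt(as.numeric(opd), 2.0)
})

test_that("OPD edge cases: no crossing, anoxic surface, overlying-only error", {
  high <- solute_profile("O2", seq(0, 2, 0.5), c(300, 250, 200, 150, 50))
  expect_true(is.na(oxygen_penetration_depth(high)))
  expect_equal(attr(oxygen_penetration_depth(high), "flag"),
               "no penetration limit reached")

  anoxic <- solute_profile("O2", seq(0, 2, 0.5), c(0.5, 0.4, 0.3, 0.2, 0.1))
  opd <- oxygen_penetration_depth(anoxic)
  expect_equal(as.numeric(opd), 0)
  expect_match(attr(opd, "flag"), "first point")

  overlying <- solute_profile("O2", c(-0.3, -0.2, -0.1), c(300, 300, 300))
  expect_error(oxygen_penetration_depth(overlying), "interface")
})

test_that("sulfide horizon mirrors the OPD rule", {
  p <- solute_profile("H2S", 0:5, c(0, 0, 0.5, 2, 5, 9))
  hz <- sulfide_horizon(p)
  # hand oracle: crossing between (2, 0.5) and (3, 2)
  expect_equal(as.numeric(hz), 2 + (1 - 0.5) / (2 - 0.5))
  expect_gt(as.numeric(hz), 2); expect_lt(as.numeric(hz), 3)

  zero <- solute_profile("H2S", 0:5, rep(0, 6))
  expect_true(is.na(sulfide_horizon(zero)))

  euxinic <- solute_profile("H2S", 0:5, c(5, 8, 12, 20, 30, 40))
  hz2 <- sulfide_horizon(euxinic)
  expect_equal(as.numeric(hz2), 0)
  expect_equal(attr(hz2, "flag"), "euxinic surface")
})

test_that("noise-free generator round trip detects within one grid step", {
  ctx <- make_ctx()
  params <- make_params()
  cfg <- profile_sim_config(surface_o2 = 310, true_opd = 1.6,
                            true_horizon = 3.8, deep_sulfide_gradient = 60)
  o2 <- simulate_o2_profile(cfg, ctx)
  expect_lt(abs(as.numeric(oxygen_penetration_depth(o2)) - 1.6), 0.1)
  ss <- simulate_sulfide_profiles(cfg, ctx, params)
  sp <- speciate_profile(ss$h2s, ss$ph, params)
  expect_lt(abs(as.numeric(sulfide_horizon(sp)) - 3.8), 0.25)
})

test_that("OPD is non-increasing under multiplicative scale-down of the profile", {
  ctx <- make_ctx()
  set.seed(42)
  for (i in 1:10) {
    cfg <- profile_sim_config(surface_o2 = runif(1, 280, 330),
                              true_opd = runif(1, 0.8, 2.3),
                              true_horizon = 3.8)
    o2 <- simulate_o2_profile(cfg, ctx)
    opd1 <- as.numeric(oxygen_penetration_depth(o2))
    scaled <- solute_profile("O2", o2$depths, o2$values * 0.3)
    opd2 <- as.numeric(oxygen_penetration_depth(scaled))
    expect_lte(opd2, opd1 + 1e-12)
  }
})

test_that("detection is idempotent on the profile truncated at the detected depth", {
  set.seed(7)
  for (i in 1:10) {
    cfg <- profile_sim_config(surface_o2 = runif(1, 280, 330),
                              true_opd = runif(1, 0.8, 2.3),
                              true_horizon = 3.8)
    o2 <- simulate_o2_profile(cfg, make_ctx())
    opd <- as.numeric(oxygen_penetration_depth(o2))
    # keep the detected crossing (reading = threshold) and everything below
    keep <- o2$depths > opd
    trunc <- solute_profile("O2", c(opd, o2$depths[keep]),
                            c(1, o2$values[keep]))
    expect_equal(as.numeric(oxygen_penetration_depth(trunc)), opd,
                 tolerance = 1e-12)
  }
})

test_that("oxidized_volume_increase matches the day-6 treatment contrast", {
  expect_equal(round(oxidized_volume_increase(6.4, 3.8)), 68)
  expect_equal(oxidized_volume_increase(4.2, 4.2), 0)
  expect_equal(oxidized_volume_increase(2.0, 4.0), -50)
  expect_error(oxidized_volume_increase(2.0, 0), "undefined|> 0")
})

test_that("suboxic width is the horizon-OPD separation with overlap flagged", {
  expect_equal(as.numeric(suboxic_width(1.6, 6.4)), 4.8)
  expect_equal(as.numeric(suboxic_width(2.0, 2.0)), 0)
  over <- suboxic_width(3.0, 2.0)
  expect_equal(as.numeric(over), -1.0)
  expect_match(attr(over, "flag"), "verlapping")
  expect_true(is.na(suboxic_width(NA, 3)))
})

test_that("horizon_result assembles zone geometry with flags", {
  ctx <- make_ctx()
  cfg <- profile_sim_config(true_opd = 1.6, true_horizon = 6.4,
                            deep_sulfide_gradient = 40)
  o2 <- simulate_o2_profile(cfg, ctx)
  ss <- simulate_sulfide_profiles(cfg, ctx, make_params())
  hr <- horizon_result(o2, speciate_profile(ss$h2s, ss$ph, make_params()))
  expect_s3_class(hr, "horizon_result")
  expect_gte(hr$sulfide_horizon, hr$opd)
  expect_equal(hr$suboxic_width, hr$sulfide_horizon - hr$opd)
  expect_equal(hr$persistence_rule, "terminal run")
})
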