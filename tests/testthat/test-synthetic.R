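test_that("O2 generator satisfies its boundary conditions noise-free", {
  cfg <- profile_sim_config(surface_o2 = 310, true_opd = 1.6,
                            true_horizon = 3.8)
  p <- simulate_o2_profile(cfg, make_ctx())
  at <- function(z) p$values[which.min(abs(p$depths - z))]
  expect_equal(at(0), 310)          # interface at surface concentration
  expect_equal(at(1.6), 0)          # zero touch at the true OPD
  expect_true(all(p$values[p$depths < 0] == 310))  # overlying water
  expect_true(all(p$values[p$depths > 1.6] == 0))
  expect_equal(p$resolution, 100)
})

test_that("generators are deterministic given a seed", {
  cfg <- profile_sim_config(noise_sd_o2 = 2, noise_sd_h2s = 2,
                            noise_sd_ph = 0.02)
  ctx <- make_ctx()
  p1 <- simulate_o2_profile(cfg, ctx, seed = 99)
  p2 <- simulate_o2_profile(cfg, ctx, seed = 99)
  expect_identical(p1$values, p2$values)
  s1 <- simulate_sulfide_profiles(cfg, ctx, make_params(), seed = 99)
  s2 <- simulate_sulfide_profiles(cfg, ctx, make_params(), seed = 99)
  expect_identical(s1$h2s$values, s2$h2s$values)
  expect_identical(s1$ph$values, s2$ph$values)
})

test_that("the e-SOx pH signature peaks exactly where configured", {
  cfg <- profile_sim_config(ph_surface = 7.8, ph_deep = 6.5,
                            esox_peak = c(8.3, 0.75))
  ss <- simulate_sulfide_profiles(cfg, make_ctx(), make_params())
  i <- which.max(ss$ph$values)
  expect_equal(ss$ph$depths[i], 0.75)
  expect_equal(ss$ph$values[i], 8.3)
})

test_that("zero deep gradient gives no sulfide and no horizon", {
  cfg <- profile_sim_config(deep_sulfide_gradient = 0)
  ss <- simulate_sulfide_profiles(cfg, make_ctx(), make_params())
  expect_true(all(ss$h2s$values == 0))
  sp <- speciate_profile(ss$h2s, ss$ph, make_params())
  expect_true(is.na(sulfide_horizon(sp)))
})

test_that("truth record is noise-invariant and flux truths carry the sign convention", {
  ctx <- make_ctx()
  dm_o2 <- diffusivity_model("O2", molecular_diffusivity("O2", 8), 0.9, 2e-5)
  dm_h2s <- diffusivity_model("H2S", molecular_diffusivity("H2S", 8), 0.9,
                              2e-5)
  quiet <- profile_sim_config(true_opd = 1.5, true_horizon = 4,
                              deep_sulfide_gradient = 30)
  loud <- profile_sim_config(true_opd = 1.5, true_horizon = 4,
                             deep_sulfide_gradient = 30, noise_sd_o2 = 5,
                             noise_sd_h2s = 5, noise_sd_ph = 0.1)
  t1 <- synthetic_truth(quiet, ctx, dm_o2, dm_h2s)
  t2 <- synthetic_truth(loud, ctx, dm_o2, dm_h2s)
  expect_equal(t1$true_j_o2, t2$true_j_o2)
  expect_equal(t1$true_j_h2s, t2$true_j_h2s)
  expect_lt(t1$true_j_o2, 0)
  expect_gt(t1$true_j_h2s, 0)
  # closed forms behind the truth fluxes
  expect_equal(t1$true_j_o2,
               0.9 * (dm_o2$d_s + dm_o2$d_b) * (-2 * quiet$surface_o2 / 1.5) * 1e3)
  expect_equal(t1$true_j_h2s, 0.9 * (dm_h2s$d_s + dm_h2s$d_b) * 30 * 1e3)
})

test_that("truth fluxes agree with the fluxes module on noise-free output", {
  ctx <- make_ctx(phi = 0.87, abundance = 1200)
  params <- make_params()
  db <- as.numeric(db_for_abundance(
    fit_biodiffusivity(db_reference_synthetic()), 1200))
  dm_o2 <- diffusivity_model("O2", molecular_diffusivity("O2", 8), 0.87, db)
  dm_h2s <- diffusivity_model("H2S", molecular_diffusivity("H2S", 8),
                              0.87, db)
  cfg <- profile_sim_config(surface_o2 = 320, true_opd = 2.0,
                            true_horizon = 5.0, deep_sulfide_gradient = 25)
  tr <- synthetic_truth(cfg, ctx, dm_o2, dm_h2s)

  o2 <- simulate_o2_profile(cfg, ctx)
  opd <- as.numeric(oxygen_penetration_depth(o2))
  gf <- fit_gradient(o2, o2_fit_window(opd))
  j_corr <- diffusive_flux(ctx, dm_o2, gf)$flux /
    o2_window_factor(gf$window_mean_depth, cfg$true_opd)
  expect_lt(abs(j_corr / tr$true_j_o2 - 1), 0.02)

  ss <- simulate_sulfide_profiles(cfg, ctx, params)
  sp <- speciate_profile(ss$h2s, ss$ph, params)
  hz <- as.numeric(sulfide_horizon(sp))
  jh <- diffusive_flux(ctx, dm_h2s, fit_gradient(sp, h2s_fit_window(hz)))$flux
  expect_lt(abs(jh / tr$true_j_h2s - 1), 0.02)
})

test_that("all generated profiles satisfy the profile invariants", {
  sim <- simulate_experiment(experiment_design(cores_per_treatment = 1,
                                               replicates = 1), seed = 3)
  for (p in sim$experiment$profiles)
    expect_s3_class(validate_solute_profile(p), "solute_profile")
})

test_that("the experiment factory enumerates the design", {
  sim <- simulate_experiment(seed = 2)
  expect_equal(sim$experiment$design$n_profiles, 324)
  expect_equal(nrow(sim$truth), 36)
  expect_equal(sim$experiment$design$cores, 12)

  tiny <- simulate_experiment(
    experiment_design(treatments = "control", cores_per_treatment = 1,
                      timepoints = 1, replicates = 1,
                      abundance_mean = 128, abundance_sd = 0,
                      opd_mean = 1.5, horizon_mean = 4,
                      sulfide_flux_target = 5), seed = 2)
  expect_equal(tiny$experiment$design$n_profiles, 3)  # one per solute

  expect_error(experiment_design(cores_per_treatment = 0), "positive")
  expect_error(experiment_design(bogus = 1), "unknown design element")
})

test_that("the same master seed reproduces the experiment byte for byte", {
  s1 <- simulate_experiment(seed = 17)
  s2 <- simulate_experiment(seed = 17)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("a written experiment reads back identically", {
  sim <- simulate_experiment(experiment_design(cores_per_treatment = 1,
                                               timepoints = 1), seed = 5)
  dir <- tempfile()
  write_experiment(sim, dir)
  back <- read_experiment(dir)
  expect_equal(back$experiment$design$n_profiles,
               sim$experiment$design$n_profiles)
  # values survive the text round trip exactly
  key <- function(p) sprintf("%s_%s_%s_%s", p$core_id, p$solute,
                             p$timepoint_day, p$profile_replicate)
  orig <- setNames(sim$experiment$profiles,
                   vapply(sim$experiment$profiles, key, character(1)))
  for (p in back$experiment$profiles) {
    expect_identical(p$values, orig[[key(p)]]$values)
    expect_identical(p$depths, orig[[key(p)]]$depths)
  }
  expect_equal(back$truth$true_j_o2, sim$truth$true_j_o2)
})
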