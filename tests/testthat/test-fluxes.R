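test_that("fit_gradient converts uM/mm slopes to mmol m-4 exactly", {
  z <- seq(0, 1, 0.1)
  p <- solute_profile("O2", z, 300 - 200 * z)
  gf <- fit_gradient(p, c(0, 1))
  expect_equal(gf$slope_uM_mm, -200, tolerance = 1e-12)
  expect_equal(gf$slope, -2.0e5, tolerance = 1e-7)
  expect_equal(gf$r2, 1)
  expect_equal(gf$n_points, 11)

  flat <- solute_profile("O2", z, rep(100, 11))
  gf0 <- fit_gradient(flat, c(0, 1))
  expect_equal(gf0$slope, 0)
  expect_true(is.na(gf0$r2))
})

test_that("fit_gradient equals the closed-form least-squares oracle on noisy data", {
  set.seed(13)
  z <- seq(0, 2, 0.1)
  y <- 250 - 120 * z + rnorm(length(z), 0, 4)
  p <- solute_profile("O2", z, y)
  gf <- fit_gradient(p, c(0, 2))
  oracle <- ols_oracle(z, y)
  expect_equal(gf$slope_uM_mm, unname(oracle["slope"]), tolerance = 1e-12)
  expect_equal(gf$intercept, unname(oracle["intercept"]), tolerance = 1e-12)
})

test_that("fit_gradient window selection and failure modes", {
  z <- seq(0, 2, 0.25)
  p <- solute_profile("H2S", z, 10 * z)
  gf <- fit_gradient(p, c(0.5, 1.5))
  expect_equal(unname(gf$window), c(0.5, 1.5))
  expect_equal(gf$n_points, 5)
  expect_error(fit_gradient(p, c(1.05, 1.15)), "fewer than 2")
  # low-r2 fits are flagged, not rejected
  set.seed(4)
  noisy <- solute_profile("H2S", z, rnorm(length(z), 5, 3))
  expect_true(fit_gradient(noisy, c(0, 2))$low_r2)
})

test_that("diffusive_flux applies Fick's first law with the sign convention", {
  ctx <- core_context("C1", "t", 0.5, 8, 10, 0)
  # phi (Ds + Db) = 1.0e-4 m2/d via Db chosen to complement Ds
  dm <- diffusivity_model("O2", 1.0e-4 / 0.25, 0.5, 0)
  expect_equal(dm$d_s, 1.0e-4)
  gf <- structure(list(slope = -1.0e5, slope_uM_mm = -100,
                       intercept = 300, window = c(0, 1),
                       window_mean_depth = 0.5, n_points = 5, r2 = 1,
                       low_r2 = FALSE), class = "gradient_fit")
  fx <- diffusive_flux(ctx, dm, gf)
  expect_equal(fx$flux, -5.0)
  # |J| = phi (Ds + Db) |slope| to machine precision
  expect_equal(abs(fx$flux),
               ctx$porosity * (dm$d_s + dm$d_b) * abs(gf$slope))
  gf$slope <- 0
  expect_equal(diffusive_flux(ctx, dm, gf)$flux, 0)
  # convention switch drops the outer porosity factor
  gf$slope <- -1.0e5
  expect_equal(diffusive_flux(ctx, dm, gf, "no_outer_porosity")$flux, -10.0)
})

test_that("flux sign follows the profile direction and offsets do not matter", {
  ctx <- make_ctx()
  dm <- diffusivity_model("O2", molecular_diffusivity("O2", 8),
                          ctx$porosity, 2e-5)
  z <- seq(0, 1, 0.1)
  dec <- solute_profile("O2", z, 300 - 150 * z)
  inc <- solute_profile("H2S", z, 5 + 40 * z)
  expect_lt(diffusive_flux(ctx, dm, fit_gradient(dec, c(0, 1)))$flux, 0)
  expect_gt(diffusive_flux(ctx, dm, fit_gradient(inc, c(0, 1)))$flux, 0)
  # uniform concentration offset leaves the flux unchanged
  shifted <- solute_profile("O2", z, 300 - 150 * z + 75)
  expect_equal(diffusive_flux(ctx, dm, fit_gradient(shifted, c(0, 1)))$flux,
               diffusive_flux(ctx, dm, fit_gradient(dec, c(0, 1)))$flux,
               tolerance = 1e-12)
})

test_that("|J| increases strictly with Db at fixed gradient", {
  ctx <- make_ctx()
  z <- seq(0, 1, 0.1)
  gf <- fit_gradient(solute_profile("O2", z, 300 - 150 * z), c(0, 1))
  dbs <- c(0, 1e-5, 5e-5, 1.2e-4)
  js <- vapply(dbs, function(db) abs(diffusive_flux(
    ctx, diffusivity_model("O2", 1.2e-4, ctx$porosity, db), gf)$flux),
    numeric(1))
  expect_true(all(diff(js) > 0))
})

test_that("synthetic sulfide flux is recovered within 2% noise-free", {
  ctx <- make_ctx(phi = 0.88, abundance = 800)
  params <- make_params()
  db <- as.numeric(db_for_abundance(
    fit_biodiffusivity(db_reference_synthetic()), 800))
  dm <- diffusivity_model("H2S", molecular_diffusivity("H2S", 8), 0.88, db)
  g <- 4.4 / (0.88 * (dm$d_s + dm$d_b) * 1e3)
  cfg <- profile_sim_config(true_opd = 1.6, true_horizon = 3.8,
                            deep_sulfide_gradient = g)
  ss <- simulate_sulfide_profiles(cfg, ctx, params)
  sp <- speciate_profile(ss$h2s, ss$ph, params)
  hz <- as.numeric(sulfide_horizon(sp))
  fx <- diffusive_flux(ctx, dm, fit_gradient(sp, h2s_fit_window(hz)))
  expect_lt(abs(fx$flux / 4.4 - 1), 0.02)
})
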