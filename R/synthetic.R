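#' Configuration for one synthetic profile set
#'
#' Describes the steady-state generating shapes of one core at one time
#' point. O2 follows the constant-volumetric-consumption solution
#' `C(z) = surface_o2 * (1 - z/true_opd)^2` (zero value and zero gradient
#' at the penetration depth); total sulfide is zero down to `true_horizon`
#' and rises linearly below it at `deep_sulfide_gradient`; pH declines
#' exponentially from `ph_surface` toward `ph_deep` with an optional
#' localized oxic-zone maximum (the electrogenic sulfur oxidation
#' signature). Sensor noise is i.i.d. Gaussian per point.
#'
#' @param surface_o2 interface O2 (uM).
#' @param true_opd depth where the O2 shape reaches zero (mm).
#' @param true_horizon depth where sulfide first appears (mm).
#' @param deep_sulfide_gradient slope of total sulfide below the horizon
#'   (uM per mm), >= 0.
#' @param ph_surface,ph_deep asymptotic pH at the interface and at depth.
#' @param ph_scale e-folding depth of the pH decline (mm).
#' @param esox_peak optional `c(peak_ph, peak_depth_mm)`: pH maximum of the
#'   electrogenic sulfur oxidation signature, e.g. `c(8.3, 0.75)`.
#' @param esox_width Gaussian width of the pH maximum (mm).
#' @param noise_sd_o2,noise_sd_h2s sensor noise standard deviation (uM).
#' @param noise_sd_ph sensor noise standard deviation (pH units).
#' @param grid_o2,grid_chem vertical step of the O2 and of the pH/H2S
#'   sensors (micrometres).
#' @param overlying length of overlying-water record (mm above the
#'   interface).
#' @param o2_bottom,profile_bottom deepest O2 and pH/H2S measurement (mm).
#' @return an object of class `profile_sim_config`.
#' @export
profile_sim_config <- function(surface_o2 = 310, true_opd = 1.6,
                               true_horizon = 3.8,
                               deep_sulfide_gradient = 60,
                               ph_surface = 7.8, ph_deep = 6.4,
                               ph_scale = 3, esox_peak = NULL,
                               esox_width = 0.3,
                               noise_sd_o2 = 0, noise_sd_h2s = 0,
                               noise_sd_ph = 0,
                               grid_o2 = 100, grid_chem = 250,
                               overlying = 0.5, o2_bottom = 4,
                               profile_bottom = 10) {
  if (!(0 < true_opd && true_opd < true_horizon &&
        true_horizon < profile_bottom))
    stop("need 0 < true_opd < true_horizon < profile_bottom", call. = FALSE)
  if (any(c(noise_sd_o2, noise_sd_h2s, noise_sd_ph) < 0))
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (grid_o2 <= 0 || grid_chem <= 0) stop("grids must be > 0", call. = FALSE)
  if (deep_sulfide_gradient < 0)
    stop("deep_sulfide_gradient must be >= 0", call. = FALSE)
  if (!is.null(esox_peak) && length(esox_peak) != 2)
    stop("esox_peak must be c(peak_ph, peak_depth_mm)", call. = FALSE)
  structure(as.list(environment()), class = "profile_sim_config")
}

# noise draw clipped at the validator's lower bound so generated profiles
# always satisfy solute_profile invariants
.noisy <- function(v, sd, lower = -4.999) {
  if (sd > 0) v <- v + stats::rnorm(length(v), 0, sd)
  pmax(v, lower)
}

#' Simulate one O2 microprofile
#'
#' @param config a [profile_sim_config].
#' @param context a [core_context] (supplies metadata).
#' @param timepoint_day,replicate profile metadata.
#' @param seed optional integer; if given, `set.seed(seed)` is applied so
#'   the same seed and config give an identical profile.
#' @return a [solute_profile] of O2.
#' @export
simulate_o2_profile <- function(config, context, timepoint_day = NA,
                                replicate = NA, seed = NULL) {
  stopifnot(inherits(config, "profile_sim_config"),
            inherits(context, "core_context"))
  if (!is.null(seed)) set.seed(seed)
  step <- config$grid_o2 / 1000
  z <- seq(-config$overlying, config$o2_bottom, by = step)
  v <- ifelse(z < 0, config$surface_o2,
              config$surface_o2 * pmax(1 - z / config$true_opd, 0)^2)
  solute_profile("O2", z, .noisy(v, config$noise_sd_o2),
                 resolution = config$grid_o2, core_id = context$core_id,
                 treatment = context$treatment,
                 timepoint_day = timepoint_day, profile_replicate = replicate)
}

# noise-free pH shape: exponential decline plus the e-SOx maximum as a
# Gaussian blend toward peak_ph, so the composite equals peak_ph exactly at
# peak_depth and is stationary there
.ph_shape <- function(z, config) {
  base <- ifelse(z <= 0, config$ph_surface,
                 config$ph_deep + (config$ph_surface - config$ph_deep) *
                   exp(-z / config$ph_scale))
  if (!is.null(config$esox_peak)) {
    g <- exp(-(z - config$esox_peak[2])^2 / (2 * config$esox_width^2))
    base <- base * (1 - g) + config$esox_peak[1] * g
  }
  base
}

#' Simulate a paired H2S/pH profile set with known total-sulfide truth
#'
#' The ground-truth total sulfide is zero above `true_horizon` and linear
#' below it. The sensor-level gas species \[H2S\] is back-computed from the
#' truth through the speciation equilibrium,
#' `[H2S] = total / (1 + 10^(pH - pK1))`, so that [speciate_profile] on the
#' noise-free output recovers the truth exactly. Noise is added last.
#'
#' @param config a [profile_sim_config].
#' @param context a [core_context].
#' @param params a [speciation_params] (its pK1 is used for the
#'   back-computation).
#' @param timepoint_day,replicate profile metadata.
#' @param seed optional integer for reproducible noise.
#' @return a list with [solute_profile]s `h2s` and `ph` and the noise-free
#'   `truth_total` (a data.frame of `depth`, `total`).
#' @export
simulate_sulfide_profiles <- function(config, context, params,
                                      timepoint_day = NA, replicate = NA,
                                      seed = NULL) {
  stopifnot(inherits(config, "profile_sim_config"),
            inherits(context, "core_context"),
            inherits(params, "speciation_params"))
  if (!is.null(seed)) set.seed(seed)
  step <- config$grid_chem / 1000
  z <- seq(-config$overlying, config$profile_bottom, by = step)
  total <- config$deep_sulfide_gradient * pmax(z - config$true_horizon, 0)
  ph <- .ph_shape(z, config)
  h2s_gas <- total / (1 + 10^(ph - params$pk1))
  h2s <- solute_profile("H2S", z, .noisy(h2s_gas, config$noise_sd_h2s),
                        resolution = config$grid_chem,
                        core_id = context$core_id,
                        treatment = context$treatment,
                        timepoint_day = timepoint_day,
                        profile_replicate = replicate)
  ph_noisy <- ph
  if (config$noise_sd_ph > 0)
    ph_noisy <- pmin(pmax(ph + stats::rnorm(length(ph), 0,
                                            config$noise_sd_ph), 0.1), 13.9)
  php <- solute_profile("pH", z, ph_noisy, resolution = config$grid_chem,
                        core_id = context$core_id,
                        treatment = context$treatment,
                        timepoint_day = timepoint_day,
                        profile_replicate = replicate)
  list(h2s = h2s, ph = php, truth_total = data.frame(depth = z, total = total))
}

#' Analytic ground truth of a synthetic core
#'
#' Computes, in closed form from the generating shapes, the quantities the
#' analysis chain is supposed to recover: interface fluxes by Fick's first
#' law with the same convention as [diffusive_flux] (O2 interface gradient
#' `-2 * surface_o2 / true_opd`; sulfide deep gradient as configured), the
#' shape parameters, and the *detectable* OPD/horizon — the depths where
#' the noise-free shapes cross the detection threshold, which is what the
#' "steadily beyond threshold" definitions identify (the O2 shape touches
#' zero only at `true_opd` itself, slightly below its 1 uM crossing).
#'
#' @param config a [profile_sim_config].
#' @param context a [core_context].
#' @param diffusivity_o2,diffusivity_h2s [diffusivity_model]s for the two
#'   solutes in this core.
#' @param threshold detection threshold (uM) for the detectable depths.
#' @param convention flux convention, as in [diffusive_flux].
#' @return an object of class `synthetic_truth`: list with `true_opd`,
#'   `detectable_opd`, `true_horizon`, `detectable_horizon`, `true_j_o2`,
#'   `true_j_h2s`, `surface_o2`, `deep_sulfide_gradient`, `phi`, `db`,
#'   `config`.
#' @export
synthetic_truth <- function(config, context, diffusivity_o2,
                            diffusivity_h2s, threshold = 1,
                            convention = c("as_printed",
                                           "no_outer_porosity")) {
  convention <- match.arg(convention)
  stopifnot(inherits(config, "profile_sim_config"),
            inherits(diffusivity_o2, "diffusivity_model"),
            inherits(diffusivity_h2s, "diffusivity_model"))
  phi_factor <- if (convention == "as_printed") context$porosity else 1
  slope_o2 <- -2 * config$surface_o2 / config$true_opd * 1e3   # mmol m-4
  slope_h2s <- config$deep_sulfide_gradient * 1e3
  g <- config$deep_sulfide_gradient
  structure(
    list(core_id = context$core_id, treatment = context$treatment,
         true_opd = config$true_opd,
         detectable_opd = config$true_opd *
           (1 - sqrt(threshold / config$surface_o2)),
         true_horizon = if (g > 0) config$true_horizon else NA_real_,
         detectable_horizon = if (g > 0) config$true_horizon + threshold / g
                              else NA_real_,
         true_j_o2 = phi_factor *
           (diffusivity_o2$d_s + diffusivity_o2$d_b) * slope_o2,
         true_j_h2s = phi_factor *
           (diffusivity_h2s$d_s + diffusivity_h2s$d_b) * slope_h2s,
         surface_o2 = config$surface_o2,
         deep_sulfide_gradient = g, phi = context$porosity,
         db = diffusivity_o2$d_b, convention = convention, config = config),
    class = "synthetic_truth")
}

#' Window factor of the parabolic O2 shape
#'
#' An OLS gradient fitted over a symmetric (equally spaced) window
#' `[0, w]` of the parabola `C0 (1 - z/L)^2` returns exactly
#' `(C0/L) * (-2 + 2 * zbar / L)`, i.e. the interface gradient times
#' `1 - zbar/L`, where `zbar` is the mean depth of the window points
#' (0.7 for the default 60%-of-OPD window). Recovery tests divide the
#' fitted flux by this factor before comparing with the interface-gradient
#' truth.
#'
#' @param window_mean_depth mean depth of the fitted points (mm), e.g.
#'   `gradient_fit$window_mean_depth`.
#' @param true_opd the generating `true_opd` (mm).
#' @return the dimensionless factor `1 - window_mean_depth / true_opd`.
#' @export
o2_window_factor <- function(window_mean_depth, true_opd) {
  1 - window_mean_depth / true_opd
}

#' Default design of the synthetic incubation experiment
#'
#' Emulates the study design: 4 treatments (control, low, medium, high
#' meiofauna) x 3 cores x 3 solutes x 3 replicate profiles x 3 weekly time
#' points = 324 profiles. Per-treatment parameter means follow the reported
#' treatment patterns: OPDs of 0.8-2.3 mm deepening with meiofauna,
#' sulfide horizons of 3.2-6.4 mm, day-6 sulfide fluxes of 8.8 / 2.9 /
#' 4.4 / 0.4 mmol m-2 d-1 attenuating over time, meiofauna abundances of
#' 128 / 191 / 828 / 2030 ind. per 10 cm2, porosity 0.85-0.93, overlying
#' O2 300-330 uM, 8 degC, salinity 10, and an oxic-zone pH maximum (up to
#' 8.3 near 0.75 mm) from the second week on. Matrices are time point x
#' treatment.
#'
#' @param ... named overrides of any design element.
#' @return a list of class `experiment_design`.
#' @export
experiment_design <- function(...) {
  d <- list(
    treatments = c("control", "low", "medium", "high"),
    cores_per_treatment = 3,
    timepoints = 3,
    replicates = 3,
    timepoint_days = c(6, 15, 23),
    abundance_mean = c(128, 191, 828, 2030),
    abundance_sd = c(45, 66, 431, 402),
    opd_mean = rbind(c(0.8, 1.6, 2.2, 1.6),
                     c(1.4, 1.6, 1.7, 2.3),
                     c(1.4, 1.8, 1.7, 2.3)),
    opd_sd = 0.15,
    horizon_mean = rbind(c(3.8, 3.9, 3.8, 6.4),
                         c(3.2, 4.8, 4.5, 4.8),
                         c(4.0, 4.4, 4.7, 5.4)),
    horizon_sd = 0.3,
    sulfide_flux_target = rbind(c(8.8, 2.9, 4.4, 0.4),
                                c(4.5, 2.5, 2.6, 2.0),
                                c(1.5, 1.4, 1.6, 1.3)),
    surface_o2_range = c(300, 330),
    ph_surface_range = c(7.6, 7.9),
    ph_deep_range = c(5.4, 7.2),
    esox_timepoints = c(2, 3),
    esox_peak_ph_range = c(7.9, 8.3),
    esox_peak_depth_range = c(0.5, 1.0),
    porosity_range = c(0.85, 0.93),
    temperature = 8,
    salinity = 10,
    noise_sd_o2 = 0.3, noise_sd_h2s = 0.3, noise_sd_ph = 0.01,
    grid_o2 = 100, grid_chem = 250,
    o2_bottom = 4, profile_bottom = 10,
    db_reference = db_reference_synthetic())
  over <- list(...)
  bad <- setdiff(names(over), names(d))
  if (length(bad))
    stop("unknown design element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  d[names(over)] <- over
  for (nm in c("cores_per_treatment", "timepoints", "replicates"))
    if (!is.numeric(d[[nm]]) || d[[nm]] < 1 || d[[nm]] != round(d[[nm]]))
      stop(nm, " must be a positive integer", call. = FALSE)
  if (!length(d$treatments)) stop("need at least one treatment",
                                  call. = FALSE)
  nt <- length(d$treatments); nw <- d$timepoints
  for (nm in c("opd_mean", "horizon_mean", "sulfide_flux_target")) {
    m <- d[[nm]]
    if (!is.matrix(m)) {
      # scalar fills the grid; a per-treatment vector repeats per time point
      m <- matrix(as.numeric(m), nrow = nw, ncol = nt, byrow = TRUE)
    } else {
      # subset/recycle the time point x treatment grid to the design counts
      m <- m[((seq_len(nw) - 1) %% nrow(m)) + 1,
             ((seq_len(nt) - 1) %% ncol(m)) + 1, drop = FALSE]
    }
    d[[nm]] <- m
  }
  for (nm in c("abundance_mean", "abundance_sd"))
    d[[nm]] <- rep_len(as.numeric(d[[nm]]), nt)
  if (length(d$timepoint_days) < nw)
    stop("timepoint_days shorter than the number of time points",
         call. = FALSE)
  structure(d, class = "experiment_design")
}

#' Simulate a full incubation experiment with ground truth
#'
#' Draws per-core contexts and per-(core, time point) generating shapes
#' from the design's parameter distributions and emits one profile per
#' core x solute x replicate x time point. The default design gives
#' 4 x 3 x 3 x 3 x 3 = 324 profiles. Fully reproducible from the master
#' seed.
#'
#' @param design an [experiment_design].
#' @param seed master seed (integer).
#' @return an object of class `synthetic_experiment`: list with
#'   `experiment` (an [experiment_set]), `truth` (a data.frame, one row per
#'   core x time point), `design`, `seed`.
#' @export
simulate_experiment <- function(design = experiment_design(), seed = 1) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(seed)
  fit_db <- fit_biodiffusivity(design$db_reference)
  profiles <- list()
  contexts <- list()
  truth <- list()
  core_no <- 0
  for (ti in seq_along(design$treatments)) {
    trt <- design$treatments[ti]
    for (ci in seq_len(design$cores_per_treatment)) {
      core_no <- core_no + 1
      core_id <- sprintf("C%02d", core_no)
      phi <- stats::runif(1, design$porosity_range[1],
                          design$porosity_range[2])
      abundance <- max(0, stats::rnorm(1, design$abundance_mean[ti],
                                       design$abundance_sd[ti]))
      surface_o2 <- stats::runif(1, design$surface_o2_range[1],
                                 design$surface_o2_range[2])
      ctx <- core_context(core_id, trt, phi, design$temperature,
                          design$salinity, abundance,
                          overlying_o2 = surface_o2)
      contexts[[core_id]] <- ctx
      params <- speciation_params(design$temperature, design$salinity)
      db <- as.numeric(db_for_abundance(fit_db, abundance))
      dm_o2 <- diffusivity_model(
        "O2", molecular_diffusivity("O2", design$temperature), phi, db)
      dm_h2s <- diffusivity_model(
        "H2S", molecular_diffusivity("H2S", design$temperature), phi, db)

      for (w in seq_len(design$timepoints)) {
        day <- design$timepoint_days[w]
        opd <- max(0.3, stats::rnorm(1, design$opd_mean[w, ti],
                                     design$opd_sd))
        horizon <- max(opd + 0.5,
                       stats::rnorm(1, design$horizon_mean[w, ti],
                                    design$horizon_sd))
        target_flux <- design$sulfide_flux_target[w, ti]
        grad <- target_flux /
          (ctx$porosity * (dm_h2s$d_s + dm_h2s$d_b) * 1e3)
        esox <- NULL
        if (w %in% design$esox_timepoints) {
          peak_ph <- stats::runif(1, design$esox_peak_ph_range[1],
                                  design$esox_peak_ph_range[2])
          peak_z <- stats::runif(1, design$esox_peak_depth_range[1],
                                 design$esox_peak_depth_range[2])
          esox <- c(peak_ph, peak_z)
        }
        cfg <- profile_sim_config(
          surface_o2 = surface_o2, true_opd = opd, true_horizon = horizon,
          deep_sulfide_gradient = grad,
          ph_surface = stats::runif(1, design$ph_surface_range[1],
                                    design$ph_surface_range[2]),
          ph_deep = stats::runif(1, design$ph_deep_range[1],
                                 design$ph_deep_range[2]),
          esox_peak = esox,
          noise_sd_o2 = design$noise_sd_o2,
          noise_sd_h2s = design$noise_sd_h2s,
          noise_sd_ph = design$noise_sd_ph,
          grid_o2 = design$grid_o2, grid_chem = design$grid_chem,
          o2_bottom = design$o2_bottom,
          profile_bottom = design$profile_bottom)
        tr <- synthetic_truth(cfg, ctx, dm_o2, dm_h2s)
        truth[[length(truth) + 1]] <- data.frame(
          core_id = core_id, treatment = trt, timepoint_day = day,
          true_opd = tr$true_opd, detectable_opd = tr$detectable_opd,
          true_horizon = tr$true_horizon,
          detectable_horizon = tr$detectable_horizon,
          true_j_o2 = tr$true_j_o2, true_j_h2s = tr$true_j_h2s,
          surface_o2 = surface_o2, deep_sulfide_gradient = grad,
          porosity = phi, db = db, abundance = abundance,
          noise_sd_o2 = design$noise_sd_o2,
          noise_sd_h2s = design$noise_sd_h2s,
          noise_sd_ph = design$noise_sd_ph, seed = seed)
        for (r in seq_len(design$replicates)) {
          profiles[[length(profiles) + 1]] <-
            simulate_o2_profile(cfg, ctx, day, r)
          sp <- simulate_sulfide_profiles(cfg, ctx, params, day, r)
          profiles[[length(profiles) + 1]] <- sp$h2s
          profiles[[length(profiles) + 1]] <- sp$ph
        }
      }
    }
  }
  structure(
    list(experiment = experiment_set(profiles, contexts),
         truth = do.call(rbind, truth), design = design, seed = seed),
    class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_experiment> seed %s: %d profiles, %d truth records\n",
    x$seed, x$experiment$design$n_profiles, nrow(x$truth)))
  invisible(x)
}

#' Write a synthetic experiment as a self-contained fixture set
#'
#' Writes one profile file per profile (in the exact dialect [read_profile]
#' reads), a `manifest.csv` mapping files to metadata, a `contexts.csv`, a
#' `truth.csv` and a `design.yml` echo, all under `dir`.
#'
#' @param sim a [simulate_experiment] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_experiment"))
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(seq_along(sim$experiment$profiles), function(i) {
    p <- sim$experiment$profiles[[i]]
    fn <- sprintf("profiles/%s_%s_d%02d_r%d.tsv", p$core_id, p$solute,
                  p$timepoint_day, p$profile_replicate)
    write_profile(p, file.path(dir, fn))
    data.frame(file = fn, solute = p$solute, core_id = p$core_id,
               treatment = p$treatment, timepoint_day = p$timepoint_day,
               profile_replicate = p$profile_replicate,
               resolution = p$resolution, depth_unit = "mm")
  })
  write_summary(do.call(rbind, rows), file.path(dir, "manifest.csv"))
  ctx <- do.call(rbind, lapply(sim$experiment$contexts, function(cc)
    data.frame(core_id = cc$core_id, treatment = cc$treatment,
               porosity = cc$porosity, temperature = cc$temperature,
               salinity = cc$salinity,
               meiofauna_abundance = cc$meiofauna_abundance,
               overlying_o2 = cc$overlying_o2)))
  write_summary(ctx, file.path(dir, "contexts.csv"))
  write_summary(sim$truth, file.path(dir, "truth.csv"))
  d <- sim$design
  d$db_reference <- as.list(d$db_reference)
  for (nm in c("opd_mean", "horizon_mean", "sulfide_flux_target"))
    d[[nm]] <- lapply(seq_len(nrow(d[[nm]])), function(i)
      as.numeric(d[[nm]][i, ]))
  yaml::write_yaml(c(unclass(d), list(seed = sim$seed)),
                   file.path(dir, "design.yml"))
  invisible(dir)
}

#' Read back an experiment written by [write_experiment]
#'
#' @param dir directory containing `manifest.csv`, `contexts.csv` and the
#'   profile files.
#' @return a list with `experiment` (an [experiment_set]) and `truth`
#'   (data.frame or `NULL` if no `truth.csv` is present).
#' @export
read_experiment <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  ctx_path <- file.path(dir, "contexts.csv")
  if (!file.exists(man_path) || !file.exists(ctx_path))
    stop("not an experiment directory (need manifest.csv and contexts.csv): ",
         dir, call. = FALSE)
  man <- read_summary(man_path)
  ctx_df <- read_summary(ctx_path)
  contexts <- lapply(seq_len(nrow(ctx_df)), function(i)
    core_context(ctx_df$core_id[i], ctx_df$treatment[i], ctx_df$porosity[i],
                 ctx_df$temperature[i], ctx_df$salinity[i],
                 ctx_df$meiofauna_abundance[i], ctx_df$overlying_o2[i]))
  profiles <- lapply(seq_len(nrow(man)), function(i)
    read_profile(file.path(dir, man$file[i]), solute = man$solute[i],
                 core_id = man$core_id[i], treatment = man$treatment[i],
                 timepoint_day = man$timepoint_day[i],
                 profile_replicate = man$profile_replicate[i],
                 resolution = man$resolution[i],
                 depth_unit = man$depth_unit[i]))
  truth <- if (file.exists(file.path(dir, "truth.csv")))
    read_summary(file.path(dir, "truth.csv")) else NULL
  list(experiment = experiment_set(profiles, contexts), truth = truth)
}
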