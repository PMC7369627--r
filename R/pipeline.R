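#' Replicate aggregation: mean, standard error, n
#'
#' @param x numeric vector; `NA`s are dropped before aggregating.
#' @return list with `mean`, `se` (sample standard deviation over sqrt(n);
#'   `NA` when n < 2), `n`.
#' @examples
#' aggregate_stats(c(2, 4, 6))  # mean 4, se 1.1547, n 3
#' @export
aggregate_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(list(mean = NA_real_, se = NA_real_, n = 0L))
  list(mean = mean(x),
       se = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
       n = as.integer(n))
}

#' Analysis options for the profile pipeline
#'
#' @param o2_window_fraction O2 gradients are fitted from the interface
#'   down to this fraction of the OPD (default 0.6, the quasi-linear
#'   diffusive zone).
#' @param h2s_window_width total-sulfide gradients are fitted over this
#'   many mm below the sulfide horizon (default 1.0).
#' @param threshold_o2,threshold_h2s detection thresholds (uM, default 1).
#' @param run_length persistence rule for horizon detection: `Inf` =
#'   terminal run (strictest), finite k = first run of k consecutive
#'   conforming points (robust to sensor noise at depth).
#' @param flux_convention see [diffusive_flux].
#' @param stoichiometry O2 per S in the oxygen budget (default 2).
#' @param db_reference data.frame of `(abundance, db)` calibration points
#'   for [fit_biodiffusivity]; required unless `db_disabled`.
#' @param db_disabled set `TRUE` to run with Db = 0 (pure molecular
#'   diffusion).
#' @param dmol_table optional per-solute Dmol table (see
#'   [molecular_diffusivity]); `dmol_units` gives its units.
#' @param dmol_units `"cm2_s"` or `"m2_d"`.
#' @param pk1_override optional pK1 override for [speciation_params].
#' @param r2_floor gradient fits below this r-squared are flagged.
#' @param horizon_on detect the sulfide horizon on the `"total"` sulfide
#'   profile (default) or on the `"raw"` \[H2S\] sensor profile — the raw
#'   signal is not amplified by the speciation factor and is therefore
#'   more robust when sensor noise approaches the threshold.
#' @return a list of class `analysis_options`.
#' @export
analysis_options <- function(o2_window_fraction = 0.6,
                             h2s_window_width = 1.0,
                             threshold_o2 = 1, threshold_h2s = 1,
                             run_length = Inf, horizon_on = c("total", "raw"),
                             flux_convention = c("as_printed",
                                                 "no_outer_porosity"),
                             stoichiometry = 2,
                             db_reference = NULL, db_disabled = FALSE,
                             dmol_table = NULL,
                             dmol_units = c("cm2_s", "m2_d"),
                             pk1_override = NULL, r2_floor = 0.9) {
  flux_convention <- match.arg(flux_convention)
  dmol_units <- match.arg(dmol_units)
  horizon_on <- match.arg(horizon_on)
  structure(as.list(environment()), class = "analysis_options")
}

# analyze the three profiles of one replicate; any error is caught by the
# caller and recorded as a flagged row, never silently dropped
.analyze_replicate <- function(o2, h2s, ph, ctx, params, dm_o2, dm_h2s,
                               opt) {
  out <- list(opd = NA_real_, sulfide_horizon = NA_real_,
              suboxic_width = NA_real_, j_o2 = NA_real_, j_h2s = NA_real_,
              r2_o2 = NA_real_, r2_h2s = NA_real_,
              o2_window_hi = NA_real_, o2_window_mean_depth = NA_real_,
              n_clipped = NA_integer_, flag = "")
  flags <- character()
  if (!is.null(o2)) {
    opd <- oxygen_penetration_depth(o2, opt$threshold_o2, opt$run_length)
    out$opd <- as.numeric(opd)
    if (!is.na(opd) && opd > 0) {
      gf <- tryCatch(
        fit_gradient(o2, o2_fit_window(opd, opt$o2_window_fraction),
                     opt$r2_floor),
        error = function(e) e)
      if (inherits(gf, "error")) {
        flags <- c(flags, paste("o2 gradient:", conditionMessage(gf)))
      } else {
        fx <- diffusive_flux(ctx, dm_o2, gf, opt$flux_convention)
        out$j_o2 <- fx$flux
        out$r2_o2 <- gf$r2
        out$o2_window_hi <- unname(gf$window[2])
        out$o2_window_mean_depth <- gf$window_mean_depth
        if (isTRUE(gf$low_r2)) flags <- c(flags, "o2 gradient low r2")
      }
    } else {
      flags <- c(flags, paste("opd:", attr(opd, "flag")))
    }
  } else flags <- c(flags, "missing O2 profile")

  if (!is.null(h2s) && !is.null(ph)) {
    sp <- speciate_profile(h2s, ph, params)
    out$n_clipped <- sp$n_clipped
    hz <- sulfide_horizon(if (identical(opt$horizon_on, "raw")) h2s else sp,
                          opt$threshold_h2s, opt$run_length)
    out$sulfide_horizon <- as.numeric(hz)
    if (!is.na(hz)) {
      gf <- tryCatch(
        fit_gradient(sp, h2s_fit_window(hz, opt$h2s_window_width),
                     opt$r2_floor),
        error = function(e) e)
      if (inherits(gf, "error")) {
        flags <- c(flags, paste("h2s gradient:", conditionMessage(gf)))
      } else {
        fx <- diffusive_flux(ctx, dm_h2s, gf, opt$flux_convention)
        out$j_h2s <- fx$flux
        out$r2_h2s <- gf$r2
        if (isTRUE(gf$low_r2)) flags <- c(flags, "h2s gradient low r2")
      }
    } else {
      flags <- c(flags, paste("sulfide horizon:", attr(hz, "flag")))
    }
  } else flags <- c(flags, "missing H2S or pH profile")

  sw <- suboxic_width(out$opd, out$sulfide_horizon)
  out$suboxic_width <- as.numeric(sw)
  if (identical(attr(sw, "flag"), "overlapping oxic and sulfidic zones"))
    flags <- c(flags, "overlapping oxic and sulfidic zones")
  out$flag <- paste(flags, collapse = "; ")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyze a full experiment: speciate, detect horizons, fit fluxes,
#' build budgets
#'
#' Runs the whole analysis chain on every replicate of every core at every
#' time point, then aggregates replicates to core level and cores to
#' treatment level (mean and standard error). Budgets are built from the
#' core-level mean fluxes. No profile is silently dropped: replicates
#' whose analysis fails appear in the per-profile table with a flag.
#'
#' @param exp an [experiment_set].
#' @param options an [analysis_options].
#' @return a list of class `pipeline_result` with data.frames
#'   `per_profile` (one row per core x time point x replicate),
#'   `per_core` (one row per core x time point, with budget columns) and
#'   `per_treatment` (one row per treatment x time point), plus the
#'   options echo.
#' @export
analyze_experiment <- function(exp, options = analysis_options()) {
  stopifnot(inherits(exp, "experiment_set"),
            inherits(options, "analysis_options"))
  if (isTRUE(options$db_disabled)) {
    fit_db <- NULL
  } else {
    if (is.null(options$db_reference))
      stop("no biodiffusivity calibration: supply options$db_reference ",
           "(data.frame of abundance, db) or set db_disabled = TRUE",
           call. = FALSE)
    fit_db <- fit_biodiffusivity(options$db_reference)
  }

  idx <- data.frame(
    i = seq_along(exp$profiles),
    core_id = vapply(exp$profiles, `[[`, character(1), "core_id"),
    solute = vapply(exp$profiles, `[[`, character(1), "solute"),
    day = vapply(exp$profiles, `[[`, integer(1), "timepoint_day"),
    rep = vapply(exp$profiles, `[[`, integer(1), "profile_replicate"))

  per_profile <- list()
  for (core_id in unique(idx$core_id)) {
    ctx <- exp$contexts[[core_id]]
    params <- speciation_params(ctx$temperature, ctx$salinity,
                                options$pk1_override)
    db <- if (is.null(fit_db)) 0
          else as.numeric(db_for_abundance(fit_db, ctx$meiofauna_abundance))
    dm_o2 <- diffusivity_model(
      "O2", molecular_diffusivity("O2", ctx$temperature,
                                  options$dmol_table, options$dmol_units),
      ctx$porosity, db)
    dm_h2s <- diffusivity_model(
      "H2S", molecular_diffusivity("H2S", ctx$temperature,
                                   options$dmol_table, options$dmol_units),
      ctx$porosity, db)
    sub <- idx[idx$core_id == core_id, ]
    for (day in sort(unique(sub$day))) {
      for (r in sort(unique(sub$rep[sub$day == day]))) {
        pick <- function(sol) {
          j <- sub$i[sub$day == day & sub$rep == r & sub$solute == sol]
          if (length(j)) exp$profiles[[j[1]]] else NULL
        }
        row <- tryCatch(
          .analyze_replicate(pick("O2"), pick("H2S"), pick("pH"), ctx,
                             params, dm_o2, dm_h2s, options),
          error = function(e) list(
            opd = NA_real_, sulfide_horizon = NA_real_,
            suboxic_width = NA_real_, j_o2 = NA_real_, j_h2s = NA_real_,
            r2_o2 = NA_real_, r2_h2s = NA_real_, o2_window_hi = NA_real_,
            o2_window_mean_depth = NA_real_, n_clipped = NA_integer_,
            flag = paste("failed:", conditionMessage(e))))
        per_profile[[length(per_profile) + 1]] <- data.frame(
          core_id = core_id, treatment = ctx$treatment, timepoint_day = day,
          replicate = r, row, stringsAsFactors = FALSE)
      }
    }
  }
  per_profile <- do.call(rbind, per_profile)

  agg_rows <- function(df, keys, n_expected_cols) {
    groups <- unique(df[keys])
    out <- list()
    for (g in seq_len(nrow(groups))) {
      sel <- rep(TRUE, nrow(df))
      for (k in keys) sel <- sel & df[[k]] == groups[[k]][g]
      d <- df[sel, ]
      stats_of <- function(col) aggregate_stats(d[[col]])
      row <- groups[g, , drop = FALSE]
      for (col in n_expected_cols) {
        s <- stats_of(col)
        row[[paste0(col, "_mean")]] <- s$mean
        row[[paste0(col, "_se")]] <- s$se
        row[[paste0(col, "_n")]] <- s$n
      }
      row$treatment <- d$treatment[1]
      out[[g]] <- row
    }
    do.call(rbind, out)
  }

  metrics <- c("opd", "sulfide_horizon", "suboxic_width", "j_o2", "j_h2s")
  per_core <- agg_rows(per_profile, c("core_id", "timepoint_day"), metrics)
  # stoichiometric oxygen budget from the core-mean fluxes
  budget_cols <- lapply(seq_len(nrow(per_core)), function(i) {
    b <- tryCatch(
      build_budget(per_core$j_o2_mean[i], max(0, per_core$j_h2s_mean[i]),
                   options$stoichiometry),
      error = function(e) NULL)
    if (is.null(b) || is.na(per_core$j_o2_mean[i]) ||
        is.na(per_core$j_h2s_mean[i]))
      return(data.frame(o2_for_sulfide = NA_real_, residual_o2 = NA_real_,
                        sulfide_fraction = NA_real_,
                        budget_inconsistent = NA))
    data.frame(o2_for_sulfide = b$o2_for_sulfide,
               residual_o2 = b$residual_o2,
               sulfide_fraction = b$sulfide_fraction,
               budget_inconsistent = b$inconsistent)
  })
  per_core <- cbind(per_core, do.call(rbind, budget_cols))

  core_means <- per_core[c("treatment", "timepoint_day",
                           paste0(metrics, "_mean"))]
  names(core_means) <- c("treatment", "timepoint_day", metrics)
  per_treatment <- agg_rows(core_means, c("treatment", "timepoint_day"),
                            metrics)

  structure(list(per_profile = per_profile, per_core = per_core,
                 per_treatment = per_treatment, options = options),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d replicate rows, %d core x timepoint rows, %d treatment x timepoint rows\n",
    nrow(x$per_profile), nrow(x$per_core), nrow(x$per_treatment)))
  invisible(x)
}

#' Build a run configuration
#'
#' @param mode `"simulate"` (generate a synthetic experiment) or `"read"`
#'   (load profile files from `input_dir`).
#' @param design an [experiment_design] (simulate mode).
#' @param input_dir experiment directory written by [write_experiment]
#'   (read mode).
#' @param output_dir where summary tables and the run log are written;
#'   `NULL` for an in-memory run.
#' @param seed master seed (simulate mode).
#' @param options an [analysis_options].
#' @return a list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "read"), design = NULL,
                       input_dir = NULL, output_dir = NULL, seed = 1,
                       options = analysis_options()) {
  mode <- match.arg(mode)
  if (mode == "read") {
    if (is.null(input_dir))
      stop("read mode needs input_dir", call. = FALSE)
    if (!dir.exists(input_dir))
      stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (mode == "simulate" && is.null(design)) design <- experiment_design()
  structure(list(mode = mode, design = design, input_dir = input_dir,
                 output_dir = output_dir, seed = seed, options = options),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys: `mode`, `seed`, `input_dir`, `output_dir`, `design`
#' (named overrides of [experiment_design]; matrices may be given as lists
#' of per-time-point rows) and `options` (named arguments of
#' [analysis_options]; `db_reference` as a mapping of `abundance` and `db`
#' lists).
#'
#' @param path YAML file.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  opt_args <- y$options %||% list()
  if (!is.null(opt_args$db_reference))
    opt_args$db_reference <- as.data.frame(opt_args$db_reference)
  if (!is.null(opt_args$run_length) &&
      identical(opt_args$run_length, "terminal"))
    opt_args$run_length <- Inf
  options <- do.call(analysis_options, opt_args)
  design <- NULL
  if (!is.null(y$design)) {
    dargs <- y$design
    if (!is.null(dargs$db_reference))
      dargs$db_reference <- as.data.frame(dargs$db_reference)
    for (nm in c("opd_mean", "horizon_mean", "sulfide_flux_target"))
      if (!is.null(dargs[[nm]]) && is.list(dargs[[nm]]))
        dargs[[nm]] <- do.call(rbind, lapply(dargs[[nm]], as.numeric))
    design <- do.call(experiment_design, dargs)
  }
  run_config(mode = y$mode %||% "simulate", design = design,
             input_dir = y$input_dir, output_dir = y$output_dir,
             seed = y$seed %||% 1, options = options)
}

#' Run the pipeline end to end
#'
#' Simulates or reads an experiment, analyzes it, and (if `output_dir` is
#' set) writes `per_profile.csv`, `per_core.csv`, `per_treatment.csv` and
#' a provenance run log.
#'
#' @param config a [run_config].
#' @return the [analyze_experiment] result, invisibly if written to disk,
#'   with the experiment (and truth, in simulate mode) attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "simulate") {
    sim <- simulate_experiment(config$design, config$seed)
    exp <- sim$experiment
    truth <- sim$truth
  } else {
    rd <- read_experiment(config$input_dir)
    exp <- rd$experiment
    truth <- rd$truth
  }
  res <- analyze_experiment(exp, config$options)
  res$experiment <- exp
  res$truth <- truth
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_summary(res$per_profile,
                  file.path(config$output_dir, "per_profile.csv"))
    write_summary(res$per_core, file.path(config$output_dir, "per_core.csv"))
    write_summary(res$per_treatment,
                  file.path(config$output_dir, "per_treatment.csv"))
    opt <- config$options
    opt$run_length <- if (is.infinite(opt$run_length)) "terminal"
                      else opt$run_length
    if (!is.null(opt$db_reference))
      opt$db_reference <- as.list(opt$db_reference)
    log <- c(
      paste("poreflux run,", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste("mode:", config$mode),
      paste("seed:", config$seed),
      "options:",
      yaml::as.yaml(unclass(opt)))
    writeLines(log, file.path(config$output_dir, "run_log.txt"))
    return(invisible(res))
  }
  res
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic experiment fixture set),
#' `analyze` (run the pipeline on a config), `demo` (simulate with the
#' default design, then analyze). Flags: `--config`, `--out`, `--seed`,
#' `--quiet`. Installed as the `inst/cli/poreflux` launcher script.
#'
#' @param args character vector of command-line arguments (default: the
#'   process's).
#' @return exit status, 0 on success (invisibly).
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: poreflux <simulate|analyze|demo> [--config F] [--out D] [--seed N] [--quiet]"
  if (!length(args) || !args[1] %in% c("simulate", "analyze", "demo")) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--quiet", action = "store_true",
                          default = FALSE)))
  opt <- optparse::parse_args(parser, args = args[-1])
  say <- function(...) if (!opt$quiet) message(...)

  status <- tryCatch({
    if (cmd == "simulate") {
      cfg <- if (!is.null(opt$config)) read_run_config(opt$config)
             else run_config("simulate", seed = opt$seed)
      if (is.null(opt$out)) stop("simulate needs --out", call. = FALSE)
      sim <- simulate_experiment(cfg$design %||% experiment_design(),
                                 opt$seed)
      write_experiment(sim, opt$out)
      say("wrote ", sim$experiment$design$n_profiles, " profiles to ",
          opt$out)
    } else if (cmd == "analyze") {
      if (is.null(opt$config)) stop("analyze needs --config", call. = FALSE)
      cfg <- read_run_config(opt$config)
      if (!is.null(opt$out)) cfg$output_dir <- opt$out
      res <- run_pipeline(cfg)
      say("analyzed ", nrow(res$per_profile), " replicate sets; ",
          "summaries in ", cfg$output_dir %||% "(memory)")
    } else { # demo
      if (is.null(opt$out)) stop("demo needs --out", call. = FALSE)
      cfg <- run_config("simulate", seed = opt$seed, output_dir = opt$out,
                        options = analysis_options(
                          db_reference = db_reference_synthetic(),
                          run_length = 2, horizon_on = "raw"))
      res <- run_pipeline(cfg)
      say("demo run: ", nrow(res$per_core), " core x timepoint rows in ",
          opt$out)
    }
    0L
  }, error = function(e) {
    message("poreflux error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
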