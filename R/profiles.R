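#' Construct a solute microprofile
#'
#' A `solute_profile` is one depth-ordered series of microsensor readings for
#' a single solute in a single sediment core at one time point. Depths are in
#' millimetres, zero at the sediment-water interface, positive downward;
#' negative depths are overlying-water readings. Values are micromolar for
#' O2 and H2S and pH units for pH.
#'
#' @param solute one of `"O2"`, `"H2S"`, `"pH"`.
#' @param depths numeric vector of depths (mm), strictly increasing.
#' @param values numeric vector of readings, same length as `depths`.
#' @param resolution nominal vertical step of the sensor (micrometres).
#' @param core_id core identifier.
#' @param treatment treatment label.
#' @param timepoint_day integer day of the incubation.
#' @param profile_replicate integer replicate index within the core.
#' @return an object of class `solute_profile`.
#' @examples
#' p <- solute_profile("O2", depths = c(-0.1, 0, 0.1, 0.2),
#'                     values = c(300, 300, 180, 40), resolution = 100,
#'                     core_id = "C1", treatment = "control",
#'                     timepoint_day = 6, profile_replicate = 1)
#' print(p)
#' @export
solute_profile <- function(solute, depths, values, resolution = NA_real_,
                           core_id = NA_character_, treatment = NA_character_,
                           timepoint_day = NA_integer_,
                           profile_replicate = NA_integer_) {
  solute <- match.arg(solute, c("O2", "H2S", "pH"))
  p <- structure(
    list(solute = solute,
         depths = as.numeric(depths),
         values = as.numeric(values),
         resolution = as.numeric(resolution),
         core_id = as.character(core_id),
         treatment = as.character(treatment),
         timepoint_day = as.integer(timepoint_day),
         profile_replicate = as.integer(profile_replicate)),
    class = "solute_profile")
  validate_solute_profile(p)
}

#' Validate a solute_profile
#'
#' Enforces the profile invariants: depths strictly increasing, equal-length
#' depth/value vectors with at least three points, all values finite, pH
#' within (0, 14), and concentration readings no lower than -5 uM (small
#' negatives are tolerated as sensor noise; large ones indicate a
#' calibration problem).
#'
#' @param p a `solute_profile`.
#' @return `p`, invisibly validated (returned unchanged on success).
#' @export
validate_solute_profile <- function(p) {
  stopifnot(inherits(p, "solute_profile"))
  if (length(p$depths) != length(p$values))
    stop("depths and values must have equal length", call. = FALSE)
  if (length(p$depths) < 3)
    stop("a profile needs at least 3 points, got ", length(p$depths),
         call. = FALSE)
  if (any(!is.finite(p$depths)) || any(!is.finite(p$values)))
    stop("non-finite depth or value in profile", call. = FALSE)
  if (any(diff(p$depths) <= 0))
    stop("depths must be strictly increasing", call. = FALSE)
  if (p$solute == "pH") {
    if (any(p$values <= 0 | p$values >= 14))
      stop("pH values must lie in (0, 14)", call. = FALSE)
  } else {
    if (any(p$values < -5))
      stop(p$solute, " readings below -5 uM: calibration problem, not noise",
           call. = FALSE)
  }
  p
}

#' @export
print.solute_profile <- function(x, ...) {
  cat(sprintf("<solute_profile> %s, core %s (%s), day %s, replicate %s\n",
              x$solute, x$core_id, x$treatment, x$timepoint_day,
              x$profile_replicate))
  cat(sprintf("  %d points, %.2f to %.2f mm, values %.3g to %.3g\n",
              length(x$depths), min(x$depths), max(x$depths),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.solute_profile <- function(x, ...) {
  unit <- if (x$solute == "pH") "pH" else paste(x$solute, "(uM)")
  plot(x$values, x$depths, type = "o", ylim = rev(range(x$depths)),
       xlab = unit, ylab = "depth (mm)", pch = 16, cex = 0.6, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Per-core environmental context
#'
#' Holds the quantities of the flux calculation that belong to the core
#' rather than to a single profile: porosity (phi of Fick's first law),
#' temperature and salinity (which set the molecular diffusivity and the
#' sulfide dissociation constant), meiofauna abundance (which sets the
#' biodiffusivity) and the overlying-water O2 concentration.
#'
#' @param core_id core identifier.
#' @param treatment treatment label.
#' @param porosity volumetric porosity, in (0, 1).
#' @param temperature degrees Celsius, within (-2, 40).
#' @param salinity practical salinity.
#' @param meiofauna_abundance individuals per 10 cm^2 (i.e. per 1e-3 m^2).
#' @param overlying_o2 overlying-water O2 (uM).
#' @return an object of class `core_context`.
#' @export
core_context <- function(core_id, treatment, porosity, temperature, salinity,
                         meiofauna_abundance, overlying_o2 = NA_real_) {
  if (!is.finite(porosity) || porosity <= 0 || porosity >= 1)
    stop("porosity must lie in (0, 1), got ", porosity, call. = FALSE)
  if (!is.finite(temperature) || temperature <= -2 || temperature >= 40)
    stop("temperature must lie in (-2, 40) degC, got ", temperature,
         call. = FALSE)
  if (!is.finite(meiofauna_abundance) || meiofauna_abundance < 0)
    stop("meiofauna_abundance must be >= 0", call. = FALSE)
  structure(
    list(core_id = as.character(core_id), treatment = as.character(treatment),
         porosity = porosity, temperature = temperature, salinity = salinity,
         meiofauna_abundance = meiofauna_abundance,
         overlying_o2 = overlying_o2),
    class = "core_context")
}

#' Bundle profiles and core contexts into an experiment set
#'
#' @param profiles list of [solute_profile] objects.
#' @param contexts list of [core_context] objects (any order; keyed by
#'   `core_id` internally).
#' @return an object of class `experiment_set` with elements `profiles`,
#'   `contexts` (named by core_id) and `design` (a summary data.frame of
#'   treatments, cores, time points and replicate counts).
#' @export
experiment_set <- function(profiles, contexts) {
  stopifnot(is.list(profiles), is.list(contexts))
  names(contexts) <- vapply(contexts, function(cc) cc$core_id, character(1))
  cores <- vapply(profiles, function(p) p$core_id, character(1))
  missing_ctx <- setdiff(unique(cores), names(contexts))
  if (length(missing_ctx))
    stop("profiles reference cores with no context: ",
         paste(missing_ctx, collapse = ", "), call. = FALSE)
  # replicate profiles of one (core, solute, timepoint) must share resolution
  key <- paste(cores,
               vapply(profiles, function(p) p$solute, character(1)),
               vapply(profiles, function(p) as.character(p$timepoint_day),
                      character(1)))
  res <- vapply(profiles, function(p) p$resolution, numeric(1))
  for (k in unique(key)) {
    r <- unique(res[key == k & !is.na(res)])
    if (length(r) > 1)
      stop("replicate profiles of ", k, " differ in resolution", call. = FALSE)
  }
  design <- data.frame(
    treatments = length(unique(vapply(contexts, `[[`, character(1),
                                      "treatment"))),
    cores = length(contexts),
    timepoints = length(unique(vapply(profiles, `[[`, integer(1),
                                      "timepoint_day"))),
    n_profiles = length(profiles))
  structure(list(profiles = profiles, contexts = contexts, design = design),
            class = "experiment_set")
}

#' @export
print.experiment_set <- function(x, ...) {
  cat(sprintf(
    "<experiment_set> %d profiles, %d cores, %d treatments, %d time points\n",
    x$design$n_profiles, x$design$cores, x$design$treatments,
    x$design$timepoints))
  invisible(x)
}

#' Read one microsensor profile from a delimited text file
#'
#' Parses a two-column (depth, reading) table as exported by sensor suites.
#' Lines starting with the comment prefix are ignored anywhere in the file;
#' leading lines that do not parse as two numbers are treated as headers.
#' After the first data row, any unparseable row is a hard error reported
#' with its line number. Duplicate depths are collapsed by averaging their
#' readings; rows are sorted by depth.
#'
#' @param path file to read.
#' @param solute,core_id,treatment,timepoint_day,profile_replicate,resolution
#'   profile metadata (see [solute_profile]).
#' @param depth_unit `"mm"` or `"um"`; depths are normalised to mm.
#' @param delim field delimiter; the default splits on any whitespace,
#'   commas and semicolons also work (e.g. `delim = ","`).
#' @param comment comment prefix (default `"#"`).
#' @return a validated [solute_profile].
#' @export
read_profile <- function(path, solute, core_id = NA, treatment = NA,
                         timepoint_day = NA, profile_replicate = NA,
                         resolution = NA, depth_unit = c("mm", "um"),
                         delim = NULL, comment = "#") {
  depth_unit <- match.arg(depth_unit)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), comment) & nzchar(trimws(lines))
  lineno <- seq_along(lines)[keep]
  lines <- lines[keep]
  if (!length(lines)) stop("empty profile file: ", path, call. = FALSE)

  parse_row <- function(s) {
    f <- if (is.null(delim)) strsplit(trimws(s), "[,;[:space:]]+")[[1]]
         else strsplit(trimws(s), delim, fixed = TRUE)[[1]]
    if (length(f) < 2) return(c(NA_real_, NA_real_))
    suppressWarnings(as.numeric(f[1:2]))
  }
  mat <- t(vapply(lines, parse_row, numeric(2), USE.NAMES = FALSE))
  ok <- !is.na(mat[, 1]) & !is.na(mat[, 2])
  first_data <- which(ok)[1]
  if (is.na(first_data))
    stop("no parseable (depth, value) rows in ", path, call. = FALSE)
  bad <- which(!ok & seq_along(ok) > first_data)
  if (length(bad))
    stop("unparseable row in ", path, " at line ", lineno[bad[1]], ": '",
         lines[bad[1]], "'", call. = FALSE)

  depth <- mat[ok, 1]
  value <- mat[ok, 2]
  if (depth_unit == "um") depth <- depth / 1000
  # collapse exact duplicate depths by mean, then sort
  if (anyDuplicated(depth)) {
    agg <- tapply(value, depth, mean)
    depth <- as.numeric(names(agg))
    value <- as.numeric(agg)
  }
  o <- order(depth)
  depth <- depth[o]; value <- value[o]
  if (length(depth) < 3)
    stop("fewer than 3 usable points in ", path, call. = FALSE)
  solute_profile(solute, depth, value, resolution = resolution,
                 core_id = core_id, treatment = treatment,
                 timepoint_day = timepoint_day,
                 profile_replicate = profile_replicate)
}

#' Write a profile to a two-column delimited file
#'
#' Writes depth (mm) and value with 17 significant digits so that a
#' subsequent [read_profile] reproduces the numbers exactly.
#'
#' @param p a [solute_profile].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  stopifnot(inherits(p, "solute_profile"))
  hdr <- sprintf("# %s profile, core %s, treatment %s, day %s, replicate %s",
                 p$solute, p$core_id, p$treatment, p$timepoint_day,
                 p$profile_replicate)
  rows <- sprintf("%.17g\t%.17g", p$depths, p$values)
  writeLines(c(hdr, "depth_mm\tvalue", rows), path)
  invisible(path)
}

#' Pair two profiles on a common depth grid
#'
#' Linearly interpolates `profile_b` onto the depths of `profile_a`,
#' dropping `profile_a` depths outside `profile_b`'s range. Needed because
#' pH/H2S share a 250 um grid while O2 uses 100 um, and real grids may be
#' offset between sensors.
#'
#' @param profile_a grid-defining [solute_profile].
#' @param profile_b profile to interpolate onto `profile_a`'s depths.
#' @return a data.frame with columns `depth`, `a`, `b`.
#' @export
align_to_grid <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "solute_profile"),
            inherits(profile_b, "solute_profile"))
  rb <- range(profile_b$depths)
  in_range <- profile_a$depths >= rb[1] & profile_a$depths <= rb[2]
  if (!any(in_range))
    stop("profiles have no overlapping depth range", call. = FALSE)
  d <- profile_a$depths[in_range]
  b <- stats::approx(profile_b$depths, profile_b$values, xout = d,
                     method = "linear", ties = "ordered")$y
  data.frame(depth = d, a = profile_a$values[in_range], b = b)
}

#' Write a results summary table
#'
#' Writes a data.frame as comma-separated text with numeric columns at
#' 17 significant digits, so [read_summary] round-trips values exactly.
#'
#' @param results a data.frame (one row per core x timepoint in the
#'   pipeline's use).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- results
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- NA_character_
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read back a summary table written by [write_summary]
#'
#' @param path file to read.
#' @return a data.frame.
#' @export
read_summary <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
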