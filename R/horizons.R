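# Threshold-horizon detection shared by OPD and sulfide horizon.
#
# direction "below": shallowest non-negative depth d such that every reading
# at depths >= d is < threshold (the "steadily below" rule used for the
# oxygen penetration depth); direction "above" is the mirror used for the
# sulfide horizon. run_length = Inf demands the condition hold down to the
# profile bottom (terminal run); a finite k accepts the first run of k
# consecutive conforming points, which is robust to noise at depth.
.threshold_horizon <- function(depths, values, threshold, direction,
                               run_length = Inf) {
  stopifnot(direction %in% c("below", "above"))
  sel <- depths >= 0
  if (!any(sel))
    stop("profile has no points at or below the interface (depth >= 0)",
         call. = FALSE)
  d <- depths[sel]; v <- values[sel]
  cond <- if (direction == "below") v < threshold else v > threshold
  n <- length(cond)

  if (is.infinite(run_length)) {
    if (!cond[n]) {
      out <- NA_real_
      attr(out, "flag") <- if (direction == "below")
        "no penetration limit reached" else "no horizon reached"
      return(out)
    }
    # start of the terminal conforming run
    i0 <- n
    while (i0 > 1 && cond[i0 - 1]) i0 <- i0 - 1
  } else {
    if (run_length < 1) stop("run_length must be >= 1", call. = FALSE)
    k <- min(run_length, n)
    runs <- rle(cond)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hit <- which(runs$values & runs$lengths >= k)
    if (!length(hit)) {
      out <- NA_real_
      attr(out, "flag") <- if (direction == "below")
        "no penetration limit reached" else "no horizon reached"
      return(out)
    }
    i0 <- starts[hit[1]]
  }

  if (i0 == 1) {
    out <- d[1]
    attr(out, "flag") <- if (direction == "below")
      "sub-threshold from the first point" else "euxinic surface"
    return(out)
  }
  # sub-grid refinement: linear interpolation at the threshold crossing
  # between the last non-conforming point and the first point of the run
  d1 <- d[i0 - 1]; v1 <- v[i0 - 1]
  d2 <- d[i0];     v2 <- v[i0]
  out <- d1 + (threshold - v1) / (v2 - v1) * (d2 - d1)
  attr(out, "flag") <- NA_character_
  out
}

#' Oxygen penetration depth
#'
#' The depth below which porewater O2 stays steadily under a detection
#' threshold (1 uM by default). Operationalised as the start of the
#' terminal sub-threshold run — every measured value deeper than the
#' returned depth is below the threshold — refined to sub-grid precision by
#' linear interpolation at the threshold crossing. A single sub-threshold
#' dip followed by recovery does not set the OPD. For noisy profiles a
#' finite `run_length` k accepts the first run of k consecutive
#' sub-threshold points instead of requiring the run to reach the profile
#' bottom.
#'
#' @param o2_profile a [solute_profile] with solute `"O2"`.
#' @param threshold detection threshold (uM), default 1.
#' @param run_length `Inf` (terminal-run rule, default) or a minimum run
#'   length in points.
#' @return depth in mm, or `NA` if oxygen persists to the profile bottom;
#'   carries a `flag` attribute (`NA`, `"no penetration limit reached"`, or
#'   `"sub-threshold from the first point"` when already anoxic at the
#'   first non-negative depth).
#' @export
oxygen_penetration_depth <- function(o2_profile, threshold = 1,
                                     run_length = Inf) {
  stopifnot(inherits(o2_profile, "solute_profile"))
  .threshold_horizon(o2_profile$depths, o2_profile$values, threshold,
                     "below", run_length)
}

#' Sulfide horizon
#'
#' The shallowest depth at which dissolved sulfide becomes detectable
#' (> 1 uM by default): mirror of the OPD rule, the start of the terminal
#' supra-threshold run, interpolated at the crossing. By default computed
#' on the total-sulfide profile; pass a raw H2S [solute_profile] to use the
#' gas species instead.
#'
#' @param profile a `speciated_profile` (total sulfide is used) or a
#'   [solute_profile].
#' @param threshold detection threshold (uM), default 1.
#' @param run_length as in [oxygen_penetration_depth].
#' @return depth in mm or `NA`, with a `flag` attribute (`"euxinic
#'   surface"` when sulfide exceeds the threshold already at the first
#'   non-negative depth).
#' @export
sulfide_horizon <- function(profile, threshold = 1, run_length = Inf) {
  if (inherits(profile, "speciated_profile")) {
    d <- profile$depths; v <- profile$total
  } else if (inherits(profile, "solute_profile")) {
    d <- profile$depths; v <- profile$values
  } else stop("profile must be a speciated_profile or solute_profile",
              call. = FALSE)
  .threshold_horizon(d, v, threshold, "above", run_length)
}

#' Relative increase in oxidized sediment volume
#'
#' The sulfide horizon depth equals the oxidized, sulfide-free sediment
#' volume per unit area, so the relative volume change between a treatment
#' and the control is the relative change in horizon depth.
#'
#' @param horizon_treatment,horizon_control sulfide horizon depths (mm),
#'   both > 0.
#' @return percent change, `100 * (treatment - control) / control`.
#' @examples
#' oxidized_volume_increase(6.4, 3.8)  # 68.4 -> "68%" at integer rounding
#' @export
oxidized_volume_increase <- function(horizon_treatment, horizon_control) {
  if (!is.finite(horizon_treatment) || !is.finite(horizon_control))
    stop("horizons must be finite", call. = FALSE)
  if (horizon_control <= 0)
    stop("control horizon must be > 0 (relative change undefined)",
         call. = FALSE)
  100 * (horizon_treatment - horizon_control) / horizon_control
}

#' Width of the suboxic separation zone
#'
#' The layer between the oxygen penetration depth and the sulfide horizon
#' where neither O2 nor free sulfide is detectable.
#'
#' @param opd oxygen penetration depth (mm) or `NA`.
#' @param sulfide_horizon sulfide horizon depth (mm) or `NA`.
#' @return `sulfide_horizon - opd` in mm (negative widths carry an
#'   `"overlapping oxic and sulfidic zones"` flag attribute), or `NA` if
#'   either input is absent.
#' @export
suboxic_width <- function(opd, sulfide_horizon) {
  if (is.na(opd) || is.na(sulfide_horizon)) {
    out <- NA_real_
    attr(out, "flag") <- "opd or horizon absent"
    return(out)
  }
  out <- as.numeric(sulfide_horizon) - as.numeric(opd)
  attr(out, "flag") <- if (out < 0) "overlapping oxic and sulfidic zones"
                       else NA_character_
  out
}

#' Zone geometry of one core at one time point
#'
#' Bundles OPD, sulfide horizon and suboxic width with the detection
#' settings used.
#'
#' @param o2_profile [solute_profile] of O2.
#' @param sulfide profile for [sulfide_horizon] (speciated or raw).
#' @param threshold_o2,threshold_h2s detection thresholds (uM).
#' @param run_length see [oxygen_penetration_depth].
#' @return an object of class `horizon_result`: list with `opd`,
#'   `sulfide_horizon`, `suboxic_width`, `flags`, `threshold_used`,
#'   `persistence_rule`.
#' @export
horizon_result <- function(o2_profile, sulfide, threshold_o2 = 1,
                           threshold_h2s = 1, run_length = Inf) {
  opd <- oxygen_penetration_depth(o2_profile, threshold_o2, run_length)
  sh <- sulfide_horizon(sulfide, threshold_h2s, run_length)
  sw <- suboxic_width(opd, sh)
  flags <- c(opd = attr(opd, "flag"), sulfide_horizon = attr(sh, "flag"),
             suboxic = attr(sw, "flag"))
  structure(
    list(opd = as.numeric(opd), sulfide_horizon = as.numeric(sh),
         suboxic_width = as.numeric(sw), flags = flags[!is.na(flags)],
         threshold_used = c(o2 = threshold_o2, h2s = threshold_h2s),
         persistence_rule = if (is.infinite(run_length)) "terminal run"
                            else paste0(run_length, " consecutive points")),
    class = "horizon_result")
}

#' @export
print.horizon_result <- function(x, ...) {
  cat(sprintf("<horizon_result> OPD %.2f mm, sulfide horizon %.2f mm, suboxic width %.2f mm (%s)\n",
              x$opd, x$sulfide_horizon, x$suboxic_width, x$persistence_rule))
  if (length(x$flags)) cat("  flags:", paste(names(x$flags), x$flags,
                                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}
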