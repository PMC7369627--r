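#' Fit a near-interface concentration gradient
#'
#' Ordinary least squares of concentration on depth over a selected depth
#' window, on the depth-down axis (depth in mm, positive downward). The
#' slope is reported both in sensor units (uM per mm) and in SI flux units
#' (mmol m-4; 1 uM mm-1 = 1e3 mmol m-4, since 1 uM = 1 mmol m-3 and
#' 1 mm = 1e-3 m).
#'
#' @param profile a [solute_profile] (or a `speciated_profile`, in which
#'   case the total-sulfide series is fitted).
#' @param window numeric length-2, `c(depth_min, depth_max)` in mm; points
#'   with `depth_min <= depth <= depth_max` enter the fit.
#' @param r2_floor fits with r-squared below this value are flagged
#'   (`low_r2 = TRUE`), never rejected. Default 0.9.
#' @return an object of class `gradient_fit`: `slope` (mmol m-4),
#'   `slope_uM_mm`, `intercept` (uM), `window`, `n_points`, `r2`, `low_r2`.
#' @examples
#' p <- solute_profile("O2", c(0, 0.1, 0.2, 0.3), c(300, 280, 260, 240))
#' fit_gradient(p, c(0, 0.3))$slope  # -200 uM/mm = -2e5 mmol m-4
#' @export
fit_gradient <- function(profile, window, r2_floor = 0.9) {
  if (inherits(profile, "speciated_profile")) {
    d <- profile$depths; v <- profile$total
  } else if (inherits(profile, "solute_profile")) {
    d <- profile$depths; v <- profile$values
  } else stop("profile must be a solute_profile or speciated_profile",
              call. = FALSE)
  stopifnot(is.numeric(window), length(window) == 2)
  if (window[1] > window[2]) window <- rev(window)
  sel <- d >= window[1] - 1e-9 & d <= window[2] + 1e-9
  n <- sum(sel)
  if (n < 2)
    stop("gradient window [", window[1], ", ", window[2],
         "] mm selects fewer than 2 points", call. = FALSE)
  x <- d[sel]; y <- v[sel]
  fit <- stats::lm(y ~ x)
  slope_uM_mm <- unname(stats::coef(fit)[2])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(slope = slope_uM_mm * 1e3, slope_uM_mm = slope_uM_mm,
         intercept = unname(stats::coef(fit)[1]),
         window = c(depth_min = window[1], depth_max = window[2]),
         window_mean_depth = mean(x), n_points = n, r2 = r2,
         low_r2 = is.finite(r2) && r2 < r2_floor),
    class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf(
    "<gradient_fit> slope %.4g mmol m-4 (%.4g uM/mm) over [%.2f, %.2f] mm, n = %d, r2 = %.4f%s\n",
    x$slope, x$slope_uM_mm, x$window[1], x$window[2], x$n_points, x$r2,
    if (isTRUE(x$low_r2)) " [low r2]" else ""))
  invisible(x)
}

#' Default O2 fit window: interface to 60% of the OPD
#'
#' The upper part of the oxic zone is the quasi-linear diffusive zone;
#' fitting to 60% of the oxygen penetration depth avoids the curved landing
#' near the OPD.
#'
#' @param opd oxygen penetration depth (mm).
#' @param fraction fraction of the OPD to include (default 0.6).
#' @return `c(0, fraction * opd)`.
#' @export
o2_fit_window <- function(opd, fraction = 0.6) {
  if (is.na(opd) || opd <= 0)
    stop("o2_fit_window needs a positive OPD", call. = FALSE)
  c(0, fraction * opd)
}

#' Default sulfide fit window: first 1 mm below the sulfide horizon
#'
#' @param horizon sulfide horizon depth (mm).
#' @param width window width below the horizon (mm, default 1.0).
#' @return `c(horizon, horizon + width)`.
#' @export
h2s_fit_window <- function(horizon, width = 1.0) {
  if (is.na(horizon))
    stop("h2s_fit_window needs a sulfide horizon", call. = FALSE)
  c(horizon, horizon + width)
}

#' Diffusive flux across the sediment-water interface (Fick's first law)
#'
#' \deqn{J = -\phi (D_s + D_b) \frac{\partial C}{\partial x}}
#' evaluated on the depth-down axis, where the sign flip of the axis
#' cancels the leading minus: `J = phi * (Ds + Db) * slope` with `slope`
#' the regression slope of concentration on downward depth. The sign
#' convention is interface-upward: sediment uptake is negative (O2, which
#' decreases downward) and efflux toward the water positive (total
#' sulfide, which increases downward). Units mmol m-2 d-1.
#'
#' @param context a [core_context] (supplies porosity).
#' @param diffusivity a [diffusivity_model] for the profile's solute.
#' @param gradient a [fit_gradient] result.
#' @param convention `"as_printed"` applies the outer porosity factor of
#'   the flux law as written above; `"no_outer_porosity"` omits it
#'   (`J = (Ds + Db) * slope`), a convention some diagenesis texts use.
#' @return an object of class `flux_result`: `solute`, `flux`
#'   (mmol m-2 d-1), `gradient_fit`, `diffusivity`, `convention`,
#'   `core_id`.
#' @export
diffusive_flux <- function(context, diffusivity, gradient,
                           convention = c("as_printed",
                                          "no_outer_porosity")) {
  convention <- match.arg(convention)
  stopifnot(inherits(context, "core_context"),
            inherits(diffusivity, "diffusivity_model"),
            inherits(gradient, "gradient_fit"))
  phi_factor <- if (convention == "as_printed") context$porosity else 1
  j <- phi_factor * (diffusivity$d_s + diffusivity$d_b) * gradient$slope
  structure(
    list(solute = diffusivity$solute, flux = j, gradient_fit = gradient,
         diffusivity = diffusivity, convention = convention,
         core_id = context$core_id),
    class = "flux_result")
}

#' @export
print.flux_result <- function(x, ...) {
  cat(sprintf(
    "<flux_result> %s: J = %.3g mmol m-2 d-1 (core %s, %s convention)\n",
    x$solute, x$flux, x$core_id, x$convention))
  invisible(x)
}
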