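#' First dissociation constant of hydrogen sulfide in seawater
#'
#' Computes pK1 of H2S <-> H+ + HS- as a function of temperature and
#' salinity, using the seawater formulation of Millero et al. (1988):
#' \deqn{\ln K_1 = 225.838 - 13275.3/T - 34.6435 \ln T + 0.3449 S^{1/2} - 0.0274 S}
#' with T in kelvin. The constant is on the pH scale of NBS-buffer-calibrated
#' sensors; no scale conversion is applied. Reference values: pK1 = 6.51 at
#' 25 degC, S = 35 and 6.98 at 25 degC, S = 0.
#'
#' @param temperature degrees Celsius; the formulation is applied over
#'   0-35 degC.
#' @param salinity practical salinity, 0-40.
#' @return pK1 (dimensionless), with attribute `source` naming the
#'   formulation.
#' @references Millero, F.J., Plese, T., Fernandez, M. (1988). The
#'   dissociation of hydrogen sulfide in seawater. Limnology and
#'   Oceanography 33, 269-274.
#' @examples
#' pk1_h2s(25, 35)  # 6.51
#' @export
pk1_h2s <- function(temperature, salinity) {
  if (any(!is.finite(temperature)) || any(!is.finite(salinity)))
    stop("non-finite temperature or salinity", call. = FALSE)
  if (any(temperature < 0 | temperature > 35))
    stop("temperature outside the formulation's validity range 0-35 degC",
         call. = FALSE)
  if (any(salinity < 0 | salinity > 40))
    stop("salinity outside the formulation's validity range 0-40",
         call. = FALSE)
  tk <- temperature + 273.15
  lnk <- 225.838 - 13275.3 / tk - 34.6435 * log(tk) +
    0.3449 * sqrt(salinity) - 0.0274 * salinity
  pk1 <- -lnk / log(10)
  attr(pk1, "source") <- "Millero et al. (1988) seawater H2S pK1"
  pk1
}

#' Speciation parameters for total-sulfide calculation
#'
#' @param temperature degrees Celsius.
#' @param salinity practical salinity.
#' @param pk1_override optional pK1 to use instead of the computed one
#'   (e.g. to reproduce an alternative formulation exactly).
#' @return an object of class `speciation_params` with elements
#'   `temperature`, `salinity`, `pk1`, `pk1_source`.
#' @export
speciation_params <- function(temperature, salinity, pk1_override = NULL) {
  if (!is.null(pk1_override)) {
    if (!is.finite(pk1_override))
      stop("pk1_override must be finite", call. = FALSE)
    pk1 <- pk1_override
    src <- "user override"
  } else {
    pk1 <- pk1_h2s(temperature, salinity)
    src <- attr(pk1, "source")
    if (pk1 <= 5.5 || pk1 >= 8.5)
      stop("computed pK1 = ", round(pk1, 3),
           " outside the plausible range (5.5, 8.5)", call. = FALSE)
  }
  structure(list(temperature = temperature, salinity = salinity,
                 pk1 = as.numeric(pk1), pk1_source = src),
            class = "speciation_params")
}

#' Total dissolved sulfide from the gas species and pH
#'
#' Given the sensor-measured gas species concentration \[H2S\] and the pH at
#' the same depth, returns the dissociated species and the total:
#' \deqn{[HS^-] = [H_2S] \cdot 10^{pH - pK_1}, \quad
#'       \Sigma H_2S = [H_2S](1 + 10^{pH - pK_1}).}
#'
#' @param h2s_gas \[H2S\] in uM, >= 0 (clip sensor noise before calling).
#' @param ph pH at the same depth.
#' @param pk1 first dissociation constant (see [pk1_h2s]).
#' @return a list with vectors `hs_minus` and `total` (uM).
#' @examples
#' total_sulfide(5, 7.5, 6.9)$total  # 5 * (1 + 10^0.6) = 24.91 uM
#' @export
total_sulfide <- function(h2s_gas, ph, pk1) {
  if (any(!is.finite(h2s_gas)) || any(!is.finite(ph)) || !is.finite(pk1))
    stop("non-finite input to total_sulfide", call. = FALSE)
  if (any(h2s_gas < 0))
    stop("h2s_gas must be >= 0; clip negative sensor noise first",
         call. = FALSE)
  hs <- h2s_gas * 10^(ph - pk1)
  list(hs_minus = hs, total = h2s_gas + hs)
}

#' Speciate a full H2S profile against its paired pH profile
#'
#' Interpolates the pH profile onto the H2S depth grid (see
#' [align_to_grid]), clips negative H2S readings to zero (counted in the
#' diagnostics), and applies [total_sulfide] pointwise.
#'
#' @param h2s_profile [solute_profile] of the H2S sensor (gas species, uM).
#' @param ph_profile paired [solute_profile] of pH, same core and timepoint.
#' @param params a [speciation_params].
#' @return an object of class `speciated_profile` with `depths`, `h2s_gas`
#'   (clipped), `hs_minus`, `total`, `ph_used`, `n_clipped`, `pk1`, plus the
#'   core metadata of the H2S profile.
#' @export
speciate_profile <- function(h2s_profile, ph_profile, params) {
  stopifnot(inherits(h2s_profile, "solute_profile"),
            inherits(ph_profile, "solute_profile"),
            inherits(params, "speciation_params"))
  if (h2s_profile$solute != "H2S" || ph_profile$solute != "pH")
    stop("speciate_profile needs an H2S profile and a pH profile",
         call. = FALSE)
  if (!is.na(h2s_profile$core_id) && !is.na(ph_profile$core_id) &&
      (h2s_profile$core_id != ph_profile$core_id ||
       !identical(h2s_profile$timepoint_day, ph_profile$timepoint_day)))
    stop("H2S and pH profiles are from different cores or time points",
         call. = FALSE)
  paired <- align_to_grid(h2s_profile, ph_profile)
  n_clipped <- sum(paired$a < 0)
  h2s <- pmax(paired$a, 0)
  sp <- total_sulfide(h2s, paired$b, params$pk1)
  structure(
    list(depths = paired$depth, h2s_gas = h2s, hs_minus = sp$hs_minus,
         total = sp$total, ph_used = paired$b, n_clipped = n_clipped,
         pk1 = params$pk1, core_id = h2s_profile$core_id,
         treatment = h2s_profile$treatment,
         timepoint_day = h2s_profile$timepoint_day,
         profile_replicate = h2s_profile$profile_replicate,
         resolution = h2s_profile$resolution),
    class = "speciated_profile")
}

#' @export
print.speciated_profile <- function(x, ...) {
  cat(sprintf(
    "<speciated_profile> core %s day %s: %d depths, max total sulfide %.3g uM (pK1 %.3f, %d clipped)\n",
    x$core_id, x$timepoint_day, length(x$depths), max(x$total), x$pk1,
    x$n_clipped))
  invisible(x)
}

#' Convert a speciated profile to a total-sulfide solute_profile
#'
#' Convenience for feeding the total into horizon detection and gradient
#' fitting, which operate on [solute_profile] objects.
#'
#' @param sp a `speciated_profile`.
#' @return a [solute_profile] with solute `"H2S"` and values = total sulfide.
#' @export
as_total_profile <- function(sp) {
  stopifnot(inherits(sp, "speciated_profile"))
  solute_profile("H2S", sp$depths, sp$total, resolution = sp$resolution,
                 core_id = sp$core_id, treatment = sp$treatment,
                 timepoint_day = sp$timepoint_day,
                 profile_replicate = sp$profile_replicate)
}
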