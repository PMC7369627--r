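#' Convert a diffusion coefficient from cm2/s to m2/d
#'
#' `1 cm2 s-1 = 1e-4 m2 s-1 * 86400 s d-1 = 8.64 m2 d-1`.
#'
#' @param value coefficient(s).
#' @param from `"cm2_s"` or `"m2_d"` (identity).
#' @return coefficient in m2 d-1.
#' @export
convert_diffusivity <- function(value, from = c("cm2_s", "m2_d")) {
  from <- match.arg(from)
  if (from == "cm2_s") value * 8.64 else value
}

# Built-in free-solution diffusion coefficients, linear in temperature
# (D0 = (m0 + m1 * t) * 1e-6 cm2 s-1, t in degC), fitted to the standard
# compilations of dissolved-gas diffusivities in water (Boudreau 1997,
# Diagenetic Models and Their Implementation, ch. 4). Salinity dependence
# (< 5% over 0-35) is not applied; supply your own table for precision work.
.dmol_table <- list(
  O2  = c(m0 = 11.7, m1 = 0.344),
  H2S = c(m0 = 10.3, m1 = 0.273)
)

#' Free-solution molecular diffusion coefficient
#'
#' Returns Dmol for a solute at in-situ temperature, from a built-in
#' linear-in-temperature fit to standard compilations, or from a
#' user-supplied per-solute table.
#'
#' @param solute `"O2"` or `"H2S"` (for the total-sulfide flux the H2S
#'   coefficient is used; H2S and HS- diffuse at nearly the same rate).
#' @param temperature degrees Celsius, 0-30 for the built-in fits.
#' @param table optional named list/vector giving Dmol per solute directly;
#'   units declared by `units`.
#' @param units units of a user-supplied `table`: `"cm2_s"` or `"m2_d"`.
#' @return Dmol in m2 d-1.
#' @export
molecular_diffusivity <- function(solute, temperature, table = NULL,
                                  units = c("cm2_s", "m2_d")) {
  units <- match.arg(units)
  if (!is.null(table)) {
    if (is.null(table[[solute]]))
      stop("no Dmol entry for solute ", solute, " in supplied table",
           call. = FALSE)
    return(convert_diffusivity(as.numeric(table[[solute]]), units))
  }
  cf <- .dmol_table[[solute]]
  if (is.null(cf))
    stop("no built-in Dmol for solute ", solute,
         "; supply a table", call. = FALSE)
  if (!is.finite(temperature) || temperature < 0 || temperature > 30)
    stop("built-in Dmol fits cover 0-30 degC, got ", temperature,
         call. = FALSE)
  d0_cm2_s <- (cf["m0"] + cf["m1"] * temperature) * 1e-6
  convert_diffusivity(unname(d0_cm2_s), "cm2_s")
}

#' Sediment diffusivity from porosity
#'
#' \deqn{D_s = \phi^2 D_{mol}} — the porosity-squared tortuosity correction.
#'
#' @param d_mol free-solution diffusion coefficient (m2 d-1), > 0.
#' @param phi porosity, in (0, 1).
#' @return Ds in m2 d-1 (always <= Dmol).
#' @export
sediment_diffusivity <- function(d_mol, phi) {
  if (!is.finite(phi) || phi <= 0 || phi >= 1)
    stop("porosity must lie in (0, 1), got ", phi, call. = FALSE)
  if (!is.finite(d_mol) || d_mol <= 0)
    stop("d_mol must be > 0", call. = FALSE)
  phi^2 * d_mol
}

#' Fit the biodiffusivity-vs-abundance calibration line
#'
#' Ordinary least squares of published biodiffusivity (Db) values against
#' the meiofauna abundances at which they were determined. The fitted line
#' is used to extrapolate a working Db for each core from its measured
#' abundance.
#'
#' @param reference_points data.frame with columns `abundance`
#'   (individuals per 10 cm2) and `db` (m2 d-1), at least two distinct
#'   abundances.
#' @return an object of class `biodiffusivity_fit`: list with `slope`,
#'   `intercept`, `r2`, `reference_points`.
#' @seealso [db_reference_synthetic] for a placeholder calibration.
#' @export
fit_biodiffusivity <- function(reference_points) {
  stopifnot(is.data.frame(reference_points),
            all(c("abundance", "db") %in% names(reference_points)))
  x <- as.numeric(reference_points$abundance)
  y <- as.numeric(reference_points$db)
  if (length(unique(x)) < 2)
    stop("need at least 2 reference points with distinct abundances",
         call. = FALSE)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2, reference_points = reference_points),
    class = "biodiffusivity_fit")
}

#' @export
print.biodiffusivity_fit <- function(x, ...) {
  cat(sprintf(
    "<biodiffusivity_fit> Db = %.3g + %.3g * abundance (m2/d; r2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r2, nrow(x$reference_points)))
  invisible(x)
}

#' Working biodiffusivity for a given meiofauna abundance
#'
#' Evaluates the calibration line; negative predictions are clipped to 0
#' (flagged via the `clipped` attribute).
#'
#' @param fit a [fit_biodiffusivity] result.
#' @param abundance individuals per 10 cm2, >= 0.
#' @return Db in m2 d-1, >= 0.
#' @export
db_for_abundance <- function(fit, abundance) {
  stopifnot(inherits(fit, "biodiffusivity_fit"))
  if (any(abundance < 0)) stop("abundance must be >= 0", call. = FALSE)
  raw <- fit$intercept + fit$slope * abundance
  out <- pmax(raw, 0)
  attr(out, "clipped") <- raw < 0
  out
}

#' Placeholder biodiffusivity calibration (synthetic)
#'
#' A SYNTHETIC stand-in for a published meiofauna Db calibration: four
#' (abundance, Db) pairs with magnitudes chosen so that Db at high
#' meiofauna abundance is comparable to the sediment diffusivity of O2
#' (meiofauna activity roughly doubling near-surface solute transport).
#' Use real literature values for any scientific application; this table
#' exists so the pipeline and its tests are runnable end to end.
#'
#' @return data.frame with columns `abundance` (ind. per 10 cm2) and `db`
#'   (m2 d-1).
#' @export
db_reference_synthetic <- function() {
  data.frame(abundance = c(100, 500, 1000, 2000),
             db = c(1.0e-5, 3.5e-5, 6.5e-5, 1.2e-4))
}

#' Assemble the diffusivity model for one solute in one core
#'
#' @param solute `"O2"` or `"H2S"`.
#' @param d_mol free-solution coefficient (m2 d-1), e.g. from
#'   [molecular_diffusivity].
#' @param phi porosity.
#' @param d_b biodiffusivity (m2 d-1), e.g. from [db_for_abundance];
#'   0 reproduces the pure-molecular-diffusion case.
#' @return an object of class `diffusivity_model` with `d_s = phi^2 * d_mol`.
#' @export
diffusivity_model <- function(solute, d_mol, phi, d_b = 0) {
  if (!is.finite(d_b) || d_b < 0) stop("d_b must be >= 0", call. = FALSE)
  d_s <- sediment_diffusivity(d_mol, phi)
  structure(list(solute = solute, d_mol = d_mol, d_s = d_s, d_b = d_b,
                 phi = phi),
            class = "diffusivity_model")
}

#' @export
print.diffusivity_model <- function(x, ...) {
  cat(sprintf(
    "<diffusivity_model> %s: Dmol %.3g, Ds %.3g, Db %.3g m2/d (phi %.3f)\n",
    x$solute, x$d_mol, x$d_s, x$d_b, x$phi))
  invisible(x)
}
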