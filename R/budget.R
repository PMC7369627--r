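#' Oxygen equivalent of an upward sulfide flux
#'
#' Complete oxidation of sulfide to sulfate consumes two moles of O2 per
#' mole of sulfide (O2:S stoichiometry 2:1), so an upward total-sulfide
#' flux `j_h2s` implies an O2 consumption of `-stoichiometry * j_h2s`.
#'
#' @param j_h2s upward total-sulfide flux (mmol m-2 d-1), >= 0.
#' @param stoichiometry moles of O2 consumed per mole of sulfide
#'   (default 2).
#' @return O2 consumption attributable to sulfide oxidation
#'   (mmol m-2 d-1, <= 0).
#' @examples
#' sulfide_o2_equivalent(8.8)  # -17.6
#' sulfide_o2_equivalent(0.4)  # -0.8
#' @export
sulfide_o2_equivalent <- function(j_h2s, stoichiometry = 2.0) {
  if (any(!is.finite(j_h2s))) stop("j_h2s must be finite", call. = FALSE)
  if (any(j_h2s < 0))
    stop("j_h2s must be >= 0: a downward sulfide flux is outside this ",
         "budget's model", call. = FALSE)
  if (!is.finite(stoichiometry) || stoichiometry < 0)
    stop("stoichiometry must be >= 0", call. = FALSE)
  -stoichiometry * j_h2s
}

#' Fraction of sediment O2 uptake spent oxidizing sulfide
#'
#' @param j_h2s upward total-sulfide flux (mmol m-2 d-1), >= 0.
#' @param j_o2 total O2 flux (mmol m-2 d-1), < 0 (uptake).
#' @param stoichiometry O2 per S (default 2).
#' @return percent of `|j_o2|`, unrounded, with attribute `rounded` giving
#'   the integer-percent presentation value.
#' @examples
#' sulfide_fraction_of_o2(8.8, -58)  # 30.34 -> "ca. 30%"
#' sulfide_fraction_of_o2(0.4, -42)  # 1.90  -> "2%"
#' @export
sulfide_fraction_of_o2 <- function(j_h2s, j_o2, stoichiometry = 2.0) {
  if (any(!is.finite(j_h2s)) || any(!is.finite(j_o2)))
    stop("fluxes must be finite", call. = FALSE)
  if (any(j_o2 == 0))
    stop("j_o2 = 0: fraction undefined", call. = FALSE)
  if (any(j_o2 > 0))
    stop("j_o2 must be < 0 (sediment O2 uptake)", call. = FALSE)
  if (any(j_h2s < 0)) stop("j_h2s must be >= 0", call. = FALSE)
  out <- 100 * (stoichiometry * j_h2s) / abs(j_o2)
  attr(out, "rounded") <- round(out)
  out
}

#' Partition sediment oxygen consumption by sulfide oxidation
#'
#' Assembles the stoichiometric oxygen budget of one core at one time
#' point from its O2 and total-sulfide flux results: the O2 consumption
#' attributable to sulfide oxidation, the residual O2 consumption (other
#' oxidants, nitrification, etc.), and the sulfide fraction of total
#' uptake.
#'
#' @param flux_o2 [diffusive_flux] result for O2 (flux < 0), or a bare
#'   numeric flux.
#' @param flux_h2s [diffusive_flux] result for total sulfide (flux >= 0),
#'   or a bare numeric flux.
#' @param stoichiometry O2 per S (default 2).
#' @return an object of class `oxygen_budget` with `j_o2`, `j_h2s`,
#'   `stoichiometry`, `o2_for_sulfide`, `residual_o2`, `sulfide_fraction`
#'   (percent, unrounded), `sulfide_fraction_rounded`, and
#'   `inconsistent` (TRUE when the fraction exceeds 100%).
#' @examples
#' b <- build_budget(-58, 8.8)
#' b$o2_for_sulfide      # -17.6
#' b$residual_o2         # -40.4
#' b$sulfide_fraction    # 30.34
#' @export
build_budget <- function(flux_o2, flux_h2s, stoichiometry = 2.0) {
  core <- NA_character_
  if (inherits(flux_o2, "flux_result") && inherits(flux_h2s, "flux_result")) {
    if (!is.na(flux_o2$core_id) && !is.na(flux_h2s$core_id) &&
        flux_o2$core_id != flux_h2s$core_id)
      stop("O2 and sulfide fluxes are from different cores", call. = FALSE)
    core <- flux_o2$core_id
  }
  j_o2 <- if (inherits(flux_o2, "flux_result")) flux_o2$flux else flux_o2
  j_h2s <- if (inherits(flux_h2s, "flux_result")) flux_h2s$flux else flux_h2s
  o2s <- sulfide_o2_equivalent(j_h2s, stoichiometry)
  frac <- sulfide_fraction_of_o2(j_h2s, j_o2, stoichiometry)
  structure(
    list(core_id = core, j_o2 = j_o2, j_h2s = j_h2s,
         stoichiometry = stoichiometry,
         o2_for_sulfide = o2s, residual_o2 = j_o2 - o2s,
         sulfide_fraction = as.numeric(frac),
         sulfide_fraction_rounded = attr(frac, "rounded"),
         inconsistent = as.numeric(frac) > 100),
    class = "oxygen_budget")
}

#' @export
print.oxygen_budget <- function(x, ...) {
  cat(sprintf(
    "<oxygen_budget> J_O2 %.3g, J_H2S %.3g mmol m-2 d-1 (O2:S = %g:1)\n",
    x$j_o2, x$j_h2s, x$stoichiometry))
  cat(sprintf("  sulfide-driven O2 consumption %.3g (%.3g%% of uptake%s); residual %.3g\n",
              x$o2_for_sulfide, x$sulfide_fraction,
              if (isTRUE(x$inconsistent)) ", INCONSISTENT > 100%" else "",
              x$residual_o2))
  invisible(x)
}
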