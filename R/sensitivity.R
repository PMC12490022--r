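#' Partial derivatives of the abatement function
#'
#' Closed-form partial derivatives of the percent abatement
#' `A = (1 - e^(-x)) * 100` with `x = k_O3*O3exp + k_OH*OHexp` with respect
#' to each of its four parameters: `dA/dk_O3 = 100 * O3exp * e^(-x)`,
#' `dA/dO3exp = 100 * k_O3 * e^(-x)`, and symmetrically for the
#' hydroxyl-radical pair. At saturation (`x -> Inf`) all partials vanish:
#' once abatement reaches 100% it no longer depends on any parameter.
#'
#' @inheritParams predict_abatement
#' @return named numeric: `k_o3`, `k_oh`, `o3_exposure`, `oh_exposure`,
#'   each in percent per parameter unit.
#' @export
abatement_partials <- function(k_o3, k_oh, o3_exposure, oh_exposure) {
  stopifnot(k_o3 >= 0, k_oh >= 0, o3_exposure >= 0, oh_exposure >= 0)
  x <- k_o3 * o3_exposure + k_oh * oh_exposure
  e <- exp(-x)
  c(k_o3 = 100 * o3_exposure * e,
    k_oh = 100 * oh_exposure * e,
    o3_exposure = 100 * k_o3 * e,
    oh_exposure = 100 * k_oh * e)
}

#' Dimensionless sensitivity indices of the abatement model
#'
#' Normalizes the raw partial derivatives into dimensionless indices so the
#' four parameters can be compared despite their different units and
#' scales. Two normalizations are available:
#' \describe{
#'   \item{`elasticity`}{`(dA/dp) * p / A` -- the percent change in
#'     abatement per percent change in the parameter.}
#'   \item{`share_of_total`}{each elasticity divided by the sum of the four
#'     elasticities; the shares sum to 1.}
#' }
#' Because each rate constant enters the model only through its product
#' with the matching exposure, the k/exposure pair within each oxidant has
#' identical elasticities.
#'
#' @inheritParams predict_abatement
#' @param mode `"share_of_total"` (default) or `"elasticity"`.
#' @return object of class `sensitivity_result`: `abatement` (%), `partials`
#'   (raw derivatives), `indices` (named numeric), `mode`.
#' @export
sensitivity_indices <- function(k_o3, k_oh, o3_exposure, oh_exposure,
                                mode = c("share_of_total", "elasticity")) {
  mode <- match.arg(mode)
  a <- predict_abatement(k_o3, k_oh, o3_exposure, oh_exposure)
  if (a <= 0)
    stop("abatement is zero; sensitivity indices are undefined")
  partials <- abatement_partials(k_o3, k_oh, o3_exposure, oh_exposure)
  p <- c(k_o3 = k_o3, k_oh = k_oh, o3_exposure = o3_exposure,
         oh_exposure = oh_exposure)
  elas <- partials * p / a
  idx <- if (mode == "elasticity") elas else elas / sum(elas)
  structure(list(abatement = a, partials = partials, indices = idx,
                 mode = mode), class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> abatement ", sprintf("%.2f%%", x$abatement),
      ", mode ", x$mode, "\n", sep = "")
  print(round(x$indices, 4))
  invisible(x)
}

#' Abatement regime of a compound at a plant
#'
#' Classifies a compound's abatement regime at a given plant from its ozone
#' rate constant: above the plant's saturation threshold the abatement
#' reaches 100% and is independent of the ozone rate constant
#' (`"o3_dominated"`); below the lower threshold ozone barely contributes
#' and the abatement is carried by hydroxyl radicals (`"oh_dominated"`);
#' in between both oxidants matter (`"mixed"`). Rate constants exactly at a
#' threshold are classified `"mixed"`. The thresholds are plant properties
#' (they scale with the exposures) and are stored in the scenario; typical
#' values are 1e3/1e4 M^-1 s^-1 for plants at moderate-to-high specific
#' ozone doses and 1e4/1e7 M^-1 s^-1 for plants at very low doses.
#'
#' @param k_o3 apparent ozone rate constant, M^-1 s^-1.
#' @param scenario a [wwtp_scenario()] carrying `regime_thresholds`.
#' @return one of `"oh_dominated"`, `"mixed"`, `"o3_dominated"`.
#' @export
classify_regime <- function(k_o3, scenario) {
  stopifnot(inherits(scenario, "wwtp_scenario"), k_o3 >= 0)
  thr <- scenario$regime_thresholds
  stopifnot(length(thr) == 2L, thr[1] <= thr[2])
  vapply(k_o3, function(k) {
    if (k > thr[2]) "o3_dominated"
    else if (k < thr[1]) "oh_dominated"
    else "mixed"
  }, character(1))
}
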