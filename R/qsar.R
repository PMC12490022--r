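#' Hammett/Taft structure-reactivity correlation
#'
#' A linear free-energy correlation `log10 k = intercept + rho * sum(sigma)`
#' for one compound family reacting with ozone. Olefin and amine
#' correlations use Taft sigma* constants; benzene, phenol, phenolate and
#' aniline correlations use Hammett sigma+ / sigma- constants. The pairing
#' between family and substituent scale is fixed and validated.
#'
#' Correlation coefficients are not bundled as code constants: they live in
#' an editable parameter file (see [read_qsar_parameters()]); the package
#' ships a clearly labelled synthetic example set for testing.
#'
#' @param family one of `"olefin"`, `"amine"`, `"benzene"`, `"phenol"`,
#'   `"phenolate"`, `"aniline"`.
#' @param intercept intercept in log10(M^-1 s^-1).
#' @param slope susceptibility rho (dimensionless).
#' @param constant_scale substituent scale: `"taft_sigma_star"`,
#'   `"hammett_sigma_plus"` or `"hammett_sigma_minus"`; defaults to the
#'   scale required by the family.
#' @param note free-text applicability note.
#' @return object of class `qsar_correlation`.
#' @export
qsar_correlation <- function(family, intercept, slope,
                             constant_scale = NULL, note = "") {
  family <- match.arg(family, c("olefin", "amine", "benzene", "phenol",
                                "phenolate", "aniline"))
  allowed <- if (family %in% c("olefin", "amine")) "taft_sigma_star"
             else c("hammett_sigma_plus", "hammett_sigma_minus")
  if (is.null(constant_scale)) constant_scale <- allowed[1]
  if (!constant_scale %in% allowed)
    stop("family '", family, "' requires scale ",
         paste(allowed, collapse = " or "), ", got '", constant_scale, "'")
  stopifnot(is.finite(intercept), is.finite(slope))
  structure(list(family = family, intercept = intercept, slope = slope,
                 constant_scale = constant_scale, note = note),
            class = "qsar_correlation")
}

#' Predict a species-specific ozone rate constant from substituent constants
#'
#' Evaluates the correlation at the summed substituent constants:
#' `k = 10^(intercept + rho * sum(sigma))`. The substituent set must be on
#' the scale the correlation was calibrated with.
#'
#' @param correlation a [qsar_correlation()].
#' @param substituents data.frame with columns `label`, `sigma` and
#'   optionally `scale` (validated against the correlation when present),
#'   or a plain numeric vector of sigma values.
#' @return predicted rate constant in M^-1 s^-1.
#' @examples
#' cor <- qsar_correlation("phenol", intercept = 3, slope = -2,
#'                         constant_scale = "hammett_sigma_plus")
#' predict_species_k(cor, data.frame(label = "Cl", sigma = 0.5))
#' @export
predict_species_k <- function(correlation, substituents) {
  stopifnot(inherits(correlation, "qsar_correlation"))
  if (is.numeric(substituents)) {
    sig <- substituents
  } else {
    stopifnot(is.data.frame(substituents), "sigma" %in% names(substituents))
    if ("scale" %in% names(substituents)) {
      bad <- substituents$scale != correlation$constant_scale
      if (any(bad))
        stop("substituent(s) on scale ",
             paste(unique(substituents$scale[bad]), collapse = ", "),
             " do not match correlation scale ", correlation$constant_scale)
    }
    sig <- substituents$sigma
  }
  if (any(!is.finite(sig))) stop("sigma values must be finite")
  10^(correlation$intercept + correlation$slope * sum(sig))
}

#' Speciation-corrected apparent rate-constant prediction
#'
#' Predicts the apparent rate constant of a compound with acid-base
#' speciation at a working pH: each protonation state gets its own
#' correlation and substituent set, the species rate constants are predicted
#' with [predict_species_k()], and the results are weighted by the species
#' fractions from [species_fractions()]. Species (and their correlations)
#' are ordered from most protonated to most deprotonated. A `NULL`
#' correlation entry marks an unreactive species (k = 0), e.g. a protonated
#' amine.
#'
#' @param correlations list of [qsar_correlation()] (or NULL for unreactive
#'   species), one per protonation state.
#' @param substituent_sets list parallel to `correlations` with the
#'   substituent input of [predict_species_k()] per species (ignored for
#'   NULL correlations).
#' @param pka_values pKa ladder (length `length(correlations) - 1`).
#' @param ph working pH.
#' @return apparent rate constant in M^-1 s^-1.
#' @export
predict_apparent_k <- function(correlations, substituent_sets, pka_values,
                               ph) {
  stopifnot(length(correlations) == length(pka_values) + 1L,
            length(substituent_sets) == length(correlations))
  ks <- mapply(function(cor, sub) {
    if (is.null(cor)) 0 else predict_species_k(cor, sub)
  }, correlations, substituent_sets)
  alpha <- species_fractions(pka_values, ph)
  sum(alpha * ks)
}

#' Measured-versus-predicted performance summary
#'
#' Summarizes the agreement between measured and predicted rate constants as
#' log10 ratios `log10(measured/predicted)`, grouped by a label (e.g.
#' prediction route or compound family): group size, mean log10 ratio, and
#' the fractions of compounds agreeing within 1 and 2 orders of magnitude.
#'
#' @param measured,predicted positive numeric vectors of rate constants.
#' @param groups grouping labels (default: one group `"all"`).
#' @param compound_ids optional identifiers carried into the per-compound
#'   table.
#' @return list with `summary` (data.frame: `group`, `n`, `mean_log10_ratio`,
#'   `frac_within_1`, `frac_within_2`) and `per_compound` (data.frame with
#'   the individual `log10_ratio`s).
#' @examples
#' perf <- prediction_performance(measured = c(120, 7), predicted = c(1.2e5, 2.7e8))
#' perf$per_compound$log10_ratio
#' @export
prediction_performance <- function(measured, predicted,
                                   groups = rep("all", length(measured)),
                                   compound_ids = NULL) {
  stopifnot(length(measured) == length(predicted),
            length(groups) == length(measured))
  if (any(measured <= 0) || any(predicted <= 0))
    stop("measured and predicted rate constants must all be > 0")
  lr <- log10(measured / predicted)
  per <- data.frame(
    compound_id = if (is.null(compound_ids))
      paste0("cpd", seq_along(lr)) else compound_ids,
    group = groups, log10_ratio = lr, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1], n = nrow(d),
               mean_log10_ratio = mean(d$log10_ratio),
               frac_within_1 = mean(abs(d$log10_ratio) <= 1),
               frac_within_2 = mean(abs(d$log10_ratio) <= 2),
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(summary = summ, per_compound = per)
}

#' Read a structure-reactivity parameter file
#'
#' Loads correlation coefficients from a YAML (or JSON) file with entries
#' `family`, `intercept`, `slope`, `scale` and optionally `source` /
#' `note`. The package ships a synthetic example at
#' `system.file("extdata", "qsar_correlations_synthetic.yaml",
#' package = "ozonekin")`; substitute a file with calibrated literature
#' coefficients for real predictions.
#'
#' @param path parameter file path.
#' @return named list of [qsar_correlation()] objects (names = family,
#'   disambiguated when a family appears twice).
#' @export
read_qsar_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                         simplifyVector = FALSE)
         else yaml::read_yaml(path)
  if (!is.null(raw$correlations)) raw <- raw$correlations
  cors <- lapply(raw, function(e)
    qsar_correlation(e$family, e$intercept, e$slope,
                     constant_scale = e$scale,
                     note = if (is.null(e$note)) "" else e$note))
  names(cors) <- make.unique(vapply(cors, `[[`, "", "family"))
  cors
}
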