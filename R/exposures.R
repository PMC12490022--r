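#' Treatment-plant ozonation scenario
#'
#' Bundles the exposure and matrix data characterizing one plant's ozonation
#' stage: the specific ozone dose (g O3 per g DOC), the ozone and
#' hydroxyl-radical exposures (M s), the secondary-effluent pH and the
#' hydroxyl-radical scavenger inventory.
#'
#' @param name plant name.
#' @param specific_ozone_dose g O3 / g DOC.
#' @param o3_exposure ozone exposure, M s.
#' @param oh_exposure hydroxyl-radical exposure, M s.
#' @param oh_exposure_sd standard deviation of `oh_exposure`, M s.
#' @param ph secondary-effluent pH.
#' @param scavengers data.frame with columns `species`, `concentration`,
#'   `unit` (one of `"mg_C_per_L"`, `"mmol_per_L"`, `"ug_N_per_L"`,
#'   `"mg_per_L"`).
#' @param o3_uncertainty_fraction half-width of the uniform uncertainty band
#'   on the ozone exposure as a fraction of its value (default 0.8, i.e.
#'   +/- 80%).
#' @param oh_sd_inflation factor applied to `oh_exposure_sd` before Monte
#'   Carlo sampling to reflect matrix variability between sampling
#'   campaigns (default 10).
#' @param regime_thresholds numeric length-2 `(lower, upper)` ozone
#'   rate-constant thresholds (M^-1 s^-1) delimiting the
#'   hydroxyl-radical-dominated / mixed / ozone-dominated abatement regimes
#'   for this plant.
#' @return object of class `wwtp_scenario`.
#' @seealso [read_scenarios()] for the bundled example plants.
#' @export
wwtp_scenario <- function(name, specific_ozone_dose, o3_exposure,
                          oh_exposure, oh_exposure_sd = 0, ph = 8,
                          scavengers = NULL,
                          o3_uncertainty_fraction = 0.8,
                          oh_sd_inflation = 10,
                          regime_thresholds = c(1e3, 1e4)) {
  stopifnot(specific_ozone_dose >= 0, o3_exposure >= 0, oh_exposure >= 0,
            oh_exposure_sd >= 0)
  structure(list(name = name, specific_ozone_dose = specific_ozone_dose,
                 o3_exposure = o3_exposure, oh_exposure = oh_exposure,
                 oh_exposure_sd = oh_exposure_sd, ph = ph,
                 scavengers = scavengers,
                 o3_uncertainty_fraction = o3_uncertainty_fraction,
                 oh_sd_inflation = oh_sd_inflation,
                 regime_thresholds = regime_thresholds),
            class = "wwtp_scenario")
}

#' @export
print.wwtp_scenario <- function(x, ...) {
  cat("<wwtp_scenario> ", x$name, ": ", x$specific_ozone_dose,
      " gO3/gDOC, O3 exposure ", format(x$o3_exposure, digits = 3),
      " M s, OH exposure ", format(x$oh_exposure, digits = 3),
      " M s, pH ", x$ph, "\n", sep = "")
  invisible(x)
}

#' Read plant scenarios from a YAML file
#'
#' @param path YAML file; defaults to the bundled example scenarios
#'   (Altenrhein, Neugut, Werdhoelzli).
#' @return named list of [wwtp_scenario()] objects.
#' @export
read_scenarios <- function(path = system.file("extdata", "scenarios.yaml",
                                              package = "ozonekin")) {
  raw <- yaml::read_yaml(path)
  out <- lapply(raw, function(s) {
    scav <- if (!is.null(s$scavengers))
      do.call(rbind, lapply(s$scavengers, function(v)
        data.frame(species = v$species, concentration = v$concentration,
                   unit = v$unit, stringsAsFactors = FALSE)))
    wwtp_scenario(
      name = s$name, specific_ozone_dose = s$specific_ozone_dose,
      o3_exposure = s$o3_exposure, oh_exposure = s$oh_exposure,
      oh_exposure_sd = if (is.null(s$oh_exposure_sd)) 0 else s$oh_exposure_sd,
      ph = s$ph, scavengers = scav,
      o3_uncertainty_fraction =
        if (is.null(s$o3_uncertainty_fraction)) 0.8
        else s$o3_uncertainty_fraction,
      oh_sd_inflation = if (is.null(s$oh_sd_inflation)) 10
                        else s$oh_sd_inflation,
      regime_thresholds = if (is.null(s$regime_thresholds)) c(1e3, 1e4)
                          else as.numeric(s$regime_thresholds))
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Hydroxyl-radical exposure from pCBA probe depletion
#'
#' pCBA is ozone-recalcitrant, so its first-order depletion during ozonation
#' measures the hydroxyl-radical exposure alone:
#' `exposure = -ln(fraction) / k_pCBA_OH` per replicate; the mean and
#' standard deviation over replicates are returned.
#'
#' @param remaining_fractions replicate remaining fractions of pCBA, each in
#'   (0, 1].
#' @param k_pcba_oh rate constant of pCBA with hydroxyl radicals
#'   (default 5.2e9 M^-1 s^-1).
#' @return list with `exposure` (mean, M s), `sd` (0 for a single
#'   replicate) and `replicates` (per-replicate exposures).
#' @examples
#' oh_exposure_from_pcba(c(0.889, 0.891, 0.887))
#' @export
oh_exposure_from_pcba <- function(remaining_fractions,
                                  k_pcba_oh = .K_PCBA_OH) {
  f <- as.numeric(remaining_fractions)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1))
    stop("remaining fractions must lie in (0, 1], got: ",
         paste(signif(f, 4), collapse = ", "))
  per <- -log(f) / k_pcba_oh
  list(exposure = mean(per),
       sd = if (length(per) > 1L) stats::sd(per) else 0,
       replicates = per)
}

#' Hydroxyl-radical scavenging shares
#'
#' Computes the percentage contribution of each matrix scavenger to the
#' total hydroxyl-radical scavenging rate,
#' `share_i = k_i [S_i] / sum_j k_j [S_j] * 100`. Scavenger concentrations
#' are converted to the basis of their rate constants: dissolved organic
#' matter stays on the mg C/L basis (its rate constant is per mg C),
#' alkalinity is split into bicarbonate and carbonate by carbonate
#' speciation at the given pH (alkalinity = [HCO3-] + 2 [CO3^2-]), and
#' N-based units are converted on the nitrogen basis.
#'
#' @param scavengers data.frame with columns `species` (one of `"DOM"`,
#'   `"alkalinity"`, `"nitrite"`, `"bromide"`), `concentration`, `unit`.
#' @param ph pH for the carbonate split.
#' @param constants data.frame of scavenger rate constants (columns
#'   `species`, `basis`, `k`); defaults to the bundled literature file.
#' @param pka2_carbonate second carbonate pKa (default 10.33 at 25 C).
#' @return data.frame with columns `species`, `concentration_molar` (or mg
#'   C/L for DOM), `k`, `rate` (k*[S], s^-1) and `share_pct`; shares sum to
#'   100.
#' @export
scavenging_shares <- function(scavengers, ph,
                              constants = read_scavenger_constants(),
                              pka2_carbonate = .PKA2_CARBONATE) {
  stopifnot(is.data.frame(scavengers),
            all(c("species", "concentration", "unit") %in% names(scavengers)))
  if (!nrow(scavengers)) stop("at least one scavenger is required")
  kfor <- function(sp) {
    row <- constants[constants$species == sp, , drop = FALSE]
    if (!nrow(row)) stop("no rate constant for scavenger species '", sp, "'")
    row$k[1]
  }
  terms <- list()
  for (i in seq_len(nrow(scavengers))) {
    sp <- scavengers$species[i]
    conc <- scavengers$concentration[i]
    unit <- scavengers$unit[i]
    if (sp == "DOM") {
      if (unit != "mg_C_per_L")
        stop("DOM concentration must be in mg_C_per_L, got ", unit)
      terms[[length(terms) + 1L]] <-
        data.frame(species = "DOM", concentration = conc, k = kfor("DOM"))
    } else if (sp == "alkalinity") {
      if (unit != "mmol_per_L")
        stop("alkalinity must be in mmol_per_L, got ", unit)
      alk <- mmol_per_l_to_molar(conc)
      # alkalinity (acid-neutralizing capacity) = [HCO3-] + 2[CO3^2-];
      # r = [CO3^2-]/[HCO3-] from the second carbonate equilibrium
      r <- 10^(ph - pka2_carbonate)
      hco3 <- alk / (1 + 2 * r)
      co3 <- hco3 * r
      terms[[length(terms) + 1L]] <-
        data.frame(species = "bicarbonate", concentration = hco3,
                   k = kfor("bicarbonate"))
      terms[[length(terms) + 1L]] <-
        data.frame(species = "carbonate", concentration = co3,
                   k = kfor("carbonate"))
    } else if (sp == "nitrite") {
      conc_m <- switch(unit,
        ug_N_per_L = ug_n_per_l_to_molar(conc),
        mol_per_L = conc,
        stop("nitrite must be in ug_N_per_L or mol_per_L, got ", unit))
      terms[[length(terms) + 1L]] <-
        data.frame(species = "nitrite", concentration = conc_m,
                   k = kfor("nitrite"))
    } else if (sp == "bromide") {
      conc_m <- switch(unit,
        mg_per_L = mg_per_l_to_molar(conc, molar_mass = 79.904),
        mol_per_L = conc,
        stop("bromide must be in mg_per_L or mol_per_L, got ", unit))
      terms[[length(terms) + 1L]] <-
        data.frame(species = "bromide", concentration = conc_m,
                   k = kfor("bromide"))
    } else {
      stop("unknown scavenger species '", sp, "'")
    }
  }
  out <- do.call(rbind, terms)
  out$rate <- out$k * out$concentration
  total <- sum(out$rate)
  if (total <= 0) stop("total scavenging rate is zero")
  out$share_pct <- out$rate / total * 100
  names(out)[names(out) == "concentration"] <- "concentration_molar"
  rownames(out) <- NULL
  out
}

#' Read the scavenger rate-constant file
#'
#' Literature second-order rate constants for the reaction of hydroxyl
#' radicals with the common wastewater scavengers, on the concentration
#' basis given in the `basis` column (`per_mg_C` for dissolved organic
#' matter, `per_M` otherwise). The bundled defaults draw on the Buxton et
#' al. (1988) radiolysis compilation and Westerhoff et al. (1999) for DOM;
#' edit or replace the file to use site-specific values.
#'
#' @param path CSV with columns `species`, `basis`, `k`, `source`.
#' @return data.frame.
#' @export
read_scavenger_constants <- function(path = system.file(
    "extdata", "scavenger_constants.csv", package = "ozonekin")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "basis", "k")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("scavenger constants file missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$k < 0)) stop("scavenger rate constants must be >= 0")
  df
}

#' Ozone stock concentration from UV absorbance
#'
#' Beer-Lambert conversion of the absorbance of an aqueous ozone stock at
#' 260 nm into molarity: `c = A / (epsilon * l)`.
#'
#' @param absorbance absorbance at 260 nm (AU).
#' @param path_length_cm cuvette path length in cm.
#' @param epsilon molar absorption coefficient of ozone at 260 nm
#'   (default 3200 M^-1 cm^-1).
#' @return concentration in M.
#' @examples
#' ozone_stock_concentration(3.2)  # 1 mM
#' @export
ozone_stock_concentration <- function(absorbance, path_length_cm = 1,
                                      epsilon = 3200) {
  stopifnot(absorbance > 0, path_length_cm > 0, epsilon > 0)
  absorbance / (epsilon * path_length_cm)
}

#' Specific-dose to ozone-exposure correlation
#'
#' Fits a linear correlation between the natural logarithm of the specific
#' ozone dose and the natural logarithm of the ozone exposure over a set of
#' reference plants, and predicts the exposure at a query dose. Used to
#' estimate the ozone exposure of a plant whose dose is outside the range
#' where direct (indigo-method) measurement is feasible.
#'
#' @param reference data.frame with columns `dose` (g O3/g DOC) and
#'   `exposure` (M s), all positive; at least two rows.
#' @param query_dose dose(s) at which to predict.
#' @return list with `exposure` (predicted, M s), `slope` and `intercept`
#'   of the ln-ln fit, and the `fit` object.
#' @export
fit_dose_exposure_correlation <- function(reference, query_dose) {
  stopifnot(is.data.frame(reference),
            all(c("dose", "exposure") %in% names(reference)))
  if (nrow(reference) < 2L)
    stop("at least 2 reference points are required")
  if (any(reference$dose <= 0) || any(reference$exposure <= 0))
    stop("reference doses and exposures must be positive")
  fit <- stats::lm(log(exposure) ~ log(dose), data = reference)
  pred <- exp(stats::predict(fit,
                             newdata = data.frame(dose = query_dose)))
  list(exposure = unname(pred),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), fit = fit)
}
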