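#' Modeled abatement during ozonation
#'
#' First-order abatement of a compound by the combined action of ozone and
#' hydroxyl radicals:
#' `abatement[%] = (1 - exp(-k_O3 * O3exp - k_OH * OHexp)) * 100`.
#'
#' @param k_o3 apparent second-order ozone rate constant, M^-1 s^-1.
#' @param k_oh second-order hydroxyl-radical rate constant, M^-1 s^-1.
#' @param o3_exposure ozone exposure, M s.
#' @param oh_exposure hydroxyl-radical exposure, M s.
#' @return abatement in percent, in [0, 100). Vectorized over all
#'   arguments.
#' @examples
#' predict_abatement(1e2, 1e9, 2.2e-4, 7.76e-11)
#' @export
predict_abatement <- function(k_o3, k_oh, o3_exposure, oh_exposure) {
  args <- list(k_o3, k_oh, o3_exposure, oh_exposure)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a < 0),
                 logical(1))))
    stop("all inputs must be finite and >= 0")
  (1 - exp(-k_o3 * o3_exposure - k_oh * oh_exposure)) * 100
}

#' Measured abatement from a field observation
#'
#' Relative abatement across the ozonation stage,
#' `(1 - c_out/c_in) * 100`. Effluent concentrations below the limit of
#' quantification are replaced by `0.5 * LOQ` before the ratio is taken.
#'
#' @param c_in influent concentration, M (> 0).
#' @param c_out effluent concentration, M; ignored for censored
#'   observations.
#' @param loq limit of quantification, M (required when `censored`).
#' @param censored logical: is `c_out` below the LOQ?
#' @return abatement in percent. Vectorized.
#' @examples
#' measured_abatement(c_in = 100e-9, c_out = 30e-9)             # 70
#' measured_abatement(c_in = 100e-9, censored = TRUE, loq = 10e-9)  # 95
#' @export
measured_abatement <- function(c_in, c_out = NA_real_, loq = NA_real_,
                               censored = FALSE) {
  n <- max(length(c_in), length(c_out), length(loq), length(censored))
  c_in <- rep_len(c_in, n); c_out <- rep_len(c_out, n)
  loq <- rep_len(loq, n); censored <- rep_len(censored, n)
  if (any(!is.finite(c_in)) || any(c_in <= 0))
    stop("c_in must be finite and > 0 (censored influent observations ",
         "give an indeterminate abatement)")
  if (any(censored & !is.finite(loq)))
    stop("loq is required for censored observations")
  eff <- ifelse(censored, 0.5 * loq, c_out)
  if (any(!is.finite(eff)))
    stop("c_out missing for uncensored observation(s)")
  (1 - eff / c_in) * 100
}

#' Distribution specification for Monte Carlo sampling
#'
#' Describes how one abatement-model parameter is sampled: `"normal"`
#' (truncated at zero by resampling -- rate constants and exposures are
#' nonnegative), `"uniform_pm_fraction"` (uniform on
#' `center * (1 - spread)` to `center * (1 + spread)`), or `"point"`
#' (degenerate).
#'
#' @param parameter one of `"k_o3"`, `"k_oh"`, `"o3_exposure"`,
#'   `"oh_exposure"`.
#' @param kind `"normal"`, `"uniform_pm_fraction"` or `"point"`.
#' @param center central value (mean for normal).
#' @param spread standard deviation (normal) or half-width fraction
#'   (uniform); ignored for point.
#' @return object of class `distribution_spec`.
#' @export
distribution_spec <- function(parameter = c("k_o3", "k_oh", "o3_exposure",
                                            "oh_exposure"),
                              kind = c("normal", "uniform_pm_fraction",
                                       "point"),
                              center, spread = 0) {
  parameter <- match.arg(parameter)
  kind <- match.arg(kind)
  stopifnot(is.finite(center), center >= 0, is.finite(spread), spread >= 0)
  structure(list(parameter = parameter, kind = kind, center = center,
                 spread = spread), class = "distribution_spec")
}

.draw_param <- function(spec, n) {
  switch(spec$kind,
    point = rep(spec$center, n),
    uniform_pm_fraction = stats::runif(
      n, spec$center * (1 - spec$spread), spec$center * (1 + spec$spread)),
    normal = {
      if (spec$spread == 0) return(rep(spec$center, n))
      x <- stats::rnorm(n, spec$center, spec$spread)
      # nonnegative parameters: resample the negative draws
      while (any(neg <- x < 0))
        x[neg] <- stats::rnorm(sum(neg), spec$center, spec$spread)
      x
    })
}

#' Monte Carlo uncertainty propagation through the abatement model
#'
#' Samples the four abatement-model parameters independently from their
#' distribution specifications, evaluates the abatement for every draw, and
#' summarizes the resulting distribution. Typical usage samples the ozone
#' rate constant and the hydroxyl-radical exposure as (truncated) normals
#' from their laboratory means and standard deviations, the
#' hydroxyl-radical rate constant as a normal over an ensemble of
#' predictions, and the ozone exposure as uniform +/- 80% around the
#' literature-derived value.
#'
#' @param specs list of four [distribution_spec()]s, one per parameter
#'   (`k_o3`, `k_oh`, `o3_exposure`, `oh_exposure`, any order).
#' @param n_draws number of Monte Carlo draws (default 10000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param compound_id identifier carried into the result.
#' @return object of class `abatement_prediction`: `point_abatement` (at
#'   the centers), `mc_mean`, `mc_sd`, `interval` (2.5th/97.5th
#'   percentiles), `n_draws`, `seed`, and the `draws` matrix (parameters +
#'   abatement).
#' @export
monte_carlo_abatement <- function(specs, n_draws = 10000L, seed = 1L,
                                  compound_id = NA_character_) {
  stopifnot(n_draws >= 1L)
  pars <- vapply(specs, `[[`, "", "parameter")
  need <- c("k_o3", "k_oh", "o3_exposure", "oh_exposure")
  if (!setequal(pars, need) || length(pars) != 4L)
    stop("specs must contain exactly one distribution per parameter: ",
         paste(need, collapse = ", "), "; got: ",
         paste(pars, collapse = ", "))
  names(specs) <- pars
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  draws <- vapply(need, function(p) .draw_param(specs[[p]], n_draws),
                  numeric(n_draws))
  if (n_draws == 1L) draws <- matrix(draws, nrow = 1,
                                     dimnames = list(NULL, need))
  ab <- predict_abatement(draws[, "k_o3"], draws[, "k_oh"],
                          draws[, "o3_exposure"], draws[, "oh_exposure"])
  point <- predict_abatement(specs$k_o3$center, specs$k_oh$center,
                             specs$o3_exposure$center,
                             specs$oh_exposure$center)
  qs <- unname(stats::quantile(ab, c(0.025, 0.975), type = 7))
  structure(list(
    compound_id = compound_id, point_abatement = point,
    mc_mean = mean(ab), mc_sd = stats::sd(ab),
    interval = qs, n_draws = n_draws, seed = seed,
    draws = cbind(draws, abatement = ab)),
    class = "abatement_prediction")
}

#' @export
print.abatement_prediction <- function(x, ...) {
  cat("<abatement_prediction>",
      if (!is.na(x$compound_id)) paste0(" ", x$compound_id), ": point ",
      sprintf("%.1f%%", x$point_abatement), ", MC ",
      sprintf("%.1f +/- %.1f%%", x$mc_mean, x$mc_sd), " [",
      sprintf("%.1f, %.1f", x$interval[1], x$interval[2]), "] (",
      x$n_draws, " draws, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Model-versus-field comparison
#'
#' Ordinary least-squares regression of measured abatements on modeled
#' abatements (free intercept), summarizing how well the exposure-based
#' abatement model reproduces field observations.
#'
#' @param modeled,measured paired abatements in percent; at least 3 pairs.
#' @return list with `slope`, `intercept`, `r_squared`, `n` and the `fit`.
#' @export
compare_model_vs_field <- function(modeled, measured) {
  stopifnot(length(modeled) == length(measured))
  ok <- is.finite(modeled) & is.finite(measured)
  if (sum(ok) < 3L) stop("at least 3 complete pairs are required")
  fit <- stats::lm(measured[ok] ~ modeled[ok])
  r2 <- suppressWarnings(summary(fit)$r.squared) # exact fits trip summary.lm
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = sum(ok), fit = fit)
}

#' Model a compound set against a plant scenario
#'
#' Convenience wrapper: for each compound builds the four distribution
#' specifications from its reactivity record and the scenario (ozone rate
#' constant: normal with the laboratory SD; hydroxyl-radical rate constant:
#' normal with the prediction-ensemble SD; ozone exposure: uniform with the
#' scenario's +/- fraction; hydroxyl-radical exposure: normal with the
#' scenario SD inflated by the scenario's factor), runs the Monte Carlo
#' propagation, and returns one row per compound.
#'
#' Phase I metabolites can be excluded via `exclude_ids` (transformation
#' products identical to them can form during ozonation itself, making
#' their field concentrations unsuitable for a mass-balance comparison).
#'
#' @param records list of [reactivity_record()]s.
#' @param scenario a [wwtp_scenario()].
#' @param n_draws,seed Monte Carlo controls.
#' @param exclude_ids compound ids to drop before modeling.
#' @return data.frame with `compound_id`, `point_abatement`, `mc_mean`,
#'   `mc_sd`, `lo95`, `hi95`; full predictions in attribute
#'   `"predictions"`.
#' @export
model_abatement <- function(records, scenario, n_draws = 10000L, seed = 1L,
                            exclude_ids = character()) {
  stopifnot(inherits(scenario, "wwtp_scenario"))
  records <- Filter(function(r) !(r$compound_id %in% exclude_ids), records)
  preds <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    k_o3 <- apply_floor(r, ph = scenario$ph)
    specs <- list(
      distribution_spec("k_o3", "normal", k_o3,
                        if (is.finite(r$k_o3_sd)) r$k_o3_sd else 0),
      distribution_spec("k_oh", "normal", r$k_oh,
                        if (is.finite(r$k_oh_sd)) r$k_oh_sd else 0),
      distribution_spec("o3_exposure", "uniform_pm_fraction",
                        scenario$o3_exposure,
                        scenario$o3_uncertainty_fraction),
      distribution_spec("oh_exposure", "normal", scenario$oh_exposure,
                        scenario$oh_exposure_sd * scenario$oh_sd_inflation))
    monte_carlo_abatement(specs, n_draws = n_draws, seed = seed + i,
                          compound_id = r$compound_id)
  })
  out <- data.frame(
    compound_id = vapply(preds, `[[`, "", "compound_id"),
    point_abatement = vapply(preds, `[[`, numeric(1), "point_abatement"),
    mc_mean = vapply(preds, `[[`, numeric(1), "mc_mean"),
    mc_sd = vapply(preds, `[[`, numeric(1), "mc_sd"),
    lo95 = vapply(preds, function(p) p$interval[1], numeric(1)),
    hi95 = vapply(preds, function(p) p$interval[2], numeric(1)),
    stringsAsFactors = FALSE)
  attr(out, "predictions") <- preds
  out
}
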