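#' Per-vial logarithmic depletions of one compound
#'
#' Converts peak areas into first-order depletion coordinates
#' `ln(A/A0)` per vial and replicate. `A0` is taken from the zero-dose vial
#' of the same replicate, which cancels replicate-level injection
#' variability; peak areas can be used directly in place of concentrations
#' because only relative abatement enters the competition-kinetics
#' regression.
#'
#' @param experiment an `experiment_table` (see
#'   [generate_competition_experiment()] / [read_experiment_csv()]).
#' @param compound_id compound to extract.
#' @return data.frame with columns `dose_index`, `replicate`,
#'   `log_depletion` (`ln(A/A0)`, <= 0 within noise) and
#'   `abatement_fraction` (`1 - A/A0`).
#' @export
log_depletions <- function(experiment, compound_id) {
  stopifnot(inherits(experiment, "experiment_table"))
  d <- experiment$data[experiment$data$compound_id == compound_id, ,
                       drop = FALSE]
  if (!nrow(d)) stop("compound '", compound_id, "' not present in experiment")
  ref <- d[d$dose_index == 0L, c("replicate", "area")]
  if (!nrow(ref))
    stop("no zero-dose reference vial for compound '", compound_id, "'")
  a0 <- stats::setNames(ref$area, ref$replicate)
  d <- d[d$dose_index > 0L, , drop = FALSE]
  miss <- setdiff(unique(d$replicate), names(a0))
  if (length(miss))
    stop("replicate(s) ", paste(miss, collapse = ", "),
         " of '", compound_id, "' lack a zero-dose reference")
  ld <- log(d$area / a0[as.character(d$replicate)])
  data.frame(dose_index = d$dose_index, replicate = d$replicate,
             log_depletion = ld, abatement_fraction = 1 - exp(ld),
             row.names = NULL)
}

#' 10--90% abatement window filter
#'
#' Keeps only depletion points whose abatement fraction lies between
#' `lower` and `upper` (default 0.10 and 0.90, inclusive). Points outside
#' the window carry little kinetic information: below 10% abatement the
#' depletion is dominated by measurement noise, above 90% the remaining
#' signal approaches the detection limit.
#'
#' @param points data.frame from [log_depletions()].
#' @param lower,upper abatement-fraction bounds.
#' @return the filtered data.frame.
#' @export
abatement_window_filter <- function(points, lower = 0.10, upper = 0.90) {
  stopifnot(is.data.frame(points), "abatement_fraction" %in% names(points))
  points[points$abatement_fraction >= lower &
         points$abatement_fraction <= upper, , drop = FALSE]
}

#' Competition-kinetics pair regression
#'
#' Ordinary least-squares regression of the target's log depletion on the
#' competitor's log depletion, with free intercept, over vials matched by
#' `(dose_index, replicate)`. Because both compounds experience the same
#' ozone exposure in each vial, the slope equals the ratio of their apparent
#' rate constants, and `k_target = slope * k_competitor`.
#'
#' The 10--90% abatement window is applied before fitting. With
#' `window = "both"` (default) a vial is retained only if both compounds'
#' points survive the window; `window = "target"` windows on the target
#' alone, which retains more points when target and competitor reactivities
#' are far apart (the competitor's log depletion remains exact under
#' multiplicative area noise, whose magnitude on the log scale does not
#' depend on the abatement level).
#'
#' @param target_points,competitor_points data.frames from
#'   [log_depletions()].
#' @param k_competitor apparent rate constant of the competitor, M^-1 s^-1.
#' @param target_id,competitor_id identifiers carried into the result.
#' @param window `"both"` or `"target"` (see Details).
#' @param window_bounds abatement-fraction window, default `c(0.10, 0.90)`.
#' @return object of class `pair_regression`: list with `target_id`,
#'   `competitor_id`, `slope`, `intercept`, `r_squared`, `n_points`,
#'   `k_competitor`, `k_estimate`.
#' @export
fit_pair <- function(target_points, competitor_points, k_competitor,
                     target_id = "target", competitor_id = "competitor",
                     window = c("both", "target"),
                     window_bounds = c(0.10, 0.90)) {
  window <- match.arg(window)
  stopifnot(k_competitor > 0)
  tw <- abatement_window_filter(target_points, window_bounds[1],
                                window_bounds[2])
  cw <- if (window == "both")
    abatement_window_filter(competitor_points, window_bounds[1],
                            window_bounds[2])
  else competitor_points
  m <- merge(tw[c("dose_index", "replicate", "log_depletion")],
             cw[c("dose_index", "replicate", "log_depletion")],
             by = c("dose_index", "replicate"), suffixes = c("_t", "_c"))
  if (nrow(m) < 2L)
    stop("fewer than 2 matched in-window points for ", target_id, " vs ",
         competitor_id)
  fit <- stats::lm(log_depletion_t ~ log_depletion_c, data = m)
  slope <- unname(stats::coef(fit)[2])
  sm <- suppressWarnings(summary(fit)) # exact fits trip summary.lm
  slope_se <- sm$coefficients[2, "Std. Error"]
  structure(list(
    target_id = target_id, competitor_id = competitor_id,
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    slope_se = slope_se,
    r_squared = sm$r.squared, n_points = nrow(m),
    k_competitor = k_competitor, k_estimate = slope * k_competitor,
    k_se = slope_se * k_competitor),
    class = "pair_regression")
}

#' @export
print.pair_regression <- function(x, ...) {
  cat("<pair_regression> ", x$target_id, " vs ", x$competitor_id,
      ": slope ", signif(x$slope, 4), ", R2 ", signif(x$r_squared, 4),
      ", n ", x$n_points, ", k ", signif(x$k_estimate, 4), " M-1 s-1\n",
      sep = "")
  invisible(x)
}

#' Quality-control gates for a pair regression
#'
#' Evaluates the four acceptance gates applied to every target/competitor
#' regression before its rate-constant estimate is retained:
#' (i) at least `min_points` data points; (ii) coefficient of determination
#' above `min_r_squared`; (iii) negligible intercept; (iv) slope between
#' `slope_range[1]` and `slope_range[2]`, i.e. target and competitor
#' reactivities within one order of magnitude.
#'
#' Gate (iii) is implemented as printed in the source protocol,
#' `|intercept| < 10 * |slope|`; a strict variant
#' `|intercept| < 0.1 * |slope|` is available via
#' `strict_intercept = TRUE`. Both readings are reported in the verdict.
#'
#' @param reg a `pair_regression`.
#' @param min_points gate (i) threshold (default 10).
#' @param min_r_squared gate (ii) threshold (default 0.9, exclusive).
#' @param slope_range gate (iv) bounds (default `c(0.1, 10)`, inclusive).
#' @param strict_intercept use the strict reading of gate (iii)?
#' @return list of class `qc_verdict`: logical `pass`, per-gate results
#'   `gates` (named logical: `n_points`, `r_squared`, `intercept`, `slope`)
#'   and the measured `values`.
#' @export
qc_evaluate <- function(reg, min_points = 10L, min_r_squared = 0.9,
                        slope_range = c(0.1, 10),
                        strict_intercept = FALSE) {
  stopifnot(inherits(reg, "pair_regression"))
  icpt_factor <- if (strict_intercept) 0.1 else 10
  gates <- c(
    n_points = reg$n_points >= min_points,
    r_squared = reg$r_squared > min_r_squared,
    intercept = abs(reg$intercept) < icpt_factor * abs(reg$slope),
    slope = reg$slope >= slope_range[1] && reg$slope <= slope_range[2])
  structure(list(
    pass = all(gates), gates = gates,
    values = list(n_points = reg$n_points, r_squared = reg$r_squared,
                  intercept = reg$intercept, slope = reg$slope,
                  intercept_rule = sprintf("|intercept| < %g*|slope|",
                                           icpt_factor),
                  intercept_loose = abs(reg$intercept) < 10 * abs(reg$slope),
                  intercept_strict = abs(reg$intercept) < 0.1 * abs(reg$slope))),
    class = "qc_verdict")
}

#' Apparent rate constant of one target from a multicompound experiment
#'
#' Fits the target against every competitor present in the experiment,
#' evaluates the QC gates on each pair, and averages the rate-constant
#' estimates of the passing pairs (unweighted mean; the standard deviation
#' across competitor-specific estimates is reported, 0 when a single pair
#' passes).
#'
#' Status is `"below_determinable"` when the target never exceeds 10%
#' abatement although the least reactive competitor is depleted beyond 90%
#' somewhere in the dose series (i.e. the dose range was sufficient and the
#' target is simply too slow); `"failed"` when no pair passes QC for any
#' other reason.
#'
#' @param experiment an `experiment_table`.
#' @param target_id compound to estimate.
#' @param competitors list of [reactivity_record()] objects, or NULL to use
#'   the competitor set stored in the experiment.
#' @param ph working pH for competitor apparent rate constants.
#' @inheritParams fit_pair
#' @inheritParams qc_evaluate
#' @return object of class `rate_estimate`: `compound_id`, `k_app`, `k_sd`
#'   (standard deviation across competitor-specific estimates, 0 for a
#'   single pair), `k_se` (standard error of the averaged estimate,
#'   combining the mean within-regression slope SE with the
#'   between-competitor spread -- see the note in the source on why the
#'   spread alone underestimates), `n_competitors`, `status`, and
#'   `regressions` (all pairs with their QC verdicts).
#' @export
estimate_k <- function(experiment, target_id, competitors = NULL, ph = 7,
                       window = c("both", "target"),
                       window_bounds = c(0.10, 0.90),
                       min_points = 10L, min_r_squared = 0.9,
                       slope_range = c(0.1, 10),
                       strict_intercept = FALSE) {
  window <- match.arg(window)
  if (is.null(competitors)) {
    comp_k <- experiment$competitor_k
    if (is.null(comp_k))
      stop("no competitors supplied and none stored in the experiment")
  } else {
    comp_k <- vapply(competitors, function(r) apparent_rate_constant(r, ph),
                     numeric(1))
    names(comp_k) <- vapply(competitors, `[[`, "", "compound_id")
  }
  comp_k <- comp_k[names(comp_k) %in% unique(experiment$data$compound_id)]
  if (!length(comp_k))
    stop("none of the competitors are present in the experiment")
  tp <- log_depletions(experiment, target_id)

  regs <- vector("list", length(comp_k))
  names(regs) <- names(comp_k)
  for (cid in names(comp_k)) {
    cp <- log_depletions(experiment, cid)
    reg <- tryCatch(
      fit_pair(tp, cp, comp_k[[cid]], target_id, cid,
               window = window, window_bounds = window_bounds),
      error = function(e) e)
    if (inherits(reg, "error")) {
      regs[[cid]] <- list(regression = NULL, qc = NULL,
                          error = conditionMessage(reg))
    } else {
      regs[[cid]] <- list(
        regression = reg,
        qc = qc_evaluate(reg, min_points, min_r_squared, slope_range,
                         strict_intercept),
        error = NULL)
    }
  }
  passing <- Filter(function(r) !is.null(r$qc) && r$qc$pass, regs)
  if (length(passing)) {
    ks <- vapply(passing, function(r) r$regression$k_estimate, numeric(1))
    ses <- vapply(passing, function(r) r$regression$k_se, numeric(1))
    between <- if (length(ks) > 1L) stats::var(ks) else 0
    # competitor-specific estimates share the same vials, so they are
    # positively correlated: the standard error of the average keeps the
    # full mean within-regression SE (no 1/sqrt(m) gain is assumed) and
    # adds the between-competitor spread in quadrature
    est <- list(compound_id = target_id, k_app = mean(ks),
                k_sd = if (length(ks) > 1L) stats::sd(ks) else 0,
                k_se = sqrt(mean(ses)^2 + between),
                n_competitors = length(ks), status = "ok",
                regressions = regs)
  } else {
    # distinguish "too slow for this dose range" from analytic failure:
    # target never leaves the noise floor while the slowest competitor is
    # fully depleted somewhere in the series
    max_target_ab <- max(tp$abatement_fraction)
    slow_cid <- names(comp_k)[which.min(comp_k)]
    slow_ab <- log_depletions(experiment, slow_cid)$abatement_fraction
    status <- if (max_target_ab < 0.10 && max(slow_ab) > 0.90)
      "below_determinable" else "failed"
    est <- list(compound_id = target_id, k_app = NA_real_, k_sd = NA_real_,
                k_se = NA_real_, n_competitors = 0L, status = status,
                regressions = regs)
  }
  structure(est, class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> ", x$compound_id, ": ", sep = "")
  if (x$status == "ok") {
    cat("k_app ", signif(x$k_app, 4), " +/- ", signif(x$k_sd, 3),
        " M-1 s-1 (", x$n_competitors, " competitor",
        if (x$n_competitors != 1) "s", ")\n", sep = "")
  } else cat(x$status, "\n")
  invisible(x)
}

#' Estimate rate constants for every target in an experiment
#'
#' Convenience wrapper running [estimate_k()] for each non-competitor
#' compound of the experiment.
#'
#' @inheritParams estimate_k
#' @param target_ids compounds to estimate; default: every compound that is
#'   not a competitor.
#' @param ... passed to [estimate_k()].
#' @return data.frame with one row per target: `compound_id`, `k_app`,
#'   `k_sd`, `n_competitors`, `status`. The full `rate_estimate` objects are
#'   attached as attribute `"estimates"`.
#' @export
fit_kinetics <- function(experiment, competitors = NULL, target_ids = NULL,
                         ph = 7, ...) {
  comp_names <- if (is.null(competitors)) names(experiment$competitor_k)
                else vapply(competitors, `[[`, "", "compound_id")
  if (is.null(target_ids))
    target_ids <- setdiff(unique(experiment$data$compound_id), comp_names)
  ests <- lapply(target_ids, function(id)
    estimate_k(experiment, id, competitors, ph = ph, ...))
  out <- data.frame(
    compound_id = target_ids,
    k_app = vapply(ests, `[[`, numeric(1), "k_app"),
    k_sd = vapply(ests, `[[`, numeric(1), "k_sd"),
    k_se = vapply(ests, `[[`, numeric(1), "k_se"),
    n_competitors = vapply(ests, `[[`, integer(1), "n_competitors"),
    status = vapply(ests, `[[`, "", "status"),
    stringsAsFactors = FALSE)
  attr(out, "estimates") <- ests
  out
}
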