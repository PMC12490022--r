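#' Synthetic competition-kinetics experiments
#'
#' Generates the vial-level peak-area table of a multicompound ozonation
#' experiment. All compounds in a vial share one true ozone exposure (the
#' core competition-kinetics assumption); each compound is depleted first
#' order, `ln(A/A0) = -k * exposure`, and multiplicative lognormal noise with
#' the stated coefficient of variation is applied to every peak area.
#' Dose index 0 is the unozonated reference vial from which `A0` is taken.
#'
#' Exposures for dose indices `1..n_doses` are log-spaced over a range
#' chosen from the mixture composition (ozone doses are fine-tuned in the
#' laboratory protocol this emulates so that enough usable data points
#' result). With `dose_design = "pairs"` (default) the range is the union
#' of the mutual 10--90% abatement windows of every target/competitor pair
#' whose reactivities lie within one order of magnitude -- the only vials
#' that can pass the pairwise QC gates -- which concentrates the doses
#' where both pair members are quantifiable. With `dose_design = "members"`
#' the range spans the union of the individual member windows, from
#' `-ln(0.9)/k_max` to `-ln(0.1)/k_min`.
#'
#' @param mixture a `mixture_spec` (see [mixture_spec()]) listing the target
#'   compounds with their true apparent rate constants.
#' @param competitors list of [reactivity_record()] competitor compounds whose
#'   apparent rate constants at `ph` are treated as known.
#' @param n_doses number of non-zero ozone dose levels (>= 2).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   peak-area noise (0 disables noise).
#' @param n_replicates number of replicate experiments.
#' @param seed integer seed; the output is deterministic given the seed.
#' @param ph working pH for competitor apparent rate constants.
#' @param a0_mean nominal unozonated peak area (arbitrary units).
#' @param dose_design `"pairs"` or `"members"` (see Details).
#' @param exposures optional explicit vector of `n_doses` vial exposures in
#'   M s, overriding the automatic log-spaced design.
#' @return An object of class `experiment_table`: a list with `data` (a
#'   data.frame with columns `dose_index`, `replicate`, `compound_id`,
#'   `area`, `area0`) and `vial_exposures` (named numeric, the true exposure
#'   per dose index -- truth retained for testing only).
#' @examples
#' mix <- mixture_spec(data.frame(compound_id = c("a", "b"),
#'                                k_true = c(500, 1500),
#'                                exact_mass = c(151.1, 230.2)))
#' comp <- list(reactivity_record("c1", species_k_o3 = 1000))
#' exp <- generate_competition_experiment(mix, comp, seed = 1)
#' head(exp$data)
#' @export
generate_competition_experiment <- function(mixture, competitors,
                                            n_doses = 12L,
                                            noise_cv = 0.05,
                                            n_replicates = 3L,
                                            seed = 1L,
                                            ph = 7,
                                            a0_mean = 1e6,
                                            dose_design = c("pairs",
                                                            "members"),
                                            exposures = NULL) {
  dose_design <- match.arg(dose_design)
  stopifnot(inherits(mixture, "mixture_spec"))
  stopifnot(n_doses >= 2L, noise_cv >= 0, n_replicates >= 1L)
  comp_k <- vapply(competitors, function(r) apparent_rate_constant(r, ph),
                   numeric(1))
  comp_id <- vapply(competitors, `[[`, "", "compound_id")
  all_id <- c(mixture$members$compound_id, comp_id)
  if (anyDuplicated(all_id))
    stop("duplicate compound ids between mixture and competitors: ",
         paste(unique(all_id[duplicated(all_id)]), collapse = ", "))
  k_all <- c(mixture$members$k_true, comp_k)
  names(k_all) <- all_id
  if (any(k_all <= 0)) stop("all true rate constants must be > 0")

  if (is.null(exposures)) {
    rng <- .dose_range(mixture$members$k_true, comp_k, dose_design)
    exposures <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_doses))
  } else {
    stopifnot(length(exposures) == n_doses, all(exposures > 0))
  }
  names(exposures) <- as.character(seq_len(n_doses))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log1p(noise_cv^2))

  grid <- expand.grid(dose_index = 0:n_doses,
                      replicate = seq_len(n_replicates),
                      compound_id = all_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expo <- ifelse(grid$dose_index == 0L, 0,
                 exposures[as.character(grid$dose_index)])
  true_area <- a0_mean * exp(-k_all[grid$compound_id] * expo)
  noise <- if (noise_cv > 0)
    exp(stats::rnorm(nrow(grid), mean = -sdlog^2 / 2, sd = sdlog)) else 1
  grid$area <- true_area * noise
  grid$area0 <- a0_mean
  structure(list(data = grid, vial_exposures = exposures,
                 competitor_k = stats::setNames(comp_k, comp_id),
                 truth = k_all, ph = ph, noise_cv = noise_cv, seed = seed),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("<experiment_table> ", length(unique(x$data$compound_id)),
      " compounds, ", length(x$vial_exposures), " dose levels, ",
      max(x$data$replicate), " replicates (noise CV ", x$noise_cv,
      ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Mixture specification for a competition experiment
#'
#' Validates a set of target compounds destined for one multicompound vial
#' series: all true rate constants must lie inside the declared reactivity
#' window, no two members may share an exact mass (within `mass_tol` Da, to
#' avoid indistinguishable full-scan signals), and no member may be a
#' declared oxidation product of another member (oxidation of the parent
#' would regenerate the product's signal mid-experiment).
#'
#' @param members data.frame with columns `compound_id`, `k_true` (M^-1
#'   s^-1) and optionally `exact_mass` (Da).
#' @param reactivity_window numeric length-2, `(k_min, k_max)` in M^-1 s^-1.
#' @param oxidation_products optional data.frame with columns `parent_id`,
#'   `product_id` declaring known oxidation relations.
#' @param mass_tol exact-mass collision tolerance in Da (default 0.005).
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(members,
                         reactivity_window = range(members$k_true),
                         oxidation_products = NULL,
                         mass_tol = 0.005) {
  stopifnot(is.data.frame(members),
            all(c("compound_id", "k_true") %in% names(members)))
  if (anyDuplicated(members$compound_id))
    stop("duplicate compound_id in mixture")
  if (any(members$k_true < reactivity_window[1] - 1e-12) ||
      any(members$k_true > reactivity_window[2] + 1e-12))
    stop("true rate constants outside the declared reactivity window: ",
         paste(members$compound_id[members$k_true < reactivity_window[1] |
                                   members$k_true > reactivity_window[2]],
               collapse = ", "))
  if ("exact_mass" %in% names(members) && nrow(members) > 1L) {
    m <- members$exact_mass
    pairs <- which(abs(outer(m, m, `-`)) < mass_tol &
                   upper.tri(matrix(0, length(m), length(m))), arr.ind = TRUE)
    if (nrow(pairs))
      stop("compounds with identical exact masses may not share a mixture: ",
           paste(apply(pairs, 1L, function(p)
             paste(members$compound_id[p], collapse = "/")), collapse = ", "))
  }
  if (!is.null(oxidation_products) && nrow(oxidation_products)) {
    ids <- members$compound_id
    hit <- oxidation_products$parent_id %in% ids &
           oxidation_products$product_id %in% ids
    if (any(hit))
      stop("mixture contains parent and its oxidation product: ",
           paste(paste(oxidation_products$parent_id[hit],
                       oxidation_products$product_id[hit], sep = " -> "),
                 collapse = ", "))
  }
  structure(list(members = members, reactivity_window = reactivity_window),
            class = "mixture_spec")
}

#' Group targets and competitors into reactivity-matched mixtures
#'
#' Assigns each target compound to the competitor nearest in log10
#' reactivity, builds one mixture per such group, and attaches every
#' competitor lying within one order of magnitude of the group's
#' reactivity range. This mirrors the experimental design in which target
#' compounds are grouped into mixtures covering limited, partially
#' overlapping reactivity ranges so that every target has one -- usually
#' several -- competitors within one order of magnitude (slope between 0.1
#' and 10), enabling competitor averaging.
#'
#' @param targets data.frame with columns `compound_id`, `k_true`.
#' @param competitors list of [reactivity_record()] objects.
#' @param ph working pH for competitor apparent rate constants.
#' @param max_ratio maximum usable target/competitor reactivity ratio
#'   (default 10, matching the slope gate).
#' @return list of elements, each with `mixture` (a [mixture_spec()]) and
#'   `competitors` (the records assigned to that mixture).
#' @export
plan_mixtures <- function(targets, competitors, ph = 7, max_ratio = 10) {
  stopifnot(is.data.frame(targets),
            all(c("compound_id", "k_true") %in% names(targets)))
  comp_k <- vapply(competitors, function(r) apparent_rate_constant(r, ph),
                   numeric(1))
  idx <- vapply(log10(targets$k_true), function(lk)
    which.min(abs(lk - log10(comp_k))), integer(1))
  groups <- split(seq_len(nrow(targets)), idx)
  lapply(groups, function(rows_idx) {
    rows <- targets[rows_idx, , drop = FALSE]
    usable <- which(vapply(comp_k, function(kc)
      any(rows$k_true / kc <= max_ratio & rows$k_true / kc >= 1 / max_ratio),
      logical(1)))
    list(mixture = mixture_spec(rows), competitors = competitors[usable])
  })
}

#' Synthetic pCBA probe assay
#'
#' Simulates replicate measurements of the remaining fraction of
#' para-chlorobenzoic acid after ozonation at a given true hydroxyl-radical
#' exposure: `fraction = exp(-k_pCBA_OH * exposure)` with multiplicative
#' lognormal noise. pCBA is ozone-recalcitrant, so its depletion reflects
#' the hydroxyl-radical exposure alone.
#'
#' @param true_oh_exposure hydroxyl-radical exposure in M s (>= 0).
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @param k_pcba_oh rate constant of pCBA with hydroxyl radicals, M^-1 s^-1.
#' @return numeric vector of remaining fractions, one per replicate.
#' @examples
#' generate_pcba_assay(2.26e-11, noise_cv = 0, n_replicates = 3, seed = 1)
#' @export
generate_pcba_assay <- function(true_oh_exposure, noise_cv = 0.02,
                                n_replicates = 3L, seed = 1L,
                                k_pcba_oh = .K_PCBA_OH) {
  if (!is.finite(true_oh_exposure) || true_oh_exposure < 0)
    stop("true_oh_exposure must be >= 0, got ", true_oh_exposure)
  stopifnot(noise_cv >= 0, n_replicates >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log1p(noise_cv^2))
  noise <- if (noise_cv > 0)
    exp(stats::rnorm(n_replicates, -sdlog^2 / 2, sdlog)) else rep(1, n_replicates)
  exp(-k_pcba_oh * true_oh_exposure) * noise
}

#' Synthetic plant field dataset
#'
#' Simulates paired influent/effluent concentrations of compounds across an
#' ozonation stage. The truth model is first-order abatement by ozone and
#' hydroxyl radicals, `c_out/c_in = exp(-k_O3*O3exp - k_OH*OHexp)`, with
#' multiplicative lognormal noise per compound and sampling day. Effluent
#' values below the limit of quantification are flagged censored.
#'
#' @param records list of [reactivity_record()] objects (apparent ozone rate
#'   constants evaluated at the scenario pH; below-determinable members get
#'   the floor value).
#' @param scenario a [wwtp_scenario()] providing the oxidant exposures.
#' @param loq limit of quantification in M.
#' @param noise_cv day-to-day coefficient of variation of the effluent/influent
#'   ratio.
#' @param n_days number of consecutive sampling days.
#' @param seed integer seed.
#' @param c_in_range range (M) from which per-compound influent
#'   concentrations are drawn log-uniformly.
#' @return data.frame of field observations with columns `compound_id`,
#'   `day`, `c_in`, `c_out`, `loq`, `censored`, plus attribute
#'   `truth` (the per-compound true abatement fraction).
#' @export
generate_wwtp_dataset <- function(records, scenario, loq = 1e-9,
                                  noise_cv = 0.10, n_days = 5L, seed = 1L,
                                  c_in_range = c(1e-8, 1e-7)) {
  stopifnot(inherits(scenario, "wwtp_scenario"), loq > 0, noise_cv >= 0,
            n_days >= 1L)
  if (scenario$o3_exposure < 0 || scenario$oh_exposure < 0)
    stop("scenario exposures must be >= 0")
  ph <- scenario$ph
  k_o3 <- vapply(records, function(r) apply_floor(r, ph = ph), numeric(1))
  k_oh <- vapply(records, `[[`, numeric(1), "k_oh")
  ids <- vapply(records, `[[`, "", "compound_id")
  if (any(is.na(k_oh)))
    stop("k_oh missing for: ", paste(ids[is.na(k_oh)], collapse = ", "))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  sdlog <- sqrt(log1p(noise_cv^2))
  surv <- exp(-k_o3 * scenario$o3_exposure - k_oh * scenario$oh_exposure)
  c_in <- exp(stats::runif(length(ids), log(c_in_range[1]),
                           log(c_in_range[2])))
  grid <- expand.grid(day = seq_len(n_days), i = seq_along(ids),
                      KEEP.OUT.ATTRS = FALSE)
  noise <- if (noise_cv > 0)
    exp(stats::rnorm(nrow(grid), -sdlog^2 / 2, sdlog)) else 1
  c_out <- c_in[grid$i] * surv[grid$i] * noise
  out <- data.frame(compound_id = ids[grid$i], day = grid$day,
                    c_in = c_in[grid$i], c_out = c_out, loq = loq,
                    censored = c_out < loq, stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(compound_id = ids, k_o3 = k_o3,
                                   k_oh = k_oh, survival = surv,
                                   abatement_pct = (1 - surv) * 100)
  out
}

# exposure range of the log-spaced dose grid; abatement window 10-90%
# corresponds to k*exposure in [-ln(0.9), -ln(0.1)]
.dose_range <- function(k_targets, k_comp, dose_design, max_ratio = 10) {
  lo_ab <- -log(0.9) # 0.105
  hi_ab <- -log(0.1) # 2.303
  k_all <- c(k_targets, k_comp)
  members_rng <- c(lo_ab / max(k_all), hi_ab / min(k_all))
  if (dose_design == "members" || !length(k_comp)) return(members_rng)
  # mutual windows of target/competitor pairs within the slope gate
  pairs <- expand.grid(kt = k_targets, kc = k_comp)
  pairs <- pairs[pairs$kt / pairs$kc <= max_ratio &
                 pairs$kt / pairs$kc >= 1 / max_ratio, , drop = FALSE]
  if (!nrow(pairs)) return(members_rng)
  lo <- min(lo_ab / pmin(pairs$kt, pairs$kc))
  hi <- max(hi_ab / pmax(pairs$kt, pairs$kc))
  if (lo >= hi) return(members_rng)
  c(lo, hi)
}

# save/restore the global RNG state so generators are pure given `seed`
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write / read an experiment table as CSV
#'
#' Plain-text round trip of the vial-level data: columns
#' `dose_index,replicate,compound_id,area,area0`. The true vial exposures
#' are written to a JSON sidecar (testing aid, not used by estimation).
#'
#' @param experiment an `experiment_table`.
#' @param path CSV path; the truth sidecar goes to `<path>.truth.json`.
#' @param sidecar write the truth sidecar? (default TRUE)
#' @return invisibly, `path`.
#' @export
write_experiment_csv <- function(experiment, path, sidecar = TRUE) {
  stopifnot(inherits(experiment, "experiment_table"))
  utils::write.csv(experiment$data, path, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(
      list(vial_exposures = as.list(experiment$vial_exposures),
           truth_k = as.list(experiment$truth)),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param competitor_k named numeric of competitor apparent rate constants
#'   (optional; enables [estimate_k()] directly on the read table).
#' @rdname write_experiment_csv
#' @export
read_experiment_csv <- function(path, competitor_k = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("dose_index", "replicate", "compound_id", "area", "area0")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("experiment table missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$area <= 0))
    stop("non-positive peak area in row(s) ",
         paste(which(df$area <= 0), collapse = ", "))
  structure(list(data = df, vial_exposures = NULL,
                 competitor_k = competitor_k, truth = NULL, ph = NA_real_,
                 noise_cv = NA_real_, seed = NA_integer_),
            class = "experiment_table")
}
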