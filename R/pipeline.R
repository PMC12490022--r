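#' Schema-validated table loading
#'
#' Reads one of the package's CSV table formats and validates its schema,
#' reporting offending columns and row numbers.
#'
#' @param path CSV file path.
#' @param schema one of `"compounds"` (compound reactivity table, see
#'   [read_compound_table()]), `"experiment"` (vial-level peak areas, see
#'   [read_experiment_csv()]), `"field"` (plant influent/effluent pairs:
#'   `compound_id,day,c_in,c_out,loq,censored`), `"pairs"`
#'   (parent--metabolite annotations, see [read_pairs_table()]).
#' @return the validated object (list of records, `experiment_table` or
#'   data.frame depending on the schema).
#' @export
load_tables <- function(path, schema = c("compounds", "experiment", "field",
                                         "pairs")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(schema,
    compounds = read_compound_table(path),
    experiment = read_experiment_csv(path),
    pairs = read_pairs_table(path),
    field = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("compound_id", "c_in", "c_out", "loq")
      miss <- setdiff(need, names(df))
      if (length(miss))
        stop("field table missing column(s): ", paste(miss, collapse = ", "))
      if (!"censored" %in% names(df)) df$censored <- df$c_out < df$loq
      if (!"day" %in% names(df)) df$day <- 1L
      bad <- which(!is.finite(df$c_in) | df$c_in <= 0)
      if (length(bad))
        stop("non-positive c_in in row(s) ", paste(bad, collapse = ", "))
      bad <- which(!is.finite(df$loq) | df$loq <= 0)
      if (length(bad))
        stop("non-positive loq in row(s) ", paste(bad, collapse = ", "))
      df
    })
}

#' End-to-end synthetic pipeline run
#'
#' Orchestrates the full chain on synthetic data: simulate competition
#' experiments for a set of true rate constants, estimate the rate
#' constants back, model abatement in a plant scenario, generate and
#' compare a synthetic field dataset, and compute sensitivity indices.
#' Intended as a reproducible smoke/demonstration run; all stages are
#' deterministic given `seed`.
#'
#' @param true_k named numeric of true apparent ozone rate constants
#'   (M^-1 s^-1) for the synthetic targets.
#' @param k_oh named numeric of hydroxyl-radical rate constants for the
#'   same compounds (default 5e9 for all).
#' @param scenario a [wwtp_scenario()]; default: the bundled Neugut-like
#'   example plant.
#' @param competitors list of [reactivity_record()]s; default: 15
#'   competitors log-spaced over 1--1e8 M^-1 s^-1.
#' @param noise_cv peak-area noise CV for the simulated experiments.
#' @param mc_draws Monte Carlo draws for the abatement stage.
#' @param seed integer seed recorded in the manifest.
#' @param window windowing mode passed to [estimate_k()].
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV with a JSON manifest.
#' @return list with `estimates` (data.frame), `abatement` (data.frame),
#'   `field_comparison` (slope/intercept/R^2), `sensitivity` (data.frame of
#'   share-of-total indices per compound) and `manifest`.
#' @export
run_pipeline <- function(true_k,
                         k_oh = stats::setNames(rep(5e9, length(true_k)),
                                                names(true_k)),
                         scenario = read_scenarios()[["Neugut"]],
                         competitors = default_competitors(),
                         noise_cv = 0.05, mc_draws = 2000L, seed = 1L,
                         window = c("both", "target"),
                         out_dir = NULL) {
  window <- match.arg(window)
  stopifnot(is.numeric(true_k), !is.null(names(true_k)),
            all(nzchar(names(true_k))))

  targets <- data.frame(compound_id = names(true_k), k_true = unname(true_k),
                        stringsAsFactors = FALSE)
  plan <- plan_mixtures(targets, competitors)
  est_rows <- list()
  for (i in seq_along(plan)) {
    expm <- generate_competition_experiment(
      plan[[i]]$mixture, plan[[i]]$competitors, noise_cv = noise_cv,
      seed = seed + i)
    est_rows[[i]] <- fit_kinetics(expm, window = window)
  }
  estimates <- do.call(rbind, lapply(est_rows, function(d) {
    attr(d, "estimates") <- NULL
    d
  }))

  recs <- lapply(seq_len(nrow(estimates)), function(i) {
    id <- estimates$compound_id[i]
    k <- estimates$k_app[i]
    if (!is.finite(k))
      reactivity_record(id, below_determinable = TRUE,
                        k_oh = k_oh[[id]])
    else
      reactivity_record(id, species_k_o3 = k,
                        k_o3_sd = estimates$k_sd[i], k_oh = k_oh[[id]])
  })
  abat <- model_abatement(recs, scenario, n_draws = mc_draws, seed = seed)

  field <- generate_wwtp_dataset(recs, scenario, seed = seed + 1000L)
  meas <- measured_abatement(field$c_in, field$c_out, field$loq,
                             field$censored)
  meas_by_cpd <- tapply(meas, field$compound_id, mean)
  modeled <- abat$point_abatement[match(names(meas_by_cpd),
                                        abat$compound_id)]
  comparison <- compare_model_vs_field(modeled, as.numeric(meas_by_cpd))

  sens <- do.call(rbind, lapply(recs, function(r) {
    k <- apply_floor(r, ph = scenario$ph)
    s <- sensitivity_indices(k, r$k_oh, scenario$o3_exposure,
                             scenario$oh_exposure)
    data.frame(compound_id = r$compound_id, t(s$indices),
               regime = classify_regime(k, scenario),
               stringsAsFactors = FALSE)
  }))

  manifest <- list(
    package = "ozonekin",
    version = as.character(utils::packageVersion("ozonekin")),
    seed = seed, noise_cv = noise_cv, mc_draws = mc_draws,
    window = window, scenario = scenario$name,
    n_targets = length(true_k),
    config_hash = config_hash(list(true_k = true_k, noise_cv = noise_cv,
                                   mc_draws = mc_draws, seed = seed,
                                   window = window)))
  out <- list(estimates = estimates, abatement = abat,
              field_comparison = comparison[c("slope", "intercept",
                                              "r_squared", "n")],
              sensitivity = sens, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(estimates, file.path(out_dir, "estimates.csv"),
                     row.names = FALSE)
    utils::write.csv(abat, file.path(out_dir, "abatement.csv"),
                     row.names = FALSE)
    utils::write.csv(sens, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Default competitor set for synthetic experiments
#'
#' Fifteen single-species competitor records with apparent rate constants
#' log-spaced over 1--1e8 M^-1 s^-1, mirroring the reactivity span of a
#' practical competitor panel.
#'
#' @param n number of competitors.
#' @param k_range range of rate constants in M^-1 s^-1.
#' @return list of [reactivity_record()]s.
#' @export
default_competitors <- function(n = 15L, k_range = c(1, 1e8)) {
  ks <- 10^seq(log10(k_range[1]), log10(k_range[2]), length.out = n)
  lapply(seq_along(ks), function(i)
    reactivity_record(sprintf("comp%02d", i), species_k_o3 = ks[i]))
}

# stable hash of a configuration list (polynomial rolling hash over its
# serialized JSON, modulo a Mersenne prime to stay in integer range)
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
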