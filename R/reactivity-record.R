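#' Compound reactivity records
#'
#' A `reactivity_record` bundles everything the abatement model needs to know
#' about one compound: its species-specific second-order rate constants for the
#' reaction with ozone (one per protonation state, ordered from the most
#' protonated to the most deprotonated species), its pKa ladder, the
#' second-order rate constant for the reaction with hydroxyl radicals, and
#' uncertainty information. Compounds whose ozone reactivity lies below the
#' minimum determinable by the competitor set are flagged
#' `below_determinable`; for those, `species_k_o3` may be empty and a floor
#' value is substituted downstream (see [apply_floor()]).
#'
#' @param compound_id character scalar, unique identifier.
#' @param name character scalar, human-readable name (defaults to the id).
#' @param species_k_o3 numeric vector of species-specific ozone rate constants
#'   in M^-1 s^-1, ordered from most protonated to most deprotonated species.
#'   Must have `length(pka_values) + 1` entries unless `below_determinable`.
#'   Optionally named with species labels.
#' @param pka_values numeric vector of acid dissociation constants (pKa
#'   units), strictly increasing. Empty for compounds without acid-base
#'   speciation.
#' @param k_oh second-order rate constant for reaction with hydroxyl radicals,
#'   M^-1 s^-1.
#' @param k_oh_sd standard deviation of `k_oh`, M^-1 s^-1.
#' @param k_o3_sd standard deviation of the apparent ozone rate constant,
#'   M^-1 s^-1.
#' @param below_determinable logical flag.
#' @return An object of class `reactivity_record`.
#' @examples
#' # tertiary amine reactive only in its neutral (deprotonated) form
#' rec <- reactivity_record("BE", "benzoylecgonine",
#'   species_k_o3 = c(protonated = 0, neutral = 5.5e5),
#'   pka_values = 9.14, k_oh = 5.9e9)
#' apparent_rate_constant(rec, ph = 7)
#' @seealso [apparent_rate_constant()], [species_fractions()], [apply_floor()]
#' @export
reactivity_record <- function(compound_id,
                              name = compound_id,
                              species_k_o3 = numeric(),
                              pka_values = numeric(),
                              k_oh = NA_real_,
                              k_oh_sd = NA_real_,
                              k_o3_sd = NA_real_,
                              below_determinable = FALSE) {
  stopifnot(is.character(compound_id), length(compound_id) == 1L,
            nzchar(compound_id))
  stopifnot(is.character(name), length(name) == 1L)
  species_k_o3 <- as.numeric2(species_k_o3)
  pka_values <- as.numeric2(pka_values)
  if (length(pka_values) && any(!is.finite(pka_values)))
    stop("pka_values must all be finite, got: ",
         paste(pka_values, collapse = ", "))
  if (length(pka_values) > 1L && any(diff(pka_values) <= 0))
    stop("pka_values must be strictly increasing for '", compound_id, "'")
  if (length(species_k_o3)) {
    if (any(!is.finite(species_k_o3)) || any(species_k_o3 < 0))
      stop("species_k_o3 must be finite and >= 0 for '", compound_id, "'")
    if (length(species_k_o3) != length(pka_values) + 1L)
      stop("'", compound_id, "': ", length(species_k_o3),
           " species rate constants do not match a pKa ladder of length ",
           length(pka_values), " (need ", length(pka_values) + 1L, ")")
  } else if (!below_determinable) {
    stop("'", compound_id,
         "': species_k_o3 may only be empty when below_determinable")
  }
  if (!is.na(k_oh) && k_oh < 0) stop("k_oh must be >= 0")
  structure(
    list(compound_id = compound_id, name = name,
         species_k_o3 = species_k_o3, pka_values = pka_values,
         k_oh = k_oh, k_oh_sd = k_oh_sd, k_o3_sd = k_o3_sd,
         below_determinable = isTRUE(below_determinable)),
    class = "reactivity_record")
}

# tolerant numeric coercion keeping names
as.numeric2 <- function(x) {
  if (is.null(x)) return(numeric())
  out <- as.numeric(x)
  names(out) <- names(x)
  out
}

#' @export
print.reactivity_record <- function(x, ...) {
  cat("<reactivity_record> ", x$compound_id,
      if (!identical(x$name, x$compound_id)) paste0(" (", x$name, ")"),
      "\n", sep = "")
  if (x$below_determinable && !length(x$species_k_o3)) {
    cat("  k(O3): below determinable\n")
  } else {
    lab <- names(x$species_k_o3)
    if (is.null(lab)) lab <- paste0("species", seq_along(x$species_k_o3))
    cat("  k(O3) by species [M-1 s-1]: ",
        paste(sprintf("%s=%.3g", lab, x$species_k_o3), collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$pka_values))
    cat("  pKa: ", paste(format(x$pka_values), collapse = ", "), "\n",
        sep = "")
  if (!is.na(x$k_oh))
    cat("  k(OH) [M-1 s-1]: ", format(x$k_oh, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Read and write compound reactivity tables
#'
#' The on-disk format is a plain CSV with one row per protonation state:
#' columns `compound_id,name,species_label,k_o3,k_o3_sd,pka_json,k_oh,
#' k_oh_sd,below_determinable`. `pka_json` holds the full pKa ladder of the
#' compound as a JSON array (repeated on each of the compound's rows);
#' species rows must appear in order from most protonated to most
#' deprotonated.
#'
#' @param path file path of the CSV.
#' @return `read_compound_table()` returns a named list of
#'   [reactivity_record()] objects; `write_compound_table()` writes and
#'   returns `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' recs <- list(reactivity_record("X", species_k_o3 = c(0, 2e6),
#'                                pka_values = 8.7, k_oh = 5e9))
#' write_compound_table(recs, tmp)
#' read_compound_table(tmp)
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "species_label", "k_o3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("compound table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"name" %in% names(df)) df$name <- df$compound_id
  if (!"pka_json" %in% names(df)) df$pka_json <- "[]"
  if (!"k_oh" %in% names(df)) df$k_oh <- NA_real_
  if (!"k_oh_sd" %in% names(df)) df$k_oh_sd <- NA_real_
  if (!"k_o3_sd" %in% names(df)) df$k_o3_sd <- NA_real_
  if (!"below_determinable" %in% names(df)) df$below_determinable <- FALSE
  bad <- which(is.finite(df$k_o3) & df$k_o3 < 0)
  if (length(bad))
    stop("negative k_o3 in row(s) ", paste(bad, collapse = ", "),
         " of ", path)
  recs <- lapply(split(df, factor(df$compound_id, unique(df$compound_id))),
    function(d) {
      pka <- jsonlite::fromJSON(d$pka_json[1])
      k <- d$k_o3
      names(k) <- d$species_label
      bd <- isTRUE(as.logical(d$below_determinable[1]))
      if (bd && all(is.na(k))) k <- numeric()
      reactivity_record(
        compound_id = d$compound_id[1], name = d$name[1],
        species_k_o3 = k, pka_values = as.numeric(pka),
        k_oh = as.numeric(d$k_oh[1]), k_oh_sd = as.numeric(d$k_oh_sd[1]),
        k_o3_sd = as.numeric(d$k_o3_sd[1]), below_determinable = bd)
    })
  names(recs) <- vapply(recs, `[[`, "", "compound_id")
  recs
}

#' @param records list of [reactivity_record()] objects.
#' @rdname read_compound_table
#' @export
write_compound_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    n <- max(1L, length(r$species_k_o3))
    lab <- names(r$species_k_o3)
    if (is.null(lab) || !length(lab))
      lab <- if (length(r$species_k_o3))
        paste0("species", seq_along(r$species_k_o3)) else NA_character_
    data.frame(
      compound_id = r$compound_id, name = r$name, species_label = lab,
      k_o3 = if (length(r$species_k_o3)) r$species_k_o3 else NA_real_,
      k_o3_sd = r$k_o3_sd,
      pka_json = as.character(
        jsonlite::toJSON(r$pka_values, digits = NA)),
      k_oh = r$k_oh, k_oh_sd = r$k_oh_sd,
      below_determinable = r$below_determinable,
      row.names = NULL)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
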