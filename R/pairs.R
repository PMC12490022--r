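#' Parent--metabolite pair annotation
#'
#' Curated qualitative annotation of a human-metabolism transformation
#' linking a parent pharmaceutical to one of its metabolites: the reaction
#' class of the functional-group change and where it occurs relative to the
#' parent's most ozone-reactive site. These annotations -- not molecular
#' structures -- are what the qualitative reactivity rules consume.
#'
#' @param parent_id,metabolite_id compound identifiers (must differ).
#' @param reaction_class one of `"aromatic_hydroxylation"`,
#'   `"alkyl_hydroxylation"`, `"n_oxidation"`,
#'   `"carboxylic_acid_formation"`, `"acetylation"`, `"sulfation"`,
#'   `"glucuronidation"`, `"glutathione_conjugation"`, `"n_dealkylation"`,
#'   `"o_dealkylation"`.
#' @param site_relation one of `"at_most_reactive_site"`,
#'   `"remote_from_most_reactive_site"`, `"creates_new_reactive_group"`.
#' @return object of class `metabolite_pair`.
#' @export
metabolite_pair <- function(parent_id, metabolite_id, reaction_class,
                            site_relation) {
  reaction_class <- match.arg(reaction_class, .REACTION_CLASSES)
  site_relation <- match.arg(site_relation, .SITE_RELATIONS)
  if (identical(parent_id, metabolite_id))
    stop("parent_id and metabolite_id must differ")
  structure(list(parent_id = parent_id, metabolite_id = metabolite_id,
                 reaction_class = reaction_class,
                 site_relation = site_relation),
            class = "metabolite_pair")
}

.REACTION_CLASSES <- c(
  "aromatic_hydroxylation", "alkyl_hydroxylation", "n_oxidation",
  "carboxylic_acid_formation", "acetylation", "sulfation",
  "glucuronidation", "glutathione_conjugation", "n_dealkylation",
  "o_dealkylation")
.SITE_RELATIONS <- c(
  "at_most_reactive_site", "remote_from_most_reactive_site",
  "creates_new_reactive_group")

#' Metabolite-versus-parent reactivity ratio
#'
#' Computes the ratio of the metabolite's to the parent's apparent ozone
#' rate constant at the working pH and classifies it by the factor-2 bands:
#' `faster` (ratio > 2), `slower` (ratio < 0.5), `similar` otherwise.
#' Below-determinable members receive the floor value (default
#' 1e-1 M^-1 s^-1, half of the lowest determinable rate constant) so the
#' ratio remains computable; the result is flagged `floored`.
#'
#' @param parent,metabolite [reactivity_record()]s.
#' @param pair optional [metabolite_pair()] annotation carried through.
#' @param ph working pH (default 7).
#' @param floor floor for below-determinable members.
#' @return object of class `pair_ratio`: `ratio`, `log10_ratio`,
#'   `classification`, `floored`, plus ids and the annotation.
#' @export
reactivity_ratio_class <- function(parent, metabolite, pair = NULL, ph = 7,
                                   floor = .K_FLOOR_DEFAULT) {
  stopifnot(inherits(parent, "reactivity_record"),
            inherits(metabolite, "reactivity_record"))
  if (parent$below_determinable && metabolite$below_determinable)
    stop("both members are below determinable; the ratio is undefined")
  k_p <- apply_floor(parent, ph = ph, floor = floor)
  k_m <- apply_floor(metabolite, ph = ph, floor = floor)
  if (k_p <= 0) stop("parent rate constant must be > 0")
  ratio <- k_m / k_p
  cls <- if (ratio > 2) "faster" else if (ratio < 0.5) "slower" else "similar"
  structure(list(
    parent_id = parent$compound_id, metabolite_id = metabolite$compound_id,
    pair = pair, ratio = ratio, log10_ratio = log10(ratio),
    classification = cls,
    floored = parent$below_determinable || metabolite$below_determinable,
    reaction_class = if (!is.null(pair)) pair$reaction_class else NA_character_),
    class = "pair_ratio")
}

#' @export
print.pair_ratio <- function(x, ...) {
  cat("<pair_ratio> ", x$metabolite_id, " / ", x$parent_id, ": ratio ",
      signif(x$ratio, 3), " (", x$classification,
      if (x$floored) ", floored", ")\n", sep = "")
  invisible(x)
}

#' Qualitative relative-reactivity verdict for a metabolite
#'
#' Rule engine condensing the observed effects of human-metabolism
#' functional-group changes on ozone reactivity into a qualitative verdict:
#' whether the metabolite is expected to react `faster`, `similar` or
#' `slower` than its parent, with a coarse magnitude hint. The rules:
#'
#' * aromatic hydroxylation creating a new phenol-type group: faster
#'   (tens to tens-of-thousands-fold), unless an equally or more reactive
#'   moiety already dominates the parent (`dominant_other_site`), then
#'   similar;
#' * alkyl hydroxylation: similar;
#' * N-oxidation at the most reactive site (the amine): slower, possibly by
#'   more than 2 orders of magnitude; remote from it: similar;
#' * carboxylic-acid formation: similar -- smallest effect of all classes --
#'   unless the new carboxylate is conjugated to the reactive olefin
#'   (`conjugated_to_olefin`), then faster by about 1 order of magnitude;
#' * acetylation or sulfation at a phenol or aniline: slower (the reactive
#'   group is converted to an amide/ester); remote: similar;
#' * glucuronidation covering the most reactive site: slower; remote:
#'   similar;
#' * N-dealkylation: slower, up to 2 orders of magnitude (loss of inductive
#'   electron donation at the nitrogen);
#' * O-dealkylation creating a phenol: faster (10- to ~800-fold), unless a
#'   phenol is already present (`dominant_other_site`), then similar;
#' * anything else (including glutathione conjugation, whose effect is
#'   case-specific): indeterminate.
#'
#' @param pair a [metabolite_pair()].
#' @param dominant_other_site logical: does the parent carry another moiety
#'   at least as reactive as the group being created/modified?
#' @param conjugated_to_olefin logical: is a newly formed carboxylate
#'   conjugated to the parent's reactive olefin?
#' @return object of class `flowchart_verdict`: `direction` (`faster`,
#'   `similar`, `slower`, `indeterminate`), `magnitude_hint` (`none`,
#'   `about_1_order`, `up_to_2_orders`, `ge_2_orders`), `rule_id`,
#'   `rationale`.
#' @examples
#' p <- metabolite_pair("efavirenz", "8-OH-efavirenz",
#'                      "aromatic_hydroxylation", "creates_new_reactive_group")
#' flowchart_predict(p)
#' @export
flowchart_predict <- function(pair, dominant_other_site = FALSE,
                              conjugated_to_olefin = FALSE) {
  stopifnot(inherits(pair, "metabolite_pair"))
  v <- function(direction, magnitude_hint, rule_id, rationale) {
    if (direction == "indeterminate") magnitude_hint <- "none"
    structure(list(direction = direction, magnitude_hint = magnitude_hint,
                   rule_id = rule_id, rationale = rationale),
              class = "flowchart_verdict")
  }
  rc <- pair$reaction_class
  sr <- pair$site_relation
  if (rc == "aromatic_hydroxylation") {
    if (dominant_other_site)
      return(v("similar", "none", "ar_oh_dominated",
               "new phenol-type group, but an equally or more reactive moiety already governs the parent's reactivity"))
    return(v("faster", "ge_2_orders", "ar_oh",
             "hydroxylation of an aromatic ring forms a phenol-type structure, raising ozone reactivity by orders of magnitude"))
  }
  if (rc == "alkyl_hydroxylation")
    return(v("similar", "none", "alkyl_oh",
             "hydroxylation of an alkyl chain leaves the reactive moieties untouched"))
  if (rc == "n_oxidation") {
    if (sr == "at_most_reactive_site")
      return(v("slower", "ge_2_orders", "n_ox_at_amine",
               "the amine lone pair is bound to oxygen, strongly reducing electron density at the nitrogen"))
    return(v("similar", "none", "n_ox_remote",
             "the parent reacts mainly at other functional groups, so oxidizing the amine changes little"))
  }
  if (rc == "carboxylic_acid_formation") {
    if (conjugated_to_olefin)
      return(v("faster", "about_1_order", "cooh_conjugated",
               "the carboxylate (deprotonated at neutral pH) donates electron density into the conjugated reactive olefin"))
    return(v("similar", "none", "cooh",
             "neither carboxylic acids nor their precursors react quickly with ozone; smallest effect of all classes"))
  }
  if (rc %in% c("acetylation", "sulfation")) {
    if (sr == "at_most_reactive_site")
      return(v("slower", "up_to_2_orders", paste0(rc, "_at_site"),
               "conjugation converts the reactive phenol/aniline into a deactivated ester/amide"))
    return(v("similar", "none", paste0(rc, "_remote"),
             "the conjugated group is not the reactivity-determining moiety"))
  }
  if (rc == "glucuronidation") {
    if (sr == "at_most_reactive_site")
      return(v("slower", "up_to_2_orders", "gluc_at_site",
               "the glucuronide covers the most reactive site"))
    return(v("similar", "none", "gluc_remote",
             "the glucuronide is far from the most reactive sites; reactivity is unchanged"))
  }
  if (rc == "n_dealkylation")
    return(v("slower", "up_to_2_orders", "n_dealk",
             "loss of the alkyl group removes inductive electron donation at the nitrogen"))
  if (rc == "o_dealkylation") {
    if (dominant_other_site)
      return(v("similar", "none", "o_dealk_dominated",
               "a phenol or more reactive moiety is already present; unmasking another changes little"))
    return(v("faster", "about_1_order", "o_dealk",
             "demethylation of the aromatic ether unmasks a phenol, raising reactivity 10- to ~800-fold"))
  }
  v("indeterminate", "none", "uncovered",
    paste0("no rule covers reaction class '", rc,
           "'; its effect is case-specific"))
}

#' @export
print.flowchart_verdict <- function(x, ...) {
  cat("<flowchart_verdict> ", x$direction,
      if (x$magnitude_hint != "none") paste0(" (", x$magnitude_hint, ")"),
      " [", x$rule_id, "]\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}

#' Per-reaction-class summary of reactivity ratios
#'
#' Summarizes a set of metabolite/parent ratios by reaction class: group
#' size, median/min/max log10 ratio, and the fractions classified faster,
#' similar and slower. Classes without any pair are omitted.
#'
#' @param ratios list of `pair_ratio` objects (from
#'   [reactivity_ratio_class()]); pairs without a reaction-class annotation
#'   are grouped under `"unannotated"`.
#' @return data.frame with one row per reaction class.
#' @export
pair_group_summary <- function(ratios) {
  stopifnot(length(ratios) > 0)
  df <- data.frame(
    reaction_class = vapply(ratios, function(r)
      if (is.na(r$reaction_class)) "unannotated" else r$reaction_class, ""),
    log10_ratio = vapply(ratios, `[[`, numeric(1), "log10_ratio"),
    classification = vapply(ratios, `[[`, "", "classification"),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(df, df$reaction_class), function(d)
    data.frame(
      reaction_class = d$reaction_class[1], n = nrow(d),
      median_log10_ratio = stats::median(d$log10_ratio),
      min_log10_ratio = min(d$log10_ratio),
      max_log10_ratio = max(d$log10_ratio),
      frac_faster = mean(d$classification == "faster"),
      frac_similar = mean(d$classification == "similar"),
      frac_slower = mean(d$classification == "slower"),
      stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Read a parent--metabolite pairs table
#'
#' CSV with columns `parent_id`, `metabolite_id`, `reaction_class`,
#' `site_relation` and optionally `dominant_other_site`,
#' `conjugated_to_olefin` (logical flags for the rule engine) and
#' `expected_direction` (curated reference verdicts, e.g. for validation
#' fixtures).
#'
#' @param path CSV file path.
#' @return data.frame with a `pair` list-column of [metabolite_pair()]
#'   objects.
#' @export
read_pairs_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("parent_id", "metabolite_id", "reaction_class", "site_relation")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pairs table missing column(s): ", paste(miss, collapse = ", "))
  if (!"dominant_other_site" %in% names(df)) df$dominant_other_site <- FALSE
  if (!"conjugated_to_olefin" %in% names(df)) df$conjugated_to_olefin <- FALSE
  df$pair <- lapply(seq_len(nrow(df)), function(i)
    metabolite_pair(df$parent_id[i], df$metabolite_id[i],
                    df$reaction_class[i], df$site_relation[i]))
  df
}
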