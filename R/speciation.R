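#' Acid-base species fractions of a polyprotic compound
#'
#' Computes the equilibrium fraction of each protonation state of a compound
#' with the given pKa ladder at the given pH, by the standard polyprotic
#' mass-action expressions. For `n` pKa values there are `n + 1` species,
#' returned in order from the most protonated to the most deprotonated state;
#' the fractions sum to 1.
#'
#' The computation is carried out on the log10 scale (relative to the largest
#' cumulative term) so that ladders far from the working pH do not underflow.
#'
#' @param pka_values numeric vector of pKa values, sorted strictly ascending;
#'   may be empty (single species, fraction 1).
#' @param ph pH at which to speciate; must lie in (0, 14).
#' @return numeric vector of `length(pka_values) + 1` fractions summing to 1.
#' @examples
#' species_fractions(8.74, ph = 8.74)  # 0.5 / 0.5 at pH = pKa
#' species_fractions(8.74, ph = 7)     # mostly protonated
#' species_fractions(c(6.3, 10.33), ph = 8)  # carbonate system
#' @export
species_fractions <- function(pka_values, ph) {
  pka_values <- as.numeric(pka_values)
  stopifnot(is.numeric(ph), length(ph) == 1L)
  if (!is.finite(ph) || ph <= 0 || ph >= 14)
    stop("ph must be a finite value in (0, 14), got ", ph)
  if (length(pka_values) && any(!is.finite(pka_values)))
    stop("pka_values must all be finite, got: ",
         paste(pka_values, collapse = ", "))
  if (length(pka_values) > 1L && any(diff(pka_values) <= 0))
    stop("pka_values must be strictly increasing")
  # cumulative log10 weight of species i (0-based deprotonation count):
  # sum_{j<=i} (ph - pKa_j); species 0 has weight 0
  lw <- c(0, cumsum(ph - pka_values))
  w <- 10^(lw - max(lw))
  w / sum(w)
}

#' Apparent second-order ozone rate constant at a given pH
#'
#' Weights the species-specific rate constants of a compound by its acid-base
#' speciation at the working pH: `k_app = sum_i alpha_i(pH) * k_i`, with the
#' fractions `alpha_i` from [species_fractions()]. This is the speciation
#' correction used when reactivity is carried by one protonation state (e.g.
#' the neutral form of an amine or the phenolate of a phenol).
#'
#' @param record a [reactivity_record()].
#' @param ph working pH.
#' @return apparent rate constant in M^-1 s^-1.
#' @examples
#' rec <- reactivity_record("X", species_k_o3 = c(0, 2e6), pka_values = 8.74)
#' apparent_rate_constant(rec, ph = 7)
#' @export
apparent_rate_constant <- function(record, ph) {
  stopifnot(inherits(record, "reactivity_record"))
  if (!length(record$species_k_o3)) {
    if (record$below_determinable)
      stop("'", record$compound_id, "' is below determinable; use ",
           "apply_floor() to obtain a usable rate constant")
    stop("'", record$compound_id, "' has no species rate constants")
  }
  if (length(record$species_k_o3) != length(record$pka_values) + 1L)
    stop("'", record$compound_id, "': number of species (",
         length(record$species_k_o3), ") does not match pKa ladder length + 1")
  alpha <- species_fractions(record$pka_values, ph)
  sum(alpha * record$species_k_o3)
}

#' Floor rule for below-determinable rate constants
#'
#' Compounds whose ozone reactivity lies below the minimum determinable by
#' the competitor set receive a nominal rate constant equal to half of the
#' lowest determined value (default 1e-1 M^-1 s^-1) so that ratio and
#' abatement calculations remain possible. Determinable compounds pass
#' through their apparent rate constant unchanged.
#'
#' @param record a [reactivity_record()].
#' @param ph working pH used for determinable compounds (default 7).
#' @param floor rate constant substituted for below-determinable compounds,
#'   M^-1 s^-1.
#' @return rate constant in M^-1 s^-1.
#' @examples
#' bd <- reactivity_record("slow", below_determinable = TRUE)
#' apply_floor(bd)          # 0.1
#' apply_floor(bd, floor = 0.05)
#' @export
apply_floor <- function(record, ph = 7, floor = .K_FLOOR_DEFAULT) {
  stopifnot(inherits(record, "reactivity_record"), floor >= 0)
  if (record$below_determinable) return(floor)
  apparent_rate_constant(record, ph)
}
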