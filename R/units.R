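#' Unit conversions and physico-chemical constants
#'
#' Package-wide unit conventions: second-order rate constants in M^-1 s^-1,
#' oxidant exposures in M s, concentrations in mol L^-1 (M). Plant scenario
#' tables usually report scavenger inventories in mixed practical units
#' (mg C/L dissolved organic matter, mmol/L alkalinity, ug N/L nitrite,
#' mg/L bromide); these helpers convert them onto the molar basis the
#' kinetic expressions need.
#'
#' @param x numeric vector of concentrations.
#' @param molar_mass molar mass in g mol^-1 of the species being converted.
#' @return numeric vector in mol L^-1.
#' @examples
#' mg_per_l_to_molar(0.06, molar_mass = 79.904)  # bromide
#' ug_n_per_l_to_molar(23.9)                     # nitrite on the N basis
#' @name units
NULL

# molar mass of nitrogen, g/mol (N-basis reporting of nitrite/ammonium)
.MM_NITROGEN <- 14.0067

#' @rdname units
#' @export
mg_per_l_to_molar <- function(x, molar_mass) {
  stopifnot(is.numeric(x), is.numeric(molar_mass), molar_mass > 0)
  x / 1000 / molar_mass # mg -> g -> mol, per L
}

#' @rdname units
#' @export
ug_n_per_l_to_molar <- function(x) {
  stopifnot(is.numeric(x))
  x * 1e-6 / .MM_NITROGEN
}

#' @rdname units
#' @export
mmol_per_l_to_molar <- function(x) {
  stopifnot(is.numeric(x))
  x * 1e-3
}

# second pKa of carbonic acid (bicarbonate/carbonate) at 25 degrees C
.PKA2_CARBONATE <- 10.33

# second-order rate constant of pCBA + hydroxyl radical, M^-1 s^-1
.K_PCBA_OH <- 5.2e9

# default floor assigned to compounds whose ozone rate constant lies below
# the minimum determinable by the competitor set (half the lowest determined
# value), M^-1 s^-1
.K_FLOOR_DEFAULT <- 1e-1
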