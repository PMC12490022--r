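---
title: "Competition kinetics and abatement modeling for wastewater ozonation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competition kinetics and abatement modeling for wastewater ozonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ozonekin)
```

## The problem

Ozonation of secondary wastewater effluent abates pharmaceuticals and their
human metabolites through two oxidants: ozone itself and the hydroxyl
radicals formed from its decomposition. For a compound with apparent
second-order rate constants $k_{O_3}$ and $k_{\bullet OH}$ (M$^{-1}$
s$^{-1}$), first-order kinetics in both oxidants give

$$-\ln\frac{c_{out}}{c_{in}} = k_{O_3}\int [O_3]\,dt
  + k_{\bullet OH}\int [\bullet OH]\,dt,$$

where the two integrals are the ozone and hydroxyl-radical *exposures*
(M s), properties of the water matrix and the applied specific ozone dose
(g O$_3$ per g DOC). Percent abatement follows as
$A = (1 - e^{-x})\cdot 100$ with
$x = k_{O_3}\int[O_3]dt + k_{\bullet OH}\int[\bullet OH]dt$.

Everything in this package serves that equation: determining $k_{O_3}$
from multicompound competition experiments, obtaining the exposures from
probe measurements and dose correlations, propagating uncertainty through
the abatement prediction, asking which of the four parameters the
prediction is sensitive to, and condensing parent-versus-metabolite
reactivity patterns into qualitative rules. A synthetic-data module
generates all inputs with the statistical structure the estimators assume,
so the chain is testable end to end without laboratory data.

## Competition kinetics

In a multicompound ozonation experiment every compound in a vial
experiences the same ozone exposure. For a target and a competitor with
known rate constant this links their depletions:

$$\ln\frac{A_t}{A_{t,0}} = \frac{k_t}{k_c}\,\ln\frac{A_c}{A_{c,0}},$$

so the slope of an ordinary least-squares regression of the target's log
depletion on the competitor's yields $k_t = \text{slope}\times k_c$. Peak
areas stand in for concentrations because only relative abatement enters.
`log_depletions()` references each area to the zero-dose vial of the same
replicate, which cancels replicate-level injection variability;
replicates are pooled into one regression to maximize the usable point
count.

Four quality-control gates decide whether a pair contributes
(`qc_evaluate()`): at least 10 data points; $R^2 > 0.9$; a negligible
intercept; and a slope between 0.1 and 10, i.e. target and competitor
within one order of magnitude. The intercept rule is implemented as
printed in the source protocol, $|b| < 10\,|m|$, which is nearly always
satisfied and is plausibly a typographical inversion of the strict
reading $|b| < 0.1\,|m|$; both readings are evaluated and reported, the
strict one behind `strict_intercept = TRUE`, and neither is asserted as
the intended rule. Estimates from all passing competitors are averaged
(`estimate_k()`); the standard deviation across competitor-specific
estimates is reported as `k_sd`.

### Windowing

Only data points between 10 and 90% abatement carry kinetic information
at realistic noise levels. Whether that window applies to the target
alone or to both pair members is ambiguous; the package defaults to the
symmetric reading (`window = "both"`) and offers `window = "target"` as a
switch. The symmetric window has a statistical virtue beyond its
plausibility: regression of a noisy response on a noisy regressor
attenuates the slope by roughly
$\mathrm{var}(x)/(\mathrm{var}(x)+\sigma_x^2)$, and competitor points
below 10% abatement have log depletions comparable to the noise floor,
biasing the slope low by up to 10--15% at a 5% area CV. Excluding them
removes most of that attenuation. Target-only windowing is useful when
target and competitor reactivities are far apart (ratio near the
slope-gate limit): the mutual 10--90% window then spans barely a factor
of two in exposure and cannot hold ten points on a practical dose grid,
whereas the competitor's log depletion beyond 90% abatement remains exact
under multiplicative noise. On synthetic data, which has no detection
limit, this is a safe trade; on real data the competitor signal
eventually hits instrument noise.

### Uncertainty of the averaged estimate

Competitor-specific estimates for one target come from the same vials and
share the target's measurement noise, so they are strongly positively
correlated and their spread (`k_sd`) understates the error of the
average. `estimate_k()` therefore also reports `k_se`, which keeps the
full mean within-regression slope standard error (no $1/\sqrt{m}$
averaging gain is assumed, the conservative choice under unknown positive
correlation) and adds the between-competitor variance in quadrature. In
recovery simulations `k_app` $\pm\ 2\,$`k_se` covers the truth at
roughly the nominal rate, while $\pm\ 2\,$`k_sd` does not; `k_sd` is
still reported because it is the conventional summary of
multi-competitor agreement.

## The synthetic-data generator

`generate_competition_experiment()` emulates: one shared true exposure
per dose level; first-order compound depletion; multiplicative lognormal
peak-area noise (default CV 5% — triplicate experiments of this kind
report few-percent area repeatability, and a lognormal keeps areas
positive); triplicate experiments; and 12 non-zero dose levels plus a
zero-dose reference, enough for the ten-point gate after windowing.
Mixture validity is enforced by `mixture_spec()`: members within the
declared reactivity window, no two members within 5 mDa in exact mass,
and no member a declared oxidation product of another.

Vial exposures are not derived from a mechanistic ozone-decay model — the
regression needs only that they are shared — but are log-spaced over a
range chosen from the mixture, mirroring a protocol in which doses are
fine-tuned in preliminary tests to yield enough usable points. Two
designs are available: `dose_design = "pairs"` (default) spans the union
of the mutual 10--90% windows of all target/competitor pairs inside the
slope gate, concentrating doses where pairs are jointly quantifiable;
`"members"` spans the union of the individual compound windows, which
covers each compound's own window at the cost of thinner pair overlap.
`plan_mixtures()` groups targets with the nearest competitor and attaches
every competitor within one order of magnitude, mimicking mixtures that
cover limited, partially overlapping reactivity ranges.

The generator does **not** emulate: detection limits on depleted peaks,
compound-derived ozone demand (starting concentrations in the tens of
nmol/L are treated as negligible consumers), matrix effects on
ionization, ozone-stock decay, or temperature variation. Passing recovery
tests therefore demonstrate the statistical soundness of the estimator
under the stated noise model, not robustness to those instrumental
effects.

`generate_pcba_assay()` and `generate_wwtp_dataset()` provide the probe
and field counterparts: pCBA depletion at a true hydroxyl-radical
exposure, and influent/effluent pairs over consecutive sampling days
(default five) with lognormal day-to-day noise (default CV 10%) and
LOQ-censored effluents. Default influent concentrations are drawn
log-uniformly from $10^{-8}$--$10^{-7}$ M (tens of ng/L to tens of µg/L)
with an LOQ of $10^{-9}$ M, typical of multi-residue wastewater
analysis.

## Speciation and apparent rate constants

For compounds with acid-base speciation the apparent constant is the
speciation-weighted sum $k_{app} = \sum_i \alpha_i(\mathrm{pH})\,k_i$
over protonation states. `species_fractions()` evaluates the standard
polyprotic mass-action expressions on the log10 scale so that ladders far
from the working pH do not underflow. Species are ordered **from most
protonated to most deprotonated** throughout the package — the
convention must be fixed somewhere, and this matches the direction of a
titration. The practical importance of getting pKa right falls out
directly: for a tertiary amine reactive in its neutral form, moving the
pKa from 9.14 to 11.8 changes the apparent constant at pH 7 by
$(1+10^{4.8})/(1+10^{2.14}) \approx 454$, about 2.7 orders of magnitude.

Compounds below the determinable range of the competitor panel receive a
floor value via `apply_floor()`, default $10^{-1}$ M$^{-1}$ s$^{-1}$
(half of the lowest determined constant). The floor is a configurable
argument, not a constant, so the sensitivity of downstream
metabolite/parent ratios to it can be examined.

## Structure-reactivity correlations

`predict_species_k()` evaluates linear free-energy correlations
$\log_{10} k = a + \rho \sum \sigma$; olefin and amine families pair with
Taft $\sigma^*$ constants, benzene/phenol/phenolate/aniline families with
Hammett $\sigma^+/\sigma^-$ constants, and the pairing is validated.
`predict_apparent_k()` adds the speciation weighting. Correlation
coefficients are deliberately **not** hard-coded: the published
calibrations are not reproduced here, so the package ships only a
parameter-file schema (`read_qsar_parameters()`) plus a clearly labelled
synthetic example; tests use synthetic correlations. When no correlation
applies, the conservative-estimate route is to adopt the rate constant of
the compound's most ozone-reactive structural moiety directly.
`prediction_performance()` summarizes measured-versus-predicted agreement
as log10 ratios and fractions within one and two orders of magnitude.

## Exposures

The hydroxyl-radical exposure comes from the depletion of the
ozone-recalcitrant probe *para*-chlorobenzoic acid:
$\int[\bullet OH]dt = -\ln(A/A_0)/k_{pCBA,\bullet OH}$ with
$k_{pCBA,\bullet OH} = 5.2\times 10^9$ M$^{-1}$ s$^{-1}$ (overridable).
Scavenging budgets (`scavenging_shares()`) apportion the total
hydroxyl-radical sink among dissolved organic matter, carbonate species,
nitrite and bromide as $k_i[S_i]/\sum_j k_j[S_j]$. Alkalinity is
interpreted as acid-neutralizing capacity,
$[\mathrm{HCO_3^-}] + 2[\mathrm{CO_3^{2-}}]$, and split by carbonate
speciation with p$K_{a2} = 10.33$ at 25 °C; nitrogen-based units are
converted on the N basis. The scavenger rate constants live in an
editable CSV whose defaults draw on the Buxton et al. (1988) radiolysis
compilation and Westerhoff et al. (1999) for DOM — site-specific values
can simply replace the file, and reported shares depend on that choice.

Where direct ozone-exposure measurement is impossible (at low specific
doses the ozone decays too fast for the indigo method),
`fit_dose_exposure_correlation()` fits $\ln(\text{exposure})$ against
$\ln(\text{dose})$ over user-supplied reference plants and extrapolates.
The two bundled example reference points do not by themselves reproduce
any particular literature extrapolation; the operation requires the
user's reference set. `ozone_stock_concentration()` converts stock
absorbance at 260 nm by Beer–Lambert with
$\varepsilon = 3200$ M$^{-1}$ cm$^{-1}$.

## Abatement modeling and Monte Carlo

`predict_abatement()` is the exponential model above;
`measured_abatement()` computes $(1 - c_{out}/c_{in})\cdot 100$ and
substitutes $0.5\times$LOQ for censored effluent values. Phase I
metabolites can be excluded from field modeling (`exclude_ids` in
`model_abatement()`): transformation products identical to them form
during ozonation itself, so their field mass balance is confounded.

`monte_carlo_abatement()` samples the four parameters independently:
normal distributions for the rate constants and the hydroxyl-radical
exposure, truncated at zero by resampling (rate constants and exposures
are nonnegative; truncation is the least informative way to impose
that), and a uniform $\pm 80\%$ band for the ozone exposure, whose
literature-derived value is the most uncertain input. Scenario files
carry an inflation factor (default 10) applied to the hydroxyl-radical
exposure SD before sampling, reflecting matrix variability between the
campaign in which the exposure was measured and the one being modeled.
The default draw count is 10,000; the summary reports the mean, the SD
and the 2.5th/97.5th percentiles — whether published error bars of this
kind are SDs or percentiles is often unstated, so both are emitted.

## Sensitivity analysis

The partial derivatives of $A$ are closed-form:
$\partial A/\partial k_{O_3} = 100\,e^{-x}\int[O_3]dt$ and symmetrically
for the other three parameters (`abatement_partials()`). Two
normalizations are implemented because the exact published normalization
is not available: `elasticity`, $(\partial A/\partial p)\,p/A$, the
percent change in abatement per percent parameter change; and
`share_of_total`, each elasticity over their sum, which sums to one.
`share_of_total` is the default since population summaries of such
indices are most interpretable as shares. Because each rate constant
enters only through its product with the matching exposure, the two
members of each oxidant pair always have identical elasticities.

`classify_regime()` encodes the saturation logic: above a plant-specific
upper threshold of $k_{O_3}$ abatement reaches 100% and is insensitive
to the ozone parameters (thresholds $10^4$ M$^{-1}$ s$^{-1}$ for the
moderate/high-dose example plants, $10^7$ for the low-dose plant);
below the lower threshold ($10^3$, resp. $10^4$) the hydroxyl-radical
pathway dominates. Thresholds are scenario configuration, and values
exactly on a threshold fall in the mixed band.

## Metabolite-versus-parent rules

`reactivity_ratio_class()` classifies $k_{met}/k_{parent}$ with the
factor-2 bands (faster / similar / slower) used for ratio plots;
below-determinable members enter at the floor value and are flagged.
`flowchart_predict()` is a rule engine over curated annotations — the
reaction class of the metabolic transformation and its position relative
to the parent's most reactive site — rather than molecular structures,
because the qualitative decision procedure it encodes operates on
exactly that information and structure perception would import a large
body of unstated chemistry. Aromatic hydroxylations creating phenol-type
groups predict faster metabolites unless another equally reactive moiety
already dominates; N-oxidations at the reactive amine predict slower,
remote ones similar; carboxylic-acid formation is neutral except when
the new carboxylate conjugates to a reactive olefin; acetylation,
sulfation and glucuronidation slow the metabolite when they cover the
reactive group; N-dealkylation slows by up to two orders of magnitude;
O-dealkylation unmasking a phenol accelerates unless a phenol was
already present. Glutathione conjugation and aromaticity-changing
glucuronidations are deliberately uncovered — their observed effects are
case-specific pKa or electronic-structure arguments, not a rule — and
return `indeterminate`, never an error. A curated table of worked pairs
with reference directions ships in `extdata/worked_pairs.csv` and the
rule engine reproduces all of their directions.

## Numerical choices and degenerate inputs

* Species fractions are computed relative to the largest cumulative
  log-weight, so extreme ladders neither overflow nor underflow; the
  fractions sum to one within $10^{-12}$ for ladders up to length 4.
* Regressions with fewer than two matched points fail with a message
  naming the pair; zero-dose references are required per replicate.
* Monte Carlo normal draws with zero spread short-circuit to the center,
  making the zero-spread case exactly equal to the point prediction.
* The below-determinable status requires both that the target never
  exceeds 10% abatement and that the least reactive competitor is
  depleted beyond 90% somewhere in the series — distinguishing "too slow
  for this panel" from an analytically failed estimate. This heuristic
  is a package decision; the underlying distinction is not standardized.
* Boundary QC slopes (exactly 0.1 or 10) pass the gate; regime
  thresholds classify as mixed.

## Problem sizes used by the test suite

Recovery is exercised with 30 targets log-spaced over
$10^{-1}$--$10^{8}$ M$^{-1}$ s$^{-1}$ against a 15-competitor panel
spanning 1--$10^{8}$, 12 doses × 3 replicates, at CV 0 and 5%; the
field-scale check uses 40 compounds over the same range with 10% noise
and five sampling days; Monte Carlo bound checks use $10^5$ draws. The
recovery simulation uses `window = "target"` with the `"members"` dose
design so that the full nine-order range — including targets a full
order below the least reactive competitor, whose mutual window cannot
hold ten points — remains estimable; the attenuation this admits is
visible in the recovery medians (about 0.015 log10 units) and is covered
by the reported `k_se`. At a 5% area CV, targets more than about a
factor of five below the least reactive competitor fail the $R^2$ gate
legitimately: over the short usable exposure range their depletion
barely exceeds the noise. The same effect caps real panels from below
and motivates the floor value.

## Known limitations

* No errors-in-variables or weighted regression: the protocol being
  implemented uses plain OLS, and the residual attenuation at wide
  reactivity gaps is documented rather than corrected.
* Temperature dependence (Arrhenius-type corrections of $k_{O_3}$) is
  out of scope; activation energies vary too much between compounds for
  a general treatment.
* Exposures are inputs or correlation-derived; there is no mechanistic
  ozone-decay or reactor-hydraulics model, and no bromate chemistry.
* QSAR predictions are only as good as the user-supplied correlation
  coefficients and substituent constants; the bundled file is synthetic
  and for testing only.
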