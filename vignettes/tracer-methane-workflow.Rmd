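---
title: "Closed-vessel tracer rates of methylphosphonate-driven methane formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-vessel tracer rates of methylphosphonate-driven methane formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpnmethane)
```

## The measurement problem

In phosphate-starved ocean surface waters, microbes cleave the C–P bond of
methylphosphonate (MPn) to scavenge phosphorus, releasing methane in oxic
water where methanogenesis should be impossible. The standard way to
quantify this is a closed incubation: seawater in a serum bottle, a
headspace of synthetic air, a ¹³C-labelled MPn amendment, and repeated
headspace sampling on a cavity ring-down spectrometer. Three features of
the protocol shape all the arithmetic downstream:

* only the **headspace** is measured, while methane partitions between gas
  and water;
* each sampling **removes tracer gas** and replaces it with clean air, so
  later measurements underestimate what the community produced;
* production is detected as **excess ¹³C**, the enrichment of the methane
  pool above the bottle's own t = 0 baseline.

## Mass balance

With liquid volume $V_l$, headspace $V_g$ and a dimensionless partition
coefficient $K_H$ (dissolved over gas-phase concentration at equilibrium),
the fraction of vessel methane in the headspace is

$$f_g = \frac{V_g}{V_g + K_H V_l},$$

so a headspace excess $A(t)\,(x^{13}(t) - x^{13}(0))$ scales to the whole
vessel by $1/f_g$. Each subsampling of volume $v_s$ removes the fraction
$a = (v_s/V_g) f_g$ of *everything then present*. Two corrections are
available:

* the classical closed-form factors $D_k = (1-a)^{-k}$
  (`dilution_correction_factors()`), exact for gas present since the start
  and the convention usually quoted with field rates;
* the per-event ledger used by `excess_13c_series()`: the excess removed
  with each prior subsample ($a$ times the excess then present, known from
  that time point's own measurement) is added back. This is the exact
  inverse of the sampling process for gas produced *between* samplings —
  for noise-free data the corrected series equals cumulative production to
  machine precision for any $K_H$, any schedule — and it is the identity
  the package's conservation tests enforce at 10⁻⁹. The two agree as
  $a \to 0$; at the default geometry (5 mL of 50 mL, $f_g = 0.89$) the
  closed-form factors would inflate a linear rate by ≈9 %, which is why the
  ledger is the computing path and the factors are reported alongside for
  comparison with conventionally corrected data.

Vessels are treated as fully re-equilibrated at each sampling instant
(bottles are swirled); no kinetic gas-exchange model is attempted. $K_H$
defaults to 0.032, a reasonable value for methane in warm (≈27 °C)
seawater, and is a settable constant of `vessel_geometry()` — the workflow
is insensitive to it within the plausible 0.02–0.04 range because $f_g$
stays near 0.9.

Instruments report either atom percent or δ¹³C; both are accepted, with
$x^{13} = R/(1+R)$, $R = (\delta/1000 + 1) R_\mathrm{VPDB}$,
$R_\mathrm{VPDB} = 0.0111802$. Rates are defined on the **excess-¹³C
scale**: what the excess calculation recovers is the ¹³C added above the
baseline, which understates total methane by the natural-abundance factor
$(1 - x_0) \approx 0.989$ — far inside measurement error, but the simulator
is explicit about it so round trips close exactly.

## Rate inference and the significance filter

The rate is the OLS slope of excess versus time over the first four time
points (0, 6, 12, 24 h), converted to per-day. A rate is kept only if the
one-sided t-test of slope > 0 gives p < 0.05 **and** R² > 0.81, on
df = 4 − 2 = 2. These two thresholds are not independent: for a simple
regression, $R^2 = t^2/(t^2 + \mathrm{df})$, and at df = 2 the one-sided
critical value $t_{0.05,2} = 2.920$ corresponds to $R^2 = 0.810$. The
joint filter is therefore an ordinary 5 % one-sided t-test made a hair
stricter by the R² inequality — its empirical type-I rate over 10⁴
simulated null incubations sits at ≈0.046–0.05, and the suite asserts the
≤ 0.05 bound under a fixed seed.

Incubations failing the filter are reported as **zero**, not dropped; they
stay in every group comparison. A failing fit whose 24 h excess is positive
and exceeds three times the larger of the 6/12 h excess and a detection
floor (default 0.01 nmol L⁻¹) is classed `exponential` — production only in
the last fitted time point, the late-onset behaviour occasionally seen when
opportunists bloom — and likewise zeroed, since only linear 0–24 h
production is quantified. The factor 3 and the floor are the package's
operationalization of "clearly exponential"; they matter only for
labelling, never for the (zero) rate. Negative slopes are by construction
never significant under the one-sided test and are never reported as
consumption.

Significant slopes are divided by the labelling fraction of the substrate
pool: 1 for MPn amendments (1 µmol L⁻¹ against sub-nanomolar in-situ
concentrations) and ≈0.1 for DIC amendments. Methane oxidation inside the
vessel is deliberately **not** corrected for — any oxidation makes the
reported formation rates underestimates, and the simulator's optional
first-order loss term (`oxidation_k`) exists to demonstrate exactly that
bias direction.

## Nutrients, statistics, coupling, marker genes

Nutrient handling is bookkeeping with censoring: LOD = blank mean + 3 sd;
OP = TP − Pi and DOP = OP − POP with negative derived pools floored and
flagged; N:P = (NOx + NH₄)/Pi reported as *censored* whenever Pi is below
its LOD (default 10 nmol L⁻¹) — no LOD/2 substitution, because
"unquantifiable because P-deplete" is the scientific signal. Default LODs
(Pi 10, NH₄ 24, NOx 583, NO₂ 33 nmol L⁻¹) are config values.

Rates are compared nonparametrically throughout (a Shapiro–Wilk gate
documents why): tie-corrected Kruskal–Wallis across the four depth
categories, then pairwise one-sided Wilcoxon rank-sum tests with
Benjamini–Hochberg adjustment — exact when both groups have n ≤ 10 without
ties, normal approximation with tie correction otherwise. Duplicates are
pooled, not averaged, before testing. Directions are configuration, with
defaults: shallower > deeper for depth pairs, repression (less) for the
Pi co-addition, enhancement (greater) for the nitrate co-addition. For
small samples `kruskal_wallis(..., p_method = "permutation")` replaces the
chi-squared approximation with full enumeration; the test suite checks
both it and the exact Wilcoxon path against independent enumeration
oracles to 10⁻¹².

Coupling to primary production uses the 1:1 CH₄:Pi stoichiometry of C–P
lyase demethylation: a carbon fixation rate implies a Redfield phosphate
demand `cfix/106`, and each methane rate is a phosphate supply, expressed
as an unclamped percentage of that demand. Quartiles of the supported
fraction use linear interpolation (`quantile` type 7); reporting rounds
demand to one decimal and percentages to integers.

Marker-gene arithmetic is the downstream end of a metagenomic pipeline
whose upstream (assembly, ORF calling, clustering, mapping) is out of
scope: counts are assumed mapped and filtered at strictly >80 % identity
(`identity_filter()` enforces the contract), TPM is the length-normalized
rate scaled to 10⁶, and *phnJ* abundance is the ratio of length-normalized
*phnJ* to *recA* counts — *recA* assumed single-copy per bacterium — as a
percentage of genomes. phnJ clusters are length-normalized individually
and then summed.

## The synthetic campaign

Every input has a seeded generator with ground truth attached. The forward
vessel model adds produced ¹³CH₄ to a natural-abundance background pool
(default 5 nmol per vessel, roughly air-equilibrated seawater plus
headspace), partitions by $f_g$, and applies the removal/replacement events
of the 0/6/12/24/48 h schedule. Gaussian noise (default sd 0.02 nmol L⁻¹
on the excess scale, a few percent of a typical surface signal and small
enough that rates near the deep medians of 0.06–0.07 remain mostly
detectable) enters the measured atom fraction; an atom-fraction-noise mode
exists for instrument-style realism.

The campaign layout is 12 stations × 4 depths × 2 replicates for each of
four amendments (96 incubations per treatment). True rates are drawn
lognormally around depth medians of 0.40, 0.30, 0.07 and 0.06
nmol CH₄ L⁻¹ d⁻¹ with a log-scale sigma of 1.36 (the value implied by a
0.21–1.31 interquartile range around a 0.40 median). Phosphate co-addition
multiplies true rates by 0.3 above and at the DCM (repression, absent
below the DCM where Pi is ambient), nitrate co-addition by 3, and the
DIC-only amendment produces nothing (its occasional "significant" rates in
a run are the filter's false positives — a realistic feature, not a bug).
Nutrient profiles censor Pi above and at the DCM and draw 100–400
nmol L⁻¹ below it, with TP = Pi + DOP + POP holding by construction.

What passing tests on this generator **does** show: the mass-balance,
filtering, statistics and normalization code is correct against known
answers, and the study design separates depth strata almost surely. What
it does **not** show: anything about real-ocean rate magnitudes or field
heterogeneity — the generator has no day/night cycling, no
*Trichodesmium*-style patchiness beyond the lognormal spread, no
photodegradation, no sequencing error model. Field quantities printed in
the literature (depth medians, per-fraction *phnJ* percentages, specific
TPM values) are recomputable only from the original expedition data, which
is why the acceptance checks that involve them use them as *inputs* to the
worked examples rather than targets of the simulation.

## Problem sizes and determinism

The test suite simulates at deliberately modest sizes — 10⁴ null
incubations for the type-I bound, 200 replicate campaigns for the
depth-separation check, 100–120 replicates per recovery case — which keeps
the full run around half a minute while leaving Monte-Carlo error well
inside the asserted tolerances. All generators consume the global R random
stream under a single recorded seed; `run_study()` seeds once at entry and
writes the seed, thresholds and md5 checksums of every output into its
manifest, so identical configurations are byte-identical end to end.
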