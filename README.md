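# mpnmethane

Aerobic methane formation in oxygenated ocean surface waters — the "marine
methane paradox" — is driven in large part by microbial cleavage of
methylphosphonate (MPn), an organic phosphorus compound used when dissolved
inorganic phosphate (Pi) is scarce. C–P lyase demethylation releases CH₄ and
Pi in 1:1 stoichiometry, so closed-vessel ¹³C-MPn tracer incubations measure
both a greenhouse-gas source and a phosphorus supply to primary producers.

`mpnmethane` implements the full quantitative chain for such campaigns, for
biogeochemists working up shipboard incubation data (or stress-testing a
design before a cruise):

1. **Tracer mass balance** — converts serially subsampled headspace
   measurements (CH₄ amount or ppm; ¹³C atom fraction or δ¹³C) from a
   closed vessel into excess ¹³C-CH₄ per litre of incubated water,
   `E(t) = CH₄(t) · (x¹³(t) − x¹³(0)) / f_g`, with
   `f_g = V_g / (V_g + K_H·V_l)` the equilibrium headspace fraction and an
   exact per-event correction for the tracer removed by each subsampling.
2. **Rate inference** — OLS slope of the first four time points (0–24 h),
   kept only when the one-sided t-test of slope > 0 gives p < 0.05 with
   R² > 0.81 on df = 2; late-onset ("exponential") and insignificant
   incubations are reported as zero; significant slopes are divided by the
   labelling fraction (1 for MPn, ~0.1 for DIC amendments).
3. **Nutrient bookkeeping** — LOD = blank mean + 3·sd, organic-phosphorus
   pools (OP = TP − Pi, DOP = OP − POP), N:P ratios with below-detection
   censoring, fluorescence-to-chlorophyll calibration.
4. **Cohort statistics** — Shapiro–Wilk gate, tie-corrected Kruskal–Wallis
   across depths, pairwise one-sided Wilcoxon with Benjamini–Hochberg
   adjustment, Spearman screening.
5. **Stoichiometric coupling** — Redfield Pi demand of carbon fixation
   (`demand = C-fixation / 106`) and the percent of that demand supportable
   by MPn-derived Pi (`100 · CH₄ rate / demand`, unclamped).
6. **Marker genes** — TPM and *phnJ* relative abundance normalized to the
   single-copy gene *recA* (strict >80 % mapping-identity contract).
7. **Synthetic campaign generator** — seeded forward simulation of every
   input (vessel physics, depth-stratified rates, nutrient profiles, count
   tables) with ground truth attached, so the whole pipeline is testable
   without field data.

## Worked example

```r
library(mpnmethane)

# read incubation time series + vessel/tracer config
recs <- read_incubations(
  system.file("extdata", "example_incubations.tsv", package = "mpnmethane"),
  system.file("extdata", "example_config.yaml", package = "mpnmethane"))
estimate_rates(recs)[, c("treatment", "replicate", "p_one_sided",
                         "r_squared", "kinetic_class", "net_rate")]
#>   treatment replicate  p_one_sided r_squared      kinetic_class  net_rate
#> 1       DIC         A 0.7410260680 0.2323743      insignificant 0.0000000
#> 2       MPn         A 0.0008955429 0.9964210 linear_significant 0.4038201
#> 3       MPn         B 0.0004694945 0.9981229 linear_significant 0.5477699

# couple methane formation to primary production
redfield_pi_demand(371)                  # 3.5 nmol P L^-1 d^-1 (371/106)
percent_support(0.40, 371 / 106)         # 11.4 -> "11 %" of the Pi demand
```

The two MPn duplicates carry significant linear rates of 0.40 and 0.55
nmol CH₄ L⁻¹ d⁻¹ (slopes that pass the p/R² filter, labelling fraction 1),
while the DIC vessel shows no production. A surface carbon fixation of
371 nmol C L⁻¹ d⁻¹ demands 3.5 nmol Pi L⁻¹ d⁻¹ at Redfield C:P, of which a
0.40 nmol L⁻¹ d⁻¹ methane (= phosphate) formation rate supplies 11 %.

## The full analysis

`analysis/01_simulate.R` … `05_marker_genes.R` run the complete workflow on
a simulated campaign (12 stations × 4 depths × 2 replicates × 4 treatments),
writing tidy TSVs under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

Stage 2 recovers depth-median net rates of 0.374 / 0.290 / 0.053 / 0.000
nmol CH₄ L⁻¹ d⁻¹ (generator medians 0.40 / 0.30 / 0.07 / 0.06 — the deepest
rates mostly fall below the significance filter, as in the field); stage 3
separates the depths (Kruskal–Wallis H = 23.6, df = 3, p = 3×10⁻⁵) with Pi
repression detectable above the DCM but not below it; stage 4 reports a
median support of 11 % of the surface Pi demand.

`run_study()` executes the same five stages in one call and writes a JSON
manifest (seed, thresholds, md5 checksums) so reruns are verifiably
byte-identical.

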