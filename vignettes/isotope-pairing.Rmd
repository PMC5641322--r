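---
title: "Isotope pairing analysis of anammox and denitrification: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope pairing analysis of anammox and denitrification: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anammoxIPT)
```

## The measurement problem

In suboxic groundwater, two microbial processes remove fixed nitrogen as
N₂: denitrification, which reduces nitrite/nitrate and takes both N
atoms of the product from that pool, and anammox, which condenses one
ammonium-N with one nitrite-N. Adding ¹⁵N-labeled substrate to anoxic
incubations and following the N₂ isotopologues ²⁸N₂/²⁹N₂/³⁰N₂ over time
separates the two, because the processes distribute label differently:
a ¹⁵N-nitrite pool produces ³⁰N₂ only through denitrification (two
draws from the labeled pool), while anammox, pairing one nitrite-N with
an unlabeled ammonium-N, contributes to ²⁹N₂ but never ³⁰N₂.

## Forward model and inversion

Let A and D be the anammox and denitrification rates (nmol N₂ L⁻¹ d⁻¹)
and Fₙ, Fₐ the ¹⁵N atom fractions of the nitrite and ammonium pools.
`forward_pairing()` implements binomial pairing:

$$P_{30} = D F_n^2 + A F_a F_n,\qquad
P_{29} = 2 D F_n(1-F_n) + A\,[F_a(1-F_n) + F_n(1-F_a)],$$
$$P_{28} = D(1-F_n)^2 + A(1-F_a)(1-F_n),$$

which conserves mass, $P_{28}+P_{29}+P_{30} = A + D$. The test suite
checks these proportions against an independent Monte-Carlo oracle
(`pairing_oracle()`) that simulates individual molecules.

The source describing the incubation protocol cites the rate derivation
without reprinting formulas; the estimators here are the unique inverse
of the pairing assumptions just stated. In the ¹⁵NO₂⁻ treatment
(Fₐ = 0):

$$D = P_{30}/F_n^2, \qquad A = (P_{29} - 2F_n(1-F_n)D)/F_n,$$

implemented in `estimate_rates_nitrite_label()`. In the ¹⁵NH₄⁺
treatment only anammox produces labeled N₂, so $A = P_{29}/F_a$
(`estimate_rate_ammonium_label()`); D is not identifiable there and a
significantly positive P₃₀ is surfaced as a model-violation warning
rather than silently absorbed. In the classic no-anammox limit the model
reduces to the familiar pairing ratio $P_{29}/P_{30} = 2(1-F_n)/F_n$,
which the suite verifies end-to-end through simulation and fitting.

**Label dilution.** `compute_labeled_fraction()` supports both field
conventions: reconstructing the total as background + added (nitrite,
where the in-situ pool is often below detection and treated as 0, giving
Fₙ = 1), or dividing by a measured post-addition total (ammonium, where
the in-situ pool is substantial). Whether a published rate used
fractions below 1 is generally not recoverable from printed values, so F
is always an explicit input, never guessed.

**Slope fitting.** `fit_production_rates()` regresses excess
isotopologue concentration on time in days (inputs in hours; the factor
24 is applied internally) by OLS over all replicate bottles pooled.
Destructive sampling makes every bottle an independent observation, so
pooling is the default; per-time averaging is available
(`average_replicates = TRUE`) but discards replicate-level information.
One-sided p-values (slope > 0) drive the detection flags at a
configurable α (default 0.05, the conventional level). Negative rate
estimates are reported with `detected = FALSE` and a warning record —
truncation would bias ensembles of incubations.

**Uncertainty.** Standard errors propagate from the slope standard
errors by the delta method; the estimators are linear in (P₂₉, P₃₀), so
the propagation is exact given the slope covariances, and the shared P₃₀
term between A and D is accounted for in the standard error of the
total. Fₙ and Fₐ are treated as exact: substrate concentration
measurement error is typically far below the regression scatter. The
parameter-recovery machinery (below) checks that the resulting
t-intervals calibrate.

**Headspace partitioning.** Measured headspace amounts are converted to
concentrations per litre of incubation water by `headspace_to_aqueous()`.
The default counts headspace N₂ only, matching protocols that measure
the headspace and apply no partition correction; a Bunsen-type
solubility coefficient can be supplied (`include_dissolved = TRUE`) to
reconstruct total bottle N₂, and β = 0 reduces exactly to the default.

## What the synthetic generators emulate

`simulate_incubation()` produces the design the estimators expect:
triplicate 30 mL / 8 mL serum bottles at 15 °C destructively sampled at
0, 14, 24, 36 and 48 h, with expected excess following the forward model
linearly in time and independent Gaussian measurement noise on every
observation (`noise_sd`, default 0.5 nmol L⁻¹ — a free choice, since
replicate-level scatter is rarely published; multiplicative noise is
available as an option). Tracer consumption is neglected: rates of a few
nmol L⁻¹ d⁻¹ consume well under 1% of a 5 µmol L⁻¹ pool in 48 h, so
zero-order kinetics are adequate. The generator does **not** model pool
dilution over time, Michaelis–Menten substrate dependence, DNRA,
nitrate-to-nitrite reduction, N-fixation, or oxygen intrusion; passing
recovery tests therefore demonstrate correctness of the estimation chain
under the stated model, not robustness to those processes in real
incubations.

`recovery_experiment()` repeats simulate → fit → invert and reports
bias, RMSE, and coverage of nominal 95% t-intervals. At the default
conditions (A = 3.5, D = 0.7 nmol N₂ L⁻¹ d⁻¹, Fₙ = 1, noise 0.5
nmol L⁻¹, 500 replications — sizes chosen to make the coverage estimate
stable to about ±1%) coverage is checked to lie in [0.90, 0.99].

`simulate_marker_survey()` emulates a transect of wells spanning an
oxygen gradient (default 8 wells over 0–100 µmol L⁻¹, evenly spaced)
with log-normal marker abundances. The anammox marker hzsA declines with
oxygen on the log scale (default −0.08 per µmol L⁻¹); the ammonia-
oxidizer (amoA), denitrifier (nirS, nirK) and 16S markers are flat.
Defaults were set to reproduce the qualitative structure of real
groundwater surveys: hzsA genes ~10⁷ L⁻¹ at the anoxic end falling to
just above the 10³ L⁻¹ quantification limit at the oxic end, so the
gene-level hzsA/amoA ratio spans roughly 100 down to 0.03, while hzsA
*transcripts* (one decade below genes) cross the quantification limit in
the most oxic wells — reproducing the situation where transcript indices
must exclude near-detection-limit wells. Dispersion (sdlog 0.5, about a
factor 1.6 scatter) keeps the imposed monotone trend detectable without
making it trivial. Real surveys additionally vary amoA with oxygen and
have irregular well spacing; the generator deliberately keeps those
fixed so the imposed effect size is the only trend.

## Marker and lipid indices

`hzsa_amoa_ratio()` computes hzsA / (amoA_AOA + amoA_AOB) per well,
separately for genes and transcripts; `nirs_16s_ratio()` approximates
the denitrifier fraction of the bacterial community. Below-detection
policy: measurements under the quantification limit (default 10³
copies L⁻¹, the typical transcript limit) are **excluded**, not imputed
at LOQ/2 — imputation would fabricate ratio values exactly where the
assay is uninformative. A well with hzsA (or both amoA domains) below
detection gets no ratio and an exclusion reason; with exactly one amoA
domain below detection the ratio is computed against the quantified one
and flagged `partial`.

`spearman_with_exclusions()` correlates an index with oxygen after
dropping an explicit exclusion set plus the below-detection exclusions.
Rho uses average ranks for ties. Because transect surveys have very few
wells, the two-sided p-value is computed by **exact enumeration of all
n! rank permutations for n ≤ 8** (at most 40 320), by seeded Monte-Carlo
permutation (20 000 draws, fixed internal seed, +1 correction) for
n of 9–10, and by the t approximation above that. The permutation choice
is this package's decision — small-n surveys sit exactly where the t
approximation is least trustworthy — and the suite checks the two agree
to within 0.02 at n = 10. A constant index is returned as degenerate
(rho `NA`) rather than 0, since zero correlation and undefined
correlation are different statements.

`ladderane_relative_concentration()` expresses anammox-specific
ladderane lipids as (ladderane-[3]-FAME + ladderane-[5]-FAME) peak area
over the C19:0 internal-standard peak area, flagging values below 0.01
as below detection; only *relative* concentrations are supported, since
absolute ladderane quantification requires calibration standards outside
this package's scope. `well_contrast_factor()` forms fold differences
between wells from quantified measurements only.

## Numerical and interface choices

* Mass-balance and round-trip identities hold to 1e-12 and 1e-9 relative
  tolerance respectively; the estimators are closed-form, so no
  iteration or initialisation is involved.
* All generators take a single integer seed, derive any substreams
  deterministically, and restore the caller's RNG state.
* Tables are comma-separated UTF-8 with mandatory header rows; designs
  and run configurations are flat `key = value` files with unknown keys
  rejected by name. Every runner writes a log with inputs, parameters,
  seed and package version, sufficient to re-run the result.
* Negative excess observations (possible within noise at early times)
  are kept and flagged on read, never dropped.

## Known limitations

* The inversion assumes the two-pool binomial pairing model; processes
  that mix label between pools during the incubation (DNRA, nitrate
  reduction to nitrite) bias the partition and are not modeled.
* Labeled fractions are treated as constant over the incubation;
  substantial pool turnover would make F time-dependent.
* The delta-method intervals rely on OLS assumptions (homoscedastic,
  independent errors); with strongly multiplicative noise the bootstrap
  over bottles (resampling at the replicate level) is the safer check.
* The survey generator's flat amoA baseline means its hzsA/amoA gradient
  is driven entirely by hzsA; real gradients also reflect nitrifier
  ecology.
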