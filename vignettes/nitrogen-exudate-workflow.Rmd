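---
title: "Methods: nitrogen in root-exudate metabolomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nitrogen in root-exudate metabolomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoN)
```

# The problem

Root exudates collected as rinseate from whole root systems carry organic
nitrogen in two measurable forms: a bulk balance (total N by combustion,
minus inorganic N measured spectrophotometrically) and a molecular profile
(accurate masses from direct-infusion FT-ICR-MS, assignable to CHNOSP
formulas). This package couples the two to characterize how progressive
drought and subsequent recovery reshape root-exudate nitrogen in an
aeroponic time series: two treatments (well-watered control, progressive
drought), sampling days 0 (baseline), 2–11 (treatment phase), and 14–18
(recovery), five of ten pots sampled per treatment per day.

# The quantitative balance

Total organic nitrogen is obtained by difference, `TON = TN − NO₃-N −
NH₄-N`, because nitrate supplied in the nutrient solution rinses from root
surfaces and is an artifact of plant culture rather than exudation. A
negative balance (possible with noisy instruments) is recorded as missing
and flagged, never clamped, so group means are not silently biased.
Masses are `concentration × 128.8 mL` of rinseate; specific exudation
divides by root dry weight. Two conventions for the C:N ratio are exposed
because they differ whenever replicates vary: the default averages
per-replicate ratios (`per_replicate_then_mean`), matching how a ratio
column of per-pot values is summarized; `ratio_of_means` divides mean
masses. Whole-pot masses are reported by default; division by the three
plants per pot is available (`per_plant = TRUE`) but disabled by default
because published mass tables of this design are consistent with
concentration × volume without the division.

Amino-acid nitrogen converts each measured concentration by
`n_N × 14.007 / M` using a built-in table of the 20 proteinogenic amino
acids (average molar masses); unknown names are an error listing accepted
names, so silent unit mistakes cannot slip through.

# Peak processing

All stages act on per-sample peak lists (m/z, intensity, S/N) and only ever
remove peaks, so the stage counts form a monotone quality-control funnel
that is logged and written with every run.

- **S/N filter.** Strictly `S/N > 7`. Phrasing of vendor thresholds is
  ambiguous between ≥ and >; the strict form is adopted and the threshold
  is a parameter.
- **Analysis window.** The closed interval [200, 900] m/z, the range over
  which the instrument's accurate-mass readings are reliable; only values
  strictly outside are excluded.
- **Blank subtraction** removes every sample peak within 1 ppm of any peak
  detected in the sampling-solution blanks. It runs *before* internal
  calibration: blanks contain no organic-matter homologous series and so
  cannot be calibrated, and subtraction requires both sides in the same
  mass state. (Matching tolerance re-uses the alignment tolerance; the
  methods literature is silent on a separate value.)
- **Internal calibration.** Dissolved organic matter produces homologous
  series spaced by exactly one CH₂ (14.0156501 amu). Chains of peaks with
  that spacing (within 5 ppm of the expected partner) are detected by a
  greedy nearest-partner walk; each chain of ≥ 5 members is anchored to a
  reference CHO formula — the candidate (within 5 ppm of the lowest-mass
  member, CHO bounds only) minimizing the worst per-member error across the
  chain — and every member then contributes a reference point
  `(observed/theoretical − 1)·10⁶` ppm. A linear ppm-correction over m/z
  is fitted to the pooled points (constant when fewer than 8 points or a
  span under 100 Da) and divided out. Anchoring matters: estimating the
  error from the observed spacing alone amplifies per-peak mass jitter by
  m/Δm ≈ 20-fold and cannot reach sub-ppm accuracy. With no usable series
  the spectrum passes through unchanged with a warning flag, and
  calibrating an already-calibrated spectrum moves masses by well under
  0.1 ppm (idempotence, tested).
- **¹³C isotopologue removal.** A peak sitting 1.003355 amu above a
  retained peak (within 1 ppm) is removed if its intensity is below 0.6 ×
  the parent's. The ceiling comes from the ¹³C binomial expectation of
  1.1% per carbon with at most ~56 C (≈ 0.62); it is a parameter because
  vendor defaults are not published.
- **Alignment and prevalence.** Peaks pool across samples and split into
  consensus bins wherever the gap between mass-adjacent peaks exceeds
  1 ppm (single-linkage in ppm space, deterministic left-to-right). A bin
  receiving two peaks from one sample is flagged ambiguous with a warning;
  the most intense peak is kept, ties toward lower m/z. Bins seen in fewer
  than 2 distinct samples are dropped — singletons at FT-ICR-MS resolution
  are overwhelmingly noise.
- **Normalization.** Per-feature z-scoring (sample SD, the `scale()`
  convention) of present intensities is provided for completeness; the
  original presence pattern travels with the normalized matrix so the
  presence/absence layer downstream is provably unaffected.

# Formula assignment

The neutral mass of an observed ion is `m/z + 1.0072765` (negative mode,
[M−H]⁻ only; the electron mass, ~0.5 mDa over the window, is far below
0.5 ppm and absorbed by the tolerance). Candidate CHNOSP formulas are
enumerated exhaustively within element bounds — defaults C 5–56, N 0–3
(the composition range of the assigned exudate metabolome), H 4–120,
O 0–40, S 0–3, P 0–2 — by looping over (C, N, O, S, P) and solving the
hydrogen count from the residual mass; a guard window of
⌈tol/1.008⌉ hydrogen units keeps the search exhaustive at any tolerance,
and a brute-force nested-loop oracle over reduced bounds guards
correctness in the test suite.

Plausibility screens (DBE = C − H/2 + N/2 + P/2 + 1 in [0, 40], H/C in
[0.3, 2.5], O/C ≤ 1.2) are recorded as flags rather than silently dropping
candidates. The best assignment is the plausible candidate with minimum
|error| in ppm; exact ties break deterministically toward fewer heteroatoms
(S+P), then fewer N, then lexicographic CHNOSP counts — a documented rule,
since the ranking heuristics of closed-source assignment tools are not
published. Both tolerances of the original workflow are exposed: 1 ppm at
assignment, then a 0.5 ppm post-filter that discards marginal assignments.

# Nitrogen-metabolome descriptors

Intensities become presence/absence (1 iff positive and non-missing);
every descriptor below is occurrence-based.

- **Relative abundance** per sample: 100 × N-containing present / all
  present. The **response ratio** normalizes day-level means:
  100 × (RA_drought − RA_control)/RA_drought, positive when drought
  enriches nitrogen molecules. It is undefined at RA_drought = 0 (missing,
  flagged). Being a ratio statistic it carries an O(CV²) negative bias
  under the null; at study scale (thousands of molecules, hundreds present
  per sample) the bias is negligible, but descriptor tests at toy scale
  must account for it.
- **Elemental classes** {CHON, CHON-S, CHON-P, CHON-SP, nonN} partition
  assigned molecules by N/S/P content; per-sample proportions sum to 1.
- **Element totals** count each molecule once per sample where present
  (occurrence weighting — this is what makes pooled counts far exceed
  distinct molecules) and total C and N atoms; the mass C:N ratio is
  (ΣC × 12.011)/(ΣN × 14.007), average atomic weights by convention.
- **Molecular-weight binning**: LMW = [200, 600), HMW = [600, 900]. The
  conventional bin labels overlap at 600; the half-open convention is
  adopted and documented. Kernel densities (Gaussian, Silverman's
  rule-of-thumb bandwidth) summarize the mass distributions per phase ×
  treatment; supports are left unclipped so each density integrates to 1.
- **Venn partition and important molecules.** Within a phase, N-containing
  molecules split into treatment-unique and shared sets; from the
  drought-unique set, molecules present on ≥ 3 distinct days and detected
  ≥ 5 times are selected as drought-important. "Detected n times" counts
  samples, which under presence/absence equals peak observations.

# Statistics

All stochastic procedures take an explicit seed and are reproducible
bit-for-bit; permutation and bootstrap p-values use add-one smoothing,
`p = (1 + exceedances)/(B + 1)`, so p = 0 never occurs.

- **Bootstrap t-test**: observed Welch t; null by recentring both groups to
  the pooled mean and resampling each with replacement (10,000 draws by
  default). The recentre-then-resample construction imposes the null while
  preserving each group's shape; a percentile-CI alternative would test a
  slightly different hypothesis. Families for Benjamini–Hochberg
  adjustment are all analytes within a timepoint.
- **Kolmogorov–Smirnov**: D by scanning all ECDF breakpoints; p exact by
  lattice-path counting when min(n, m) ≤ 10 without ties, else the
  asymptotic Kolmogorov series with the standard finite-sample λ
  correction.
- **Bray–Curtis on presence/absence**: (A + B − 2J)/(A + B); two empty
  samples get distance 0 with a warning (the quantity is undefined there).
- **PERMANOVA**: Gower-centred inner-product matrix, sequential (Type I)
  sums of squares via cumulative hat-matrix projections in the order
  treatment, day, treatment × day; pseudo-F per term; free permutation of
  sample rows (the design is a simple crossed layout per phase, so no
  restricted blocks). Equivalence with classical ANOVA F on univariate
  Euclidean data and with the ecology-standard implementation is asserted
  in tests.
- **PCA with squared cosines**: variables standardized, SVD decomposition;
  a variable's squared cosine on a component is its squared correlation
  with the component scores, so each main variable's squared cosines sum
  to 1 over all components. Supplementary categorical variables (treatment,
  phase) are one-hot coded and projected the same way without influencing
  the axes. Zero-variance variables are dropped with a warning.

The permutation/bootstrap sizes (999 / 10,000) are package defaults: the
original analysis does not state them, so third-decimal agreement of
p-values is not a meaningful target — structure and calibration are.
Both procedures hold their nominal type-I error within ±0.02 of α = 0.05
over 500 null simulations (tested); the slight conservatism visible there
is the expected effect of add-one smoothing on a discrete permutation
distribution.

# The synthetic-data generator

The generator defines the study conditions under which everything is
validated; its defaults are fixed once:

- catalog of 4,000 distinct CHNOSP formulas (C 5–56, N 0–3, ~40%
  N-containing, integer DBE, conventional H/C and O/C), [M−H]⁻ in
  [200, 900];
- per-molecule baseline presence probability uniform on [0.02, 0.10], so a
  sample carries ≈ 370 peaks (matching ≈ 33,870 observations / 90 samples)
  once noise (80 uniform low-S/N peaks), ¹³C isotopologues (rate 0.2,
  intensity 1.1% × C of the parent), and 10 blank contaminants are added;
- drought enrichment: presence probability of N-containing molecules
  inside the 275–390 and 450–550 amu windows is raised by +0.25 for
  drought samples on days 2–11 only — the recovery target for the
  end-to-end tests;
- two ever-present CHO homologous series (10 members each) act as
  calibrants; a configurable multiplicative ppm offset plus 0.1 ppm
  per-peak jitter emulate instrument mass error;
- quantitative tables center control means on the observed composition
  (end of treatment: TOC 79.0 ± 4.2, TON 20.4 ± 6.8 mg/L; recovery:
  77.5 ± 0.8, 23.4 ± 5.2), generate NO₃-N ≈ 20% of TN, set NH₄-N = 0
  (none is detected in this system), and scale drought means by the
  effect multipliers (defaults TON ×1.686, TOC ×1.066 at end of
  treatment, ×1.530 / ×1.013 at recovery, amino acids ×6.62 — the
  magnitudes of the drought response this design emulates). Root dry
  weights (≈ 3.1 g at end of treatment, ≈ 1.0 g at recovery) are set so
  specific exudation lands in the observed range. Negative draws are
  clipped to zero and counted.

Intensities are log-normal with S/N proportional to intensity — downstream
analysis is presence/absence, so this choice is non-critical but
configurable. What the generator does *not* emulate: chromatography or ion
suppression, adducts beyond [M−H]⁻, charge states beyond 1, correlated
molecule co-occurrence, or real DOM compositional continuity. Passing
recovery tests therefore demonstrate that the pipeline's inference is
correct *given* the ionization and presence model, not that the model
captures every feature of real spectra.

# Problem sizes and numerical choices

Test and acceptance runs use scaled-down catalogs chosen as a
power/runtime compromise and stated here as the package's own sizing:
end-to-end recovery runs 100 seeded pipelines at 400 catalog molecules
(the drought contrast is then ≈ 42 ± 4 response-ratio points against an
off-treatment noise of ± 7, so the success criterion — positive treatment
enrichment dominating the off-treatment magnitude — is met with margin);
descriptor-level null-symmetry and day-contrast properties use 1,000
molecules, where day-mean RA noise is small enough that the response
ratio's O(CV²) bias is negligible. Statistical calibration uses 500 null
simulations at n = 5 per group (1,000 bootstrap draws / 199 permutations),
the regime matching five pots per treatment per day.

Degenerate inputs degrade explicitly, never silently: empty spectra pass
through stages; calibration without a series flags and returns identity;
zero-variance features normalize to 0 with a warning; empty samples give
missing RA; negative TON flags as missing; response ratio at RA_drought = 0
is missing; all-empty sample pairs get Bray–Curtis 0 with a warning.

# Known limitations

- Candidate ranking may disagree with closed-source assignment tools on
  ambiguous masses; the tie-break rule is documented and deterministic but
  not identical to unpublished vendor heuristics.
- At sub-0.5 ppm residual calibration error, near-degenerate CHNOSP
  formulas (notably S/P-containing alternatives) can still outrank the
  true composition for a few percent of bins; isotope-pattern validation
  beyond ¹³C partner removal is out of scope.
- KEGG annotation is a stub hook: N-containing exudate molecules have no
  database matches in this workflow, and the package does not bundle an
  annotator.
- The quantitative and metabolomic layers are linked only through shared
  design metadata; no joint model is fitted.
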