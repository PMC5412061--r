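---
title: "Methods: internal-standard quantification and the LCRT classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internal-standard quantification and the LCRT classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the
measurement model, the statistical machinery, the synthetic world the
generator describes, and the judgement calls made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

Targeted competitive amplicon sequencing spikes each reaction with a
synthetic internal standard (IS) per assay: a sequence sharing the
assay's primers but differing from the native template (NT) at exactly
six bases, at a known input copy number (600 copies per target assay,
6000 for the ACTB reference). Because NT and IS compete through the same
primers with equal efficiency, PCR changes their joint abundance but not
their ratio; sequencing then samples reads from that preserved ratio.
The loaded NT copy number is estimated by

\[
\widehat{N}_{\mathrm{NT}} \;=\; N_{\mathrm{IS}} \cdot
\frac{r_{\mathrm{NT}}}{r_{\mathrm{IS}}},
\]

and abundance is expressed as target molecules per \(10^6\) ACTB
molecules, then log10-transformed. Two failure modes motivate the QC
chain: scarce NT molecules (stochastic loading error, low
\(r_{\mathrm{NT}}\)) and IS starvation for very abundant targets (low
\(r_{\mathrm{IS}}\), unstable ratio denominator).

**Stochastic-sampling CV filter.** A measurement with \(M\) molecules
loaded and \(R\) reads obtained has predicted coefficient of variation

\[
\mathrm{CV} = -1 + 10^{\,M^{-0.54} + R^{-0.54} - (MR)^{-0.54}},
\]

strictly decreasing in each argument and vanishing as both grow.
Measurements with \(\mathrm{CV} \ge 1.0\) are set missing. The formula
does not bind its arguments to NT or IS counts; this package takes
\(M = \widehat{N}_{\mathrm{NT}}\) (the scarce quantity that drives
sampling error) and \(R = r_{\mathrm{NT}} + r_{\mathrm{IS}}\) (the
counting resolution of the cell), switchable via `cv_reads`. Two further
rules: `min_is_reads = 10` guards the ratio denominator (the published
threshold set is not printed; the ratio estimator is unusable at tiny IS
counts), and an ACTB reference failure invalidates the subject's whole
library, since every abundance is a ratio to ACTB.

**Missingness filters.** Gene features missing in strictly more than
30% of subjects are removed; subjects with fewer than 6 measured assays
are removed; zero abundances map to missing after log10 (a zero NT count
carries no magnitude information and is handed to imputation). Both
filters are idempotent and log what they removed.

## 2. Multiple imputation

Missing cells (genes and demographics alike) are imputed by chained
equations with predictive mean matching (PMM). Each of \(M\) copies is
initialised from observed marginals, then incomplete features are
visited in ascending missingness for `n_iterations = 10` cycles. Each
visit draws regression parameters from their approximate posterior
(scaled inverse-\(\chi^2\) residual variance, normal coefficients — a
proper imputation, so between-copy variance reflects imputation
uncertainty), predicts the missing cells, and copies the observed value
of a donor sampled uniformly among the `k_donors = 5` observed rows with
nearest predicted mean (type-1 matching). Defaults follow standard MICE
practice; the source protocol states neither. Consequences tested as
properties: observed cells are immutable; imputed values always lie in
the feature's observed support, so the 0/1 gender encoding stays binary
without a logistic sub-model (PMM on a linear score); a fixed seed
reproduces the stack exactly. Demographics are imputed along with genes
because the final discriminant needs complete rows; restricting
imputation to assays only amounts to subsetting the matrix first.

**Rubin's rules.** An estimate \(\hat\theta_m\) with within-copy
variance \(v_m\) pools to \(\bar\theta\), with total variance
\(T = W + (1 + 1/M)B\), \(W = \bar v\), \(B\) the between-copy sample
variance; intervals are normal by default with a Barnard–Rubin t option.

## 3. Feature ranking, voting, and honest cross-validation

Per copy, features are ranked by absolute correlation-adjusted t (CAT)
score \(\tau = R^{-1/2} t\): two-sample pooled-variance t statistics
(CA minus NC) decorrelated by the inverse square root of a shrinkage
correlation matrix (sample correlation shrunk toward the identity with
the analytic variance-over-squares intensity, clipped to [0, 1]).
Eigenvalues are floored at \(10^{-8}\) before the root; ranking ties
break by feature name for determinism.

For each candidate model size \(k\), every copy votes for its top-\(k\)
features; features with vote fraction \(\ge 0.60\) form the candidate
set; the denominator of the vote fraction is the number of copies (the
most direct reading of "at least 60% of votes"). The set is evaluated
by pooled-covariance LDA (ridge \(10^{-6}\) for numerical safety at
\(p \approx 13\), \(n \approx 115\)) under stratified 10-fold
cross-validation on every copy; AUC (rank/Mann–Whitney with tie
correction) and accuracy are averaged over copies; the best \(k\)
maximises average AUC with ties to the smaller model.

Whether the source protocol re-ran ranking inside CV folds is unstated.
The default and acceptance mode here is *honest*: ranking and voting are
recomputed inside every training fold, so held-out subjects never
influence selection. The full-data mode is provided (`mode = "full"`)
and demonstrably optimistic on null data — the suite asserts both the
honest null calibration (average AUC in [0.4, 0.6] over 20 effect-free
seeds) and the optimism ordering. If a fold's vote set is empty at small
\(k\), the highest-vote features are used for that fold rather than
aborting; with full-data voting an empty set skips that \(k\) with a
warning.

Pooled reporting: AUC intervals come from Rubin pooling on the logit
scale (per-copy variance by Hanley–McNeil; degenerate per-copy AUCs are
clamped at the estimator's resolution \(1/(2 n_1 n_0)\)); proportion
metrics pool with binomial within-copy variance. The report also gives
the specificity at the smallest threshold reaching 95% cross-validated
sensitivity (the screening operating point) and a feature table (CAT
rank, selection frequency, missing fraction). Model comparison
(genes + demographics versus demographics only) uses a class-stratified
paired bootstrap of the AUC difference over subjects.

## 4. The synthetic world

The generator states one cohort and keeps it fixed; none of its
defaults were chosen by looking at test outcomes.

* **Cohort**: 58 CA / 57 NC (the post-filter cohort size), 68 assays on
  33 genes, one ACTB reference assay. Demographics follow the published
  cohort table: age NC 59.3 (SD 14.2) vs CA 64.4 (SD 9.5); pack-years
  43 (28.7) vs 53 (31.3); male fraction 28/57 vs 40/56; each demographic
  value masked missing at 3% (the table reports 2 missing ages and 2
  missing genders of 115).
* **Abundance**: log10 abundance = per-assay baseline + factor loadings
  × subject factors + N(0, 0.3) residual, 4 latent factors with N(0,
  0.25) loadings. The latent-factor structure exists precisely because
  CAT scores are designed for correlated features. Baselines are uniform
  on [1.5, 4.5] log10 molecules per 10^6 ACTB; at 60,000 ACTB copies/µL
  the low end sits below the CV filter's detection limit, so a realistic
  subset of assays (roughly a third) acquires >30% missingness — the
  mechanism, not the count, is calibrated; the published 23-of-68 count
  is reproduced in a test by construction.
* **Effects**: 13 informative assays (the published model size) shifted
  by ±0.5 log10 in the CA class by default; class means differ by
  exactly the configured effect (tested at large n).
* **Counts**: NT molecules ~ Poisson(abundance × ACTB/10^6) for a 1-µL
  aliquot; IS fixed at its spike (Poisson jitter optional); total reads
  per cell lognormal (mean 3000, CV 0.5); NT reads binomial with
  probability NT/(NT+IS) — the equal-efficiency competitive model.
* **Reads**: joined layout
  `[barcode_f][primer_f][captured][rc(primer_r)][rc(barcode_r)]`,
  101-bp amplicons, 8-nt barcodes, substitution errors only at rate
  0.001 (indels excluded by design: short joined amplicons, and the
  edit-distance classifier is still exercised by substitutions and by
  deliberate indels in the oracle tests). Barcode sets enforce pairwise
  Hamming ≥ 3 up to 200 subjects; beyond that only uniqueness is
  feasible for 8-mers and only uniqueness is required.

**What a green test does not establish.** The simulator has no PCR
chimeras, index hopping, primer dimers, quality degradation, batch
effects, or amplification-efficiency differences between NT and IS; the
missingness it produces is driven by abundance (informative or not),
not by disease status. Passing the suite therefore validates the
machinery and its statistical calibration, not the published biological
result; the headline cohort results are not reproducible at desk scale
because no raw data were deposited.

## 5. Numerical and design choices

* Demultiplexing requires both barcodes within 1 mismatch, locus
  assignment both primers within 2, allele calls an edit distance ≤ 2
  with margin ≥ 1 — six diagnostic positions give clean reads a margin
  of 6, so these tolerances reject chimeric/low-quality reads without
  losing real ones. Ties at equal distance are unassigned/ambiguous,
  never guessed. Every read lands in exactly one accounting bucket
  (conservation is a property test).
* Allele classification uses true Levenshtein distance (`utils::adist`)
  although the simulator emits substitutions only: real data contain
  indels, and the brute-force DP oracle in the tests covers them.
* The abundance-recovery criterion is evaluated against molecules
  actually loaded (and their ACTB-normalised ratio), not the latent
  expected abundance: Poisson aliquot sampling is upstream of the assay
  and irreducible by depth (a mid-range assay loads ~60 molecules →
  ~13% CV before sequencing touches it).
* Feature-recovery (Jaccard ≥ 0.6 against truth) restricts truth to
  informative assays surviving the missingness filter — an assay below
  the detection limit is absent from the feature matrix and no method
  can select it — and is computed over gene features only.
* The MICE recovery criterion ("within 3 pooled SEs over 20 repeats")
  is asserted as ≥ 18/20 repeats inside 3 SE plus a centred mean pivot:
  a perfectly calibrated imputer misses a 3-SE window ~2% of the time,
  so an all-20 assertion would fail by chance in roughly one run in
  three.
* Fisher exact tests: 2×2 always by hypergeometric enumeration
  (two-sided by summing tables no more probable than observed); r×c by
  exhaustive enumeration of margin-fixed tables within an enumeration
  budget, else seeded Monte-Carlo (`r2dtable`).
* All randomness flows from explicit seeds; the pipeline derives
  per-stage sub-seeds from one global seed, and rerunning a config
  reproduces every artifact byte for byte.

## 6. Known limitations

Joined-read demultiplexing assumes the fixed simulated layout
(non-overlapping halves, known barcode/primer offsets); it is not a
general-purpose read merger. The Hanley–McNeil within-copy AUC variance
is an approximation, and with few copies and near-degenerate AUCs the
pooled logit interval is wide and conservative. PMM with small donor
pools can understate tail uncertainty when missingness is heavy. The
vote-selection denominator and the CV-formula argument binding are
config-switchable precisely because the source protocol leaves them
open.
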