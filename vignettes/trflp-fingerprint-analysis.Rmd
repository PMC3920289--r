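---
title: "Community fingerprint analysis with trflpr: models, conventions and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community fingerprint analysis with trflpr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trflpr)
```

# The data and its processing model

A T-RFLP experiment reduces a microbial community to a vector of terminal
restriction fragment (T-RF) sizes with fluorescence intensities. Intensities
are only meaningful within a profile, so every analysis here operates on
compositions: peak heights are expressed relative to the total peak height
of their sample, peaks below a background threshold (default 0.5% of the
total) are removed, and the survivors are re-normalized to sum to 100.

Two processing conventions deserve attention because the literature leaves
them open:

* **Threshold base.** The 0.5% rule is applied to heights relative to the
  total of *all* detected peaks, and the retained peaks are then
  re-normalized. The alternative — re-expressing heights relative to the
  retained total before thresholding — is circular (the threshold would
  depend on what it removes). Our reading keeps the rule a single pass and
  leaves downstream descriptors operating on a proper composition.
* **Binning.** Instruments report fragment sizes with sub-bp jitter but no
  binning rule comes with the data. `bin_trfs()` clusters all sizes across
  samples by single linkage, starting a new bin whenever the gap between
  adjacent sorted sizes exceeds `bin_tolerance_bp` (default 0.5 bp — wide
  enough to absorb size-calling jitter, too narrow to merge distinct
  integer-spaced fragments). Bins are labeled with the rounded mean of
  their member sizes; in the rare event that two sub-bp-separated bins
  round to the same label they are merged. Binning is order-independent by
  construction.

Duplicate DNA extractions of one pot are averaged T-RF-wise, a fragment
absent from one replicate contributing zero — the conservative reading of
"mean values per peak" — and pot profiles are re-normalized. Pots, not
extractions, are the biological replicates, and all statistics below run on
pot-averaged profiles.

# Descriptors

**Pareto–Lorenz / PL20.** T-RFs are ranked from most to least abundant; the
cumulative normalized band count (x) against cumulative normalized
abundance (y) forms the Lorenz curve, and PL20 is its linear interpolation
at x = 0.2, on the 0–100 scale. Two conventions are fixed here:

* *Common band axis.* When profiles come from a binned community matrix,
  T-RFs of the matrix absent from a given sample count as bands — they rank
  last and stretch the x-axis without adding abundance. This keeps every
  sample of one study on the same axis and is the only reading under which
  a strongly dominated community (top ~8 of 39 bands holding ~87% of
  signal) can coexist with per-sample retained band counts of 20–30, as
  fingerprint studies report. A bare positive abundance vector, by
  contrast, is scored on its own bands.
* *Single band.* With one band the curve has no interior point; the step
  convention (the curve jumps to 1 at the first band, PL20 = 100) matches
  the intuition that a one-band profile is maximal dominance. The linear
  convention (PL20 = 20) is available via `single_band = "linear"`.

**Moving-window Δt.** Dissimilarity between two profiles is
100·(1 − r), r the Pearson correlation over the union of T-RF bins with
absences as zeros (the convention of the moving-window literature; the
range is 0–200). Δt between consecutive harvests is the mean ± sd of this
percent change over **all cross-group pot pairs** within a treatment
(6 × 6 = 36 pairs per window in the default design). The pair set is not
dictated by the sources; all-cross-pairs is symmetric, uses every pot once
per window, and yields a well-defined sd.

# Ordination

`nmds()` implements non-metric multidimensional scaling minimizing
Kruskal's stress formula 1 (reported ×100), by majorization: configuration
distances are fitted by isotonic regression on the dissimilarity order
(primary tie treatment — tied dissimilarities may receive distinct
disparities), disparities are rescaled to a fixed norm (which keeps the
Guttman update from drifting in scale), and the configuration is updated
until the stress decrease over the last 10 iterations falls below 1e-7 or
500 iterations elapse. Each fit takes the best of 250 random starts
(uniform in [−1, 1]^k, centered) plus one deterministic principal
coordinates start; random-start counts are a compute knob, and tests use
smaller values without affecting the stated defaults.

`select_dimensionality()` fits k = 1…6 and keeps the smallest k for which
one more axis lowers the best stress by less than 5 (×100 scale). Each
dimensionality is warm-started with the previous solution padded by a zero
axis, which enforces monotone non-increasing best stress — a property the
test suite asserts. `monte_carlo_stress_test()` shuffles each T-RF column
independently, refits at the same k with equal search effort, and reports
`(1 + #(stress_rand ≤ stress_real)) / (1 + n_rand)`; 50 randomizations by
default (a desk-scale default, exposed as a parameter).

On metric, exactly low-rank input the optimizer reaches stress below 1e-4
at the true rank, and planted configurations are recovered to under 1% of
the configuration scale after Procrustes alignment. A caution from
cross-checking against vegan's `monoMDS`: on tiny structureless matrices
NMDS admits degenerate near-zero-stress solutions (point clumping); the
majorization path here does not seek them, so stress comparisons between
implementations are meaningful only on structured data — where the two
agree to ~1e-3.

# Permutation inference

**PerMANOVA.** The distance matrix is Gower-centered
(G = −½·J D² J) and partitioned sequentially (Type I, order as given in
the formula; the crossed seasonal design is balanced, so the order is
inconsequential there) via hat-matrix projections; pseudo-F per term is the
term mean square over the residual mean square. p-values come from
unrestricted permutation of whole sample rows — "raw data units" — for all
terms, including the interaction; restricted and residual-permutation
schemes are deliberately out of scope. With Euclidean distances on
univariate data the pseudo-F reproduces the classical ANOVA F exactly, and
per-term SS equals the summed univariate sequential SS across columns —
both asserted in the tests at 1e-10. Pairwise comparisons re-run the
one-way analysis on each level pair (t = √F), unadjusted by default as is
conventional for this workflow, with `p.adjust` methods available.

**Asymptotic fallback.** When too few distinct permutations exist, a
two-moment gamma distribution is fitted to the permuted pseudo-F values and
the observed statistic's upper-tail probability is reported. The exact
construction used by the historical FORTRAN program is not public; the
gamma fit is a documented substitute, not a claim of equivalence.

**IndVal.** For T-RF i and group g, specificity
A = mean_g(i) / Σ_h mean_h(i) and fidelity B = occurrence fraction of i in
g give IndVal = 100·A·B; a T-RF is assigned the maximizing group (ties
broken by level order and flagged). Significance is by permutation of group
labels, with one shared permutation stream across T-RFs per run. Presence
means abundance > 0 after the 0.5% filter. The univariate follow-up ANOVA
uses the classical one-way F under label permutation with pooled-t pairwise
comparisons, mirroring the indicator-table workflow of fingerprint studies.

# The synthetic world

`study_design()` encodes the emulated experiment: 2 ozone treatments × 3
seasons × 6 pots, duplicate DNA extractions per pot, 39 true T-RFs.
Its defaults are the stated world of that experiment, chosen once and
frozen:

* **Community structure.** Six dominant T-RFs (relative shares
  24:20:16:12:9:6, placed at 162, 69, 579, 102, 380 and 226 bp; T-RF 102
  sits near 12% in spring and becomes the top peak after its planted summer
  doubling). The minor tail is bimodal: 10 mid-abundance T-RFs decaying
  geometrically from 2.0% to 0.9% (reliably detected), and 23 rare T-RFs at
  0.24% each, below the 0.5% threshold on average and surfacing in only a
  few percent of extractions — enough that the cross-study union reaches
  ~39 binned T-RFs while each single profile retains ~16–20 bands. This
  bimodality is what the targets jointly force: a strongly dominated
  community (PL20 ≈ 87) cannot carry 33 minors all comfortably above the
  threshold (their mass would destroy the dominance), and a uniform
  threshold-hugging tail makes rare-peak presence so patchy that chance
  seasonal imbalance produces spurious indicator values. The preset was
  calibrated by simulation against the PL20 ≈ 87 target and the
  planted-responder recovery property, then frozen.
* **Noise.** Log-normal and multiplicative throughout: extraction noise on
  major peaks calibrated to the 6.5% replicate CV target; mid minors at
  log-sd 0.3 and rare minors at 0.5 (peaks near the detection limit
  fluctuate far more than major peaks); pot-to-pot compositional noise at
  12% CV, estimated from the within-group SD/mean ratios (~13%) that
  studies of this design report for non-responding major peaks, net of the
  extraction component. The Dirichlet concentration is high (5·10^4 ×
  target): one study samples one soil community, so the draw perturbs the
  preset only slightly.
* **Planted effects.** Multiplicative fold changes on a cell's composition
  followed by re-normalization — the compositional reading of reported
  relative-abundance shifts. The defaults mirror the two responders of the
  emulated study: T-RF 102 ×1.82 in summer and ×1.47 in autumn (12.3% →
  22.4% → 18.1%), and T-RF 579 ×0.6 under ozone in summer only.
  Re-normalization means a planted fold also depresses all other T-RFs in
  the affected cells (closure) — visible, for example, as slightly lower
  rare-peak detection in summer. This is faithful to how compositional
  data behave, not an artifact.
* **Nuisance peaks.** Each electropherogram receives a Poisson(4) number of
  spurious peaks at 0.05–0.4% relative height and random sizes, so the
  background filter is exercised, never vacuous.

What a green test on this world establishes — and what it does not: the
generator reproduces the design's dimensions, dominance structure,
replicate reproducibility and responder structure, so pipeline-level
properties (test size, planted-effect recovery, descriptor calibration)
are meaningful. It does not emulate PCR amplification bias, ribosomal
operon copy-number variation, pseudo-T-RF artifacts, electropherogram
baseline behavior, or taxon-level phylogenetic structure; conclusions
about those must come from real data.

Replicate reproducibility is measured by `replicate_cv()` as a
root-mean-square pool of per-(pot, T-RF) CVs over major peaks: with only
two extractions per pot, the plain mean of sd/mean estimates would be
biased low by ~20% (the n = 2 standard-deviation bias), misrepresenting
the calibrated target.

# In-silico digestion

Enzymes are modeled by recognition sequence plus strand-specific cut
offsets from the recognition start: MboI ^GATC (0/4), FauI CCCGC(4/6) —
an offset cutter cleaving 4 nt (top) and 6 nt (bottom) past its site — and
HhaI GCG^C (3/1), standard catalogue definitions. Matching is IUPAC-aware
(two codes match when their expansion sets intersect; inosine matches any
base) and scans both strands; a bottom-strand site at top position s with
recognition length L cuts the labeled strand at s + L − offset_bottom.
The labeled fragment length equals the cut position counted from the first
base of the labeled forward primer, and a double digest's terminal fragment
is the minimum over the enzymes' cuts. Cuts falling outside the molecule
are discarded.

Observed capillary sizes run systematically below sequence-predicted sizes
(typically 0–9 bp short). `match_trfs()` offers a fixed ±5 bp window and a
linear-calibration mode (fit observed ≈ a + b·expected on provisional
matches, re-match on residuals, refit once); neither tolerance is dictated
by the sources — 5 bp spans the drift range reported for this assay.
Matching is per prediction: several clones may legitimately map to the same
observed profile peak.

# Numerical and degenerate-input policy

Row compositions are maintained to 1e-6 of 100 after every operation.
Correlations are undefined for zero-variance profiles and raise an error
naming the sample. PerMANOVA refuses all-identical samples (zero total SS),
single-level factors, and designs without residual degrees of freedom; the
gamma fallback refuses fewer than 30 permuted statistics or a degenerate
(zero-variance) permutation distribution. Permutation p-values are always
(1 + exceedances) / (1 + permutations) and can never be zero. All
stochastic stages take and record seeds; a fixed configuration reproduces
byte-identical pipeline outputs.

# Known limitations

* Sequential (Type I) SS with fixed term order is the only PerMANOVA
  scheme; unbalanced designs should interpret term order accordingly.
* The per-axis "% of information" statistic some ordination programs print
  for NMS solutions has no public definition and is not reproduced.
* The Monte Carlo stress test's 50-randomization default bounds p at
  1/51 ≈ 0.02; raise `n_randomizations` for smaller p-values.
* Indicator analysis uses the original two-way IndVal on single groups;
  site-group-combination extensions are out of scope.
* The digest model is combinatorial: digestion efficiency, star activity,
  partial digests and single-strand (pseudo-T-RF) artifacts are not
  modeled.
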