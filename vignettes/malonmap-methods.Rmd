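---
title: "Methods: quantification, screening and motif discovery in malonmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification, screening and motif discovery in malonmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malonmap)
```

# Scope and data model

`malonmap` analyzes label-free PTM quantification experiments: a site-level
intensity table (protein, lysine position, localization probability, one
intensity column per sample), an optional protein-level table, protein
sequences, protein→term annotation maps and an interaction edge table. The
canonical design is two groups × two replicates — small enough that
classical per-site tests are underpowered, which drives several of the
choices below. Zero intensities are loaded as missing: in label-free data a
zero is an absent measurement, not an abundance, and keeping it would poison
every ratio downstream.

# Relative quantification

Each site row is centralized by its own mean over observed samples,
`R = I / mean(I)`, so complete rows average exactly 1. The mean is taken
per site (not per sample or globally): the downstream fold change and CV
are per-site statistics, and per-site centering is the transformation that
makes them scale-free. Means ignore missing values rather than imputing;
no imputation scheme is assumed anywhere in the pipeline. Sites observed in
fewer than two samples carry no between-sample information and are dropped
(counted in the log).

Protein correction divides each site cell by the parent protein's relative
value in the same sample, turning "the modified peptide changed" into "the
modification stoichiometry changed". The correction is cell-wise with
per-cell fallback: if the protein is absent from the protein table, or
missing in one sample, the affected cells keep their uncorrected values and
the site is flagged, so one dropout does not discard an otherwise complete
site. A useful identity for intuition (and used as a property test): when
the protein profile is constant within each group, the corrected fold
change equals `fc(site) / fc(protein)` exactly. With replicate noise on the
protein values the identity is only approximate — the mean of ratios is not
the ratio of means — which is also why correction adds the protein table's
measurement noise to the site values. The end-to-end recovery benchmarks
therefore characterize the site-level screen on site-level noise, and the
protein-correction benchmark (confounding rescue) is run separately with
its own bundle.

# Differential screening

Fold change is the ratio of observed-group means of `R`, treatment over
control. Significance uses two routes:

* **t-test route** (≥ 3 observed values per group): two-sided Welch test on
  `log2 R`. Logs are taken because multiplicative noise dominates intensity
  data; degenerate zero-variance sites return p = 1 when means agree.
* **CV route** (duplicate designs, where no t-test is computable):
  replicate *m* of the treatment group is paired with replicate *m* of the
  control group in column order, and the coefficient of variation of those
  ratios — sample SD (n−1) over mean — must fall below 0.1. A small CV
  means the treated/control ratio is consistent across pairs, the only
  reproducibility evidence a duplicate design can offer. Sites with fewer
  than two complete pairs are unscorable and stay non-significant.

A site is called UP when significant with fold change strictly above 1.5,
DOWN when strictly below 1/1.5; a fold change exactly at a threshold is NS
(the thresholds are "greater than"/"less than", not "at least"). Regulated
sites are binned Q1 (≤ 1/2), Q2 ((1/2, 1/1.5)), Q3 ((1.5, 2]), Q4 (> 2):
the fold-change axis splits symmetrically at ×2 on either side of the
regulation thresholds. These bounds are a design choice of this package
(configurable in `assign_q_group`), chosen so that strong and moderate
changes land in separate bins on both sides.

The heatmap export keeps differential sites quantified in at least
`ceiling(2/3 × n_samples)` samples. The "top sites" ranking uses
|log2 FC| descending — the magnitude scale on which up- and down-regulation
are comparable — with ties broken by smaller CV (more reproducible first)
and then site id for determinism.

# Enrichment

The 2×2 table per term is (k, n−k; K−k, N−n−K+k): k differential carriers
among n differential proteins, K carriers among N background proteins. The
background universe is the set of proteins bearing quantified modification
sites — enrichment is asked *within* the malonylated proteome — and can be
overridden to a full proteome list. The two-sided p uses the
minimum-likelihood rule (sum of all fixed-margin table probabilities not
exceeding the observed table's), computed directly from the hypergeometric
mass so that thousands of terms and the exhaustive verification sweep are
cheap; the unit tests pin it to `stats::fisher.test` to machine precision.
Terms with no differential carrier are skipped. Significance is flagged at
raw p < 0.05; BH-adjusted values are reported alongside for the reader,
and the label-permutation test confirms the raw-p false-positive rate stays
at or below nominal (Fisher is conservative under discreteness).

Per-Q-group matrices of −log10 p are row-clustered with average linkage on
Euclidean distance (missing cells contribute 0 to the distance only);
linkage and metric are recorded in the result metadata since the choice is
conventional, not forced.

# Motif discovery

Foreground windows are ±10 residues around each modified lysine (21-mers,
`_`-padded at termini; a site whose stated residue disagrees with the
sequence is skipped with a warning, which catches coordinate-base bugs).
The background is one window per lysine in the supplied proteome — all
potential modification sites, including the modified ones.

Discovery is the canonical greedy fix-and-reduce scheme: score every
(offset ≠ 0, residue) pair by the binomial tail `P(X ≥ k_fg)` with success
probability equal to the residue's frequency at that offset among the
background windows matching the current partial motif (pads excluded from
numerator and denominator); fix the smallest p if `p < 1e-6` and
`k_fg ≥ 20`; reduce both sets to matching windows; repeat. When no pair
qualifies the motif is emitted, its foreground windows leave the pool, the
background is restored, and the search restarts — so motifs consume
disjoint foreground sets. The binomial (not hypergeometric) tail and the
recomputation of background frequencies after each reduction follow the
standard motif-x formulation. Ties in minimal p are broken by smaller
|offset| then alphabetical residue, making the output deterministic.
Rendering uses colon notation (`Kmal:::C` = C at +4); the internal
representation stays offset-based.

The residue-composition heatmap reports `log2` foreground/background
frequency ratios per (residue, offset) with a pseudo-count of 0.5 per cell
(so depletion of an absent residue stays finite).

# Network and QC

Edges at confidence strictly above 0.7 whose endpoints are both
differential proteins form the network; "closest interactions" is
interpreted as highest degree, and the top 50 nodes are reported with ties
broken by id. Degree is computed on the filtered graph, so the degree sum
equals twice the edge count — one of the invariant tests.

QC summarizes per-sample log10 raw intensities (five-number summaries over
observed values) and runs a sample-level PCA on complete-case sites of the
relative matrix, column-centered, no scaling (relative values are already
on a common scale). Complete-case selection avoids imputation at the cost
of discarding sites with any dropout; the number used is logged.

# The synthetic-data generator

`simulate_bundle()` emulates the study conditions the pipeline targets:
two groups × two replicates; per-site baseline intensities log-normal with
log10 mean 7 and SD 0.5 (typical label-free dynamic range); multiplicative
per-replicate noise `2^N(0, σ)` with σ = 0.1 log2 units by default (a
realistic technical+biological spread for replicate LC-MS runs; benchmarks
that probe the screen's operating point use σ = 0.05); 10% of sites
differential with fold changes drawn from [2, 4] (down-regulated sites use
reciprocals); missingness completely at random at 5%. Protein confounding
plants sites whose shift is entirely protein-driven, so correction should
return them to fc ≈ 1. Motif planting rewrites the flanking residue in the
protein sequence itself (so foreground and background stay consistent);
planted enrichment gives a term to differential proteins at a high carry
rate versus a background rate. All randomness flows from one seed and the
emitted files are byte-identical across reruns.

What the generator does **not** emulate: intensity-dependent (non-random)
dropout, correlated sites on one peptide, shared sample-level batch
effects, sequence composition biases of real proteomes, or search-engine
identification error. Passing the recovery benchmarks therefore shows the
statistics are implemented correctly and behave as designed under their
assumptions — not that real data meet those assumptions.

# Numerical choices and problem sizes

* CV uses the sample SD (n−1): with two observations the population SD
  would halve every CV and silently loosen the 0.1 gate.
* Fisher two-sided p follows `fisher.test`'s relative tolerance
  (`1 + 1e-7`) when comparing table probabilities, avoiding
  floating-point ties at the observed probability.
* Replicate pairing for the CV follows column order within each group —
  the only stable convention when replicates carry no pairing metadata.
* Hierarchical clustering leaf order comes from `stats::hclust`, which is
  deterministic for fixed input.
* Test and verification problem sizes — 2,000-site bundles over 10 seeds
  for recovery, 20 null runs and 10 planted runs for the motif engine,
  exhaustive Fisher enumeration to N = 60 — were chosen so the full suite
  characterizes every stage's behavior at comfortable statistical
  resolution while remaining quick to run routinely.

# Known limitations

Between-sample normalization (median/quantile) is out of scope — inputs
are assumed comparably loaded, as centralization removes per-site but not
per-sample scale. Site-level p-values are not multiplicity-corrected
(mirroring the screening convention this pipeline implements; BH is applied
in the enrichment stage where term families make it meaningful). The CV
gate is a reproducibility filter, not an error-rate guarantee: its
operating characteristics at σ = 0.05 (≈ 96% sensitivity for 3-fold
changes, near-zero false calls) are established empirically by the
benchmark suite, and degrade with noisier replicates.
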