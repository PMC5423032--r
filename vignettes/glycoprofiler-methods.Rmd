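---
title: "Methods and design of the glycoprofiler pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the glycoprofiler pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoprofiler)
```

This vignette is the package's own account of the statistics it
implements, the choices that were genuinely open, and what its
synthetic-data validation does and does not establish about real data.

## Lectin-microarray model

A lectin microarray block carries replicate spots per lectin, each with
a foreground and a local background fluorescence. Processing follows
three steps.

**Spot filtering.** The block's backgrounds are averaged and spots with
foreground below mean(bg) + 2·SD(bg) are discarded as noise-level.
The rule is stated in the field as "values less than the average
background ± 2 SD were removed"; only the *plus* branch removes
anything, so that is the implemented reading. Filtering is applied to
the raw foreground, and the kept spots are reported as net =
foreground − mean(bg); kept nets are necessarily ≥ 2·SD(bg) ≥ 0, but a
clamp at 0 (with a warning) guards pathological inputs. SD uses the
n − 1 denominator throughout (0 when a single background value exists).
Background statistics are computed per block, not per slide.

**NFI normalization.** The median net of each lectin is divided by the
sum of medians over all non-control lectins in the block, giving
normalized fluorescence intensities that sum to 1 within 1e-9. An even
number of spots takes the mean of the two central values — the standard
median convention, fixed for bit-reproducibility. NFIs are
*compositional*: planting one lectin at fold f deflates every other
lectin's share, so the recoverable NFI fold for a planted lectin of
baseline share s is f / (1 + (f − 1)s), a few percent below f at
typical shares. This is a property of the measurement model, not a bug,
and the recovery suites account for it.

**Differential analysis.** Sample-level profiles (mean NFI over the 9
replicate blocks) are compared between groups per lectin: fold change
is the ratio of the group means over paired subgroups, and the p-value
comes from a two-sided paired t-test matching TD-k with ASD-k by
subgroup index — the only pairing key available for pooled subgroups.
Calls are gated on both the fold (≥ 1.5 or ≤ 0.67) and p < 0.05, which
makes the null call rate conservative relative to 0.05. No
multiple-testing correction is applied across the ~37 lectins by
default, mirroring field practice for these small panels; a
Benjamini–Hochberg option exists (`adjust = "BH"`) but the direction
call always uses the raw p-value. A lectin absent from a sample's
effective spots contributes 0 to that sample, and a TD mean of exactly
0 yields an infinite fold carrying a flag rather than a silent NA.

**Clustering.** Samples and lectins are clustered by unweighted average
linkage (UPGMA) on 1 − Pearson distances. The agglomeration is written
in the package rather than delegated, because a deterministic tie-break
(lowest-index pair first) is part of the contract; on tie-free data it
agrees with `stats::hclust(method = "average")` to numerical precision,
which the tests verify, along with a from-scratch oracle that
re-averages original pairwise distances at every step. Zero-variance
profiles get correlation 0 (distance 1) with a warning. Dendrograms
serialize to Newick via `ape`.

## Spectral-count quantification

Run depths differ, so raw counts R_i are scaled to N_i = R_i · C̄ / C_i
with C_i the run's total count and C̄ the mean total over *all* runs
under comparison (both groups jointly — "all the runs under
comparison"). After scaling, every run's normalized total equals C̄,
which the tests assert to 1e-6 relative on random matrices.

The spectral-index literature leaves the exact SI summary open; this
package defines SI(protein, group) as the mean of the protein's N_i
over the group's runs, zero runs included. This is documented
prominently as an interpretation: it is the simplest summary consistent
with using C̄/C_i to "normalize the total spectral count of each run",
and it makes the ASD/TD ratio well-defined. Ratios are oriented
ASD/TD; the classification boundaries 1.5 and 0.67 are inclusive, and
one-sided identifications (one group's SI = 0) are reported as
`asd_only`/`td_only` rather than forced into a ratio. Proteins with low
peptide support can be flagged via `peptide_counts`/`min_peptides`
(default 1: nothing flagged), mirroring ProteinExtractor-style
thresholds whose values the emulated design does not state.

## Glyco categories and the sequon scanner

Known N/O-glycoprotein status and predicted O-sites must be supplied as
flags — O-glycosite prediction is a proprietary ML server's output and
is consumed, not reimplemented. Predicted N-status is the supplied flag
OR-ed with a built-in scanner for N-X-S/T sequons with X ≠ P;
overlapping sequons are all reported, and the scanner is
property-tested against a brute-force window check. Category
percentages are reported with explicit denominators (known proteins for
N^Y/O^Y, the novel subset for N^P/O^P), because the headline
percentages in such studies are quoted over the known-protein subset;
`tallyPrimaryCategories()` additionally tallies the partitioning
primary category so percentages sum to 100.

## Motif extraction

Windows of width 2k + 1 (default k = 13) are cut around candidate
glycosites, padded with "X" at termini; "X" never matches a fixed
position, and position-frequency matrices exclude it from denominators.
Extraction is the classical iterative position-specific binomial
procedure: for every (offset, residue) the exact binomial tail
P(X ≥ c) with n foreground windows and background frequency q is
computed; the minimum-p pair with c ≥ `min_occurrences` (20) and
p < `p_threshold` (1e-6) is fixed, both sets are reduced to matching
windows, and the loop repeats. Ties break toward the larger foreground
count, then the smaller offset magnitude, then the alphabetically first
residue, making extraction fully deterministic. A finished motif is
emitted when its fold increase — foreground over background match
fractions *on the original, unreduced sets* — exceeds
`min_fold_increase` (30, the conventional filter); its matching
foreground windows are then removed (whether or not it was emitted, so
the search always terminates) and the search restarts against the
original background. Motif score is Σ −log10 p with tails floored at
1e-16 so scores stay finite. Patterns render at full width; a
13-position trimming (`trimPattern()`) matches the compact renderings
common in reports, and `mergeMotifPatterns()` merges motifs differing
at a single position into a bracketed residue class — presentation
only, statistics stay per-motif. The default background in a real
analysis should be windows drawn from the same protein set at
non-identified centers; the generator uses a uniform residue
background, and a user-supplied background is accepted anywhere.

## Validation arrays and ROC

Antibody microarray blocks pass the same ±2SD background rule; the
per-sample, per-antibody signal is the median net over all effective
replicate spots across blocks, and a pair whose spots are all rejected
is *missing*, dropped from that antibody's test rather than imputed at
zero. The group test defaults to a paired t-test by sample index
because that is how such validation panels are conventionally reported,
with a documented caveat: the two groups are independent children, so
the pairing is arbitrary and a Welch mode is provided
(`mode = "welch"`).

The ROC is empirical: every distinct score is a threshold
(score ≥ threshold calls the positive class, ASD by default), AUC uses
the Mann–Whitney identity with ties counting ½ — hence exact agreement
with pair counting and invariance under strictly increasing transforms,
both asserted in tests (and cross-checked against `pROC`) — and the
operating point maximizes Youden's J with ties resolved toward higher
specificity.

## The synthetic-data generators

Each generator emulates one input of the study design: (a) lectin-array
spots as lognormal baseline medians (meanlog log 1000, sdlog 0.5)
multiplied by the planted fold for ASD samples, spot-level
multiplicative noise at CV 0.15, and additive Normal(200, 20)
background truncated at 0; (b) spectral counts as Poisson draws around
lognormal protein baselines (mean count 50, sdlog 1) times the group
ratio and a per-run depth multiplier; (c) glycosite windows with i.i.d.
uniform background residues and planted (offset, residue) enrichments
imposed at their penetrance; (d) biomarker scores as Normal(0, 1) vs
Normal(δ, 1), whose true AUC is Φ(δ/√2). A master seed feeds
independent per-generator streams at fixed offsets, and identical
configurations produce byte-identical files.

These generators deliberately omit several features of real data:
correlated lectin responses (real lectins share glycan epitopes),
subgroup-level biological variability beyond spot noise (available via
`subgroup_cv`, default 0), protein-dependent peptide detectability and
zero-inflation in spectral counts, compositional sequence bias in
peptide windows, and any link between the four generators (real MBG
abundance drives both the MS and the validation arrays). Passing
recovery suites therefore demonstrates that the *estimators* are
correct and well-calibrated under their stated models — not that the
biological effect sizes of any particular cohort are recoverable.

## Validation problem sizes

The recovery suites use: 200 repetitions of the 5-pairs × 9-blocks ×
37-lectins design for the planted 3.33× lectin fold (recovered within
15% and called up in ≥95% of repetitions) and 200 null repetitions for
the call-rate bound; 200 repetitions per ratio r ∈ {1.5, 2, 3} with
1:2:4 run depths for spectral recovery (median within 20%); 100
repetitions of a 200/2000-window two-position plant at penetrance 0.7
for motif recovery; and 200 repetitions at n = 200/group for the
binormal AUC. These sizes give the binomial success counts enough
resolution for the stated rates while keeping the default test run
desk-scale.

One calibration note: at δ = 1.664 and n = 200 per group, a ±0.03 band
around the true AUC spans fewer than two standard errors of the
Mann–Whitney estimator, so its per-repetition coverage falls short of
95% — the AUC recovery suite measures and exposes exactly this. The
median empirical AUC across repetitions, reported by the acceptance
script, is the stable summary of the estimator's accuracy.

## Degenerate inputs and numerical conventions

- Sample SD (n − 1) everywhere; SD of a single value is 0.
- A block whose lectin medians sum to ≤ 0 is a degenerate-block error,
  not a silent NaN.
- A paired t-test with all differences zero reports p = 1 (no
  evidence); a perfectly constant nonzero difference reports p = 0
  (`stats::t.test` cannot run on zero-variance differences).
- Binomial p-values: P(X ≥ c) exactly via `pbinom`; q = 0 with c > 0
  gives p = 0, floored at 1e-16 inside motif scores.
- All thresholds (1.5 / 0.67 / 0.05 / 30 / 1e-6 / 20) are configurable;
  defaults are the conventional values and every run log records the
  thresholds actually applied.
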