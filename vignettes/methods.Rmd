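---
title: "Methods: from peptide intensities to concordant network annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peptide intensities to concordant network annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteonet)
```

proteonet implements the inference chain used to read out TORC1–S6K
signaling from factorial TMT proteomics: peptide normalization →
detection filtering → imputation → moderated differential expression →
network propagation → Fisher term enrichment with signed scores →
rule-based classification and three-dataset concordance. This vignette
explains each model, its assumptions, the defaults, and what the
synthetic benchmark does and does not establish.

## The normalization model and what it preserves

Peptide intensities are log2-transformed, z-scored *within each peptide
row* over its present values, and rescaled by the global standard
deviation of the log2 data plus the global mean:

$$y_{ij} = \frac{x_{ij} - \bar x_i}{s_i}\,\widehat{SD} + \widehat{M}.$$

After this step every retained peptide row has exactly the global mean
and global SD (the package asserts this to 1e-9). Two consequences
matter for interpretation:

* The transform removes per-peptide location *and scale*. Peptides with
  poor ionization or compressed dynamic range are put on a common
  footing, which is the point of the procedure.
* Because each row is forced to the same spread, the *magnitude* of a
  downstream fold change is not the planted biological magnitude — a
  1-unit log2 effect on a low-variance peptide is expanded, and pure
  noise rows are expanded too. Sign, relative ranking within a
  contrast, and module coherence are preserved; absolute effect sizes
  are not. All downstream machinery (moderated tests, propagation,
  enrichment) consumes ranks, signs and p-values, so the pipeline's
  conclusions are invariant to this; but reported log2FC columns should
  be read as normalized scores, not literal abundance ratios.

Rows that cannot be z-scored (fewer than two present values, or zero
variance) are dropped and counted; an all-constant table is an error.

## Detection, aggregation and imputation

Peptides aggregate to proteins by the per-sample median over present
peptides (robust to a single aberrant peptide; a protein–sample cell is
missing only if all its peptides are). A protein is kept only when it
has at least `min_detected = 3` present values in *every*
age × drug × induction cell — the strict reading of "detected in at
least three out of four replicates for each treatment". The strictness
is configurable via `group_by`, and it changes protein counts: the
every-cell rule is the conservative choice and the default.

Missing values are then imputed by k-nearest neighbours in protein
space (`k = 10`, the convention of the kNN imputation tool family):
distances are root-mean-square differences over mutually present
samples, each missing cell takes the mean of the neighbours' present
values there, rows more than 50% missing fall back to the row mean, and
observed entries are never modified. Neighbour ties break by protein id
so imputation is deterministic.

Batch (the dissection/labeling plex) is handled two ways, mirroring how
such designs are analysed in practice: mean-centering per batch for PCA
and visualization only, and as a model covariate in the differential
fit. In the default simulated design each age is one TMT plex, so batch
is aliased with age; the pipeline detects the aliasing, omits the
covariate with a message, and the ageing contrast consequently absorbs
batch noise — a truthful reproduction of the design's limitation, and
the reason within-plex contrasts (drug, induction) are the sharp ones.

## Moderated differential expression

Each protein is fit by OLS on cell-mean coding (one coefficient per
design cell, no intercept), so a contrast is just a signed combination
of cell means and is estimable exactly when its cells are populated.
Residual variances are shrunk with the standard empirical-Bayes
hierarchy: a scaled inverse chi-square prior with parameters estimated
by the log-variance moment method — match the mean and variance of
log s² using digamma/trigamma identities, invert the trigamma by
Newton iteration (verified against bisection to 1e-8), and set
`d0 = Inf` with `s0² = mean(s²)` when the empirical variance of log s²
does not exceed the sampling term (no excess dispersion). Then

$$s^2_{post} = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d},\qquad
t = \frac{\hat\beta_c}{\sqrt{c'(X'X)^{-1}c\; s^2_{post}}}$$

with a two-sided p-value on `d0 + d` degrees of freedom. The estimator
agrees with the installed limma reference on identical inputs (a test
asserts this to 1e-8 for finite `d0`; for `d0 = Inf` limma additionally
caps the total df at the pooled df, a pragmatic deviation from the
formula that we do not copy). p-value filters throughout use raw
p-values at 0.05 — the convention of the source analyses — with BH
adjustment always reported alongside. Moderation is estimated per
stratum: contrasts that live inside one age (one TMT plex) share a fit
and prior separate from the cross-age contrast.

The TORC1–S6K dependence rule for proteins is a pure function of three
p-values: changed by knockdown induction (p < 0.05) *and* by rapamycin
(p < 0.05) *but not* by rapamycin under constitutive activation
(p ≥ 0.05). Gene-set readouts (5′TOP-like, AMP-like panels) use the
two-sided Wilcoxon rank-sum shift test — exact enumeration when both
sides have ≤ 10 values, normal approximation with tie correction
otherwise — and a detection-intersection fold-change matrix.

## Network propagation

The interaction graph keeps STRING-convention edges with combined
score strictly greater than 899 (integer scores, so ≥ 900 survive),
de-duplicated and undirected. The propagation operator defaults to the
symmetric normalization `W = D^(-1/2) A D^(-1/2)` with binary weights:
the source analysis names only the smoothing package, α and the iteration count,
and the symmetric operator is the standard choice with spectrum in
[-1, 1]; row normalization and score weights (scores/1000) are provided
and recorded in the output metadata. Scores follow

$$x_{t+1} = \alpha W x_t + (1-\alpha) x_0$$

run for exactly the configured number of iterations (26 for the fly
setting, 25 for mouse) rather than to a convergence tolerance, matching
the stated counts. With α = 0.5 the iterate is within `0.5^26 ≈ 1.5e-8`
of the closed-form limit `(1-α)(I-αW)^(-1)x0`, which the package also
implements as the convergence oracle. Unmeasured graph nodes enter at
x0 = 0; measured proteins absent from the graph are excluded from
propagation and from the enrichment universe, since the network is the
analysis background. Selection takes the top and bottom
`ceiling(0.05 · m)` nodes among the `m` nodes with more than four
interaction partners (filter first, then quantile — the order is not
stated in the source and filter-first keeps the quantile interpretable
over eligible nodes); boundary ties break lexicographically and the up
set is removed from the candidate pool before the down set is drawn, so
the two are disjoint and reruns are bit-identical.

## Enrichment and classification

Term enrichment is the one-sided Fisher exact (hypergeometric tail)
test of each direction's selection against the degree-filtered,
measured background, for terms with at least 5 background genes
("classic" Fisher; topology-aware GO variants are out of scope, and the
exact variant the cited tooling ran is not recoverable, so the choice
is recorded in output metadata). Signed significance scores are
−log10 p with a positive sign for up-selections and negative for down;
a term tested in both directions reports the direction with the smaller
p. No multiple-testing correction enters the classification rules —
they operate on raw p-values, as in the source analyses — and the BH
column is available in every table.

The annotation-level rules, all pure functions of (p, direction):

* **age_related** — p < 0.05 in the old-vs-young control enrichment.
* **s6kca_dependent_rapa** — `(−log10 p_rapa) − (−log10 p_rapa|CA) > 2`
  (rapamycin annotation at least 100× more significant than under
  activation). **s6kca_independent_rapa** — `−log10 p_rapa > 2` and the
  difference ≤ 2. Terms missing from a table count as p = 1 (absence =
  no evidence). The sign convention reads "log10_pvalue" as −log10 p;
  only under that reading does "at least 100 times" match a +2
  difference.
* **s6k_inhibition_induced** — `−log10 p > 2` in the knockdown
  induction enrichment; the source does not print this rule, so the
  default mirrors the rapamycin margin for internal consistency and is
  configurable.
* **Concordance** — a term is shared across three datasets iff p < 0.05
  with the same direction in all three, after restricting every
  dataset's differential table to the common gene universe and
  re-running propagation and enrichment on it. The source analysis's further
  REVIGO redundancy reduction is an external service and is not
  reimplemented.

Direction for a term is taken from the selection set in which it was
tested (not from mean propagated scores) — the two coincide except for
terms straddling both tails, where the smaller p wins.

## The synthetic benchmark: what it emulates

`synth_config()` defaults define the study conditions: 2,000 proteins,
2 ages × {vehicle, rapamycin} × {uninduced, induced} × 4 replicates
(the fly factorial with four replicates per group), batch tied to age
as in the two-plex layout, ~3 peptides per protein with SD-1 ionization
offsets, residual peptide noise of 0.25 log2 units (a convention —
replicate variance in the deposited data is not characterized —
flagged here and in the config docs), protein baselines N(18, 1.5²) on
the log2 scale. Missingness is MCAR (2%) plus logistic
intensity-dependent MNAR (midpoint 14, slope 0.8); a slope of 0
disables the MNAR channel, since a literal logistic would give 50%
dropout everywhere at slope 0. The network is a stochastic block model
(10 modules × 20 nodes, within-module edge probability 0.4, between
0.02) with edge scores drawn in 900–999 so the whole graph survives the
high-confidence read path; annotations are one true term per module
(members swapped out with 5% noise) plus size-matched decoy terms.
Decoys — and the noise swaps — are drawn from the network-node universe
rather than all simulated proteins, so they survive the min-size
background filter and term recovery is a contest among live
alternatives rather than a walkover. A planted effect adds δ to the
positive cells of a named contrast at the protein level (peptides
inherit it), so the truth tables record exact per-contrast log2 fold
changes for every protein.

What passing the benchmark shows: the chain recovers planted modular
signal (the true term is top-ranked and the up-selection is pure module
at δ = 1, noise 0.25), the moderation prior is recovered within ±25%,
the moderated test holds its size on nulls, and all rule logic matches
exhaustive enumeration. What it does not show: behaviour under ratio
compression, isotope impurity, shared-peptide ambiguity (excluded at
read time), real PPI degree distributions (SBM modules are
near-regular), or real annotation redundancy — conclusions about the
deposited data still require the deposited data.

## Numerical choices and problem sizes

Determinism is enforced everywhere: one RNG seed per run drawn once at
the top (`simulate_dataset` seeds and draws network → annotations →
experiment in a fixed order), lexicographic tie-breaks in imputation
neighbours and node selection, sorted row order and 6-significant-digit
floats in every written table, so identical configs produce
bit-identical outputs. p-values are floored at the double minimum
before logs. The trigamma inversion runs Newton from the asymptotic
start `0.5 + 1/y` and is exact to ~1e-10 relative.

The tests and the acceptance script use 2,000-protein single-dataset
runs (the study scale) and 600-protein triplets for the three-dataset
integration, sizes chosen so a complete verification pass, including
twenty seeded end-to-end repetitions of each recovery experiment, runs
in a couple of minutes on one CPU while leaving all pass criteria far
from their thresholds.
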