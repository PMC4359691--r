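---
title: "Region-centric differential methylation in trio cohorts: models and choices"
author: "bopscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-centric differential methylation in trio cohorts: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bopscan)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic cohort generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## Probe classes and blocks of probes

Array probes are partitioned by two binary attributes: whether the probe lies
in a CpG island or its flanking sequence (shores, 0–2 kb; shelves, 2–4 kb; on
either side), and whether it is annotated to at least one gene.  The four
cells of that cross are classes A (island context, genic), B (island context,
non-genic), C (open sea, genic) and D (open sea, non-genic).  A blank
island-relation cell in the manifest means open sea — that is the manifest
convention of leaving the field empty, so the parser treats the empty string
as `OpenSea` rather than as missing data.

Class A/B probes in the *same* island, the *same* shore or the *same* shelf
form one block of probes (BOP).  Two consequences of that definition are
deliberate:

* The north and south shore (and the two shelves) of one island are
  *different* BOPs.  They are separated by the island itself, often by
  several kilobases, and regional methylation is not expected to be coherent
  across that gap.
* Class A BOPs are keyed by gene as well as by region, so a probe annotated
  to *k* genes contributes to *k* BOPs.  The alternative — collapsing to the
  first listed gene — loses per-gene interpretability of the results table
  and makes the output depend on the manifest's arbitrary gene order; it
  remains available as `build_bops(multi_gene = "first")`.  Gene symbols are
  matched by exact string comparison after trimming and uppercasing; no
  alias resolution is attempted.

Coordinates are 1-based inclusive, as in the manifest; the BED export
converts to 0-based half-open.

## Quality control

Two filters run in a fixed order, both reading "more than 75%" as a strict
inequality (a sample or probe sitting exactly at the threshold is kept):

1. sample level — a sample is dropped iff strictly more than `frac = 0.75`
   of its probes have detection p > `1e-5`;
2. probe level — probes are removed when (a) detection p > `0.05` in
   strictly more than 75% of samples, then (b) any beta value is missing,
   then (c) the probe maps to chromosome X or Y.

Because the rules apply sequentially, each removed probe is attributed to
exactly one rule and the per-rule counts plus the retained count reconstruct
the input count.  No normalization (quantile, beta-mixture, dye-bias) is
applied: the pipeline starts from an already background-corrected beta
matrix, and its statistics operate on betas as delivered.

## Cell-type deconvolution

Whole blood is a mixture of leukocyte compartments with distinct methylomes.
We model a bulk profile over selected sites as `y = S x + e`, `x ≥ 0`, where
the columns of `S` are per-cell-type mean reference profiles from sorted
cells.  Two choices deserve comment:

* **Informativeness.**  Sites are ranked by the one-way ANOVA F statistic
  across cell types in the reference — the standard screening statistic in
  reference-based deconvolution.  Sites with zero within-type variance and
  distinct means sort first (infinite F); ties break on the CpG identifier
  so the ranking is reproducible.  The default of `n = 500` sites keeps the
  projection well-conditioned for six cell types while staying small enough
  that reference and target platforms usually share almost all sites;
  missing sites are dropped with a warning and a count.
* **Constraint.**  The solve enforces non-negativity only
  (`pracma::lsqnonneg`), followed by normalization to sum to one, rather
  than a simplex-constrained solve.  Post-hoc normalization is the
  convention of this algorithm family; reporting both the raw and the
  normalized solutions lets users see when the raw vector sums far from one
  (a sign the reference does not span the target).  Within-type reference
  variance is not propagated — `S` uses type means only.

Estimated fractions enter downstream scans as covariates.  Because the six
fractions sum to one, including all of them would make the design singular;
the granulocyte fraction — the largest compartment — is dropped as the
reference category (`make_design(drop_celltype = "Gran")`).

## Differential methylation scans

Testing contrasts the case group (DSP) against unaffected siblings (DSS);
mothers (DSM) are excluded from tests and serve descriptive comparisons.
The linear model per response is `beta ~ group + sex + batch + cell
proportions`, on the original [0, 1] beta scale.  Logit-type transforms
stabilize variance but destroy the delta-beta effect-size scale on which the
signature rule (below) is defined; betas are therefore analyzed raw.

**Region level.**  For each BOP with at least 3 surviving probes, a window
of 3 consecutive CpGs slides with step 1; each window is tested with a
multivariate linear model of the 3 beta responses.  The group term uses
type-II sums of squares — the hypothesis SSCP is the increase in residual
SSCP when the group factor is dropped with all covariates retained — so the
order of covariates is irrelevant.  The test statistic is Pillai's trace
with its standard F approximation (for a 2-level factor the four classical
MANOVA statistics coincide); Wilks' lambda via Rao's F is available with
`scan_bops(statistic = "wilks")`.  The lowest window p-value represents the
BOP and is carried to BH correction *without* within-BOP multiplicity
adjustment.  That carry-over is anti-conservative for BOPs with several
windows — the minimum of correlated p-values is stochastically smaller than
uniform — and is retained deliberately as the procedure's defining
convention; it is documented rather than "fixed", and the null-calibration
checks below therefore use single-window BOPs, where the BOP p-value *is*
the window p-value and BH's exact global-null error control applies.

**Site level.**  Class C/D probes are tested one at a time with the
univariate analogue (type-II F for the group term).  With no covariates this
reduces exactly to the pooled-variance two-sample t-test, which the tests
assert to 1e-10.

**Degeneracy.**  A constant probe makes the residual SSCP singular.  A
genome-wide scan must not die on one bad probe, so degenerate fits return
p = 1 with a flag — a conservative sentinel that never creates a discovery.

**Multiplicity.**  BH runs separately within each class (A, B, C, D),
matching the per-class reporting of the results; q-values are monotone and
dominate their p-values.

**Chromosome distributions.**  Per chromosome and per group pair, all
(probe, sample) beta values are pooled and compared with the two-sample
Kolmogorov–Smirnov test, Bonferroni-corrected by chromosomes × pairs.  The
KS statistic is computed on the pooled raw values; the 100-bin histograms
are attached for reporting only.  Binning before testing would discard
within-bin information and make the result depend on bin placement, so the
histogram is never the test input.

**Deltas.**  Per-probe delta is mean beta in cases minus mean beta in
siblings; a BOP's direction (hyper/hypo in cases) comes from the mean of its
per-probe deltas.  Window-level means would tie the effect size to whichever
window happened to win, which is less stable for long BOPs.

## Signature selection

From the significant BOPs (q < 0.05), the stringent signature keeps those
containing at least `min_adjacent = 2` genomically consecutive probes, each
with |delta| > `delta_thresh = 0.15`, moving in the same direction.  Two
readings of that rule were possible: absolute differences with or without a
sign-consistency requirement across the adjacent probes.  The package
requires consistent signs by default — a region where neighboring CpGs move
by 0.2 in opposite directions is not a coherent differential region —
and exposes `same_sign = FALSE` for the permissive reading.  "Adjacent"
means consecutive among the BOP's probes surviving QC, not bounded by
genomic distance: QC removals shorten runs rather than silently bridging
them.

Each signature BOP is summarized by its most significant probe under the
*site-level* test (ties break to the smaller genomic position).  The
alternative — a member of the best window — would tie the choice to the
window search; the site-level criterion is defined for every probe and
independent of window boundaries.

Per-family case−sibling differences over the representative probes cancel
any additive component shared by both members of a family (genetic
background, shared environment, family-confounded batch); the trio-design
tests assert this cancellation to 1e-12.  Cohort geometry uses classical
metric MDS on Euclidean distances (orientation fixed by making the first
non-zero coordinate of each axis non-negative; rank-1 configurations get a
zero second axis and a flag) and average-linkage hierarchical clustering on
Euclidean distance, with items pre-sorted by label so tied merges are
deterministic.  Distance and linkage are conventional defaults, not
claims of optimality; both are configurable.

## Enrichment

Chromosomal enrichment builds, per chromosome, the 2×2 table of
(significant vs not) × (on vs off chromosome) over the tested units — BOPs
for classes A/B, probes for C/D, since those are the units that received
q-values — and applies the two-tailed Fisher exact test with BH across
chromosomes.  The reported odds ratio is the closed form (ad)/(bc), not the
conditional MLE, so it matches the contingency counts exactly.  Gene-set
enrichment is the same test over user-supplied GMT collections intersected
with the tested-gene universe; no pathway database is bundled, because
set membership depends on database versions and the statistics should not.

## The synthetic cohort generator

The generator exists so that every stage — parsing, QC, deconvolution,
scanning, signature, enrichment, clustering — can be exercised end to end
with known ground truth.  Its defaults encode the study conditions of a
29-trio whole-blood design: case sex ratio 18M/11F, sibling 7M/22F, mothers
female; four processing batches; control leukocyte means (granulocytes 0.55,
CD4+ T 0.20, CD8+ T 0.10, B 0.08, NK 0.04, monocytes 0.03) against a
case-specific shift (B 0.03, CD4+ T 0.13, CD8+ T 0.18) reproducing the
reported direction of immune alterations in cases — fewer B and CD4+ T
cells, more CD8+ T cells; per-sample composition is Dirichlet around the
group mean with concentration 200, which gives the few-percent
sample-to-sample spread seen in flow-cytometry panels.

Expected beta per probe and sample is assembled additively — base level (or
a composition mixture, below) + family shift + sex shift + batch shift +
planted group effect — clipped to [1e-6, 1 − 1e-6], then observed through
beta-distributed noise with precision 100 (standard deviation ≈ 0.05 at
beta = 0.5, shrinking toward the boundaries as array noise does).  Gaussian
noise would need ad-hoc clipping that distorts means near 0 and 1; the beta
observation model is bounded by construction and mean-preserving.  Base
levels follow island biology: islands mostly unmethylated (Beta(3,12)),
open sea mostly methylated (Beta(8,3)), flanks intermediate, clipped to
[0.05, 0.95] because probes pinned to the extremes are uninformative and
typically fail QC on real arrays.  Probes carrying a planted effect re-draw
their base level from [0.25, 0.55] so the full planted delta fits inside the
beta range — the generator's contract is that a planted delta of 0.2 is
realized as 0.2, which the tests verify empirically within CLT bounds.

The family effect is one shared shift per (probe, family), drawn with sd
0.02: it models what the trio design is *for*, and the pipeline's
family-difference matrix must cancel it exactly.  Sex and batch shifts (sd
0.01) are small nuisance structure for the covariate adjustment to absorb.
A configurable fraction of probes (default 0.3) carries cell-type-specific
mean profiles mixed through each sample's true proportions, which is what
makes composition a genuine confounder in generated cohorts; when a
reference panel is supplied, its discriminative CpGs overlap the cohort's
probes so deconvolution of the cohort against that panel is consistent.
Detection p-values are tiny for good measurements with a configurable
failure rate, plus optional engineered always-failing and missing-value
probes to exercise each QC rule.  Randomness is seeded with one substream
per sample, so cohorts are byte-reproducible and adding a sample does not
reshuffle the others.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: probe-type chemistry differences and
dye bias, spatial correlation of noise along the genome beyond BOP
structure, SNPs under probes (a known caveat for polymorphic loci such as
the HLA region), age effects, and any normalization artefacts.  The planted
effects are additive mean shifts, uniform across affected probes; real
regional differences taper at region edges.

## Problem sizes and numerical checks

The shipped checks run at desk scale, chosen so the full suite and the
acceptance script each finish in minutes on one CPU while keeping every
statistical property measurable: null calibration uses cohorts of 2100
single-window BOPs (≥ 2000 window p-values per cohort, 29 + 29 samples)
across 20 seeds; planted-effect recovery uses 20 affected BOPs among 480
null BOPs; deconvolution benchmarks 50 mixtures over 500 sites with noise
sd 0.02; the composition-confounding contrast uses 1000 probes, half of
them cell-type-variable.  Analytic results are verified against independent
oracles rather than re-derivations: the window MANOVA against a
10,000-draw permutation null and against an independent multivariate
type-II implementation, the site test against the closed-form t-test,
Fisher p-values against exhaustive hypergeometric enumeration, and the KS
statistic against a brute-force ECDF sweep.

Known limitations worth restating: the minimum-window-p convention is
anti-conservative for multi-window BOPs (by design, documented above);
between-family independence is assumed by the tests even though the trio
structure correlates cases and siblings (the family-difference analysis,
not the scan, is the design's answer to that); and beta-scale linear models
are heteroscedastic near the boundaries, which the rank-based and
permutation cross-checks bound but do not remove.
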