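---
title: "Methods: depth-based copy number, dN/dS and phylogenetically corrected chemotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-based copy number, dN/dS and phylogenetically corrected chemotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvchemo)
```

This vignette is the package's account of its statistical machinery: the
models, the assumptions behind them, the parameters that matter, what the
synthetic-data generators do and do not emulate, and the numerical and
design choices made where the field leaves room.

## Copy number from read depth

A gene present in *c* copies collects, on average, *c* times the read
depth of a single-copy locus. With total aligned bases $B$ and genome size
$G$, the expected single-copy coverage is $E = B/G$, and the copy-number
estimate for a region is

$$\widehat{CN} = \frac{\text{mean per-base depth over the region}}{E}.$$

The estimate is reported as a continuous value, never rounded: downstream
correlations use the scaled depth directly, and rounding would discard
exactly the variation they rely on. Assumptions worth keeping in mind:

* **Uniform mappability.** The model assumes reads map evenly; GC bias,
  repeats and mapping ambiguity between near-identical paralogs all
  perturb it. For this gene family the paralogs are similar enough that
  reads cross-map, which is why per-paralog estimates are complemented by
  the collapsed-reference mode: with only one family representative
  retained in the reference, all family reads co-map onto it and the
  scaled depth estimates the *total* family CN (`collapse_family_cn()`).
* **Coordinate conventions.** Depth files are 1-based (the convention of
  standard depth emitters); BED regions are 0-based half-open. The
  conversion happens exactly once, where a region is applied to a depth
  table: a region `[start, end)` covers depth positions `start + 1 … end`.
  Positions absent from a depth file count as depth 0, because standard
  depth output omits zero rows unless asked not to.
* **Genome size.** A per-sample parameter, defaulting to 818 Mb (female)
  with 843 Mb (male) available, since sex is often unrecorded in sample
  sheets. `total_aligned_bases` is taken from metadata, one number per
  sample; re-deriving it from alignments is out of scope here.

Under Poisson sequencing noise the estimator is unbiased with variance
$c\,E / (L E^2) = c/(LE)$ for a region of length $L$; at $E = 20$ and
$L = 1500$ bp the standard error at CN 5 is about 0.013, which is why the
test suite can demand a cohort-level mean absolute error below 0.15 with a
wide margin.

## Paralog family characterization

**Distances.** The default pairwise metric is the p-distance, with a
Jukes–Cantor option (`distance_matrix(model = "jc")`). Sites with a gap or
`N` in either sequence are removed pairwise. The Jukes–Cantor transform
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ saturates at $p = 3/4$; the
standalone `jukes_cantor()` raises a classed error there, while
`nei_gojobori()` reports `NA` for a saturated distance so that the
counting columns survive for short or highly diverged pairs.

**dN/dS.** `nei_gojobori()` implements counting-based estimation:

1. Per codon, each of the three positions contributes a synonymous-site
   fraction equal to the share of its possible changes that preserve the
   amino acid. Changes that would create a stop codon are excluded from
   both numerator and denominator, so each codon's synonymous plus
   nonsynonymous site counts always sum to 3. $S$ is averaged over the two
   sequences; $N = 3\,\text{codons} - S$.
2. Between two codons differing at $k$ sites, the $k!$ orderings of the
   changes are enumerated and the per-step synonymous/nonsynonymous labels
   averaged with equal weight. Orderings that pass through an intermediate
   stop codon are excluded; if every ordering is blocked, all are used as
   a fallback (the alternative — dropping the codon — would silently
   shrink $S_d + N_d$). This stop handling is configurable
   (`exclude_stop_paths = FALSE`) because the literature's tools differ
   and the choice is a convention, not a theorem.
3. $p_S = S_d/S$ and $p_N = N_d/N$ are Jukes–Cantor corrected to $d_S$,
   $d_N$; the ratio is reported as `NA` — undefined, not zero, not
   infinite — when $d_S = 0$, so a lack of synonymous divergence is never
   mistaken for strong selection.

Codons containing a gap, an `N`, or a stop in either sequence are dropped
pairwise before any counting.

**Truncation.** `detect_premature_stop()` scans codons in the declared
frame and flags a sequence truncated only when a stop occurs strictly
before the final complete codon — a terminal stop is a healthy reading
frame. Incomplete tail codons are ignored rather than erroring, because
annotated paralog spans frequently end mid-codon.

**Trees.** `nj_tree()` wraps the standard neighbour-joining algorithm as a
plumbing utility (the package takes a phylogeny as *input* for PGLS; it
does not claim tree inference as a contribution). Negative branch-length
estimates, which NJ can produce on non-additive matrices, are clamped to
zero.

## Group statistics

One-way ANOVA is computed from the sums of squares, $F = MS_B / MS_W$ with
$(k-1, n-k)$ degrees of freedom, with means *and* medians reported per
group — group comparisons in this setting are routinely discussed in terms
of both. Tukey HSD adjusts all pairwise comparisons through the
studentized range distribution using the pooled within-group mean square;
with two groups it collapses exactly to the ANOVA p-value. Degenerate
inputs are classed errors, not silent `NaN`s: zero within-group variance,
singleton groups, and zero-variance paired differences each have their own
condition class.

Samples with lineage `"unassigned"` are excluded from lineage ANOVAs (the
three named lineages are the objects of comparison). No multiple-testing
correction is applied across per-paralog ANOVAs by default — the
per-paralog tables are reported as-is, which matches how such scans are
usually presented — with a Benjamini–Hochberg column available via
`adjust = TRUE`.

## Phylogenetic generalized least squares

Closely related cultivars resemble each other in both copy number and
chemotype for no causal reason; a regression that ignores this treats
shared ancestry as evidence. Under Brownian motion, trait covariance
between two tips equals the shared root-to-tip path length, giving the
covariance matrix $V$ (`bm_covariance()`, with the hand-checkable property
$V_{ij} = $ depth of the MRCA of tips $i, j$). The GLS estimator

$$\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$$

is computed by Cholesky whitening (solve $L^\top z = v$, then ordinary
least squares on the whitened data), which is both the fastest and the
most stable route. Standard errors use
$\hat\sigma^2 (X^\top V^{-1}X)^{-1}$ with
$\hat\sigma^2 = r^\top V^{-1} r/(n-2)$; p-values are two-sided from the t
distribution with $n-2$ degrees of freedom. The reported correlation
coefficient is the sign-preserving square root of the GLS $R^2$, where the
total sum of squares is taken around the GLS intercept-only mean — this is
the quantity that reduces exactly to the Pearson correlation when
$V \propto I$.

Design choices made where the field is genuinely open:

* **Correlation structure fixed to pure Brownian motion.** A Pagel's-λ
  structure would add a nuisance parameter whose estimate is unstable at
  these sample sizes; the pure-BM fit is also the structure that the
  standard `nlme::gls(correlation = corBrownian(...))` call fits, and the
  test suite verifies agreement with it to 1e-10.
* **Chemotype matching.** Per-sample (individual) chemotype values are
  used where available and cultivar averages otherwise; the output records
  how many samples used individual values. Averages suppress environmental
  noise at the cost of blurring genotype-specific signal — both modes are
  legitimate, so the provenance is kept visible rather than hidden.
* **Decarboxylation factor 0.877.** Total cannabinoid content is
  `neutral + 0.877 × acid`; 0.877 is the molar-mass ratio of the neutral
  to the acidic form (loss of CO₂), configurable per cannabinoid.
* **Conditioning.** $V$ from a tree with duplicated zero-length splits can
  be numerically singular. A ridge of `1e-10 × mean(diag(V))` is added
  only when the Cholesky factorization fails, with a warning — never
  silently.
* **Both corrected and uncorrected statistics are always reported.** The
  interesting scientific cases are exactly the disagreements: an
  association that is significant before correction and gone after it is
  the signature of phylogenetic confounding, and
  `confounded_clades_fixture()` constructs that case deterministically
  (two deeply split clades, within-clade slope exactly zero by
  orthogonality of the within-clade trait vectors).

## Expression

FPKM is `count × 10⁹/(length × library size)`. The comparison report adds
pairwise log2 fold changes with a pseudocount of 0.1 FPKM on both sides of
every ratio — expression tables of this kind contain exact zeros, and a
fold change against zero is otherwise undefined; every comparison touching
a zero is flagged. The report carries an empty `significance` column: the
layout anticipates differential-expression results, but count-model
testing is deliberately out of scope and this package will not fabricate
p-values where it has no dispersion model.

## The synthetic-data generators

All validation rests on generators whose truth is known:

* `simulate_depth()` / `simulate_cohort()`: per-base depth is independent
  Poisson with mean `true_cn × E`. The default cohort mimics the shape of
  a realistic diversity panel — 67 samples in lineages of 15/31/16 plus 5
  unassigned, 11 regions of 1600 bp, integer CN 1–10, E = 20 — shape only,
  no claim of matching any real panel's values.
* `simulate_tree_and_traits()`: a Yule (pure-birth) tree; the predictor
  evolves by Brownian motion; the response adds a Brownian residual and an
  optional iid residual to `intercept + slope × x`. With the iid residual
  at 0 the PGLS model is exactly correct, which is the regime used for
  calibration checks (slope recovery, 95% CI coverage, null type-I rate).
* `simulate_codon_pair()`: a stop-free random ancestor; single-nucleotide
  substitution proposals accepted in a synonymous:nonsynonymous ratio set
  by `omega` (proposals creating stops always rejected); optional planted
  TAA codons at stated positions for truncation tests. The substitution
  log is the oracle for downstream counting checks.
* Determinism: every generator derives a child seed from its master seed
  by a fixed per-stream offset, so outputs are byte-identical across runs
  and adding a new generator never perturbs existing fixtures.

What passing these tests does *not* show about real data: Poisson depth
has no GC bias, no mappability structure and no cross-paralog read
stealing; Yule-plus-BM traits have no measurement error and no model
misspecification; simulated codon evolution has no codon usage bias or
rate heterogeneity. The tests validate the *estimators*, not the
field-readiness of any particular dataset.

## Problem sizes and runtime choices

The validation suite uses a 67-sample × 11-region cohort for copy-number
recovery, 500 replicates of 50-tip trees for PGLS slope recovery and
coverage, 2000 replicates for the PGLS null rejection rate, 5000 small
ANOVA datasets for the ANOVA null rate, all ~2100 sense-codon pairs within
two differences for the dN/dS pathway check, and 100 planted stops for
truncation recovery. These sizes put Monte-Carlo standard errors well
inside the asserted bands (e.g. a binomial SE of 0.005 on the 2000-rep
type-I rate against a ±0.01 band) while keeping the whole suite
comfortably fast on a single CPU.

## Known limitations

* CN estimation degrades when paralogs diverge enough that reads map
  uniquely but the annotation still treats them as one family, or when
  coverage is strongly GC-biased; no bias correction is applied.
* PGLS assumes the supplied tree; tree estimation error propagates
  unmodelled into the covariance.
* The dN/dS counting method underestimates at high divergence relative to
  likelihood codon models; it is the right tool for the nearly identical
  paralog pairs it is aimed at, where most pairwise comparisons have few
  differences.
* Lineage labels are consumed as metadata; no population-structure
  inference is performed.
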