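---
title: "Tissue-specificity classification and IHC biomarker evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specificity classification and IHC biomarker evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuespec)
```

# The model

`tissuespec` operates on a genes × samples FPKM matrix spanning many tissue
types, with several replicate samples per tissue. The per-tissue expression
level of a gene is estimated by the arithmetic mean FPKM over that tissue's
samples (`tissue_means()`); all specificity decisions are made on these
tissue means. FPKM is already length- and depth-normalised, so no further
normalisation is applied, and means are taken on the raw FPKM scale — the
log2 transform is used only for correlation analysis, where variance
stabilisation matters and where the `+1` pseudo-count keeps zeros at zero.

## Detection and the category chain

A gene counts as *detected* in a tissue when its mean FPKM is strictly
greater than the detection limit (default 1 FPKM, roughly one mRNA copy per
cell). "Not detected" means not detected in *any* tissue: a gene absent from
the target but expressed elsewhere is informative (it is `mixed`), so
non-detection is defined matrix-wide.

`classify_gene()` walks a fixed precedence chain, which makes the eight
categories mutually exclusive and exhaustive:

1. **not_detected** — no tissue above the detection limit;
2. **highly_enriched** — target mean ≥ 50 × the maximum of all other tissues;
3. **moderately_enriched** — target mean ≥ 5 × that maximum;
4. **group_enriched** — a group of 2–7 tissues containing the target whose
   mean is ≥ 5 × the maximum of all excluded tissues, every member detected;
5. **expressed_all_high** / **expressed_all_low** — detected in every tissue,
   split at 10 FPKM on the minimum tissue mean;
6. **enhanced** — target detected and ≥ 5 × the average over *all* tissue
   means (target included in the denominator);
7. **mixed** — everything else that is detected somewhere.

Fold criteria are inclusive (≥): a gene at exactly 50-fold is highly
enriched, which keeps the moderate tier a half-open band `[5, 50)` of the
tissue-specific score. The enrichment tiers are tested before
expressed-in-all, so a gene that is detected everywhere but still towers
over every other tissue is reported as enriched — specificity information
outranks ubiquity. Enhanced is tested after expressed-in-all, so it
describes genes with a raised target level against a *partial* expression
background. One guard is added that the category definitions leave
implicit: `enhanced` requires the target itself to be detected. Without
it, a sub-detection target level could satisfy the 5×-average inequality
purely because many other tissues are silent, and calling such a gene
"enhanced in the target" would be biologically meaningless.

## The tissue-specific score

```
score = mean FPKM(target) / max mean FPKM(other tissues)
```

The score is scale-invariant (multiplying the whole matrix by a positive
constant leaves it unchanged) and maps directly onto the two single-tissue
tiers. Two degenerate cases need conventions: when no other tissue is
expressed at all the score is `Inf` (and the gene is highly enriched
provided the target is detected); when the gene is silent everywhere the
score is 0.

## The group-enrichment search

The group criterion is combinatorial — any subset of 2–7 tissues containing
the target could qualify. The search exploits that for this criterion the
*top-k* candidate is optimal: among groups of size k, the one containing
the k−1 highest-expressing other tissues has both the largest group mean
and the smallest excluded maximum, and its members dominate any other
candidate's members for the detection requirement. So `find_enriched_group()`
tests only one candidate per size, smallest size first, and returns the
first that qualifies. The test suite verifies this equivalence against
exhaustive subset enumeration on matrices of up to 10 tissues (300+ random
profiles). Ties in the top-k ordering are broken by tissue label, making
output deterministic. Members must each be detected: a "group" propped up
by tissues below the detection limit would not be a group expressing the
gene.

All group sizes are recorded in the per-gene results; the network export
(`build_network()`) additionally applies a display cutoff (default: groups
of ≤ 4 tissues) while `shared_tissue_counts()` deliberately does not, so
per-tissue sharing counts remain complete whatever is plotted.

## Correlation structure

`pairwise_correlations()` computes Spearman and Pearson coefficients
between samples (or tissue-mean profiles) on `log2(FPKM + 1)` over *all*
genes — no detection filter, since the joint distribution of
low/zero-expression genes is part of what distinguishes two samples.
Spearman uses midranks for ties (the standard convention; ties are common
because of zeros). A zero-variance profile yields `NA` coefficients for its
pairs rather than an error, so a degenerate sample cannot abort a
matrix-wide run. Both computations delegate to `stats::cor`; an independent
midrank oracle cross-checks the Spearman path in the tests.

## IHC marker evaluation

Staining intensity is scored 0–3 and dichotomized at the conventional cut:
0–1 negative (absent/faint), 2–3 positive (moderate/strong). Replicate
cores of a case are collapsed by the maximum score before tabulation (the
common tissue-microarray convention: a marker seen convincingly in any core
is present), configurable via `collapse = "none"`.

The 2×2 table has rows marker negative/positive and columns benign/tumor
(tumor pooling all Gleason grades and metastases). On it:

* **chi-square**: the uncorrected Pearson form `n(ad−bc)²/(r₁r₂c₁c₂)`.
  No Yates correction is applied — at the cohort sizes this package targets
  (hundreds of cases) the correction is both unnecessary and a source of
  discrepancy with the closed form.
* **G statistic**: `2 Σ O ln(O/E)` with `0·ln 0 ≡ 0`, expectations from the
  margins.
* **phi**: `(ad−bc)/√(r₁r₂c₁c₂)`; for two binary variables the Spearman
  rank correlation is identical to phi, so both are reported equal. Under
  the stated row/column orientation a benign-gland marker has negative phi.
* **sensitivity / specificity**: with *benign tissue* as the condition and
  marker expression as the positive test — sensitivity is the positive
  fraction among benign cases, specificity the negative fraction among
  tumors.
* **AUC**: a dichotomized marker has a one-point ROC, whose trapezoidal
  area is exactly `(sensitivity + specificity)/2`. For un-dichotomized 0–3
  scores `ordinal_auc()` gives the Mann–Whitney AUC with tie correction,
  computed via midranks; on scores that are then dichotomized the two
  agree, which the tests assert.

A zero marginal (a cohort with one histology class, or a marker that is
constant) makes chi-square, G and phi undefined; these are reported as `NA`
sentinels and the pipeline warns rather than fails, since partial cohorts
are a routine occurrence. Truncated "p = 0.000" outputs are avoided:
p-values are reported in full precision and should be read as `p < 5e-4`
when quoting at three decimals.

# The synthetic-data generator

`generate_matrix()` plants genes per category so that classification has
known truth. The defaults emulate the conditions this pipeline is designed
for: 27 tissues, 4 samples per tissue, detection limit 1 FPKM, target-level
expression drawn log-normally (median ~80 FPKM, clipped to 3–8000) so the
matrix spans roughly four orders of magnitude.

Planted profiles keep a comfortable margin to every decision boundary so
that the zero-noise limit is unambiguous: highly enriched genes are ≥ 75×
their closest competitor, moderately enriched exactly 10× (inside the
[5, 50) band), group members sit 8× above the excluded background, and
enhanced genes pair the raised target with a half-level competitor (to
block the single-tissue tiers), a detected mid-level band (to block the
group criterion) and an undetected tail (to keep them out of
expressed-in-all). That last pattern needs ≥ 20 tissues to satisfy the
5×-average inequality, so the generator refuses to plant enhanced genes in
smaller matrices rather than plant them ambiguously. Sample noise is
multiplicative log-normal on the log2 scale (`noise_sd`, default 0.2 —
a typical inter-replicate spread for bulk RNA-seq of homogeneous tissue);
at 0 the sample values equal the planted means and classification recovers
the truth exactly, which is a regression test, and at 0.2 recovery stays
above 95%.

What the generator does *not* emulate: correlated noise across genes,
library-size artefacts, transcript-length effects, cell-type heterogeneity
within a tissue, or any read-level process. Passing tests therefore
demonstrate the correctness of the classification logic and statistics, not
robustness to every failure mode of real RNA-seq.

`generate_cohort()` draws staining scores per histology class from
configurable score distributions (defaults: benign positivity 0.814, tumor
positivity 0.164 — the profile of a good benign-gland marker at a ~330-case
validation-cohort scale). Empirical sensitivity/specificity converge to the
planted positivities within binomial Monte-Carlo error, and the chi-square
grows monotonically with the planted positivity gap; both are tested.

Both generators take their seed from the spec object and restore the
caller's RNG state, so fixtures are reproducible bit for bit and
generation never perturbs an enclosing analysis.

# Numerical and design choices

* Statistics on 2×2 tables use the closed forms above; `stats::chisq.test`
  (uncorrected) serves as an independent oracle in the test suite.
* The identity `chi² = n·phi²` is asserted on 1,000 random tables — it ties
  the two implementations together algebraically.
* Matrices are written at `%.6g` precision, which round-trips FPKM values
  through text exactly at the precision the pipeline uses.
* Tissue labels are trimmed and case-sensitive; missing values are not
  accepted anywhere (an absent measurement must be written as 0 upstream).
* Problem sizes in the shipped tests are deliberately modest — 80-gene
  matrices with 27 tissues, 10-tissue matrices for the exhaustive oracle,
  10,000-case cohorts for convergence checks — chosen so the full suite
  runs in well under a minute while every code path and boundary is
  exercised.

# Known limitations

* Classification consumes FPKM-level matrices; upstream read processing
  (alignment, quantification, duplicate marking) is out of scope.
* The expressed-in-all / enriched boundary depends on the precedence
  convention described above; pipelines using the opposite convention
  (ubiquity outranks specificity) will differ for the small set of genes
  that are both.
* Survival analysis (Kaplan–Meier, Cox) on marker expression is out of
  scope; the evaluation here is purely cross-sectional association and
  diagnostic performance.
* The single-threshold AUC is a coarse summary; with only one operating
  point, values near 0.5 cannot distinguish a useless marker from a
  miscalibrated cut.
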