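---
title: "Methods: downstream analysis of pan-cancer DIA proteome matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of pan-cancer DIA proteome matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancanproteo)
```

## Scope and data model

`pancanproteo` covers the analysis stages downstream of DIA/SWATH protein
quantification for multi-cancer tissue cohorts. The central object is a
plain numeric matrix of raw, non-negative MS intensities — proteins in
rows, samples in columns — with `NA` marking cells that were not
quantified. Missingness is first-class: zero is never used to encode
"absent" (readers coerce non-positive cells to `NA` and report the count),
because the imputation rules presuppose positive observed intensities and
label-free zeroes mean "not quantified", not "absent protein".

Sample metadata carries a closed vocabulary of 16 tissue labels
(`pcp_tissues()`); each cancer-type cohort corresponds to one tissue, so
"cancer type" and "tissue" are interchangeable here. Disease states are
tumor / NAT / normal, with NAT (tumor-adjacent normal) and true normal
pooled as "normal" in every analysis — the convention for this study
design. All testing happens on log2 intensities: label-free abundances are
approximately log-normal, so "fold change > 2" is `|log2 FC| > 1` and
"> 4-fold" is `log2 FC > 2`.

## The statistical core

Per-protein two-group comparisons use the **Welch (unequal-variance)
t-test** on log2 intensities, vectorized over matrix rows
(`row_welch_t()`). The study design only says "t test"; Welch is the
robust default for the unequal group sizes and variances typical of
tissue cohorts, and the pooled-variance Student variant remains selectable
(`var_equal = TRUE`) everywhere. Zero-variance degenerate rows are defined
explicitly (equal constant groups: t = 0, p = 1; unequal constant groups:
p = 0) so that synthetic edge cases cannot produce NaNs. Groups with fewer
than two observations yield `NA` rather than an error — the protein is
skipped, never the run.

Multiple testing uses Benjamini–Hochberg (`bh_adjust()`, a validated
wrapper over `stats::p.adjust`). The adjustment family is the comparison
in which the p-values are consumed: **per tissue pair across proteins**
for tissue enrichment and **per cancer type across proteins** for the
differential analysis. The family choice is not stated in such study
designs; these families match how each table of results is read, and both
analyses expose their thresholds so stricter global schemes can be
emulated by the caller.

Replicate QC metrics are conventional: CV (`100·SD/mean`) on the **raw**
intensity scale, Pearson correlation on log2 with pairwise-complete
observations.

## Sample qualification: operationalizing the five criteria

The 3-of-5 qualification rule is stated in prose in this kind of study
("at least 50% of proteins quantified", "similar median", "correlation
above 0.6", "similar distribution", "grouped in the PCA"); only the
correlation threshold is numeric. The package's reading, every knob
exposed via `qc_config()`:

| criterion | operationalization | default |
|---|---|---|
| 1 quantified fraction | fraction of the cohort-detected proteins observed in the sample | ≥ 0.5 |
| 2 similar median | sample median log2 within k·MAD of the median of same-tissue sample medians | k = 3 |
| 3 correlation | mean pairwise Pearson (log2, pairwise-complete) vs same-tissue samples | > 0.6 |
| 4 similar distribution | two-sample Kolmogorov–Smirnov D vs pooled same-tissue values | ≤ 0.3 |
| 5 PCA grouping | nearest tissue centroid on PC1/2 is the sample's own tissue | — |

Criteria 1–4 are evaluated within each cancer-type cohort independently
(tumor and normal pooled per tissue). Criterion 5 is necessarily global:
the PCA runs once on the median-normalized log2 matrix restricted to
proteins observed in ≥80% of all samples, residual missing cells filled
with the protein mean (a neutral value that cannot move a sample toward
any centroid). A tissue with a single sample leaves criteria 2–5
undefined; such a sample qualifies on criterion 1 alone, with a warning.
The MAD rule in criterion 2 gets an absolute epsilon (1e-8) so that
zero-noise degenerate cohorts (MAD = 0) do not disqualify identical
samples.

These are this package's readings, not published formulas; they were
chosen to be robust, parameter-light and deterministic, and the planted
outliers of the generator (below) are disqualified by criteria 1–3 alone,
so the conclusions do not hinge on the PCA or KS readings.

## Quantifiability and the two-branch imputation

A protein is retained when observed in at least 40% (inclusive) of the
qualified samples of at least one cancer type. The per-cancer observed
fractions and the retaining cancer set are returned alongside the
filtered matrix, so the decision is auditable per protein.

Imputation distinguishes two missingness regimes within each tissue
(tumor + normal pooled, consistent with the tissue-as-single-entity
convention):

* **mostly-absent** (protein observed in < 50% of the tissue's samples):
  the protein is plausibly below detection in that tissue; the fill is
  5% of the sample's smallest observed intensity above 100 — a
  left-censored, per-sample detection-limit surrogate. "5% of the lowest
  intensity (> 100)" is read as `0.05 × min{v observed in s : v > 100}`,
  not as the 5th percentile: the parenthetical qualifies the minimum, and
  only this reading yields a value tied to the sample's detection floor.
* **mostly-present** (≥ 50% observed): the value is a stochastic dropout
  from an expressed distribution; the fill is that tissue's
  `mean − 2·SD` for the protein.

The scale of the second branch matters more than it looks. Computed
literally on raw intensities, `mean − 2·SD` is negative whenever the
pooled CV exceeds 50% — which is true for *every* strongly regulated
protein, since a 4-fold tumor/normal split alone produces a pooled CV
near 70%. A positivity floor then produces fills at essentially zero
log2, i.e. extreme outliers that inflate within-group variance and
suppress exactly the differential calls the analysis is after (in our
synthetic experiments, sensitivity at 8 vs 8 / SD 0.3 / 4-fold drops from
≥ 0.95 to ≈ 0.6). The default is therefore the standard left-censored
down-shift for log-normal abundances: mean and SD on **log2** values and
a fill of `2^(mean − 2·SD)`, always positive and always in the low tail
of the tissue's distribution. `scale = "raw"` provides the literal
raw-scale arithmetic (with a floor at 1) for comparability, and both
branches are pinned by exact-arithmetic unit tests.

Imputation is idempotent, never alters observed cells, and runs after the
quantifiability filter, mirroring the stage order of the study design.

## Housekeeping proteins

A protein is called housekeeping when observed — pre-imputation — in more
than 90% (strict) of the pooled tumor samples *and* more than 90% of the
pooled normal samples. Whether the 90% rule pools samples or requires 90%
within every tissue type is ambiguous in prose descriptions; the pooled
reading is the default (it matches counting samples rather than the 16
tissue categories) and `mode = "per_tissue"` ships the stricter
alternative. `expression_stability()` adds the across-tissue CV of
tissue-mean log2 intensity, the quantitative handle for the
constant-vs-fluctuating distinction among housekeeping proteins.

## Tissue enrichment

For every tissue pair, per-protein Welch tests with BH adjustment within
the pair; a protein is enriched in tissue t when it beats at least
`ceil(0.7 × (T−1))` other tissues at > 4-fold and adjusted p < 0.05 —
with 16 tissues, exactly 11 of 15 comparisons. The ceiling is the
conservative integerization of "compared with 70% of other tissue types":
at T = 16 the 70% point (10.5) is non-integral, so inclusive-vs-strict is
moot. Multiplicity (how many tissues a protein is enriched in) is
categorized 1/2/3/4+. A consequence worth knowing: a protein planted in m
tissues wins at most T−m comparisons per enriched tissue, so
multiplicity-4 proteins are only detectable with the full 16-tissue
design — with few tissues the coverage bar is unreachable, which is a
property of the rule, not a bug.

Tissue-group enrichment (digestive: colon, stomach, esophagus, pancreas,
liver; urinary: bladder, prostate, kidney; gynecologic: breast, uterus,
ovary) reuses the identical rule with the pooled group as the entity and
each non-member tissue as a comparator — the minimal consistent extension
of the tissue-level rule, since no group-level formula is ever stated.

## Differential analysis, aggregation, protein groups

Per cancer type with at least two tumor and two normal qualified samples:
Welch on log2, BH across proteins, calls at |FC| > 2 and adjusted
p < 0.05. Cancers without enough normals (brain, in the default design)
are skipped with a logged notice and excluded from the aggregation
denominator — the "more than 40% of cancer types" rule is strict
(7 of 16; 7 > 6.4) and is computed over cancers actually analyzed.
Uniquely overexpressed proteins are up-calls in exactly one cancer.

Protein groups: cancer-associated proteins (≥1 up/down call) are Z-scored
per protein across all samples, clustered with Ward linkage (`ward.D2`)
on Euclidean distances, and cut at k = 4. Only "hierarchical clustering"
is ever specified; Ward/Euclidean on Z-scores is the standard heat-map
recipe, the linkage is selectable, and the PG-1..4 labels are assigned in
descending order of each cluster's mean tumor-minus-normal Z difference,
making the labelling deterministic and interpretable (PG-1 most
tumor-elevated, PG-k most normal-elevated).

## The synthetic-cohort generator

`generate_cohort()` emulates the cohort structure such a study rests on:
16 tissues with the per-cancer tumor/normal counts of the default design
(246 samples; brain tumors have no matched normals), log-normal protein
intensities (per-protein baselines `N(14, 2)` on log2, within-tissue
residual SD 0.5 by default), and four planted signal classes recorded in
a ground-truth object: housekeeping proteins (high, tight baselines:
+2 log2, SD/4 — emulating ribosomal/cytoskeletal abundance, and thereby
largely exempt from intensity-dependent dropout), tissue-enriched
proteins (+3 log2 in 1–4 tissues), per-cancer regulated proteins
(±2 log2 in tumor samples of cancers that have normals — a tumor-vs-normal
effect is not identifiable in a normal-free cohort, so none is planted
there), and outlier samples (missingness raised to 65%, a ±2 log2 global
shift, half the values replaced by independent draws — enough to fail
qualification criteria 1–3 by construction).

Dropout is logistic in latent log2 intensity (slope 1 per log2 unit),
centered numerically so the marginal missing rate hits its target; slope
0 gives uniform missingness. The default marginal rate is 5%, a
deep-coverage DIA completeness level chosen — together with the noise
defaults — for clear planted-signal recovery, and not claimed to match
any particular study (no such magnitudes are published). All knobs are
config-exposed, and the generator is byte-deterministic given its seed.

What the generator does **not** emulate: peptide-level structure,
retention-time drift, batch effects beyond the outlier mechanism,
correlated protein modules, or heavy-tailed noise. Passing recovery tests
on these cohorts therefore demonstrates that the pipeline's logic is
correct and well-calibrated under the stated model, not that real
cohorts will behave as cleanly.

## Problem sizes and validation design

The test suite and `scripts/acceptance.R` validate against planted truth
at these scales, chosen as the smallest sizes at which each property is
cleanly measurable: QC recovery on twenty 246-sample cohorts with 300
proteins; enrichment recovery aggregated over twenty 2000-protein
16-tissue cohorts; differential recovery on 16-tissue cohorts at 8 vs 8
samples per cancer and SD 0.3; the null type-I rate on 10,000 simulated
tests; clustering on 160-protein archetype matrices; determinism on the
full default pipeline.

Two validation choices deserve explanation rather than a footnote:

* **Differential sensitivity is measured on complete matrices.** The
  tumor-vs-normal operation contracts a complete (post-imputation)
  matrix, and its recovery target derives from a power calculation at the
  stated n/SD/effect, which presumes clean groups. End-to-end through
  MNAR dropout and imputation, sensitivity is lower (≈ 0.90 at the same
  conditions): a single left-censored fill inflates a group's variance
  enough to push a raw p of ~1e-3 past the BH bar. The acceptance script
  reports both numbers (`differential_sensitivity` and
  `differential_sensitivity_imputed`) so the gap is visible, not hidden.
* **Enrichment false discoveries are reported as a 20-seed aggregate.**
  The residual false-positive class is imputation-driven: a
  barely-quantifiable null protein can receive min-based fills in some
  tissues and mean−2SD fills in others, and the branch asymmetry mimics
  a 4-fold difference. A handful of such calls arise per cohort
  (aggregate FDP ≈ 0.04 against an ≈ 1.0 sensitivity); single seeds
  fluctuate around that.

## Known limitations

* The five QC criteria are this package's quantitative readings of prose
  descriptions; alternatives (e.g. quantile-based median rules) would
  disqualify slightly different boundary samples.
* Min-based imputation fills collapse within-sample variance and can
  fabricate significance for sparsely observed proteins — the classic
  left-censored imputation pathology. The 40% quantifiability filter
  removes the worst cases; the remainder is quantified above. Model-based
  imputation (kNN, MNAR mixtures) is deliberately out of scope.
* BH families are per-comparison; a global family across all tissue pairs
  would be more conservative for the enrichment analysis.
* The 90% housekeeping rule and the 40% quantifiability rule count pooled
  qualified samples; per-tissue variants exist as config switches but the
  two interpretations can genuinely disagree for uneven cohort sizes.
* Annotation joins consume pre-built flag tables; no live database
  parsing (DrugBank/TTD/CTdatabase versions are not reproducible inputs),
  and id mapping between quantification and annotation id spaces is the
  caller's responsibility.
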