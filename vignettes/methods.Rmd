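---
title: "Methods: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptclscape)
```

# Scope

`ptclscape` implements the analysis stages of a cross-species study of
SMARCB1-deficient peripheral T-cell lymphoma (PTCL-NOS): cohort
statistics, bulk DNA-methylation concordance between human and murine
tumors, single-cell annotation of tumor and microenvironment
populations, ligand–receptor interaction testing, drug-screen scoring,
and immunofluorescence ROI quantification. Clustering, read alignment,
count quantification and array normalization are deliberately *inputs*:
the package consumes cluster labels, count matrices and beta values and
implements everything downstream of them.

# Statistical primitives

**Fisher's exact test (two-sided).** The two-sided p-value uses the
point-probability convention: the sum of hypergeometric point
probabilities, over all 2×2 tables with the observed margins, that do
not exceed the observed table's probability. Several two-sided
conventions exist (doubling the smaller tail is the common alternative);
the point-probability convention is the one that reproduces the
reference cohort p-values (0.0284 for a 4/13 vs 1/28 split, 0.0026 for
8/17 vs 2/29), and it matches `stats::fisher.test`. Probabilities are
evaluated in log space with a relative guard of 1e-7 against
floating-point ties.

**Exact Mann–Whitney.** For combined sample sizes up to 30 the
permutation distribution of the rank-sum is computed exactly by a
generating-function dynamic program over all group reassignments;
mid-ranks handle ties (ranks are doubled internally so tied mid-ranks
stay integral). The two-sided p is the fraction of reassignments whose
U deviates from its null mean at least as much as observed. This matters
at ROI scale: with four regions per group the minimal attainable
two-sided p is 2/70 ≈ 0.0286, exactly the value reported for complete
separation. Beyond n = 30 a tie-corrected normal approximation with
continuity correction is used.

**Per-CpG t-test.** The differential-methylation stage uses the
pooled-variance Student t-test rather than Welch: the underlying report
says only "t-test", pooled is the default of the array-analysis software
family its cutoff notation (σ/σmax) comes from, and group variances are
exchangeable in the generator. The scalar and the vectorised (row-wise)
implementations share the same formula and are cross-checked in the
tests. Zero pooled variance with equal means yields p = 1 by convention.

**BH adjustment.** Step-up `q_(i) = min_{j≥i} m·p_(j)/j`, capped at 1.
Note that BH is *not* idempotent — re-adjusting q-values inflates them
(p = (0.2, 0.3, 0.9) adjusts to (0.45, 0.45, 0.9) and again to
(0.675, 0.675, 0.9); base R's `p.adjust` behaves identically) — so the
tests assert the step-up definition and agreement with `p.adjust`, not
idempotence.

**Logistic Wald test.** `status ~ age` is fitted by `stats::glm`
(binomial family, IRLS epsilon 1e-8). Complete or quasi-complete
separation is detected (non-convergence, fitted probabilities collapsing
to 0/1, or a slope beyond ±50 on the logit scale) and flagged instead of
reporting a spurious p.

# Methylome concordance

Beta values (methylation fractions in [0,1]) arrive as CpG × sample
matrices per species with a CpG→gene map and a one-to-one ortholog map.
The stage applies, per species:

1. **Variance filter:** keep CpGs with σ/σmax > 0.4, where σmax is the
   empirical maximum across-CpG standard deviation of the analyzed
   matrix. A "theoretical" alternative (σmax = 0.5, the maximum sd of a
   bounded [0,1] variable) is a config switch; the empirical convention
   is the default because it is what the σ/σmax notation denotes in the
   filtering software family it originates from.
2. **Per-CpG test:** pooled t-test tumor vs control, BH over tested
   CpGs only.
3. **Direction calls:** hyper (Δβ > 0) and hypo (Δβ < 0) at separate q
   cutoffs, both 0.01 by default. The stringent hypermethylation variant
   (q < 1e-5), which shrinks the high-confidence hypermethylated set, is
   expressible by overriding `q_cut_hyper`.
4. **Gene-level calls:** a gene carries a direction if ≥1 mapped CpG is
   called in that direction. No aggregation rule was stated for the
   reference gene counts; the ≥1-CpG rule is the most permissive and
   discordant genes (CpGs called in both directions) are kept in both
   sets and tallied rather than silently dropped.
5. **Concordance:** human genes whose ortholog carries the same call;
   genes without orthologs are excluded and tallied.
6. **ORA:** hypergeometric upper-tail enrichment of concordant sets
   against a GMT collection, sets retained only when larger than 10
   genes after intersection with the universe (strictly more than 10),
   with BH over retained sets and enrichment ratio k/(n·K/N).

**Synthetic beta model.** Group means are baseline (uniform on
[0.25, 0.65]) plus a planted ±Δβ for hyper-/hypomethylated genes; noise
is normal on the logit (M-value) scale with constant sd = 4·`noise_sd`.
This makes `noise_sd` the beta-scale sd at β = 0.5, with variance
shrinking toward the boundaries — the standard heteroscedastic behaviour
of beta values — and keeps every value strictly inside (0,1) with no
clip mass. Each gene has 10 CpGs by default (methylation arrays average
well above 10 probes per gene locus). The default planting (150 hyper /
75 hypo per species, of which 100 / 50 concordant, among 2,000 genes at
Δβ = 0.3, noise 0.05, 5 samples per group) keeps a roughly 2:1
hyper:hypo ratio, qualitatively matching the predominance of
hypermethylated loci in the tumors. A separate `global_delta` parameter
shifts *all* tumor CpGs (global hypomethylation); it defaults to 0 so
the planted truth table remains the complete ground truth for recovery
scoring.

# Single-cell landscape

Counts are depth-normalised to 10,000 per cell and log1p-transformed.
All cluster-level statistics work off the `cluster_profile`: mean
log-normalised expression and fraction of expressing cells per
cluster × gene.

**Five-criterion tumor classifier.** A cluster is tumor iff (i)
SMARCB1 mean ≤ the 10th percentile of cluster means, (ii–iv) CD2, EZH2
and KIT means ≥ the 60th percentile, and (v) MKI67-expressing fraction
≥ 2× the median cluster fraction. The source criteria are qualitative
("negligible", "positivity", "high proliferative activity"); the
quantile and fold thresholds are this package's documented defaults,
all configurable.

**Annotation rubrics.** Ordered rubrics assign the first matching
label. Two threshold families are used deliberately: quantile senses
(`high`/`low`) for genes whose positive cluster is extreme (the tumor
rubric), and detection-fraction senses (`expressed` ≥ 25% of cells /
`absent` ≤ 10%) for lineage markers. Interpolated quantile thresholds
are knife-edged when exactly k of n clusters are positive — the
threshold lands strictly above the smallest positive cluster mean — so
lineage rubrics (CD3E for T-cells, MS4A1/CD79A for B-cells, LYZ/CD68
for myeloid, MZB1/JCHAIN with MS4A1-absent for plasma cells) use
detection fractions, which are stable for strongly bimodal markers.

**DEGs and metaprograms.** One-vs-rest rank-sum tests per gene
(tie-corrected normal approximation; cluster sizes are far beyond the
exact-enumeration regime), retained at q < 0.05, log fold-change >
0.25, and ≥10% expressing cells in the cluster — conventional
single-cell retention thresholds, stated here because the source states
none. Metaprogram overlap reports the raw hit count k of each cluster's
DEG list against each 50-gene signature, a hypergeometric upper-tail p
with the universe N equal to the number of detected genes (the source
reports raw hit counts without naming a universe), and a per-cluster
row z-score of k across programs (computed on hit counts; whether the
reference z-scores were computed on counts or a derived statistic is
not stated).

**Functional states.** A decision ladder guarantees exactly one state
per cluster: Treg (FOXP3 high) → Tex (HAVCR2 & LAG3 high) → Tpex
(PDCD1 & TIGIT high, HAVCR2/LAG3 not high) → CTL (GZMB & PRF1 high) →
Naive-like (nothing high) → Other. "High" means strictly above the
cross-cluster median of the gene's cluster means *and* at or above an
absolute floor of 0.25 log-normalised units. The floor is essential,
not cosmetic: among k clusters, some cluster's mean is strictly above
the median with probability ~1 even for a gene nobody expresses, so a
bare median rule would hand out one false Treg call per profile. Exact
ties at the median resolve to "not high".

**Synthetic count model.** Gamma–Poisson (negative-binomial-like)
counts: per-gene baseline weights (log-normal for filler genes, low
fixed weight for marker and metaprogram genes, higher for broadly
detected ligand/receptor genes and SMARCB1), multiplied by population
marker folds, per-cell log-normal library sizes, and a per-entry gamma
factor (dispersion 0.25). The default tumor-bearing mixture has 8
populations (one tumor population at 30%, B 10%, myeloid 30%, four
T-cell states, plasma cells); the wild-type mixture has B-cells at 70%
and myeloid at 5%, and the HDACi-treated mixture partially restores
B-cells (40%) while shrinking tumor and myeloid — so the B:myeloid
ratio orders WT > treated > tumor. A single tumor population is used
deliberately: the classifier's 10th-percentile "negligible" threshold
interpolates between the two lowest cluster means, so two near-zero
SMARCB1 clusters cannot both sit at or below it — a structural property
of quantile thresholds, not of the data. Multi-tumor-cluster datasets
remain expressible through `sc_sim_params`.

# Ligand–receptor permutation test

The interaction score for a sender/receiver cluster pair is the average
of the mean ligand expression in the sender and mean receptor
expression in the receiver, computed only when both genes are detected
in >10% of the respective cells (the cited tool's convention). The
null is a cluster-label permutation over all cells, the same
permutation reused across pairs within an iteration; the one-sided p is
(1 + #{permuted ≥ observed})/(1 + n_perm), never exactly zero.
Heteromeric receptor complexes are out of scope (single-gene ligands
and receptors only).

Calibration has a subtlety worth stating: in any simulation with
population structure, *every* gene is differentially expressed across
clusters, because marker and program folds change each population's
compositional denominator. Those are true signals, so "null pairs" on
structured data do not have uniform p-values — the test is detecting
real differences. The `"null"` scenario of `sc_sim_params` therefore
generates eight clusters with identical expression profiles (the
exchangeable null), on which the permutation p-values are uniform; the
calibration tests use it.

# Screens and ROI quantification

**Viability.** Treated/vehicle replicate-mean fractions per compound
and line, floored at 1e-4 before logs (single-dose screens exceed 90%
kill; the floor keeps log2 fold changes finite). The relative efficacy
of a compound is the index line's log2 fold change minus the mean over
the reference-panel lines — translation-invariant, so uniform toxicity
cancels. Mean (not per-replicate) viabilities enter the log, matching
the screen's summary-level readout. "Active" defaults to relative
log2FC ≤ −1 (≥2-fold selective kill); the reference figure shows but
does not define "active", so the cutoff is configurable.

**ROI tables.** Per-ROI marker-positive cell counts (tumor marker
Ezh2-high, pan-B B220, neutrophil Ly6g) over 1500×1500 µm regions; the
group comparison is the exact Mann–Whitney test above, with optional
density conversion (counts per mm²; 450 cells in one ROI = 200/mm²).
Image segmentation belongs to the imaging platform and is out of scope;
the per-cell marker-call table is the input.

# Problem sizes and what the tests show

The default simulation sizes — 2,000 genes × 10 CpGs × 2 species for
methylation, 5,000 cells × 1,500 genes for single cell, 999
permutations for the interaction test, 200 replicate screens — were
chosen as the smallest sizes at which every stage's statistical
behaviour (recovery, calibration, ordering) is stably measurable.
Passing recovery tests demonstrate that the pipeline's thresholds and
rubrics correctly invert the generative model they were pointed at;
they do not certify performance on real arrays or real single-cell
data, whose batch effects, doublets, ambient RNA, platform chemistry
and cluster-boundary ambiguity the generators deliberately omit.
Known limitations: one-to-one ortholog maps only; single-gene
ligand/receptor pairs; cluster labels are trusted as given; no
embedding or trajectory inference.
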