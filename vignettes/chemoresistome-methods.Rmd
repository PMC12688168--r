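---
title: "Methods: longitudinal pattern classification and chemoresistome scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal pattern classification and chemoresistome scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoresistome)
```

## The problem and the data model

Neoadjuvant chemotherapy (systemic treatment given before surgery) offers a
rare longitudinal window on a tumor: a diagnostic biopsy before treatment, the
residual tumor at surgery, and adjacent normal epithelium from the surgical
specimen. `chemoresistome` analyzes such **matched triplets** — per patient,
one sample at each of three timepoints (`normal`, `pre`, `post`) — to ask not
*which genes differ*, but *how each gene travels* through
carcinogenesis and treatment in each individual patient, and which of those
trajectories mark adaptive resistance.

The in-memory model is deliberately plain: a genes × samples integer count
matrix, a sample table (`sample_id`, `patient_id`, `timepoint`), a patient
table (Miller–Payne response grade, subtype, recurrence-free survival), and
gene-set collections read from GMT. Gene identifiers are opaque strings; no
identifier mapping is attempted, because mapping is dataset-specific and out
of the method's scope. Gene-set members absent from the expression matrix are
silently intersected out at use time.

## The eight temporal patterns

Over three timepoints there are two transitions, each qualitatively up, down,
or unchanged: nine trajectories, of which the fully unchanged one carries no
signal, leaving **eight theoretical patterns**:

| pattern | levels (normal, pre, post) | scenario |
|---|---|---|
| P1 / P2 | (0, ±1, 0)  | reregulated: tumor change reverts after treatment |
| P3 / P4 | (0, ±1, ±1) | resistance: tumor change persists |
| P5 / P6 | (0, 0, ∓1)  | treatment effect: change appears only after treatment |
| P7 / P8 | (0, ±1, ±2) | worsening: monotone intensification |

The level triples encode the verbal shape descriptions with unit steps; they
are not canonical numbers. Because assignment uses Pearson correlation, only
the *shape* matters — any positive affine transform of a profile gets the same
pattern, and negating a profile maps each pattern to its direction partner
(P1↔P2, P3↔P4, P5↔P6, P7↔P8). The templates are exposed as data
(`theoretical_templates()`) because the correlation argmax does depend on the
relative step sizes chosen for P7/P8 (two equal unit steps here; the
amplitude is a modeling choice, not a measurement).

**Assignment.** For every (gene, patient) pair the VST triplet is correlated
with all eight templates and assigned to the argmax
(`assign_patterns()`). Numerical choices:

* a triplet with standard deviation below `1e-12` is `UNCLASSIFIED` (no
  shape information);
* exact ties on the maximal correlation are broken by the smallest Euclidean
  distance between z-scored profile and template, then by lowest pattern
  index. For three-point profiles the z-score distance is a monotone
  function of the correlation, so in practice the index rule decides; the
  distance rule is kept for transparency and for alternative template sets;
* the phrase "correlating the changes in expression" admits two readings.
  The default correlates the **levels** (3-point Pearson). A
  **differences** variant is exposed (`on = "differences"`): Pearson on a
  two-point change vector is degenerate (always ±1), so that variant uses
  the cosine of the angle between the observed and template step vectors,
  which partitions the change plane into the eight qualitative sectors.

**Cross-patient summary** (`classify_genes()`): a gene has a *main* pattern
if one pattern covers ≥ 50% of its classified patients (a strict `>` reading
is available via `strict_main`, since both readings appear in common usage);
failing that it is *bimodal* if two patterns each cover ≥ 30% of classified
patients **and** each occurs in ≥ 5 patients; otherwise *unclassified*.
Denominators always count patients with a non-`UNCLASSIFIED` assignment.

**Per-patient fractions** (`pattern_fractions()`): the fraction of each
patient's classified genes in each pattern, and the response ratio
(P1 + P2) / (P7 + P8). The denominator choice (classified DE genes, excluding
`UNCLASSIFIED`) is logged in the output; a zero dysregulated fraction yields
`Inf`, flagged rather than silently dropped.

## Normalization and the DE gene filter

The pattern analysis runs on the universe of differentially expressed genes.
Counts are normalized by **median-of-ratios size factors** and transformed by
a **shifted log** (`log2(count/factor + 1)`) as a documented stand-in for a
model-based variance-stabilizing transform: it is monotone, keeps zeros
finite, and flattens the NB mean–variance trend enough for three-point shape
comparison (the tests verify the slope reduction). Reproducing a dispersion-
trend VST numerically is a non-goal.

The filter (`de_filter()`) pairs samples **within patient** on VST
differences — pairing absorbs the patient effect exactly as a patient
covariate would in a count model, which keeps the stand-in dependency-free;
the paired test is pluggable (t-test default, Wilcoxon signed-rank option).
Per contrast (pre vs normal, post vs normal, post vs pre), p-values are BH
adjusted, and a gene is retained if in **any** contrast
|fold change| > 2 (strict), adjusted p ≤ 0.05 (inclusive), and its largest
raw count anywhere is ≥ 100. Fold change is `2^|mean VST difference|`; no
shrinkage, outlier trimming, or independent filtering is applied. Thresholds
are flags (`--fc-threshold`, `--alpha`, `--min-count` equivalents as
function arguments), defaulting to 2 / 0.05 / 100.

## Response association

* **Persistent resistance genes** (`persistent_resistance_genes()`): a gene
  qualifies when the classified-patient share of P3 alone, P3+P7, P4 alone,
  or P4+P8 **exceeds** 50%.
* **Bimodal gene screen** (`wilcoxon_response()`): per gene and per direction
  cluster (up: P1 vs P3/P7; down: P2 vs P4/P8), a two-sided rank-sum test
  compares Miller–Payne grades of patients where the gene reregulated vs
  persisted. Patients whose assignment is P5/P6 or `UNCLASSIFIED` carry no
  information for that contrast and are dropped from that gene's test.
  MP grades are heavily tied, so for combined n ≤ 20 the p-value is computed
  **exactly by enumerating all group-label assignments on midranks** (exact
  under ties, unlike classical no-tie tables); larger samples use the normal
  approximation with tie and continuity correction. Selection uses **raw**
  p < 0.05 — this is a screen, not a confirmatory test — with BH-adjusted
  values emitted alongside for transparency. A subtype filter reruns the
  screen on a patient subset (e.g. HR+ only).
* **Ratio ANOVA** (`ratio_anova()`): one-way ANOVA of the response ratio
  across MP groups. The grouping is configurable; the default
  `{1}, {2}, {3–5}` splits the grades observed in partial responders into
  three groups of comparable size. Infinite ratios are excluded by default
  (undefined on the real line; `cap` substitutes the largest finite ratio).
* **Survival** (`km_logrank()`): Kaplan–Meier curves and the two-group
  log-rank test for the dichotomy ratio > 5 vs ≤ 5 (cutoff configurable).
  Infinite ratios fall in the high stratum: they indicate maximal
  reregulation, which is exactly what the high stratum means.

## Enrichment, resistance scores, and the bootstrap null

**Over-representation** (`hypergeom_enrich()`) is an upper-tail
hypergeometric test per pathway, run separately per pattern cluster
(P1_P3_P7 and P2_P4_P8 hit lists), with BH q-values within a run. The
universe is the DE gene list — the natural background for hits that were
themselves drawn from it; it is an argument, not a constant. The **robust
pathway list** (`robust_pathway_list()`) intersects the significant pathways
of the full-cohort and subtype-restricted runs, then adds the top 5 most
significant pathways unique to each run (by q, ties by p). Any further
curation for functional redundancy is a judgement call and is accepted as a
user-supplied subset, never automated. The same holds for grouping pathways
into functional modules for display: a user-supplied mapping.

**Resistance score** (`resistance_scores()`): per patient and pathway, the
fraction of **resistance-pattern genes** (P3/P4/P7/P8) among the pathway's
*considered* genes — DE genes with an assigned pattern in that patient;
P1/P2 genes count as reregulated. Its p-value is the fraction of `n_boot`
(default 10 000) random same-size gene sets from the patient's considered
universe whose score is ≥ the observed score. Implementation note: a random
set's score depends on the draw only through its count of resistance genes,
so the count is drawn directly from the corresponding hypergeometric
distribution (binomial under the with-replacement option) —
distributionally identical to resampling gene sets, and orders of magnitude
faster. No pseudocount is added, so p = 0 is representable at resolution
1/`n_boot`, exactly as the defining formula states; human-readable output
should render it as "< 1/n_boot".

Because the p-value uses "≥ observed" on a discrete score, it is
conservative for small pathways: the null expectation of p is
(1 + P(tie))/2. This is a property of the formula, not a defect of the
resampler; the calibration test therefore checks approximate uniformity in a
large-set regime where the discreteness is second-order, and exactness
against full enumeration in a 12-gene universe.

## Pathway deregulation score (PDS)

`compute_pds()` is a documented **simplification** of the published
principal-curve deregulation algorithm: per pathway, genes are standardized
by the normal samples' mean and SD, samples are reduced by PCA to the
components explaining ≥ 90% of variance (cap 5 — both invented defaults,
exposed as arguments), and a principal curve is fitted through **all**
samples by a simplified Hastie–Stuetzle iteration (initialize at PC1;
alternate projection onto the current polyline and lowess smoothing of each
coordinate against arc length; stop when the mean squared projection
distance changes < 1e-6 or at 100 iterations). A sample's deviation is the
absolute arc-length distance of its projection from the normal samples'
median position. Two normalization choices:

* the normals' own typical spread along the curve (their upper median
  deviation) is subtracted and negatives are clipped, so the **median normal
  sample scores exactly 0** — the score reads as "deviation beyond normal
  variability" rather than raw spread (the upper median, rather than the
  interpolated one, makes the zero exact for even normal counts too);
* scores are divided by their per-pathway maximum, giving PDS ∈ [0, 1].

Distance is measured **along the curve**, an explicit interpretation of
"distance from the sample's projection to the normals' projection". The
published algorithm's gene filtering and curve-stability heuristics are
omitted; outputs are to be read as the simplified variant's.

## The synthetic cohort generator

`generate_cohort()` states a world in which every downstream claim is
checkable; defaults are chosen once, from the study design the pipeline
targets, and not revisited:

* **24 patients** × complete triplets (the scale of a single-center
  neoadjuvant cohort with complete triplet data), 2 000 genes;
* **negative-binomial counts** (`variance = mu + phi mu^2`, `phi = 0.05`, a
  typical bulk RNA-seq dispersion) around pattern-defined log2 means:
  per-gene baseline log2 mean uniform in (5, 10), plus
  `effect_size` × template level, `effect_size = 2` (a 4-fold step, the
  scale of clear DE calls); `phi = 0` degenerates to Poisson;
* **library sizes** log-uniform in (0.5, 2), so the normalization stage is
  exercised nontrivially;
* each gene draws a **base pattern** (60% FLAT — true negatives for the DE
  filter; FLAT is deliberately *not* one of the eight patterns, which
  describe differentially expressed genes); P1/P2 base genes flip to their
  persistent counterparts P3/P4 per patient with a patient-specific
  probability uniform in (0.1, 0.9) — this single mechanism creates bimodal
  genes, inter-patient heterogeneity, and a per-patient planted
  dysregulated fraction;
* **Miller–Payne grades** decrease stochastically with that fraction
  (`mp_coupling` scales the noise; 0 decouples them for null calibration),
  truncated to 1–4 — grade 5 means complete response, which leaves no
  residual tumor to profile; recurrence hazard rises with the same fraction;
* **gene sets**: `n_pathways` sets sized uniformly in (10, 30); designated
  resistant pathways draw ≥ 70% of their members from resistance hubs
  (genes dysregulated in a majority of patients), the rest are uniform
  draws.

What the generator does **not** emulate: stromal/immune admixture, spatial
heterogeneity, single-cell structure, gene–gene correlation, or realistic
effect-size distributions (the last is unknown for real pattern genes and is
exposed as configuration, not asserted as realistic). A green test therefore
establishes that the pipeline recovers what it is told was planted under NB
noise — not that the biology of any real cohort satisfies these defaults.

Determinism: the full cohort derives from a single seed; identical
configurations are byte-identical.

## Interfaces

The package's functions, the orchestrator `run_pipeline()` (which writes
every stage output as a plain table plus a JSON manifest with parameters,
per-stage row counts and file checksums), and `render_reports()` (stacked
pattern fractions, balloon plot, circular per-patient chemoresistome maps,
PDS heatmap — each with a 1:1 companion data table; p-value color bands
{<0.01, <0.05, <0.1, ≥0.1}) are the interface; `scripts/acceptance.R` is a
thin command-line wrapper over them. Formats: TSV, MatrixMarket with index
files, GMT, JSON.

## Known limitations

* The shifted-log transform is a stand-in; very low counts retain some
  mean–variance dependence, and the scale-invariance of the DE filter is
  exact only up to pseudocount effects at such counts.
* Exact rank-sum enumeration is quadratic-ish in `choose(n, n1)`; above
  combined n = 20 the normal approximation takes over.
* The principal curve is fitted on sample projections without stability
  selection; very small pathways (3–5 usable genes) give noisy curves.
* The bootstrap p-value is conservative for small pathways (discreteness),
  and `p = 0` means "below 1/n_boot", not zero.
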