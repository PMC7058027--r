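---
title: "Quantifying astrocyte subtypes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying astrocyte subtypes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`astromap` implements three quantification pipelines used to characterize
astrocyte heterogeneity across the adult mouse cortex (CX) and hippocampus
(HP), together with a synthetic-data generator that plants ground truth for
every stage:

1. **Single-cell pipeline** — count-matrix QC, ln-normalization,
   highly-variable-gene (HVG) selection, hierarchical clustering with
   silhouette-selected cluster number, higher-order cell typing, astrocyte
   re-clustering and marker-gene calling.
2. **ISH quantification** — cell boundaries around DAPI nuclei, puncta
   counting per probe channel, "+"/"−" marker calls, ordered rule-based
   subtype classification, regional distributions and a
   fluorescence-threshold robustness sweep.
3. **Calcium transient analysis** — dF/F₀ computation, peak detection
   under four thresholds, per-cell parameterization, PHE-responder
   filtering, physiology clustering, and nonparametric group comparisons
   (Shapiro–Wilk gate, Kruskal–Wallis, Dunn's post-hoc, Benjamini–Hochberg).

The pipeline starts at a count matrix; read alignment and counting, gene-set
enrichment, tSNE embeddings and atlas registration are out of scope.

# Single-cell model and parameters

**QC floor.** Cells are kept when their total transcript count is at least
`minTotal = 54`; the floor is read as the minimal acceptable value, so a
cell with exactly 54 transcripts survives.

**Normalization.** `lnNormalize()` computes
`ln(1 + scaleFactor * count / total)` with `scaleFactor = 1e4` (natural
log). The transform is zero-preserving, monotone in the count at fixed
library size, and invariant to rescaling a cell's counts.

**HVG selection.** Per gene, the ln-mean and the dispersion
(variance/mean of the ln-normalized values) are computed; a gene is
selected when it strictly exceeds both thresholds. The all-cell pass uses
(0.3, 0.1); the astrocyte pass uses (0.5, 0.5). "Variance/mean" is
interpreted on the ln scale, which reproduces the documented behaviour of
a marker with ln-mean 0.28 and dispersion 0.41 falling below the
astrocyte-pass cut. Constant and silent genes have dispersion 0 by
definition and are never selected.

**Clustering.** The exact legacy clustering default behind the original
analysis is era-specific and not recoverable, so the package defines a
deterministic pipeline and validates it by planted-structure recovery:
per-gene z-scaling of the HVG submatrix, PCA to `nPcs = 20` components,
Ward (`ward.D2`) agglomeration on Euclidean distances, and the cluster
number chosen as the arg-max of the mean silhouette width over
`k = 2..kMax` (`kMax = 10`), ties toward smaller k. When the best mean
silhouette falls below 0.15 the result carries a `noSubstructure` flag;
the floor is arbitrary, logged and configurable.

**Marker criteria.** For a cluster versus the rest, each gene is tested
with a two-sided Wilcoxon rank-sum test on ln values; the fold change is
the ratio of de-logged means (ε = 1e-9 regularized), i.e. "1.28-fold" is
linear-scale; percent expressing is the fraction of cluster cells with a
nonzero count. A marker passes when p < 0.01, fold ≥ 1.28 and percent
expressing > 0.25. `wilcox.test()` uses the exact distribution for small
tie-free samples and the tie-corrected normal approximation otherwise; on
a 20-cell toy the p value matches an exhaustive permutation oracle.

# ISH model and parameters

Cell boundaries are disks centred on nucleus centroids with area
`areaScale = 1.3` times the DAPI area (the published average relative
size); the original polygons are not further specified, so disks are the
minimal faithful shape. A punctum is counted for a cell when its
intensity strictly exceeds the background threshold and it lies inside
the disk; puncta inside overlapping disks go to the nearest centroid,
exact ties to the lowest cell id (documented, configurable behaviour the
source leaves open). Marker calls use per-gene count thresholds
`thetaHi = 5` ("+" at or above) and `thetaLo = 2` ("−" at or below), with
an indeterminate band between; the source gives only qualitative "+"/"−"
classes, so these defaults are covered by the robustness sweep rather
than asserted as ground truth.

Classification evaluates the rule table in a fixed order — AST4 (Frzb+,
Ascl1+, Slc1a3+), AST5 (Ogt−, Fam107a+, Slc1a3+), AST1 (Gfap+, Agt+,
Slc1a3+), AST2 (Agt−, Unc13c+, Slc1a3+), AST3 (Agt+, Slc1a3+ with Gfap−
in panel A or Unc13c− in panel B) — specific progenitor rules before the
broad mature rules, first satisfied rule wins. Astrocytes are gated on a
"+" Slc1a3 call. The AST3 split clause mirrors the three-channel limit of
the original stainings; the synthetic full panel may satisfy either
alternative. Regional distributions report mean counts per section, SEM
across sections (0 with a flag for a single section), and fractions
normalized to all Slc1a3+ cells of the region.

# Calcium model and parameters

dF/F₀ uses F₀ = mean fluorescence over the first 100 s of each recording.
Transients are strict local maxima with dF/F₀ > 1.15, topographic
prominence ≥ 0.1, width at half prominence ≥ 2 s (linear-interpolated
crossings), and ≥ 1 s separation; among closer survivors the taller peak
wins (greedy by descending amplitude — the source does not state which of
two close peaks survives). Width is enforced at half prominence because
that is the width the analysis reports; series endpoints are excluded
(prominence undefined there). Per cell and condition the summary holds
mean amplitude, prominence, width and peak time, frequency
(peaks/duration) and the trapezoidal AUC over the whole window including
negative excursions.

Only cells with at least one PHE transient are retained; BASE/TTX
analyses additionally require activity in that condition, and the
fraction of PHE responders active under BASE/TTX is reported. Physiology
clustering z-scales the six parameters (mean peak time is retained as a
feature because it is one of the measured parameters; a flag can exclude
it) and selects k by mean silhouette under Ward agglomeration with
`kMax = 8`, pure arg-max (the original adds visual inspection, which is
not automatable). Group comparisons always proceed nonparametrically;
Shapiro–Wilk p values are recorded as a gate, not branched on. Dunn's
post-hoc uses pooled average ranks with tie correction and two-sided
normal p values, BH-adjusted within the pairwise family of one parameter.

# The synthetic-data generator

The generator defines the study conditions the tests and the acceptance
script run under; its defaults are fixed, not tuning knobs.

**Expression.** 2031 libraries = 1811 astrocytes + 204 contaminants
(oligodendrocytes 60, OPC 30, microglia 50, endothelial 30, neurons 34)
+ 16 low-quality libraries thinned below the 54-transcript floor. The
astrocyte/contaminant/low-quality composition is planted as exact counts
so QC and typing round-trip deterministically; subtype labels are drawn
multinomially at AST1 0.365, AST2 0.25, AST3 0.30, AST4 0.071, AST5 0.014
— the two extremes are published values, the middle three are
unpublished fills documented as such. Counts are negative-binomial with
per-level (high/low/housekeeping) mean and size rather than per-gene
parameters, for tractability. Of 3000 genes, exactly 886 are planted
above both astrocyte-pass HVG thresholds: each planted gene is "high" in
a subtype combination covering 25–74% of astrocytes, which puts its
expected ln-mean and dispersion at least 20% above the (0.5, 0.5)
thresholds, while every other gene fails at least one threshold by a
comparable margin — so the selected count equals the planted count
rather than fluctuating around it. Markers private to the rare subtypes
(Frzb, Ascl1, Fam107a) deliberately fail the ln-mean threshold, as a real
rare-subtype marker would.

**ISH sections.** The default layout stacks five cortical layers and six
hippocampal strata as non-overlapping rectangles with per-region subtype
frequencies following the published maps qualitatively (AST4 dominant in
the subgranular zone, AST1 subpially and in stratum
lacunosum-moleculare). Puncta counts are Poisson with mean 12 for "+"
markers and 0.3 for "−" markers, placed uniformly inside the cell disk;
background puncta arrive at 1e-4 per µm² with intensities N(60, 15)
versus N(150, 20) for true signal, so the default intensity threshold of
100 separates them. `ishLayoutUniform()` provides a single-region layout
for population-level draws at the global subtype profile.

**Calcium traces.** Each condition is 300 s at 2 Hz with F₀ = 100 and
Gaussian noise SD 0.02·F₀. Events have instant rise and exponential
decay; onsets are uniform subject to a refractory gap of ~2.5 decay
constants, which keeps events from piling on each other's decaying
shoulder, and the first 100 s of each recording are event-free so the
baseline is well defined. Cell-level random effects (8% SD on amplitude,
decay and rate) give continuous within-regime parameter spreads. The
three PHE regimes are separated along complementary axes — rate
0.035/0.055/0.085 events/s, amplitude 1.5/3.5/6.0 dF/F₀, decay
3.5/6.0/4.5 s, onset latency 0/30/60 s for L1 / L3–5 / CA1 — so
neighbouring regimes sit several within-regime SDs apart in the z-scaled
feature space, the regime the silhouette selection is asked to recover.
A planted 20% of cells are PHE non-responders (zero PHE events). BASE
and TTX rates are low (TTX below BASE, reflecting removal of neuronal
drive), so condition activity fractions are non-trivial.

**What the generator does not emulate.** Dropout bursts and batch
effects in counts, segmentation errors and intensity gradients in
sections, drift, bleaching and movement artefacts in traces, and any
rostro-caudal structure. Passing tests show the procedures recover
planted structure under the stated noise models, not that they are
robust to these real-data pathologies.

# Numerical choices and degenerate inputs

Average ranks resolve ties in every rank-based procedure. Silhouette
selection breaks ties toward smaller k and skips infeasible k. Constant
parameter columns are dropped (with a warning) before physiology
clustering; constant vectors make the Shapiro–Wilk W undefined and are
reported as non-normal with a warning. Zero-total cells are a hard error
in normalization, directing the user to the QC step. Groups with fewer
than two observations skip their comparison with a warning. An
indeterminate marker call fails any rule requirement on that gene. Region
membership of a cell is decided by its nucleus centroid; cells outside
every region polygon are excluded from regional summaries. The
polygon-overlap screen tests vertices and centroids, which covers the
rectangular atlas-style layouts used here.

The rank-sum/BH machinery delegates to `stats::kruskal.test`,
`stats::shapiro.test` and `stats::p.adjust`; Dunn's test is implemented
in the package. Note that BH re-adjustment is not idempotent in general
(the step-up transform of an already adjusted sequence can only inflate
it); the package therefore asserts the defining properties — adjusted
values never below raw values, monotone in rank order, capped at 1 —
rather than idempotence.

# Problem sizes

The default simulated conditions (2031 cells × 3000 genes; 1811-nucleus
sections; 614 three-condition recordings of 600 samples) run the full
pipelines in about two minutes on a single core; the test suite uses
scaled-down configurations (≈160 cells, 400 genes, ≈45 recordings) for
unit-level checks and the full defaults only for the end-to-end
round-trip tests.

# Known limitations

- The clustering pipeline is a deterministic stand-in validated by
  synthetic recovery, not a re-implementation of any specific legacy
  tool version.
- Marker call thresholds (5/2 puncta) and the ISH intensity threshold
  are design defaults; conclusions about a real section should always be
  read together with `thresholdSweep()` output.
- The subtype fingerprint table is completed beyond the published
  rule-relevant entries to be classifier-consistent; the fills are
  synthetic conventions, not measurements.
- Silhouette arg-max can be short-sighted on real data with nested or
  elongated clusters; inspect `silhouetteByK()` rather than trusting k
  blindly.
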