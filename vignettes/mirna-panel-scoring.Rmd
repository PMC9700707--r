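---
title: "Consensus scoring of miRNAs against a gene panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus scoring of miRNAs against a gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirScore)
```

## The model

A miRNA that simultaneously represses several genes of a disease panel is
a candidate multi-target therapeutic. Evidence for individual
miRNA–target interactions comes from two resource classes: curated
databases of experimentally supported interactions, and sequence- or
thermodynamics-based prediction tools. Neither class suffices alone —
validated databases are sparse, prediction tools are false-positive
prone — so the package scores their consensus.

Let the panel have $G$ genes and the prediction-tool registry $D$ tools.
For miRNA $m$,

$$
V_m = \#\{\,g \in \text{panel} : (m,g)\ \text{validated}\,\},
\qquad
P_m = \sum_{g \in \text{panel}} d_{mg},
$$

where $d_{mg} \in [0, D]$ is the number of distinct tools predicting the
pair, and the combined score is

$$
C_m = \frac{P_m}{D\,G} + \frac{V_m}{G} \in [0, 2].
$$

The validated flag is a union: a gene counts once in $V_m$ however many
validated databases confirm it. Both normalizers use the *panel size*
$G$, not the number of genes the miRNA happens to hit; each term is then
a fraction of the attainable maximum and the bound $C = 2$ is reached
exactly at full evidence. (Under the per-miRNA reading, any miRNA with
only validated evidence would score $C \ge 1$ regardless of coverage,
which contradicts the published two-decimal scores this convention
reproduces; see below.)

Two conventions matter downstream:

* **Reporting versus ranking.** C-Scores are conventionally printed at 2
  decimals, but ranking uses full precision, with ties broken by higher
  $V$, then higher $P$, then lexicographic identifier — a total order, so
  ranks are a deterministic permutation.
* **Multi-target filter.** miRNAs with evidence (validated *or*
  predicted) on fewer than `min_target_genes` distinct panel genes are
  dropped before ranking; the default 2 encodes the "more than one gene"
  selection that motivates multi-target candidates. The filter uses the
  union of evidence kinds; at threshold 2 this coincides with filtering
  within each class separately for every bundled table.

```{r scores}
ev <- atheroEvidence()
head(as.data.frame(scoreMirnas(ev))[,
  c("rank", "mirna", "v_score", "p_score", "c_score_reported")])
```

### Inverting rounded scores

Published C-Scores are rounded; with a known $V$ the formula can be
inverted to the *set* of integer P-Scores consistent with a printed
value. The set typically has more than one element — e.g. both 22 and 23
yield a 2-dp C-Score of 0.68 at $V = 4$ — so `invertCScore()` returns
all candidates, and any claim depending on an unpublished P-Score should
be checked over the whole set:

```{r invert}
invertCScore(0.68, v = 4)
invertCScore(0.62, v = 3)
```

## Identifier handling

miRNA identifiers are matched case-insensitively; the arm suffix
(`-3p`/`-5p`) distinguishes mature miRNAs and is preserved, as is the
species prefix. Gene symbols are uppercased and passed through an alias
map (default: `APOCIII -> APOC3`, since both spellings circulate for
apolipoprotein C-III). The alias map is this package's mechanism for
reconciling symbols across databases — different resources disagree, and
no standard reconciliation is prescribed — so users with richer alias
needs supply their own map. Off-panel genes in an export are retained
with an `on_panel = FALSE` flag rather than dropped, so one export can be
re-scored against another panel.

The tool registry is deliberately user-supplied configuration (default
size $D = 30$): published prioritizations rarely enumerate their tools in
the main text, and $D$ is always taken from the registry rather than
hard-coded, so partial registries score consistently.

## PPI edge lists

STRING-style exports attach a combined confidence score to each
undirected protein pair, printed either in $[0,1]$ or as integers in
$[0,1000]$; if any raw score exceeds 1, the whole column is divided by
1000. Self-loops are dropped, duplicate orientations collapse to one
edge keeping the maximum score, and tier filtering keeps edges at or
above 0.15 (lowest), 0.4 (medium), 0.7 (high) or 0.9 (highest) — the
conventional STRING cutoffs; "lowest" is the conventional low-confidence
default since only "below 0.4" is implied by the tier above it. Edge
counts are therefore non-increasing across rising tiers.

Published node/edge counts for a live database query depend on the
database version and are not reproducible offline; the shipped
`ppi_edges_synthetic.tsv` is a constructed 7-node edge list whose tier
profile (8 / 14 / 20 edges at highest / high / medium) demonstrates the
filtering on a realistic shape without asserting anything about the
external database.

```{r ppi}
e <- readEdgeList(system.file("extdata", "ppi_edges_synthetic.tsv",
                              package = "mirScore"))
tierProfile(e)
```

## Relative expression and viability

`ddctFoldChange()` implements the standard relative-quantification
chain: technical replicates are averaged to one Ct per (sample, assay)
(arithmetic mean, no outlier rejection); per biological replicate
$\Delta Ct = Ct_{\text{target}} - Ct_{\text{reference}}$ (GAPDH for
mRNA, SNORD47 for miRNA assays); $\Delta\Delta Ct$ subtracts the control
group's mean $\Delta Ct$; and the fold change is $2^{-\Delta\Delta Ct}$.
The reported mean and SD are taken across biological replicates *on the
fold scale*, matching how "fold change ± SD relative to control" is
conventionally reported; significance, however, is assessed on the
$\Delta Ct$ scale (approximately normal, where ANOVA assumptions hold)
by one-way ANOVA with Tukey HSD contrasts against the control, annotated
`*` ($p<0.05$) / `**` ($p<0.01$). Normality is checked with the
Lilliefors-corrected Kolmogorov–Smirnov test (the correct form when the
normal's parameters are estimated from the sample); the correction is
undefined below $n = 5$, so smaller samples raise an insufficient-data
error. With fewer than two biological replicates the SD is undefined and
flagged rather than silently zero. Amplification-efficiency correction
(Pfaffl-style) is out of scope.

MTT viability subtracts the 630 nm reference absorbance from the 570 nm
reading per well and reports the mean treated signal as a percentage of
the mean control signal at the same timepoint; wells with negative
background-corrected signal are flagged, and a non-positive control mean
is a normalization error rather than a silent division.

## What the generators emulate

The synthetic generators exist because prioritization inputs (database
exports) and wet-lab measurements (Ct tables, MTT plates) are rarely
redistributable; every generator plants a known truth and is
deterministic under its seed.

* `generateEvidenceExports()` realizes a planted truth — per-miRNA
  validated gene sets and per-gene tool counts — as exactly the file set
  the readers consume. Tool subsets are drawn without replacement; which
  tools are chosen cannot affect any score, only the counts do. The
  default miRNA pool reuses the bundled candidate ids so fixtures look
  like real output.
* `generateCtTable()` shifts the treated target Ct by $-\log_2(\text{fold})$
  around realistic baselines (reference ≈ 18, targets ≈ 24 cycles) with
  Gaussian cycle noise (default SD 0.1, a typical qPCR technical
  spread), 3 biological × 3 technical replicates by default — the usual
  triplicate design. At zero noise the pipeline recovers planted folds
  exactly; at SD 0.1 the median recovery error across seeds stays below
  10% of the planted fold.
* `generateViabilityPlate()` puts a baseline at 630 nm and a signal
  proportional to the planted viability fraction on top at 570 nm, six
  wells per condition, 2% well-to-well noise.

What passing these tests does *not* show: real exports have messier
symbol vocabularies than the alias map covers; real Ct noise is not
exactly Gaussian and can be heteroscedastic near detection limits; real
plates have edge effects and blank drift. The generators validate the
arithmetic and the plumbing, not those biological and instrumental
artifacts.

## Numerical and design choices

* Scores are integer-exact by construction; the only floating-point
  quantity is the C-Score, computed at full precision and rounded only
  in the `c_score_reported` column.
* A miRNA present in only one evidence class still receives a C-Score
  (the other term is 0); absent miRNAs score 0 rather than erroring.
* Pipeline outputs serialize non-integer numbers at fixed 6-decimal
  precision so reruns with the same configuration and seed are
  byte-identical; the long-format evidence TSV round-trips the matrix
  bit-identically, including the registry recorded in its header.
* Problem sizes in the test suite (e.g. 100 seeded export round trips,
  200-seed fold-recovery sweeps, 1000-replicate null calibration) were
  chosen as the smallest sizes at which the stochastic properties are
  stable across reruns.

## Limitations

The package scores whatever evidence it is given; it does not query
TarBase, miRTarBase, STRING or any prediction server, and it cannot
detect staleness or bias in an export. The C-Score weights every tool
and every validated database equally — there is no reliability
weighting — and the evidence matrix is binary/count-valued, ignoring
interaction strength or context. PPI enrichment p-values, pathway
analysis and sequence-level duplex thermodynamics are out of scope.
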