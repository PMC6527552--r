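---
title: "perturbtopics: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perturbtopics: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbtopics)
```

# The problem

Pooled single-cell CRISPR screens read out the transcriptome of thousands
of cells, each carrying one guide RNA against one gene (or a non-targeting
control guide). Two features make naive differential expression misleading
here. First, the readout is sparse and noisy, and perturbations are
captured by wildly different cell numbers, so effect estimates must be put
on a common footing. Second, editing is imperfect: roughly 20–30% of
guide-carrying cells show a wild-type phenotype, and those "escapers"
dilute every downstream contrast if left in place.

`perturbtopics` addresses both with a fixed pipeline: screen-specific
filtering, a topic-model representation of cells, and bootstrap t-statistic
scores that rank perturbations overall, per functional topic, and between
experimental conditions.

# Filtering

**Cell QC.** Cells pass if genes detected ≥ `min_genes` (default 500),
total UMIs ≥ `min_umi` (default 1000), and the fraction of mitochondrial
genes among *detected* genes ≤ `max_mito_fraction` (default 0.10). We read
the mitochondrial criterion literally as a detected-gene-count fraction,
not a UMI fraction, and recognise mitochondrial genes by the id prefix
`"MT-"` (case-insensitive, configurable) since no recognition rule is
otherwise implied by the data.

**Imputation.** The pipeline treats imputation as a pluggable step:
`impute(ds, "none")` passes raw counts through, and any external imputer's
output matrix can be supplied upstream. The built-in `"shrink"` method is a
deliberately simple stand-in — per gene, zeros are replaced by
`lambda` × the mean over non-zero cells (`lambda` = 0.1) — which preserves
all observed values and only softens the zero mass. It makes no claim to
recover true expression; serious analyses should plug in a dedicated
scRNA-seq imputation tool.

**Escaper filter.** For each perturbation we find genes that differ from
controls by a two-sample Kolmogorov–Smirnov test at raw p < 0.05 (no
multiplicity correction: the list feeds a similarity computation, not an
inference), then compare every perturbed cell's DE-gene profile by cosine
similarity with its same-label peers (median `M_P`) and with the controls
(median `M_C`). A cell is removed iff `M_C > M_P`, strictly, so ties retain
the cell. Controls are never filtered by this step — they define the
reference, and removing them would bias every later contrast. Cells whose
DE vector has zero norm are given similarity 0 to everything. If removals
reach `drop_fraction` (default 0.90) of a perturbation's cells the whole
perturbation is dropped. The KS test is run on the post-imputation matrix,
matching the pipeline's stage order.

A structural caveat worth knowing: the filter's reference for "looks like
an edited cell" is the perturbation's own cell population. Its per-cell
sensitivity is high when most peers are edited (the benchmark below
measures ~84% at 25% escapers), but it degrades as the escaper share grows
— with, say, 95% escapers, the peer population is itself essentially
wild-type, `M_P` and `M_C` estimate the same quantity, and the decision
approaches a coin flip. The 90% drop rule therefore fires reliably only
for perturbations whose cells are heterogeneous *and* control-like, not
for arbitrarily escaper-saturated ones. This is a property of the method,
not of the implementation.

**Minimum cells.** Perturbations with fewer than `min_cells` (default 30)
remaining cells are discarded — below that a perturbation phenotype is not
reliably captured. The control population must itself satisfy the
threshold; if it does not, the run stops rather than proceed with an
untrustworthy reference.

# Features and the topic model

**DDE genes.** Per-gene dispersion is `D = ln(variance/mean)` (natural
log; genes with zero mean or variance are unusable). Genes are binned into
`n_bins` = 20 equal-frequency bins by mean expression, and D is z-scored
within each bin with the sample SD (n − 1); a zero-SD bin contributes
z = 0. The selection statistic is `DD = |ZD_case − ZD_control|`, with
binning done independently in the pooled perturbed cells and the controls,
and the top `n_dde` = 500 genes are kept (ties broken by gene id so runs
are reproducible). The z-scoring-of-dispersion reading is the only one
that makes the statistic a z-score of dispersion, which is what the
binning is for; and 20 bins / 500 genes are conventional values for
dispersion-based gene selection — neither is critical.

**Normalization.** Selected genes are transformed by
`round((X − μ_ctrl)/μ_ctrl × 10)` with rounding half away from zero.
The topic model needs non-negative word counts, so negative values
(down-regulation) are clipped to 0 and the clipped fraction is logged.
Down-regulation signal is thereby discarded; encoding it as separate
"down" pseudo-genes would be a possible extension, noted but not
implemented.

**LDA.** The collapsed Gibbs sampler assigns each expression token to one
of `n` topics; after the final sweep, θ (cells × topics) and φ
(topics × genes) come from the standard smoothed estimators. Defaults
follow common LDA practice: α = 50/n, β = 0.1, 1000 sweeps with 500
burn-in. Estimates use the final sweep's counts so a run is exactly
reproducible from its seed; averaging over post-burn-in sweeps is
available via `average = TRUE` (slightly smoother, no longer a single
identifiable sample). Control cells are part of the corpus: topics are
learned on the entire screen so that perturbed and control cells live in
the same topic space. All-zero cells carry no tokens and are dropped with
a warning.

**Topic number.** For each candidate n, the specificity score
`SS = ln(mean_j var_j/mean_j²)` (the mean squared coefficient of variation
of topic occupancy — large when topics differ strongly between cells) and
the purity score `PS = ln(mean_i var_i)` (large when each cell is
dominated by few topics) are combined as
`CS = alpha_cs·norm(SS) + (1 − alpha_cs)·norm(PS)`, `alpha_cs` = 0.5, where
`norm` is min–max over the candidate set — the two scores live on
different scales, and min–max is the minimal normalization that makes a
weighted average meaningful. Ties go to the smaller n (the more
parsimonious model). SS and PS are computed over all cells; a
per-perturbation-mean variant would weight rare perturbations up, and can
be obtained by averaging θ rows per label before scoring. Scores are
floored at ε = 1e-12 inside the log to keep degenerate θ finite. The
default candidate range 4:6 reflects the practical regime for screens with
a handful of biological programs; the validation suite scans 2:6.

**Annotation.** Per topic, the top `ceil(0.10 × G)` genes by φ are tested
for over-representation in each user-supplied gene set (GMT) by the
hypergeometric tail against the model's gene universe, BH-corrected within
the topic, top 5 terms reported. Using a local GMT keeps the step
deterministic and offline; any ontology export can be supplied.

# Effect statistics

θ columns are z-normalized against the control mean and SD (ε-guarded if a
control column is constant). For perturbation i and topic j:

- `TPD_ij`: median over `n_boot` = 1000 bootstrap draws of the pooled
  two-sample t statistic comparing M sampled cells of perturbation i
  against **all** control cells. M is the minimal cell count over
  perturbations, so every perturbation enters the statistic with the same
  case-side sample size regardless of capture depth. Draws are without
  replacement (subsampling); a perturbation with exactly M cells yields
  identical draws, and the median degenerates to the single t value. The
  control side is the full control population: the case side is already
  equalised at M, and discarding control cells would only lose precision.
- `TPD_random,j`: the same scheme with the case side drawn from the
  controls themselves; the median null t per topic.
- `TPDA = TPD − TPD_random` (row-wise); `TPDS_i = Σ_j |TPDA_ij|` is the
  overall score, also reported max-normalized for cross-run comparison.
- `TPDR_ij = |TPD_ij| / Σ_j' |TPD_ij'|`: the share of perturbation i's
  absolute effect on topic j. The summation runs over topics — the
  statistic measures how concentrated a perturbation's effect is, so the
  denominator must aggregate that perturbation's own topics; summing over
  perturbations (available via `sum_over = "perturbations"`) would instead
  measure dominance of a topic between perturbations.
- `CS_ij = ½(minmax_j |TPD_ij| + minmax_j TPDR_ij)`, min–max over topics
  within the perturbation's row; a degenerate extent contributes 0. The
  significance threshold per topic is the median CS over 1000 null
  repetitions (each: one M-cell control draw, its t statistics, its CS
  row).
- Perturbation relationships: Pearson r of TPDA rows; zero-variance rows
  give NA, flagged.
- `PID_i` (two conditions): the ratio of perturbation i's share of total
  TPDS in condition 2 to its share in condition 1, over the common
  perturbations; zero condition-1 TPDS gives Inf, flagged.

**Randomness discipline.** Every bootstrap stream is seeded from the
master seed plus a hash of the perturbation label (one stream per
perturbation, the same M-cell draws evaluated on every topic), and draws
index cells by sorted cell id. Results are therefore bitwise reproducible
and independent of cell order, gene order, and the order in which
perturbations are iterated. Reusing one cell draw across topics is the
natural bootstrap — a resample of cells is a resample of their whole topic
vectors — and halves the stream bookkeeping.

**Robustness check.** `robustness_test()` relabels a random 20% of control
cells as a pseudo-perturbation, reruns the ranking against the remaining
80%, and reports the mean fraction of real perturbations ranking below the
pseudo-perturbation and the mean Pearson correlation of normalized TPDS
with the unrelabeled run.

# The synthetic-screen generator

`simulate_screen()` mirrors the generative assumptions of the topic model
so every stage can be validated against planted truth: topic gene loadings
are symmetric Dirichlet(0.1) draws over genes (small concentration gives
well-separated programs); control cells draw topic proportions from
Dirichlet(`dirichlet_base`, default 1 per topic); an edited cell for
perturbation k adds its effect size to the assigned topic's concentration;
escapers (default fraction 0.25, matching the observed 20–30% wild-type
rate) keep the control law but retain the perturbed label; counts are
multinomial at a Poisson library size (mean 1000 tokens — the scale of a
post-selection expression matrix rather than raw sequencing depth);
dropout zeroes entries independently (rate 0.2, the simplest mechanism
producing the sparse regime); and the target gene's counts are scaled by
0.1 in edited cells so target knockdown is visible to the filters.

What it does **not** emulate: realistic zero-inflated negative-binomial
noise, ambient RNA, doublets, batch effects, guide-level (multi-sgRNA)
structure, or correlated gene modules beyond the planted topics. Passing
the synthetic benchmark shows the statistics recover what the model class
assumes; it does not certify performance on a real screen, where the
filtering defaults in particular should be inspected against the logged
removal counts.

# Validation scales and regimes

The test-suite and `scripts/acceptance.R` run at sizes chosen to exercise
the statistics properly while keeping a full run in minutes on one CPU:
screens of 500–600 cells × 300 genes, LDA with 200–300 sweeps (half
burn-in), 100–500 bootstrap repetitions. The package defaults (1000
sweeps, 1000 repetitions) remain the recommendation for real data.
Benchmarks that need a "strong effect" regime (the escaper filter's
sensitivity target) use `dirichlet_base = 5` with effect size 20:
concentrated control mixtures and a well-separated edited program, i.e.
the regime in which wild-type and edited transcriptomes are actually
distinguishable. In diffuse regimes (base 1), a sizeable minority of
wild-type draws resemble the edited program by chance and no similarity
filter can label them escapers; the measured sensitivity there (~65%) is a
ceiling imposed by the overlap of the two populations, not a property of
the implementation.

# Degenerate inputs and numerical choices

- Pooled t with zero pooled variance: 0 for equal means, signed infinity
  otherwise (flagged downstream).
- `tpdr` rows with all-zero TPD are NaN and flagged rather than invented.
- Single-topic models cannot be scored topic-specifically (`CS` needs
  min–max extents over ≥ 2 topics) and raise an error.
- ε = 1e-12 floors: inside the SS/PS logs, and for constant control
  columns in θ normalization (with a warning).
- Rounding in the expression transform is half away from zero, not R's
  banker's rounding, so ±x map symmetrically.
- Perturbation labels with no matching gene row (e.g. promoter-named
  CRISPRi guides) skip the silent-target check with a warning instead of
  failing; pooling of all non-targeting guides under one `"CTRL"` label is
  assumed upstream.
- CRISPRi screens should skip the off-target module (knockdown is highly
  specific); it is a separate entry point, not wired into
  `run_pipeline()`.

# Known limitations

Clipping down-regulation to zero discards half the effect direction at the
feature stage (the t statistics recover direction at the topic level).
The off-target search is a plain Hamming scan with an optional NGG-PAM
filter — it finds candidate sequences for the correlation test and is not
a substitute for a dedicated guide-specificity scorer. The Fisher-z
"significant increase" test for off-target coupling is our choice of
standard two-correlation test; the method itself does not prescribe one.
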