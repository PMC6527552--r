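#' Cell quality-control thresholds
#'
#' @param min_genes minimum number of genes detected per cell (default 500).
#' @param min_umi minimum total UMI count per cell (default 1000).
#' @param max_mito_fraction maximum fraction of mitochondrial genes among the
#'   detected genes (default 0.10). Read as a detected-gene-count fraction,
#'   not a UMI fraction.
#' @return a `QCThresholds` list.
#' @export
QCThresholds <- function(min_genes = 500, min_umi = 1000,
                         max_mito_fraction = 0.10) {
  stopifnot(min_genes >= 0, min_umi >= 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes = min_genes, min_umi = min_umi,
                 max_mito_fraction = max_mito_fraction),
            class = "QCThresholds")
}

#' Quality-control filter on cells
#'
#' Retains cells with at least `min_genes` detected genes, at least `min_umi`
#' total counts, and a mitochondrial detected-gene fraction of at most
#' `max_mito_fraction`. Mitochondrial genes are recognised by id prefix
#' (case-insensitive `"MT-"` by default).
#'
#' @param dataset a [ScreenDataset] of raw counts.
#' @param thresholds a [QCThresholds].
#' @param mito_prefix gene-id prefix marking mitochondrial genes.
#' @return the filtered [ScreenDataset].
#' @export
qc_filter_cells <- function(dataset, thresholds = QCThresholds(),
                            mito_prefix = "MT-") {
  m <- dataset$counts
  detected <- Matrix::rowSums(m > 0)
  umi <- Matrix::rowSums(m)
  is_mito <- startsWith(toupper(dataset$gene_ids), toupper(mito_prefix))
  mito_detected <- if (any(is_mito))
    Matrix::rowSums(m[, is_mito, drop = FALSE] > 0) else rep(0, nrow(m))
  mito_frac <- ifelse(detected > 0, mito_detected / detected, 0)
  keep <- detected >= thresholds$min_genes & umi >= thresholds$min_umi &
    mito_frac <= thresholds$max_mito_fraction
  if (!any(keep))
    stop("QC removed every cell; lower min_genes/min_umi or raise max_mito_fraction")
  pt_log("QC removed %d of %d cells", sum(!keep), length(keep))
  subset_cells(dataset, which(keep))
}

#' Imputation of dropout zeros
#'
#' `method = "none"` passes the matrix through. `method = "shrink"` is the
#' built-in stand-in: for each gene, zero entries are replaced by a shrunken
#' estimate `lambda * mean-over-nonzero-cells`; nonzero entries are never
#' touched. An externally imputed matrix (e.g. from a dedicated scRNA-seq
#' imputation package) can equally be supplied as the dataset's counts
#' upstream.
#'
#' @param dataset a [ScreenDataset].
#' @param method `"none"` or `"shrink"`.
#' @param lambda shrinkage factor for `"shrink"` (default 0.1).
#' @return a [ScreenDataset] with the imputed matrix.
#' @export
impute <- function(dataset, method = c("none", "shrink"), lambda = 0.1) {
  method <- match.arg(method)
  if (method == "none") return(dataset)
  m <- as.matrix(dataset$counts)
  nz_mean <- apply(m, 2, function(g) {
    nz <- g[g > 0]
    if (length(nz)) mean(nz) else 0
  })
  fill <- lambda * nz_mean
  for (j in seq_len(ncol(m))) {
    z <- m[, j] == 0
    if (any(z) && fill[j] > 0) m[z, j] <- fill[j]
  }
  ScreenDataset(m, dataset$perturbation, condition = dataset$condition,
                control_label = dataset$control_label)
}

#' Drop perturbations whose target gene is silent everywhere
#'
#' A knockout label whose own gene has zero expression in every cell of the
#' dataset cannot be validated and is removed together with its cells.
#' Labels without a matching gene row (e.g. promoter-named CRISPRi guides)
#' are skipped with a warning.
#'
#' @param dataset a [ScreenDataset].
#' @return list with `dataset` (filtered) and `dropped` (labels removed).
#' @export
filter_zero_perturbations <- function(dataset) {
  labels <- perturbation_labels(dataset)
  total <- Matrix::colSums(dataset$counts)
  dropped <- character()
  for (lab in labels) {
    j <- match(lab, dataset$gene_ids)
    if (is.na(j)) {
      warning("perturbation label '", lab,
              "' has no matching gene row; zero-expression check skipped")
      next
    }
    if (total[j] == 0) dropped <- c(dropped, lab)
  }
  if (length(dropped)) {
    pt_log("dropping all-zero-target perturbation(s): %s",
           paste(dropped, collapse = ", "))
    dataset <- subset_cells(dataset,
                            which(!dataset$perturbation %in% dropped))
  }
  list(dataset = dataset, dropped = dropped)
}

#' Differentially expressed genes by two-sample Kolmogorov-Smirnov test
#'
#' For each gene, compares the per-cell expression values between case and
#' control cells with the asymptotic two-sided two-sample KS test and keeps
#' genes with p below `alpha`. No multiplicity correction is applied: the
#' gene list feeds a similarity filter, not an inference.
#'
#' @param case,control numeric matrices, cells x genes, same genes.
#' @param alpha raw p-value threshold (default 0.05).
#' @return character vector of gene ids (colnames) passing the threshold.
#' @export
ks_de_genes <- function(case, control, alpha = 0.05) {
  case <- as.matrix(case); control <- as.matrix(control)
  if (nrow(case) < 2 || nrow(control) < 2)
    stop("need at least 2 cells on each side for the KS test")
  stopifnot(ncol(case) == ncol(control))
  p <- vapply(seq_len(ncol(case)), function(j) {
    x <- case[, j]; y <- control[, j]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
    suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)
  }, numeric(1))
  colnames(case)[p < alpha]
}

cosine_sim_matrix <- function(a, b) {
  # rows of a vs rows of b; zero-norm rows get similarity 0
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  s <- tcrossprod(a, b)
  s <- s / outer(na, nb)
  s[!is.finite(s)] <- 0
  s
}

#' Filter cells that escaped editing (sgRNA efficiency filter)
#'
#' Only 70-80% of guide-carrying cells show true loss of function; the rest
#' retain a wild-type phenotype and dilute the perturbation signal. For each
#' perturbation this filter finds KS-significant DE genes vs control, then
#' for every perturbed cell computes the median cosine similarity of its
#' DE-gene expression profile to its same-label peers (M_P) and to the
#' control cells (M_C). A cell closer to controls than to its peers
#' (M_C > M_P, strictly) is removed. If at least `drop_fraction` of a
#' perturbation's cells are removed the whole perturbation is dropped.
#' Control cells are never filtered here: they define the reference.
#'
#' @param dataset a [ScreenDataset] (post-imputation).
#' @param alpha KS threshold passed to [ks_de_genes].
#' @param drop_fraction proportion of removed cells at which the whole
#'   perturbation is discarded (default 0.90).
#' @return list with `dataset` (filtered) and `report`, a data.frame with
#'   one row per perturbed cell (`cell_id`, `label`, `M_P`, `M_C`,
#'   `removed`), plus attributes `dropped_perturbations` and `de_genes`.
#' @export
efficiency_filter <- function(dataset, alpha = 0.05, drop_fraction = 0.90) {
  ctrl_idx <- control_cells(dataset)
  if (length(ctrl_idx) < 2) stop("efficiency filter requires control cells")
  m <- as.matrix(dataset$counts)
  ctrl_m <- m[ctrl_idx, , drop = FALSE]
  report <- list()
  de_sets <- list()
  dropped_perts <- character()
  removed_cells <- integer()
  for (lab in sort(perturbation_labels(dataset))) {
    idx <- which(dataset$perturbation == lab)
    if (length(idx) < 2) {
      warning("perturbation '", lab,
              "' has a single cell; peer similarity undefined, cell retained")
      next
    }
    de <- ks_de_genes(m[idx, , drop = FALSE], ctrl_m, alpha = alpha)
    de_sets[[lab]] <- de
    if (length(de) == 0) {
      warning("no KS-significant genes for '", lab, "'; no cells filtered")
      next
    }
    pm <- m[idx, de, drop = FALSE]
    cm <- ctrl_m[, de, drop = FALSE]
    s_peer <- cosine_sim_matrix(pm, pm)
    s_ctrl <- cosine_sim_matrix(pm, cm)
    mp <- vapply(seq_along(idx),
                 function(i) stats::median(s_peer[i, -i]), numeric(1))
    mc <- apply(s_ctrl, 1, stats::median)
    rm_here <- mc > mp
    report[[lab]] <- data.frame(cell_id = dataset$cell_ids[idx],
                                label = lab, M_P = mp, M_C = mc,
                                removed = rm_here,
                                stringsAsFactors = FALSE)
    if (sum(rm_here) >= drop_fraction * length(idx)) {
      dropped_perts <- c(dropped_perts, lab)
      removed_cells <- c(removed_cells, idx)
      report[[lab]]$removed <- TRUE
    } else {
      removed_cells <- c(removed_cells, idx[rm_here])
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(cell_id = character(), label = character(), M_P = numeric(),
               M_C = numeric(), removed = logical())
  rownames(report) <- NULL
  attr(report, "dropped_perturbations") <- dropped_perts
  attr(report, "de_genes") <- de_sets
  keep <- setdiff(seq_len(nrow(m)), removed_cells)
  pt_log("efficiency filter removed %d cell(s), dropped %d perturbation(s)",
         length(removed_cells), length(dropped_perts))
  list(dataset = subset_cells(dataset, keep), report = report)
}

#' Minimum cells per perturbation
#'
#' At least 30 cells per perturbation are needed to capture a perturbation
#' phenotype; labels below `min_cells` are removed with their cells. The
#' control population must itself satisfy the threshold, otherwise the
#' downstream comparisons are meaningless and an error is raised.
#'
#' @param dataset a [ScreenDataset].
#' @param min_cells drop perturbations with fewer cells than this
#'   (default 30).
#' @return list with `dataset` and `dropped` labels.
#' @export
min_cell_filter <- function(dataset, min_cells = 30) {
  tab <- table(dataset$perturbation)
  n_ctrl <- if (dataset$control_label %in% names(tab))
    tab[[dataset$control_label]] else 0L
  if (n_ctrl < min_cells)
    stop(sprintf("only %d control cells remain (< %d); cannot proceed",
                 n_ctrl, min_cells))
  low <- names(tab)[tab < min_cells]
  low <- setdiff(low, dataset$control_label)
  if (length(low)) {
    pt_log("min-cell filter dropped %d perturbation(s): %s", length(low),
           paste(low, collapse = ", "))
    dataset <- subset_cells(dataset, which(!dataset$perturbation %in% low))
  }
  list(dataset = dataset, dropped = low)
}
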