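#' ScreenDataset: the pipeline's data container
#'
#' A `ScreenDataset` bundles a cells x genes expression matrix with per-cell
#' perturbation labels. Raw input is integer UMI counts; after imputation the
#' matrix may hold non-integer expression values. Control (non-targeting)
#' cells carry the reserved label given by `control_label` (default `"CTRL"`).
#'
#' @param counts numeric matrix or Matrix, cells x genes, non-negative.
#' @param perturbation character vector, one label per cell. Either the
#'   control label or a gene symbol identifying the knockout/knockdown.
#' @param cell_ids,gene_ids unique identifier vectors; default taken from
#'   `dimnames(counts)`.
#' @param condition optional per-cell experimental-condition tag.
#' @param control_label reserved label marking non-targeting control cells.
#' @return An object of class `ScreenDataset` with fields `counts`
#'   (dgCMatrix, cells x genes), `cell_ids`, `gene_ids`, `perturbation`,
#'   `condition`, `control_label`.
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("G", 1:4)))
#' sd <- ScreenDataset(m, c("G1", "G1", "CTRL"))
#' dim(sd)
#' @export
ScreenDataset <- function(counts, perturbation,
                          cell_ids = rownames(counts),
                          gene_ids = colnames(counts),
                          condition = NULL,
                          control_label = "CTRL") {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  perturbation <- as.character(perturbation)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("cell_ids/gene_ids lengths do not match counts dimensions")
  if (length(perturbation) != nrow(counts))
    stop("perturbation must have one label per cell")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (any(counts@x < 0)) stop("counts must be non-negative")
  if (!is.null(condition)) {
    condition <- as.character(condition)
    if (length(condition) != nrow(counts))
      stop("condition must have one tag per cell")
  }
  dimnames(counts) <- list(cell_ids, gene_ids)
  ko <- setdiff(unique(perturbation), control_label)
  missing_gene <- setdiff(ko, gene_ids)
  if (length(missing_gene))
    warning("perturbation label(s) with no matching gene row: ",
            paste(missing_gene, collapse = ", "))
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 perturbation = perturbation, condition = condition,
                 control_label = control_label),
            class = "ScreenDataset")
}

#' @export
dim.ScreenDataset <- function(x) dim(x$counts)

#' @export
print.ScreenDataset <- function(x, ...) {
  tab <- table(x$perturbation)
  cat(sprintf("ScreenDataset: %d cells x %d genes, %d perturbations (+%s)\n",
              nrow(x$counts), ncol(x$counts),
              sum(names(tab) != x$control_label),
              if (x$control_label %in% names(tab))
                sprintf("%d %s cells", tab[[x$control_label]], x$control_label)
              else "no control cells"))
  invisible(x)
}

#' Subset a dataset to a set of cells
#'
#' @param dataset a `ScreenDataset`.
#' @param cells logical, integer or character index into the cells.
#' @return a `ScreenDataset` restricted to the selected cells.
#' @keywords internal
subset_cells <- function(dataset, cells) {
  if (is.character(cells)) cells <- match(cells, dataset$cell_ids)
  ScreenDataset(dataset$counts[cells, , drop = FALSE],
                dataset$perturbation[cells],
                condition = if (!is.null(dataset$condition))
                  dataset$condition[cells],
                control_label = dataset$control_label)
}

#' Indices of control cells
#' @keywords internal
control_cells <- function(dataset) {
  which(dataset$perturbation == dataset$control_label)
}

#' Non-control perturbation labels present in a dataset
#' @keywords internal
perturbation_labels <- function(dataset) {
  setdiff(unique(dataset$perturbation), dataset$control_label)
}
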