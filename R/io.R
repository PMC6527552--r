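#' Read a Matrix Market screen into a ScreenDataset
#'
#' Reads a coordinate-format `.mtx` matrix together with one-id-per-line
#' barcode and gene files and a perturbation table. The on-disk matrix may be
#' cells x genes or genes x cells; orientation is resolved by matching the
#' dimension sizes against the barcode and gene file lengths and is never
#' assumed. A square matrix with equally many barcodes and genes is rejected
#' as ambiguous.
#'
#' The perturbation file is TSV with a header and columns
#' `cell_id`, `perturbation` and optionally `condition`. Cells whose label is
#' missing or empty are dropped (the count is logged); remaining cells are
#' returned in barcode-file order regardless of the perturbation file's row
#' order.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param barcodes_path,genes_path one identifier per line.
#' @param perturbation_path TSV mapping cell barcodes to labels.
#' @param control_label reserved non-targeting control label.
#' @return a [ScreenDataset].
#' @export
read_mtx <- function(matrix_path, barcodes_path, genes_path,
                     perturbation_path, control_label = "CTRL") {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  genes <- readLines(genes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  genes <- genes[nzchar(genes)]
  nb <- length(barcodes); ng <- length(genes)
  if (nrow(m) == nb && ncol(m) == ng) {
    if (nrow(m) == ncol(m) && nb == ng)
      stop("ambiguous orientation: square matrix with equal barcode and gene counts")
  } else if (nrow(m) == ng && ncol(m) == nb) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf("dimension mismatch: matrix %d x %d vs %d barcodes, %d genes",
                 nrow(m), ncol(m), nb, ng))
  }
  dimnames(m) <- list(barcodes, genes)
  pert <- read_perturbation_table(perturbation_path)
  build_dataset_from_labels(m, pert, control_label)
}

#' Read a dense count table into a ScreenDataset
#'
#' Accepts a TSV/CSV with a header row and identifiers in the first column,
#' laid out either genes x cells or cells x genes. Orientation is resolved by
#' matching row/column identifiers against the perturbation table's cell ids.
#'
#' @inheritParams read_mtx
#' @param path count table path (`.csv` uses comma, anything else tab).
#' @return a [ScreenDataset].
#' @export
read_counts_table <- function(path, perturbation_path, control_label = "CTRL") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) == 0L) stop("empty count table: ", path)
  if (!all(vapply(tab, is.numeric, logical(1))))
    stop("non-numeric entries in count table: ", path)
  m <- as.matrix(tab)
  if (min(m) < 0) stop("negative counts in ", path)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate row or column identifiers in ", path)
  pert <- read_perturbation_table(perturbation_path)
  in_cols <- mean(pert$cell_id %in% colnames(m))
  in_rows <- mean(pert$cell_id %in% rownames(m))
  if (in_cols > in_rows) m <- t(m)          # genes x cells on disk
  else if (in_cols == in_rows && in_cols == 0)
    stop("no perturbation-table cell id matches the count table")
  build_dataset_from_labels(Matrix::Matrix(m, sparse = TRUE), pert,
                            control_label)
}

read_perturbation_table <- function(path) {
  pert <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "perturbation")
  if (!all(need %in% names(pert)))
    stop("perturbation file must have columns cell_id and perturbation")
  if (anyDuplicated(pert$cell_id)) stop("duplicate cell ids in perturbation file")
  pert
}

build_dataset_from_labels <- function(m, pert, control_label) {
  unknown <- setdiff(pert$cell_id, rownames(m))
  if (length(unknown))
    stop("perturbation file lists barcode(s) absent from the matrix: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  lab <- pert$perturbation[match(rownames(m), pert$cell_id)]
  cond <- if ("condition" %in% names(pert))
    pert$condition[match(rownames(m), pert$cell_id)]
  keep <- !is.na(lab) & nzchar(lab)
  n_drop <- sum(!keep)
  if (n_drop > 0)
    pt_log("dropped %d cell(s) without a perturbation label", n_drop)
  ScreenDataset(m[keep, , drop = FALSE], lab[keep],
                condition = if (!is.null(cond)) cond[keep],
                control_label = control_label)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: each line is `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Genes are deduplicated preserving first occurrence; empty sets and
#' duplicate set names are errors.
#'
#' @param path GMT file path.
#' @return a `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  empty <- which(lengths(sets) == 0L)
  if (length(empty)) stop("gene set with no genes: ", nm[empty[1]])
  names(sets) <- nm
  desc <- vapply(fields, `[[`, "", 2L)
  names(desc) <- nm
  structure(list(sets = sets, description = desc),
            class = "GeneSetCollection")
}

#' Write a ranking or statistics table as TSV
#'
#' Writes a header plus rows in deterministic order (by a `rank` column when
#' present, ties and otherwise by the first label-like column), with floats
#' printed at 6 significant digits.
#'
#' @param table a data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ranking <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) > 0) {
    keys <- list()
    if ("rank" %in% names(table)) keys <- c(keys, list(table$rank))
    chr <- which(vapply(table, is.character, logical(1)))
    if (length(chr)) keys <- c(keys, list(table[[chr[1]]]))
    if (length(keys)) table <- table[do.call(order, keys), , drop = FALSE]
  }
  out <- table
  num <- vapply(out, function(x) is.numeric(x) && !is.integer(x), logical(1))
  out[num] <- lapply(out[num], function(x) as.character(signif(x, 6)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal line-oriented logger (level, timestamp, message) to stderr
#' @keywords internal
pt_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...)))
}
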