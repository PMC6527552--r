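#' Per-gene dispersion
#'
#' Dispersion of gene i is `D_i = ln(variance_i / mean_i)` over cells
#' (natural log). A Poisson-like gene (variance equal to mean) has D = 0.
#' Genes with zero mean or zero variance have no defined dispersion and are
#' flagged unusable (NA).
#'
#' @param matrix numeric matrix, cells x genes, at least 2 cells.
#' @return data.frame with `gene`, `mean`, `variance`, `dispersion`,
#'   `usable`.
#' @export
dispersion <- function(matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2) stop("dispersion needs at least 2 cells")
  mu <- colMeans(matrix)
  v <- apply(matrix, 2, stats::var)
  usable <- mu > 0 & v > 0
  d <- rep(NA_real_, length(mu))
  d[usable] <- log(v[usable] / mu[usable])
  data.frame(gene = colnames(matrix) %||% paste0("gene", seq_along(mu)),
             mean = mu, variance = v, dispersion = d, usable = usable,
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binned z-score of dispersion
#'
#' Genes are binned into `n_bins` equal-frequency bins by average
#' expression; within each bin the dispersion values are standardised:
#' `ZD_i = (D_i - mean(D_bin)) / sd(D_bin)` with the sample SD (n-1).
#' Bins whose dispersion SD is zero give ZD = 0. When fewer usable genes
#' than bins are supplied, the bin count collapses to
#' `max(1, floor(usable/2))`.
#'
#' @param D per-gene dispersion (NA = unusable).
#' @param mean_expr per-gene average expression, same length.
#' @param n_bins number of equal-frequency bins (default 20).
#' @return numeric vector of ZD values (NA where D is NA).
#' @export
binned_dispersion_zscore <- function(D, mean_expr, n_bins = 20) {
  stopifnot(length(D) == length(mean_expr))
  zd <- rep(NA_real_, length(D))
  ok <- which(!is.na(D))
  if (!length(ok)) return(zd)
  if (length(ok) < n_bins) n_bins <- max(1L, floor(length(ok) / 2))
  # equal-frequency binning on the rank of mean expression; ties share the
  # rank average so bin membership does not depend on input order
  r <- rank(mean_expr[ok], ties.method = "average")
  bin <- ceiling(r / length(ok) * n_bins)
  bin[bin < 1] <- 1L
  for (b in unique(bin)) {
    i <- ok[bin == b]
    d <- D[i]
    s <- stats::sd(d)
    zd[i] <- if (length(d) < 2 || !is.finite(s) || s == 0) 0
             else (d - mean(d)) / s
  }
  zd
}

#' Select highly dispersion differentially expressed (DDE) genes
#'
#' The feature statistic is the dispersion difference
#' `DD_i = |ZD_case(i) - ZD_control(i)|`, where the binned dispersion
#' z-scores are computed independently within the pooled perturbed cells
#' (case) and the control cells. The top `n_top` genes by descending DD are
#' selected (ties broken by gene id, ascending); genes unusable in either
#' population are excluded.
#'
#' @param case,control numeric matrices, cells x genes, identical genes.
#' @param n_top number of genes to keep (default 500).
#' @param n_bins expression bins passed to [binned_dispersion_zscore].
#' @return list with `genes` (selected ids) and `stats`, a per-gene
#'   data.frame with means, dispersions, ZD in each population and DD.
#' @export
select_dde_genes <- function(case, control, n_top = 500, n_bins = 20) {
  case <- as.matrix(case); control <- as.matrix(control)
  stopifnot(identical(colnames(case), colnames(control)))
  dc <- dispersion(case)
  dk <- dispersion(control)
  zd_case <- binned_dispersion_zscore(dc$dispersion, dc$mean, n_bins)
  zd_ctrl <- binned_dispersion_zscore(dk$dispersion, dk$mean, n_bins)
  dd <- abs(zd_case - zd_ctrl)
  stats <- data.frame(gene = dc$gene,
                      mean_case = dc$mean, mean_control = dk$mean,
                      dispersion_case = dc$dispersion,
                      dispersion_control = dk$dispersion,
                      ZD_case = zd_case, ZD_control = zd_ctrl,
                      DD = dd, stringsAsFactors = FALSE)
  usable <- which(!is.na(dd))
  if (n_top > length(usable)) {
    warning(sprintf("requested %d DDE genes but only %d usable; returning all",
                    n_top, length(usable)))
    n_top <- length(usable)
  }
  ord <- usable[order(-dd[usable], stats$gene[usable])]
  list(genes = stats$gene[ord[seq_len(n_top)]], stats = stats)
}

#' Normalize and round expression for the topic model
#'
#' Centres each gene on its control mean, scales by the same mean, magnifies
#' by 10 and rounds to the nearest integer (half away from zero):
#' `round((X - mu_control) / mu_control * 10)`. The topic model consumes
#' word counts, so negative results (down-regulation) are clipped to 0; the
#' clipped fraction is logged.
#'
#' @param matrix numeric matrix, cells x genes, restricted to DDE genes.
#' @param control_mean per-gene control means, all strictly positive.
#' @return integer matrix, same shape, all entries >= 0.
#' @export
normalize_and_round <- function(matrix, control_mean) {
  matrix <- as.matrix(matrix)
  stopifnot(length(control_mean) == ncol(matrix))
  if (any(control_mean == 0))
    stop("control mean of 0 for gene(s): ",
         paste(colnames(matrix)[control_mean == 0], collapse = ", "))
  x <- sweep(sweep(matrix, 2, control_mean, "-"), 2, control_mean, "/") * 10
  x <- sign(x) * floor(abs(x) + 0.5)       # round half away from zero
  clipped <- mean(x < 0)
  x[x < 0] <- 0
  pt_log("normalize_and_round clipped %.1f%% of entries to 0", 100 * clipped)
  storage.mode(x) <- "double"
  x
}
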