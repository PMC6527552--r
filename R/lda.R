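#' Fit a latent Dirichlet allocation model by collapsed Gibbs sampling
#'
#' Cells play the role of documents and the normalized, rounded expression
#' values the role of word counts: each cell is modelled as a mixture over
#' `n` latent topics (biological-function programs), each topic as a
#' distribution over genes. Token-level topic assignments are resampled by
#' collapsed Gibbs; the returned parameters use the standard smoothed
#' estimators `theta[d,t] = (N_dt + alpha) / (N_d + n*alpha)` and
#' `phi[t,w] = (N_tw + beta) / (N_t + V*beta)` from the final sweep
#' (or, with `average = TRUE`, from the mean of post-burn-in sweeps).
#' The same seed reproduces the fit bitwise.
#'
#' @param counts non-negative integer matrix, cells x genes (the output of
#'   [normalize_and_round]). Cells whose row is all zero carry no tokens and
#'   are dropped with a warning.
#' @param n number of topics (>= 2 for downstream scoring; 1 is allowed and
#'   gives a degenerate single-topic model).
#' @param alpha,beta Dirichlet hyperparameters; defaults `50/n` and `0.1`.
#' @param n_iter,burn_in Gibbs sweeps and burn-in (defaults 1000 / 500).
#' @param seed integer seed.
#' @param average if TRUE, estimate from the average of post-burn-in sweeps
#'   instead of the final sweep.
#' @return a `TopicModel`: list with `theta` (cells x n, rows sum to 1),
#'   `phi` (n x genes, rows sum to 1), `n`, `alpha`, `beta`, `n_iter`,
#'   `burn_in`, `seed`.
#' @export
fit_lda <- function(counts, n, alpha = 50 / n, beta = 0.1,
                    n_iter = 1000, burn_in = 500, seed = 1,
                    average = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (n > nrow(counts)) stop("more topics than cells")
  keep <- rowSums(counts) > 0
  if (!any(keep)) stop("zero total tokens")
  if (!all(keep)) {
    warning(sum(!keep), " cell(s) with all-zero rows dropped from the LDA fit")
    counts <- counts[keep, , drop = FALSE]
  }
  trip <- which(counts > 0, arr.ind = TRUE)
  # token order fixed to (cell, then gene) so the fit does not depend on how
  # the matrix was stored
  ord <- order(trip[, 1], trip[, 2])
  trip <- trip[ord, , drop = FALSE]
  fit <- with_seed(seed, lda_gibbs_cpp(
    as.integer(trip[, 1] - 1L), as.integer(trip[, 2] - 1L),
    as.integer(counts[trip]), nrow(counts), ncol(counts),
    as.integer(n), alpha, beta, as.integer(n_iter), as.integer(burn_in),
    isTRUE(average)))
  theta <- fit$theta
  phi <- fit$phi
  dimnames(theta) <- list(rownames(counts), paste0("topic", seq_len(n)))
  dimnames(phi) <- list(paste0("topic", seq_len(n)), colnames(counts))
  structure(list(theta = theta, phi = phi, n = n, alpha = alpha,
                 beta = beta, n_iter = n_iter, burn_in = burn_in,
                 seed = seed),
            class = "TopicModel")
}

#' @export
print.TopicModel <- function(x, ...) {
  cat(sprintf("TopicModel: %d cells x %d topics over %d genes (alpha=%.3g, beta=%.3g, seed=%d)\n",
              nrow(x$theta), x$n, ncol(x$phi), x$alpha, x$beta, x$seed))
  invisible(x)
}

# run expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Topic-number specificity score
#'
#' `SS_n = ln( (1/n) * sum_j var_j / mean_j^2 )` over the columns of theta:
#' the mean squared coefficient of variation of topic occupancy across
#' cells. A good topic count lets each topic's occupancy differ strongly
#' between cells. Columns with zero mean contribute 0; the mean inside the
#' log is floored at `eps` before taking the log.
#'
#' @param theta cells x topics probability matrix.
#' @param use_sd if TRUE use SD instead of variance in the numerator.
#' @param eps floor inside the log (default 1e-12).
#' @return the scalar score.
#' @export
specificity_score <- function(theta, use_sd = FALSE, eps = 1e-12) {
  theta <- as.matrix(theta)
  v <- apply(theta, 2, stats::var)
  if (use_sd) v <- sqrt(v)
  mu <- colMeans(theta)
  term <- ifelse(mu == 0, 0, v / mu^2)
  log(max(mean(term), eps))
}

#' Topic-number purity score
#'
#' `PS_n = ln( (1/m) * sum_i var_i )` over the rows of theta: cells
#' dominated by few topics have high row variance. Floored at `eps` inside
#' the log.
#'
#' @inheritParams specificity_score
#' @return the scalar score.
#' @export
purity_score <- function(theta, eps = 1e-12) {
  theta <- as.matrix(theta)
  log(max(mean(apply(theta, 1, stats::var)), eps))
}

#' Automatic topic-number selection
#'
#' Fits one model per candidate topic count (seeding candidate k with
#' `seed + k`'s position index so the scan is reproducible), computes the
#' specificity and purity scores, min-max normalizes each across the
#' candidates, and combines them as
#' `CS = alpha_cs * norm(SS) + (1 - alpha_cs) * norm(PS)`. The best
#' candidate maximises CS; ties go to the smaller topic count.
#'
#' @param counts matrix for [fit_lda].
#' @param candidates integer topic counts to try (default 4:6).
#' @param alpha_cs weight on the specificity score in `[0, 1]`.
#' @param seed master seed; candidate i is fitted with `seed + i`.
#' @param ... further arguments to [fit_lda] (`n_iter`, `burn_in`, ...).
#' @return a `TopicNumberScan`: data.frame (`n`, `SS`, `PS`, `CS`) with
#'   attributes `best` (chosen topic count) and `models` (the fitted
#'   `TopicModel`s, named by topic count).
#' @export
select_topic_number <- function(counts, candidates = 4:6, alpha_cs = 0.5,
                                seed = 1, ...) {
  stopifnot(alpha_cs >= 0, alpha_cs <= 1, length(candidates) >= 1)
  if (length(candidates) == 1)
    warning("single candidate topic number; CS is trivially 1")
  models <- list()
  ss <- ps <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    m <- fit_lda(counts, n = candidates[i], seed = seed + i, ...)
    models[[as.character(candidates[i])]] <- m
    ss[i] <- specificity_score(m$theta)
    ps[i] <- purity_score(m$theta)
  }
  norm01 <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) rep(1, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  cs <- alpha_cs * norm01(ss) + (1 - alpha_cs) * norm01(ps)
  scan <- data.frame(n = candidates, SS = ss, PS = ps, CS = cs)
  best <- candidates[order(-cs, candidates)][1]
  attr(scan, "best") <- best
  attr(scan, "models") <- models
  class(scan) <- c("TopicNumberScan", "data.frame")
  scan
}

#' Annotate topic function by gene-set over-representation
#'
#' For each topic, takes the top `top_fraction` of genes by occurrence
#' probability (ceiling of `top_fraction * G`, ties broken by gene id) and
#' tests each gene set for over-representation against the model's gene
#' universe with the hypergeometric tail. q-values are Benjamini-Hochberg
#' within each topic; the top `n_terms` sets by q are reported.
#'
#' @param model a `TopicModel`.
#' @param sets a `GeneSetCollection` from [read_gmt] or built in code.
#' @param top_fraction fraction of genes per topic (default 0.10).
#' @param n_terms terms reported per topic (default 5).
#' @return data.frame with `topic`, `term`, `overlap`, `set_size`,
#'   `fold_enrichment`, `p`, `q`, sorted by topic then q.
#' @export
annotate_topics <- function(model, sets, top_fraction = 0.10, n_terms = 5) {
  universe <- colnames(model$phi)
  usable <- lapply(sets$sets, intersect, universe)
  keep <- lengths(usable) > 0
  if (!any(keep)) {
    warning("no gene set overlaps the model's gene universe")
    return(data.frame(topic = character(), term = character(),
                      overlap = integer(), set_size = integer(),
                      fold_enrichment = numeric(), p = numeric(),
                      q = numeric()))
  }
  usable <- usable[keep]
  N <- length(universe)
  k_top <- ceiling(top_fraction * N)
  out <- list()
  for (t in seq_len(model$n)) {
    pr <- model$phi[t, ]
    top <- universe[order(-pr, universe)][seq_len(k_top)]
    p <- vapply(usable, function(g) {
      x <- length(intersect(top, g))
      stats::phyper(x - 1, length(g), N - length(g), k_top,
                    lower.tail = FALSE)
    }, numeric(1))
    overlap <- vapply(usable, function(g) length(intersect(top, g)),
                      integer(1))
    fe <- (overlap / k_top) / (lengths(usable) / N)
    q <- stats::p.adjust(p, method = "BH")
    df <- data.frame(topic = rownames(model$phi)[t], term = names(usable),
                     overlap = overlap, set_size = lengths(usable),
                     fold_enrichment = fe, p = p, q = q,
                     row.names = NULL, stringsAsFactors = FALSE)
    df <- df[order(df$q, df$p, df$term), ]
    out[[t]] <- utils::head(df, n_terms)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
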