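#' Z-normalize topic probabilities against the control population
#'
#' Each topic column is centred and scaled by the mean and standard
#' deviation of the control cells, applied to every cell (controls
#' included), so the bootstrap t-statistics downstream compare standardised
#' quantities. A constant control column (SD 0) is guarded with
#' `eps = 1e-12` and a warning.
#'
#' @param theta cells x topics probability matrix with rownames.
#' @param control_cells indices (or rownames) of the control cells.
#' @return matrix of the same shape, z-scored per topic.
#' @export
normalize_theta <- function(theta, control_cells) {
  theta <- as.matrix(theta)
  if (is.character(control_cells))
    control_cells <- match(control_cells, rownames(theta))
  if (length(control_cells) < 2) stop("need at least 2 control cells")
  ctrl <- theta[control_cells, , drop = FALSE]
  mu <- colMeans(ctrl)
  s <- apply(ctrl, 2, stats::sd)
  if (any(s == 0)) {
    warning("constant control topic column(s); SD replaced by 1e-12")
    s[s == 0] <- 1e-12
  }
  sweep(sweep(theta, 2, mu, "-"), 2, s, "/")
}

#' Pooled-variance two-sample t statistic
#'
#' The kernel of the topic probability difference: mean difference over the
#' square root of the pooled variance times `(1/n1 + 1/n2)`, with
#' `n1 + n2 - 2` degrees of freedom in the pooling. If the pooled variance
#' is zero the statistic is 0 for equal means and a signed infinity for
#' unequal means.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return the scalar t statistic.
#' @export
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each side needs at least 2 values")
  num <- mean(x) - mean(y)
  pool <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
    (n1 + n2 - 2)
  den <- sqrt(pool * (1 / n1 + 1 / n2))
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

# vectorized pooled t over topic columns: case summary vs control summary
pooled_t_cols <- function(mx, vx, n1, mc, vc, n2) {
  num <- mx - mc
  pool <- ((n1 - 1) * vx + (n2 - 1) * vc) / (n1 + n2 - 2)
  den <- sqrt(pool * (1 / n1 + 1 / n2))
  out <- ifelse(den == 0, ifelse(num == 0, 0, sign(num) * Inf), num / den)
  out
}

col_var <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

# deterministic per-label seed substream: independent of the order in which
# perturbations are visited, stays below 2^31
sub_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% 1000003
  as.integer((as.double(seed) * 131 + h) %% 2147483587 + 1)
}

min_pert_cells <- function(perturbation, control_label) {
  tab <- table(perturbation[perturbation != control_label])
  if (!length(tab)) stop("no perturbed cells")
  min(tab)
}

#' Topic probability difference (TPD) matrix
#'
#' For every perturbation and topic, the bootstrap-median pooled t
#' statistic comparing the perturbation's normalized topic probabilities to
#' the control cells'. Because perturbations differ greatly in cell number,
#' every draw subsamples `M` cells (the minimal cell count over all
#' perturbations) without replacement — at `n_i = M` every draw is the full
#' population — and the median over `n_boot` draws is reported. One seeded
#' stream of draws per perturbation (derived from `seed` and the label, so
#' results do not depend on iteration order) is shared across topics.
#'
#' @param norm_theta output of [normalize_theta].
#' @param perturbation per-cell labels aligned to `norm_theta` rows.
#' @param control_label reserved control label.
#' @param M subsample size; default the minimal perturbation cell count.
#' @param n_boot bootstrap repetitions (default 1000).
#' @param seed master seed.
#' @return perturbations x topics numeric matrix.
#' @export
tpd <- function(norm_theta, perturbation, control_label = "CTRL",
                M = NULL, n_boot = 1000, seed = 1) {
  norm_theta <- as.matrix(norm_theta)
  labels <- sort(setdiff(unique(perturbation), control_label))
  if (is.null(M)) M <- min_pert_cells(perturbation, control_label)
  if (M < 2) stop("minimal perturbation cell count M must be >= 2")
  ctrl <- norm_theta[perturbation == control_label, , drop = FALSE]
  if (nrow(ctrl) < 2) stop("need at least 2 control cells")
  mc <- colMeans(ctrl); vc <- col_var(ctrl); n2 <- nrow(ctrl)
  out <- matrix(NA_real_, length(labels), ncol(norm_theta),
                dimnames = list(labels, colnames(norm_theta)))
  for (lab in labels) {
    idx <- which(perturbation == lab)
    # key the resampling to cell ids so results are invariant to row order
    if (!is.null(rownames(norm_theta)))
      idx <- idx[order(rownames(norm_theta)[idx])]
    out[lab, ] <- with_seed(sub_seed(seed, lab), {
      ts <- matrix(0, n_boot, ncol(norm_theta))
      for (b in seq_len(n_boot)) {
        draw <- if (length(idx) > M) sample(idx, M) else
          if (length(idx) == M) idx else sample(idx, M, replace = TRUE)
        sub <- norm_theta[draw, , drop = FALSE]
        ts[b, ] <- pooled_t_cols(colMeans(sub), col_var(sub), M, mc, vc, n2)
      }
      apply(ts, 2, stats::median)
    })
  }
  out
}

#' Per-topic random (null) TPD baseline
#'
#' The same bootstrap scheme as [tpd] with the case side drawn from the
#' control cells themselves: `M` controls, sampled without replacement,
#' against the full control population. Its median over `n_boot` draws is
#' the per-topic baseline subtracted to form the adjusted TPD.
#'
#' @inheritParams tpd
#' @param control_idx indices of control cells in `norm_theta`.
#' @return numeric vector, one baseline per topic.
#' @export
tpd_random <- function(norm_theta, control_idx, M, n_boot = 1000, seed = 1) {
  norm_theta <- as.matrix(norm_theta)
  if (!is.null(rownames(norm_theta)))
    control_idx <- control_idx[order(rownames(norm_theta)[control_idx])]
  ctrl <- norm_theta[control_idx, , drop = FALSE]
  n2 <- nrow(ctrl)
  replace <- n2 < M + 2
  if (replace)
    warning("fewer than M+2 control cells; null draws use replacement")
  mc <- colMeans(ctrl); vc <- col_var(ctrl)
  with_seed(sub_seed(seed, ".null"), {
    ts <- matrix(0, n_boot, ncol(norm_theta))
    for (b in seq_len(n_boot)) {
      draw <- sample(seq_len(n2), M, replace = replace)
      sub <- ctrl[draw, , drop = FALSE]
      ts[b, ] <- pooled_t_cols(colMeans(sub), col_var(sub), M, mc, vc, n2)
    }
    apply(ts, 2, stats::median)
  })
}

#' Adjusted TPD
#'
#' `TPDA[i, j] = TPD[i, j] - TPD_random[j]`: the control-vs-control
#' baseline is subtracted from every perturbation's row.
#'
#' @param TPD perturbations x topics matrix.
#' @param TPD_random per-topic baseline vector.
#' @return matrix of the same shape as `TPD`.
#' @export
tpda <- function(TPD, TPD_random) {
  if (length(TPD_random) != ncol(TPD)) stop("baseline length != topic count")
  sweep(TPD, 2, TPD_random, "-")
}

#' Topic probability difference ratio
#'
#' The share of a perturbation's absolute TPD that falls on each topic:
#' `TPDR[i, j] = |TPD[i, j]| / sum_j' |TPD[i, j']|`. A large ratio means
#' the perturbation concentrates its effect on that topic. Rows with all
#' zero TPD are undefined (NaN). The summation runs over topics for a
#' fixed perturbation; `sum_over = "perturbations"` gives the column-wise
#' variant.
#'
#' @param TPD perturbations x topics matrix.
#' @param sum_over `"topics"` (default) or `"perturbations"`.
#' @return matrix of ratios; defined rows (columns) sum to 1.
#' @export
tpdr <- function(TPD, sum_over = c("topics", "perturbations")) {
  sum_over <- match.arg(sum_over)
  a <- abs(TPD)
  if (sum_over == "topics") sweep(a, 1, rowSums(a), "/")
  else sweep(a, 2, colSums(a), "/")
}

cs_row <- function(abs_tpd_row, tpdr_row) {
  mm <- function(x) {
    r <- range(x)
    if (r[2] == r[1]) rep(0, length(x)) else (x - r[1]) / (r[2] - r[1])
  }
  0.5 * (mm(abs_tpd_row) + mm(tpdr_row))
}

#' Topic-specific perturbation scores with significance thresholds
#'
#' Combines effect strength and concentration per perturbation: each row's
#' `|TPD|` and TPDR values are min-max scaled over topics and averaged,
#' `CS[i, j] = 0.5 * (minmax(|TPD[i, .]|)[j] + minmax(TPDR[i, .])[j])`, so
#' the topic carrying both the largest absolute effect and the largest
#' share scores 1. A degenerate extent (max = min over the row) sets that
#' term to 0.
#'
#' When `norm_theta` and `control_idx` are supplied, a per-topic
#' significance threshold is computed: `n_reps` times, `M` control cells
#' are drawn and a CS row computed from their pooled t statistics; the
#' per-topic median of these null CS rows is the threshold, and
#' `CS[i, j] > threshold[j]` is flagged significant.
#'
#' @param TPD perturbations x topics matrix (needs >= 2 topics).
#' @param TPDR matching ratio matrix from [tpdr].
#' @param norm_theta,control_idx optional, enable threshold computation.
#' @param M subsample size for the null draws.
#' @param n_reps null repetitions (default 1000).
#' @param seed master seed.
#' @return list with `CS` (matrix in `[0, 1]`), `threshold` (per-topic, or
#'   NULL), `significant` (logical matrix, or NULL).
#' @export
topic_specific_scores <- function(TPD, TPDR, norm_theta = NULL,
                                  control_idx = NULL, M = NULL,
                                  n_reps = 1000, seed = 1) {
  if (ncol(TPD) < 2)
    stop("topic-specific scores need at least 2 topics")
  CS <- t(vapply(seq_len(nrow(TPD)),
                 function(i) cs_row(abs(TPD[i, ]), TPDR[i, ]),
                 numeric(ncol(TPD))))
  dimnames(CS) <- dimnames(TPD)
  threshold <- significant <- NULL
  if (!is.null(norm_theta) && !is.null(control_idx)) {
    norm_theta <- as.matrix(norm_theta)
    if (!is.null(rownames(norm_theta)))
      control_idx <- control_idx[order(rownames(norm_theta)[control_idx])]
    ctrl <- norm_theta[control_idx, , drop = FALSE]
    n2 <- nrow(ctrl)
    replace <- n2 < M + 2
    mc <- colMeans(ctrl); vc <- col_var(ctrl)
    null_cs <- with_seed(sub_seed(seed, ".threshold"), {
      t(vapply(seq_len(n_reps), function(r) {
        draw <- sample(seq_len(n2), M, replace = replace)
        sub <- ctrl[draw, , drop = FALSE]
        tt <- pooled_t_cols(colMeans(sub), col_var(sub), M, mc, vc, n2)
        rr <- abs(tt) / sum(abs(tt))
        cs_row(abs(tt), rr)
      }, numeric(ncol(TPD))))
    })
    threshold <- apply(null_cs, 2, stats::median)
    names(threshold) <- colnames(TPD)
    significant <- sweep(CS, 2, threshold, ">")
  }
  list(CS = CS, threshold = threshold, significant = significant)
}

#' Overall perturbation effect ranking
#'
#' The overall impact of perturbation i is the summed absolute adjusted
#' TPD over topics, `TPDS_i = sum_j |TPDA[i, j]|`. Also emits the
#' max-normalized score used for cross-run comparisons.
#'
#' @param TPDA adjusted TPD matrix from [tpda].
#' @return data.frame (`perturbation`, `TPDS`, `TPDS_norm`, `rank`) sorted
#'   by descending TPDS, ties by label.
#' @export
overall_ranking <- function(TPDA) {
  tpds <- rowSums(abs(TPDA))
  mx <- max(tpds)
  df <- data.frame(perturbation = rownames(TPDA), TPDS = tpds,
                   TPDS_norm = if (mx > 0) tpds / mx else tpds,
                   row.names = NULL, stringsAsFactors = FALSE)
  df <- df[order(-df$TPDS, df$perturbation), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Pairwise perturbation relationships
#'
#' Pearson correlation of every pair of perturbations' adjusted TPD
#' profiles; functionally related perturbations shift the same topics and
#' correlate strongly. Rows with zero variance give an undefined (NA)
#' correlation, flagged in the output.
#'
#' @param TPDA adjusted TPD matrix, >= 2 perturbations.
#' @return data.frame edge list (`a`, `b`, `r`, `defined`) sorted by
#'   decreasing `|r|`.
#' @export
perturbation_correlations <- function(TPDA) {
  if (nrow(TPDA) < 2) stop("need at least 2 perturbations")
  labs <- rownames(TPDA)
  pairs <- utils::combn(seq_along(labs), 2)
  v <- apply(TPDA, 1, stats::var)
  r <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    if (v[i] == 0 || v[j] == 0) return(NA_real_)
    stats::cor(TPDA[i, ], TPDA[j, ])
  }, numeric(1))
  df <- data.frame(a = labs[pairs[1, ]], b = labs[pairs[2, ]], r = r,
                   defined = !is.na(r), stringsAsFactors = FALSE)
  df[order(-abs(ifelse(is.na(df$r), -Inf, df$r)), df$a, df$b), ,
     drop = FALSE]
}

#' Perturbation impact difference between two conditions
#'
#' For perturbations measured under two experimental conditions, the PID is
#' the ratio of the perturbation's share of total TPDS in condition 2 to
#' its share in condition 1: values far from 1 mark effects that changed.
#' Restricted to perturbations present in both conditions; a zero
#' condition-1 TPDS makes the ratio undefined (Inf, flagged).
#'
#' @param tpds_cond1,tpds_cond2 named TPDS vectors (or the data.frames from
#'   [overall_ranking]).
#' @return data.frame (`perturbation`, `TPDS_cond1`, `TPDS_cond2`, `PID`,
#'   `abs_log_PID`) sorted by decreasing `|ln PID|`.
#' @export
pid <- function(tpds_cond1, tpds_cond2) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$TPDS, x$perturbation) else x
  }
  t1 <- as_vec(tpds_cond1); t2 <- as_vec(tpds_cond2)
  common <- intersect(names(t1), names(t2))
  if (!length(common)) stop("no common perturbations between conditions")
  t1 <- t1[common]; t2 <- t2[common]
  if (sum(t1) <= 0 || sum(t2) <= 0)
    stop("each condition's TPDS must have positive sum")
  share1 <- t1 / sum(t1); share2 <- t2 / sum(t2)
  p <- ifelse(share1 == 0, Inf, share2 / share1)
  df <- data.frame(perturbation = common, TPDS_cond1 = t1, TPDS_cond2 = t2,
                   PID = p, abs_log_PID = abs(log(p)),
                   row.names = NULL, stringsAsFactors = FALSE)
  df[order(-df$abs_log_PID, df$perturbation), , drop = FALSE]
}

#' Compute the full perturbation-effect profile from a topic model
#'
#' Convenience wrapper running [normalize_theta], [tpd], [tpd_random],
#' [tpda], [tpdr], [topic_specific_scores] and [overall_ranking] in one
#' call. Fully reproducible from `(theta, labels, seed)`.
#'
#' @param theta cells x topics matrix (from [fit_lda]).
#' @param perturbation per-cell labels aligned to the rows of `theta`.
#' @param control_label reserved control label.
#' @param n_boot bootstrap repetitions for TPD (default 1000).
#' @param n_thresh null repetitions for the CS thresholds (default 1000).
#' @param seed master seed.
#' @return an `EffectProfile`: list with `TPD`, `TPD_random`, `TPDA`,
#'   `TPDR`, `CS`, `CS_threshold`, `CS_significant`, `ranking`,
#'   `correlations`, `M`, `n_boot`, `seed`.
#' @export
effect_profile <- function(theta, perturbation, control_label = "CTRL",
                           n_boot = 1000, n_thresh = 1000, seed = 1) {
  theta <- as.matrix(theta)
  stopifnot(length(perturbation) == nrow(theta))
  ctrl_idx <- which(perturbation == control_label)
  nt <- normalize_theta(theta, ctrl_idx)
  M <- min_pert_cells(perturbation, control_label)
  TPD <- tpd(nt, perturbation, control_label, M = M, n_boot = n_boot,
             seed = seed)
  TPDr <- tpd_random(nt, ctrl_idx, M = M, n_boot = n_boot, seed = seed)
  TPDA <- tpda(TPD, TPDr)
  TPDR <- tpdr(TPD)
  cs <- if (ncol(TPD) >= 2)
    topic_specific_scores(TPD, TPDR, nt, ctrl_idx, M = M,
                          n_reps = n_thresh, seed = seed)
  else list(CS = NULL, threshold = NULL, significant = NULL)
  ranking <- overall_ranking(TPDA)
  cors <- if (nrow(TPD) >= 2) perturbation_correlations(TPDA) else NULL
  structure(list(TPD = TPD, TPD_random = TPDr, TPDA = TPDA, TPDR = TPDR,
                 CS = cs$CS, CS_threshold = cs$threshold,
                 CS_significant = cs$significant, ranking = ranking,
                 correlations = cors, M = M, n_boot = n_boot, seed = seed),
            class = "EffectProfile")
}

#' @export
print.EffectProfile <- function(x, ...) {
  cat(sprintf("EffectProfile: %d perturbations x %d topics (M=%d, n_boot=%d, seed=%d)\n",
              nrow(x$TPD), ncol(x$TPD), x$M, x$n_boot, x$seed))
  cat("Top of overall ranking:\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Robustness of the overall ranking to pseudo-perturbations
#'
#' Repeatedly relabels a random `frac` (default 20%) of the control cells
#' as a pseudo-perturbation, reruns the effect ranking against the
#' remaining controls, and records (a) the fraction of real perturbations
#' that rank below the pseudo-perturbation and (b) the Pearson correlation
#' of the real perturbations' normalized TPDS with the unrelabeled run. A
#' robust pipeline keeps both the below-rate low and the correlation high.
#'
#' @param theta cells x topics matrix.
#' @param perturbation per-cell labels.
#' @param control_label reserved control label.
#' @param frac fraction of controls relabeled per repetition.
#' @param n_reps repetitions (default 10).
#' @param n_boot bootstrap repetitions per run.
#' @param seed master seed; repetition r uses `seed + r`.
#' @return list with `mean_below_rate`, `mean_correlation` and `per_rep`
#'   (data.frame with one row per repetition).
#' @export
robustness_test <- function(theta, perturbation, control_label = "CTRL",
                            frac = 0.2, n_reps = 10, n_boot = 1000,
                            seed = 1) {
  theta <- as.matrix(theta)
  ctrl_idx <- which(perturbation == control_label)
  n_take <- floor(frac * length(ctrl_idx))
  if (n_take < 2 || length(ctrl_idx) - n_take < 2)
    stop("too few control cells to split off a pseudo-perturbation")
  base <- effect_profile(theta, perturbation, control_label,
                         n_boot = n_boot, n_thresh = 2, seed = seed)
  base_norm <- stats::setNames(base$ranking$TPDS_norm,
                               base$ranking$perturbation)
  pseudo <- ".pseudo_control"
  per_rep <- data.frame(rep = seq_len(n_reps), below_rate = NA_real_,
                        correlation = NA_real_)
  for (r in seq_len(n_reps)) {
    take <- with_seed(seed + r, sample(ctrl_idx, n_take))
    lab <- perturbation
    lab[take] <- pseudo
    prof <- effect_profile(theta, lab, control_label, n_boot = n_boot,
                           n_thresh = 2, seed = seed + r)
    tpds <- stats::setNames(prof$ranking$TPDS, prof$ranking$perturbation)
    real <- setdiff(names(tpds), pseudo)
    per_rep$below_rate[r] <- mean(tpds[real] < tpds[pseudo])
    norm <- stats::setNames(prof$ranking$TPDS_norm,
                            prof$ranking$perturbation)
    per_rep$correlation[r] <- stats::cor(base_norm[real], norm[real])
  }
  list(mean_below_rate = mean(per_rep$below_rate),
       mean_correlation = mean(per_rep$correlation),
       per_rep = per_rep)
}
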