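random_theta <- function(n_cells, n_topics, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n_cells * n_topics, 1), n_cells, n_topics)
  th <- g / rowSums(g)
  dimnames(th) <- list(paste0("c", seq_len(n_cells)),
                       paste0("topic", seq_len(n_topics)))
  th
}

test_that("normalize_theta standardises against the control population", {
  th <- random_theta(50, 4)
  ctrl <- 1:20
  nt <- normalize_theta(th, ctrl)
  expect_equal(colMeans(nt[ctrl, ]), rep(0, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(nt[ctrl, ], 2, sd), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # brute-force agreement
  mu <- colMeans(th[ctrl, ]); s <- apply(th[ctrl, ], 2, sd)
  expect_equal(nt, t((t(th) - mu) / s), tolerance = 1e-12)
  # constant control column takes the epsilon guard
  th2 <- th; th2[ctrl, 1] <- 0.3
  expect_warning(normalize_theta(th2, ctrl), "constant")
  expect_error(normalize_theta(th, 1), "at least 2")
})

test_that("pooled_t reproduces the textbook pooled two-sample statistic", {
  x <- c(1, 2, 3); y <- c(0, 0, 0)
  expect_equal(pooled_t(x, y), 2 / sqrt(((2 * 1 + 2 * 0) / 4) * (2 / 3)),
               tolerance = 1e-12)
  # oracle: equal-variance t.test over random draws
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(7 + i); b <- rnorm(12, mean = 0.5)
    expect_equal(pooled_t(a, b),
                 unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
    expect_equal(pooled_t(a, b), -pooled_t(b, a))
  }
  expect_equal(pooled_t(x, x), 0)
  expect_equal(pooled_t(c(1, 1), c(0, 0)), Inf)
  expect_error(pooled_t(1, c(1, 2)), "at least 2")
})

test_that("tpd is a seeded bootstrap median, degenerate at n_i = M", {
  th <- random_theta(60, 3, seed = 12)
  pert <- c(rep("A", 10), rep("B", 20), rep("CTRL", 30))
  nt <- normalize_theta(th, which(pert == "CTRL"))
  T1 <- tpd(nt, pert, M = 10, n_boot = 50, seed = 3)
  # perturbation A has exactly M cells: every draw is the full population,
  # so the bootstrap median equals the single pooled t value
  ctrl <- nt[pert == "CTRL", ]
  direct <- vapply(1:3, function(j)
    pooled_t(nt[pert == "A", j], ctrl[, j]), numeric(1))
  expect_equal(unname(T1["A", ]), direct, tolerance = 1e-12)
  # determinism and invariance to cell order
  T2 <- tpd(nt, pert, M = 10, n_boot = 50, seed = 3)
  expect_identical(T1, T2)
  p <- sample(60)
  T3 <- tpd(nt[p, ], pert[p], M = 10, n_boot = 50, seed = 3)
  expect_equal(T3, T1, tolerance = 1e-9)
  # n_boot = 1 reproduces one seeded pooled_t evaluation
  T4 <- tpd(nt, pert, M = 10, n_boot = 1, seed = 3)
  expect_equal(unname(T4["A", ]), direct, tolerance = 1e-12)
})

test_that("tpd and tpd_random are near zero under the null at M >= 20", {
  # the perturbation's normalized topic columns equal the controls': the
  # control population is four copies of the perturbed cells' rows
  th40 <- random_theta(40, 3, seed = 21)
  th <- rbind(th40, th40[rep(1:40, 4), ])
  rownames(th) <- paste0("c", 1:200)
  pert <- c(rep("NULLP", 40), rep("CTRL", 160))
  nt <- normalize_theta(th, which(pert == "CTRL"))
  T1 <- tpd(nt, pert, M = 30, n_boot = 200, seed = 5)
  expect_true(all(abs(T1) < 0.5))
  tr <- tpd_random(nt, which(pert == "CTRL"), M = 30, n_boot = 200, seed = 5)
  expect_true(all(abs(tr) < 0.5))
  # the baseline ignores perturbation labels entirely (same control set)
  tr2 <- tpd_random(nt, which(pert == "CTRL"), M = 30, n_boot = 200,
                    seed = 5)
  expect_identical(tr, tr2)
})

test_that("tpda subtracts the per-topic baseline elementwise", {
  set.seed(2)
  TPD <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("P", 1:4), NULL))
  base <- rnorm(3)
  A <- tpda(TPD, base)
  expect_equal(A, TPD - matrix(base, 4, 3, byrow = TRUE))
  expect_equal(tpda(TPD, rep(0, 3)), TPD)
  expect_equal(unname(tpda(TPD, TPD[2, ])[2, ]), rep(0, 3))
  expect_error(tpda(TPD, rnorm(2)))
})

test_that("tpdr computes per-topic shares of |TPD| summing to one", {
  TPD <- matrix(c(2, -1, 1), 1, 3, dimnames = list("P1", NULL))
  expect_equal(unname(tpdr(TPD)[1, ]), c(0.5, 0.25, 0.25))
  one <- matrix(c(0, 3, 0), 1, 3)
  expect_equal(as.vector(tpdr(one)), c(0, 1, 0))
  set.seed(6)
  R <- tpdr(matrix(rnorm(30), 5, 6))
  expect_equal(rowSums(R), rep(1, 5), tolerance = 1e-9)
  # perturbation-sum variant normalises columns instead
  Rc <- tpdr(matrix(abs(rnorm(30)), 5, 6), sum_over = "perturbations")
  expect_equal(colSums(Rc), rep(1, 6), tolerance = 1e-9)
})

test_that("topic-specific CS hits its extremes and stays within [0, 1]", {
  TPD <- matrix(c(5, 1, 0.5,
                  -2, 4, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("P1", "P2"), paste0("topic", 1:3)))
  R <- tpdr(TPD)
  cs <- topic_specific_scores(TPD, R)
  # P1: topic 1 is both the max |TPD| and the max share -> CS = 1; topic 3
  # sits at both minima -> CS = 0
  expect_equal(cs$CS["P1", 1], 1)
  expect_equal(cs$CS["P1", 3], 0)
  set.seed(13)
  TPDr <- matrix(rnorm(40), 8, 5)
  rownames(TPDr) <- paste0("P", 1:8)
  csr <- topic_specific_scores(TPDr, tpdr(TPDr))
  expect_true(all(csr$CS >= 0 & csr$CS <= 1))
  expect_error(topic_specific_scores(TPD[, 1, drop = FALSE],
                                     R[, 1, drop = FALSE]), "at least 2")
})

test_that("CS thresholds come from seeded null draws and gate significance", {
  th <- random_theta(150, 3, seed = 33)
  pert <- c(rep("A", 30), rep("CTRL", 120))
  nt <- normalize_theta(th, which(pert == "CTRL"))
  TPD <- tpd(nt, pert, M = 30, n_boot = 100, seed = 7)
  res <- topic_specific_scores(TPD, tpdr(TPD), nt, which(pert == "CTRL"),
                               M = 30, n_reps = 100, seed = 7)
  expect_length(res$threshold, 3)
  expect_true(all(res$threshold >= 0 & res$threshold <= 1))
  expect_identical(res$significant, sweep(res$CS, 2, res$threshold, ">"))
  res2 <- topic_specific_scores(TPD, tpdr(TPD), nt, which(pert == "CTRL"),
                                M = 30, n_reps = 100, seed = 7)
  expect_identical(res$threshold, res2$threshold)
})

test_that("overall ranking sums |TPDA| with deterministic tie-breaking", {
  TPDA <- rbind(P_zero = c(0, 0, 0), P_big = c(5, 0, 0), P_neg = c(-3, 0, 0))
  r <- overall_ranking(TPDA)
  expect_equal(r$perturbation, c("P_big", "P_neg", "P_zero"))
  expect_equal(r$TPDS, c(5, 3, 0))
  expect_equal(r$TPDS_norm, c(1, 0.6, 0))
  set.seed(14)
  M <- matrix(rnorm(21), 7, 3, dimnames = list(paste0("P", 1:7), NULL))
  expect_equal(overall_ranking(M)$TPDS,
               sort(rowSums(abs(M)), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("perturbation correlations match direct Pearson computation", {
  A <- rbind(P1 = c(1, 2, 3, 4), P2 = c(2, 4, 6, 8), P3 = c(-1, -2, -3, -4),
             P4 = c(5, 5, 5, 5))
  e <- perturbation_correlations(A)
  get <- function(a, b) e$r[(e$a == a & e$b == b) | (e$a == b & e$b == a)]
  expect_equal(get("P1", "P2"), 1)
  expect_equal(get("P1", "P3"), -1)
  expect_true(is.na(get("P1", "P4")))          # zero-variance row flagged
  set.seed(15)
  B <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("Q", 1:4), NULL))
  eb <- perturbation_correlations(B)
  for (k in seq_len(nrow(eb)))
    expect_equal(eb$r[k], cor(B[eb$a[k], ], B[eb$b[k], ]), tolerance = 1e-12)
  expect_error(perturbation_correlations(A[1, , drop = FALSE]), "at least 2")
})

test_that("PID is the ratio of TPDS shares, scale invariant, 1 under identity", {
  t1 <- c(A = 2, B = 3, C = 5)
  expect_equal(pid(t1, t1)$PID, rep(1, 3))
  expect_equal(pid(t1, t1 * 2)$PID, rep(1, 3))     # shares are scale free
  t2 <- c(A = 4, B = 3, C = 5)
  tab <- pid(t1, t2)
  # hand-computed: shares cond1 = (0.2, 0.3, 0.5); cond2 = (1/3, 0.25, 5/12)
  expect_equal(tab$PID[tab$perturbation == "A"], (4 / 12) / 0.2)
  expect_equal(tab$PID[tab$perturbation == "B"], (3 / 12) / 0.3)
  expect_equal(tab$PID[tab$perturbation == "C"], (5 / 12) / 0.5)
  expect_equal(tab$perturbation[1], "A")           # largest |ln PID| first
  expect_error(pid(c(X = 1), c(Y = 1)), "no common")
  # zero condition-1 TPDS flagged infinite
  expect_true(is.infinite(pid(c(A = 0, B = 1), c(A = 1, B = 1))$PID[1]))
})

test_that("the full effect profile is reproducible bitwise from (theta, seed)", {
  th <- random_theta(130, 3, seed = 44)
  pert <- c(rep(c("A", "B", "C"), each = 20), rep("CTRL", 70))
  p1 <- effect_profile(th, pert, n_boot = 60, n_thresh = 60, seed = 17)
  p2 <- effect_profile(th, pert, n_boot = 60, n_thresh = 60, seed = 17)
  expect_identical(p1$TPD, p2$TPD)
  expect_identical(p1$ranking, p2$ranking)
  expect_identical(p1$CS_threshold, p2$CS_threshold)
  # invariance to label iteration order: shuffle cells
  o <- sample(130)
  p3 <- effect_profile(th[o, ], pert[o], n_boot = 60, n_thresh = 60,
                       seed = 17)
  expect_equal(p3$TPD, p1$TPD, tolerance = 1e-9)
})

test_that("robustness: pseudo-control perturbations land at the bottom of the ranking", {
  sim <- default_sim(seed = 202)
  prof_theta <- sim$truth$theta_true   # exact topic proportions
  rb <- robustness_test(prof_theta, sim$dataset$perturbation,
                        frac = 0.2, n_reps = 3, n_boot = 80, seed = 6)
  expect_lte(rb$mean_below_rate, 0.15)
  expect_gte(rb$mean_correlation, 0.9)
  rb2 <- robustness_test(prof_theta, sim$dataset$perturbation,
                         frac = 0.2, n_reps = 1, n_boot = 80, seed = 6)
  rb3 <- robustness_test(prof_theta, sim$dataset$perturbation,
                         frac = 0.2, n_reps = 1, n_boot = 80, seed = 6)
  expect_identical(rb2, rb3)
  expect_error(robustness_test(prof_theta, sim$dataset$perturbation,
                               frac = 0.001, n_reps = 1), "too few")
})
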