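test_that("qc_filter_cells applies the detected-gene, UMI and mito-fraction rules", {
  # cell 1: 600 detected genes, 1200 UMI, mito fraction 30/600 = 0.05 -> kept
  # cell 2: 499 detected genes -> removed
  # cell 3: high mito detected fraction -> removed
  n_genes <- 1000
  genes <- c(paste0("MT-", 1:100), paste0("G", 1:(n_genes - 100)))
  m <- matrix(0, 3, n_genes, dimnames = list(paste0("c", 1:3), genes))
  m[1, c(1:30, 101:670)] <- 2                      # 600 genes, 30 mito
  m[2, 101:599] <- 3                               # 499 genes, 1497 UMI
  m[3, c(1:100, 101:500)] <- 3                     # mito fraction 0.2
  ds <- tiny_dataset(m, rep("CTRL", 3))
  suppressMessages(kept <- qc_filter_cells(ds, QCThresholds(500, 1000, 0.10)))
  expect_equal(kept$cell_ids, "c1")
  # all-permissive thresholds are the identity filter
  suppressMessages(all_kept <- qc_filter_cells(ds, QCThresholds(0, 0, 1)))
  expect_equal(all_kept$cell_ids, ds$cell_ids)
  expect_error(suppressMessages(
    qc_filter_cells(ds, QCThresholds(10000, 0, 1))), "every cell")
})

test_that("impute: none is identity; shrink fills zeros with lambda * nonzero mean", {
  m <- matrix(c(10, 0, 10, 0,
                0, 0, 0, 0,
                3, 6, 0, 0), 4, 3,
              dimnames = list(paste0("c", 1:4), paste0("G", 1:3)))
  ds <- tiny_dataset(m, rep("CTRL", 4))
  expect_identical(as.matrix(impute(ds, "none")$counts), m)
  sh <- as.matrix(impute(ds, "shrink", lambda = 0.1)$counts)
  expect_equal(unname(sh[c(2, 4), 1]), c(1, 1))    # mean over nonzero = 10
  expect_equal(unname(sh[, 2]), c(0, 0, 0, 0))     # all-zero gene untouched
  expect_equal(unname(sh[1:2, 3]), c(3, 6))        # nonzero entries preserved
  expect_error(impute(ds, "magic"))
})

test_that("filter_zero_perturbations drops silent-target labels and warns on unmatched ones", {
  m <- matrix(1, 6, 3, dimnames = list(paste0("c", 1:6), c("G1", "G2", "G3")))
  m[, "G1"] <- 0
  ds <- suppressWarnings(
    tiny_dataset(m, c("G1", "G1", "G2", "NTC-like", "CTRL", "CTRL")))
  w <- testthat::capture_warnings(
    suppressMessages(res <- filter_zero_perturbations(ds)))
  expect_true(any(grepl("no matching gene row", w)))
  expect_equal(res$dropped, "G1")
  expect_false(any(res$dataset$perturbation == "G1"))
  expect_true("NTC-like" %in% res$dataset$perturbation)   # unmatched label kept
})

test_that("ks_de_genes matches a gene-by-gene KS oracle and handles degenerate input", {
  set.seed(42)
  case <- matrix(rnorm(30 * 5, mean = c(0, 0, 2, 0, 5)), 30, 5, byrow = TRUE)
  control <- matrix(rnorm(40 * 5), 40, 5)
  colnames(case) <- colnames(control) <- paste0("G", 1:5)
  got <- ks_de_genes(case, control, alpha = 0.05)
  oracle <- colnames(case)[vapply(1:5, function(j)
    suppressWarnings(stats::ks.test(case[, j], control[, j],
                                    exact = FALSE)$p.value) < 0.05,
    logical(1))]
  expect_identical(got, oracle)
  # identical distributions -> nothing significant
  expect_length(ks_de_genes(control[1:20, ], control[21:40, ]), 0)
  # maximal separation -> included
  case2 <- matrix(100, 30, 1, dimnames = list(NULL, "G1"))
  ctrl2 <- matrix(0, 30, 1, dimnames = list(NULL, "G1"))
  expect_identical(ks_de_genes(case2, ctrl2), "G1")
  expect_error(ks_de_genes(case[1, , drop = FALSE], control), "at least 2")
})

test_that("efficiency filter removes cells at the cosine extremes exactly as defined", {
  # controls expressed on genes 1:3; perturbed peers on genes 4:6; one
  # perturbed cell identical to controls and orthogonal to peers
  m <- rbind(matrix(rep(c(5, 5, 5, 0, 0, 0), 10), 10, byrow = TRUE),  # CTRL
             matrix(rep(c(0, 0, 0, 5, 5, 5), 9), 9, byrow = TRUE),    # G9 edited
             c(5, 5, 5, 0, 0, 0))                                     # G9 escaper
  rownames(m) <- paste0("c", 1:20)
  colnames(m) <- paste0("G", 1:6)
  m <- m + matrix(runif(120, 0, 0.01), 20)  # break exact ties in the KS test
  ds <- suppressWarnings(tiny_dataset(m, c(rep("CTRL", 10), rep("G9", 10))))
  suppressMessages(suppressWarnings(
    res <- efficiency_filter(ds, alpha = 0.05, drop_fraction = 0.9)))
  rep_row <- res$report[res$report$cell_id == "c20", ]
  expect_true(rep_row$removed)
  expect_gt(rep_row$M_C, rep_row$M_P)
  expect_false("c20" %in% res$dataset$cell_ids)
  # edited peers are all retained
  expect_true(all(paste0("c", 11:19) %in% res$dataset$cell_ids))
  # controls never filtered
  expect_true(all(paste0("c", 1:10) %in% res$dataset$cell_ids))
})

test_that("efficiency filter drops nothing when all perturbed cells agree", {
  m <- rbind(matrix(rep(c(4, 4, 0, 0), 8), 8, byrow = TRUE),
             matrix(rep(c(0, 0, 4, 4), 8), 8, byrow = TRUE))
  rownames(m) <- paste0("c", 1:16)
  colnames(m) <- paste0("G", 1:4)
  m <- m + matrix(runif(64, 0, 0.01), 16)
  ds <- suppressWarnings(tiny_dataset(m, c(rep("CTRL", 8), rep("G9", 8))))
  suppressMessages(suppressWarnings(
    res <- efficiency_filter(ds)))
  expect_equal(nrow(res$dataset$counts), 16L)
  expect_false(any(res$report$removed))
})

test_that("a perturbation whose cells all sit closer to controls than to each other is dropped whole", {
  # controls are tight noisy copies of one profile; the perturbation's cells
  # carry much larger independent noise around the same profile, so every
  # perturbed cell is more similar to the controls than to its peers and the
  # 90% rule removes the label entirely
  set.seed(55)
  base <- rep(50, 20)
  ctrl <- t(replicate(30, base + rnorm(20, sd = 0.2)))
  pert <- t(replicate(10, base + rnorm(20, sd = 20)))
  m <- pmax(rbind(ctrl, pert), 0)
  rownames(m) <- paste0("c", 1:40)
  colnames(m) <- paste0("G", 1:20)
  ds <- suppressWarnings(tiny_dataset(m, c(rep("CTRL", 30), rep("G9", 10))))
  suppressMessages(suppressWarnings(
    res <- efficiency_filter(ds, alpha = 0.05, drop_fraction = 0.9)))
  expect_equal(attr(res$report, "dropped_perturbations"), "G9")
  expect_false(any(res$dataset$perturbation == "G9"))
})

test_that("efficiency filter decisions are invariant to cell and gene order", {
  sim <- default_sim(seed = 77)
  ds <- sim$dataset
  suppressMessages(suppressWarnings(r1 <- efficiency_filter(ds)))
  set.seed(1)
  cp <- sample(nrow(ds$counts)); gp <- sample(ncol(ds$counts))
  ds2 <- ScreenDataset(ds$counts[cp, gp], ds$perturbation[cp])
  suppressMessages(suppressWarnings(r2 <- efficiency_filter(ds2)))
  expect_setequal(r1$dataset$cell_ids, r2$dataset$cell_ids)
})

test_that("min_cell_filter drops below-threshold labels, keeps the boundary, guards controls", {
  m <- matrix(rpois(100 * 3, 2), 100, 3)
  rownames(m) <- paste0("c", 1:100)
  colnames(m) <- c("G1", "G2", "G3")
  pert <- c(rep("G1", 29), rep("G2", 30), rep("CTRL", 41))
  ds <- tiny_dataset(m, pert)
  suppressMessages(res <- min_cell_filter(ds, 30))
  expect_equal(res$dropped, "G1")
  expect_true(all(c("G2", "CTRL") %in% res$dataset$perturbation))
  expect_equal(sum(res$dataset$perturbation == "G2"), 30L)
  # min_cells = 0 is the identity
  expect_equal(min_cell_filter(ds, 0)$dataset$cell_ids, ds$cell_ids)
  # too few controls is fatal
  ds2 <- tiny_dataset(m, c(rep("G1", 60), rep("CTRL", 40)))
  expect_error(min_cell_filter(ds2, 50), "control")
})
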