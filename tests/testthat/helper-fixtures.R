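# Fixture builders shared across the suite; everything is generated in code.

# tiny dataset with explicit counts
tiny_dataset <- function(counts, perturbation, ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("c", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("G", seq_len(ncol(counts)))
  ScreenDataset(counts, perturbation, ...)
}

# write a simulated screen's MTX bundle into a temp dir, return paths
write_mtx_fixture <- function(counts, perturbation, dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  rn <- rownames(counts); cn <- colnames(counts)
  Matrix::writeMM(Matrix::t(Matrix::Matrix(counts, sparse = TRUE)),
                  file.path(dir, "matrix.mtx"))
  writeLines(rn, file.path(dir, "barcodes.tsv"))
  writeLines(cn, file.path(dir, "genes.tsv"))
  write.table(data.frame(cell_id = rn, perturbation = perturbation),
              file.path(dir, "perturbations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(matrix = file.path(dir, "matrix.mtx"),
       barcodes = file.path(dir, "barcodes.tsv"),
       genes = file.path(dir, "genes.tsv"),
       perturbations = file.path(dir, "perturbations.tsv"),
       dir = dir)
}

# best-permutation mean Pearson correlation between recovered and true theta
best_perm_cor <- function(theta, theta_true) {
  k <- ncol(theta)
  perms <- asplit(perms_matrix(k), 1)
  max(vapply(perms, function(p)
    mean(diag(stats::cor(theta[, p, drop = FALSE], theta_true))),
    numeric(1)))
}

perms_matrix <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) cbind(i, sub + (sub >= i))))
}

# a moderate simulated screen reused by several effect-statistics tests
default_sim <- function(seed = 101, ...) {
  simulate_screen(SimConfig(n_perturbations = 4,
                            n_cells_per_perturbation = 50,
                            n_control_cells = 120, n_genes = 200,
                            seed = seed, ...))
}

# independent oracle for the mismatch search: all-window Hamming scan in plain R
brute_force_candidates <- function(sgrna, transcripts, max_mismatch) {
  sg <- strsplit(toupper(sgrna), "")[[1]]
  k <- length(sg)
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                 collapse = ""))
  res <- list()
  for (g in names(transcripts)) {
    best <- Inf
    for (seqs in c(toupper(transcripts[[g]]), rc(toupper(transcripts[[g]])))) {
      ch <- strsplit(seqs, "")[[1]]
      if (length(ch) < k) next
      for (s in 1:(length(ch) - k + 1)) {
        d <- sum(ch[s:(s + k - 1)] != sg)
        if (d < best) best <- d
      }
    }
    if (best <= max_mismatch)
      res[[g]] <- data.frame(candidate_gene = g, mismatches = best)
  }
  if (!length(res)) return(data.frame(candidate_gene = character(),
                                      mismatches = integer()))
  do.call(rbind, res)
}

random_tx <- function(n, len, seed) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""),
    character(1)), paste0("T", seq_len(n)))
}

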