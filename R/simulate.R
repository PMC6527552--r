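#' Configuration for a synthetic single-cell CRISPR screen
#'
#' The generator mirrors the topic-model view of a screen: each topic is a
#' distribution over genes, each cell a Dirichlet-distributed mixture of
#' topics, and a perturbation shifts its target cells' mixtures toward one
#' designated topic. A fraction of guide-carrying cells escape editing and
#' keep the wild-type (control) expression program while retaining the
#' perturbed label — the generator's `escaper_fraction` default of 0.25
#' matches the 20-30% of sgRNA-positive cells that show no functional edit.
#'
#' @param n_perturbations number of perturbed gene labels.
#' @param n_cells_per_perturbation cells per perturbation (default 60).
#' @param n_control_cells control cells (default 200).
#' @param n_genes genes (default 300).
#' @param n_topics_true planted topic count (default 3).
#' @param dirichlet_base concentration of the control topic law (scalar or
#'   per-topic vector, default 1).
#' @param effect_sizes per-perturbation concentration added to the assigned
#'   topic (default 4 for every perturbation); 0 plants a null perturbation.
#' @param escaper_fraction fraction of perturbed cells drawn from the
#'   control law (default 0.25).
#' @param library_size mean tokens per cell, Poisson (default 1000).
#' @param dropout_rate independent zeroing probability per entry
#'   (default 0.2).
#' @param phi_concentration symmetric Dirichlet concentration of the
#'   per-topic gene loadings; small values give well-separated topics
#'   (default 0.1).
#' @param knockdown_factor scaling of the target gene's counts in edited
#'   cells (default 0.1).
#' @param seed integer seed.
#' @return a `SimConfig` list.
#' @export
SimConfig <- function(n_perturbations = 5, n_cells_per_perturbation = 60,
                      n_control_cells = 200, n_genes = 300,
                      n_topics_true = 3, dirichlet_base = 1,
                      effect_sizes = rep(4, n_perturbations),
                      escaper_fraction = 0.25, library_size = 1000,
                      dropout_rate = 0.2, phi_concentration = 0.1,
                      knockdown_factor = 0.1, seed = 1) {
  if (length(dirichlet_base) == 1)
    dirichlet_base <- rep(dirichlet_base, n_topics_true)
  stopifnot(length(dirichlet_base) == n_topics_true,
            all(dirichlet_base > 0),
            length(effect_sizes) == n_perturbations,
            all(effect_sizes >= 0),
            escaper_fraction >= 0, escaper_fraction < 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(n_perturbations = n_perturbations,
                 n_cells_per_perturbation = n_cells_per_perturbation,
                 n_control_cells = n_control_cells, n_genes = n_genes,
                 n_topics_true = n_topics_true,
                 dirichlet_base = dirichlet_base,
                 effect_sizes = effect_sizes,
                 escaper_fraction = escaper_fraction,
                 library_size = library_size, dropout_rate = dropout_rate,
                 phi_concentration = phi_concentration,
                 knockdown_factor = knockdown_factor, seed = seed),
            class = "SimConfig")
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a single-cell CRISPR screen with planted structure
#'
#' Draws per-topic gene distributions from a symmetric Dirichlet, per-cell
#' topic proportions from the control Dirichlet law (shifted on the
#' assigned topic for edited cells), token counts from a multinomial at a
#' Poisson library size, then applies independent dropout and scales the
#' target gene's counts down in edited cells to emulate the knockdown.
#' Perturbation k targets gene `G<k>` and is assigned topic
#' `1 + (k-1) mod n_topics_true`.
#'
#' @param config a [SimConfig].
#' @return list with `dataset` (a [ScreenDataset]) and `truth` (a
#'   `SimTruth`: `theta_true` cells x topics, `escaper` logical per cell,
#'   `phi_true` topics x genes, `assignment` data.frame of per-perturbation
#'   topic and effect size).
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, simulate_screen_impl(config))
}

simulate_screen_impl <- function(config) {
  K <- config$n_topics_true
  G <- config$n_genes
  phi_true <- rdirichlet(K, rep(config$phi_concentration, G))
  colnames(phi_true) <- paste0("G", seq_len(G))
  rownames(phi_true) <- paste0("topic", seq_len(K))
  simulate_screen_impl_shared_phi(config, phi_true)
}

#' Simulate the same screen under two experimental conditions
#'
#' Condition 1 uses the configured effect sizes; condition 2 multiplies
#' them by per-perturbation `modulation` factors. The per-topic gene
#' loadings are shared between conditions (same seed for the loadings;
#' cell-level draws use offset seeds).
#'
#' @param config a [SimConfig].
#' @param modulation non-negative factor per perturbation.
#' @return list of two `list(dataset, truth)` pairs named `cond1`, `cond2`.
#' @export
simulate_two_conditions <- function(config, modulation) {
  stopifnot(length(modulation) == config$n_perturbations,
            all(modulation >= 0))
  cfg2 <- config
  cfg2$effect_sizes <- config$effect_sizes * modulation
  cfg2$seed <- config$seed + 1L
  c1 <- simulate_screen(config)
  # share the gene loadings: regenerate condition 2 with the same phi_true
  c2 <- with_seed(cfg2$seed,
                  simulate_screen_impl_shared_phi(cfg2, c1$truth$phi_true))
  c1$dataset$condition <- rep("cond1", nrow(c1$dataset$counts))
  c2$dataset$condition <- rep("cond2", nrow(c2$dataset$counts))
  list(cond1 = c1, cond2 = c2)
}

simulate_screen_impl_shared_phi <- function(config, phi_true) {
  # identical to simulate_screen_impl but with fixed gene loadings
  K <- config$n_topics_true
  G <- config$n_genes
  genes <- colnames(phi_true)
  labels <- paste0("G", seq_len(config$n_perturbations))
  topic_of <- 1 + (seq_len(config$n_perturbations) - 1) %% K
  n_cells <- config$n_perturbations * config$n_cells_per_perturbation +
    config$n_control_cells
  pert <- c(rep(labels, each = config$n_cells_per_perturbation),
            rep("CTRL", config$n_control_cells))
  cell_ids <- sprintf("cell%04d", seq_len(n_cells))
  escaper <- rep(FALSE, n_cells)
  theta_true <- matrix(0, n_cells, K,
                       dimnames = list(cell_ids, rownames(phi_true)))
  for (i in seq_len(n_cells)) {
    lab <- pert[i]
    base <- config$dirichlet_base
    if (lab != "CTRL") {
      k <- match(lab, labels)
      esc <- stats::runif(1) < config$escaper_fraction
      escaper[i] <- esc
      if (!esc && config$effect_sizes[k] > 0)
        base[topic_of[k]] <- base[topic_of[k]] + config$effect_sizes[k]
    }
    theta_true[i, ] <- rdirichlet(1, base)
  }
  counts <- matrix(0L, n_cells, G, dimnames = list(cell_ids, genes))
  for (i in seq_len(n_cells)) {
    lib <- stats::rpois(1, config$library_size)
    if (lib > 0)
      counts[i, ] <- stats::rmultinom(1, lib,
                                      as.vector(theta_true[i, ] %*% phi_true))
  }
  if (config$dropout_rate > 0) {
    drop <- matrix(stats::runif(length(counts)) < config$dropout_rate,
                   nrow(counts), ncol(counts))
    counts[drop] <- 0L
  }
  for (k in seq_along(labels)) {
    idx <- which(pert == labels[k] & !escaper)
    counts[idx, labels[k]] <-
      as.integer(round(counts[idx, labels[k]] * config$knockdown_factor))
  }
  list(dataset = ScreenDataset(counts, pert),
       truth = structure(list(theta_true = theta_true, escaper = escaper,
                              phi_true = phi_true,
                              assignment = data.frame(
                                perturbation = labels, topic = topic_of,
                                effect_size = config$effect_sizes,
                                stringsAsFactors = FALSE)),
                         class = "SimTruth"))
}

#' Write a simulated screen to disk in pipeline input formats
#'
#' Emits `matrix.mtx` (genes x cells, the common on-disk orientation),
#' `barcodes.tsv`, `genes.tsv`, `perturbations.tsv` and `truth.tsv` under
#' `dir`.
#'
#' @param sim output of [simulate_screen].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_screen <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- sim$dataset
  Matrix::writeMM(Matrix::t(ds$counts), file.path(dir, "matrix.mtx"))
  writeLines(ds$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(ds$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(cell_id = ds$cell_ids, perturbation = ds$perturbation),
    file.path(dir, "perturbations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  truth <- data.frame(cell_id = ds$cell_ids,
                      escaper = sim$truth$escaper,
                      sim$truth$theta_true, check.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
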