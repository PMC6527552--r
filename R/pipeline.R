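#' Run configuration for the end-to-end pipeline
#'
#' Collects every tunable parameter of the pipeline in one serializable
#' object; [run_pipeline] writes the fully resolved configuration alongside
#' its outputs so a run can be reproduced exactly.
#'
#' @param min_genes,min_umi,max_mito_fraction QC thresholds (see
#'   [QCThresholds]).
#' @param mito_prefix mitochondrial gene-id prefix.
#' @param impute_method `"none"` or `"shrink"` (see [impute]).
#' @param ks_alpha KS threshold for the efficiency filter.
#' @param drop_fraction perturbation-drop proportion for the efficiency
#'   filter.
#' @param min_cells minimum cells per perturbation.
#' @param n_dde number of DDE genes.
#' @param n_bins dispersion bins.
#' @param topic_candidates topic counts scanned; a single value skips the
#'   scan and fits that count directly.
#' @param alpha_cs weight of the specificity score in the scan.
#' @param lda_alpha,lda_beta LDA hyperparameters (NULL = `50/n` and 0.1).
#' @param n_iter,burn_in Gibbs sweeps.
#' @param n_boot,n_thresh bootstrap and threshold repetitions.
#' @param seed master seed for every stochastic stage.
#' @return a `RunConfig` list.
#' @export
RunConfig <- function(min_genes = 500, min_umi = 1000,
                      max_mito_fraction = 0.10, mito_prefix = "MT-",
                      impute_method = "none", ks_alpha = 0.05,
                      drop_fraction = 0.90, min_cells = 30,
                      n_dde = 500, n_bins = 20,
                      topic_candidates = 4:6, alpha_cs = 0.5,
                      lda_alpha = NULL, lda_beta = 0.1,
                      n_iter = 1000, burn_in = 500,
                      n_boot = 1000, n_thresh = 1000, seed = 1) {
  structure(as.list(environment()), class = "RunConfig")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

write_stage_table <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# perturbtopics %s config=%s",
                     as.character(utils::packageVersion("perturbtopics")),
                     config_hash(config)), con)
  close(con)
  tmp <- tempfile()
  write_ranking(df, tmp)
  file.append(path, tmp)
  unlink(tmp)
  invisible(path)
}

matrix_to_df <- function(m, label_col = "perturbation") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- label_col
  rownames(df) <- NULL
  df
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes preprocessing (QC, imputation, zero-expression perturbation
#' filter, sgRNA efficiency filter, minimum-cell filter), DDE gene
#' selection and normalization, topic-model fitting with optional
#' topic-number scan, and the perturbation-effect statistics; every
#' intermediate table is written as TSV under `out_dir` together with the
#' resolved configuration. Identical configuration and seed reproduce the
#' outputs byte for byte.
#'
#' @param dataset a [ScreenDataset] of raw counts.
#' @param config a [RunConfig].
#' @param out_dir output directory; NULL skips writing.
#' @param sets optional `GeneSetCollection` for topic annotation.
#' @return list with `dataset` (filtered), `dde`, `model`, `scan`
#'   (NULL without a scan), `profile` (an `EffectProfile`),
#'   `annotation` (NULL without `sets`), `config`.
#' @export
run_pipeline <- function(dataset, config = RunConfig(), out_dir = NULL,
                         sets = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ds <- stage("qc", qc_filter_cells(
    dataset, QCThresholds(config$min_genes, config$min_umi,
                          config$max_mito_fraction),
    mito_prefix = config$mito_prefix))
  ds <- stage("impute", impute(ds, config$impute_method))
  ds <- stage("zero_perturbation", filter_zero_perturbations(ds)$dataset)
  eff <- stage("efficiency", efficiency_filter(
    ds, alpha = config$ks_alpha, drop_fraction = config$drop_fraction))
  ds <- eff$dataset
  ds <- stage("min_cell", min_cell_filter(ds, config$min_cells)$dataset)

  ctrl <- control_cells(ds)
  if (!length(ctrl)) stop("[stage features] no control cells remain")
  m <- as.matrix(ds$counts)
  dde <- stage("features", select_dde_genes(
    m[-ctrl, , drop = FALSE], m[ctrl, , drop = FALSE],
    n_top = config$n_dde, n_bins = config$n_bins))
  mu_ctrl <- colMeans(m[ctrl, dde$genes, drop = FALSE])
  usable <- mu_ctrl > 0
  tokens <- stage("features", normalize_and_round(
    m[, dde$genes[usable], drop = FALSE], mu_ctrl[usable]))

  lda_args <- list(n_iter = config$n_iter, burn_in = config$burn_in)
  if (!is.null(config$lda_alpha)) lda_args$alpha <- config$lda_alpha
  lda_args$beta <- config$lda_beta
  scan <- NULL
  if (length(config$topic_candidates) > 1) {
    scan <- stage("topics", do.call(select_topic_number, c(
      list(counts = tokens, candidates = config$topic_candidates,
           alpha_cs = config$alpha_cs, seed = config$seed), lda_args)))
    model <- attr(scan, "models")[[as.character(attr(scan, "best"))]]
  } else {
    model <- stage("topics", do.call(fit_lda, c(
      list(counts = tokens, n = config$topic_candidates,
           seed = config$seed), lda_args)))
  }
  annotation <- if (!is.null(sets))
    stage("topics", annotate_topics(model, sets))

  # cells dropped from the LDA fit (all-zero token rows) are dropped here too
  kept <- match(rownames(model$theta), ds$cell_ids)
  profile <- stage("effects", effect_profile(
    model$theta, ds$perturbation[kept], control_label = ds$control_label,
    n_boot = config$n_boot, n_thresh = config$n_thresh,
    seed = config$seed))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    write_stage_table(eff$report,
                      file.path(out_dir, "efficiency_report.tsv"), config)
    write_stage_table(data.frame(gene = dde$genes),
                      file.path(out_dir, "dde_genes.tsv"), config)
    write_stage_table(matrix_to_df(model$theta, "cell_id"),
                      file.path(out_dir, "theta.tsv"), config)
    write_stage_table(matrix_to_df(model$phi, "topic"),
                      file.path(out_dir, "phi.tsv"), config)
    if (!is.null(scan))
      write_stage_table(as.data.frame(scan),
                        file.path(out_dir, "topic_scan.tsv"), config)
    if (!is.null(annotation))
      write_stage_table(annotation,
                        file.path(out_dir, "topic_annotation.tsv"), config)
    write_stage_table(matrix_to_df(profile$TPD),
                      file.path(out_dir, "tpd.tsv"), config)
    write_stage_table(matrix_to_df(profile$TPDA),
                      file.path(out_dir, "tpda.tsv"), config)
    write_stage_table(matrix_to_df(profile$TPDR),
                      file.path(out_dir, "tpdr.tsv"), config)
    if (!is.null(profile$CS)) {
      cs_df <- matrix_to_df(profile$CS)
      write_stage_table(cs_df, file.path(out_dir, "cs.tsv"), config)
      write_stage_table(
        data.frame(topic = names(profile$CS_threshold),
                   threshold = profile$CS_threshold, row.names = NULL),
        file.path(out_dir, "cs_thresholds.tsv"), config)
    }
    write_stage_table(profile$ranking,
                      file.path(out_dir, "overall_ranking.tsv"), config)
    if (!is.null(profile$correlations))
      write_stage_table(profile$correlations,
                        file.path(out_dir, "correlations.tsv"), config)
  }
  list(dataset = ds, dde = dde, model = model, scan = scan,
       profile = profile, annotation = annotation, config = config)
}

#' Compare perturbation effects between two conditions
#'
#' Runs the pipeline on each condition's dataset and computes the
#' perturbation impact difference (PID) over the perturbations present in
#' both, sorted by `|ln PID|` descending.
#'
#' @param dataset_a,dataset_b [ScreenDataset]s for the two conditions.
#' @param config_a,config_b [RunConfig]s (default shared).
#' @param out_dir optional output directory for the PID table.
#' @return list with `pid` (data.frame), `run_a`, `run_b`.
#' @export
compare_conditions <- function(dataset_a, dataset_b,
                               config_a = RunConfig(),
                               config_b = config_a, out_dir = NULL) {
  run_a <- run_pipeline(dataset_a, config_a)
  run_b <- run_pipeline(dataset_b, config_b)
  common <- intersect(run_a$profile$ranking$perturbation,
                      run_b$profile$ranking$perturbation)
  if (!length(common)) stop("no common perturbations between conditions")
  tab <- pid(run_a$profile$ranking, run_b$profile$ranking)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_stage_table(tab, file.path(out_dir, "pid.tsv"), config_a)
  }
  list(pid = tab, run_a = run_a, run_b = run_b)
}
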