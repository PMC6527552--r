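#' Find candidate off-target transcripts for an sgRNA
#'
#' Scans every transcript (both strands) for windows of the sgRNA's length
#' within a Hamming distance of `max_mismatch`, and reports each gene once
#' with its minimal distance. This is a deliberately plain mismatch search:
#' the candidates feed the expression-correlation test, which does the
#' actual flagging. With `require_pam = TRUE`, only windows followed
#' immediately 3' by an NGG protospacer-adjacent motif are counted.
#' Intended for knockout (CRISPR-cut) screens; CRISPRi knockdown is highly
#' specific and screens of that type skip this module.
#'
#' @param sgrna 18-23 nt guide sequence over ACGT.
#' @param transcripts a named character vector or `Biostrings::DNAStringSet`
#'   keyed by gene id.
#' @param target_gene the guide's intended target (excluded from results).
#' @param max_mismatch maximal Hamming distance (default 3).
#' @param require_pam require an NGG immediately 3' of the match.
#' @return data.frame (`candidate_gene`, `mismatches`, `offset`, `strand`),
#'   one row per candidate gene at its minimal distance.
#' @export
find_candidates <- function(sgrna, transcripts, target_gene = NULL,
                            max_mismatch = 3, require_pam = FALSE) {
  sgrna <- toupper(sgrna)
  if (!grepl("^[ACGT]+$", sgrna)) stop("invalid nucleotide characters in sgRNA")
  if (nchar(sgrna) < 18 || nchar(sgrna) > 23)
    stop("sgRNA must be 18-23 nt")
  if (!methods::is(transcripts, "DNAStringSet"))
    transcripts <- Biostrings::DNAStringSet(toupper(unlist(transcripts)))
  if (is.null(names(transcripts))) stop("transcripts must be named by gene id")
  pat <- Biostrings::DNAString(sgrna)
  k <- nchar(sgrna)
  hits <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") transcripts
            else Biostrings::reverseComplement(transcripts)
    mm <- Biostrings::vmatchPattern(pat, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
    for (g in seq_along(subj)) {
      starts <- BiocGenerics::start(mm[[g]])
      if (!length(starts)) next
      seqg <- subj[[g]]
      for (s in starts) {
        if (s < 1 || s + k - 1 > length(seqg)) next
        if (require_pam) {
          pam_end <- s + k + 2
          if (pam_end > length(seqg)) next
          pam <- as.character(Biostrings::subseq(seqg, s + k + 1, pam_end))
          if (!grepl("^.GG$", pam)) next
        }
        win <- as.character(Biostrings::subseq(seqg, s, s + k - 1))
        d <- sum(strsplit(win, "")[[1]] != strsplit(sgrna, "")[[1]])
        if (d > max_mismatch) next
        hits[[length(hits) + 1]] <- data.frame(
          candidate_gene = names(subj)[g], mismatches = d, offset = s,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(candidate_gene = character(), mismatches = integer(),
                      offset = integer(), strand = character()))
  df <- do.call(rbind, hits)
  if (!is.null(target_gene)) df <- df[df$candidate_gene != target_gene, ,
                                      drop = FALSE]
  # one row per gene at its minimal distance (first offset at that distance)
  df <- df[order(df$candidate_gene, df$mismatches, df$offset), , drop = FALSE]
  df <- df[!duplicated(df$candidate_gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Test for a correlation increase between target and candidate genes
#'
#' An off-target cut at a candidate gene couples its expression to the
#' intended target's in perturbed cells. For every candidate, the Pearson
#' correlation between target and candidate expression is computed inside
#' the case cells (perturbed for `target_gene`) and inside the controls;
#' a candidate is flagged when the case correlation exceeds the control
#' correlation by a one-sided Fisher z test at `alpha`.
#'
#' @param dataset a [ScreenDataset].
#' @param target_gene the perturbation/gene under test.
#' @param candidates character vector of candidate gene ids (e.g. from
#'   [find_candidates]).
#' @param alpha one-sided significance level (default 0.05).
#' @return data.frame (`candidate_gene`, `r_case`, `r_control`, `p`,
#'   `flagged`); candidates with zero-variance expression on either side
#'   are skipped with a warning.
#' @export
correlation_increase_test <- function(dataset, target_gene, candidates,
                                      alpha = 0.05) {
  case_idx <- which(dataset$perturbation == target_gene)
  ctrl_idx <- control_cells(dataset)
  if (length(case_idx) < 3 || length(ctrl_idx) < 3)
    stop("need at least 3 case and 3 control cells")
  if (!target_gene %in% dataset$gene_ids)
    stop("target gene not in the expression matrix")
  m <- as.matrix(dataset$counts)
  tgt_case <- m[case_idx, target_gene]
  tgt_ctrl <- m[ctrl_idx, target_gene]
  out <- lapply(candidates, function(g) {
    if (!g %in% dataset$gene_ids) return(NULL)
    x_case <- m[case_idx, g]; x_ctrl <- m[ctrl_idx, g]
    if (stats::var(tgt_case) == 0 || stats::var(x_case) == 0 ||
        stats::var(tgt_ctrl) == 0 || stats::var(x_ctrl) == 0) {
      warning("zero-variance expression for candidate '", g, "'; skipped")
      return(NULL)
    }
    r1 <- stats::cor(tgt_case, x_case)
    r0 <- stats::cor(tgt_ctrl, x_ctrl)
    p <- fisher_z_p(r1, length(case_idx), r0, length(ctrl_idx))
    data.frame(candidate_gene = g, r_case = r1, r_control = r0, p = p,
               flagged = p < alpha, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(candidate_gene = character(), r_case = numeric(),
                      r_control = numeric(), p = numeric(),
                      flagged = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# one-sided p for H1: rho_case > rho_control via Fisher z
fisher_z_p <- function(r1, n1, r0, n0) {
  clamp <- function(r) max(min(r, 1 - 1e-12), -1 + 1e-12)
  z1 <- atanh(clamp(r1)); z0 <- atanh(clamp(r0))
  se <- sqrt(1 / (n1 - 3) + 1 / (n0 - 3))
  stats::pnorm((z1 - z0) / se, lower.tail = FALSE)
}
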