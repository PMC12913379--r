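#' Probe-fidelity recall against a reference expression panel
#'
#' For every probe, the Spearman correlation between its measurements across
#' a panel of reference cell lines and every gene of a reference RNA-seq
#' matrix (log2 RPKM) over the same cell lines is computed.  The recall rank
#' is the percentage of reference genes with a strictly higher correlation
#' than the probe's matched gene; a probe passes when its recall rank is
#' below `pass_threshold_pct` (default 5%).
#'
#' Probes whose matched gene is absent from the reference, or constant in
#' either matrix, are excluded from the denominator (logged), mirroring an
#' analyzed set smaller than the panel.
#'
#' @param panel_matrix numeric matrix, probes x cell lines (rownames = gene
#'   ids), or a [gct].
#' @param rnaseq numeric matrix, reference genes x cell lines (log2 RPKM), or
#'   a [gct]; columns are matched to `panel_matrix` by name.
#' @param pass_threshold_pct recall-rank pass cutoff in percent.
#' @return list of class `recall_report`: `probes` (data.frame with
#'   `gene_id`, `spearman_r`, `recall_rank_pct`, `passed`), `excluded`
#'   (data.frame with `gene_id`, `reason`), and `summary` (n_passed, n_total,
#'   fraction_passed, pass_threshold_pct).
#' @export
probe_recall <- function(panel_matrix, rnaseq, pass_threshold_pct = 5) {
  if (inherits(panel_matrix, "gct")) panel_matrix <- panel_matrix$mat
  if (inherits(rnaseq, "gct")) rnaseq <- rnaseq$mat
  shared <- intersect(colnames(panel_matrix), colnames(rnaseq))
  if (length(shared) < 3L)
    stop("need >= 3 shared reference cell lines; found ", length(shared))
  pm <- panel_matrix[, shared, drop = FALSE]
  rs <- rnaseq[, shared, drop = FALSE]
  const_ref <- apply(rs, 1L, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                       all(is.na(v)))
  excluded <- data.frame(gene_id = character(0), reason = character(0))
  probes <- rownames(pm)
  keep <- logical(length(probes))
  reason <- character(length(probes))
  for (i in seq_along(probes)) {
    g <- probes[i]
    if (!g %in% rownames(rs)) {
      reason[i] <- "matched gene absent from reference"
    } else if (isTRUE(const_ref[g])) {
      reason[i] <- "matched gene constant in reference"
    } else if (stats::sd(pm[i, ], na.rm = TRUE) == 0) {
      reason[i] <- "probe constant across cell lines"
    } else keep[i] <- TRUE
  }
  if (any(!keep)) {
    excluded <- data.frame(gene_id = probes[!keep], reason = reason[!keep],
                           stringsAsFactors = FALSE)
    message(sum(!keep), " probes excluded from recall analysis")
  }
  pm <- pm[keep, , drop = FALSE]
  # correlate every probe against every reference gene in one pass
  rho <- suppressWarnings(stats::cor(t(rs), t(pm), method = "spearman",
                                     use = "pairwise.complete.obs"))
  n_ref <- nrow(rs)
  res <- data.frame(gene_id = rownames(pm), spearman_r = NA_real_,
                    recall_rank_pct = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pm))) {
    r_all <- rho[, i]
    r_match <- r_all[res$gene_id[i]]
    res$spearman_r[i] <- r_match
    res$recall_rank_pct[i] <- 100 * sum(r_all > r_match, na.rm = TRUE) / n_ref
  }
  res$passed <- res$recall_rank_pct < pass_threshold_pct
  summary <- list(n_passed = sum(res$passed), n_total = nrow(res),
                  fraction_passed = if (nrow(res)) sum(res$passed) / nrow(res)
                  else NA_real_,
                  pass_threshold_pct = pass_threshold_pct)
  structure(list(probes = res, excluded = excluded, summary = summary),
            class = "recall_report")
}

#' @export
print.recall_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("probe recall: %d of %d probes passed (%.0f%%) at rank < %g%%\n",
              s$n_passed, s$n_total, 100 * s$fraction_passed,
              s$pass_threshold_pct))
  if (nrow(x$excluded))
    cat(sprintf("  %d probes excluded before analysis\n", nrow(x$excluded)))
  invisible(x)
}

#' Annotate recall failures with low-expression status
#'
#' Probes that fail recall often correspond to genes expressed at very low
#' levels in the reference panel, where rank correlations are uninformative.
#' Each failed probe is annotated `low_expression` when its reference mean
#' (log2 RPKM) is below `low_expr_threshold`.
#'
#' @param report a `recall_report` from [probe_recall].
#' @param rnaseq the reference matrix used for the recall (matrix or [gct]).
#' @param low_expr_threshold mean log2 RPKM below which a gene counts as
#'   lowly expressed (default 1).
#' @return the report with a `failures` data.frame (`gene_id`,
#'   `reference_mean`, `low_expression`) and summary fields
#'   `n_failed_low_expression` / `fraction_failed_low_expression` added.
#' @export
annotate_failures <- function(report, rnaseq, low_expr_threshold = 1) {
  stopifnot(inherits(report, "recall_report"))
  if (inherits(rnaseq, "gct")) rnaseq <- rnaseq$mat
  failed <- report$probes[!report$probes$passed, , drop = FALSE]
  if (!nrow(failed)) {
    report$failures <- data.frame(gene_id = character(0),
                                  reference_mean = numeric(0),
                                  low_expression = logical(0))
    report$summary$n_failed_low_expression <- 0L
    report$summary$fraction_failed_low_expression <- NA_real_
    return(report)
  }
  mu <- rowMeans(rnaseq[failed$gene_id, , drop = FALSE], na.rm = TRUE)
  ann <- data.frame(gene_id = failed$gene_id, reference_mean = unname(mu),
                    low_expression = unname(mu) < low_expr_threshold,
                    stringsAsFactors = FALSE)
  report$failures <- ann
  report$summary$n_failed_low_expression <- sum(ann$low_expression)
  report$summary$fraction_failed_low_expression <-
    sum(ann$low_expression) / nrow(ann)
  report
}

#' Compound signature recall against a reference collection
#'
#' For each test signature passing the activity gate (TAS >= `tas_threshold`),
#' Spearman correlations to every reference signature over the shared gene
#' space are ranked descending; the compound is recalled when the best rank of
#' a matched reference signature (same pert_id) is <= `rank_threshold`.
#' Inactive signatures are reported with `recalled = NA`: recall is only
#' evaluated after the activity gate.
#'
#' @param test a level-5 [gct] of test signatures with `pert_id` column
#'   metadata.
#' @param reference a level-5 [gct] reference collection with `pert_id`.
#' @param test_tas numeric vector of TAS per test signature (same order as
#'   columns), or NULL to take a `tas` column from `test$cdesc`.
#' @param tas_threshold activity gate (default 0.212).
#' @param rank_threshold best-rank cutoff for successful recall (default 190,
#'   i.e. roughly the top 10% of a 1,886-signature reference).
#' @return list of class `signature_recall_report`: `signatures` data.frame
#'   (`sig_id`, `pert_id`, `tas`, `active`, `best_rank`, `recalled`) and
#'   `summary` (n_active, n_recalled, fraction_recalled, n_reference).
#' @export
signature_recall <- function(test, reference, test_tas = NULL,
                             tas_threshold = 0.212, rank_threshold = 190) {
  stopifnot(inherits(test, "gct"), inherits(reference, "gct"))
  if (is.null(test_tas)) test_tas <- test$cdesc$tas
  if (is.null(test_tas)) stop("no TAS available for the test signatures")
  stopifnot(length(test_tas) == ncol(test$mat))
  shared_genes <- intersect(rownames(test$mat), rownames(reference$mat))
  if (length(shared_genes) < 3L) stop("shared gene space too small")
  shared_perts <- intersect(test$cdesc$pert_id, reference$cdesc$pert_id)
  if (!length(shared_perts))
    stop("no compounds shared between test and reference collections")
  tm <- test$mat[shared_genes, , drop = FALSE]
  rm_ <- reference$mat[shared_genes, , drop = FALSE]
  rho <- suppressWarnings(stats::cor(tm, rm_, method = "spearman",
                                     use = "pairwise.complete.obs"))
  out <- data.frame(sig_id = test$cdesc$id, pert_id = test$cdesc$pert_id,
                    tas = test_tas, active = test_tas >= tas_threshold,
                    best_rank = NA_integer_, recalled = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (!out$active[i] || !out$pert_id[i] %in% shared_perts) next
    r <- rho[i, ]
    rk <- rank(-r, ties.method = "min")
    matched <- reference$cdesc$pert_id == out$pert_id[i]
    out$best_rank[i] <- min(rk[matched])
    out$recalled[i] <- out$best_rank[i] <= rank_threshold
  }
  summary <- list(n_active = sum(out$active),
                  n_recalled = sum(out$recalled, na.rm = TRUE),
                  fraction_recalled = if (any(out$active & !is.na(out$recalled)))
                    mean(out$recalled[out$active & !is.na(out$recalled)])
                  else NA_real_,
                  n_reference = ncol(reference$mat),
                  rank_threshold = rank_threshold,
                  rank_threshold_pct = 100 * rank_threshold /
                    ncol(reference$mat))
  structure(list(signatures = out, summary = summary),
            class = "signature_recall_report")
}
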