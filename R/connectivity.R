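#' Build an up/down query signature from a DEG table
#'
#' DEGs (optionally filtered on FDR) are sorted by log2 fold change; the
#' `n_up` most up-regulated and `n_down` most down-regulated genes form the
#' disjoint up/down lists.  Genes absent from the measured panel are dropped
#' with a logged count.
#'
#' @param degs a [deg_table] (columns `gene_id`, `log2_fold_change`,
#'   optionally `fdr`).
#' @param n_up,n_down number of genes requested per list.
#' @param fdr_max optional FDR filter applied before sorting.
#' @param panel optional character vector of measurable gene ids; query genes
#'   outside it are dropped (count logged).
#' @param min_genes,max_genes allowed size range per list after filtering.
#' @return object of class `query_signature`: list with character vectors
#'   `up` and `down` (ordered by |log2FC|, strongest first).
#' @export
prepare_query_from_degs <- function(degs, n_up = 137, n_down = 150,
                                    fdr_max = NULL, panel = NULL,
                                    min_genes = 10, max_genes = 150) {
  df <- as.data.frame(degs)
  if (!is.null(fdr_max)) {
    if (!"fdr" %in% names(df)) stop("no fdr column to filter on")
    df <- df[!is.na(df$fdr) & df$fdr <= fdr_max, , drop = FALSE]
  }
  if (!nrow(df)) stop("no DEGs survive the significance filter")
  if (!is.null(panel)) {
    out_of_panel <- !df$gene_id %in% panel
    if (any(out_of_panel))
      message(sum(out_of_panel), " DEG genes dropped: not in measured panel")
    df <- df[!out_of_panel, , drop = FALSE]
  }
  pos <- df[df$log2_fold_change > 0, , drop = FALSE]
  neg <- df[df$log2_fold_change < 0, , drop = FALSE]
  up <- pos$gene_id[order(-pos$log2_fold_change)][seq_len(min(n_up, nrow(pos)))]
  down <- neg$gene_id[order(neg$log2_fold_change)][
    seq_len(min(n_down, nrow(neg)))]
  query_signature(up, down, min_genes = min_genes, max_genes = max_genes)
}

#' @rdname prepare_query_from_degs
#' @param up,down character vectors of gene ids (must be disjoint).
#' @export
query_signature <- function(up, down, min_genes = 10, max_genes = 150) {
  up <- as.character(up); down <- as.character(down)
  if (length(intersect(up, down)))
    stop("up and down lists overlap: ",
         paste(utils::head(intersect(up, down), 5), collapse = ", "))
  sizes <- c(up = length(up), down = length(down))
  if (any(sizes < min_genes) || any(sizes > max_genes))
    stop("query list sizes (up = ", sizes[1L], ", down = ", sizes[2L],
         ") outside [", min_genes, ", ", max_genes, "]")
  structure(list(up = up, down = down), class = "query_signature")
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum statistic of a gene set against a signature ranked
#' by descending z-score, with hit increments weighted by |z| (weight
#' exponent 1) and miss decrements of 1/(number of misses).  The score is the
#' running-sum extremum (the deviation of largest magnitude, signed).
#'
#' @param z named numeric vector (signature z-scores, any order).
#' @param genes character vector of set members.
#' @return enrichment score in [-1, 1]; NA when the set does not intersect
#'   the signature.
#' @export
enrichment_score <- function(z, genes) {
  z <- z[!is.na(z)]
  ord <- order(z, decreasing = TRUE)
  z <- z[ord]
  hit <- names(z) %in% genes
  nh <- sum(hit)
  if (nh == 0L) return(NA_real_)
  n <- length(z)
  if (nh == n) return(1)
  w <- abs(z)
  w[!hit] <- 0
  sw <- sum(w)
  inc <- if (sw > 0) w / sw else as.numeric(hit) / nh
  dec <- as.numeric(!hit) / (n - nh)
  run <- cumsum(inc - dec)
  unname(run[which.max(abs(run))])
}

#' Weighted two-sided connectivity score (WTCS)
#'
#' Scores an up/down query against one signature: ES_up and ES_down are
#' [enrichment_score]s of the two lists; when they disagree in sign
#' WTCS = (ES_up - ES_down) / 2, otherwise 0 (a query cannot coherently
#' connect when both lists fall on the same flank).
#'
#' @param query a [query_signature].
#' @param z named numeric signature vector (level-5 z-scores).
#' @return WTCS in [-1, 1]; NA when neither list intersects the signature.
#' @export
wtcs <- function(query, z) {
  es_up <- enrichment_score(z, query$up)
  es_down <- enrichment_score(z, query$down)
  if (is.na(es_up) && is.na(es_down)) return(NA_real_)
  if (is.na(es_up)) es_up <- 0
  if (is.na(es_down)) es_down <- 0
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Normalize connectivity scores within (cell line, perturbagen type) groups
#'
#' NCS = WTCS divided by the mean |WTCS| of same-sign scores in the same
#' group (the group mean includes the score itself, so a singleton group
#' self-normalizes to +/-1; zero scores stay 0).
#'
#' @param wtcs numeric vector of raw scores.
#' @param cell_id,pert_type grouping vectors, recycled against `wtcs`.
#' @return numeric vector of normalized connectivity scores.
#' @export
normalize_scores <- function(wtcs, cell_id, pert_type) {
  cell_id <- rep_len(cell_id, length(wtcs))
  pert_type <- rep_len(pert_type, length(wtcs))
  grp <- paste(cell_id, pert_type, sep = "|")
  ncs <- wtcs
  for (g in unique(grp)) {
    idx <- which(grp == g)
    w <- wtcs[idx]
    pos <- !is.na(w) & w > 0
    neg <- !is.na(w) & w < 0
    if (any(pos)) ncs[idx][pos] <- w[pos] / mean(abs(w[pos]))
    if (any(neg)) ncs[idx][neg] <- w[neg] / mean(abs(w[neg]))
  }
  ncs
}

#' Signed tau percentile
#'
#' tau = sign(ncs) * 100 * (fraction of the touchstone |NCS| background
#' strictly less than |ncs|), on [-100, 100].  Positive tau marks a mimic,
#' negative a reversal; |tau| is the percentile standing of the connection
#' against the reference collection.
#'
#' @param ncs numeric vector of normalized connectivity scores to convert.
#' @param background numeric vector, the touchstone |NCS| distribution for
#'   the same cell line (absolute values are taken internally).
#' @return numeric vector of tau scores.
#' @export
tau_score <- function(ncs, background) {
  background <- abs(background[!is.na(background)])
  if (!length(background)) stop("empty touchstone background")
  vapply(ncs, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v == 0) return(0)
    sign(v) * 100 * mean(background < abs(v))
  }, numeric(1))
}

#' Score a query against a signature collection
#'
#' Computes WTCS of the query against every column of a level-5 signature
#' matrix, normalizes within (cell_id, pert_type) groups, and converts to tau
#' against a per-cell-line touchstone background (by default the query's own
#' |NCS| distribution in that cell line; pass `background` to use an external
#' touchstone, as a named list of numeric vectors keyed by cell_id).
#'
#' @param query a [query_signature].
#' @param signatures a level-5 [gct] whose `cdesc` carries `pert_id`,
#'   `pert_type`, `cell_id` (and optionally `pert_dose`, `pert_time`).
#' @param background optional named list: cell_id -> numeric |NCS| vector.
#' @param query_id label recorded in the result.
#' @return data.frame of class `connectivity_result`: one row per reference
#'   signature with `query_id`, `sig_id`, `pert_id`, `pert_type`, `cell_id`,
#'   dose/time when available, `wtcs`, `ncs`, `tau`.
#' @export
run_query <- function(query, signatures, background = NULL,
                      query_id = "query") {
  stopifnot(inherits(query, "query_signature"), inherits(signatures, "gct"))
  cd <- signatures$cdesc
  need <- c("pert_id", "pert_type", "cell_id")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    stop("signature metadata missing: ", paste(miss, collapse = ", "))
  w <- apply(signatures$mat, 2L, function(col) {
    names(col) <- rownames(signatures$mat)
    wtcs(query, col)
  })
  if (all(is.na(w)))
    stop("query genes do not intersect the signature gene space")
  ncs <- normalize_scores(w, cd$cell_id, cd$pert_type)
  tau <- rep(NA_real_, length(ncs))
  for (cl in unique(cd$cell_id)) {
    idx <- which(cd$cell_id == cl)
    bg <- if (!is.null(background)) {
      if (is.null(background[[cl]]))
        stop("no touchstone background for cell line '", cl, "'")
      background[[cl]]
    } else ncs[idx]
    tau[idx] <- tau_score(ncs[idx], bg)
  }
  out <- data.frame(query_id = query_id, sig_id = cd$id,
                    pert_id = cd$pert_id, pert_type = cd$pert_type,
                    cell_id = cd$cell_id, stringsAsFactors = FALSE)
  for (f in c("pert_dose", "pert_time"))
    if (f %in% names(cd)) out[[f]] <- cd[[f]]
  out$wtcs <- w
  out$ncs <- ncs
  out$tau <- tau
  class(out) <- c("connectivity_result", "data.frame")
  out
}

#' Aggregate connectivity results to per-perturbagen median tau
#'
#' The median tau across cell lines summarizes the strength and direction of
#' a perturbagen's connectivity: positive medians are mimics, negative are
#' reversers.  The even-count median is the midpoint of the central pair.
#'
#' @param results a `connectivity_result` data.frame from [run_query].
#' @param top_k how many top mimics/reversers to flag (default 25).
#' @return data.frame sorted by descending `median_tau`, one row per
#'   `pert_id`: `median_tau`, `n_cell_lines`, `classification` ("mimic",
#'   "reverse" or "neutral"), `top_mimic`/`top_reverse` flags for the top-k
#'   of each direction.
#' @export
summarize_median_tau <- function(results, top_k = 25) {
  dt <- data.table::as.data.table(results)
  agg <- dt[!is.na(dt$tau),
            list(median_tau = stats::median(tau),
                 n_cell_lines = length(unique(cell_id))),
            by = "pert_id"]
  agg <- as.data.frame(agg)
  agg <- agg[order(-agg$median_tau, agg$pert_id), , drop = FALSE]
  if (top_k > nrow(agg)) {
    warning("top_k exceeds number of perturbagens; returning full list")
    top_k <- nrow(agg)
  }
  agg$classification <- ifelse(agg$median_tau > 0, "mimic",
                               ifelse(agg$median_tau < 0, "reverse",
                                      "neutral"))
  n <- nrow(agg)
  agg$top_mimic <- seq_len(n) <= top_k & agg$median_tau > 0
  rev_rank <- rank(agg$median_tau, ties.method = "first")
  agg$top_reverse <- rev_rank <= top_k & agg$median_tau < 0
  rownames(agg) <- NULL
  agg
}

#' Touchstone-style compound similarity
#'
#' Selects one reference signature (by perturbagen id plus optional cell
#' line, dose and time filters), builds a query from that signature's own
#' most extreme genes (top `n_top` up, bottom `n_bottom` down), and scores it
#' against the whole collection, including KD/OE classes.  Ties are broken
#' lexicographically by pert_id, then sig_id.
#'
#' Alternatively (`method = "correlation"`) ranks the collection by Spearman
#' correlation to the selected signature.
#'
#' @param signatures a level-5 [gct] collection.
#' @param pert_id perturbagen id to select.
#' @param cell_id,pert_idose,pert_itime optional filters (the field
#'   vocabulary of the platform: dose/time of the selected profile).
#' @param n_top,n_bottom query sizes drawn from the selected signature.
#' @param method "query" (enrichment-based, default) or "correlation".
#' @return data.frame ranked by descending score with columns `rank`,
#'   `sig_id`, `pert_id`, `pert_type`, `cell_id`, `score` (and `ncs`, `tau`
#'   for the query method).
#' @export
touchstone_similarity <- function(signatures, pert_id, cell_id = NULL,
                                  pert_idose = NULL, pert_itime = NULL,
                                  n_top = 50, n_bottom = 50,
                                  method = c("query", "correlation")) {
  method <- match.arg(method)
  stopifnot(inherits(signatures, "gct"))
  cd <- signatures$cdesc
  sel <- cd$pert_id == pert_id
  if (!is.null(cell_id)) sel <- sel & cd$cell_id == cell_id
  if (!is.null(pert_idose) && "pert_dose" %in% names(cd))
    sel <- sel & cd$pert_dose == pert_idose
  if (!is.null(pert_itime) && "pert_time" %in% names(cd))
    sel <- sel & cd$pert_time == pert_itime
  if (!any(sel, na.rm = TRUE))
    stop("selection matches no signature (pert_id = '", pert_id, "')")
  j <- which(sel)[1L]
  ref <- signatures$mat[, j]
  names(ref) <- rownames(signatures$mat)
  ref <- ref[!is.na(ref)]
  if (method == "query") {
    ord <- order(ref, decreasing = TRUE)
    q <- query_signature(names(ref)[utils::head(ord, n_top)],
                         names(ref)[utils::tail(ord, n_bottom)],
                         min_genes = 1, max_genes = length(ref))
    res <- run_query(q, signatures, query_id = paste0("touchstone:", pert_id))
    res <- res[order(-res$wtcs, res$pert_id, res$sig_id), , drop = FALSE]
    res$score <- res$wtcs
  } else {
    rho <- suppressWarnings(stats::cor(
      signatures$mat[names(ref), , drop = FALSE], ref,
      method = "spearman", use = "pairwise.complete.obs"))[, 1L]
    res <- data.frame(sig_id = cd$id, pert_id = cd$pert_id,
                      pert_type = cd$pert_type, cell_id = cd$cell_id,
                      score = rho, stringsAsFactors = FALSE)
    res <- res[order(-res$score, res$pert_id, res$sig_id), , drop = FALSE]
  }
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("rank", setdiff(names(res), "rank")), drop = FALSE]
}
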