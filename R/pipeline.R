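#' Subset a gct object
#'
#' @param x a [gct].
#' @param i,j row and column indices (numeric, logical or names).
#' @param ... unused.
#' @return a [gct] with metadata subset in step.
#' @export
`[.gct` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$mat))
  if (missing(j)) j <- seq_len(ncol(x$mat))
  if (is.character(i)) i <- match(i, rownames(x$mat))
  if (is.character(j)) j <- match(j, colnames(x$mat))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  gct(x$mat[i, j, drop = FALSE], rdesc = x$rdesc[i, , drop = FALSE],
      cdesc = x$cdesc[j, , drop = FALSE], level = x$level)
}

#' Run the full five-level processing pipeline
#'
#' Bead-level fluorescence -> MFI (level 2) -> invariant calibration and
#' per-plate quantile normalization (level 3) -> per-plate gene-wise robust
#' z-scores over the panel genes (level 4) -> correlation-weighted replicate
#' collapse (level 5), plus per-replicate-group QC metrics.  Wells failing
#' invariant QC (< 2 usable ladder levels) are excluded after calibration,
#' with counts recorded in the returned `qc` table.
#'
#' @param beads bead-level data.frame (plate_id, well, bead_barcode,
#'   fluorescence_intensity).
#' @param samples a [sample_table].
#' @param probes a [probe_table].
#' @param reference an [invariant_reference].
#' @param G panel size for TAS (default: number of non-invariant probes).
#' @return list of class `screen_result`: [gct]s `level2`..`level5`, the
#'   `metrics` data.frame (with TAS also attached to `level5$cdesc`), and
#'   `qc` (per-well invariant-calibration diagnostics, `failed` flag).
#' @export
process_screen <- function(beads, samples, probes,
                           reference = invariant_reference(), G = NULL) {
  probes <- validate_probe_table(probes)
  level2 <- level1_to_level2(beads, probes, samples = samples)
  cal <- invariant_normalize(level2, reference = reference)
  qc <- attr(cal, "qc")
  if (any(qc$failed)) {
    message(sum(qc$failed), " wells excluded: failed invariant QC")
    cal <- cal[, !qc$failed]
  }
  level3 <- quantile_normalize(cal)
  panel_rows <- which(level3$rdesc$invariant_level == 0L)
  level4 <- robust_zscore(level3[panel_rows, ])
  level5 <- collapse_replicates(level4)
  metrics <- signature_metrics(level4, G = G)
  level5$cdesc$cc <- metrics$cc[match(level5$cdesc$id,
                                      metrics$replicate_group)]
  level5$cdesc$ss <- metrics$ss[match(level5$cdesc$id,
                                      metrics$replicate_group)]
  level5$cdesc$tas <- metrics$tas[match(level5$cdesc$id,
                                        metrics$replicate_group)]
  structure(list(level2 = level2, level3 = level3, level4 = level4,
                 level5 = level5, metrics = metrics, qc = qc),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d wells -> %d signatures over %d panel genes\n",
              ncol(x$level2$mat), ncol(x$level5$mat), nrow(x$level5$mat)))
  cat(sprintf("  wells failed invariant QC: %d\n", sum(x$qc$failed)))
  invisible(x)
}

#' Write all processing-level artifacts of a screen
#'
#' @param result a `screen_result` from [process_screen].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_screen_result <- function(result, dir, prefix = "screen") {
  stopifnot(inherits(result, "screen_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lv in c("level2", "level3", "level4", "level5")) {
    p <- file.path(dir, sprintf("%s_%s.gct", prefix, lv))
    write_gct(result[[lv]], p)
    paths <- c(paths, p)
  }
  mp <- file.path(dir, sprintf("%s_metrics.tsv", prefix))
  utils::write.table(result$metrics, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  qp <- file.path(dir, sprintf("%s_qc.tsv", prefix))
  utils::write.table(result$qc, qp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, mp, qp))
}

# exact (O(n^2)) t-SNE; adequate for screen-scale signature collections.
# eta/exaggeration are modest: collections here are hundreds of points, not
# tens of thousands, and large steps destabilize small embeddings.
.tsne <- function(X, dims = 2, perplexity = 30, max_iter = 500, eta = 100,
                  seed = 1) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  perplexity <- max(perplexity, 2)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D2[i, -i]
    for (it in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP == 0) { Pi <- rep(1 / length(Di), length(Di)); break }
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      Pi <- Pi / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  # deterministic PCA initialization (duplicated inputs start, and therefore
  # stay, coincident); the seed covers the degenerate zero-variance fallback
  set.seed(seed)
  pc <- stats::prcomp(X, rank. = dims, center = TRUE, scale. = FALSE)
  Y <- pc$x
  if (ncol(Y) < dims)
    Y <- cbind(Y, matrix(0, n, dims - ncol(Y)))
  s1 <- stats::sd(Y[, 1L])
  Y <- if (is.na(s1) || s1 == 0)
    matrix(stats::rnorm(n * dims, sd = 1e-4), n, dims)
  else Y / s1 * 1e-4
  G <- matrix(0, n, dims)
  gains <- matrix(1, n, dims)
  P_run <- P * 4  # early exaggeration
  momentum <- 0.5
  for (iter in seq_len(max_iter)) {
    if (iter == 101) P_run <- P
    if (iter == 251) momentum <- 0.8
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (P_run - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- momentum * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  Y
}

#' 2-D stochastic-neighbor embedding of a signature collection
#'
#' Embeds level-5 signatures into two dimensions with an exact t-SNE
#' (deterministic under `seed`), returning coordinates alongside TAS and
#' perturbation metadata so that points can be sized by transcriptional
#' activity.
#'
#' @param x a level-5 [gct] (>= 5 signatures).
#' @param tas optional numeric TAS per signature; defaults to a `tas` column
#'   of `x$cdesc` when present.
#' @param perplexity t-SNE perplexity (capped at (n-1)/3).
#' @param max_iter gradient-descent iterations.
#' @param seed integer RNG seed for the embedding initialization.
#' @return data.frame: `id`, `x`, `y`, `tas`, plus `cell_id` and `pert_id`
#'   when available.
#' @export
embed_signatures <- function(x, tas = NULL, perplexity = 30, max_iter = 500,
                             seed = 1) {
  stopifnot(inherits(x, "gct"))
  n <- ncol(x$mat)
  if (n < 5L) stop("need >= 5 signatures to embed; have ", n)
  if (is.null(tas)) tas <- x$cdesc$tas
  m <- t(x$mat)
  m[is.na(m)] <- 0
  # exact duplicates are embedded once and share coordinates: t-SNE places
  # no attraction strong enough to merge them at small n, and coincident
  # points are the only faithful representation of identical signatures
  key <- apply(m, 1L, paste, collapse = "\r")
  uniq <- !duplicated(key)
  idx <- match(key, key[uniq])
  Y <- .tsne(m[uniq, , drop = FALSE], perplexity = perplexity,
             max_iter = max_iter, seed = seed)[idx, , drop = FALSE]
  out <- data.frame(id = colnames(x$mat), x = Y[, 1L], y = Y[, 2L],
                    stringsAsFactors = FALSE)
  out$tas <- if (is.null(tas)) NA_real_ else tas
  for (f in c("cell_id", "pert_id"))
    if (f %in% names(x$cdesc)) out[[f]] <- x$cdesc[[f]]
  out
}

#' Read / write a run configuration
#'
#' A run configuration is a plain named list (paths, grouping columns,
#' metric flags, query parameters, seed) serialized losslessly to JSON; every
#' pipeline run should write its resolved configuration next to its outputs.
#'
#' @param config named list.
#' @param path JSON path.
#' @return `read_run_config`: the named list; `write_run_config`: `path`,
#'   invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
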