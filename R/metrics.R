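#' Replicate correlation (CC)
#'
#' The 75th quantile (linear-interpolation type 7) of the Spearman
#' correlations of all n(n-1)/2 replicate pairs of level-4 profiles.  A
#' single replicate has no pairs: CC is defined as 0 with a warning.
#'
#' @param z numeric matrix of level-4 z-scores, genes x replicates.
#' @return CC in [-1, 1].
#' @export
replicate_correlation <- function(z) {
  z <- as.matrix(z)
  n <- ncol(z)
  if (n < 2L) {
    warning("single replicate: replicate correlation defined as 0")
    return(0)
  }
  rho <- suppressWarnings(
    stats::cor(z, method = "spearman", use = "pairwise.complete.obs"))
  pairs <- rho[upper.tri(rho)]
  pairs <- pairs[!is.na(pairs)]  # constant profiles have no rank correlation
  if (!length(pairs)) return(0)
  unname(stats::quantile(pairs, 0.75, type = 7))
}

#' Signature strength (SS)
#'
#' The number of panel genes whose replicate-moderated z-score exceeds 2 in
#' absolute value (strict inequality).  The moderated z is
#' Za_i = mean over replicates of z_i * sqrt(n); with `moderated = FALSE` the
#' plain replicate mean is used instead.
#'
#' @param z numeric matrix, genes x replicates (level 4), or a single
#'   signature column.
#' @param threshold absolute moderated-z cutoff (default 2).
#' @param moderated multiply the replicate mean by sqrt(n) (default TRUE).
#' @return integer count in [0, nrow(z)].
#' @export
signature_strength <- function(z, threshold = 2, moderated = TRUE) {
  z <- as.matrix(z)
  n <- ncol(z)
  za <- rowMeans(z, na.rm = TRUE)
  if (moderated) za <- za * sqrt(n)
  sum(abs(za) > threshold, na.rm = TRUE)
}

#' Transcriptional activity score (TAS)
#'
#' Combines the magnitude (SS) and consistency (CC) of a replicate set on
#' [0, 1]: TAS = sqrt(SS * max(CC, 0) / G), where G is the panel size.
#' With `sqrt_scale = FALSE` the unrooted product SS * max(CC, 0) / G is
#' returned instead.
#'
#' @param ss signature strength, in [0, G].
#' @param cc replicate correlation, in [-1, 1].
#' @param G panel size (number of genes eligible for SS).
#' @param sqrt_scale take the square root (default TRUE).
#' @return TAS in [0, 1].
#' @export
tas <- function(ss, cc, G = 467, sqrt_scale = TRUE) {
  stopifnot(all(ss >= 0), all(ss <= G), all(cc >= -1), all(cc <= 1))
  v <- ss * pmax(cc, 0) / G
  if (sqrt_scale) sqrt(v) else v
}

#' Per-group signature metrics
#'
#' Computes CC, SS, TAS and the replicate count for every replicate group of
#' a level-4 matrix.  Invariant-ladder probes (when identifiable from row
#' metadata) are excluded so that G is the panel size.
#'
#' @param x a level-4 [gct].
#' @param groups replicate-group key per column (default: `replicate_group`
#'   column metadata).
#' @param G panel size; defaults to the number of non-invariant rows.
#' @inheritParams signature_strength
#' @return data.frame, one row per replicate group: `replicate_group`,
#'   `pert_id`, `pert_type`, `cell_id`, `pert_dose`, `pert_time`, `cc`, `ss`,
#'   `tas`, `n_replicates`.
#' @export
signature_metrics <- function(x, groups = NULL, G = NULL, threshold = 2,
                              moderated = TRUE) {
  stopifnot(inherits(x, "gct"))
  if (is.null(groups)) groups <- x$cdesc$replicate_group
  if (is.null(groups)) stop("no replicate grouping available")
  lv <- x$rdesc$invariant_level
  panel_rows <- if (is.null(lv)) seq_len(nrow(x$mat)) else which(lv == 0L)
  if (is.null(G)) G <- length(panel_rows)
  ug <- unique(groups)
  res <- lapply(ug, function(g) {
    z <- x$mat[panel_rows, groups == g, drop = FALSE]
    cc <- if (ncol(z) >= 2L) replicate_correlation(z) else 0
    ss <- signature_strength(z, threshold = threshold, moderated = moderated)
    data.frame(replicate_group = g, cc = cc, ss = ss,
               tas = tas(ss, cc, G = G), n_replicates = ncol(z))
  })
  out <- do.call(rbind, res)
  first <- match(ug, groups)
  keep <- intersect(c("pert_id", "pert_type", "cell_id", "pert_dose",
                      "pert_time"), names(x$cdesc))
  cbind(out[1L], x$cdesc[first, keep, drop = FALSE],
        out[-1L], row.names = NULL)
}

#' Upper-tail p-value of the F distribution
#'
#' Convenience wrapper for one-way ANOVA reporting:
#' returns P(F_{df1, df2} > f).
#'
#' @param f observed F statistic, >= 0.
#' @param df1,df2 numerator and denominator degrees of freedom, >= 1.
#' @return upper-tail probability.
#' @export
f_test_pvalue <- function(f, df1, df2) {
  if (any(df1 < 1) || any(df2 < 1)) stop("degrees of freedom must be >= 1")
  if (any(f < 0)) stop("F statistic must be nonnegative")
  stats::pf(f, df1, df2, lower.tail = FALSE)
}
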