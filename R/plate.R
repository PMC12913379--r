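#' Aggregate bead-level fluorescence to median fluorescence intensity (MFI)
#'
#' Level 1 -> Level 2.  For every (well, barcode) the median fluorescence
#' intensity across all measured beads is taken.  With a 1:1 barcode:gene
#' panel no peak deconvolution is needed.  Wells with no beads for a gene get
#' a missing value.
#'
#' @param beads data.frame with columns `plate_id`, `well`, `bead_barcode`,
#'   `fluorescence_intensity` (nonnegative).
#' @param probes a [probe_table] describing the panel.
#' @param samples optional [sample_table]; when given, columns are named by
#'   `sample_id` (matched on plate_id + well) and carried as column metadata,
#'   and only wells present in `samples` are returned.
#' @return a level-2 [gct], genes x wells.
#' @export
level1_to_level2 <- function(beads, probes, samples = NULL) {
  bc <- unique(beads$bead_barcode)
  unknown <- setdiff(bc, probes$bead_barcode)
  if (length(unknown))
    stop("unknown bead barcode(s): ", paste(utils::head(unknown, 5),
                                            collapse = ", "))
  dt <- data.table::as.data.table(beads)
  mfi <- as.data.frame(dt[, list(mfi = stats::median(fluorescence_intensity)),
                          by = c("plate_id", "well", "bead_barcode")])
  mfi$wkey <- paste(mfi$plate_id, mfi$well, sep = ":")
  wells <- unique(mfi[c("wkey", "plate_id", "well")])
  wells <- wells[order(wells$wkey), , drop = FALSE]
  mat <- matrix(NA_real_, nrow(probes), nrow(wells),
                dimnames = list(probes$gene_id, wells$wkey))
  gi <- match(mfi$bead_barcode, probes$bead_barcode)
  wi <- match(mfi$wkey, wells$wkey)
  mat[cbind(gi, wi)] <- mfi$mfi
  cdesc <- data.frame(id = wells$wkey, plate_id = wells$plate_id,
                      well = wells$well, stringsAsFactors = FALSE)
  if (!is.null(samples)) {
    skey <- paste(samples$plate_id, samples$well, sep = ":")
    keep <- match(skey, wells$wkey)
    if (anyNA(keep))
      stop("sample table references wells absent from bead data: ",
           paste(utils::head(skey[is.na(keep)], 5), collapse = ", "))
    mat <- mat[, keep, drop = FALSE]
    colnames(mat) <- samples$sample_id
    cdesc <- as.data.frame(samples)
    names(cdesc)[names(cdesc) == "sample_id"] <- "id"
  }
  gct(mat, rdesc = as.data.frame(probes), cdesc = cdesc, level = 2L)
}

#' Canonical invariant ladder reference
#'
#' Expected expression of each invariant ladder level.  Default is a
#' geometric ladder 2^k, k = 6..15 for levels 1..10: the printed values are
#' not part of the assay definition, only the monotone mapping matters.
#'
#' @param levels integer vector of ladder levels.
#' @param log2_base log2 canonical value of level 1.
#' @return data.frame with columns `level`, `canonical_value`.
#' @export
invariant_reference <- function(levels = 1:10, log2_base = 6) {
  data.frame(level = as.integer(levels),
             canonical_value = 2^(log2_base + as.integer(levels) - 1L))
}

# fit one well's calibration curve on log2 scale.
# obs, canon: log2 medians of invariant level sets and log2 canonical values.
# Returns function(log2 x) -> calibrated log2, or NULL when < 2 usable points.
.calibration_curve <- function(obs, canon, loess_span = 0.9) {
  ok <- is.finite(obs) & is.finite(canon)
  obs <- obs[ok]; canon <- canon[ok]
  if (length(obs) < 2L) return(NULL)
  ord <- order(canon)
  obs <- obs[ord]; canon <- canon[ord]
  if (is.unsorted(obs, strictly = FALSE)) {
    warning("non-monotone invariant medians; applying isotonic adjustment")
    obs <- stats::isoreg(seq_along(obs), obs)$yf
  }
  # collapse ties in obs (flat isotonic segments) to keep approx() happy
  if (anyDuplicated(obs)) {
    obs <- obs + seq_along(obs) * 1e-9
  }
  if (length(obs) >= 7L) {
    fit <- stats::loess(canon ~ obs, span = loess_span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    canon_s <- stats::predict(fit, data.frame(obs = obs))
    if (all(is.finite(canon_s)) && !is.unsorted(canon_s)) canon <- canon_s
  }
  n <- length(obs)
  slope_lo <- (canon[2L] - canon[1L]) / (obs[2L] - obs[1L])
  slope_hi <- (canon[n] - canon[n - 1L]) / (obs[n] - obs[n - 1L])
  function(x) {
    y <- stats::approx(obs, canon, xout = x, rule = 2)$y
    lo <- !is.na(x) & x < obs[1L]
    hi <- !is.na(x) & x > obs[n]
    y[lo] <- canon[1L] + slope_lo * (x[lo] - obs[1L])
    y[hi] <- canon[n] + slope_hi * (x[hi] - obs[n])
    y
  }
}

#' Invariant-set calibration of MFI values (loess-style, per well)
#'
#' Level 2 -> calibrated expression.  Within each well, the median MFI of
#' each invariant ladder level set is mapped onto its canonical value and the
#' resulting monotone curve (piecewise-linear through the calibration points,
#' isotonic-adjusted, loess-smoothed when >= 7 points, linearly extrapolated
#' beyond the ladder) is applied to every gene in the well.  Calibration is
#' performed on log2(MFI + 1) and returned on the fluorescence scale.
#'
#' Wells with fewer than 2 usable invariant levels are flagged failed-QC
#' (columns set to NA) in the attached `qc` attribute.
#'
#' @param x a level-2 [gct] whose `rdesc` carries `invariant_level`.
#' @param reference an [invariant_reference] data.frame.
#' @param loess_span span used for the smoothing fit when >= 7 calibration
#'   points are available.
#' @return a [gct] of calibrated, fluorescence-scale values with an attached
#'   `attr(, "qc")` data.frame (per well: n_invariant_levels, rms residual of
#'   the invariant medians after calibration, failed flag).
#' @export
invariant_normalize <- function(x, reference = invariant_reference(),
                                loess_span = 0.9) {
  stopifnot(inherits(x, "gct"))
  lv <- x$rdesc$invariant_level
  if (is.null(lv)) stop("row metadata lacks 'invariant_level'")
  canon_log2 <- log2(reference$canonical_value + 1)  # same scale as data
  present <- sort(unique(lv[lv > 0L]))
  out <- x$mat
  lmat <- log2(x$mat + 1)
  qc <- data.frame(id = colnames(x$mat), n_invariant_levels = 0L,
                   rms_residual = NA_real_, failed = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(lmat))) {
    obs <- vapply(present, function(l)
      stats::median(lmat[lv == l, j], na.rm = TRUE), numeric(1))
    canon <- canon_log2[match(present, reference$level)]
    curve <- .calibration_curve(obs, canon, loess_span)
    qc$n_invariant_levels[j] <- sum(is.finite(obs))
    if (is.null(curve)) {
      qc$failed[j] <- TRUE
      out[, j] <- NA_real_
      next
    }
    cal <- curve(lmat[, j])
    out[, j] <- 2^cal - 1
    qc$rms_residual[j] <- sqrt(mean((curve(obs) - canon)^2, na.rm = TRUE))
  }
  res <- gct(out, rdesc = x$rdesc, cdesc = x$cdesc, level = x$level)
  attr(res, "qc") <- qc
  res
}

#' Per-plate quantile normalization
#'
#' All wells on the same detection plate are quantile-normalized so that
#' every sample on the plate has the same empirical distribution (the mean of
#' the plate's sorted columns; ties receive the mean of their target
#' quantiles).  Produces level-3 data when run after invariant calibration.
#'
#' @param x a [gct].
#' @param plate a vector of plate ids, one per column; defaults to the
#'   `plate_id` column metadata.
#' @return a level-3 [gct].
#' @export
quantile_normalize <- function(x, plate = NULL) {
  stopifnot(inherits(x, "gct"))
  if (is.null(plate)) plate <- x$cdesc$plate_id
  if (is.null(plate)) stop("no plate grouping available")
  stopifnot(length(plate) == ncol(x$mat))
  out <- x$mat
  for (p in unique(plate)) {
    idx <- which(plate == p)
    if (length(idx) < 2L) {
      warning("plate '", p, "' has a single well; returned unchanged")
      next
    }
    out[, idx] <- limma::normalizeQuantiles(x$mat[, idx, drop = FALSE],
                                            ties = TRUE)
  }
  gct(out, rdesc = x$rdesc, cdesc = x$cdesc, level = 3L)
}

#' Gene-wise robust z-scores against the plate distribution
#'
#' Level 3 -> Level 4.  For every gene, z = (x - median) / (1.4826 * MAD),
#' where median and MAD are taken over all samples on the same detection
#' plate.  The MAD is floored at `mad_floor`; genes constant across the plate
#' get z = 0.
#'
#' @param x a level-3 [gct].
#' @param plate plate ids per column (default: `plate_id` column metadata).
#' @param mad_floor lower bound on the scaled MAD.
#' @return a level-4 [gct] of unitless z-scores.
#' @export
robust_zscore <- function(x, plate = NULL, mad_floor = 1e-6) {
  stopifnot(inherits(x, "gct"))
  if (is.null(plate)) plate <- x$cdesc$plate_id
  if (is.null(plate)) stop("no plate grouping available")
  stopifnot(length(plate) == ncol(x$mat))
  out <- x$mat
  for (p in unique(plate)) {
    idx <- which(plate == p)
    if (length(idx) < 3L)
      stop("plate '", p, "' has fewer than 3 samples; cannot form a ",
           "reference distribution")
    m <- x$mat[, idx, drop = FALSE]
    med <- apply(m, 1L, stats::median, na.rm = TRUE)
    sc <- apply(m, 1L, stats::mad, na.rm = TRUE)  # includes 1.4826
    const <- !is.na(sc) & sc < mad_floor
    sc[const] <- Inf  # constant rows -> z = 0
    sc[!const] <- pmax(sc[!const], mad_floor)
    out[, idx] <- (m - med) / sc
    out[const, idx][!is.na(m[const, , drop = FALSE])] <- 0
  }
  gct(out, rdesc = x$rdesc, cdesc = x$cdesc, level = 4L)
}

#' Replicate-collapse weights (MODZ)
#'
#' Each replicate is weighted by its average Spearman correlation to the
#' other replicates (pairwise-complete, average-rank ties), clipped below at
#' `clip`, and normalized to sum to one.  n = 1 gives weight 1; n = 2 gives
#' equal weights (the pairwise correlation is symmetric).
#'
#' @param z numeric matrix, genes x replicates.
#' @param clip lower clip applied to the mean correlations before
#'   normalization.
#' @return numeric vector of weights summing to 1.
#' @export
modz_weights <- function(z, clip = 0.01) {
  n <- ncol(z)
  if (n == 1L) return(1)
  rho <- suppressWarnings(
    stats::cor(z, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- NA
  w <- rowMeans(rho, na.rm = TRUE)
  w[is.na(w)] <- clip
  w <- pmax(w, clip)
  w / sum(w)
}

#' Collapse biological replicates into level-5 signatures
#'
#' Level 4 -> Level 5.  Replicate columns sharing a replicate-group key are
#' collapsed by the weighted average of [modz_weights]; missing values are
#' excluded cell-wise (weights renormalized over observed replicates).
#'
#' @param x a level-4 [gct].
#' @param groups replicate-group key per column (default: `replicate_group`
#'   column metadata).
#' @param clip weight clip, see [modz_weights].
#' @return a level-5 [gct] with one column per replicate group; column
#'   metadata keeps the first replicate's perturbation fields plus
#'   `n_replicates`.
#' @export
collapse_replicates <- function(x, groups = NULL, clip = 0.01) {
  stopifnot(inherits(x, "gct"))
  if (is.null(groups)) groups <- x$cdesc$replicate_group
  if (is.null(groups)) stop("no replicate grouping available")
  stopifnot(length(groups) == ncol(x$mat))
  ug <- unique(groups)
  mat <- matrix(NA_real_, nrow(x$mat), length(ug),
                dimnames = list(rownames(x$mat), ug))
  n_rep <- integer(length(ug))
  for (k in seq_along(ug)) {
    idx <- which(groups == ug[k])
    n_rep[k] <- length(idx)
    z <- x$mat[, idx, drop = FALSE]
    if (length(idx) == 1L) {
      mat[, k] <- z[, 1L]
      next
    }
    w <- modz_weights(z, clip = clip)
    obs <- !is.na(z)
    wm <- obs * rep(w, each = nrow(z))
    mat[, k] <- rowSums(z * wm, na.rm = TRUE) / rowSums(wm)
  }
  first <- match(ug, groups)
  keep <- intersect(c("pert_id", "pert_type", "pert_dose", "pert_time",
                      "cell_id", "dose_value", "dose_unit", "time_value",
                      "time_unit", "plate_id"), names(x$cdesc))
  cdesc <- data.frame(id = ug, x$cdesc[first, keep, drop = FALSE],
                      n_replicates = n_rep, stringsAsFactors = FALSE)
  gct(mat, rdesc = x$rdesc, cdesc = cdesc, level = 5L)
}
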