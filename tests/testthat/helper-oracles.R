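# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# sort-and-pick median
oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) x[(n + 1L) / 2L] else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

# quantile normalization: every column takes the across-column mean of
# sorted values, assigned back in rank order (tie-free inputs assumed)
oracle_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- target[rank(m[, j])]
  out
}

oracle_mad <- function(x) 1.4826 * oracle_median(abs(x - oracle_median(x)))

oracle_robust_z <- function(m, mad_floor = 1e-6) {
  out <- m
  for (i in seq_len(nrow(m))) {
    med <- oracle_median(m[i, ])
    sc <- oracle_mad(m[i, ])
    out[i, ] <- if (is.na(sc) || sc < mad_floor) 0 else (m[i, ] - med) / sc
  }
  out
}

# Spearman correlation as Pearson on average ranks, by the textbook formula
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  rx <- rank(x[ok]); ry <- rank(y[ok])
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# linear-interpolation (type 7) quantile
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p
  lo <- floor(h)
  x[lo + 1] + (h - lo) * (x[min(lo + 2, length(x))] - x[lo + 1])
}

oracle_cc <- function(z) {
  n <- ncol(z)
  r <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    r <- c(r, oracle_spearman(z[, i], z[, j]))
  oracle_quantile(r, 0.75)
}

oracle_modz_weights <- function(z, clip = 0.01) {
  n <- ncol(z)
  w <- numeric(n)
  for (i in seq_len(n)) {
    r <- c()
    for (j in seq_len(n)[-i]) r <- c(r, oracle_spearman(z[, i], z[, j]))
    w[i] <- max(mean(r), clip)
  }
  w / sum(w)
}

oracle_ss <- function(z, threshold = 2) {
  n <- ncol(z)
  count <- 0L
  for (i in seq_len(nrow(z))) {
    za <- mean(z[i, ], na.rm = TRUE) * sqrt(n)
    if (abs(za) > threshold) count <- count + 1L
  }
  count
}

# weighted KS enrichment score by explicit step-by-step running sum
oracle_es <- function(z, genes) {
  ord <- order(z, decreasing = TRUE)
  ranked <- names(z)[ord]
  zs <- unname(z[ord])
  hit <- ranked %in% genes
  sum_w <- sum(abs(zs[hit]))
  n_miss <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(ranked)) {
    run <- run + if (hit[i]) abs(zs[i]) / sum_w else -1 / n_miss
    if (abs(run) > abs(best)) best <- run
  }
  best
}

oracle_wtcs <- function(up, down, z) {
  eu <- oracle_es(z, up)
  ed <- oracle_es(z, down)
  if (sign(eu) != sign(ed)) (eu - ed) / 2 else 0
}

oracle_tau <- function(ncs, background) {
  if (ncs == 0) return(0)
  k <- 0
  for (b in background) if (abs(b) < abs(ncs)) k <- k + 1
  sign(ncs) * 100 * k / length(background)
}
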