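make_beads <- function(fis, gene = "G1", barcode = "b1", well = "A01",
                       plate = "P1") {
  data.frame(plate_id = plate, well = well, bead_barcode = barcode,
             fluorescence_intensity = fis, stringsAsFactors = FALSE)
}

test_that("MFI is the bead median, matching a sort-and-pick oracle", {
  probes <- probe_table("G1", bead_barcode = "b1")
  expect_equal(level1_to_level2(make_beads(500), probes)$mat[1, 1], 500)
  expect_equal(level1_to_level2(make_beads(c(100, 300, 200)), probes)$mat[1, 1],
               200)
  expect_equal(level1_to_level2(make_beads(c(10, 20, 30, 40)), probes)$mat[1, 1],
               25)
  # randomized instances against the oracle
  for (seed in 1:20) {
    set.seed(seed)
    fis <- runif(sample(1:9, 1), 0, 1e4)
    expect_equal(level1_to_level2(make_beads(fis), probes)$mat[1, 1],
                 oracle_median(fis))
  }
})

test_that("level-2 output is invariant to bead order and flags unknowns", {
  probes <- probe_table(c("G1", "G2"), bead_barcode = c("b1", "b2"))
  beads <- rbind(make_beads(c(5, 7, 9), barcode = "b1"),
                 make_beads(c(4, 2), barcode = "b2"))
  shuffled <- beads[sample(nrow(beads)), ]
  expect_equal(level1_to_level2(beads, probes)$mat,
               level1_to_level2(shuffled, probes)$mat)
  expect_error(level1_to_level2(make_beads(5, barcode = "zz"), probes), "zz")
  # well with no beads for a gene -> missing value
  g <- level1_to_level2(make_beads(c(5, 7), barcode = "b1"), probes)
  expect_true(is.na(g$mat["G2", 1]))
})

inv_fixture <- function(distort = identity, n_panel = 4, seed = 5) {
  set.seed(seed)
  ref <- invariant_reference()
  probes <- probe_table(c(sprintf("P%d", 1:n_panel), sprintf("I%d", 1:10)),
                        bead_barcode = sprintf("b%02d", 1:(n_panel + 10)),
                        invariant_level = c(rep(0L, n_panel), 1:10))
  truth <- c(runif(n_panel, 2^7, 2^13), ref$canonical_value)
  mat <- matrix(distort(truth), ncol = 1,
                dimnames = list(probes$gene_id, "P1:A01"))
  g <- gct(mat, rdesc = as.data.frame(probes),
           cdesc = data.frame(id = "P1:A01", plate_id = "P1"))
  list(g = g, truth = truth, probes = probes)
}

test_that("identity calibration leaves an already-calibrated well unchanged", {
  fx <- inv_fixture()
  out <- invariant_normalize(fx$g)
  expect_equal(out$mat[, 1], fx$g$mat[, 1], tolerance = 1e-9)
  qc <- attr(out, "qc")
  expect_false(qc$failed[1])
  expect_lt(qc$rms_residual[1], 1e-9)
})

test_that("a doubled-intensity distortion is calibrated back to truth", {
  fx <- inv_fixture(distort = function(x) 2 * x)
  out <- invariant_normalize(fx$g)
  in_range <- fx$truth >= 2^6 & fx$truth <= 2^15
  expect_equal(unname(out$mat[in_range, 1]), fx$truth[in_range],
               tolerance = 0.01)
})

test_that("values below the ladder extrapolate from the two lowest points", {
  fx <- inv_fixture()
  # shift everything so one panel gene sits below the lowest invariant median
  g <- fx$g
  g$mat["P1", 1] <- 2^4
  out <- invariant_normalize(g)
  # identity ladder -> extrapolation is the identity line continued
  expect_equal(out$mat["P1", 1], 2^4, tolerance = 1e-6)
})

test_that("wells with <2 usable invariant levels are flagged failed-QC", {
  fx <- inv_fixture()
  g <- fx$g
  g$mat[5:14, 1] <- NA  # wipe the ladder
  out <- invariant_normalize(g)
  qc <- attr(out, "qc")
  expect_true(qc$failed[1])
  expect_true(all(is.na(out$mat[, 1])))
})

test_that("non-monotone invariant medians trigger isotonic pre-adjustment", {
  fx <- inv_fixture(distort = function(x) {
    x[6] <- x[7] * 1.5  # invariant level 2 above level 3
    x
  })
  expect_warning(invariant_normalize(fx$g), "isotonic")
})

test_that("quantile normalization matches the mean-of-sorted oracle", {
  g <- gct(matrix(c(1, 3, 2, 4), 2, 2,
                  dimnames = list(c("g1", "g2"), c("s1", "s2"))),
           cdesc = data.frame(id = c("s1", "s2"), plate_id = "P1"))
  out <- quantile_normalize(g)
  expect_equal(unname(out$mat), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))
  expect_equal(out$level, 3L)
  # identical columns unchanged
  g2 <- gct(matrix(c(5, 1, 9, 5, 1, 9), 3, 2),
            cdesc = data.frame(id = c("c1", "c2"), plate_id = "P1"))
  expect_equal(quantile_normalize(g2)$mat, g2$mat)
  # randomized instances
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    gg <- gct(m, cdesc = data.frame(id = colnames(m), plate_id = "P1"))
    expect_equal(unname(quantile_normalize(gg)$mat),
                 unname(oracle_quantile_normalize(m)))
  }
})

test_that("after per-plate quantile normalization all sorted columns agree", {
  set.seed(9)
  m <- matrix(rexp(60), 10, 6, dimnames = list(paste0("g", 1:10),
                                               paste0("s", 1:6)))
  plate <- rep(c("P1", "P2"), each = 3)
  out <- quantile_normalize(gct(m), plate = plate)
  for (p in unique(plate)) {
    cols <- apply(out$mat[, plate == p], 2L, sort)
    expect_true(all(abs(cols - cols[, 1]) < 1e-12))
  }
})

test_that("single-well plates are returned unchanged with a warning", {
  g <- gct(matrix(1:3, 3, 1), cdesc = data.frame(id = "c1", plate_id = "P1"))
  expect_warning(out <- quantile_normalize(g), "single well")
  expect_equal(out$mat, g$mat)
})

test_that("robust z-scores match the hand-computed MAD oracle", {
  m <- matrix(c(1, 2, 3, 4, 100), 1, 5,
              dimnames = list("g1", paste0("s", 1:5)))
  z <- robust_zscore(gct(m), plate = rep("P1", 5))
  expect_equal(z$mat[1, 5], 97 / 1.4826, tolerance = 1e-12)
  expect_equal(z$mat[1, 3], 0)  # the median sample
  # constant rows give z = 0
  mc <- matrix(5, 1, 4)
  expect_equal(unname(robust_zscore(gct(mc), plate = rep("P1", 4))$mat),
               matrix(0, 1, 4))
  # randomized instances against the oracle
  for (seed in 1:20) {
    set.seed(seed)
    mm <- matrix(rnorm(6 * 7), 6, 7)
    out <- robust_zscore(gct(mm), plate = rep("P1", 7))
    expect_equal(unname(out$mat), oracle_robust_z(mm))
  }
  expect_error(robust_zscore(gct(matrix(1:4, 2, 2)), plate = c("P1", "P1")),
               "fewer than 3")
})

test_that("robust z is location/scale equivariant up to the scale sign", {
  set.seed(11)
  m <- matrix(rnorm(40), 4, 10)
  z1 <- robust_zscore(gct(m), plate = rep("P1", 10))$mat
  z2 <- robust_zscore(gct(3.7 * m + 2), plate = rep("P1", 10))$mat
  z3 <- robust_zscore(gct(-1.3 * m + 5), plate = rep("P1", 10))$mat
  expect_equal(unname(z2), unname(z1), tolerance = 1e-9)
  expect_equal(unname(z3), -unname(z1), tolerance = 1e-9)
})

test_that("replicate collapse weights and output behave as MODZ", {
  set.seed(13)
  z <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("g", 1:10), NULL))
  # identical replicates -> output equals any one of them
  zz <- cbind(z[, 1], z[, 1], z[, 1])
  colnames(zz) <- paste0("s", 1:3)
  g <- gct(zz)
  out <- collapse_replicates(g, groups = rep("grp", 3))
  expect_equal(unname(out$mat[, 1]), unname(z[, 1]))
  # n = 2 -> arithmetic mean regardless of correlation
  g2 <- gct(z[, 1:2, drop = FALSE])
  out2 <- collapse_replicates(g2, groups = rep("grp", 2))
  expect_equal(unname(out2$mat[, 1]), unname(rowMeans(z[, 1:2])))
  # n = 1 -> identity
  g1 <- gct(z[, 1, drop = FALSE])
  expect_equal(unname(collapse_replicates(g1, groups = "grp")$mat[, 1]),
               unname(z[, 1]))
})

test_that("an anti-correlated outlier replicate gets the smallest weight", {
  set.seed(17)
  base <- rnorm(50)
  # partially anti-correlated outlier: its mean correlation is clipped while
  # the two concordant replicates keep clearly positive means
  z <- cbind(base + rnorm(50, sd = 0.2), base + rnorm(50, sd = 0.2),
             -0.4 * base + rnorm(50))
  w <- modz_weights(z)
  expect_equal(w, oracle_modz_weights(z), tolerance = 1e-12)
  expect_equal(which.min(w), 3L)
  expect_equal(sum(w), 1)
})

test_that("collapse output is a convex combination of replicates", {
  for (seed in 1:10) {
    set.seed(seed)
    z <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(paste0("g", 1:20),
                                                      paste0("s", 1:4)))
    out <- collapse_replicates(gct(z), groups = rep("grp", 4))$mat[, 1]
    expect_true(all(out >= apply(z, 1, min) - 1e-12))
    expect_true(all(out <= apply(z, 1, max) + 1e-12))
  }
})
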