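toy_signature <- function(n = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- sort(rnorm(n), decreasing = TRUE)
  names(z) <- paste0("g", seq_len(n))
  z
}

test_that("query preparation sorts by log2FC and respects list sizes", {
  df <- data.frame(gene_id = paste0("g", 1:6),
                   log2_fold_change = c(3, 2, 1, -1, -2, -3))
  q <- prepare_query_from_degs(deg_table(df), n_up = 2, n_down = 2,
                               min_genes = 1)
  expect_equal(q$up, c("G1", "G2"))
  expect_equal(q$down, c("G6", "G5"))
  # only-positive table -> empty down list -> error
  pos <- data.frame(gene_id = paste0("g", 1:12),
                    log2_fold_change = seq(0.1, 1.2, by = 0.1))
  expect_error(prepare_query_from_degs(deg_table(pos), n_up = 5, n_down = 5,
                                       min_genes = 1), "outside")
})

test_that("a 383-row DEG table yields the platform's 137/150 query", {
  set.seed(21)
  df <- data.frame(gene_id = sprintf("G%04d", 1:383),
                   log2_fold_change = c(runif(200, 0.1, 5),
                                        runif(183, -5, -0.1)))
  q <- prepare_query_from_degs(deg_table(df), n_up = 137, n_down = 150)
  expect_length(q$up, 137)
  expect_length(q$down, 150)
  expect_length(intersect(q$up, q$down), 0)
})

test_that("FDR filtering and panel intersection prune query genes", {
  set.seed(22)
  df <- data.frame(gene_id = sprintf("G%03d", 1:60),
                   log2_fold_change = c(runif(30, 0.5, 4),
                                        runif(30, -4, -0.5)),
                   fdr = rep(c(0.001, 0.5), 30))
  deg <- deg_table(df, sig_column = "fdr")
  q <- prepare_query_from_degs(deg, n_up = 15, n_down = 15, fdr_max = 0.01,
                               min_genes = 5)
  expect_true(all(df$fdr[match(tolower(q$up), tolower(df$gene_id))] <= 0.01))
  panel <- sprintf("G%03d", c(1:15, 31:45))  # both signs represented
  expect_message(
    q2 <- prepare_query_from_degs(deg, n_up = 15, n_down = 15,
                                  panel = panel, min_genes = 5),
    "not in measured panel")
  expect_true(all(c(q2$up, q2$down) %in% panel))
})

test_that("up/down overlap is rejected", {
  expect_error(query_signature(c("a", "b"), c("b", "c"), min_genes = 1),
               "overlap")
})

test_that("enrichment and WTCS match the brute-force running-sum oracle", {
  z <- toy_signature(10, seed = 30)
  up <- names(z)[1:2]     # the 2 highest-z genes
  down <- names(z)[9:10]  # the 2 lowest
  expect_equal(wtcs(query_signature(up, down, min_genes = 1), z),
               oracle_wtcs(up, down, z))
  # constructed extreme query scores positive and beats random queries
  w_best <- wtcs(query_signature(up, down, min_genes = 1), z)
  expect_gt(w_best, 0)
  set.seed(31)
  for (i in 1:25) {
    g <- sample(names(z), 4)
    w <- wtcs(query_signature(g[1:2], g[3:4], min_genes = 1), z)
    expect_lte(w, w_best)
  }
  # randomized oracle equivalence
  for (seed in 40:64) {
    z <- toy_signature(30, seed = seed)
    g <- sample(names(z), 12)
    up <- g[1:6]; down <- g[7:12]
    expect_equal(wtcs(query_signature(up, down, min_genes = 1), z),
                 oracle_wtcs(up, down, z), tolerance = 1e-12)
  }
})

test_that("swapping up and down lists exactly negates WTCS", {
  for (seed in 1:15) {
    z <- toy_signature(25, seed = seed)
    g <- sample(names(z), 10)
    q <- query_signature(g[1:5], g[6:10], min_genes = 1)
    qs <- query_signature(g[6:10], g[1:5], min_genes = 1)
    expect_equal(wtcs(qs, z), -wtcs(q, z), tolerance = 1e-12)
  }
})

test_that("disjoint query genes absent from the signature are tolerated", {
  z <- toy_signature(10, seed = 3)
  q <- query_signature(c("zz1", "zz2"), c("zz3", "zz4"), min_genes = 1)
  expect_true(is.na(wtcs(q, z)))
})

test_that("score normalization divides by the same-sign group mean", {
  ncs <- normalize_scores(c(0.2, 0.4), cell_id = c("A", "A"),
                          pert_type = c("CP", "CP"))
  expect_equal(ncs, c(2 / 3, 4 / 3))
  # all equal scores -> ncs 1
  expect_equal(normalize_scores(rep(0.37, 4), rep("A", 4), rep("CP", 4)),
               rep(1, 4))
  # singleton group self-normalizes, sign preserved
  expect_equal(normalize_scores(-0.5, "A", "CP"), -1)
  expect_equal(normalize_scores(0, "A", "CP"), 0)
  # groups are (cell, type) strata
  ncs2 <- normalize_scores(c(0.2, 0.4, 0.2, 0.4),
                           cell_id = c("A", "A", "B", "B"),
                           pert_type = "CP")
  expect_equal(ncs2, c(2 / 3, 4 / 3, 2 / 3, 4 / 3))
})

test_that("tau is the signed strict percentile of |ncs|", {
  bg <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(tau_score(0.25, bg), 50)
  expect_equal(tau_score(-0.25, bg), -50)
  expect_equal(tau_score(0.5, bg), 100)
  expect_equal(tau_score(-0.5, bg), -100)
  expect_equal(tau_score(0, bg), 0)
  expect_error(tau_score(0.2, numeric(0)), "empty touchstone")
  for (seed in 1:25) {
    set.seed(seed)
    bg <- rnorm(40)
    v <- rnorm(1)
    expect_equal(tau_score(v, bg), oracle_tau(v, bg))
  }
})

test_that("tau is invariant under strictly monotone rescaling of |ncs|", {
  set.seed(50)
  bg <- abs(rnorm(60))
  v <- c(-1.2, 0.4, 2.2)
  expect_equal(tau_score(v, bg), tau_score(sign(v) * abs(v)^3, bg^3))
  expect_equal(tau_score(v, bg), tau_score(sign(v) * exp(abs(v)), exp(bg)))
})

test_that("median tau summarises across cell lines with midpoint medians", {
  res <- data.frame(query_id = "q", sig_id = paste0("s", 1:6),
                    pert_id = rep(c("cpA", "cpB", "cpC"), each = 2),
                    pert_type = "CP",
                    cell_id = rep(c("X", "Y"), 3),
                    wtcs = 0, ncs = 0,
                    tau = c(-40, 10, -10, 30, 20, 20))
  s <- summarize_median_tau(res, top_k = 1)
  expect_equal(s$median_tau[s$pert_id == "cpA"], -15)  # even-count midpoint
  expect_equal(s$median_tau[s$pert_id == "cpB"], 10)
  expect_equal(s$pert_id[1], "cpC")
  expect_true(s$top_mimic[s$pert_id == "cpC"])
  expect_true(s$top_reverse[s$pert_id == "cpA"])
  # single cell line -> median is that tau; odd-count median
  one <- res[1, ]
  expect_equal(summarize_median_tau(one, top_k = 1)$median_tau, -40)
  odd <- data.frame(query_id = "q", sig_id = paste0("s", 1:3),
                    pert_id = "cp", pert_type = "CP",
                    cell_id = c("X", "Y", "Z"), wtcs = 0, ncs = 0,
                    tau = c(-10, 0, 30))
  expect_equal(summarize_median_tau(odd, top_k = 1)$median_tau, 0)
  expect_warning(summarize_median_tau(res, top_k = 10), "full list")
})

test_that("full query run is antisymmetric under list swap", {
  sim <- small_screen(seed = 61)
  res <- suppressMessages(process_screen(sim$beads, sim$samples, sim$probes))
  cpd <- names(which(sim$truth$active))[1]
  mod <- sim$truth$modules[[cpd]]
  q <- query_signature(mod$gene_id[mod$sign > 0], mod$gene_id[mod$sign < 0],
                       min_genes = 1)
  qs <- query_signature(q$down, q$up, min_genes = 1)
  r1 <- run_query(q, res$level5)
  r2 <- run_query(qs, res$level5)
  expect_equal(r2$wtcs, -r1$wtcs, tolerance = 1e-12)
  expect_equal(r2$ncs, -r1$ncs, tolerance = 1e-12)
  expect_equal(r2$tau, -r1$tau, tolerance = 1e-12)
})

test_that("a query from a signature's own extremes recalls it first", {
  set.seed(70)
  for (rep in 1:20) {
    n_genes <- 60; n_sigs <- 15
    m <- matrix(rnorm(n_genes * n_sigs), n_genes, n_sigs,
                dimnames = list(sprintf("g%02d", 1:n_genes),
                                sprintf("sig%02d", 1:n_sigs)))
    cd <- data.frame(id = colnames(m), pert_id = colnames(m),
                     pert_type = "CP", cell_id = "CL1")
    coll <- gct(m, cdesc = cd, level = 5L)
    j <- sample(n_sigs, 1)
    ord <- order(m[, j], decreasing = TRUE)
    q <- query_signature(rownames(m)[head(ord, 8)],
                         rownames(m)[tail(ord, 8)], min_genes = 1)
    r <- run_query(q, coll)
    expect_equal(which.max(r$wtcs), j)
    expect_equal(max(r$tau), r$tau[j])
  }
})

test_that("touchstone similarity ranks the selected signature first", {
  set.seed(80)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:12)))
  cd <- data.frame(id = colnames(m), pert_id = sprintf("pert%02d", 1:12),
                   pert_type = rep(c("CP", "KD", "OE"), 4),
                   cell_id = "CL1", pert_dose = "10 uM", pert_time = "24 h")
  coll <- gct(m, cdesc = cd, level = 5L)
  r <- touchstone_similarity(coll, "pert03", n_top = 10, n_bottom = 10)
  expect_equal(r$pert_id[1], "pert03")
  expect_equal(r$rank[1], 1)
  expect_true(all(c("CP", "KD", "OE") %in% r$pert_type))
  rc <- touchstone_similarity(coll, "pert03", method = "correlation")
  expect_equal(rc$pert_id[1], "pert03")
  expect_equal(rc$score[1], 1)
  expect_error(touchstone_similarity(coll, "nope"), "matches no signature")
})

test_that("identical signatures tie at the top, broken lexicographically", {
  set.seed(81)
  v <- rnorm(40)
  m <- cbind(sigB = v, sigA = v, sigC = rnorm(40))
  rownames(m) <- sprintf("g%02d", 1:40)
  cd <- data.frame(id = colnames(m), pert_id = c("pertB", "pertA", "pertC"),
                   pert_type = "CP", cell_id = "CL1")
  coll <- gct(m, cdesc = cd, level = 5L)
  r <- touchstone_similarity(coll, "pertB", n_top = 8, n_bottom = 8)
  expect_equal(r$score[1], r$score[2])
  expect_equal(r$pert_id[1:2], c("pertA", "pertB"))
})

test_that("random queries on a null collection centre tau at zero", {
  set.seed(90)
  n_genes <- 80
  m <- matrix(rnorm(n_genes * 40), n_genes, 40,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%02d", 1:40)))
  cd <- data.frame(id = colnames(m), pert_id = colnames(m),
                   pert_type = "CP", cell_id = "CL1")
  coll <- gct(m, cdesc = cd, level = 5L)
  med <- replicate(200, {
    g <- sample(rownames(m), 16)
    q <- query_signature(g[1:8], g[9:16], min_genes = 1)
    median(run_query(q, coll)$tau, na.rm = TRUE)
  })
  expect_lt(abs(mean(med)), 5)
})
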