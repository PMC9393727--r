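test_that("fpkm implements the length- and depth-normalised formula", {
  expect_equal(fpkm(matrix(10, 1, 1), 1000, 1e6)[1, 1], 10)
  # scale invariance: multiplying counts and totals by c leaves FPKM unchanged
  set.seed(1)
  counts <- matrix(rpois(300, 40), 50, 6)
  len <- sample(500:3000, 50)
  f1 <- fpkm(counts, len)
  f2 <- fpkm(counts * 3, len, mapped_totals = colSums(counts) * 3)
  expect_equal(f1, f2, tolerance = 1e-12)
  # brute-force elementwise oracle
  totals <- colSums(counts)
  oracle <- matrix(0, 50, 6)
  for (g in 1:50) for (s in 1:6) {
    oracle[g, s] <- counts[g, s] * 1e9 / (len[g] * totals[s])
  }
  expect_equal(f1, oracle, tolerance = 1e-12)
  expect_error(fpkm(counts, rep(0, 50)), "length")
  expect_error(fpkm(counts, len, mapped_totals = rep(0, 6)), "total")
})

test_that("replicate correlation reports per-group minima and flags degenerate groups", {
  set.seed(2)
  x <- rnorm(100)
  mat <- cbind(a1 = x, a2 = x, b1 = x, b2 = -x)
  samples <- data.frame(sample = c("a1", "a2", "b1", "b2"),
                        group = c("A", "A", "B", "B"))
  out <- replicate_correlation(mat, samples)
  expect_equal(out$min_r[out$group == "A"], 1.0)
  expect_equal(out$min_r[out$group == "B"], -1.0)
  expect_false(out$ok[out$group == "B"])
  # zero-variance replicate: undefined, flagged, not NaN-propagated
  mat2 <- cbind(a1 = x, a2 = rep(1, 100))
  out2 <- replicate_correlation(mat2, samples[1:2, ])
  expect_true(is.na(out2$min_r))
  expect_false(out2$ok)
  expect_error(replicate_correlation(mat[, 1, drop = FALSE], samples[1, ]),
               "fewer than 2")
})

test_that("simulated replicate correlations match a direct pairwise recomputation", {
  sim <- small_sim(seed = 4, n_genes = 200)
  lf <- log2(fpkm(sim$counts, sim$lengths) + 1)
  out <- replicate_correlation(lf, sim$samples)
  cols <- sim$samples$sample[sim$samples$group == "WT_24h"]
  oracle <- min(cor(lf[, cols[1]], lf[, cols[2]]),
                cor(lf[, cols[1]], lf[, cols[3]]),
                cor(lf[, cols[2]], lf[, cols[3]]))
  expect_equal(out$min_r[out$group == "WT_24h"], oracle, tolerance = 1e-12)
})

test_that("status calls follow strict fold-change and FDR thresholds", {
  expect_identical(de_status(1.2, 0.01), "up")
  expect_identical(de_status(0.9, 0.001), "ns")
  expect_identical(de_status(-1.2, 0.01), "down")
  expect_identical(de_status(1.2, 0.05), "ns")   # FDR exactly at threshold
  expect_identical(de_status(1.0, 0.001), "ns")  # log2FC exactly at threshold
  expect_identical(de_status(NA_real_, 0.01), "ns")
  # partition is exhaustive and exclusive
  set.seed(3)
  st <- de_status(rnorm(200, sd = 2), runif(200))
  expect_true(all(st %in% c("up", "down", "ns")))
})

test_that("identical groups give log2FC 0 and no calls", {
  counts <- matrix(rep(c(5L, 50L, 500L), 4), nrow = 3)
  rownames(counts) <- paste0("g", 1:3)
  colnames(counts) <- paste0("s", 1:4)
  samples <- data.frame(sample = paste0("s", 1:4),
                        group = c("B", "B", "A", "A"))
  res <- de_test_rna(counts, samples, c("B", "A"))
  expect_equal(res$log2fc, rep(0, 3))
  expect_identical(res$status, rep("ns", 3))
})

test_that("Welch p-values match an independent per-gene t.test to 1e-12", {
  sim <- small_sim(seed = 6, n_genes = 500)
  res <- de_test_rna(sim$counts, sim$samples, c("OX_24h", "OX_0h"))
  norm <- log2(cpm_normalize(sim$counts) + 1)
  b <- sim$samples$sample[sim$samples$group == "OX_24h"]
  a <- sim$samples$sample[sim$samples$group == "OX_0h"]
  oracle <- vapply(seq_len(nrow(norm)), function(i) {
    stats::t.test(norm[i, b], norm[i, a])$p.value
  }, numeric(1))
  expect_equal(res$p, oracle, tolerance = 1e-12)
})

test_that("flipping the contrast negates log2FC and preserves p", {
  sim <- small_sim(seed = 8, n_genes = 200)
  fwd <- de_test_rna(sim$counts, sim$samples, c("WT_24h", "WT_0h"))
  rev <- de_test_rna(sim$counts, sim$samples, c("WT_0h", "WT_24h"))
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  # pseudocount on normalised means makes the flip exact on log2(FC)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  up_fwd <- fwd$feature[fwd$status == "up"]
  down_rev <- rev$feature[rev$status == "down"]
  expect_setequal(up_fwd, down_rev)
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(9)
  p <- runif(50)
  adj <- bh_adjust(p)
  # step-up oracle computed independently
  o <- order(p)
  stepped <- p[o] * 50 / seq_len(50)
  oracle <- numeric(50)
  oracle[o] <- pmin(1, rev(cummin(rev(stepped))))
  expect_equal(adj, oracle, tolerance = 1e-12)
  expect_gte(min(adj), min(p))
  # order-preserving under permutation
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
})

test_that("empirical FDR among calls stays controlled on simulated data", {
  false_calls <- total_calls <- 0
  for (seed in 1:20) {
    sim <- small_sim(seed = 200 + seed, n_genes = 500)
    res <- de_test_rna(sim$counts, sim$samples, c("WT_24h", "WT_0h"))
    called <- res$status != "ns"
    truly_null <- abs(sim$truth$lfc_rna_wt) <= 1
    false_calls <- false_calls + sum(called & truly_null)
    total_calls <- total_calls + sum(called)
  }
  expect_gt(total_calls, 100)
  expect_lte(false_calls / total_calls, 0.10)
})
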