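test_that("quadrant assignment matches the anchored convention", {
  expect_identical(assign_quadrant(2, 1), 3L)    # concordant up
  expect_identical(assign_quadrant(-2, -1), 7L)  # concordant down
  expect_identical(assign_quadrant(0.1, 0.05), 5L)
  # exhaustive 3x3 grid against a lookup-table oracle
  grid <- expand.grid(rna = c(-2, 0, 2), prot = c(-1, 0, 1))
  lookup <- function(r, p) {
    row <- if (p > log2(1.5)) 1 else if (p < -log2(1.5)) 3 else 2
    col <- if (r < -1) 1 else if (r > 1) 3 else 2
    as.integer((row - 1) * 3 + col)
  }
  got <- assign_quadrant(grid$rna, grid$prot)
  expect_setequal(got, 1:9)  # bijection onto the nine cells
  expect_identical(got, mapply(lookup, grid$rna, grid$prot))
})

test_that("values exactly at a threshold fall to the middle band", {
  expect_identical(assign_quadrant(1, 0), 5L)
  expect_identical(assign_quadrant(-1, 0), 5L)
  expect_identical(assign_quadrant(0, log2(1.5)), 5L)
  expect_identical(assign_quadrant(2, log2(1.5)), 6L)
  expect_error(assign_quadrant(NA, 1), "undefined")
})

test_that("association crosses layers, excludes unmeasured genes and splits by significance", {
  genes <- paste0("g", 1:6)
  prots <- paste0("p", 1:5)  # g6 has no protein
  rna <- toy_rna_result(genes, c(2, -2, 0.2, 2, -2, 3),
                        sig = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  prot <- toy_prot_result(prots, c(1, -1, 0.1, 1, 2),
                          sig = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  map <- data.frame(gene = genes[1:5], protein = prots)
  assoc <- associate_omics(rna, prot, map)
  expect_equal(nrow(assoc$records), 5)
  expect_false("g6" %in% assoc$records$gene)
  expect_identical(assoc$records$quadrant,
                   c(3L, 7L, 5L, 3L, 1L))
  # significant in BOTH layers: g1 only (g2 protein ns, g4 rna ns)
  q3 <- assoc$counts[assoc$counts$quadrant == 3, ]
  expect_equal(q3$n, 2L)
  expect_equal(q3$n_significant, 1L)
  expect_equal(sum(assoc$counts$n), nrow(assoc$records))

  dup <- rbind(map, map[1, ])
  expect_warning(associate_omics(rna, prot, dup), "duplicated")
  conflict <- rbind(map, data.frame(gene = "g1", protein = "p9"))
  expect_error(associate_omics(rna, prot, conflict), "one-to-one")

  none <- data.frame(gene = "gX", protein = "pX")
  empty <- associate_omics(rna, prot, none)
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$counts$n), 0L)
})

test_that("a quadrant-3 pool of 104 with 78 non-significant leaves 26 significant", {
  n <- 104
  genes <- sprintf("g%03d", 1:n)
  prots <- sprintf("p%03d", 1:n)
  sig <- c(rep(TRUE, 26), rep(FALSE, 78))
  rna <- toy_rna_result(genes, rep(2, n), sig)
  prot <- toy_prot_result(prots, rep(1, n), sig)
  assoc <- associate_omics(rna, prot, data.frame(gene = genes, protein = prots))
  q3 <- assoc$counts[assoc$counts$quadrant == 3, ]
  expect_equal(q3$n, 104L)
  expect_equal(q3$n_significant, 26L)
})

test_that("simulated per-quadrant counts equal a brute-force reclassification", {
  sim <- small_sim(seed = 17, n_genes = 400)
  de <- run_four_contrasts(sim)
  assoc <- associate_omics(de$rna_wt, de$prot_wt, sim$gene2protein)
  rec <- assoc$records
  oracle <- integer(9)
  for (i in seq_len(nrow(rec))) {
    r <- rec$rna_log2fc[i]; p <- rec$prot_log2fc[i]
    row <- if (p > log2(1.5)) 1 else if (p < -log2(1.5)) 3 else 2
    col <- if (r < -1) 1 else if (r > 1) 3 else 2
    q <- (row - 1) * 3 + col
    oracle[q] <- oracle[q] + 1L
  }
  expect_identical(assoc$counts$n, oracle)
  expect_equal(sum(assoc$counts$n), nrow(rec))
})

test_that("overlap summaries reproduce the published percentages", {
  expect_equal(venn_pct(4887, 6384, 4069), 56.50)
  expect_equal(venn_pct(304, 319, 73), 13.27)
  # same arithmetic through explicit sets
  a <- paste0("d", 1:4887)
  b <- c(paste0("d", 1:4069), paste0("x", 1:(6384 - 4069)))
  v <- venn_overlap(a, b)
  expect_equal(v$n_common, 4069)
  expect_equal(v$pct_common, 56.50)
  expect_equal(venn_overlap(letters, letters)$pct_common, 100.00)
  # symmetry and intersection bound
  set.seed(18)
  s1 <- sample(letters, 10); s2 <- sample(letters, 15)
  v12 <- venn_overlap(s1, s2); v21 <- venn_overlap(s2, s1)
  expect_equal(v12$pct_common, v21$pct_common)
  expect_lte(v12$n_common, min(v12$n_a, v12$n_b))
  expect_error(venn_pct(10, 10, 11), "intersection")
})
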