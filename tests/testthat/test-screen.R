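test_that("the differential-response statistic is the log2 ratio of fold changes", {
  expect_equal(round(differential_response(2.91, 6.27), 2), 1.11)
  expect_equal(round(differential_response(4.61, 2.25), 2), -1.03)
  expect_equal(differential_response(3.7, 3.7), 0)
  # differential_response(f, f * 2^k) = k for any f > 0
  set.seed(21)
  f <- runif(20, 0.01, 100)
  k <- runif(20, -4, 4)
  expect_equal(differential_response(f, f * 2^k), k, tolerance = 1e-12)
  expect_true(is.na(differential_response(0, 2)))
  expect_true(is.na(differential_response(NA, 2)))
  expect_true(is.na(differential_response(2, -1)))
})

test_that("genotype swap negates deltas and preserves pass flags", {
  set.seed(22)
  tab <- data.frame(gene = paste0("g", 1:50),
                    fc1 = runif(50, 0.02, 20), fc2 = runif(50, 0.02, 20),
                    fc3 = runif(50, 0.02, 20), fc4 = runif(50, 0.02, 20))
  tab$fc3[1:5] <- NA
  fwd <- screen_records(tab)
  swapped <- tab
  names(swapped)[2:5] <- c("fc2", "fc1", "fc4", "fc3")
  rev <- screen_records(swapped)
  expect_equal(rev$delta_rna, -fwd$delta_rna, tolerance = 1e-12)
  expect_equal(rev$delta_prot, -fwd$delta_prot, tolerance = 1e-12)
  expect_identical(rev$pass_rna, fwd$pass_rna)
  expect_identical(rev$pass_any, fwd$pass_any)
})

test_that("the bundled 36-gene table is fully retained by the screen", {
  tab <- zmpdi_screen()
  expect_equal(nrow(tab), 36)
  rec <- screen_records(tab)
  pass <- screen_genes(rec)
  expect_equal(nrow(pass), 36)
  # the five genes singled out in the source study all pass
  expect_equal(sum(pass$highlighted), 5)
  expect_setequal(pass$gene_name[pass$highlighted],
                  c("TUBB2", "PXG4", "PLDa2", "PFK4", "4CL1"))
  # a record with both deltas zero is excluded
  null_rec <- screen_records(data.frame(gene = "z", fc1 = 2, fc2 = 2,
                                        fc3 = 0.5, fc4 = 0.5))
  expect_equal(nrow(screen_genes(null_rec)), 0)
})

test_that("boundary and missing-level rows pass through the correct layer", {
  rec <- screen_records(zmpdi_screen())
  # PXG4: printed FCs give delta_rna of exactly -1; strict > rule means the
  # row passes via the protein level alone
  px <- rec[!is.na(rec$gene_name) & rec$gene_name == "PXG4", ]
  expect_equal(px$delta_rna, -1)
  expect_false(px$pass_rna)
  expect_true(px$pass_prot)
  # MEE55 lacks an RNA fold change entirely
  me <- rec[!is.na(rec$gene_name) & rec$gene_name == "MEE55", ]
  expect_true(is.na(me$delta_rna))
  expect_true(me$pass_prot)
})

test_that("recomputed deltas agree with the published rounded columns", {
  rec <- screen_records(zmpdi_screen())
  # rows whose printed delta is consistent with its rounded fold changes
  # match exactly at two decimals
  exact_rna <- c("BBE", "CHT2", "CHT8", "GLIP", "HB2", "LEA14-A", "PFK4", "XIP2")
  for (g in exact_rna) {
    r <- rec[!is.na(rec$gene_name) & rec$gene_name == g, ][1, ]
    expect_equal(round(r$delta_rna, 2), r$printed_delta_rna, info = g)
  }
  exact_prot <- c("4CL1", "CHT2", "HB2", "LEA14-A", "PLDa2", "XIP2")
  for (g in exact_prot) {
    r <- rec[!is.na(rec$gene_name) & rec$gene_name == g, ][1, ]
    expect_equal(round(r$delta_prot, 2), r$printed_delta_prot, info = g)
  }
  # every protein-level delta sits within rounding distance of the printed
  # value; RNA deltas do too except where the printed FCs are so small that
  # their own rounding dominates the ratio
  dp <- abs(rec$delta_prot - rec$printed_delta_prot)
  expect_true(all(dp <= 0.05, na.rm = TRUE))
  dr <- abs(rec$delta_rna - rec$printed_delta_rna)
  expect_gte(sum(dr <= 0.05, na.rm = TRUE), 30)
})

test_that("screen reports recover planted differential responses on simulated data", {
  sim <- small_sim(seed = 23, n_genes = 1000)
  de <- run_four_contrasts(sim)
  rep_all <- build_screen_report(de$rna_wt, de$rna_ox, de$prot_wt, de$prot_ox,
                                 sim$gene2protein, pool = "all")
  expect_equal(nrow(rep_all), 1000)
  called <- rep_all$gene[rep_all$pass_any]
  truth <- sim$truth
  sens <- mean(truth$gene[truth$screen_true] %in% called)
  spec <- 1 - mean(truth$gene[!truth$screen_true] %in% called)
  expect_gte(sens, 0.8)
  expect_gte(spec, 0.9)
  # the quadrant-3/7 candidate pool is a subset of the full-universe pool
  rep_q <- build_screen_report(de$rna_wt, de$rna_ox, de$prot_wt, de$prot_ox,
                               sim$gene2protein, pool = "quadrant37")
  expect_true(all(rep_q$gene %in% rep_all$gene))
})

test_that("degenerate screen inputs are handled", {
  # an all-null simulation leaves the quadrant-3/7 candidate pool empty
  sim <- small_sim(seed = 24, n_genes = 150, frac_de_wt = 0, frac_de_ox = 0,
                   frac_diff_response = 0)
  de <- run_four_contrasts(sim)
  rep_q <- build_screen_report(de$rna_wt, de$rna_ox, de$prot_wt, de$prot_ox,
                               sim$gene2protein, pool = "quadrant37")
  expect_equal(nrow(rep_q), 0)
  # mismatched gene universes are rejected
  expect_error(
    build_screen_report(de$rna_wt[-1, ], de$rna_ox, de$prot_wt, de$prot_ox,
                        sim$gene2protein),
    "universe")
})
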