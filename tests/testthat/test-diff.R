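test_that("rank-sum p-values match enumeration, symmetry, and the base-R test", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p.value, 0.1)
  x <- c(2, 2, 5)
  expect_equal(wilcoxon_rank_sum(x, x)$p.value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  # cross-check the large-sample branch against stats::wilcox.test
  a <- plasmapipe:::with_seed(1, rnorm(40))
  b <- plasmapipe:::with_seed(2, rnorm(35, 0.4))
  w <- wilcoxon_rank_sum(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(w$p.value, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(w$statistic), unname(ref$statistic))
})

test_that("log2 fold change follows the pseudocount formula", {
  m <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"), c("G1", "G2")))
  # craft cells with total 10000 so CP10K equals raw counts
  m[, "G1"] <- c(3, 3, 1, 1)
  m[, "G2"] <- 10000 - m[, "G1"]
  norm <- log1p(m * 1e4 / rowSums(m))
  norm <- methods::as(norm, "CsparseMatrix")
  lfc <- log2_fold_change(norm, c("a", "b"), c("c", "d"), "G1")
  expect_equal(unname(lfc), log2((3 + 1) / (1 + 1)))
  expect_equal(unname(log2_fold_change(norm, c("a", "b"), c("a", "b"), "G1")), 0)
  # both groups zero -> pseudocount floor gives 0
  m0 <- methods::as(matrix(c(0, 0, 5, 5), 2,
    dimnames = list(c("x", "y"), c("Z", "W"))), "CsparseMatrix")
  n0 <- normalize_log_cp10k(m0)
  expect_equal(unname(log2_fold_change(n0, "x", "y", "Z")), 0)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.005, 0.04, 0.5)), c(0.015, 0.06, 0.5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  for (s in 1:25) {
    p <- plasmapipe:::with_seed(s, runif(sample(1:40, 1))^2)
    adj <- bh_adjust(p)
    expect_equal(adj, stepup_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("differential tables apply modality cutoffs, directions, and detection filter", {
  sim <- simulate_de_matrix(n_in = 60, n_out = 60, n_genes = 300, n_de = 20,
                            seed = 2L)
  norm <- normalize_log_cp10k(sim$counts)
  deg <- differential_features(norm, sim$in_cells, sim$out_cells, "RNA")
  expect_true(all(deg$pass == (abs(deg$log2FC) > 1.5 & deg$fdr < 0.05)))
  expect_true(all(deg$direction[deg$log2FC < 0] == "down"))
  expect_true(all(deg$fdr >= deg$p_val - 1e-12))
  dac <- differential_features(norm, sim$in_cells, sim$out_cells, "ATAC")
  expect_true(all(dac$pass == (abs(dac$log2FC) > 1.25 & dac$fdr < 0.05)))
  # a feature between the cutoffs passes for ATAC but not RNA
  mid <- abs(deg$log2FC) > 1.25 & abs(deg$log2FC) < 1.5 & deg$fdr < 0.05
  if (any(mid)) {
    f <- deg$feature[which(mid)[1]]
    expect_false(deg$pass[deg$feature == f])
    expect_true(dac$pass[dac$feature == f])
  }
  # detection filter: features seen in < 3 cells of the union are not tested
  m <- as.matrix(sim$counts)
  m[, 1] <- 0
  m[c(1, 2), 1] <- 5
  norm2 <- normalize_log_cp10k(methods::as(m, "CsparseMatrix"))
  deg2 <- differential_features(norm2, sim$in_cells, sim$out_cells, "RNA")
  expect_false(colnames(m)[1] %in% deg2$feature)
  expect_error(differential_features(norm, sim$in_cells[1:5], sim$in_cells[3:8],
                                     "RNA"), "disjoint")
})

test_that("gene activity sums peaks over strand-aware windows and conserves counts", {
  gm <- data.frame(gene = c("Gp", "Gm"), chrom = "chr1",
                   start = c(5000L, 5000L), end = c(6000L, 6000L),
                   strand = c("+", "-"), arm = "chr1p")
  peaks <- data.frame(chrom = "chr1",
                      start = c(3100L, 8000L, 7500L, 2000L),
                      end = c(3200L, 8100L, 7600L, 2500L),
                      peak = sprintf("PK%d", 1:4))
  atac <- matrix(c(4, 1, 2, 7), 1, dimnames = list("cell1", peaks$peak))
  act <- gene_activity(methods::as(atac, "CsparseMatrix"), peaks, gm,
                       upstream = 2000)
  # + strand window [3000, 6000): PK1 only; - strand window [5000, 8000): PK3
  expect_equal(unname(act["cell1", "Gp"]), 4)
  expect_equal(unname(act["cell1", "Gm"]), 2)
  # conservation bound: each peak contributes once per overlapping window, so
  # the total gene-level count equals the window-multiplicity-weighted total
  co <- generate_cohort(small_config(seed = 8L))
  act2 <- gene_activity(co$atac[1:50, ], co$peaks, co$gene_model)
  ident <- Matrix::Diagonal(ncol(co$atac))
  dimnames(ident) <- list(co$peaks$peak, co$peaks$peak)
  windows_per_peak <- Matrix::rowSums(
    gene_activity(methods::as(ident, "CsparseMatrix"), co$peaks, co$gene_model))
  expect_equal(sum(act2),
               sum(Matrix::colSums(co$atac[1:50, ]) * windows_per_peak))
  expect_lte(sum(act2), max(windows_per_peak) * sum(co$atac[1:50, ]))
})

test_that("Fisher overlap matches the 2x2 arithmetic and base-R fisher.test", {
  u <- sprintf("g%03d", 1:100)
  res <- set_overlap_fisher(u[1:20], u[11:30], u)
  expect_equal(unname(res$table), c(10, 10, 10, 70))
  expect_equal(res$odds_ratio, 7)
  expect_equal(res$p.value,
               fisher.test(matrix(c(10, 10, 10, 70), 2))$p.value,
               tolerance = 1e-9)
  expect_length(res$intersection, 10)
  expect_equal(set_overlap_fisher(u[1:10], u[21:40], u)$odds_ratio, 0)
  expect_error(set_overlap_fisher("a", "b", character(0)), "universe")
  for (s in 1:30) {
    ns <- plasmapipe:::with_seed(s, {
      N <- sample(5:30, 1)
      na <- sample(0:N, 1); nb <- sample(0:N, 1)
      list(N = N, A = sample(N, na), B = sample(N, nb))
    })
    un <- sprintf("x%02d", seq_len(ns$N))
    mine <- set_overlap_fisher(un[ns$A], un[ns$B], un)
    a <- mine$table[["a"]]; b <- mine$table[["b"]]
    c2 <- mine$table[["c"]]; d <- mine$table[["d"]]
    expect_equal(mine$p.value,
                 fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE))$p.value,
                 tolerance = 1e-8)
  }
})

test_that("signature intersections respect direction consistency", {
  deg <- data.frame(feature = c("A", "B", "C", "D"),
                    direction = c("up", "up", "down", "up"),
                    pass = c(TRUE, TRUE, TRUE, FALSE))
  dac <- data.frame(feature = c("A", "B", "C", "D"),
                    direction = c("up", "down", "down", "up"),
                    pass = c(TRUE, TRUE, TRUE, TRUE))
  sig <- structure(list(name = "kd", genes = c("A", "C"),
                        direction = c(1L, -1L)), class = "signature_set")
  out <- intersect_signatures(deg, dac, list(sig))
  expect_equal(out$consistent_up, "A")    # B disagrees in direction, D fails DEG
  expect_equal(out$consistent_down, "C")
  expect_equal(out$signatures$kd$up, "A")
  expect_equal(out$signatures$kd$down, "C")
  empty <- structure(list(name = "none", genes = character(0),
                          direction = integer(0)), class = "signature_set")
  out2 <- intersect_signatures(deg, dac, list(empty))
  expect_length(out2$signatures$none$any, 0)
  expect_equal(out2$consistent_up, "A")
})
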