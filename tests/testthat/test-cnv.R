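# shared small clone fixture: 2 chromosomes, gain/amp planted on chr1q
clone_fixture <- function(seed = 5L, n_per = 60, n_genes = 240L) {
  gm <- make_gene_model(n_genes, 2L)
  clones <- rep(c("ref", "gain", "amp"), each = n_per)
  bm <- plasmapipe:::with_seed(seed + 1000L, rlnorm(n_genes, log(5), 0.4))
  m <- simulate_clone_matrix(gm, clones,
                             list(gain = c(chr1q = 1.5), amp = c(chr1q = 2.0)),
                             base_means = bm, dispersion = 4, seed = seed)
  list(gm = gm, clones = clones,
       norm = normalize_log_cp10k(m),
       ref = rownames(m)[clones == "ref"], barcodes = rownames(m))
}

test_that("window 1 is identity smoothing and reference cells center near zero", {
  fx <- clone_fixture()
  prof <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 1)
  # self-reference: per-gene mean of the smoothed profile over reference cells ~ 0
  prof31 <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 31)
  expect_lt(max(abs(colMeans(prof31$mat[fx$ref, ]))), 0.1)
  # window 1 equals the unsmoothed clamped signal (before per-cell recentering)
  x <- as.matrix(fx$norm[, prof$gene_model$gene]) / log(2)
  raw <- x - rep(colMeans(x[fx$ref, ]), each = nrow(x))
  raw <- pmin(pmax(raw, -3), 3)
  raw <- raw - apply(raw, 1, median)
  expect_equal(prof$mat, raw, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 4), "odd")
  expect_error(infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 121+1e3), "chromosome")
  expect_error(infer_cnv_profile(fx$norm, fx$gm, character(0), 1), "empty")
})

test_that("planted dosages appear at the expected smoothed signal levels", {
  fx <- clone_fixture(seed = 5L, n_per = 100, n_genes = 800L)
  prof <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 51)
  arm_genes <- which(prof$gene_model$arm == "chr1q")
  interior <- arm_genes[seq(26, length(arm_genes) - 25)]
  gain_mean <- mean(prof$mat[fx$clones == "gain", interior])
  amp_mean <- mean(prof$mat[fx$clones == "amp", interior])
  expect_lt(abs(gain_mean - log2(1.5)), 0.15)
  expect_lt(abs(amp_mean - log2(2.0)), 0.15)
})

test_that("smoothing never crosses chromosome boundaries", {
  # sharp dosage step at the chr1/chr2 boundary: genes on chr2 farther than
  # window/2 from the boundary must look like genes far inside chr2
  fx <- clone_fixture(seed = 8L, n_per = 80, n_genes = 400L)
  prof <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 31)
  chr2 <- which(prof$gene_model$chrom == "chr2")
  amp_cells <- fx$clones == "amp"
  near <- chr2[1:15]    # within window/2 of the boundary
  far <- chr2[51:150]
  expect_lt(abs(mean(prof$mat[amp_cells, near]) - mean(prof$mat[amp_cells, far])),
            0.1)
})

test_that("arm classes follow the thresholds and are monotone in signal", {
  fx <- clone_fixture()
  prof <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 31)
  arm <- call_arm_events(prof, t_loss = -0.15, t_gain = 0.15, t_amp = 0.45)
  # classes consistent with thresholds applied to the reported means
  expect_true(all((arm$class == "amp") == (arm$mean >= 0.45)))
  expect_true(all((arm$class == "gain") == (arm$mean >= 0.15 & arm$mean < 0.45)))
  expect_true(all((arm$class == "loss") == (arm$mean < -0.15)))
  # raising every value cannot demote a class
  prof_up <- prof
  prof_up$mat <- prof$mat + 0.2
  arm_up <- call_arm_events(prof_up, t_loss = -0.15, t_gain = 0.15, t_amp = 0.45)
  rank_of <- function(cl) c(loss = 1, neutral = 2, gain = 3, amp = 4)[cl]
  expect_true(all(rank_of(arm_up$class) >= rank_of(arm$class)))
  expect_error(call_arm_events(prof, t_gain = -1), "thresholds")
})

test_that("clone assignment recovers planted clones and passes labels through", {
  fx <- clone_fixture(seed = 5L, n_per = 100, n_genes = 800L)
  prof <- infer_cnv_profile(fx$norm, fx$gm, fx$ref, window = 51)
  ca <- assign_clones(prof, "hierarchical", k = 3, t_gain = 0.28, t_amp = 0.74)
  tab <- table(ca$clone, fx$clones)
  expect_gte(sum(apply(tab, 1, max)) / length(fx$clones), 0.95)
  # clone annotated with its majority arm classes
  amp_clone <- ca$clone[fx$barcodes[fx$clones == "amp"][1]]
  expect_equal(unname(ca$clone_events[as.character(amp_clone), "chr1q"]), "amp")

  labels <- rep(c("x", "y"), length.out = nrow(prof$mat))
  ca2 <- assign_clones(prof, "from_labels", labels = labels)
  expect_equal(unname(ca2$clone), as.integer(factor(labels, levels = c("x", "y"))))
  ca3 <- assign_clones(prof, "hierarchical", k = 1)
  expect_equal(length(unique(ca3$clone)), 1)
  expect_error(assign_clones(prof, "hierarchical", k = 1e6), "exceeds")
})

test_that("translocation imputation calls the overexpressing patient only once", {
  gm <- make_gene_model(60L, 2L)
  pats <- rep(sprintf("P%02d", 1:12), each = 30)
  cells <- sprintf("C%04d", seq_along(pats))
  m <- plasmapipe:::with_seed(1, {
    base <- rlnorm(60, log(3), 0.4)
    mm <- matrix(rnbinom(length(pats) * 60, mu = rep(base, each = length(pats)),
                         size = 2), length(pats))
    mm[pats == "P05", 7] <- rnbinom(sum(pats == "P05"), mu = base[7] * 8, size = 2)
    mm
  })
  dimnames(m) <- list(cells, gm$gene)
  norm <- normalize_log_cp10k(methods::as(m + 1L, "CsparseMatrix"))
  res <- impute_translocation(norm, pats, c(CCND1 = gm$gene[7], NSD2 = gm$gene[9]))
  expect_equal(res$call[res$patient == "P05"], gm$gene[7])
  # identical expression across patients gives no calls
  norm0 <- normalize_log_cp10k(methods::as(matrix(3L, 40, 4,
    dimnames = list(sprintf("c%d", 1:40), c("A", "B", "C", "D"))), "CsparseMatrix"))
  res0 <- impute_translocation(norm0, rep(sprintf("P%d", 1:4), each = 10),
                               c(m1 = "A", m2 = "B"))
  expect_true(all(is.na(res0$call)))
  expect_error(impute_translocation(norm0, rep("P1", 40), c(m1 = "A")), "3 patients")
})

test_that("with two elevated markers only the stronger one is called", {
  gm <- make_gene_model(40L, 2L)
  pats <- rep(sprintf("P%02d", 1:10), each = 25)
  m <- plasmapipe:::with_seed(3, {
    base <- rlnorm(40, log(4), 0.3)
    mm <- matrix(rnbinom(length(pats) * 40, mu = rep(base, each = length(pats)),
                         size = 4), length(pats))
    sel <- pats == "P02"
    mm[sel, 5] <- rnbinom(sum(sel), mu = base[5] * 10, size = 4)
    mm[sel, 9] <- rnbinom(sum(sel), mu = base[9] * 3, size = 4)
    mm
  })
  dimnames(m) <- list(sprintf("C%04d", seq_along(pats)), gm$gene)
  norm <- normalize_log_cp10k(methods::as(m + 1L, "CsparseMatrix"))
  res <- impute_translocation(norm, pats, c(a = gm$gene[5], b = gm$gene[9]))
  expect_equal(res$call[res$patient == "P02"], gm$gene[5])
  expect_equal(sum(!is.na(res$call[res$patient == "P02"])), 1)
})

test_that("hyperdiploidy needs gains on at least the configured number of trisomy arms", {
  calls <- rbind(P1 = c("neutral", "neutral", "neutral"),
                 P2 = c("gain", "neutral", "neutral"),
                 P3 = c("gain", "amp", "neutral"),
                 P4 = c("gain", "gain", "gain"))
  colnames(calls) <- c("chr1p", "chr3p", "chr3q")
  hrd <- impute_hyperdiploidy(calls, c("chr1p", "chr3p", "chr3q"), min_gains = 2)
  expect_equal(unname(hrd), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("patient-level arm calls take the majority with severity tie-breaks", {
  cls <- matrix(c("gain", "gain", "neutral",
                  "amp", "gain", "amp"), 3, 2,
                dimnames = list(c("c1", "c2", "c3"), c("chr1q", "chr2p")))
  obj <- structure(list(class = cls, mean = matrix(0, 3, 2)),
                   class = "arm_event_call")
  pc <- patient_arm_calls(obj, c("P1", "P1", "P1"))
  expect_equal(unname(pc["P1", "chr1q"]), "gain")
  expect_equal(unname(pc["P1", "chr2p"]), "amp")
})
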