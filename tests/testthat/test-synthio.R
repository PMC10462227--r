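test_that("invalid configurations raise errors naming the offending field", {
  expect_error(synth_config(contaminant_fraction = 1.5), "contaminant_fraction")
  expect_error(synth_config(gain_multiplier = 0), "gain_multiplier")
  expect_error(synth_config(cells_per_patient = 10L), "cells_per_patient")
  expect_error(synth_config(rare_mean = c(0.5, 0.6)), "rare_mean")
  expect_error(synth_config(normal_fraction = 0.95, rare_mean = c(0.1, 0.1, 0.1)),
               "normal_fraction")
})

test_that("cohort generation is deterministic and respects basic structure", {
  cfg <- small_config(seed = 4L)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1$rna, co2$rna)
  expect_identical(co1$atac, co2$atac)
  expect_identical(co1$truth$cells, co2$truth$cells)

  expect_equal(nrow(co1$rna), sum(cfg$n_patients) * cfg$cells_per_patient)
  expect_equal(ncol(co1$rna), cfg$n_genes)
  expect_equal(ncol(co1$atac), cfg$n_peaks)
  # counts are non-negative integers; dimensions match identifier lists
  expect_true(all(co1$rna@x >= 0) && all(co1$rna@x == floor(co1$rna@x)))
  expect_true(all(co1$atac@x >= 0) && all(co1$atac@x == floor(co1$atac@x)))
  expect_false(anyDuplicated(rownames(co1$rna)) > 0)
  # every cell has exactly one population label and clone id
  expect_equal(nrow(co1$truth$cells), nrow(co1$rna))
  expect_true(all(co1$truth$cells$population %in%
                    c("contaminant", "normal", "bulk", "rare")))
  # planted segments reference genes present in the gene model
  expect_true(all(co1$truth$events$arm %in% co1$gene_model$arm))
  expect_true(all(co1$truth$de_genes %in% co1$gene_model$gene))
})

test_that("contaminant fraction zero yields no contaminant cells, and the marker is silenced", {
  co <- generate_cohort(small_config(seed = 2L, contaminant_fraction = 0))
  expect_false(any(co$truth$cells$population == "contaminant"))
  co2 <- generate_cohort(small_config(seed = 2L))
  cont <- co2$truth$cells$barcode[co2$truth$cells$population == "contaminant"]
  expect_gt(length(cont), 0)
  expect_equal(sum(co2$rna[cont, co2$truth$marker_gene]), 0)
})

test_that("per-patient contaminant fractions concentrate around the configured rate", {
  co <- generate_cohort(small_config(seed = 9L))
  tc <- co$truth$cells
  frac <- tapply(tc$population == "contaminant", tc$patient, mean)
  n <- co$config$cells_per_patient
  se <- sqrt(0.1 * 0.9 / n)
  expect_true(all(abs(frac - 0.1) <= 3 * se))
})

test_that("rare-cluster proportions track the configured stage means over seeds", {
  # Monte-Carlo check of the compositional layer against its own parameters
  means <- matrix(0, 50, 3)
  for (s in 1:50) {
    sp <- simulate_proportions(synth_config(seed = s))
    stage <- sp$stage
    means[s, ] <- tapply(sp$proportions[, "rare"], stage[rownames(sp$proportions)],
                         mean)[c("SMM", "NDMM", "RRMM")]
  }
  expect_true(all(abs(colMeans(means) - c(0.01, 0.03, 0.08)) <= 0.02))
})

test_that("doubling a dosage multiplier raises the mean of affected genes in carrier cells", {
  gm <- make_gene_model(200L, 2L)
  clones <- rep(c("ref", "carrier"), each = 80)
  mean_arm <- function(dosage, seed) {
    m <- simulate_clone_matrix(gm, clones, list(carrier = c(chr1q = dosage)),
                               seed = seed)
    mean(as.matrix(m[clones == "carrier", gm$gene[gm$arm == "chr1q"]]))
  }
  for (s in 1:5) {
    expect_lt(mean_arm(1.5, s), mean_arm(3.0, s))
  }
})

test_that("write/read round-trip reproduces matrices and accounts all barcodes", {
  co <- generate_cohort(small_config(seed = 6L))
  d <- withr::local_tempdir()
  paths <- write_cohort(co, d)
  rna <- read_10x(file.path(d, "rna"))
  atac <- read_10x(file.path(d, "atac"))
  expect_true(all(rna == co$rna))
  expect_identical(dimnames(rna), dimnames(co$rna))
  expect_true(all(atac == co$atac))
  expect_equal(length(readLines(file.path(d, "rna", "barcodes.tsv"))),
               sum(co$config$n_patients) * co$config$cells_per_patient)
  back <- load_cohort(d)
  expect_equal(back$metadata$patients$patient, co$metadata$patients$patient)
  expect_equal(back$truth$de_genes, co$truth$de_genes)
})

test_that("an empty matrix writes valid triplet files with zero data lines", {
  m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(0, 3))
  colnames(m) <- c("A", "B", "C")
  rownames(m) <- character(0)
  d <- withr::local_tempdir()
  plasmapipe:::write_10x(m, file.path(d, "rna"), "RNA", colnames(m))
  back <- read_10x(file.path(d, "rna"))
  expect_equal(dim(back), c(0L, 3L))
})
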