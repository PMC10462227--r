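test_that("log CP10K normalization matches its definition and is scale invariant", {
  m <- tiny_counts(5, 4)
  norm <- normalize_log_cp10k(m)
  tot <- Matrix::rowSums(m)
  expect_equal(as.matrix(norm),
               log1p(as.matrix(m) * 1e4 / tot), ignore_attr = TRUE)
  # zero counts stay zero; tripling a cell's counts changes nothing
  m2 <- m
  m2[2, ] <- m[2, ] * 3
  expect_equal(as.numeric(normalize_log_cp10k(m2)[2, ]), as.numeric(norm[2, ]))
  m3 <- m
  m3[1, ] <- 0
  expect_error(normalize_log_cp10k(m3), "QC")
})

test_that("PCA matches a brute-force eigendecomposition and fixes signs", {
  x <- plasmapipe:::with_seed(7, matrix(rnorm(200), 20, 10))
  dimnames(x) <- list(sprintf("C%02d", 1:20), sprintf("F%02d", 1:10))
  e <- reduce(methods::as(x, "CsparseMatrix"), 5)
  # oracle: eigendecomposition of the covariance matrix
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(abs(e$rotation), abs(ev$vectors[, 1:5]), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(e$sdev^2, ev$values[1:5], tolerance = 1e-8)
  # orthonormal loadings, decreasing variance, deterministic sign convention
  expect_equal(crossprod(e$rotation), diag(5), ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(diff(e$sdev) <= 1e-8))
  for (j in 1:5) expect_gt(e$rotation[which.max(abs(e$rotation[, j])), j], 0)
  expect_identical(e$mat, reduce(methods::as(x, "CsparseMatrix"), 5)$mat)
  # rank-1 structure is captured by the first component
  r1 <- outer(rnorm(30), rnorm(8))
  dimnames(r1) <- list(sprintf("C%02d", 1:30), sprintf("F%02d", 1:8))
  er1 <- reduce(methods::as(r1, "CsparseMatrix"), 3)
  expect_gt(er1$sdev[1]^2 / sum(er1$sdev^2), 0.99)
  expect_error(reduce(methods::as(x, "CsparseMatrix"), 10), "n_components")
})

test_that("the Gram-matrix PCA path (features > cells) agrees with prcomp", {
  x <- plasmapipe:::with_seed(8, matrix(rnorm(15 * 40), 15, 40))
  dimnames(x) <- list(sprintf("C%02d", 1:15), sprintf("F%02d", 1:40))
  e <- reduce(methods::as(x, "CsparseMatrix"), 4)
  pr <- prcomp(x, rank. = 4)
  expect_equal(abs(e$mat), abs(pr$x[, 1:4]), ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(e$sdev, pr$sdev[1:4], tolerance = 1e-6)
})

test_that("well-separated blobs are recovered exactly; one blob stays whole", {
  b <- make_blobs(100, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 2)
  # low resolution: the two connected components are recovered exactly
  lab <- snn_cluster(b$x, k_neighbors = 15, resolution = 0.05, seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(unname(vapply(split(lab, b$truth),
                             function(v) length(unique(v)), integer(1))),
               c(1L, 1L))
  # higher resolution may split blobs further but never mixes them
  lab_hi <- snn_cluster(b$x, k_neighbors = 15, resolution = 1, seed = 1)
  expect_equal(length(unique(paste(lab_hi, b$truth))), length(unique(lab_hi)))
  one <- make_blobs(120, rbind(c(0, 0)), sd = 1, seed = 3)
  lab1 <- snn_cluster(one$x, k_neighbors = 15, resolution = 0.05, seed = 1)
  expect_equal(length(unique(lab1)), 1)
  expect_error(snn_cluster(one$x[1:10, ], k_neighbors = 20, seed = 1), "fewer cells")
})

test_that("clustering is deterministic and invariant to cell order", {
  b <- make_blobs(80, rbind(c(0, 0), c(8, 8), c(-8, 8)), sd = 1, seed = 5)
  lab1 <- snn_cluster(b$x, k_neighbors = 10, seed = 9)
  lab2 <- snn_cluster(b$x, k_neighbors = 10, seed = 9)
  expect_identical(lab1, lab2)
  perm <- plasmapipe:::with_seed(1, sample(nrow(b$x)))
  lab3 <- snn_cluster(b$x[perm, ], k_neighbors = 10, seed = 9)
  expect_identical(as.integer(lab3[match(rownames(b$x), rownames(b$x)[perm])]),
                   as.integer(lab1))
})

test_that("modality fusion weights behave under symmetry, equal mode, and noise", {
  b <- make_blobs(80, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 4)
  emb <- b$x
  f_eq <- fuse_modalities(emb, emb, mode = "equal", k_neighbors = 10)
  expect_true(all(f_eq$weights$w_rna == 0.5))
  expect_true(all(f_eq$weights$w_rna + f_eq$weights$w_atac == 1))
  f_wnn <- fuse_modalities(emb, emb, mode = "wnn", k_neighbors = 10)
  expect_true(all(abs(f_wnn$weights$w_rna - 0.5) <= 0.05))
  # informative RNA vs pure-noise ATAC: RNA dominates for most cells
  ok <- 0
  for (s in 1:10) {
    noise <- plasmapipe:::with_seed(100 + s,
      matrix(rnorm(length(emb) * 5), nrow(emb)))
    rownames(noise) <- rownames(emb)
    fw <- fuse_modalities(emb, noise, mode = "wnn", k_neighbors = 10)
    ok <- ok + (median(fw$weights$w_rna) > 0.5)
  }
  expect_gte(ok, 9)
  bad <- emb[seq_len(nrow(emb) - 1), ]
  expect_error(fuse_modalities(emb, bad, k_neighbors = 10), "barcode")
})

test_that("joint clustering of a fused graph recovers shared structure", {
  b <- make_blobs(80, rbind(c(0, 0), c(10, 10)), sd = 1, seed = 6)
  f <- fuse_modalities(b$x, b$x, mode = "equal", k_neighbors = 10)
  lab <- joint_cluster(f, resolution = 0.05, seed = 2)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(lab), nrow(b$x))
})
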