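# small builders shared across test files

# tiny deterministic count matrix with named dims
tiny_counts <- function(nr = 6, nc = 5, seed = 1) {
  m <- plasmapipe:::with_seed(seed, matrix(rpois(nr * nc, 3), nr, nc))
  dimnames(m) <- list(sprintf("C%02d", seq_len(nr)), sprintf("G%02d", seq_len(nc)))
  methods::as(m, "CsparseMatrix")
}

# two (or more) well-separated Gaussian blobs in d dimensions
make_blobs <- function(n_per = 100, centers = rbind(c(0, 0), c(10, 10)),
                       sd = 1, seed = 1) {
  plasmapipe:::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
        rep(centers[i, ], each = n_per)
    }))
    rownames(x) <- sprintf("B%04d", seq_len(nrow(x)))
    list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
  })
}

# small cohort config for fast tests
small_config <- function(seed = 1L, ...) {
  synth_config(n_patients = c(2L, 2L, 2L), cells_per_patient = 120L,
               n_genes = 300L, n_peaks = 500L,
               n_gain_carriers = 1L, n_amp_carriers = 1L,
               n_hyperdiploid_carriers = 1L, n_translocation_carriers = 1L,
               n_tp53_carriers = 1L, seed = seed, ...)
}

# default clustering closure used by plasma-selection tests
counts_cluster_fn <- function(seed = 0L, n_comp = 20, k = 20) {
  function(counts) {
    norm <- normalize_log_cp10k(counts)
    emb <- reduce(norm, min(n_comp, ncol(norm) - 1, nrow(norm) - 1))
    snn_cluster(emb, k_neighbors = min(k, nrow(norm) - 1), seed = seed)
  }
}

# independent enumeration oracle for the two-sided rank-sum p-value
enum_wilcoxon_p <- function(x, y) {
  r <- rank(c(x, y))
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  sums <- combn(r, nx, sum)
  min(1, 2 * min(mean(sums <= obs + 1e-9), mean(sums >= obs - 1e-9)))
}

# independent hand application of the BH step-up definition
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- min(prev, 1)
  }
  adj
}
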