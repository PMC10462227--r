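#' Log CP10K normalization
#'
#' `value = ln(1 + 10000 * count / cell_total)`. Zero-total cells are a QC
#' failure and raise an error.
#'
#' @param m sparse cells x features count matrix.
#' @return sparse normalized matrix of the same shape.
#' @export
normalize_log_cp10k <- function(m) {
  totals <- Matrix::rowSums(m)
  if (any(totals == 0)) {
    stop("zero-total cells present; run QC filtering first", call. = FALSE)
  }
  out <- Matrix::Diagonal(x = 1e4 / totals) %*% m
  out <- methods::as(out, "CsparseMatrix")
  out@x <- log1p(out@x)
  dimnames(out) <- dimnames(m)
  out
}

#' Select the most variable features
#'
#' Ranks features by variance of the normalized values and keeps the top
#' `n` (all features if fewer).
#'
#' @param norm normalized cells x features matrix.
#' @param n number of features to keep.
#' @return character vector of feature ids, in original column order.
#' @export
select_variable_features <- function(norm, n = 2000) {
  mu <- Matrix::colMeans(norm)
  ex2 <- Matrix::colMeans(norm^2)
  v <- ex2 - mu^2
  keep <- sort(utils::head(order(v, decreasing = TRUE), n))
  colnames(norm)[keep]
}

#' Principal-component embedding
#'
#' Exact PCA by eigendecomposition of the feature covariance matrix (or the
#' cell Gram matrix when cells are fewer), with components ordered by
#' decreasing explained variance. The sign of each component is fixed by
#' forcing the largest-magnitude loading positive, so the result is fully
#' deterministic.
#'
#' @param norm normalized cells x features matrix.
#' @param n_components number of components (< min(cells, features)).
#' @param modality optional tag stored on the result.
#' @return list of class `embedding`: `mat` (cells x components), `sdev`,
#'   `rotation` (features x components), `modality`.
#' @export
reduce <- function(norm, n_components = 30, modality = NA_character_) {
  n <- nrow(norm)
  p <- ncol(norm)
  if (n_components >= min(n, p)) {
    stop("n_components must be < min(cells, features)", call. = FALSE)
  }
  mu <- Matrix::colMeans(norm)
  if (p <= n) {
    xd <- as.matrix(norm)
    cov <- (crossprod(xd) - n * tcrossprod(mu)) / (n - 1)
    eig <- eigen(cov, symmetric = TRUE)
    rot <- eig$vectors[, seq_len(n_components), drop = FALSE]
    ev <- eig$values[seq_len(n_components)]
    scores <- xd %*% rot - rep(colSums(mu * rot), each = n)
  } else {
    xc <- as.matrix(norm) - rep(mu, each = n)
    gram <- tcrossprod(xc) / (n - 1)
    eig <- eigen(gram, symmetric = TRUE)
    ev <- eig$values[seq_len(n_components)]
    u <- eig$vectors[, seq_len(n_components), drop = FALSE]
    scores <- u * rep(sqrt(pmax(ev, 0) * (n - 1)), each = n)
    rot <- crossprod(xc, u) / rep(sqrt(pmax(ev, 0) * (n - 1)) + 1e-300, each = p)
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(norm)
  rownames(rot) <- colnames(norm)
  structure(list(mat = scores, sdev = sqrt(pmax(ev, 0)), rotation = rot,
                 modality = modality), class = "embedding")
}

# brute-force exact kNN (Euclidean, C++ kernel); returns n x (k+1) index
# matrix, self included as first neighbor. Ties broken by (distance, index).
knn_index <- function(x, k) {
  n <- nrow(x)
  if (k >= n) stop("fewer cells than k_neighbors", call. = FALSE)
  .knn_brute(as.matrix(x), as.integer(k))
}

# shared-nearest-neighbor graph: Jaccard overlap of (k+1)-neighbor sets
# (self included), restricted to kNN pairs, pruned below `prune`.
snn_graph <- function(emb, k = 20, prune = 1 / 15) {
  x <- if (inherits(emb, "embedding")) emb$mat else as.matrix(emb)
  nn <- knn_index(x, k)
  n <- nrow(x)
  kk <- ncol(nn)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kk),
                              j = as.vector(t(nn)), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(adj)          # shared neighbor counts
  mask <- (adj + Matrix::t(adj)) > 0        # kNN pairs only
  inter <- inter * mask
  w <- inter
  w@x <- w@x / (2 * kk - w@x)               # Jaccard: |I| / (|A|+|B|-|I|)
  w@x[w@x < prune] <- 0
  w <- Matrix::drop0(w)
  Matrix::diag(w) <- 0
  w <- Matrix::drop0(w)
  rownames(w) <- colnames(w) <- rownames(x)
  w
}

# modularity community detection on a weighted adjacency; labels 0-based,
# relabeled by decreasing size (ties by first canonical occurrence).
cluster_graph <- function(adj, resolution = 1.0, seed = 0L) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.numeric(sizes), as.numeric(first))
  relabel <- stats::setNames(seq_along(ord) - 1L, names(sizes)[ord])
  out <- unname(relabel[as.character(memb)])
  names(out) <- rownames(adj)
  out
}

#' Shared-nearest-neighbor modularity clustering
#'
#' Builds a kNN graph (Euclidean, ties broken by distance then index),
#' weights edges by the Jaccard overlap of neighbor sets, and partitions by
#' Louvain modularity at the given resolution. Cells are processed in a
#' canonical order derived from the embedding values, so the partition is
#' invariant to the input row order and deterministic for a fixed seed.
#' Cluster ids are contiguous integers from 0, ordered by decreasing size.
#'
#' @param emb an `embedding` (or plain cells x components matrix).
#' @param k_neighbors neighbors per cell.
#' @param resolution modularity resolution.
#' @param seed RNG seed for the community step.
#' @return named integer vector of cluster ids with attributes `resolution`
#'   and `seed`.
#' @export
snn_cluster <- function(emb, k_neighbors = 20, resolution = 1.0, seed = 0L) {
  x <- if (inherits(emb, "embedding")) emb$mat else as.matrix(emb)
  ord <- do.call(order, as.data.frame(x))
  adj <- snn_graph(x[ord, , drop = FALSE], k = k_neighbors)
  lab_canon <- cluster_graph(adj, resolution = resolution, seed = seed)
  labels <- integer(nrow(x))
  labels[ord] <- lab_canon
  names(labels) <- rownames(x)
  attr(labels, "resolution") <- resolution
  attr(labels, "seed") <- seed
  labels
}

#' Fuse RNA and ATAC neighbor graphs with per-cell modality weights
#'
#' Mode `"equal"` gives every cell weights (0.5, 0.5). Mode `"wnn"` scores
#' each modality per cell by its within-modality neighborhood prediction
#' accuracy: the distance from the cell to the mean of its k nearest
#' neighbors, normalized by the cell's mean distance to all cells in that
#' modality; weights are a softmax of the two accuracy scores. The fused
#' graph is the per-edge weighted average of the two SNN graphs, using the
#' mean of the two incident cells' weights.
#'
#' @param emb_rna,emb_atac `embedding` objects sharing barcode order.
#' @param mode "equal" or "wnn".
#' @param k_neighbors neighbors per cell.
#' @param tau softmax temperature for wnn weights.
#' @return list with `graph` (fused sparse adjacency, usable with
#'   [joint_cluster()]) and `weights` (data.frame barcode, w_rna, w_atac).
#' @export
fuse_modalities <- function(emb_rna, emb_atac, mode = c("equal", "wnn"),
                            k_neighbors = 20, tau = 0.2) {
  mode <- match.arg(mode)
  x_rna <- if (inherits(emb_rna, "embedding")) emb_rna$mat else as.matrix(emb_rna)
  x_atac <- if (inherits(emb_atac, "embedding")) emb_atac$mat else as.matrix(emb_atac)
  if (nrow(x_rna) != nrow(x_atac) ||
      !identical(rownames(x_rna), rownames(x_atac))) {
    stop("embeddings must share barcode order", call. = FALSE)
  }
  n <- nrow(x_rna)
  if (mode == "equal") {
    w_rna <- rep(0.5, n)
  } else {
    s_rna <- neighborhood_score(x_rna, k_neighbors)
    s_atac <- neighborhood_score(x_atac, k_neighbors)
    w_rna <- 1 / (1 + exp((s_rna - s_atac) / tau))
  }
  w_atac <- 1 - w_rna
  g_rna <- snn_graph(x_rna, k = k_neighbors)
  g_atac <- snn_graph(x_atac, k = k_neighbors)
  wr <- (outer_mean_weights(g_rna, w_rna))
  wa <- (outer_mean_weights(g_atac, w_atac))
  fused <- wr + wa
  rownames(fused) <- colnames(fused) <- rownames(x_rna)
  list(graph = fused,
       weights = data.frame(barcode = rownames(x_rna) %||% seq_len(n),
                            w_rna = w_rna, w_atac = w_atac,
                            stringsAsFactors = FALSE))
}

# scale each edge of adjacency `g` by the mean of its incident cells' weights
outer_mean_weights <- function(g, w) {
  d <- Matrix::Diagonal(x = w / 2)
  d %*% g + g %*% d
}

# within-modality neighborhood prediction error, normalized by the cell's
# root-mean-square distance to all cells (lower = more informative structure)
neighborhood_score <- function(x, k) {
  n <- nrow(x)
  nn <- knn_index(x, min(k, n - 1L))
  nn <- nn[, -1, drop = FALSE]  # drop self
  pred <- matrix(0, n, ncol(x))
  for (j in seq_len(ncol(nn))) pred <- pred + x[nn[, j], , drop = FALSE]
  pred <- pred / ncol(nn)
  err <- sqrt(rowSums((x - pred)^2))
  dev2 <- rowSums((x - rep(colMeans(x), each = n))^2)
  spread <- sqrt(dev2 + mean(dev2))  # E||x_i - x_j||^2 = dev2_i + mean(dev2)
  err / (spread + 1e-12)
}

#' Cluster a fused multimodal graph
#'
#' Community detection on the adjacency returned by [fuse_modalities()];
#' deterministic for a fixed seed.
#'
#' @param fused result of [fuse_modalities()].
#' @param resolution modularity resolution.
#' @param seed RNG seed.
#' @return named integer vector of 0-based cluster ids.
#' @export
joint_cluster <- function(fused, resolution = 1.0, seed = 0L) {
  cluster_graph(fused$graph, resolution = resolution, seed = seed)
}
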