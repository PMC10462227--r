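#' Wilcoxon rank-sum test (Mann-Whitney U)
#'
#' Midranks for ties. The p-value is exact when the combined sample size is
#' at most 12 (full enumeration of the conditional permutation distribution
#' of the midranks, so ties are handled exactly); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param correct apply the 0.5 continuity correction in the normal
#'   approximation (the convention for the feature-level differential
#'   tests); rank tests on per-patient proportions use `FALSE`.
#' @return list with `statistic` (U for the first sample) and `p.value`
#'   (two-sided).
#' @export
wilcoxon_rank_sum <- function(x, y, correct = TRUE) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0 || ny == 0) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  n <- nx + ny
  ties <- table(r)
  if (n <= 12) {
    us <- utils::combn(r, nx, sum) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    p <- min(p, 1)
  } else {
    mu <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nx * ny / 12 * ((n + 1) - tie_term))
    if (sigma == 0) return(list(statistic = u, p.value = 1))
    z <- (abs(u - mu) - if (correct) 0.5 else 0) / sigma
    p <- if (z <= 0) 1 else min(1, 2 * stats::pnorm(-z))
  }
  list(statistic = u, p.value = p)
}

#' Log2 fold change of group means on the CP10K scale
#'
#' `log2((m_in + 1) / (m_out + 1))` where each `m` is the group mean of
#' CP10K-normalized counts (the log-normalized input is un-logged first).
#'
#' @param norm normalized (log CP10K) cells x features matrix.
#' @param in_cells,out_cells barcodes of the two groups (non-empty).
#' @param features features to evaluate (default all).
#' @return named numeric vector of log2 fold changes.
#' @export
log2_fold_change <- function(norm, in_cells, out_cells, features = colnames(norm)) {
  if (length(in_cells) == 0 || length(out_cells) == 0) {
    stop("both cell groups must be non-empty", call. = FALSE)
  }
  m_in <- group_mean_cp10k(norm, in_cells, features)
  m_out <- group_mean_cp10k(norm, out_cells, features)
  log2((m_in + 1) / (m_out + 1))
}

group_mean_cp10k <- function(norm, cells, features) {
  sub <- norm[cells, features, drop = FALSE]
  ex <- expm1(sub)
  Matrix::colMeans(ex)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_(j >= i) (p_(j) * m / j)`, capped at 1 and mapped back to
#' the input order.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted values (the BH false discovery rate).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Cluster-vs-rest differential features
#'
#' Per feature: log2 fold change of group mean CP10K plus a two-sided
#' Wilcoxon rank-sum p-value on the normalized values, BH-adjusted across
#' all tested features of the contrast. Only features detected (nonzero) in
#' at least `min_cells` cells of the two groups' union are tested. The pass
#' flag applies the modality cutoff (|log2FC| > 1.5 for RNA, > 1.25 for
#' gene-level ATAC) together with FDR < `fdr`.
#'
#' @param norm normalized cells x features matrix.
#' @param in_cells,out_cells disjoint non-empty barcode sets.
#' @param modality "RNA" or "ATAC" (sets the fold-change cutoff).
#' @param lfc_cutoff override of the modality cutoff.
#' @param fdr FDR cutoff for the pass flag.
#' @param min_cells detection filter.
#' @return data.frame of class `diff_table`: feature, mean_in, mean_out,
#'   log2FC, p_val, fdr, direction, pass.
#' @export
differential_features <- function(norm, in_cells, out_cells,
                                  modality = c("RNA", "ATAC"),
                                  lfc_cutoff = NULL, fdr = 0.05,
                                  min_cells = 3) {
  modality <- match.arg(modality)
  if (length(intersect(in_cells, out_cells))) {
    stop("cell groups must be disjoint", call. = FALSE)
  }
  if (length(in_cells) == 0 || length(out_cells) == 0) {
    stop("both cell groups must be non-empty", call. = FALSE)
  }
  cutoff <- lfc_cutoff %||% if (modality == "RNA") 1.5 else 1.25
  all_cells <- c(in_cells, out_cells)
  sub <- norm[all_cells, , drop = FALSE]
  detected <- Matrix::colSums(sub > 0) >= min_cells
  feats <- colnames(norm)[detected]
  sub <- as.matrix(sub[, feats, drop = FALSE])
  grp_in <- seq_along(in_cells)

  m_in <- colMeans(expm1(sub[grp_in, , drop = FALSE]))
  m_out <- colMeans(expm1(sub[-grp_in, , drop = FALSE]))
  lfc <- log2((m_in + 1) / (m_out + 1))
  n <- length(all_cells)
  if (n <= 12) {
    pv <- vapply(seq_along(feats), function(j) {
      wilcoxon_rank_sum(sub[grp_in, j], sub[-grp_in, j])$p.value
    }, numeric(1))
  } else {
    # vectorized normal approximation (same formula as wilcoxon_rank_sum):
    # midranks per column, tie correction via tabulated doubled ranks
    nx <- length(in_cells)
    rk <- apply(sub, 2, rank)
    u <- colSums(rk[grp_in, , drop = FALSE]) - nx * (nx + 1) / 2
    tie_term <- vapply(seq_along(feats), function(j) {
      cnt <- tabulate(as.integer(2 * rk[, j]), nbins = 2L * n)
      sum(cnt^3 - cnt)
    }, numeric(1)) / (n * (n - 1))
    sigma <- sqrt(nx * (n - nx) / 12 * ((n + 1) - tie_term))
    z <- (abs(u - nx * (n - nx) / 2) - 0.5) / pmax(sigma, 1e-300)
    pv <- ifelse(sigma == 0 | z <= 0, 1, pmin(1, 2 * stats::pnorm(-z)))
  }
  q <- bh_adjust(pv)
  out <- data.frame(
    feature = feats, mean_in = m_in, mean_out = m_out,
    log2FC = lfc, p_val = pv, fdr = q,
    direction = ifelse(lfc >= 0, "up", "down"),
    pass = abs(lfc) > cutoff & q < fdr,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "modality") <- modality
  attr(out, "cutoff") <- cutoff
  class(out) <- c("diff_table", "data.frame")
  out
}

#' Gene-level aggregation of peak accessibility
#'
#' Per cell and gene, sums the counts of all peaks overlapping the gene
#' body extended by `upstream` bp beyond the strand-aware TSS (intervals
#' 0-based half-open). A peak overlapping several genes' windows counts
#' toward each of them; genes without overlapping peaks get 0.
#'
#' @param atac sparse cells x peaks count matrix (peak ids as colnames).
#' @param peaks peak data.frame (chrom, start, end, peak) aligned by peak id.
#' @param gene_model gene model data.frame.
#' @param upstream upstream extension in bp (default 2000).
#' @return sparse cells x genes gene-activity matrix.
#' @export
gene_activity <- function(atac, peaks, gene_model, upstream = 2000) {
  pk <- peaks[match(colnames(atac), peaks$peak), , drop = FALSE]
  win_start <- ifelse(gene_model$strand == "+",
                      pmax(0, gene_model$start - upstream), gene_model$start)
  win_end <- ifelse(gene_model$strand == "+",
                    gene_model$end, gene_model$end + upstream)
  ii <- integer(0)
  jj <- integer(0)
  for (ch in unique(gene_model$chrom)) {
    gs <- which(gene_model$chrom == ch)
    ps <- which(pk$chrom == ch)
    if (!length(gs) || !length(ps)) next
    for (g in gs) {
      hit <- ps[pk$start[ps] < win_end[g] & pk$end[ps] > win_start[g]]
      ii <- c(ii, hit)
      jj <- c(jj, rep(g, length(hit)))
    }
  }
  map <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(ncol(atac), nrow(gene_model)),
                              dimnames = list(colnames(atac), gene_model$gene))
  out <- atac %*% map
  out <- methods::as(out, "CsparseMatrix")
  attr(out, "modality") <- "ATAC"
  out
}

#' Fisher exact test for gene-set overlap
#'
#' Builds the 2x2 table (a = |A and B|, b = |A only|, c = |B only|,
#' d = rest of universe), reports the sample odds ratio `ad/bc`, and a
#' two-sided Fisher exact p-value by hypergeometric tail summation (all
#' tables with probability at most that of the observed one).
#'
#' @param setA,setB gene sets (subsets of `universe`).
#' @param universe finite gene universe.
#' @return list of class `overlap_result`: table (a, b, c, d), odds_ratio,
#'   p.value, universe_size, intersection.
#' @export
set_overlap_fisher <- function(setA, setB, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  A <- intersect(unique(setA), universe)
  B <- intersect(unique(setB), universe)
  a <- length(intersect(A, B))
  b <- length(setdiff(A, B))
  c <- length(setdiff(B, A))
  d <- length(universe) - a - b - c
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else 0
  # hypergeometric: a ~ Hyper(m = |A|, n = N - |A|, k = |B|)
  m <- a + b
  nn <- c + d
  k <- a + c
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  p <- sum(probs[probs <= stats::dhyper(a, m, nn, k) * (1 + 1e-7)])
  structure(list(table = c(a = a, b = b, c = c, d = d),
                 odds_ratio = or, p.value = min(1, p),
                 universe_size = length(universe),
                 intersection = intersect(A, B)),
            class = "overlap_result")
}

#' Direction-consistent signature intersections
#'
#' Intersects the up-regulated (and, separately, down-regulated) passing
#' features of a DEG table and a DAC table, then intersects each
#' direction-consistent list with every signature (respecting signature
#' direction when present). All intermediate lists are returned.
#'
#' @param deg,dac `diff_table`s over the same feature namespace.
#' @param signatures list of `signature_set` objects.
#' @return list with `deg_up`, `deg_down`, `dac_up`, `dac_down`,
#'   `consistent_up`, `consistent_down`, and per-signature intersections
#'   under `signatures`.
#' @export
intersect_signatures <- function(deg, dac, signatures = list()) {
  pick <- function(tab, dir) tab$feature[tab$pass & tab$direction == dir]
  deg_up <- pick(deg, "up"); deg_down <- pick(deg, "down")
  dac_up <- pick(dac, "up"); dac_down <- pick(dac, "down")
  cons_up <- intersect(deg_up, dac_up)
  cons_down <- intersect(deg_down, dac_down)
  sig_out <- lapply(signatures, function(s) {
    sg_up <- if (is.null(s$direction)) s$genes else s$genes[s$direction > 0]
    sg_down <- if (is.null(s$direction)) s$genes else s$genes[s$direction < 0]
    list(up = intersect(cons_up, sg_up),
         down = intersect(cons_down, sg_down),
         any = intersect(union(cons_up, cons_down), s$genes))
  })
  names(sig_out) <- vapply(signatures, function(s) s$name, character(1))
  list(deg_up = deg_up, deg_down = deg_down, dac_up = dac_up,
       dac_down = dac_down, consistent_up = cons_up,
       consistent_down = cons_down, signatures = sig_out)
}
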