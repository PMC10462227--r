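#' Per-cell quality-control thresholds
#'
#' @param min_counts minimum total counts per cell.
#' @param min_features,max_features bounds on detected (nonzero) features.
#' @param max_mito maximum mitochondrial count fraction, in `[0, 1]`.
#' @param mito_prefix feature-name prefix identifying mitochondrial genes.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_counts = 500, min_features = 200,
                          max_features = 6000, max_mito = 0.20,
                          mito_prefix = "MT-") {
  if (min_features >= max_features) {
    stop_config("min_features", "must be below max_features")
  }
  if (max_mito < 0 || max_mito > 1) stop_config("max_mito", "must be in [0, 1]")
  structure(list(min_counts = min_counts, min_features = min_features,
                 max_features = max_features, max_mito = max_mito,
                 mito_prefix = mito_prefix), class = "qc_thresholds")
}

#' Filter cells on counts, detected features and mitochondrial fraction
#'
#' A cell is kept iff total counts >= `min_counts`,
#' `min_features` <= detected features <= `max_features`, and mitochondrial
#' fraction <= `max_mito`. Removals are attributed to the first failing
#' filter in that fixed order. If no feature carries the mitochondrial
#' prefix and the threshold is below 1, the mitochondrial filter is skipped
#' with a warning.
#'
#' @param m sparse cells x features count matrix.
#' @param thresholds a [qc_thresholds()].
#' @return list with `kept` (barcodes) and `report` (per-filter removal
#'   counts plus totals).
#' @export
qc_filter_cells <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  totals <- Matrix::rowSums(m)
  nfeat <- Matrix::rowSums(m > 0)
  mito_genes <- startsWith(colnames(m), thresholds$mito_prefix)
  if (!any(mito_genes) && thresholds$max_mito < 1) {
    warning("no features match the mitochondrial prefix; mito filter skipped")
    mito_frac <- rep(0, nrow(m))
  } else {
    mito_frac <- Matrix::rowSums(m[, mito_genes, drop = FALSE]) / pmax(totals, 1)
  }
  fail_counts <- totals < thresholds$min_counts
  fail_minf <- !fail_counts & nfeat < thresholds$min_features
  fail_maxf <- !fail_counts & !fail_minf & nfeat > thresholds$max_features
  fail_mito <- !fail_counts & !fail_minf & !fail_maxf & mito_frac > thresholds$max_mito
  keep <- !(fail_counts | fail_minf | fail_maxf | fail_mito)
  report <- data.frame(
    filter = c("min_counts", "min_features", "max_features", "max_mito"),
    removed = c(sum(fail_counts), sum(fail_minf), sum(fail_maxf), sum(fail_mito)),
    stringsAsFactors = FALSE
  )
  list(kept = rownames(m)[keep], report = report,
       n_in = nrow(m), n_kept = sum(keep))
}

#' Nearest-rank percentile of a count vector
#'
#' Sorts ascending and returns the element at rank `ceiling(q * n)`: the
#' value seen in the "q-th percentile cell". Operates on raw counts so that
#' a zero result is exact.
#'
#' @param values non-empty numeric vector.
#' @param q percentile fraction in (0, 1].
#' @return the nearest-rank percentile value.
#' @export
percentile_cell_value <- function(values, q) {
  if (length(values) == 0) stop("percentile of an empty vector", call. = FALSE)
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]", call. = FALSE)
  sort(values)[ceiling(q * length(values))]
}

#' Flag clusters whose marker percentile cell has zero counts
#'
#' For each cluster, summarizes the raw counts of `marker` at the
#' nearest-rank percentile `q`; clusters whose percentile cell has 0 counts
#' are flagged as marker-silent contaminants.
#'
#' @param m sparse cells x features count matrix.
#' @param labels cluster id per cell (aligned with rows of `m`).
#' @param marker marker feature id (e.g. the SDC1 analog).
#' @param q percentile fraction.
#' @return sorted vector of flagged cluster ids.
#' @export
flag_contaminant_clusters <- function(m, labels, marker, q = 0.9) {
  if (!marker %in% colnames(m)) {
    stop(sprintf("marker gene '%s' not present in features", marker), call. = FALSE)
  }
  if (length(labels) != nrow(m)) stop("every cell must be labeled", call. = FALSE)
  counts <- as.numeric(m[, marker])
  flagged <- vapply(split(counts, labels),
                    function(v) percentile_cell_value(v, q) == 0, logical(1))
  sort(names(flagged)[flagged])
}

#' Iterative marker-percentile removal of contaminant clusters
#'
#' Two-pass (by default) procedure: cluster all cells and drop clusters
#' whose marker expression is 0 counts in the `schedule[1]` percentile cell;
#' re-cluster the survivors and drop clusters failing the `schedule[2]`
#' percentile rule; and so on for longer schedules. The clustering function
#' must be deterministic for a fixed seed.
#'
#' @param m sparse cells x features count matrix (raw counts).
#' @param cluster_fn function(matrix) -> per-cell cluster labels.
#' @param marker marker feature id.
#' @param schedule percentile fractions, one per iteration.
#' @return list with `kept` barcodes and `report` (per-iteration dropped
#'   cluster ids and cell counts).
#' @export
iterative_plasma_selection <- function(m, cluster_fn, marker,
                                       schedule = c(0.90, 0.75)) {
  kept <- rownames(m)
  dropped <- list()
  counts <- integer(0)
  for (it in seq_along(schedule)) {
    sub <- m[kept, , drop = FALSE]
    labels <- cluster_fn(sub)
    flagged <- flag_contaminant_clusters(sub, labels, marker, schedule[it])
    if (length(flagged) == length(unique(labels))) {
      stop("no plasma-like cells retained", call. = FALSE)
    }
    keep_mask <- !(as.character(labels) %in% flagged)
    dropped[[it]] <- flagged
    counts[it] <- sum(!keep_mask)
    kept <- kept[keep_mask]
  }
  list(kept = kept,
       report = list(schedule = schedule, dropped_clusters = dropped,
                     removed_cells = counts, n_in = nrow(m),
                     n_kept = length(kept)))
}
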