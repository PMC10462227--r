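#' Reference-based CNV profile from expression
#'
#' Simplified inferCNV-style signal: per gene, the cell's log2-scale
#' normalized expression minus the mean over a reference cell set, clamped
#' to `[-3, 3]`, then smoothed by a centered moving average over `window`
#' genes within each chromosome (never across chromosome boundaries; the
#' window shrinks symmetrically at chromosome edges), and finally re-centered
#' per cell by its median. Genes are ordered by (chromosome, start).
#'
#' @param norm normalized (log CP10K) cells x genes matrix.
#' @param gene_model gene model data.frame (gene, chrom, start, end, arm).
#' @param reference_cells barcodes of the reference (normal) cell set;
#'   reference cells may also be profiled.
#' @param window odd moving-average width in genes.
#' @return list of class `cnv_profile`: `mat` (cells x genes, smoothed log2
#'   signal in genome order), `gene_model` (reordered), `window`,
#'   `reference_cells`.
#' @export
infer_cnv_profile <- function(norm, gene_model, reference_cells, window = 51) {
  if (length(reference_cells) == 0) stop("reference cell set is empty", call. = FALSE)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1", call. = FALSE)
  gm <- gene_model[gene_model$gene %in% colnames(norm), , drop = FALSE]
  chrn <- as.integer(sub("^chr", "", gm$chrom))
  gm <- gm[order(chrn, gm$start), , drop = FALSE]
  min_chr <- min(table(gm$chrom))
  if (window > min_chr) {
    stop(sprintf("window (%d) exceeds the smallest chromosome's gene count (%d)",
                 window, min_chr), call. = FALSE)
  }
  x <- as.matrix(norm[, gm$gene, drop = FALSE]) / log(2)
  miss <- setdiff(reference_cells, rownames(x))
  if (length(miss)) stop("reference cells absent from matrix", call. = FALSE)
  ref_mean <- colMeans(x[reference_cells, , drop = FALSE])
  x <- x - rep(ref_mean, each = nrow(x))
  x[x > 3] <- 3
  x[x < -3] <- -3

  half <- (window - 1) / 2
  sm <- x
  for (ch in unique(gm$chrom)) {
    idx <- which(gm$chrom == ch)
    cs <- cbind(0, t(apply(x[, idx, drop = FALSE], 1, cumsum)))
    nc <- length(idx)
    lo <- pmax(seq_len(nc) - half, 1L)
    hi <- pmin(seq_len(nc) + half, nc)
    sm[, idx] <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
      rep(hi - lo + 1L, each = nrow(x))
  }
  sm <- sm - apply(sm, 1, stats::median)
  structure(list(mat = sm, gene_model = gm, window = window,
                 reference_cells = reference_cells),
            class = "cnv_profile")
}

#' @exportS3Method base::print
print.cnv_profile <- function(x, ...) {
  cat(sprintf("CNV profile: %d cells x %d genes, window %d, %d reference cells\n",
              nrow(x$mat), ncol(x$mat), x$window, length(x$reference_cells)))
  invisible(x)
}

#' Per-cell arm-level event calls
#'
#' Averages the smoothed signal over each arm's genes and classifies:
#' loss if below `t_loss`, amp if at or above `t_amp`, gain if at or above
#' `t_gain`, neutral otherwise. Arms without genes are skipped with a
#' warning.
#'
#' @param profile a `cnv_profile`.
#' @param t_loss,t_gain,t_amp thresholds with `t_loss < 0 < t_gain < t_amp`,
#'   in smoothed log2-signal units (not copy numbers).
#' @return list of class `arm_event_call`: `mean` (cells x arms signal
#'   means) and `class` (character matrix of the same shape).
#' @export
call_arm_events <- function(profile, t_loss = -0.15, t_gain = 0.15, t_amp = 0.45) {
  stopifnot(inherits(profile, "cnv_profile"))
  if (!(t_loss < 0 && 0 < t_gain && t_gain < t_amp)) {
    stop("thresholds must satisfy t_loss < 0 < t_gain < t_amp", call. = FALSE)
  }
  arms <- unique(profile$gene_model$arm)
  keep <- vapply(arms, function(a) sum(profile$gene_model$arm == a) > 0, logical(1))
  if (any(!keep)) warning("arms without genes skipped")
  arms <- arms[keep]
  mn <- vapply(arms, function(a) {
    rowMeans(profile$mat[, profile$gene_model$arm == a, drop = FALSE])
  }, numeric(nrow(profile$mat)))
  if (is.null(dim(mn))) mn <- matrix(mn, nrow = 1, dimnames = list(rownames(profile$mat), arms))
  cls <- matrix("neutral", nrow(mn), ncol(mn), dimnames = dimnames(mn))
  cls[mn < t_loss] <- "loss"
  cls[mn >= t_gain] <- "gain"
  cls[mn >= t_amp] <- "amp"
  structure(list(mean = mn, class = cls,
                 thresholds = c(t_loss = t_loss, t_gain = t_gain, t_amp = t_amp)),
            class = "arm_event_call")
}

#' Assign cells to clones from a CNV profile
#'
#' `method = "from_labels"` passes through an existing clustering (e.g. the
#' joint multimodal clusters). `method = "hierarchical"` clusters cells by
#' average-linkage hierarchical clustering of their per-arm mean signal
#' vectors, cut to `k` clones. Each clone is annotated with its majority
#' arm-event class per arm.
#'
#' @param profile a `cnv_profile`.
#' @param method "from_labels" or "hierarchical".
#' @param k number of clones (hierarchical).
#' @param labels per-cell labels (from_labels), aligned with profile rows.
#' @param ... thresholds passed to [call_arm_events()] for the annotation.
#' @return list of class `clone_assignment`: `clone` (named integer vector,
#'   contiguous from 1) and `clone_events` (clone x arm majority classes).
#' @export
assign_clones <- function(profile, method = c("from_labels", "hierarchical"),
                          k = NULL, labels = NULL, ...) {
  stopifnot(inherits(profile, "cnv_profile"))
  method <- match.arg(method)
  arm <- call_arm_events(profile, ...)
  if (method == "from_labels") {
    if (is.null(labels)) stop("from_labels requires cluster labels", call. = FALSE)
    ids <- as.integer(factor(labels, levels = unique(labels)))
  } else {
    if (is.null(k)) stop("hierarchical requires k", call. = FALSE)
    if (k > nrow(profile$mat)) stop("k exceeds the number of cells", call. = FALSE)
    hc <- stats::hclust(stats::dist(arm$mean), method = "average")
    ids <- unname(stats::cutree(hc, k = k))
  }
  names(ids) <- rownames(profile$mat)
  ev <- t(vapply(sort(unique(ids)), function(cl) {
    apply(arm$class[ids == cl, , drop = FALSE], 2, function(v) {
      tb <- sort(table(v), decreasing = TRUE)
      names(tb)[1]
    })
  }, character(ncol(arm$class))))
  rownames(ev) <- sort(unique(ids))
  structure(list(clone = ids, clone_events = ev), class = "clone_assignment")
}

#' Impute translocations from marker-gene expression
#'
#' Per patient and marker gene, averages normalized expression over that
#' patient's cells, converts each marker's patient means to robust z-scores
#' (median / MAD across the cohort), and calls the translocation whose
#' marker z exceeds the threshold; at most one call per patient (highest z
#' wins).
#'
#' @param norm normalized cells x genes matrix.
#' @param cell_patients patient id per cell (aligned with rows).
#' @param markers marker gene ids (names optionally giving the
#'   translocation label).
#' @param z_threshold robust z cutoff (default 2).
#' @return data.frame: patient, call (marker id or NA), z of the call.
#' @export
impute_translocation <- function(norm, cell_patients, markers, z_threshold = 2) {
  miss <- setdiff(markers, colnames(norm))
  if (length(miss)) {
    stop(sprintf("marker genes absent: %s", paste(miss, collapse = ", ")), call. = FALSE)
  }
  pats <- unique(cell_patients)
  if (length(pats) < 3) stop("need >= 3 patients for a reference distribution", call. = FALSE)
  pm <- vapply(markers, function(g) {
    tapply(as.numeric(norm[, g]), cell_patients, mean)[pats]
  }, numeric(length(pats)))
  z <- apply(pm, 2, function(v) {
    s <- stats::mad(v)
    if (s == 0) return(rep(0, length(v)))
    (v - stats::median(v)) / s
  })
  best <- apply(z, 1, which.max)
  bestz <- z[cbind(seq_along(pats), best)]
  data.frame(patient = pats,
             call = ifelse(bestz > z_threshold, markers[best], NA_character_),
             z = bestz, stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate per-cell arm calls to per-patient calls
#'
#' Majority vote of the per-cell arm classes within each patient; ties go to
#' the more severe class (amp > gain > neutral > loss).
#'
#' @param arm_call an `arm_event_call`.
#' @param cell_patients patient per cell, aligned with the call rows.
#' @return patients x arms character matrix of classes.
#' @export
patient_arm_calls <- function(arm_call, cell_patients) {
  stopifnot(inherits(arm_call, "arm_event_call"))
  severity <- c(amp = 4, gain = 3, neutral = 2, loss = 1)
  pats <- unique(cell_patients)
  out <- matrix("neutral", length(pats), ncol(arm_call$class),
                dimnames = list(pats, colnames(arm_call$class)))
  for (p in pats) {
    sub <- arm_call$class[cell_patients == p, , drop = FALSE]
    out[p, ] <- apply(sub, 2, function(v) {
      tb <- table(v)
      win <- names(tb)[tb == max(tb)]
      win[order(-severity[win])][1]
    })
  }
  out
}

#' Impute hyperdiploidy from patient-level arm calls
#'
#' A patient is called hyperdiploid iff gains (gain or amp) are present on
#' at least `min_gains` of the configured trisomy arms.
#'
#' @param patient_calls patients x arms class matrix ([patient_arm_calls()]).
#' @param trisomy_arms arm labels making up the trisomy set.
#' @param min_gains minimum gained arms (default 2).
#' @return named logical vector per patient.
#' @export
impute_hyperdiploidy <- function(patient_calls, trisomy_arms, min_gains = 2) {
  arms <- intersect(trisomy_arms, colnames(patient_calls))
  gained <- patient_calls[, arms, drop = FALSE] %in% c("gain", "amp")
  gained <- matrix(gained, nrow = nrow(patient_calls))
  stats::setNames(rowSums(gained) >= min_gains, rownames(patient_calls))
}
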