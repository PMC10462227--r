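#' Per-patient cluster proportions
#'
#' Entry (p, c) is the fraction of patient p's cells assigned to cluster c;
#' every row sums to 1. Clusters absent from a patient get 0. Patients with
#' zero cells are excluded with a warning.
#'
#' @param labels per-cell cluster ids, named by barcode.
#' @param cell_patients patient id per cell, aligned with `labels`.
#' @return patients x clusters proportion matrix.
#' @export
cluster_proportions <- function(labels, cell_patients) {
  if (length(labels) != length(cell_patients)) {
    stop("labels and patients must align", call. = FALSE)
  }
  tab <- table(cell_patients, labels)
  tot <- rowSums(tab)
  if (any(tot == 0)) {
    warning("patients with zero cells excluded")
    tab <- tab[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  prop <- sweep(unclass(tab), 1, tot, "/")
  dimnames(prop) <- list(rownames(tab), colnames(tab))
  prop
}

#' Rank-based association of cluster proportions with a covariate
#'
#' For a binary covariate, a two-sided Wilcoxon rank-sum test of each
#' cluster's per-patient proportion between the two groups. For a covariate
#' with three or more ordered levels, all pairwise contrasts are reported.
#' BH adjustment is applied across the whole family of (cluster x contrast)
#' tests of the call. Contrasts with fewer than two patients in a group are
#' skipped and flagged.
#'
#' @param proportions patients x clusters matrix ([cluster_proportions()]).
#' @param covariate named factor/vector over the same patients.
#' @return data.frame: cluster, contrast, n1, n2, statistic, p_val, fdr,
#'   direction (which group has the higher median), median1, median2,
#'   skipped.
#' @export
group_test <- function(proportions, covariate) {
  pats <- rownames(proportions)
  cov <- covariate[pats]
  if (any(is.na(cov))) stop("covariate missing for some patients", call. = FALSE)
  lev <- if (is.factor(cov)) levels(droplevels(as.factor(cov))) else unique(cov)
  if (length(lev) < 2) stop("need >= 2 non-empty groups", call. = FALSE)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- list()
  for (cl in colnames(proportions)) {
    for (pr in pairs) {
      g1 <- proportions[cov == pr[1], cl]
      g2 <- proportions[cov == pr[2], cl]
      skipped <- length(g1) < 2 || length(g2) < 2
      if (skipped) {
        stat <- NA_real_; p <- NA_real_
      } else {
        w <- wilcoxon_rank_sum(g1, g2, correct = FALSE)
        stat <- w$statistic; p <- w$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, contrast = paste(pr[1], "vs", pr[2]),
        n1 = length(g1), n2 = length(g2), statistic = stat, p_val = p,
        direction = if (stats::median(g1) >= stats::median(g2)) pr[1] else pr[2],
        median1 = stats::median(g1), median2 = stats::median(g2),
        skipped = skipped, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  tested <- !out$skipped
  out$fdr[tested] <- bh_adjust(out$p_val[tested])
  out[order(out$fdr), ]
}

#' Correlation of a cluster's proportion with a per-patient alteration count
#'
#' Pearson correlation with a two-sided p-value from the t transform with
#' n - 2 degrees of freedom. Zero variance in either vector is flagged as
#' undefined.
#'
#' @param proportion named per-patient proportions of one cluster.
#' @param alteration_count named non-negative integer count per patient
#'   (e.g. how many of {1q gain/amp, TP53 mutation} the patient carries).
#' @return list: pcc, p.value, n, defined.
#' @export
alteration_count_correlation <- function(proportion, alteration_count) {
  pats <- intersect(names(proportion), names(alteration_count))
  if (length(pats) < 3) stop("need >= 3 patients", call. = FALSE)
  x <- proportion[pats]
  y <- alteration_count[pats]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pcc = NA_real_, p.value = NA_real_, n = length(pats),
                defined = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pcc = unname(ct$estimate), p.value = ct$p.value, n = length(pats),
       defined = TRUE)
}
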