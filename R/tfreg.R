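#' Transcription factors targeting a gene
#'
#' Looks the gene up as a target in one or more TF-target maps, returning
#' the TF set per source and their union.
#'
#' @param gene target gene id.
#' @param map TF-target data.frame (tf, target, source), e.g. from
#'   [read_tf_map()].
#' @return list: `per_source` (named list of TF vectors), `union`,
#'   `counts` (per-source TF counts).
#' @export
tfs_targeting <- function(gene, map) {
  hit <- map[map$target == gene, , drop = FALSE]
  per_source <- lapply(split(hit$tf, hit$source), function(v) sort(unique(v)))
  list(per_source = per_source,
       union = sort(unique(hit$tf)),
       counts = vapply(per_source, length, integer(1)))
}

#' Restrict TFs to a genomic region (arm)
#'
#' Keeps the TFs whose gene-model arm equals the region label; TFs missing
#' from the gene model are excluded with a warning.
#'
#' @param tfs TF gene ids.
#' @param gene_model gene model data.frame.
#' @param region arm label (e.g. "chr1q").
#' @return character vector of retained TFs.
#' @export
filter_tfs_by_region <- function(tfs, gene_model, region) {
  idx <- match(tfs, gene_model$gene)
  if (any(is.na(idx))) {
    warning(sprintf("TFs without coordinates excluded: %s",
                    paste(tfs[is.na(idx)], collapse = ", ")))
  }
  tfs[!is.na(idx) & gene_model$arm[idx] == region]
}

#' Peaks in a gene's promoter window
#'
#' Returns the peaks overlapping the strand-aware upstream window of width
#' `distance` ending at the TSS (`[TSS - distance, TSS)` on the + strand,
#' `[TSS, TSS + distance)` on the - strand) or overlapping the TSS itself.
#' All intervals are 0-based half-open.
#'
#' @param peaks peak data.frame (chrom, start, end, ...).
#' @param gene gene id.
#' @param gene_model gene model data.frame.
#' @param distance window width in bp (default 5000).
#' @return the overlapping rows of `peaks`.
#' @export
promoter_peaks <- function(peaks, gene, gene_model, distance = 5000) {
  g <- gene_model[gene_model$gene == gene, , drop = FALSE]
  if (nrow(g) == 0) stop(sprintf("gene '%s' not in gene model", gene), call. = FALSE)
  tss <- if (g$strand == "+") g$start else g$end - 1L
  if (g$strand == "+") {
    ws <- tss - distance; we <- tss
  } else {
    ws <- tss + 1L; we <- tss + 1L + distance
  }
  sel <- peaks$chrom == g$chrom &
    ((peaks$start < we & peaks$end > ws) |           # window overlap
       (peaks$start <= tss & peaks$end > tss))       # TSS overlap
  peaks[sel, , drop = FALSE]
}

#' Percentile rank of query peaks among all scored peaks
#'
#' Ranks all peaks by score (rank 1 = highest, ties get the average rank)
#' and reports `percentile = 100 * rank / total` for the queries, so a
#' smaller percentile means a stronger peak ("top X %").
#'
#' @param scores named numeric vector of genome-wide peak scores.
#' @param query names (or indices) of the query peaks.
#' @return data.frame: peak, score, rank, percentile.
#' @export
peak_percentile <- function(scores, query) {
  if (length(scores) == 0) stop("empty score list", call. = FALSE)
  if (is.character(query)) {
    idx <- match(query, names(scores))
    if (any(is.na(idx))) {
      stop(sprintf("query peaks not in score list: %s",
                   paste(query[is.na(idx)], collapse = ", ")), call. = FALSE)
    }
  } else {
    idx <- query
    if (any(idx < 1 | idx > length(scores))) {
      stop("query index out of range", call. = FALSE)
    }
  }
  r <- rank(-scores, ties.method = "average")
  data.frame(peak = if (!is.null(names(scores))) names(scores)[idx] else idx,
             score = unname(scores[idx]), rank = r[idx],
             percentile = 100 * r[idx] / length(scores),
             stringsAsFactors = FALSE, row.names = NULL)
}
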