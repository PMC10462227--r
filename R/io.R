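#' Read a 10x-style triplet directory into a sparse count matrix
#'
#' Expects `matrix.mtx` (MatrixMarket coordinate format, 1-based indices,
#' rows = cells), `barcodes.tsv` (one barcode per line) and `features.tsv`
#' (feature id, feature name, modality tag). Counts are returned exactly;
#' feature order follows the features file.
#'
#' @param dir directory containing the three files.
#' @return sparse cells x features matrix (`dgCMatrix`) with barcode
#'   rownames, feature-id colnames, and a `modality` attribute.
#' @export
read_10x <- function(dir) {
  mtx <- file.path(dir, "matrix.mtx")
  bcf <- file.path(dir, "barcodes.tsv")
  ftf <- file.path(dir, "features.tsv")
  for (f in c(mtx, bcf, ftf)) {
    if (!file.exists(f)) stop(sprintf("missing triplet file '%s'", f), call. = FALSE)
  }
  m <- Matrix::readMM(mtx)
  # pattern matrices (all-zero writes) carry no x slot; coerce to numeric
  m <- methods::as(methods::as(m, "dMatrix"), "CsparseMatrix")
  barcodes <- readLines(bcf)
  feats <- utils::read.table(ftf, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE, quote = "")
  if (nrow(m) != length(barcodes) || ncol(m) != nrow(feats)) {
    stop(sprintf(
      "format error: matrix is %d x %d but barcodes/features files list %d / %d entries",
      nrow(m), ncol(m), length(barcodes), nrow(feats)), call. = FALSE)
  }
  if (anyDuplicated(barcodes)) stop("format error: duplicate barcodes", call. = FALSE)
  if (anyDuplicated(feats[[1]])) stop("format error: duplicate features", call. = FALSE)
  dimnames(m) <- list(barcodes, feats[[1]])
  check_count_matrix(m, "matrix.mtx")
  attr(m, "modality") <- if (ncol(feats) >= 3) feats[[3]][1] else NA_character_
  m
}

# writer counterpart used by write_cohort; rows are cells
write_10x <- function(m, dir, modality, feature_names) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(as.character(rownames(m) %||% character(0)),
             file.path(dir, "barcodes.tsv"))
  utils::write.table(
    data.frame(colnames(m), feature_names, modality, stringsAsFactors = FALSE),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  dir
}

#' Read a BED file of intervals (0-based half-open)
#'
#' Tab-separated, at least three columns (chrom, start, end); a numeric
#' fourth column is stored as `score`. Intervals are kept 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame with columns chrom, start, end and optionally score.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", fill = TRUE)
  if (ncol(raw) < 3) stop("format error: BED needs >= 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]),
                    end = as.integer(raw[[3]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    stop(sprintf("format error at line %d: start >= end", bad[1]), call. = FALSE)
  }
  if (ncol(raw) >= 4 && is.numeric(raw[[4]])) out$score <- raw[[4]]
  out
}

# BED writer; extra columns after chrom/start/end are kept in order
write_bed <- function(df, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  cols <- c("chrom", "start", "end", setdiff(names(df), c("chrom", "start", "end")))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene model TSV
#'
#' Columns: gene, chrom, start, end, strand, arm (and optionally name).
#' Coordinates are 0-based half-open; strand is "+" or "-".
#'
#' @param path TSV path.
#' @return validated gene model data.frame.
#' @export
read_gene_model <- function(path) {
  gm <- read_tsv(path)
  need <- c("gene", "chrom", "start", "end", "strand", "arm")
  miss <- setdiff(need, names(gm))
  if (length(miss)) stop(sprintf("gene model missing columns: %s",
                                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(gm$start >= gm$end)) stop("gene model has start >= end", call. = FALSE)
  if (!all(gm$strand %in% c("+", "-"))) stop("gene model strand must be + or -", call. = FALSE)
  if (anyDuplicated(gm$gene)) stop("gene model has duplicate gene ids", call. = FALSE)
  gm
}

#' Read TF-target map TSVs
#'
#' Each file has columns tf, target, source. Duplicate (tf, target, source)
#' triples are dropped.
#'
#' @param paths one or more TSV paths.
#' @return data.frame with columns tf, target, source.
#' @export
read_tf_map <- function(paths) {
  maps <- lapply(paths, function(p) {
    m <- read_tsv(p)
    need <- c("tf", "target", "source")
    if (!all(need %in% names(m))) {
      stop(sprintf("TF map '%s' needs columns tf, target, source", p), call. = FALSE)
    }
    m[, need]
  })
  out <- do.call(rbind, maps)
  out[!duplicated(out), ]
}

#' Load a gene signature from a differential-expression table
#'
#' Applies fold-change and p-value cutoffs to an external DE table (e.g. a
#' knockdown experiment) at load time, returning the surviving genes with
#' their direction.
#'
#' @param path TSV with columns gene, log2FC, p_val (optionally p_adj).
#' @param fc minimum fold change (applied as |log2FC| >= log2(fc)).
#' @param p p-value cutoff.
#' @param name signature source tag.
#' @return list of class `signature_set`: name, genes, direction (+1/-1).
#' @export
load_signature <- function(path, fc = 2, p = 0.05, name = basename(path)) {
  tab <- read_tsv(path)
  need <- c("gene", "log2FC", "p_val")
  if (!all(need %in% names(tab))) {
    stop("signature table needs columns gene, log2FC, p_val", call. = FALSE)
  }
  keep <- abs(tab$log2FC) >= log2(fc) & tab$p_val < p
  tab <- tab[keep, ]
  if (anyDuplicated(tab$gene)) tab <- tab[!duplicated(tab$gene), ]
  structure(list(name = name,
                 genes = tab$gene,
                 direction = ifelse(tab$log2FC > 0, 1L, -1L)),
            class = "signature_set")
}

#' Read and validate a pipeline configuration file
#'
#' A YAML file with per-stage sections. Unknown keys at the top level or
#' inside a stage section raise a configuration error before any stage runs.
#'
#' @param path YAML file path (or a list already in memory).
#' @return validated nested list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- list(
    seed = NULL, out_dir = NULL, input_dir = NULL,
    simulate = names(formals(synth_config)),
    qc = c("min_counts", "min_features", "max_features", "max_mito",
           "mito_prefix", "marker", "schedule"),
    cluster = c("k", "resolution", "n_components", "n_features", "fusion"),
    cnv = c("window", "t_loss", "t_gain", "t_amp", "reference_cluster",
            "clone_method", "k_clones", "z_threshold", "min_trisomy_gains"),
    assoc = c("alpha"),
    diff = c("cutoff_rna", "cutoff_atac", "fdr", "min_cells", "upstream",
             "signature_fc", "signature_p"),
    tf = c("distance", "region")
  )
  extra <- setdiff(names(cfg), names(known))
  if (length(extra)) {
    stop(sprintf("configuration error: unknown key '%s'", extra[1]), call. = FALSE)
  }
  for (sec in names(known)) {
    if (is.null(known[[sec]]) || is.null(cfg[[sec]])) next
    bad <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad)) {
      stop(sprintf("configuration error: unknown key '%s.%s'", sec, bad[1]),
           call. = FALSE)
    }
  }
  cfg
}
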