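`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the RNG to `seed`, runs `expr`, and restores the caller's RNG state,
#' so that library code never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible substream seed from a global seed. Kept below 2^31-1.
# Patient substreams (index = i) stay stable when the patient count changes.
derive_seed <- function(seed, i, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + as.numeric(i) * 100003 + as.numeric(salt) * 7919) %% 2147483629)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# shared check that a matrix looks like a cells x features count matrix
check_count_matrix <- function(x, what = "matrix") {
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop(sprintf("%s must carry barcode rownames and feature colnames", what), call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop(sprintf("%s has duplicate barcodes", what), call. = FALSE)
  if (anyDuplicated(colnames(x))) stop(sprintf("%s has duplicate features", what), call. = FALSE)
  vals <- if (inherits(x, "sparseMatrix")) x@x else as.vector(x)
  if (length(vals) && (min(vals) < 0 || any(vals != floor(vals)))) {
    stop(sprintf("%s must contain non-negative integer counts", what), call. = FALSE)
  }
  invisible(TRUE)
}

# write a data.frame as deterministic TSV (no quoting, no row names)
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "", ...)
}
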