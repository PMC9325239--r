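# Internal helpers shared across modules.

#' Normalize gene identifiers
#'
#' Upper-cases and strips surrounding whitespace. All identifier matching in
#' the package is exact string match after this normalization; no alias or
#' ortholog resolution is attempted.
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @export
normalize_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

# Deterministic substream seed derived from a master seed and a stage offset.
# Kept strictly inside 32-bit integer range.
substream_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483629)
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Write a table atomically: write to a temp file in the same directory, then
# rename, so a failed run never leaves a truncated output behind.
write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
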