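#' Construct a differential-expression signature
#'
#' A `de_signature` is a data frame with one row per gene and columns
#' `gene`, `logFC` (log2 fold change), `pvalue` and `fdr`
#' (Benjamini-Hochberg adjusted), carrying a `label` and the significance
#' threshold applied downstream as attributes. Gene ids must be unique.
#'
#' @param gene character gene ids (normalized internally).
#' @param logFC numeric log2 fold changes.
#' @param pvalue,fdr numeric values in \[0, 1\].
#' @param label signature label, e.g. a drug name or "disease".
#' @param q_threshold default FDR threshold used when the signature is
#'   interpreted downstream.
#' @return a data frame of class `de_signature`.
#' @export
de_signature <- function(gene, logFC, pvalue, fdr, label, q_threshold = 0.05) {
  gene <- normalize_ids(gene)
  if (anyDuplicated(gene)) stopf("duplicate gene ids in signature '%s'", label)
  n <- length(gene)
  stopifnot(length(logFC) == n, length(pvalue) == n, length(fdr) == n)
  if (any(pvalue < 0 | pvalue > 1, na.rm = TRUE) ||
      any(fdr < 0 | fdr > 1, na.rm = TRUE)) {
    stopf("pvalue and fdr must lie in [0, 1]")
  }
  out <- data.frame(gene = gene, logFC = as.numeric(logFC),
                    pvalue = as.numeric(pvalue), fdr = as.numeric(fdr),
                    stringsAsFactors = FALSE)
  attr(out, "label") <- as.character(label)
  attr(out, "q_threshold") <- q_threshold
  class(out) <- c("de_signature", "data.frame")
  out
}

#' @export
print.de_signature <- function(x, ...) {
  qt <- attr(x, "q_threshold")
  cat(sprintf("de_signature '%s': %d genes, %d at FDR <= %g\n",
              attr(x, "label"), nrow(x), sum(x$fdr <= qt, na.rm = TRUE), qt))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Write a signature table as TSV
#'
#' Columns: `gene`, `logFC`, `pvalue`, `fdr`.
#'
#' @param x a [de_signature()].
#' @param path output path.
#' @export
write_signature <- function(x, path) {
  stopifnot(inherits(x, "de_signature"))
  write_tsv_atomic(as.data.frame(x)[, c("gene", "logFC", "pvalue", "fdr")], path)
}

#' Load a differential-expression signature from a TSV file
#'
#' Reads a tab-separated summary table, maps its columns to the signature
#' schema, normalizes gene identifiers (upper case, whitespace stripped)
#' and collapses duplicated genes to the record with the smallest q-value
#' (ties broken by largest absolute logFC, then first occurrence).
#'
#' @param path TSV file with a header row.
#' @param column_map named character vector mapping the schema fields
#'   `gene`, `logfc`, `qvalue` (required) and `pvalue` (optional) to column
#'   names in the file.
#' @param label signature label.
#' @param q_threshold FDR threshold recorded on the signature.
#' @return a [de_signature()].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tlogFC\tpvalue\tfdr", "g1\t1.2\t0.001\t0.01"), f)
#' load_signature(f, label = "demo")
#' @export
load_signature <- function(path,
                           column_map = c(gene = "gene", logfc = "logFC",
                                          pvalue = "pvalue", qvalue = "fdr"),
                           label = basename(path),
                           q_threshold = 0.05) {
  df <- read_tsv(path)
  for (field in c("gene", "logfc", "qvalue")) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(df)) {
      stopf("signature file %s is missing required column '%s' (field %s)",
            path, if (is.null(col)) field else col, field)
    }
  }
  numeric_col <- function(field) {
    col <- column_map[[field]]
    if (is.null(col) || !col %in% names(df)) return(rep(NA_real_, nrow(df)))
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad)) {
      stopf("unparsable numeric in column '%s' of %s at line %d",
            col, path, bad[1] + 1L)  # +1 for the header row
    }
    val
  }
  gene <- normalize_ids(df[[column_map[["gene"]]]])
  logfc <- numeric_col("logfc")
  pval <- numeric_col("pvalue")
  qval <- numeric_col("qvalue")
  if (nrow(df) == 0) {
    warnf("signature file %s has a header but no rows", path)
    return(de_signature(character(), numeric(), numeric(), numeric(),
                        label = label, q_threshold = q_threshold))
  }
  # Deduplicate: smallest q wins, then largest |logFC|, then first occurrence.
  ord <- order(qval, -abs(logfc), seq_along(gene))
  keep <- ord[!duplicated(gene[ord])]
  keep <- sort(keep)
  n_dup <- nrow(df) - length(keep)
  message(sprintf("loaded %d rows from %s (%d duplicate gene records collapsed)",
                  nrow(df), basename(path), n_dup))
  de_signature(gene[keep], logfc[keep],
               ifelse(is.na(pval[keep]), qval[keep], pval[keep]), qval[keep],
               label = label, q_threshold = q_threshold)
}
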