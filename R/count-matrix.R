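#' Construct a labelled count matrix
#'
#' Light container for a gene-by-sample matrix of non-negative integer
#' counts together with the treated/vehicle group assignment of each
#' sample. Both groups must be non-empty.
#'
#' @param counts numeric matrix of non-negative integers with gene ids as
#'   row names and sample ids as column names.
#' @param groups character or factor of length `ncol(counts)` with values
#'   `"treated"` or `"vehicle"`; may be named by sample id.
#' @param label free-text label (e.g. the drug name).
#' @return an object of class `count_matrix` with elements `counts`,
#'   `groups` (factor named by sample) and `label`.
#' @export
count_matrix <- function(counts, groups, label = "drug") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample ids in counts")
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stopf("counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) stopf("counts must be integers")
  storage.mode(counts) <- "integer"
  groups <- as.character(groups)
  if (length(groups) != ncol(counts)) {
    stopf("groups must assign each of the %d samples", ncol(counts))
  }
  if (!all(groups %in% c("treated", "vehicle"))) {
    stopf("groups must be 'treated' or 'vehicle'")
  }
  groups <- factor(groups, levels = c("treated", "vehicle"))
  if (any(table(groups) == 0)) stopf("both groups must be non-empty")
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups, label = label),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix '%s': %d genes x %d samples (%d treated, %d vehicle)\n",
              x$label, nrow(x$counts), ncol(x$counts),
              sum(x$groups == "treated"), sum(x$groups == "vehicle")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Write / read a count matrix as TSV plus a group sidecar
#'
#' The matrix file holds one `gene` column followed by one column per
#' sample; the sidecar maps `sample` to `group`.
#'
#' @param x a [count_matrix()].
#' @param counts_path,groups_path file paths for matrix and sidecar.
#' @param label label attached on read.
#' @return `write_count_matrix` returns the paths invisibly;
#'   `read_count_matrix` returns a [count_matrix()].
#' @export
write_count_matrix <- function(x, counts_path, groups_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  write_tsv_atomic(df, counts_path)
  write_tsv_atomic(
    data.frame(sample = colnames(x$counts), group = as.character(x$groups)),
    groups_path)
  invisible(c(counts_path, groups_path))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_path, groups_path, label = "drug") {
  df <- read_tsv(counts_path)
  if (names(df)[1] != "gene") stopf("first column of %s must be 'gene'", counts_path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  g <- read_tsv(groups_path)
  if (!all(c("sample", "group") %in% names(g))) {
    stopf("%s must have columns 'sample' and 'group'", groups_path)
  }
  idx <- match(colnames(m), g$sample)
  if (anyNA(idx)) stopf("samples missing from group sidecar: %s",
                        paste(colnames(m)[is.na(idx)], collapse = ", "))
  count_matrix(m, g$group[idx], label = label)
}
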