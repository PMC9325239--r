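#' Genes regulated by a drug opposite to the disease
#'
#' The core reversal rule: a gene is reversed when it is present in both
#' signatures, significant on both sides (`fdr <= q_disease` in the
#' disease table, `fdr <= q_drug` in the drug table), and its log2 fold
#' changes have strictly opposite signs (a logFC of exactly 0 on either
#' side never counts). With `direction = "concordant"` the same rule is
#' applied with a strictly positive sign product, which is useful for
#' sanity checks.
#'
#' @param disease,drug [de_signature()] objects.
#' @param q_disease FDR threshold on the disease side (default 0.1).
#' @param q_drug FDR threshold on the drug side (default 0.05).
#' @param direction `"opposite"` (reversal, default) or `"concordant"`.
#' @return sorted character vector of gene ids.
#' @examples
#' d <- de_signature("G1", 1.2, 0.001, 0.05, "disease")
#' s <- de_signature("G1", -0.5, 0.001, 0.01, "drug")
#' reversed_genes(d, s)
#' @export
reversed_genes <- function(disease, drug, q_disease = 0.1, q_drug = 0.05,
                           direction = c("opposite", "concordant")) {
  stopifnot(inherits(disease, "de_signature"), inherits(drug, "de_signature"))
  direction <- match.arg(direction)
  shared <- intersect(disease$gene, drug$gene)
  di <- disease[match(shared, disease$gene), ]
  dr <- drug[match(shared, drug$gene), ]
  prod_sign <- di$logFC * dr$logFC
  sig <- di$fdr <= q_disease & dr$fdr <= q_drug
  hit <- if (direction == "opposite") prod_sign < 0 else prod_sign > 0
  sort(shared[sig & hit])
}

#' Intersection accounting over per-drug reversed gene sets
#'
#' Builds the full exclusive-region decomposition of the per-drug
#' reversed sets: the union, the common-to-all set, a gene-by-drug
#' membership matrix, and one count per non-empty drug subset (each gene
#' assigned to exactly the subset of drugs that reversed it), i.e. the
#' regions an UpSet plot displays.
#'
#' @param per_drug named list mapping drug label to a character vector of
#'   reversed gene ids.
#' @return an object of class `reversal_result` with elements
#'   `drug_labels`, `reversed_sets`, `union_set`, `common_set`,
#'   `membership` (logical genes x drugs matrix) and `exclusive_regions`
#'   (named integer vector; names are `&`-joined drug labels).
#' @examples
#' r <- intersect_across_drugs(list(A = c("g1", "g2", "g3"),
#'                                  B = c("g2", "g3"), C = "g3", D = "g3"))
#' r$exclusive_regions
#' @export
intersect_across_drugs <- function(per_drug) {
  if (length(per_drug) < 1 || is.null(names(per_drug)) ||
      any(names(per_drug) == "")) {
    stopf("per_drug must be a non-empty named list of gene sets")
  }
  per_drug <- lapply(per_drug, function(g) sort(unique(normalize_ids(g))))
  labels <- names(per_drug)
  union_set <- sort(unique(unlist(per_drug, use.names = FALSE)))
  membership <- vapply(per_drug, function(g) union_set %in% g,
                       logical(length(union_set)))
  membership <- matrix(membership, nrow = length(union_set),
                       ncol = length(labels),
                       dimnames = list(union_set, labels))
  common_set <- union_set[rowSums(membership) == length(labels)]
  region_of <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))
  exclusive_regions <- if (length(region_of)) {
    tab <- table(region_of)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(
    list(drug_labels = labels, reversed_sets = per_drug,
         union_set = union_set, common_set = common_set,
         membership = membership, exclusive_regions = exclusive_regions),
    class = "reversal_result")
}

#' Exclusive intersection counts in display order
#'
#' Returns one row per non-empty exclusive region of a
#' [intersect_across_drugs()] result, sorted by count descending (ties by
#' region label), with per-drug inclusive totals attached as the
#' `per_drug_totals` attribute.
#'
#' @param result a `reversal_result`.
#' @return data frame with columns `drugs`, `degree`, `count`.
#' @export
upset_counts <- function(result) {
  stopifnot(inherits(result, "reversal_result"))
  regions <- result$exclusive_regions
  df <- data.frame(
    drugs = names(regions),
    degree = lengths(strsplit(names(regions), "&", fixed = TRUE)),
    count = as.integer(regions),
    stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$drugs), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "per_drug_totals") <-
    stats::setNames(lengths(result$reversed_sets), result$drug_labels)
  df
}

#' @export
print.reversal_result <- function(x, ...) {
  cat(sprintf("reversal_result over %d drugs (%s)\n",
              length(x$drug_labels), paste(x$drug_labels, collapse = ", ")))
  cat(sprintf("  per-drug reversed: %s\n",
              paste(sprintf("%s=%d", x$drug_labels,
                            lengths(x$reversed_sets)), collapse = ", ")))
  cat(sprintf("  union %d, common to all %d\n",
              length(x$union_set), length(x$common_set)))
  invisible(x)
}

#' @export
summary.reversal_result <- function(object, ...) {
  list(per_drug = lengths(object$reversed_sets),
       union = length(object$union_set),
       common = length(object$common_set),
       regions = object$exclusive_regions)
}

#' Write reversal outputs as TSV/plain text
#'
#' Writes per-drug reversed gene tables (with both logFCs and q-values),
#' the membership matrix, the exclusive-region counts and the common set.
#'
#' @param result a `reversal_result`.
#' @param disease the disease [de_signature()].
#' @param drug_sigs named list of drug [de_signature()] objects.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_reversal <- function(result, disease, drug_sigs, dir) {
  stopifnot(inherits(result, "reversal_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (lab in result$drug_labels) {
    genes <- result$reversed_sets[[lab]]
    sig <- drug_sigs[[lab]]
    di <- disease[match(genes, disease$gene), ]
    dr <- sig[match(genes, sig$gene), ]
    p <- file.path(dir, sprintf("reversed_genes_%s.tsv", lab))
    write_tsv_atomic(data.frame(
      gene = genes, disease_logFC = di$logFC, drug_logFC = dr$logFC,
      disease_q = di$fdr, drug_q = dr$fdr), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "membership.tsv")
  write_tsv_atomic(data.frame(gene = rownames(result$membership),
                              result$membership + 0L, check.names = FALSE), p)
  paths <- c(paths, p)
  p <- file.path(dir, "upset_counts.tsv")
  write_tsv_atomic(upset_counts(result), p)
  paths <- c(paths, p)
  p <- file.path(dir, "common_set.txt")
  writeLines(result$common_set, p)
  invisible(c(paths, p))
}
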