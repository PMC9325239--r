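#' Consensus drug direction and mean logFC for one gene
#'
#' For a gene in the common reversed set, every drug moved it the same
#' way (each drug must oppose the single disease sign), so a consensus
#' direction is well defined: `"up"` when all drug logFCs are positive,
#' `"down"` when all are negative. Mixed signs violate the common-reversal
#' contract and raise an error, as does a gene missing from any signature.
#'
#' @param gene a single gene id.
#' @param drug_sigs named list of drug [de_signature()] objects.
#' @return list with `gene_id`, `direction` (`"up"`/`"down"`) and
#'   `mean_logfc` (unweighted arithmetic mean over drugs).
#' @examples
#' sigs <- list(a = de_signature("G1", 0.5, 0.01, 0.02, "a"),
#'              b = de_signature("G1", 0.2, 0.01, 0.02, "b"))
#' consensus_direction("G1", sigs)
#' @export
consensus_direction <- function(gene, drug_sigs) {
  gene <- normalize_ids(gene)
  stopifnot(length(gene) == 1)
  lfc <- vapply(drug_sigs, function(sig) {
    i <- match(gene, sig$gene)
    if (is.na(i)) stopf("gene %s missing from signature '%s'",
                        gene, attr(sig, "label"))
    sig$logFC[i]
  }, numeric(1))
  if (all(lfc > 0)) {
    direction <- "up"
  } else if (all(lfc < 0)) {
    direction <- "down"
  } else {
    stopf("gene %s has mixed drug logFC signs; not a common-reversed gene", gene)
  }
  list(gene_id = gene, direction = direction, mean_logfc = mean(lfc))
}

#' Flag genes present in an eQTL list
#'
#' Exact-match membership flags after identifier normalization. The eQTL
#' input is a flat list of implicated genes (a file with one id per line,
#' or a character vector); duplicates are harmless.
#'
#' @param genes character vector of gene ids to flag.
#' @param eqtl path to a one-id-per-line text file, or a character vector.
#' @return named logical vector over `genes`.
#' @export
flag_eqtl <- function(genes, eqtl) {
  genes <- normalize_ids(genes)
  ids <- if (length(eqtl) == 1 && file.exists(eqtl)) readLines(eqtl) else eqtl
  ids <- unique(normalize_ids(ids))
  ids <- ids[nzchar(ids)]
  if (length(ids) == 0) warnf("eQTL list is empty; all flags FALSE")
  flags <- stats::setNames(genes %in% ids, genes)
  message(sprintf("%d of %d gene(s) flagged as eQTL", sum(flags), length(flags)))
  flags
}

#' Annotate common-reversed genes for network export
#'
#' Applies [consensus_direction()] and [flag_eqtl()] across a gene list
#' and returns the node-annotation table consumed by [write_graphml()].
#'
#' @param genes character vector (typically the common reversed set).
#' @param drug_sigs named list of drug [de_signature()] objects.
#' @param eqtl eQTL list (path or character vector); `NULL` for no flags.
#' @return data frame with columns `gene`, `direction`, `mean_logFC`,
#'   `is_eqtl`.
#' @export
annotate_nodes <- function(genes, drug_sigs, eqtl = NULL) {
  genes <- normalize_ids(genes)
  ann <- lapply(genes, consensus_direction, drug_sigs = drug_sigs)
  flags <- if (is.null(eqtl)) {
    stats::setNames(rep(FALSE, length(genes)), genes)
  } else {
    flag_eqtl(genes, eqtl)
  }
  data.frame(gene = genes,
             direction = vapply(ann, `[[`, character(1), "direction"),
             mean_logFC = vapply(ann, `[[`, numeric(1), "mean_logfc"),
             is_eqtl = unname(flags[genes]),
             stringsAsFactors = FALSE)
}
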