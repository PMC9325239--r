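#' Gene-set collection
#'
#' Flat, unordered collection of named gene sets (no ontology structure).
#' Gene ids are normalized as everywhere else in the package.
#'
#' @param sets named list of character vectors (set id -> gene ids);
#'   ids must be unique and sets non-empty.
#' @param descriptions optional character vector of set descriptions.
#' @param source free-text provenance label.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, source = "") {
  if (is.null(names(sets)) || any(names(sets) == "") ||
      anyDuplicated(names(sets))) {
    stopf("sets must have unique non-empty ids")
  }
  sets <- lapply(sets, function(g) sort(unique(normalize_ids(g))))
  if (any(lengths(sets) == 0)) stopf("gene sets must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %d-%d)%s\n",
              length(x), min(lengths(x)), max(lengths(x)),
              if (nzchar(attr(x, "source"))) {
                sprintf(", source: %s", attr(x, "source"))
              } else ""))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is one set per line: set id, description, then tab-separated gene
#' ids. Duplicate genes within a line are collapsed; lines whose gene
#' fields are all empty are skipped with a warning; lines with fewer than
#' 3 fields are an error.
#'
#' @param path file path.
#' @return `read_gmt` returns a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warnf("GMT file %s is empty", path)
    return(structure(list(), descriptions = stats::setNames(character(), character()),
                     source = path, class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short)) {
    stopf("GMT line %d of %s has fewer than 3 fields", short[1], path)
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  genes <- lapply(fields, function(f) {
    g <- normalize_ids(f[-(1:2)])
    unique(g[nzchar(g)])
  })
  empty <- lengths(genes) == 0
  if (any(empty)) {
    warnf("skipping %d GMT line(s) with no genes", sum(empty))
    ids <- ids[!empty]; desc <- desc[!empty]; genes <- genes[!empty]
  }
  gene_set_collection(stats::setNames(genes, ids), descriptions = desc,
                      source = path)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  desc <- attr(collection, "descriptions")
  lines <- vapply(names(collection), function(id) {
    d <- desc[[id]]
    paste(c(id, if (nzchar(d)) d else "na", collection[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a draw of `n`
#' genes from a universe of `N` genes of which `K` are annotated:
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, computed stably via
#' `stats::phyper`.
#'
#' @param k observed overlap (vectorized).
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability in \[0, 1\].
#' @examples
#' hypergeom_tail(3, 4, 5, 10)  # 66/252
#' @export
hypergeom_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stopf("inconsistent hypergeometric arguments")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a gene set
#'
#' For each gene set in a collection, intersects the set with the
#' declared universe, discards sets whose in-universe size falls outside
#' `[min_size, max_size]` before testing, computes the exact
#' hypergeometric upper-tail p-value of the query overlap, and adjusts
#' over the tested sets with Benjamini-Hochberg. Query genes outside the
#' universe are dropped with a warning. Results are sorted by p ascending
#' (ties: larger overlap first, then set id).
#'
#' @param query character vector of gene ids (e.g. the common reversed set).
#' @param universe character vector of background gene ids.
#' @param collection a [gene_set_collection()].
#' @param min_size,max_size in-universe set-size bounds applied before
#'   testing (defaults 10 and 500).
#' @param q_cut FDR threshold recorded on the result (default 0.05).
#' @return data frame of class `ora_result` with columns `set_id`,
#'   `name`, `k`, `K`, `n`, `N`, `pvalue`, `fdr`, `overlap`
#'   (`;`-separated gene ids).
#' @export
ora <- function(query, universe, collection, min_size = 10, max_size = 500,
                q_cut = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- sort(unique(normalize_ids(universe)))
  if (length(universe) == 0) stopf("empty universe")
  query <- unique(normalize_ids(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe were dropped", length(outside))
    query <- intersect(query, universe)
  }
  n <- length(query); N <- length(universe)
  in_universe <- lapply(collection, intersect, y = universe)
  K <- lengths(in_universe)
  tested <- which(K >= min_size & K <= max_size)
  if (length(tested) == 0) {
    warnf("no gene set within the size bounds [%d, %d]", min_size, max_size)
  }
  rows <- lapply(tested, function(i) {
    ov <- intersect(in_universe[[i]], query)
    data.frame(set_id = names(collection)[i],
               name = attr(collection, "descriptions")[[names(collection)[i]]],
               k = length(ov), K = K[[i]], n = n, N = N,
               pvalue = hypergeom_tail(length(ov), K[[i]], n, N),
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) {
    out <- data.frame(set_id = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      pvalue = numeric(), fdr = numeric(),
                      overlap = character(), stringsAsFactors = FALSE)
  } else {
    out$fdr <- bh_adjust(out$pvalue)
    out <- out[order(out$pvalue, -out$k, out$set_id),
               c("set_id", "name", "k", "K", "n", "N", "pvalue", "fdr", "overlap")]
    rownames(out) <- NULL
  }
  attr(out, "q_cut") <- q_cut
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  q <- attr(x, "q_cut")
  cat(sprintf("ora_result: %d sets tested, %d at FDR <= %g\n",
              nrow(x), sum(x$fdr <= q), q))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x)[
      , c("set_id", "k", "K", "n", "N", "pvalue", "fdr")], 8))
  }
  invisible(x)
}
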