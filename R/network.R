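#' Read a STRING-style edge list
#'
#' Expects a TSV with two identifier columns (`protein1`, `protein2`, or
#' the first two columns) and a `combined_score` column (or the third
#' column). Scores on the integer 0-1000 scale are detected (any score
#' > 1) and divided by 1000. Identifiers are normalized, self-loops are
#' dropped with a warning, and duplicate undirected pairs are collapsed
#' keeping the maximum score.
#'
#' @param path TSV file path.
#' @return data frame with columns `gene1`, `gene2`, `score` (in \[0, 1\]).
#' @export
read_edges <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 3) stopf("edge file %s needs at least 3 columns", path)
  id_cols <- if (all(c("protein1", "protein2") %in% names(df))) {
    c("protein1", "protein2")
  } else names(df)[1:2]
  score_col <- if ("combined_score" %in% names(df)) "combined_score" else names(df)[3]
  raw <- df[[score_col]]
  score <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(score) & !is.na(raw))
  if (length(bad)) {
    stopf("non-numeric score in %s at line %d", path, bad[1] + 1L)
  }
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  if (any(score < 0 | score > 1, na.rm = TRUE)) {
    stopf("scores in %s fall outside [0, 1] after rescaling", path)
  }
  g1 <- normalize_ids(df[[id_cols[1]]])
  g2 <- normalize_ids(df[[id_cols[2]]])
  loops <- g1 == g2
  if (any(loops)) {
    warnf("dropping %d self-loop edge(s)", sum(loops))
    g1 <- g1[!loops]; g2 <- g2[!loops]; score <- score[!loops]
  }
  a <- pmin(g1, g2); b <- pmax(g1, g2)
  ord <- order(a, b, -score)
  a <- a[ord]; b <- b[ord]; score <- score[ord]
  keep <- !duplicated(paste(a, b))
  data.frame(gene1 = a[keep], gene2 = b[keep], score = score[keep],
             stringsAsFactors = FALSE)
}

#' Query-induced high-confidence interaction subgraph
#'
#' Keeps the edges whose both endpoints belong to the query and whose
#' score is at least `min_score`; every query gene becomes a node, so
#' isolated (interaction-free) genes stay in the data, flagged via the
#' `isolated` vertex attribute, even though network drawings usually omit
#' them.
#'
#' @param edges data frame as returned by [read_edges()] (columns
#'   `gene1`/`gene2`/`score`, or `protein1`/`protein2`/`combined_score`).
#' @param query non-empty character vector of gene ids.
#' @param min_score inclusive confidence cutoff (default 0.7, the STRING
#'   "high confidence" preset).
#' @return an `igraph` object with edge attribute `score` and vertex
#'   attribute `isolated`.
#' @export
induced_subgraph <- function(edges, query, min_score = 0.7) {
  edges <- as_edge_df(edges)
  query <- sort(unique(normalize_ids(query)))
  if (length(query) == 0) stopf("query must be non-empty")
  keep <- edges$gene1 %in% query & edges$gene2 %in% query &
    edges$score >= min_score
  kept <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("gene1", "gene2")], directed = FALSE,
    vertices = data.frame(name = query))
  igraph::E(g)$score <- kept$score
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  g
}

as_edge_df <- function(edges) {
  if (all(c("gene1", "gene2", "score") %in% names(edges))) {
    return(data.frame(gene1 = normalize_ids(edges$gene1),
                      gene2 = normalize_ids(edges$gene2),
                      score = edges$score, stringsAsFactors = FALSE))
  }
  if (all(c("protein1", "protein2", "combined_score") %in% names(edges))) {
    return(data.frame(gene1 = normalize_ids(edges$protein1),
                      gene2 = normalize_ids(edges$protein2),
                      score = edges$combined_score, stringsAsFactors = FALSE))
  }
  stopf("edges must have columns gene1/gene2/score or protein1/protein2/combined_score")
}

#' Connected components of the edge-bearing subgraph
#'
#' Extracts the connected components among nodes that carry at least one
#' edge (the network "clusters"), sorted by size descending with ties
#' broken by the lexicographically smallest member. Components below
#' `min_size` are left out of the report but counted.
#'
#' @param graph an `igraph` object (from [induced_subgraph()]).
#' @param min_size smallest component size reported (default 3).
#' @return an object of class `cluster_report`: list with `components`
#'   (list of sorted gene-id vectors), `n_dropped` (components below
#'   `min_size`) and `min_size`.
#' @export
graph_components <- function(graph, min_size = 3) {
  sub <- igraph::induced_subgraph(graph, igraph::V(graph)[igraph::degree(graph) > 0])
  comp <- igraph::components(sub)
  members <- split(igraph::V(sub)$name, comp$membership)
  members <- lapply(members, sort)
  ord <- order(-lengths(members), vapply(members, `[`, character(1), 1))
  members <- unname(members[ord])
  big <- lengths(members) >= min_size
  if (any(!big)) {
    message(sprintf("%d component(s) below min_size %d omitted from the report",
                    sum(!big), min_size))
  }
  structure(list(components = members[big], n_dropped = sum(!big),
                 min_size = min_size),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d component(s) of size >= %d (%s)%s\n",
              length(x$components), x$min_size,
              paste(lengths(x$components), collapse = ", "),
              if (x$n_dropped) sprintf("; %d smaller omitted", x$n_dropped) else ""))
  invisible(x)
}

#' Permutation test for interaction enrichment of a gene set
#'
#' Asks whether the query gene set carries more high-confidence
#' interactions among its members than a random gene set of the same size
#' drawn from the background. The null is built by drawing `n_perm`
#' uniform same-size gene sets and counting their induced edges at
#' `min_score`; the empirical p-value uses the standard +1 pseudo-count,
#' `p = (1 + #[null >= observed]) / (n_perm + 1)`, so it can never be 0.
#'
#' @param query character vector of gene ids, a subset of `background_genes`.
#' @param edges edge data frame ([read_edges()] / [make_ppi_edges()] format).
#' @param background_genes character vector to permute over.
#' @param min_score inclusive score cutoff (default 0.7).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return an object of class `edge_enrichment`: list with `observed`,
#'   `expected` (null mean), `p`, `n_perm`, `seed`.
#' @export
edge_enrichment_p <- function(query, edges, background_genes, min_score = 0.7,
                              n_perm = 10000, seed = 1) {
  edges <- as_edge_df(edges)
  background_genes <- unique(normalize_ids(background_genes))
  query <- unique(normalize_ids(query))
  if (length(query) > length(background_genes)) {
    stopf("query (%d genes) larger than background (%d genes)",
          length(query), length(background_genes))
  }
  if (!all(query %in% background_genes)) {
    stopf("query contains %d gene(s) outside the background",
          sum(!query %in% background_genes))
  }
  hi <- edges[edges$score >= min_score &
                edges$gene1 %in% background_genes &
                edges$gene2 %in% background_genes, , drop = FALSE]
  e1 <- match(hi$gene1, background_genes)
  e2 <- match(hi$gene2, background_genes)
  count_induced <- function(member) sum(member[e1] & member[e2])

  member <- background_genes %in% query
  observed <- count_induced(member)
  nb <- length(background_genes); nq <- length(query)
  null_counts <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      m <- logical(nb)
      m[sample.int(nb, nq)] <- TRUE
      count_induced(m)
    }, numeric(1))
  })
  structure(list(observed = as.numeric(observed),
                 expected = mean(null_counts),
                 p = (1 + sum(null_counts >= observed)) / (n_perm + 1),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "edge_enrichment")
}

#' @export
print.edge_enrichment <- function(x, ...) {
  cat(sprintf(
    "edge enrichment: observed %g induced edges vs %.2f expected (p = %.3g, %d permutations)\n",
    x$observed, x$expected, x$p, x$n_perm))
  invisible(x)
}

#' Export an annotated interaction graph as GraphML
#'
#' Attaches per-node annotations (consensus direction, mean drug logFC,
#' eQTL flag, component id) to the graph and writes GraphML via igraph.
#'
#' @param graph an `igraph` object from [induced_subgraph()].
#' @param annotations data frame from [annotate_nodes()].
#' @param report optional [graph_components()] result used to label
#'   component membership.
#' @param path output path.
#' @return the annotated `igraph`, invisibly.
#' @export
write_graphml <- function(graph, annotations, path, report = NULL) {
  idx <- match(igraph::V(graph)$name, annotations$gene)
  igraph::V(graph)$direction <- annotations$direction[idx]
  igraph::V(graph)$mean_logfc <- annotations$mean_logFC[idx]
  igraph::V(graph)$is_eqtl <- annotations$is_eqtl[idx]
  comp_id <- rep(NA_integer_, igraph::vcount(graph))
  if (!is.null(report)) {
    for (i in seq_along(report$components)) {
      comp_id[igraph::V(graph)$name %in% report$components[[i]]] <- i
    }
  }
  igraph::V(graph)$component_id <- comp_id
  igraph::write_graph(graph, path, format = "graphml")
  invisible(graph)
}
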