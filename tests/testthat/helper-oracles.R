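# Independent oracles used to cross-check package computations.
# These deliberately use naive, transparent algorithms.

# Step-up FDR adjustment computed directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j on sorted p-values, capped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(ps[i:m] * m / (i:m), 1))
  }, numeric(1))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Hypergeometric upper tail by direct summation of binomial-coefficient
# ratios: P(X >= k) = sum_{i=k..min(K,n)} C(K,i) C(N-K,n-i) / C(N,n).
hyper_tail_oracle <- function(k, K, n, N) {
  top <- min(K, n)
  if (k > top) return(0)
  i <- k:top
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Connected components by breadth-first search over an adjacency list.
# Returns a canonical partition: list of sorted member vectors, sorted by
# size descending then first member.
bfs_components_oracle <- function(nodes, edge_a, edge_b) {
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), identity)
  for (i in seq_along(edge_a)) {
    adj[[edge_a[i]]] <- c(adj[[edge_a[i]]], edge_b[i])
    adj[[edge_b[i]]] <- c(adj[[edge_b[i]]], edge_a[i])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[[v]]) next
    queue <- v
    seen[[v]] <- TRUE
    members <- character()
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      members <- c(members, u)
      for (w in adj[[u]]) {
        if (!seen[[w]]) { seen[[w]] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1]] <- sort(members)
  }
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1))
  unname(comps[ord])
}

canonical_partition <- function(comps) {
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1))
  unname(comps[ord])
}

# Random significance table over a fixed gene pool.
random_signature <- function(genes, label, q_threshold = 0.05) {
  n <- length(genes)
  de_signature(genes,
               logFC = stats::rnorm(n),
               pvalue = stats::runif(n),
               fdr = stats::runif(n),
               label = label, q_threshold = q_threshold)
}

# Small count matrix with exactly controllable columns.
toy_counts <- function(mat, groups, label = "toy") {
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  count_matrix(mat, groups, label = label)
}
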