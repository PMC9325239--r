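#' Counts per million
#'
#' Scales each column of a count matrix to counts per million mapped
#' reads, optionally dividing the library size by a per-sample
#' normalization factor (e.g. from [tmm_factors()]).
#'
#' @param x a [count_matrix()] or a plain numeric matrix.
#' @param factors optional per-sample positive normalization factors
#'   (default all 1).
#' @return a numeric matrix of the same shape.
#' @examples
#' m <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' cpm(m)  # 300000, 700000
#' @export
cpm <- function(x, factors = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stopf("zero library size for sample(s): %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (length(factors) != ncol(counts) || any(!is.finite(factors)) ||
      any(factors <= 0)) {
    stopf("factors must be positive and one per sample")
  }
  t(t(counts) * 1e6 / (lib * factors))
}

#' Remove genes expressed below a CPM threshold
#'
#' Two rules are supported. `"fraction"` keeps a gene when its CPM exceeds
#' `min_cpm` (strictly) in strictly more than `threshold` of the samples —
#' the ">1 CPM in >50% of samples" convention used for large cohort
#' tables. `"smallest_group"` keeps a gene when its CPM is at least
#' `min_cpm` in at least `n` samples, where `n` is the size of the
#' smallest treatment group — the convention used for small two-group
#' designs. Gene order is preserved; an empty result is allowed with a
#' warning.
#'
#' @param x a [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param mode `"smallest_group"` (default) or `"fraction"`.
#' @param threshold for `"fraction"` mode, the required fraction of
#'   samples in (0, 1].
#' @return the filtered [count_matrix()].
#' @export
filter_low_expression <- function(x, min_cpm = 1,
                                  mode = c("smallest_group", "fraction"),
                                  threshold = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  mode <- match.arg(mode)
  v <- cpm(x)
  keep <- if (mode == "fraction") {
    if (is.null(threshold) || threshold <= 0 || threshold > 1) {
      stopf("fraction mode requires a threshold in (0, 1]")
    }
    rowSums(v > min_cpm) > threshold * ncol(v)
  } else {
    n_small <- min(table(x$groups))
    rowSums(v >= min_cpm) >= n_small
  }
  if (!any(keep)) warnf("low-expression filter removed every gene")
  count_matrix(x$counts[keep, , drop = FALSE], as.character(x$groups),
               label = x$label)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of
#' M-values: each sample is compared to a reference sample via per-gene
#' log2 ratios of relative expression (M) and average log2 relative
#' expression (A) over genes expressed in both; the most extreme 30% of M
#' values and 5% of A values are trimmed on each side and the factor is
#' `2^` the precision-weighted mean of the remaining M values (weights are
#' inverse asymptotic variances of M). Factors are rescaled to geometric
#' mean 1, so they carry composition-bias corrections only, not library
#' size.
#'
#' @param x a [count_matrix()] (already filtered for low expression).
#' @param ref_sample reference sample id, or `NULL` to pick the sample
#'   whose upper-quartile relative expression is closest to the mean
#'   upper quartile.
#' @param logratio_trim two-sided trim fraction on M (default 0.30).
#' @param abs_trim two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of positive factors, geometric mean 1.
#' @export
tmm_factors <- function(x, ref_sample = NULL, logratio_trim = 0.30,
                        abs_trim = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  if (ncol(counts) < 2) stopf("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stopf("zero library size for sample(s): %s",
                           paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
    ref_idx <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_idx <- match(ref_sample, colnames(counts))
    if (is.na(ref_idx)) stopf("reference sample '%s' not found", ref_sample)
  }
  ref <- counts[, ref_idx]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_one(counts[, j], ref, lib[j], lib[ref_idx], logratio_trim, abs_trim,
            colnames(counts)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One-sample TMM against a fixed reference column.
tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim, sample_id) {
  keep0 <- obs > 0 & ref > 0
  if (!any(keep0)) stopf("sample '%s' shares no expressed gene with the reference",
                         sample_id)
  o <- obs[keep0]; r <- ref[keep0]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- (log2(o / n_obs) + log2(r / n_ref)) / 2
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)  # asymptotic var of M
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1;      hi_a <- n + 1 - lo_a
  rm_ <- rank(m); ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  f <- sum(m[keep] / w[keep], na.rm = TRUE) / sum(1 / w[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Welch test for differential expression on log2-CPM
#'
#' Per-gene two-sided unequal-variance comparison of treated versus
#' vehicle samples on normalized log2-CPM (pseudocount 0.5 on the counts
#' and +1 on the effective library size guard against zeros). The log2
#' fold change is `mean(treated) - mean(vehicle)`. Degenerate genes with
#' zero variance in both groups get p = 1 when the means agree and the
#' smallest representable p (flagged via the `degenerate` attribute)
#' otherwise. q-values come from [bh_adjust()].
#'
#' @param x a [count_matrix()] with at least 2 samples per group.
#' @param factors optional per-sample normalization factors from
#'   [tmm_factors()].
#' @param q_threshold FDR threshold recorded on the signature (default 0.05).
#' @return a [de_signature()] labelled after `x$label`.
#' @export
de_welch <- function(x, factors = NULL, q_threshold = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  if (any(table(x$groups) < 2)) stopf("both groups need at least 2 samples")
  counts <- x$counts
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  y <- log2(t(t(counts + 0.5) / (lib * factors + 1)) * 1e6)

  g1 <- x$groups == "treated"; g0 <- x$groups == "vehicle"
  n1 <- sum(g1); n0 <- sum(g0)
  m1 <- rowMeans(y[, g1, drop = FALSE]); m0 <- rowMeans(y[, g0, drop = FALSE])
  v1 <- rowSums((y[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((y[, g0, drop = FALSE] - m0)^2) / (n0 - 1)
  logfc <- m1 - m0
  se2 <- v1 / n1 + v0 / n0
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  tt <- logfc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)

  zero_var <- se2 == 0
  p[zero_var & logfc == 0] <- 1
  degen <- zero_var & logfc != 0
  p[degen] <- .Machine$double.xmin
  out <- de_signature(rownames(counts), logfc, p, bh_adjust(p),
                      label = x$label, q_threshold = q_threshold)
  if (any(degen)) {
    warnf("%d gene(s) had zero within-group variance with nonzero difference",
          sum(degen))
    attr(out, "degenerate") <- rownames(counts)[degen]
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and mapped back to
#' input order. Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the full per-drug differential-expression step
#'
#' Convenience wrapper chaining [filter_low_expression()],
#' [tmm_factors()] and [de_welch()].
#'
#' @param x a [count_matrix()].
#' @param min_cpm,mode,threshold passed to [filter_low_expression()].
#' @param q_threshold passed to [de_welch()].
#' @return a [de_signature()] over the retained genes.
#' @export
de_analysis <- function(x, min_cpm = 1, mode = "smallest_group",
                        threshold = NULL, q_threshold = 0.05) {
  filtered <- filter_low_expression(x, min_cpm = min_cpm, mode = mode,
                                    threshold = threshold)
  de_welch(filtered, tmm_factors(filtered), q_threshold = q_threshold)
}
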