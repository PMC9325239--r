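#' Generate the disease differential-expression summary table
#'
#' Emulates a published case-control brain cohort signature at desk scale:
#' every gene gets a log2 fold change equal to its true signed effect plus
#' Gaussian estimation noise, a two-sided normal p-value consistent with
#' that noise model, and a Benjamini-Hochberg q-value. Genes with a true
#' disease effect are strongly enriched below FDR 0.1.
#'
#' The noise model fixes the logFC standard error at
#' `1 / sqrt(50)` (unit noise SD over a pseudo sample size of 50),
#' chosen so that the default parameters yield a significant-gene
#' fraction of roughly 5% at FDR < 0.1, in line with large post-mortem
#' cohorts.
#'
#' @param truth a [make_truth()] object.
#' @param params the [sim_params()] that produced `truth`.
#' @return a [de_signature()] labelled `"disease"` with `q_threshold` 0.1.
#' @export
make_disease_table <- function(truth, params) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  with_seed(substream_seed(params$seed, 2L), {
    n <- params$n_genes
    se <- 1 / sqrt(50)
    effect <- r_effect(n, params$disease_effect_scale)
    logfc <- as.numeric(truth$disease_direction) * effect + stats::rnorm(n, 0, se)
    z <- logfc / se
    p <- 2 * stats::pnorm(-abs(z))
    de_signature(truth$gene_ids, logfc, p, bh_adjust(p),
                 label = "disease", q_threshold = 0.1)
  })
}

#' Generate a drug-versus-vehicle count matrix
#'
#' Draws a negative-binomial gene-by-sample count matrix for one drug arm.
#' Gene baselines are log-normal; for genes the drug truly regulates, the
#' drug-group mean is shifted by a factor `2^(direction * |effect|)` with
#' the effect magnitude drawn from the shifted-gamma family at
#' `drug_effect_scale`. Columns are labelled treated/vehicle with
#' `reps_per_group` replicates each.
#'
#' @param truth a [make_truth()] object.
#' @param params the matching [sim_params()].
#' @param drug_index which drug arm to simulate (1-based).
#' @return a [count_matrix()] labelled with the drug name.
#' @export
make_drug_counts <- function(truth, params, drug_index) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  drug_index <- as.integer(drug_index)
  if (is.na(drug_index) || drug_index < 1L || drug_index > params$n_drugs) {
    stopf("drug_index must lie in 1..%d", params$n_drugs)
  }
  with_seed(substream_seed(params$seed, 10L + drug_index), {
    n <- params$n_genes
    r <- params$reps_per_group
    mu0 <- exp(stats::rnorm(n, params$mean_log_expression, params$sd_log_expression))
    effect <- r_effect(n, params$drug_effect_scale)
    fold <- 2^(as.numeric(truth$drug_direction[, drug_index]) * effect)
    size <- 1 / params$nb_dispersion
    treated <- matrix(stats::rnbinom(n * r, mu = rep(mu0 * fold, r), size = size), n, r)
    vehicle <- matrix(stats::rnbinom(n * r, mu = rep(mu0, r), size = size), n, r)
    counts <- cbind(treated, vehicle)
    label <- params$drug_labels[drug_index]
    dimnames(counts) <- list(
      truth$gene_ids,
      c(sprintf("%s_T%d", label, seq_len(r)), sprintf("%s_V%d", label, seq_len(r))))
    count_matrix(counts, rep(c("treated", "vehicle"), each = r), label = label)
  })
}
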