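#' Draw the planted ground truth of a synthetic study
#'
#' Decides, gene by gene, the true disease direction, the true per-drug
#' response direction, and the derived reversal status, then plants dense
#' interaction modules among the genes truly reversed by every drug. All
#' downstream generator operations condition on this object, so detection
#' performance of the whole pipeline can be scored against known truth.
#'
#' Exactly `round(n_genes * frac_disease_de)` genes receive a nonzero
#' disease direction (sign fair-coin). Conditional on a nonzero disease
#' direction, each drug independently opposes it with probability
#' `reversal_prob`, matches it with probability `concordant_prob`, and
#' leaves the gene untouched otherwise. Genes without a disease effect have
#' no drug effect: the generator models drug action on the disease
#' signature, not the drugs' full pharmacology.
#'
#' @param params a [sim_params()] object.
#' @return an object of class `sim_truth` with elements
#'   `gene_ids`, `disease_direction` (named -1/0/+1 vector),
#'   `drug_direction` (genes x drugs matrix of -1/0/+1),
#'   `true_reversed` (genes x drugs logical matrix),
#'   `module_members` (list of gene-id vectors) and
#'   `enriched_set_ids` (ids of gene sets planted as enriched).
#' @examples
#' tr <- make_truth(sim_params(n_genes = 500, seed = 3))
#' sum(tr$disease_direction != 0)
#' @export
make_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(substream_seed(params$seed, 1L), {
    n <- params$n_genes
    gene_ids <- sprintf("G%06d", seq_len(n))
    n_de <- round(n * params$frac_disease_de)

    disease_direction <- integer(n)
    de_idx <- sample.int(n, n_de)
    disease_direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
    names(disease_direction) <- gene_ids

    drug_direction <- matrix(0L, n, params$n_drugs,
                             dimnames = list(gene_ids, params$drug_labels))
    for (d in seq_len(params$n_drugs)) {
      u <- stats::runif(n_de)
      resp <- integer(n_de)
      resp[u < params$reversal_prob] <- -1L
      resp[u >= params$reversal_prob &
             u < params$reversal_prob + params$concordant_prob] <- 1L
      # resp is relative to the disease sign: -1 opposes, +1 matches
      drug_direction[de_idx, d] <- resp * disease_direction[de_idx]
    }

    true_reversed <- drug_direction == -disease_direction & disease_direction != 0L
    dimnames(true_reversed) <- dimnames(drug_direction)

    module_members <- plant_modules(gene_ids, true_reversed, params)

    structure(
      list(
        gene_ids = gene_ids,
        disease_direction = disease_direction,
        drug_direction = drug_direction,
        true_reversed = true_reversed,
        module_members = module_members,
        enriched_set_ids = "SET_PLANTED"
      ),
      class = "sim_truth"
    )
  })
}

# Planted modules are drawn preferentially from the genes reversed by every
# drug (the set the network stage analyses); if that pool is too small the
# pool widens to genes reversed by at least one drug, then to all genes.
plant_modules <- function(gene_ids, true_reversed, params) {
  need <- params$n_modules * params$module_size
  if (need == 0L) return(list())
  pool <- gene_ids[rowSums(true_reversed) == ncol(true_reversed)]
  if (length(pool) < need) {
    extra <- setdiff(gene_ids[rowSums(true_reversed) > 0], pool)
    pool <- c(pool, extra)
  }
  if (length(pool) < need) pool <- c(pool, setdiff(gene_ids, pool))
  chosen <- sample(pool, need)
  split(chosen, rep(seq_len(params$n_modules), each = params$module_size))
}

#' @export
print.sim_truth <- function(x, ...) {
  common <- sum(rowSums(x$true_reversed) == ncol(x$true_reversed))
  cat(sprintf(
    "Synthetic truth: %d genes, %d with disease effect, %d truly reversed by all %d drugs\n",
    length(x$gene_ids), sum(x$disease_direction != 0), common, ncol(x$true_reversed)))
  cat(sprintf("  planted modules: %s\n",
              paste(lengths(x$module_members), collapse = ", ")))
  invisible(x)
}
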