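#' Simulation parameters for the synthetic reversal study
#'
#' Bundles every knob of the synthetic-data generator into a validated
#' parameter object. The defaults describe the desk-scale study the package
#' emulates: a post-mortem disease signature over ~20,000 expressed genes
#' with roughly 5% of genes differentially expressed at FDR < 0.1, and four
#' independent drug-versus-vehicle RNA-seq experiments on a clonal neuronal
#' cell line with 6 replicates per group.
#'
#' @param n_genes number of genes simulated (>= 100).
#' @param frac_disease_de fraction of genes with a true disease effect.
#' @param disease_effect_scale mean absolute log2 fold change of true
#'   disease effects (shifted-gamma distributed with minimum 0.25; must
#'   exceed 0.25). Post-mortem case-control differences are subtle, hence
#'   the modest default of 1.
#' @param drug_effect_scale mean absolute log2 fold change of true drug
#'   responses (same shifted-gamma family). Acute compound exposure of a
#'   clonal cell line produces much larger fold changes than a
#'   case-control tissue contrast, hence the default of 2.
#' @param reversal_prob probability, for a gene with a disease effect, that
#'   a given drug regulates it in the opposite direction.
#' @param concordant_prob probability that the drug regulates it in the same
#'   direction as the disease. `reversal_prob + concordant_prob` must be <= 1;
#'   the remainder of the mass is "no drug effect".
#' @param n_drugs number of drug signatures.
#' @param reps_per_group biological replicates per treatment group (2-6;
#'   the emulated experiment used 4-6).
#' @param nb_dispersion negative-binomial dispersion of the counts. The
#'   default 0.01 (biological coefficient of variation 0.1) is the standard
#'   figure for technical-grade replicates of a clonal cell line.
#' @param mean_log_expression mean of the natural-log baseline expression;
#'   gene baselines are log-normal with this mean and standard deviation
#'   `sd_log_expression`.
#' @param sd_log_expression spread of baseline log expression across genes.
#' @param n_modules number of dense interaction modules planted among the
#'   commonly reversed genes.
#' @param module_size genes per planted module.
#' @param drug_labels character labels for the drug arms. Defaults to the
#'   four atypical antipsychotics emulated when `n_drugs == 4`, otherwise
#'   `"drug1"`, `"drug2"`, ...
#' @param seed master integer seed; every generator operation derives its
#'   own substream from it, so identical parameters reproduce every output
#'   byte for byte.
#'
#' @return an object of class `sim_params`.
#' @examples
#' p <- sim_params(n_genes = 1000, seed = 7)
#' p$n_genes
#' @export
sim_params <- function(n_genes = 20000L,
                       frac_disease_de = 0.05,
                       disease_effect_scale = 1,
                       drug_effect_scale = 2,
                       reversal_prob = 0.6,
                       concordant_prob = 0.1,
                       n_drugs = 4L,
                       reps_per_group = 6L,
                       nb_dispersion = 0.01,
                       mean_log_expression = 5,
                       sd_log_expression = 1.5,
                       n_modules = 2L,
                       module_size = 10L,
                       drug_labels = NULL,
                       seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_drugs <- as.integer(n_drugs)
  reps_per_group <- as.integer(reps_per_group)
  if (is.na(n_genes) || n_genes < 100L) stopf("n_genes must be an integer >= 100")
  if (!is.finite(frac_disease_de) || frac_disease_de <= 0 || frac_disease_de >= 1) {
    stopf("frac_disease_de must lie in (0, 1)")
  }
  for (nm in c("disease_effect_scale", "drug_effect_scale")) {
    if (!is.finite(get(nm)) || get(nm) <= 0.25) {
      stopf("%s must exceed the minimum effect of 0.25", nm)
    }
  }
  for (nm in c("reversal_prob", "concordant_prob")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) stopf("%s must lie in [0, 1]", nm)
  }
  if (reversal_prob + concordant_prob > 1 + 1e-12) {
    stopf("reversal_prob + concordant_prob must not exceed 1")
  }
  if (is.na(n_drugs) || n_drugs < 1L) stopf("n_drugs must be a positive integer")
  if (is.na(reps_per_group) || reps_per_group < 2L) {
    stopf("reps_per_group must be an integer >= 2")
  }
  if (!is.finite(nb_dispersion) || nb_dispersion <= 0) {
    stopf("nb_dispersion must be a positive real")
  }
  if (!is.finite(mean_log_expression)) stopf("mean_log_expression must be finite")
  if (!is.finite(sd_log_expression) || sd_log_expression <= 0) {
    stopf("sd_log_expression must be positive")
  }
  n_modules <- as.integer(n_modules)
  module_size <- as.integer(module_size)
  if (n_modules < 0L) stopf("n_modules must be non-negative")
  if (n_modules > 0L && module_size < 3L) stopf("module_size must be >= 3")
  if (is.null(drug_labels)) {
    drug_labels <- if (n_drugs == 4L) {
      c("amisulpride", "aripiprazole", "clozapine", "risperidone")
    } else {
      paste0("drug", seq_len(n_drugs))
    }
  }
  drug_labels <- as.character(drug_labels)
  if (length(drug_labels) != n_drugs || anyDuplicated(drug_labels)) {
    stopf("drug_labels must be %d unique labels", n_drugs)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stopf("seed must be an integer")

  structure(
    list(
      n_genes = n_genes,
      frac_disease_de = frac_disease_de,
      disease_effect_scale = disease_effect_scale,
      drug_effect_scale = drug_effect_scale,
      reversal_prob = reversal_prob,
      concordant_prob = concordant_prob,
      n_drugs = n_drugs,
      reps_per_group = reps_per_group,
      nb_dispersion = nb_dispersion,
      mean_log_expression = mean_log_expression,
      sd_log_expression = sd_log_expression,
      n_modules = n_modules,
      module_size = module_size,
      drug_labels = drug_labels,
      seed = seed
    ),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  genes: %d (%.1f%% with disease effect, mean |logFC| %.2f)\n",
              x$n_genes, 100 * x$frac_disease_de, x$disease_effect_scale))
  cat(sprintf("  drugs: %s\n", paste(x$drug_labels, collapse = ", ")))
  cat(sprintf("  P(reversal) = %.2f, P(concordant) = %.2f per drug\n",
              x$reversal_prob, x$concordant_prob))
  cat(sprintf("  counts: %d vs %d replicates, NB dispersion %.3g\n",
              x$reps_per_group, x$reps_per_group, x$nb_dispersion))
  cat(sprintf("  planted modules: %d x %d genes; seed %d\n",
              x$n_modules, x$module_size, x$seed))
  invisible(x)
}

# Absolute effect sizes: shifted gamma with minimum 0.25 and the requested
# mean. Shape 2 keeps the bulk near the mean while allowing weak effects.
r_effect <- function(n, scale) {
  0.25 + stats::rgamma(n, shape = 2, scale = (scale - 0.25) / 2)
}
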