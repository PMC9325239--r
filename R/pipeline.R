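#' Run the full disease-drug reversal analysis
#'
#' One call executes the whole study on synthetic inputs with planted
#' ground truth: simulate -> per-drug differential expression (CPM
#' filter, TMM, Welch test, BH) -> reversal detection against the disease
#' signature -> multi-drug intersection accounting -> over-representation
#' analysis of the common reversed set -> high-confidence interaction
#' subgraph, connected components and permutation edge-enrichment ->
#' node annotation. The returned object is classed and carries every
#' intermediate result, the planted truth, and a compact summary; it has
#' `print`, `summary` and `plot` methods.
#'
#' The run is fully deterministic given `params` (which embeds the master
#' seed): repeating a call reproduces every number and file byte for
#' byte.
#'
#' @param params a [sim_params()] object describing the synthetic study.
#' @param q_disease disease-side FDR threshold (default 0.1).
#' @param q_drug drug-side FDR threshold (default 0.05).
#' @param min_cpm,filter_mode,filter_threshold low-expression filter
#'   settings for the drug count matrices (see [filter_low_expression()]).
#' @param ora_min_size,ora_max_size,ora_q_cut gene-set size bounds and
#'   significance cut for [ora()].
#' @param min_score interaction confidence cutoff (default 0.7).
#' @param min_component_size smallest reported network cluster (default 3).
#' @param n_perm permutations for [edge_enrichment_p()] (default 10000).
#' @param gene_set_args optional list of arguments forwarded to
#'   [make_gene_sets_and_eqtl()] (e.g. `enrichment_factor`).
#' @param verbose emit per-stage progress messages with record counts.
#' @return an object of class `reversal_analysis`; see Details.
#' @details The object contains `params`, `truth`, `disease`,
#'   `drug_sigs`, `universe`, `reversal` (a `reversal_result`), `ora`,
#'   `graph`, `clusters`, `enrichment`, `annotations`, `thresholds` and
#'   `summary`. `summary` has exactly the elements `per_drug_counts`,
#'   `union`, `common`, `ora_significant`, `components`, `enrichment_p`
#'   and `seed`.
#' @examples
#' \donttest{
#' fit <- run_reversal_pipeline(sim_params(n_genes = 500, seed = 1),
#'                              n_perm = 200, verbose = FALSE)
#' fit$summary$common
#' }
#' @export
run_reversal_pipeline <- function(params = sim_params(),
                                  q_disease = 0.1, q_drug = 0.05,
                                  min_cpm = 1,
                                  filter_mode = "smallest_group",
                                  filter_threshold = NULL,
                                  ora_min_size = 10, ora_max_size = 500,
                                  ora_q_cut = 0.05,
                                  min_score = 0.7,
                                  min_component_size = 3,
                                  n_perm = 10000,
                                  gene_set_args = list(),
                                  verbose = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  for (thr in c(q_disease, q_drug, ora_q_cut)) {
    if (!is.finite(thr) || thr <= 0 || thr > 1) stopf("q thresholds must lie in (0, 1]")
  }
  if (!is.finite(min_score) || min_score < 0 || min_score > 1) {
    stopf("min_score must lie in [0, 1]")
  }
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    res
  }

  sim <- stage("simulate", do.call(simulate_inputs,
                                   c(list(params = params), gene_set_args)))
  say("[simulate] %d genes, %d with disease effect", params$n_genes,
      sum(sim$truth$disease_direction != 0))

  drug_sigs <- stage("de", lapply(sim$drug_counts, function(cm) {
    sig <- de_analysis(cm, min_cpm = min_cpm, mode = filter_mode,
                       threshold = filter_threshold, q_threshold = q_drug)
    say("[de] %s: %d genes kept, %d at FDR <= %g", cm$label, nrow(sig),
        sum(sig$fdr <= q_drug), q_drug)
    sig
  }))

  universe <- intersect(
    sim$disease$gene,
    Reduce(intersect, lapply(drug_sigs, function(s) s$gene)))
  say("[universe] %d genes measured in the disease table and all drug arms",
      length(universe))

  per_drug <- stage("reversal", lapply(drug_sigs, function(sig) {
    reversed_genes(sim$disease, sig, q_disease = q_disease, q_drug = q_drug)
  }))
  reversal <- intersect_across_drugs(per_drug)
  say("[reversal] union %d, common to all drugs %d",
      length(reversal$union_set), length(reversal$common_set))

  ora_res <- stage("ora", ora(reversal$common_set, universe, sim$gene_sets,
                              min_size = ora_min_size, max_size = ora_max_size,
                              q_cut = ora_q_cut))

  common <- reversal$common_set
  if (length(common) > 0) {
    graph <- stage("network", induced_subgraph(sim$ppi_edges, common,
                                               min_score = min_score))
    clusters <- graph_components(graph, min_size = min_component_size)
    enrichment <- edge_enrichment_p(common, sim$ppi_edges, universe,
                                    min_score = min_score, n_perm = n_perm,
                                    seed = substream_seed(params$seed, 90L))
    annotations <- stage("annotate",
                         annotate_nodes(common, drug_sigs, eqtl = sim$eqtl))
  } else {
    say("[network] common set empty; skipping network and annotation")
    graph <- NULL
    clusters <- structure(list(components = list(), n_dropped = 0L,
                               min_size = min_component_size),
                          class = "cluster_report")
    enrichment <- structure(list(observed = 0, expected = NA_real_,
                                 p = NA_real_, n_perm = as.integer(n_perm),
                                 seed = substream_seed(params$seed, 90L)),
                            class = "edge_enrichment")
    annotations <- data.frame(gene = character(), direction = character(),
                              mean_logFC = numeric(), is_eqtl = logical())
  }

  thresholds <- list(q_disease = q_disease, q_drug = q_drug,
                     min_cpm = min_cpm, filter_mode = filter_mode,
                     min_score = min_score, ora_q_cut = ora_q_cut,
                     ora_min_size = ora_min_size, ora_max_size = ora_max_size,
                     min_component_size = min_component_size, n_perm = n_perm)
  summary <- list(
    per_drug_counts = lapply(reversal$reversed_sets, length),
    union = length(reversal$union_set),
    common = length(reversal$common_set),
    ora_significant = sum(ora_res$fdr <= ora_q_cut),
    components = as.integer(lengths(clusters$components)),
    enrichment_p = enrichment$p,
    seed = params$seed)

  structure(
    list(params = params, thresholds = thresholds, truth = sim$truth,
         disease = sim$disease, drug_sigs = drug_sigs, universe = universe,
         gene_sets = sim$gene_sets, ppi_edges = sim$ppi_edges,
         eqtl = sim$eqtl, reversal = reversal, ora = ora_res, graph = graph,
         clusters = clusters, enrichment = enrichment,
         annotations = annotations, summary = summary),
    class = "reversal_analysis")
}

#' @export
print.reversal_analysis <- function(x, ...) {
  s <- x$summary
  cat("Disease-drug transcriptomic reversal analysis\n")
  cat(sprintf("  %d genes simulated, seed %d\n", x$params$n_genes, s$seed))
  cat(sprintf("  reversed per drug: %s\n",
              paste(sprintf("%s=%d", names(s$per_drug_counts),
                            unlist(s$per_drug_counts)), collapse = ", ")))
  cat(sprintf("  union %d, common to all drugs %d\n", s$union, s$common))
  cat(sprintf("  enriched gene sets (FDR <= %g): %d\n",
              x$thresholds$ora_q_cut, s$ora_significant))
  cat(sprintf("  network clusters (size >= %d): %s\n",
              x$thresholds$min_component_size,
              if (length(s$components)) paste(s$components, collapse = ", ")
              else "none"))
  cat(sprintf("  interaction enrichment p = %s (%d permutations)\n",
              format(s$enrichment_p, digits = 3), x$thresholds$n_perm))
  invisible(x)
}

#' @export
summary.reversal_analysis <- function(object, ...) {
  s <- object$summary
  truth_common <- sum(rowSums(object$truth$true_reversed) ==
                        ncol(object$truth$true_reversed))
  c(s, list(truth_common = truth_common,
            disease_significant = sum(object$disease$fdr <=
                                        object$thresholds$q_disease)))
}

#' @export
plot.reversal_analysis <- function(x, max_regions = 12, ...) {
  uc <- upset_counts(x$reversal)
  uc <- utils::head(uc, max_regions)
  if (nrow(uc) == 0) {
    warnf("nothing to plot: no reversed genes")
    return(invisible(x))
  }
  op <- graphics::par(mar = c(10, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(uc$count, names.arg = uc$drugs, las = 2,
                    ylab = "genes in exclusive region",
                    main = "Reversed genes by drug combination", ...)
  invisible(x)
}

#' Write the run reports of a reversal analysis
#'
#' Writes `summary.json` (run summary, thresholds and simulation
#' parameters), `upset_counts.tsv`, per-drug reversed-gene tables, the
#' membership matrix, the common set, `ora_results.tsv`,
#' `annotations.tsv`, `clusters.tsv`, `enrichment.json`, the annotated
#' `network.graphml` and a plain-text run report. Refuses to overwrite an
#' existing report directory unless `force = TRUE`.
#'
#' @param x a `reversal_analysis` object.
#' @param out_dir output directory.
#' @param force overwrite an existing report (default `FALSE`).
#' @return invisibly, the path of `summary.json`.
#' @export
write_reports <- function(x, out_dir, force = FALSE) {
  stopifnot(inherits(x, "reversal_analysis"))
  marker <- file.path(out_dir, "summary.json")
  if (file.exists(marker) && !force) {
    stopf("report already exists in '%s'; use force = TRUE to replace it", out_dir)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  payload <- list(summary = x$summary, thresholds = x$thresholds,
                  params = unclass(x$params))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tmp <- paste0(marker, ".tmp")
  writeLines(json, tmp)
  file.rename(tmp, marker)

  write_reversal(x$reversal, x$disease, x$drug_sigs, out_dir)
  write_tsv_atomic(as.data.frame(x$ora), file.path(out_dir, "ora_results.tsv"))
  write_tsv_atomic(x$annotations, file.path(out_dir, "annotations.tsv"))

  comp <- x$clusters$components
  clusters_df <- if (length(comp)) {
    data.frame(component = rep(seq_along(comp), lengths(comp)),
               gene = unlist(comp))
  } else data.frame(component = integer(), gene = character())
  write_tsv_atomic(clusters_df, file.path(out_dir, "clusters.tsv"))

  writeLines(jsonlite::toJSON(unclass(x$enrichment), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             file.path(out_dir, "enrichment.json"))
  if (!is.null(x$graph)) {
    write_graphml(x$graph, x$annotations, file.path(out_dir, "network.graphml"),
                  report = x$clusters)
  }

  rpt <- utils::capture.output(print(x))
  writeLines(rpt, file.path(out_dir, "run_report.txt"))
  invisible(marker)
}
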