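#' Generate a score-weighted protein-protein interaction edge list
#'
#' Produces a STRING-style undirected edge list over all simulated genes.
#' Within each planted module every gene pair is included independently
#' with probability `module_edge_prob` and scored uniformly on
#' \[0.7, 1\] (the "high confidence" band); background edges are sparse
#' random pairs scored uniformly on \[0.15, 0.7), so they vanish at the
#' standard 0.7 cutoff. Scores are quantized to the STRING 0-1000 grid so
#' that writing and re-reading the file is lossless. No self-loops, no
#' duplicate undirected pairs.
#'
#' @param truth a [make_truth()] object.
#' @param params the matching [sim_params()].
#' @param module_edge_prob within-module edge probability.
#' @param background_degree expected background edges per gene.
#' @return a data frame with columns `protein1`, `protein2`,
#'   `combined_score` (numeric in \[0, 1\]).
#' @export
make_ppi_edges <- function(truth, params, module_edge_prob = 0.6,
                           background_degree = 2) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  with_seed(substream_seed(params$seed, 30L), {
    n <- params$n_genes
    ids <- truth$gene_ids

    mod_edges <- lapply(truth$module_members, function(members) {
      pairs <- t(utils::combn(sort(members), 2))
      keep <- stats::runif(nrow(pairs)) < module_edge_prob
      pairs <- pairs[keep, , drop = FALSE]
      data.frame(protein1 = pairs[, 1], protein2 = pairs[, 2],
                 combined_score = stats::runif(nrow(pairs), 0.7, 1),
                 stringsAsFactors = FALSE)
    })
    mod_edges <- do.call(rbind, c(mod_edges, list(NULL)))

    n_bg <- round(background_degree * n)
    i <- sample.int(n, n_bg, replace = TRUE)
    j <- sample.int(n, n_bg, replace = TRUE)
    ok <- i != j
    a <- pmin(i[ok], j[ok]); b <- pmax(i[ok], j[ok])
    bg <- data.frame(protein1 = ids[a], protein2 = ids[b],
                     combined_score = stats::runif(length(a), 0.15, 0.7),
                     stringsAsFactors = FALSE)

    edges <- rbind(mod_edges, bg)
    # quantize to the 0-1000 integer grid (floor keeps background < 0.7)
    edges$combined_score <- floor(edges$combined_score * 1000) / 1000
    key <- paste(edges$protein1, edges$protein2)
    edges <- edges[!duplicated(key), , drop = FALSE]  # module scores take precedence
    rownames(edges) <- NULL
    edges
  })
}

#' Write a STRING-style edge TSV
#'
#' Scores are written on the integer 0-1000 scale used by STRING exports;
#' [read_edges()] detects and rescales them on read.
#'
#' @param edges data frame as returned by [make_ppi_edges()].
#' @param path output path.
#' @export
write_ppi_edges <- function(edges, path) {
  out <- data.frame(protein1 = edges$protein1, protein2 = edges$protein2,
                    combined_score = as.integer(round(edges$combined_score * 1000)))
  write_tsv_atomic(out, path)
}

#' Generate gene-set collection and eQTL list with a planted enrichment
#'
#' Builds a flat gene-set collection in which one set (`SET_PLANTED`)
#' over-samples the genes truly reversed by every drug, alongside uniform
#' decoy sets, and draws a short eQTL gene list biased towards planted
#' module members (mirroring disease-risk genes landing inside the
#' interaction clusters).
#'
#' With `enrichment_factor = Inf` (the default) the planted set is exactly
#' the truly common-reversed genes plus `noise_frac` extra random genes;
#' finite factors sample the set with that relative weight on reversed
#' genes, and factor 1 reduces the planted set to one more decoy.
#'
#' @param truth a [make_truth()] object.
#' @param params the matching [sim_params()].
#' @param n_sets total number of gene sets (planted + decoys).
#' @param set_size_range integer range for decoy set sizes.
#' @param enrichment_factor sampling weight of truly reversed genes in the
#'   planted set; `Inf` plants them all.
#' @param noise_frac fraction of extra random genes mixed into the planted set.
#' @return a list with elements `gene_sets` (a `gene_set_collection`) and
#'   `eqtl` (character vector of gene ids).
#' @export
make_gene_sets_and_eqtl <- function(truth, params, n_sets = 50,
                                    set_size_range = c(20, 200),
                                    enrichment_factor = Inf,
                                    noise_frac = 0.2,
                                    n_eqtl = 3, module_bias = 0.9) {
  stopifnot(inherits(truth, "sim_truth"), inherits(params, "sim_params"))
  with_seed(substream_seed(params$seed, 40L), {
    ids <- truth$gene_ids
    common <- ids[rowSums(truth$true_reversed) == ncol(truth$true_reversed)]

    planted <- if (length(common) == 0) {
      sample(ids, min(set_size_range[2], length(ids)))
    } else if (is.infinite(enrichment_factor)) {
      n_noise <- round(noise_frac * length(common))
      c(common, sample(setdiff(ids, common), n_noise))
    } else {
      s <- max(10L, round(length(common) * (1 + noise_frac)))
      w <- ifelse(ids %in% common, enrichment_factor, 1)
      sample(ids, s, prob = w)
    }

    sets <- vector("list", n_sets)
    sets[[1]] <- sort(unique(planted))
    sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets - 1,
                    replace = TRUE)
    for (k in seq_len(n_sets - 1)) sets[[k + 1]] <- sort(sample(ids, sizes[k]))
    names(sets) <- c("SET_PLANTED",
                     sprintf("SET_DECOY_%03d", seq_len(n_sets - 1)))
    collection <- gene_set_collection(
      sets,
      descriptions = c("planted reversed-gene set",
                       rep("decoy set", n_sets - 1)),
      source = "synthetic")

    mod_pool <- unique(unlist(truth$module_members))
    n_from_mod <- min(stats::rbinom(1, n_eqtl, module_bias), length(mod_pool))
    eqtl <- c(sample(mod_pool, n_from_mod),
              sample(setdiff(ids, mod_pool), n_eqtl - n_from_mod))

    list(gene_sets = collection, eqtl = sort(eqtl))
  })
}

#' Generate and optionally write every pipeline input
#'
#' One call produces the full synthetic study: truth, disease summary
#' table, per-drug count matrices, gene sets, PPI edges and eQTL list.
#' When `dir` is given, all inputs are also written in their on-disk
#' interchange formats (TSV, GMT, plain text, JSON truth).
#'
#' @param params a [sim_params()] object.
#' @param dir optional output directory (created if missing).
#' @param ... passed on to [make_gene_sets_and_eqtl()].
#' @return a list with `params`, `truth`, `disease`, `drug_counts` (named
#'   list of [count_matrix()]), `gene_sets`, `ppi_edges`, `eqtl`, and
#'   `paths` (NULL unless `dir` was given).
#' @examples
#' sim <- simulate_inputs(sim_params(n_genes = 300, seed = 2))
#' names(sim$drug_counts)
#' @export
simulate_inputs <- function(params, dir = NULL, ...) {
  stopifnot(inherits(params, "sim_params"))
  truth <- make_truth(params)
  disease <- make_disease_table(truth, params)
  drug_counts <- lapply(seq_len(params$n_drugs), function(d) {
    make_drug_counts(truth, params, d)
  })
  names(drug_counts) <- params$drug_labels
  anno <- make_gene_sets_and_eqtl(truth, params, ...)
  ppi_edges <- make_ppi_edges(truth, params)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(disease = file.path(dir, "disease_signature.tsv"),
                  gmt = file.path(dir, "gene_sets.gmt"),
                  edges = file.path(dir, "ppi_edges.tsv"),
                  eqtl = file.path(dir, "eqtl_genes.txt"),
                  truth = file.path(dir, "truth.json"))
    write_signature(disease, paths$disease)
    write_gmt(anno$gene_sets, paths$gmt)
    write_ppi_edges(ppi_edges, paths$edges)
    writeLines(anno$eqtl, paths$eqtl)
    for (lab in params$drug_labels) {
      write_count_matrix(drug_counts[[lab]],
                         file.path(dir, sprintf("counts_%s.tsv", lab)),
                         file.path(dir, sprintf("groups_%s.tsv", lab)))
    }
    truth_json <- list(
      disease_direction = as.list(truth$disease_direction),
      drug_direction = as.data.frame(truth$drug_direction),
      module_members = truth$module_members,
      enriched_set_ids = truth$enriched_set_ids)
    writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE, digits = NA),
               paths$truth)
  }

  list(params = params, truth = truth, disease = disease,
       drug_counts = drug_counts, gene_sets = anno$gene_sets,
       ppi_edges = ppi_edges, eqtl = anno$eqtl, paths = paths)
}
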