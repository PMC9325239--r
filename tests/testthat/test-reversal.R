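sig_file <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlogFC\tpvalue\tfdr", rows), f)
  f
}

test_that("load_signature normalizes, deduplicates and validates", {
  f <- sig_file(c("g1\t1.0\t0.1\t0.2", "G1\t-2.0\t0.005\t0.01"))
  sig <- suppressMessages(load_signature(f, label = "dup"))
  expect_equal(nrow(sig), 1)
  expect_equal(sig$gene, "G1")
  expect_equal(sig$logFC, -2.0)

  # empty file with header: empty signature plus a warning
  f2 <- sig_file(character())
  expect_warning(sig2 <- load_signature(f2, label = "empty"), "no rows")
  expect_equal(nrow(sig2), 0)

  # well-formed rows come back in file order
  f3 <- sig_file(c("b\t1\t0.2\t0.3", "a\t-1\t0.1\t0.2", "c\t2\t0.3\t0.4"))
  sig3 <- suppressMessages(load_signature(f3, label = "three"))
  expect_equal(sig3$gene, c("B", "A", "C"))

  # missing required column is named in the error
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tlogFC\tpvalue", "a\t1\t0.1"), f4)
  expect_error(suppressMessages(load_signature(f4, label = "x")), "fdr")

  # unparsable numeric reports the line
  f5 <- sig_file(c("a\t1\t0.1\t0.2", "b\toops\t0.1\t0.2"))
  expect_error(suppressMessages(load_signature(f5, label = "x")), "line 3")

  # dedup tie on q: larger |logFC| wins
  f6 <- sig_file(c("a\t1\t0.1\t0.2", "a\t-3\t0.1\t0.2"))
  sig6 <- suppressMessages(load_signature(f6, label = "tie"))
  expect_equal(sig6$logFC, -3)
})

test_that("reversal rule: doubly significant, strictly opposite sign", {
  d <- de_signature("G1", 1.2, 0.001, 0.05, "disease", 0.1)
  expect_equal(reversed_genes(d, de_signature("G1", -0.5, 0.001, 0.01, "dr")), "G1")
  expect_equal(reversed_genes(d, de_signature("G1", 0.5, 0.001, 0.01, "dr")),
               character(0))

  # exhaustive 6-gene case table covering all four sign combinations
  # (g1..g4) plus one q-failure on each side (g5 disease, g6 drug);
  # only g1 (opposite signs, doubly significant) survives
  genes <- paste0("g", 1:6)
  dis <- de_signature(genes,
                      logFC = c(+1, +1, -1, -1, +1, +1),
                      pvalue = rep(0.001, 6),
                      fdr = c(0.05, 0.05, 0.05, 0.05, 0.5, 0.05),
                      label = "disease", q_threshold = 0.1)
  dru <- de_signature(genes,
                      logFC = c(-1, +1, -1, +1, -1, -1),
                      pvalue = rep(0.001, 6),
                      fdr = c(0.01, 0.01, 0.01, 0.5, 0.01, 0.5),
                      label = "drug", q_threshold = 0.05)
  expect_equal(reversed_genes(dis, dru, 0.1, 0.05), "G1")

  # zero logFC on either side never counts
  dis0 <- de_signature("g9", 0, 0.001, 0.01, "disease")
  dru0 <- de_signature("g9", -2, 0.001, 0.01, "drug")
  expect_equal(reversed_genes(dis0, dru0), character(0))
})

test_that("sign-flip antisymmetry and threshold monotonicity", {
  set.seed(17)
  genes <- sprintf("R%04d", 1:300)
  for (i in 1:200) {
    d <- random_signature(sample(genes, 250), "disease")
    s <- random_signature(sample(genes, 250), "drug")
    s_neg <- de_signature(s$gene, -s$logFC, s$pvalue, s$fdr, "neg")

    rev_set <- reversed_genes(d, s, 0.3, 0.3)
    conc_set <- reversed_genes(d, s, 0.3, 0.3, direction = "concordant")
    expect_identical(reversed_genes(d, s_neg, 0.3, 0.3), conc_set)
    expect_identical(reversed_genes(d, s_neg, 0.3, 0.3, direction = "concordant"),
                     rev_set)
    # their union is the doubly-significant overlap with nonzero sign product
    shared <- intersect(d$gene, s$gene)
    both_sig <- shared[d$fdr[match(shared, d$gene)] <= 0.3 &
                         s$fdr[match(shared, s$gene)] <= 0.3 &
                         d$logFC[match(shared, d$gene)] *
                           s$logFC[match(shared, s$gene)] != 0]
    expect_setequal(union(rev_set, conc_set), both_sig)

    # tightening either threshold never adds genes
    expect_true(all(reversed_genes(d, s, 0.1, 0.3) %in% rev_set))
    expect_true(all(reversed_genes(d, s, 0.3, 0.1) %in% rev_set))
  }

  # with thresholds at 1 the rule reduces to opposite-sign overlap
  set.seed(18)
  d <- random_signature(genes, "disease")
  s <- random_signature(genes, "drug")
  all_opposite <- d$gene[d$logFC * s$logFC[match(d$gene, s$gene)] < 0]
  expect_setequal(reversed_genes(d, s, 1, 1), all_opposite)
})

test_that("intersection accounting: toys and brute-force agreement", {
  r <- intersect_across_drugs(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"),
                                   C = "g3", D = "g3"))
  expect_equal(length(r$union_set), 3)
  expect_equal(r$common_set, "G3")
  expect_equal(r$exclusive_regions[["A"]], 1L)
  expect_equal(r$exclusive_regions[["A&B"]], 1L)
  expect_equal(r$exclusive_regions[["A&B&C&D"]], 1L)
  expect_equal(sum(r$exclusive_regions), 3L)

  k_set <- paste0("x", 1:7)
  r2 <- intersect_across_drugs(list(A = k_set, B = k_set, C = k_set, D = k_set))
  expect_equal(length(r2$exclusive_regions), 1L)
  expect_equal(unname(r2$exclusive_regions[["A&B&C&D"]]), 7L)
  expect_equal(length(r2$common_set), 7L)

  set.seed(23)
  pool <- sprintf("P%04d", 1:1000)
  for (i in 1:100) {
    sets <- lapply(1:4, function(j) sample(pool, 200))
    names(sets) <- LETTERS[1:4]
    res <- intersect_across_drugs(sets)
    # brute force: per-gene membership enumeration
    uni <- sort(unique(unlist(sets)))
    mem <- sapply(sets, function(s) uni %in% s)
    key <- apply(mem, 1, function(m) paste(LETTERS[1:4][m], collapse = "&"))
    brute <- table(key)
    expect_equal(sum(res$exclusive_regions), length(uni))
    expect_identical(res$exclusive_regions[sort(names(res$exclusive_regions))],
                     stats::setNames(as.integer(brute[sort(names(brute))]),
                                     sort(names(brute))))
    for (j in LETTERS[1:4]) {
      with_j <- grepl(j, names(res$exclusive_regions), fixed = TRUE)
      expect_equal(sum(res$exclusive_regions[with_j]), length(unique(sets[[j]])))
    }
    expect_identical(res$common_set, sort(Reduce(intersect, sets)))
  }
})

test_that("upset counts: ordering, totals, multinomial consistency of the truth", {
  r <- intersect_across_drugs(list(A = c("g1", "g2", "g3"), B = c("g2", "g3"),
                                   C = "g3", D = "g3"))
  uc <- upset_counts(r)
  expect_equal(nrow(uc), 3)
  expect_true(all(diff(uc$count) <= 0))
  totals <- attr(uc, "per_drug_totals")
  expect_equal(unname(totals[c("A", "B", "C", "D")]), c(3L, 2L, 1L, 1L))

  single <- upset_counts(intersect_across_drugs(list(only = c("a", "b"))))
  expect_equal(single$count, 2L)

  # truth-level region counts follow the multinomial implied by
  # independent per-drug reversal at probability 0.5
  tr <- make_truth(sim_params(n_genes = 5000, frac_disease_de = 0.3,
                              reversal_prob = 0.5, concordant_prob = 0,
                              seed = 97))
  sets <- lapply(colnames(tr$true_reversed),
                 function(d) rownames(tr$true_reversed)[tr$true_reversed[, d]])
  names(sets) <- colnames(tr$true_reversed)
  res <- intersect_across_drugs(sets)
  regions <- res$exclusive_regions
  degree <- lengths(strsplit(names(regions), "&", fixed = TRUE))
  p_rev <- 0.5
  # P(region of degree d | reversed by >= 1 drug)
  prob_d <- p_rev^degree * (1 - p_rev)^(4 - degree) / (1 - (1 - p_rev)^4)
  chi <- stats::chisq.test(as.integer(regions), p = prob_d, rescale.p = TRUE)
  expect_gt(chi$p.value, 0.001)
})
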