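test_that("cpm follows the counts-per-million formula", {
  m <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(unname(cpm(m)[, 1]), c(500000, 500000))
  m2 <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(unname(cpm(m2)[, 1]), c(3e6 / 10, 7e6 / 10))
  m3 <- matrix(c(0L, 10L), 2, 1, dimnames = list(c("A", "B"), "s1"))
  expect_equal(cpm(m3)["A", 1], 0)

  bad <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
                dimnames = list(c("A", "B"), c("ok", "empty")))
  bad[, 2] <- 0L
  expect_error(cpm(bad), "empty")

  # factors scale the effective library size
  m4 <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(cpm(m4, factors = c(1, 2))[, 2], cpm(m4)[, 2] / 2)
})

test_that("low-expression filter applies strict-fraction and smallest-group rules", {
  # library sizes 2e6 so CPM = counts / 2
  filler <- function(gene_counts) {
    m <- rbind(gene_counts, matrix(0L, 1, length(gene_counts)))
    m[2, ] <- as.integer(2e6 - colSums(m[1, , drop = FALSE]))
    rownames(m) <- c("TARGET", "FILLER")
    colnames(m) <- paste0("s", seq_along(gene_counts))
    m
  }
  # CPM (1.5, 1.5, 0, 0): 2 of 4 samples pass, not > 50% -> dropped
  cm <- toy_counts(filler(c(3L, 3L, 0L, 0L)), rep(c("treated", "vehicle"), each = 2))
  kept <- filter_low_expression(cm, min_cpm = 1, mode = "fraction", threshold = 0.5)
  expect_false("TARGET" %in% rownames(kept$counts))

  # CPM (1.5, 1.5, 1.5, 0.2): 3 of 4 is > 50% -> kept
  cm2 <- toy_counts(filler(c(3L, 3L, 3L, 0L)), rep(c("treated", "vehicle"), each = 2))
  kept2 <- filter_low_expression(cm2, min_cpm = 1, mode = "fraction", threshold = 0.5)
  expect_true("TARGET" %in% rownames(kept2$counts))

  # smallest-group rule: groups of 4 vs 6, CPM >= 1 in exactly 4 samples -> kept
  gc <- c(2L, 2L, 2L, 2L, rep(0L, 6))
  m <- rbind(TARGET = gc, FILLER = as.integer(2e6 - gc))
  colnames(m) <- paste0("s", 1:10)
  cm3 <- count_matrix(m, rep(c("treated", "vehicle"), c(4, 6)), "toy")
  kept3 <- filter_low_expression(cm3, min_cpm = 1, mode = "smallest_group")
  expect_true("TARGET" %in% rownames(kept3$counts))
  # and with only 3 samples passing -> dropped
  gc4 <- c(2L, 2L, 2L, 0L, rep(0L, 6))
  m4 <- rbind(TARGET = gc4, FILLER = as.integer(2e6 - gc4))
  colnames(m4) <- paste0("s", 1:10)
  cm4 <- count_matrix(m4, rep(c("treated", "vehicle"), c(4, 6)), "toy")
  expect_false("TARGET" %in%
                 rownames(filter_low_expression(cm4, mode = "smallest_group")$counts))

  # fraction mode requires a threshold
  expect_error(filter_low_expression(cm, mode = "fraction"), "threshold")

  # idempotence on random data, both modes
  set.seed(8)
  rnd <- toy_counts(matrix(rnbinom(400 * 8, mu = 3, size = 1), 400, 8),
                    rep(c("treated", "vehicle"), each = 4))
  for (args in list(list(mode = "smallest_group"),
                    list(mode = "fraction", threshold = 0.5))) {
    once <- do.call(filter_low_expression, c(list(rnd), args))
    twice <- do.call(filter_low_expression, c(list(once), args))
    expect_identical(twice$counts, once$counts)
  }
})

test_that("TMM factors: identity, scaling invariance, composition bias, edgeR agreement", {
  set.seed(11)
  base <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200, 4,
                 dimnames = list(sprintf("G%03d", 1:200), paste0("s", 1:4)))
  groups <- rep(c("treated", "vehicle"), each = 2)

  same <- base; same[, 2:4] <- same[, 1]
  expect_equal(unname(tmm_factors(toy_counts(same, groups))), rep(1, 4))

  doubled <- cbind(s1 = base[, 1], s2 = 2L * base[, 1])
  cm2 <- count_matrix(doubled, c("treated", "vehicle"), "toy")
  expect_equal(unname(tmm_factors(cm2)), c(1, 1))

  # one gene consuming half of sample B's reads depresses B's factor
  a <- rep(100L, 20); b <- rep(100L, 20)
  b[1] <- sum(b[-1])  # gene 1 = 50% of B's library
  comp <- cbind(A = a, B = b)
  rownames(comp) <- sprintf("G%02d", 1:20)
  f <- tmm_factors(count_matrix(comp, c("treated", "vehicle"), "toy"),
                   ref_sample = "A")
  expect_lt(f[["B"]], 1)
  expect_gt(f[["A"]], 1)

  # direct evaluation of the doubly-trimmed weighted mean on that instance,
  # written out step by step (sort-based trimming)
  nA <- sum(a); nB <- sum(b)
  M <- log2((b / nB) / (a / nA))
  A_ <- (log2(b / nB) + log2(a / nA)) / 2
  w <- (nB - b) / (nB * b) + (nA - a) / (nA * a)
  n <- length(M)
  keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
  keepA <- rank(A_) >= floor(n * 0.05) + 1 & rank(A_) <= n - floor(n * 0.05)
  fB_raw <- 2^(sum((M / w)[keepM & keepA]) / sum((1 / w)[keepM & keepA]))
  fA_raw <- 1  # A against itself
  geo <- sqrt(fA_raw * fB_raw)
  expect_lt(abs(f[["B"]] - fB_raw / geo), 1e-9)
  expect_lt(abs(f[["A"]] - fA_raw / geo), 1e-9)

  # permuting samples permutes factors
  cm <- toy_counts(base, groups)
  f0 <- tmm_factors(cm)
  perm <- c(3, 1, 4, 2)
  cmp <- count_matrix(base[, perm], groups[perm], "toy")
  expect_equal(unname(tmm_factors(cmp)), unname(f0[perm]))

  # agreement with the reference implementation on random matrices
  for (s in 1:5) {
    set.seed(100 + s)
    x <- matrix(rnbinom(500 * 6, mu = exp(rnorm(500, 4, 1)), size = 5), 500, 6,
                dimnames = list(sprintf("G%03d", 1:500), paste0("s", 1:6)))
    x <- x[rowSums(x) > 0, ]
    mine <- tmm_factors(count_matrix(x, rep(c("treated", "vehicle"), each = 3), "x"))
    ref <- edgeR::calcNormFactors(x, method = "TMM")
    expect_equal(unname(mine), unname(ref), tolerance = 1e-8)
  }
})

test_that("Welch DE: null genes, label symmetry, degenerate variance, effect recovery", {
  set.seed(21)
  m <- matrix(rnbinom(300 * 10, mu = 200, size = 20), 300, 10,
              dimnames = list(sprintf("G%03d", 1:300), paste0("s", 1:10)))
  m[1, ] <- rep(c(50L, 80L, 120L, 90L, 60L), 2)  # identical across groups
  groups <- rep(c("treated", "vehicle"), each = 5)
  # equalize libraries so the pseudo-count normalization cancels exactly
  cs <- colSums(m)
  m[300, ] <- m[300, ] + as.integer(max(cs) - cs)
  cm <- toy_counts(m, groups)
  sig <- de_welch(cm)
  expect_equal(sig$logFC[1], 0)
  expect_equal(sig$pvalue[1], 1)

  # swapping group labels negates logFC and keeps p
  cm_sw <- count_matrix(m, rev(groups), "toy")
  sig_sw <- de_welch(cm_sw)
  expect_equal(sig_sw$logFC, -sig$logFC)
  expect_equal(sig_sw$pvalue, sig$pvalue)

  # zero variance with nonzero difference is flagged at the smallest p
  m2 <- m
  m2[2, groups == "treated"] <- 100L
  m2[2, groups == "vehicle"] <- 400L
  cs2 <- colSums(m2); m2[300, ] <- m2[300, ] + as.integer(max(cs2) - cs2)
  expect_warning(sig2 <- de_welch(toy_counts(m2, groups)), "zero within-group")
  expect_equal(sig2$pvalue[2], .Machine$double.xmin)
  expect_true("G002" %in% attr(sig2, "degenerate"))

  # planted 2-fold change, n = 5 per group: median logFC within 0.2 of 1
  set.seed(22)
  n <- 2000; r <- 5
  mu <- exp(rnorm(n, 5, 1))
  fold <- rep(1, n); planted <- 1:150; fold[planted] <- 2
  cnt <- cbind(matrix(rnbinom(n * r, mu = rep(mu * fold, r), size = 100), n, r),
               matrix(rnbinom(n * r, mu = rep(mu, r), size = 100), n, r))
  dimnames(cnt) <- list(sprintf("G%04d", 1:n), paste0("s", 1:(2 * r)))
  cmx <- count_matrix(cnt, rep(c("treated", "vehicle"), each = r), "fold2")
  sigx <- de_welch(cmx, tmm_factors(cmx))
  est <- sigx$logFC[match(sprintf("G%04d", planted), sigx$gene)]
  expect_lt(abs(stats::median(est) - 1), 0.2)
})

test_that("Welch test keeps its type-I error on null counts", {
  set.seed(99)
  n <- 20000; r <- 6
  mu <- exp(rnorm(n, 5, 1.5))
  cnt <- matrix(rnbinom(n * 2 * r, mu = rep(mu, 2 * r), size = 100), n, 2 * r)
  dimnames(cnt) <- list(sprintf("G%05d", 1:n), paste0("s", 1:(2 * r)))
  cm <- count_matrix(cnt, rep(c("treated", "vehicle"), each = r), "null")
  f <- filter_low_expression(cm)
  sig <- de_welch(f, tmm_factors(f))
  expect_gt(nrow(sig), 10000)
  expect_lt(abs(mean(sig$pvalue < 0.05) - 0.05), 0.01)
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  # monotone in p-rank
  set.seed(3)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))

  # independent step-up oracle on random vectors
  for (s in 1:200) {
    set.seed(s)
    p <- runif(sample(5:80, 1))
    expect_lt(max(abs(bh_adjust(p) - bh_stepup_oracle(p))), 1e-12)
  }
})
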