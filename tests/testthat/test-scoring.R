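test_that("sgRNA enrichment does forced arithmetic and depth normalisation", {
  # equal tail frequencies -> 0
  cts <- counts_table(c("a", "b"), c("g1", NON_TARGETING),
                      rep1_high = c(100, 300), rep1_low = c(100, 300))
  expect_equal(sgrna_enrichment(cts, pseudocount = 0)$enrichment, c(0, 0))
  # high=200, low=50 at equal totals, pc=0 -> exactly 2
  cts <- counts_table(c("a", "b"), c("g1", NON_TARGETING),
                      rep1_high = c(200, 50), rep1_low = c(50, 200))
  expect_equal(sgrna_enrichment(cts, pseudocount = 0)$enrichment, c(2, -2))
  # unequal depth is normalised away: doubling one sample's counts is a no-op
  cts2 <- counts_table(c("a", "b"), c("g1", NON_TARGETING),
                       rep1_high = c(400, 100), rep1_low = c(50, 200))
  expect_equal(sgrna_enrichment(cts2, pseudocount = 0)$enrichment, c(2, -2))
})

test_that("zero counts demand a positive pseudocount", {
  cts <- counts_table("a", "g1", rep1_high = 0, rep1_low = 5)
  expect_error(sgrna_enrichment(cts, pseudocount = 0), "pseudocount")
  expect_silent(sgrna_enrichment(cts, pseudocount = 1))
})

test_that("gene score averages the top three sgRNAs ranked by magnitude", {
  brute <- function(x, n = 3) mean(x[order(abs(x), decreasing = TRUE)][1:n])
  cases <- list(c(3.0, 2.8, 2.5, 0.2, -0.1),
                c(-3.0, 2.9, -2.8, 0.1, 0.0),
                c(2, 2, 2, 2, 2))
  for (x in cases) expect_equal(gene_score(x), brute(x))
  expect_equal(gene_score(c(3.0, 2.8, 2.5, 0.2, -0.1)), 2.766667,
               tolerance = 1e-6)
  expect_equal(gene_score(c(-3.0, 2.9, -2.8, 0.1, 0.0)), -0.966667,
               tolerance = 1e-6)
  # signed ranking variant and the unscorable case
  expect_equal(gene_score(c(-3, 2.9, -2.8, 0.1, 0), rank_by = "signed"), 1)
  expect_true(is.na(gene_score(c(1, 2))))
})

test_that("exact Mann-Whitney p matches full enumeration on interleaved ranks", {
  # gene scores at alternating ranks 2, 5, 8 of 9 pooled values
  pooled <- as.numeric(1:9)
  x <- pooled[c(2, 5, 8)]
  y <- pooled[-c(2, 5, 8)]
  # brute-force oracle over all choose(9, 3) assignments
  u_obs <- sum(rank(c(x, y))[1:3]) - 6
  us <- apply(combn(9, 3), 2, function(ix) sum(ix) - 6)
  p_oracle <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
  expect_equal(gene_pvalue(x, y), p_oracle, tolerance = 1e-12)
  expect_gte(gene_pvalue(x, y), 0.9)
})

test_that("normal-approximation p matches the closed-form U moments at maximal U", {
  null_scores <- rnorm(1895)
  gene_scores <- max(null_scores) + 1:5
  u <- 5 * 1895
  z <- (u - 5 * 1895 / 2) / sqrt(5 * 1895 * (5 + 1895 + 1) / 12)
  expect_equal(z, 3.87, tolerance = 1e-3)
  p_closed <- 2 * pnorm(-z)
  expect_equal(gene_pvalue(gene_scores, null_scores), p_closed,
               tolerance = 1e-12)
  expect_equal(p_closed, 1.1e-4, tolerance = 0.01)
})

test_that("rank-based p is invariant under common monotone transforms", {
  set.seed(21)
  x <- rnorm(5); y <- rnorm(200)
  p0 <- gene_pvalue(x, y)
  for (f in list(function(v) exp(v), function(v) atan(v),
                 function(v) 3 * v + 7)) {
    expect_equal(gene_pvalue(f(x), f(y)), p0, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks exact enumeration for small null sets", {
  # the exact U distribution at n1 = 5 is a coarse lattice, so the relative
  # error of the normal approximation is assessed distributionally
  set.seed(31)
  rel_err <- numeric(50)
  for (i in 1:50) {
    x <- rnorm(5); y <- rnorm(60)
    p_exact <- gene_pvalue(x, y, exact_max = 1e6)
    p_norm <- gene_pvalue(x, y, exact_max = 0)
    rel_err[i] <- abs(p_norm - p_exact) / p_exact
    # independent oracle for the exact branch
    p_ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)$p.value
    expect_equal(p_exact, p_ref, tolerance = 1e-12)
  }
  expect_lt(median(rel_err), 0.05)
  expect_gte(mean(rel_err < 0.10), 0.9)
  expect_lt(max(rel_err), 0.20)
})

test_that("Fisher combination matches its closed-form chi-square survival", {
  expect_equal(combine_replicates(c(1, 1))$p_combined, 1)
  x <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(combine_replicates(c(0.05, 0.05))$p_combined,
               exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(combine_replicates(c(0.05, 0.05))$p_combined, 0.0174,
               tolerance = 5e-3)
  expect_equal(combine_replicates(0.3)$p_combined, 0.3, tolerance = 1e-12)
  expect_equal(combine_replicates(c(0.2, 0.8), c(1, 3))$enrichment, 2)
  expect_error(combine_replicates(c(0, 0.5)), "0, 1")
})

test_that("quasi-gene grouping partitions the non-targeting set", {
  lib <- make_library(3, 5, 1895)
  q <- make_quasi_genes(lib, group_size = 5, seed = 9)
  expect_equal(length(unique(q$gene)), 379)
  expect_equal(nrow(q), 1895)
  expect_false(anyDuplicated(q$sgRNA_id) > 0)
  expect_true(all(q$sgRNA_id %in% lib$sgRNA_id[is_nontargeting(lib)]))
  expect_identical(q, make_quasi_genes(lib, group_size = 5, seed = 9))
  expect_false(identical(q, make_quasi_genes(lib, group_size = 5, seed = 10)))
  expect_error(make_quasi_genes(make_library(1, 5, 3), group_size = 5),
               "non-targeting")
})

test_that("hit calling applies the strict quasi-gene threshold with directions", {
  genes <- data.frame(gene = c("g1", "g2", "g3"), score = c(2, 0.1, -1.5),
                      product = c(5.0, 0.4, -3.0), stringsAsFactors = FALSE)
  quasi <- data.frame(gene = "q1", score = 0.5, product = 1.2,
                      stringsAsFactors = FALSE)
  h <- call_hits(genes, quasi)
  expect_equal(h$threshold, 1.2)
  expect_equal(h$n_enriched, 1)
  expect_equal(h$n_depleted, 1)
  expect_equal(h$genes$hit, c(TRUE, FALSE, TRUE))
  expect_error(call_hits(genes, quasi[0, ]), "quasi")
})

test_that("exchanging tails negates enrichments and leaves p-values unchanged", {
  lib <- make_library(6, 5, 40)
  cts <- simulate_screen(lib, NULL, default_calibration(),
                         screen_design(coverage = 40, seed = 33))
  swapped <- cts
  for (r in 1:2) {
    hi <- sprintf("rep%d_high", r); lo <- sprintf("rep%d_low", r)
    swapped[[hi]] <- cts[[lo]]; swapped[[lo]] <- cts[[hi]]
  }
  a <- score_screen(cts, lib, seed = 5)
  b <- score_screen(swapped, lib, seed = 5)
  expect_equal(b$genes$score, -a$genes$score, tolerance = 1e-12)
  expect_equal(b$genes$p_combined, a$genes$p_combined, tolerance = 1e-12)
  expect_equal(b$threshold, a$threshold, tolerance = 1e-12)
})

test_that("low-count sgRNAs can be floored out, making sparse genes unscorable", {
  lib <- make_library(2, 5, 10)
  n <- nrow(lib)
  set.seed(4)
  cts <- counts_table(lib$sgRNA_id, lib$gene,
                      rep1_high = rpois(n, 50), rep1_low = rpois(n, 50))
  # starve three sgRNAs of gene_0001
  starved <- lib$sgRNA_id[1:3]
  cts[cts$sgRNA_id %in% starved, c("rep1_high", "rep1_low")] <- 0L
  res <- score_screen(cts, lib, min_total = 5, quasi_size = 5)
  expect_true("gene_0001" %in% res$unscorable)
  expect_false("gene_0002" %in% res$unscorable)
})

test_that("FASTQ protospacer counting is exact-match with indexed errors", {
  lib <- as_sgrna_library(data.frame(
    sgRNA_id = c("sg1", "sg2"), gene = c("g1", NON_TARGETING)))
  spacers <- c(sg1 = "ACGTACGTACGT", sg2 = "TTTTGGGGCCCC")
  fq <- tempfile(fileext = ".fastq")

  writeLines(character(0), fq)
  empty <- count_sgrnas_from_fastq(fq, lib, spacers)
  expect_equal(unname(empty$counts), c(0L, 0L))
  expect_equal(empty$unmatched, 0L)

  rec <- function(seq) c("@r", seq, "+", strrep("I", nchar(seq)))
  writeLines(c(rep(rec("ACGTACGTACGT"), 100), rec("ACGTACGTACGA")), fq)
  res <- count_sgrnas_from_fastq(fq, lib, spacers)
  expect_equal(unname(res$counts["sg1"]), 100L)   # one-mismatch read excluded
  expect_equal(res$unmatched, 1L)

  writeLines(c("@r", "ACGT", "+"), fq)
  expect_error(count_sgrnas_from_fastq(fq, lib, spacers), "record 1")
  writeLines(c("xr", "ACGT", "+", "IIII"), fq)
  expect_error(count_sgrnas_from_fastq(fq, lib, spacers), "record 1")
})
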