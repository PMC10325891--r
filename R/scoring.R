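#' Per-sgRNA log2 tail enrichment
#'
#' For each replicate, each sgRNA's high-tail and low-tail read counts are
#' pseudocounted, normalised to sample frequencies (so unequal sequencing
#' depths cancel), and log2-ratioed:
#' `log2( ((high + pc)/high_total) / ((low + pc)/low_total) )` with totals
#' taken after pseudocounting. At equal depth this reduces to the plain
#' log2 count ratio. Replicate scores are arithmetically averaged.
#'
#' @param counts a `screen_counts` data.frame (columns `sgRNA_id`, `gene`,
#'   `rep<k>_high`, `rep<k>_low`).
#' @param pseudocount nonnegative pseudocount; must be positive if any count
#'   is zero.
#' @return a data.frame with `sgRNA_id`, `gene`, one `enrichment_rep<k>`
#'   column per replicate, and the replicate-averaged `enrichment`.
#' @export
sgrna_enrichment <- function(counts, pseudocount = 1) {
  stopifnot(is.data.frame(counts), pseudocount >= 0)
  high_cols <- grep("^rep[0-9]+_high$", names(counts), value = TRUE)
  low_cols <- sub("high$", "low", high_cols)
  if (length(high_cols) == 0 || !all(low_cols %in% names(counts)))
    stop("counts must contain paired rep<k>_high / rep<k>_low columns")
  cts <- as.matrix(counts[c(high_cols, low_cols)])
  if (any(cts < 0) || any(cts != floor(cts)))
    stop("counts must be nonnegative integers")
  if (pseudocount == 0 && any(cts == 0))
    stop("zero counts present: use a positive pseudocount")

  out <- data.frame(sgRNA_id = counts$sgRNA_id, gene = counts$gene,
                    stringsAsFactors = FALSE)
  reps <- sub("_high$", "", high_cols)
  for (i in seq_along(high_cols)) {
    hi <- counts[[high_cols[i]]] + pseudocount
    lo <- counts[[low_cols[i]]] + pseudocount
    # difference-of-logs form: exactly antisymmetric under tail exchange
    out[[paste0("enrichment_", reps[i])]] <-
      log2(hi / sum(hi)) - log2(lo / sum(lo))
  }
  enr_cols <- paste0("enrichment_", reps)
  out$enrichment <- rowMeans(out[, enr_cols, drop = FALSE])
  out
}

#' Gene-level enrichment score
#'
#' Ranks a gene's sgRNAs by the magnitude of their (replicate-averaged)
#' enrichment and returns the signed arithmetic mean of the top three, so a
#' gene is summarised by its most active sgRNAs in either direction.
#'
#' @param scores numeric vector of per-sgRNA enrichment scores for one gene.
#' @param n_top number of top sgRNAs averaged (default 3).
#' @param rank_by `"absolute"` (default: rank by `|score|`, average with
#'   signs retained) or `"signed"`.
#' @return the gene score, or `NA` (unscorable) for fewer than `n_top`
#'   sgRNAs.
#' @export
gene_score <- function(scores, n_top = 3, rank_by = c("absolute", "signed")) {
  rank_by <- match.arg(rank_by)
  scores <- scores[!is.na(scores)]
  if (length(scores) < n_top) return(NA_real_)
  ord <- if (rank_by == "absolute") order(abs(scores), decreasing = TRUE)
         else order(scores, decreasing = TRUE)
  mean(scores[ord[seq_len(n_top)]])
}

#' Two-sided Mann-Whitney p-value against a null score set
#'
#' Rank-sum comparison of a gene's sgRNA scores to the non-targeting null
#' distribution. Small problems without ties use the exact U distribution;
#' otherwise the tie-corrected normal approximation
#' `z = (U - n1*n2/2) / sd(U)` is used without continuity correction.
#'
#' @param gene_scores numeric vector (>= 1 value).
#' @param null_scores numeric vector (>= 2 values) of non-targeting scores.
#' @param exact_max use exact enumeration when `n1 * n2 <= exact_max` and no
#'   ties are present.
#' @return two-sided p-value in `(0, 1]`.
#' @export
gene_pvalue <- function(gene_scores, null_scores, exact_max = 2000) {
  n1 <- length(gene_scores); n2 <- length(null_scores)
  if (n1 < 1) stop("need at least one gene score")
  if (n2 < 2) stop("need at least two non-targeting scores")
  all_scores <- c(gene_scores, null_scores)
  r <- rank(all_scores)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(all_scores)
  has_ties <- any(ties > 1)

  if (!has_ties && n1 * n2 <= exact_max) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Combine replicate p-values and enrichments
#'
#' Fisher's combined probability test across replicates
#' (`-2 * sum(log p)` against chi-square with `2k` df) together with the
#' arithmetic mean of the replicate enrichment scores.
#'
#' @param p_values numeric vector of per-replicate p-values in `(0, 1]`.
#' @param enrichments numeric vector of per-replicate enrichment scores
#'   (same length, optional).
#' @return list with `p_combined` and `enrichment` (mean; `NA` if
#'   enrichments not supplied).
#' @export
combine_replicates <- function(p_values, enrichments = NULL) {
  if (any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stat <- -2 * sum(log(p_values))
  p_comb <- stats::pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
  list(p_combined = p_comb,
       enrichment = if (is.null(enrichments)) NA_real_ else mean(enrichments))
}

#' Group non-targeting sgRNAs into quasi-genes
#'
#' Partitions the non-targeting controls into disjoint pseudo-genes of
#' `group_size` sgRNAs by a seeded shuffle (remainder dropped). Scored
#' identically to real genes, the quasi-genes provide the empirical null for
#' the hit threshold.
#'
#' @param library an `sgrna_library`.
#' @param group_size sgRNAs per quasi-gene (default 5).
#' @param seed shuffle seed.
#' @return a data.frame with columns `sgRNA_id` and `gene`
#'   (`quasi_0001`, ...).
#' @export
make_quasi_genes <- function(library, group_size = 5, seed = 1) {
  library <- as_sgrna_library(library)
  nt <- library$sgRNA_id[is_nontargeting(library)]
  if (length(nt) < group_size)
    stop(sprintf("need at least %d non-targeting sgRNAs, have %d",
                 group_size, length(nt)))
  set.seed(as.integer(seed) %% 2147483647L)
  nt <- sample(nt)
  n_groups <- length(nt) %/% group_size
  kept <- nt[seq_len(n_groups * group_size)]
  data.frame(sgRNA_id = kept,
             gene = rep(sprintf("quasi_%04d", seq_len(n_groups)),
                        each = group_size),
             stringsAsFactors = FALSE)
}

# score one gene group: top-n mean, per-replicate MW p vs the null scores,
# Fisher combination, product statistic
score_gene_group <- function(enr_rows, enr_cols, null_by_rep, n_top, rank_by,
                             exact_max) {
  score <- gene_score(enr_rows$enrichment, n_top = n_top, rank_by = rank_by)
  if (is.na(score))
    return(list(score = NA_real_, p_reps = NA_real_, p_combined = NA_real_,
                product = NA_real_))
  p_reps <- vapply(seq_along(enr_cols), function(i)
    gene_pvalue(enr_rows[[enr_cols[i]]], null_by_rep[[i]],
                exact_max = exact_max), 0)
  p_comb <- combine_replicates(p_reps)$p_combined
  list(score = score, p_reps = p_reps, p_combined = p_comb,
       product = score * -log10(p_comb))
}

#' Call screen hits against the quasi-gene threshold
#'
#' The hit threshold is the maximum `|product statistic|` over quasi-genes
#' (the product statistic is `enrichment * -log10(combined p)`); a gene is a
#' hit iff its `|product|` strictly exceeds that threshold, so by
#' construction no quasi-gene is ever called. Direction is the sign of the
#' averaged enrichment.
#'
#' @param gene_results data.frame with columns `gene`, `score`, `product`.
#' @param quasi_results like `gene_results` but for quasi-genes (non-empty).
#' @return a list with the augmented `genes` table (`hit`, `direction`),
#'   `threshold`, `n_enriched` and `n_depleted`.
#' @export
call_hits <- function(gene_results, quasi_results) {
  if (nrow(quasi_results) == 0 || all(is.na(quasi_results$product)))
    stop("empty quasi-gene set: threshold undefined")
  threshold <- max(abs(quasi_results$product), na.rm = TRUE)
  g <- gene_results
  g$hit <- !is.na(g$product) & abs(g$product) > threshold
  g$direction <- ifelse(is.na(g$score), NA_character_,
                        ifelse(g$score > 0, "enriched", "depleted"))
  list(genes = g, threshold = threshold,
       n_enriched = sum(g$hit & g$direction == "enriched", na.rm = TRUE),
       n_depleted = sum(g$hit & g$direction == "depleted", na.rm = TRUE))
}

#' Score a tail-sorted CRISPRi screen end to end
#'
#' Runs the full gene-scoring pipeline: per-sgRNA log2 tail enrichment
#' (pseudocounted, depth-normalised), per-gene top-3 mean enrichment,
#' per-replicate Mann-Whitney p-values of each gene's sgRNAs against the
#' non-targeting null, Fisher combination across replicates, quasi-gene
#' scoring of randomly grouped non-targeting controls, and hit calling
#' against the empirical quasi-gene threshold.
#'
#' @param counts a `screen_counts` table.
#' @param library the matching `sgrna_library`.
#' @param pseudocount pseudocount for enrichment (default 1).
#' @param quasi_size quasi-gene group size (default 5).
#' @param seed seed for the quasi-gene shuffle.
#' @param n_top sgRNAs averaged into the gene score (default 3).
#' @param rank_by top-sgRNA ranking rule, `"absolute"` or `"signed"`.
#' @param min_total drop sgRNAs whose summed counts across all samples fall
#'   below this floor (default 0 = keep all).
#' @param exact_max see [gene_pvalue()].
#' @return an object of class `screen_result`: list with `sgrnas`, `genes`,
#'   `quasi`, `threshold`, `n_enriched`, `n_depleted`, `unscorable` and the
#'   call parameters.
#' @export
score_screen <- function(counts, library, pseudocount = 1, quasi_size = 5,
                         seed = 1, n_top = 3,
                         rank_by = c("absolute", "signed"), min_total = 0,
                         exact_max = 2000) {
  rank_by <- match.arg(rank_by)
  library <- as_sgrna_library(library)
  missing_sg <- setdiff(counts$sgRNA_id, library$sgRNA_id)
  if (length(missing_sg))
    stop("counts contain sgRNAs absent from the library: ",
         paste(utils::head(missing_sg, 5), collapse = ", "))

  if (min_total > 0) {
    cts <- as.matrix(counts[grep("^rep[0-9]+_(high|low)$", names(counts))])
    counts <- counts[rowSums(cts) >= min_total, , drop = FALSE]
  }
  enr <- sgrna_enrichment(counts, pseudocount = pseudocount)
  enr_cols <- grep("^enrichment_rep", names(enr), value = TRUE)

  nt_mask <- enr$gene == NON_TARGETING
  if (sum(nt_mask) < 2)
    stop("need at least two scored non-targeting sgRNAs")

  score_groups <- function(groups) {
    ids <- unique(groups$gene)
    rows <- lapply(ids, function(g) {
      members <- groups$sgRNA_id[groups$gene == g]
      sub <- enr[enr$sgRNA_id %in% members, , drop = FALSE]
      # a group's own sgRNAs never enter its null (quasi-genes are built
      # from non-targeting sgRNAs and must be scored like real genes)
      null_mask <- nt_mask & !(enr$sgRNA_id %in% members)
      null_by_rep <- lapply(enr_cols, function(cl) enr[[cl]][null_mask])
      res <- score_gene_group(sub, enr_cols, null_by_rep, n_top, rank_by,
                              exact_max)
      out <- data.frame(gene = g, n_sgrnas = nrow(sub), score = res$score,
                        stringsAsFactors = FALSE)
      for (i in seq_along(enr_cols))
        out[[sub("enrichment_", "p_", enr_cols[i])]] <- res$p_reps[i]
      out$p_combined <- res$p_combined
      out$product <- res$product
      out
    })
    do.call(rbind, rows)
  }

  gene_tab <- score_groups(enr[!nt_mask, c("sgRNA_id", "gene")])
  quasi_tab <- score_groups(make_quasi_genes(library, group_size = quasi_size,
                                             seed = seed))
  hits <- call_hits(gene_tab, quasi_tab)

  structure(list(sgrnas = enr, genes = hits$genes, quasi = quasi_tab,
                 threshold = hits$threshold, n_enriched = hits$n_enriched,
                 n_depleted = hits$n_depleted,
                 unscorable = gene_tab$gene[is.na(gene_tab$score)],
                 params = list(pseudocount = pseudocount,
                               quasi_size = quasi_size, seed = seed,
                               n_top = n_top, rank_by = rank_by,
                               min_total = min_total)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result>\n")
  cat(sprintf("  genes scored : %d (%d unscorable)\n",
              nrow(x$genes), length(x$unscorable)))
  cat(sprintf("  quasi-genes  : %d, |product| threshold = %.4f\n",
              nrow(x$quasi), x$threshold))
  cat(sprintf("  hits         : %d enriched, %d depleted\n",
              x$n_enriched, x$n_depleted))
  invisible(x)
}

#' Count sgRNA protospacers in a FASTQ file by exact matching
#'
#' Extracts the protospacer substring from each read (fixed offset and
#' length) and exact-matches it against the library protospacers; reads with
#' no exact match are tallied as unmatched. Records must be 4-line FASTQ;
#' a malformed record is reported with its index.
#'
#' @param path FASTQ file path (uncompressed).
#' @param library an `sgrna_library`.
#' @param protospacers named character vector mapping `sgRNA_id` to
#'   protospacer sequence; defaults to using the sgRNA ids themselves.
#' @param offset 0-based offset of the protospacer within the read.
#' @param length protospacer length; defaults to the (common) protospacer
#'   length.
#' @return list with `counts` (named integer vector along the library) and
#'   `unmatched` (count of unassigned reads).
#' @export
count_sgrnas_from_fastq <- function(path, library, protospacers = NULL,
                                    offset = 0, length = NULL) {
  library <- as_sgrna_library(library)
  if (is.null(protospacers)) {
    protospacers <- library$sgRNA_id
    names(protospacers) <- library$sgRNA_id
  }
  if (!all(library$sgRNA_id %in% names(protospacers)))
    stop("protospacers must cover every library sgRNA")
  protospacers <- protospacers[library$sgRNA_id]
  if (anyDuplicated(protospacers))
    stop("duplicate protospacer sequences in library")
  if (is.null(length)) length <- nchar(protospacers[1])

  lines <- readLines(path)
  if (base::length(lines) %% 4 != 0)
    stop(sprintf("malformed FASTQ: truncated record %d",
                 base::length(lines) %/% 4 + 1))
  n_rec <- base::length(lines) %/% 4
  counts <- integer(nrow(library))
  names(counts) <- library$sgRNA_id
  if (n_rec == 0) return(list(counts = counts, unmatched = 0L))

  hdr <- lines[seq(1, by = 4, length.out = n_rec)]
  sep <- lines[seq(3, by = 4, length.out = n_rec)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (base::length(bad))
    stop(sprintf("malformed FASTQ record %d (missing @/+ markers)", bad[1]))
  seqs <- lines[seq(2, by = 4, length.out = n_rec)]
  quals <- lines[seq(4, by = 4, length.out = n_rec)]
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (base::length(bad_len))
    stop(sprintf("malformed FASTQ record %d (sequence/quality length mismatch)",
                 bad_len[1]))

  spacers <- substr(seqs, offset + 1, offset + length)
  idx <- match(spacers, protospacers)
  tab <- table(factor(names(protospacers)[idx], levels = library$sgRNA_id))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, unmatched = sum(is.na(idx)))
}
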