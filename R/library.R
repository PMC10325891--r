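#' Label used for non-targeting control sgRNAs in the `gene` column
#' @export
NON_TARGETING <- "non-targeting"

#' Validate an sgRNA library table
#'
#' An sgRNA library maps sgRNA identifiers to target genes; non-targeting
#' negative controls carry the gene label [NON_TARGETING]. The table is the
#' sampling frame for every screen statistic.
#'
#' @param x a data.frame with character columns `sgRNA_id` and `gene`.
#' @return the validated data.frame, classed `sgrna_library`.
#' @export
as_sgrna_library <- function(x) {
  stopifnot(is.data.frame(x), all(c("sgRNA_id", "gene") %in% names(x)))
  x$sgRNA_id <- as.character(x$sgRNA_id)
  x$gene <- as.character(x$gene)
  if (anyDuplicated(x$sgRNA_id))
    stop("duplicate sgRNA_id in library: ",
         paste(unique(x$sgRNA_id[duplicated(x$sgRNA_id)]), collapse = ", "))
  if (any(is.na(x$sgRNA_id)) || any(is.na(x$gene)))
    stop("library contains missing sgRNA_id or gene values")
  class(x) <- c("sgrna_library", "data.frame")
  x
}

#' Build a synthetic sgRNA library
#'
#' Mirrors the structure of a compact genome-wide CRISPRi library: a fixed
#' number of sgRNAs per targeting gene plus a large panel of non-targeting
#' controls.
#'
#' @param n_genes number of targeting genes (`gene_0001`, ...).
#' @param sgrnas_per_gene sgRNAs per gene (default 5).
#' @param n_nontargeting number of non-targeting control sgRNAs
#'   (default 1895).
#' @return an `sgrna_library` data.frame.
#' @export
make_library <- function(n_genes, sgrnas_per_gene = 5, n_nontargeting = 1895) {
  stopifnot(n_genes >= 0, sgrnas_per_gene >= 1, n_nontargeting >= 0)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  gene_rep <- rep(genes, each = sgrnas_per_gene)
  tg <- data.frame(
    sgRNA_id = if (n_genes > 0)
      paste0(gene_rep, "_sg", rep(seq_len(sgrnas_per_gene), times = n_genes))
    else character(0),
    gene = gene_rep,
    stringsAsFactors = FALSE)
  nt <- data.frame(
    sgRNA_id = sprintf("non_targeting_%04d", seq_len(n_nontargeting)),
    gene = rep(NON_TARGETING, n_nontargeting),
    stringsAsFactors = FALSE)
  as_sgrna_library(rbind(tg, nt))
}

#' Is an sgRNA (row) non-targeting?
#' @param library an `sgrna_library`.
#' @return logical vector along the library rows.
#' @export
is_nontargeting <- function(library) library$gene == NON_TARGETING

#' Per-sgRNA perturbation effects
#'
#' Builds the per-sgRNA effect table used by the simulator: a multiplicative
#' fold-change on the near-cognate GFP initiation term, a multiplicative
#' fold-change on IRES-driven mCherry output, and a penetrance (the fraction
#' of infected cells in which the effect manifests). Non-targeting sgRNAs are
#' forced to effect 1.
#'
#' @param library an `sgrna_library`.
#' @param gfp_effect,mcherry_effect named numeric vectors (names = sgRNA ids)
#'   of fold-changes, `> 0`; unnamed sgRNAs default to 1.
#' @param penetrance named numeric vector in `[0, 1]`; defaults to 1.
#' @return a data.frame classed `effect_map` with one row per library sgRNA.
#' @export
effect_map <- function(library, gfp_effect = NULL, mcherry_effect = NULL,
                       penetrance = NULL) {
  library <- as_sgrna_library(library)
  fill <- function(v, default) {
    out <- rep(default, nrow(library))
    names(out) <- library$sgRNA_id
    if (!is.null(v)) {
      bad <- setdiff(names(v), library$sgRNA_id)
      if (length(bad))
        stop("effects refer to unknown sgRNAs: ", paste(bad, collapse = ", "))
      out[names(v)] <- v
    }
    unname(out)
  }
  out <- data.frame(sgRNA_id = library$sgRNA_id,
                    gfp_effect = fill(gfp_effect, 1),
                    mcherry_effect = fill(mcherry_effect, 1),
                    penetrance = fill(penetrance, 1),
                    stringsAsFactors = FALSE)
  if (any(out$gfp_effect <= 0) || any(out$mcherry_effect <= 0))
    stop("effects must be strictly positive fold-changes")
  if (any(out$penetrance < 0 | out$penetrance > 1))
    stop("penetrance must lie in [0, 1]")
  nt <- is_nontargeting(library)
  if (any(out$gfp_effect[nt] != 1) || any(out$mcherry_effect[nt] != 1))
    stop("non-targeting sgRNAs must have unit effects")
  class(out) <- c("effect_map", "data.frame")
  out
}

#' Screen sorting/sequencing design
#'
#' Parameters of the tail-sort-and-sequence design: the sorted tail fraction,
#' the number of biological replicates, per-replicate cell numbers and
#' sequencing depth (either given explicitly or derived from a coverage
#' multiple of the library size), and the fraction of cells carrying an
#' sgRNA after selection.
#'
#' @param tail_fraction sorted fraction per tail, in `(0, 0.5)`; default 0.15.
#' @param replicates number of replicates, default 2.
#' @param coverage cells (and reads) per library sgRNA used to derive
#'   `cells_per_replicate` and `reads_per_sample` when those are `NULL`.
#' @param cells_per_replicate,reads_per_sample explicit overrides.
#' @param infected_fraction fraction of sgRNA-carrying (BFP+) cells after
#'   selection, in `(0, 1]`; default 0.9.
#' @param abundance_sd_log log-scale SD of the sgRNA abundance skew in the
#'   infected pool (0 = uniform representation).
#' @param sort_retention optional uniform random retention of sorted tail
#'   cells modelling finite sort efficiency; default 1 (off).
#' @param seed top-level simulation seed.
#' @return a classed list `screen_design`.
#' @export
screen_design <- function(tail_fraction = 0.15, replicates = 2, coverage = 100,
                          cells_per_replicate = NULL, reads_per_sample = NULL,
                          infected_fraction = 0.9, abundance_sd_log = 0,
                          sort_retention = 1, seed = 1) {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5, replicates >= 1,
            infected_fraction > 0, infected_fraction <= 1,
            abundance_sd_log >= 0, sort_retention > 0, sort_retention <= 1)
  if (is.null(cells_per_replicate)) stopifnot(coverage > 0)
  structure(list(tail_fraction = tail_fraction, replicates = replicates,
                 coverage = coverage, cells_per_replicate = cells_per_replicate,
                 reads_per_sample = reads_per_sample,
                 infected_fraction = infected_fraction,
                 abundance_sd_log = abundance_sd_log,
                 sort_retention = sort_retention, seed = seed),
            class = "screen_design")
}

#' Derive a child RNG seed from a top-level seed and a stage label
#'
#' Every simulation stage and replicate uses an independent stream derived by
#' a stable string hash of the top-level seed and the stage labels, so that
#' results are reproducible end to end and replicates are statistically
#' independent.
#'
#' @param seed integer top-level seed.
#' @param ... stage labels (strings or integers) folded into the hash.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
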