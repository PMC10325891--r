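#' Per-gene log2 fold-change between two conditions
#'
#' `log2((b + pseudo) / (a + pseudo))` on normalised abundances
#' (counts-per-million scale), so positive values mean higher expression in
#' `condition_b`.
#'
#' @param table data.frame of nonnegative abundances with a `gene` column
#'   and one column per condition.
#' @param condition_a,condition_b column names (reference, comparison).
#' @param pseudo pseudocount (default 1).
#' @return named numeric vector of log2 fold-changes along `table$gene`.
#' @export
fold_change <- function(table, condition_a, condition_b, pseudo = 1) {
  stopifnot(is.data.frame(table), "gene" %in% names(table), pseudo >= 0)
  for (cond in c(condition_a, condition_b))
    if (!cond %in% names(table)) stop("condition missing from table: ", cond)
  a <- table[[condition_a]]; b <- table[[condition_b]]
  if (any(a < 0) || any(b < 0)) stop("abundances must be nonnegative")
  fc <- log2((b + pseudo) / (a + pseudo))
  names(fc) <- table$gene
  fc
}

#' Gene-set response at a fold threshold
#'
#' Counts how many evaluable members of a gene set respond above a fold
#' threshold: `n` is the number of set members present in the expression
#' table and above `expression_floor` in at least one of the two conditions;
#' `k` is the number of those with log2 fold-change strictly greater than
#' `log2(fold_threshold)`.
#'
#' @param table expression table (see [fold_change()]).
#' @param condition_a,condition_b reference and comparison columns.
#' @param set character vector of member gene identifiers (or a list with a
#'   `genes` field as returned by [read_gmt()]).
#' @param fold_threshold linear fold threshold (default 2).
#' @param expression_floor minimum abundance for a member to be evaluable
#'   (default 1, counts-per-million scale).
#' @param pseudo pseudocount passed to [fold_change()].
#' @return list with `k` (upregulated members), `n` (evaluable members) and
#'   the evaluable `members`.
#' @export
set_response <- function(table, condition_a, condition_b, set,
                         fold_threshold = 2, expression_floor = 1,
                         pseudo = 1) {
  if (is.list(set) && !is.null(set$genes)) set <- set$genes
  set <- unique(as.character(set))
  stopifnot(fold_threshold > 0)
  fc <- fold_change(table, condition_a, condition_b, pseudo = pseudo)
  present <- table$gene %in% set
  expressed <- table[[condition_a]] > expression_floor |
    table[[condition_b]] > expression_floor
  members <- table$gene[present & expressed]
  n <- length(members)
  if (n == 0) stop("no evaluable members of the set in the table")
  k <- sum(fc[members] > log2(fold_threshold))
  list(k = k, n = n, members = members)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k` responding members among `n` draws from a universe of `N_universe`
#' genes of which `K_universe` respond.
#'
#' @param k observed responding members of the set.
#' @param n evaluable set size (draws).
#' @param K_universe responding genes in the universe.
#' @param N_universe universe size.
#' @return the one-sided p-value.
#' @export
overrepresentation_p <- function(k, n, K_universe, N_universe) {
  stopifnot(k >= 0, n >= 0, K_universe >= 0, N_universe >= 0)
  if (n > N_universe || K_universe > N_universe)
    stop("inconsistent totals: n and K_universe must not exceed N_universe")
  if (k > min(n, K_universe))
    stop("k cannot exceed min(n, K_universe)")
  stats::phyper(k - 1, K_universe, N_universe - K_universe, n,
                lower.tail = FALSE)
}

#' Read gene sets in GMT format
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members are
#' deduplicated with a warning; a line with fewer than three fields is an
#' error.
#'
#' @param path GMT file path.
#' @return named list of gene sets, each `list(name, description, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character(0)))
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has %d fields; need name, description and at least one member",
                   i, length(fields)))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate members deduplicated", fields[1]))
      genes <- unique(genes)
    }
    list(name = fields[1], description = fields[2], genes = genes)
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}
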