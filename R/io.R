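# Tabular dialect: TSV with headers, UTF-8, '.' decimal. Flow events use CSV
# to mirror instrument exports.

#' Read and write screen count tables
#'
#' TSV with columns `sgRNA_id`, `gene`, then paired `rep<k>_high` /
#' `rep<k>_low` integer read counts. Readers validate rather than coerce:
#' duplicate sgRNA ids, negative or non-integer counts are rejected with the
#' offending line.
#'
#' @param path file path.
#' @param counts a `screen_counts` data.frame.
#' @return `read_counts()` returns a `screen_counts` data.frame;
#'   `write_counts()` returns `path` invisibly.
#' @export
read_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sgRNA_id", "gene")
  if (!all(req %in% names(x)))
    stop("counts file must have sgRNA_id and gene columns")
  if (anyDuplicated(x$sgRNA_id)) {
    dup <- which(duplicated(x$sgRNA_id))[1]
    stop(sprintf("duplicate sgRNA_id '%s' at line %d", x$sgRNA_id[dup], dup + 1))
  }
  cols <- grep("^rep[0-9]+_(high|low)$", names(x), value = TRUE)
  if (length(cols) == 0) stop("counts file has no rep<k>_high/low columns")
  for (cl in cols) {
    v <- x[[cl]]
    bad <- which(!is.finite(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf("invalid count in column %s at line %d", cl, bad[1] + 1))
    x[[cl]] <- as.integer(v)
  }
  class(x) <- c("screen_counts", "data.frame")
  x
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write flow-event tables
#'
#' CSV with columns `FSC_A`, `FSC_H`, `SSC_A`, `BFP`, `GFP`, `mCherry` and
#' optional `well`, `sgRNA`, `class`. All channels must be finite and
#' nonnegative.
#'
#' @param path file path.
#' @param events a flow-events data.frame.
#' @return `read_events()` returns the validated data.frame;
#'   `write_events()` returns `path` invisibly.
#' @export
read_events <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("FSC_A", "FSC_H", "SSC_A", "BFP", "GFP", "mCherry")
  if (!all(req %in% names(x)))
    stop("events file missing channels: ",
         paste(setdiff(req, names(x)), collapse = ", "))
  for (cl in req) {
    bad <- which(!is.finite(x[[cl]]) | x[[cl]] < 0)
    if (length(bad))
      stop(sprintf("invalid value in channel %s at line %d", cl, bad[1] + 1))
  }
  x
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write sgRNA library tables
#'
#' TSV with columns `sgRNA_id` and `gene`; non-targeting controls carry the
#' gene label [NON_TARGETING].
#'
#' @param path file path.
#' @param library an `sgrna_library`.
#' @return `read_library()` returns an `sgrna_library`; `write_library()`
#'   returns `path` invisibly.
#' @export
read_library <- function(path) {
  as_sgrna_library(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_library
#' @export
write_library <- function(library, path) {
  utils::write.table(library, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write perturbation profile matrices
#'
#' TSV with row identifiers in the first column and gene identifiers as the
#' header.
#'
#' @param path file path.
#' @param mat numeric matrix with dimnames.
#' @return `read_profiles()` returns a numeric matrix; `write_profiles()`
#'   returns `path` invisibly.
#' @export
read_profiles <- function(path) {
  x <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("profile matrix must be numeric")
  if (any(!is.finite(m))) stop("profile matrix entries must be finite")
  m
}

#' @rdname read_profiles
#' @export
write_profiles <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-result table
#'
#' TSV with one row per gene: score, per-replicate and combined p-values,
#' product statistic, hit flag and direction.
#'
#' @param result a `screen_result` (see [score_screen()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_gene_results <- function(result, path) {
  stopifnot(inherits(result, "screen_result"))
  utils::write.table(result$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Validated stage parameters for [run_pipeline()]; unknown keys are
#' rejected.
#'
#' @param n_genes,sgrnas_per_gene,n_nontargeting library dimensions.
#' @param effects optional [effect_map()] overrides as a named list
#'   `list(gfp_effect =, mcherry_effect =, penetrance =)`.
#' @param design a [screen_design()].
#' @param calibration a [reporter_calibration()].
#' @param codon reporter start codon.
#' @param pseudocount,quasi_size scoring parameters.
#' @param seed top-level seed (propagated to every stage).
#' @param out_dir output directory.
#' @return a classed list `run_config`.
#' @export
run_config <- function(n_genes = 50, sgrnas_per_gene = 5,
                       n_nontargeting = 100, effects = NULL,
                       design = NULL, calibration = NULL, codon = "CUG",
                       pseudocount = 1, quasi_size = 5, seed = 1,
                       out_dir = tempfile("ratioscreen_run_")) {
  cfg <- list(n_genes = n_genes, sgrnas_per_gene = sgrnas_per_gene,
              n_nontargeting = n_nontargeting, effects = effects,
              design = design, calibration = calibration, codon = codon,
              pseudocount = pseudocount, quasi_size = quasi_size,
              seed = seed, out_dir = out_dir)
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `design` and
#' `effects` may be given as nested maps of [screen_design()] /
#' [effect_map()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$design)) y$design <- do.call(screen_design, y$design)
  do.call(run_config, y)
}

#' Run the simulate-and-score pipeline
#'
#' Simulates a screen under the configuration, scores it, and writes the
#' library, count table, gene results and a JSON run summary (threshold, hit
#' counts, parameters, seed) plus a manifest with md5 checksums of every
#' output. Identical configuration and seed produce byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return the `screen_result`, invisibly, with `attr(, "manifest")`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  library <- make_library(config$n_genes, config$sgrnas_per_gene,
                          config$n_nontargeting)
  effects <- if (is.null(config$effects)) effect_map(library)
             else do.call(effect_map, c(list(library), config$effects))
  design <- if (is.null(config$design)) screen_design(seed = config$seed)
            else config$design
  calibration <- if (is.null(config$calibration)) default_calibration()
                 else config$calibration

  counts <- simulate_screen(library, effects, calibration, design,
                            codon = config$codon)
  result <- score_screen(counts, library, pseudocount = config$pseudocount,
                         quasi_size = config$quasi_size, seed = config$seed)

  paths <- c(
    library = write_library(library, file.path(config$out_dir, "library.tsv")),
    counts = write_counts(counts, file.path(config$out_dir, "counts.tsv")),
    genes = write_gene_results(result, file.path(config$out_dir,
                                                 "gene_results.tsv")))
  summary_path <- file.path(config$out_dir, "run_summary.json")
  jsonlite::write_json(
    list(threshold = result$threshold, n_enriched = result$n_enriched,
         n_depleted = result$n_depleted, seed = config$seed,
         params = result$params),
    summary_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, summary = summary_path)

  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  attr(result, "manifest") <- manifest
  invisible(result)
}
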