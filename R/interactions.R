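#' Additive no-interaction expectation for a double knockdown
#'
#' On the reporter-score scale the no-interaction expectation for a double
#' knockdown is simply the sum of the two single-knockdown scores.
#'
#' @param e_a,e_b single-knockdown reporter scores.
#' @return `e_a + e_b`.
#' @export
additive_expectation <- function(e_a, e_b) e_a + e_b

#' Classify a dual-sgRNA phenotype against the additive model
#'
#' Compares the observed double-knockdown score to the additive expectation
#' using well-replicate variability: the deviation
#' `d = mean(e_AB) - mean(e_A) - mean(e_B)` is tested with a z-statistic on
#' the pooled standard error of the three independent well means. `|z|` at
#' or below `z_threshold` is `additive`; larger deviations are `buffering`
#' when the observed double effect is weaker in magnitude than expected
#' (`|e_AB| < |expected|`) and `synergistic` otherwise. With fewer than two
#' wells in any condition the SE is undefined and the pair is reported
#' `untested`.
#'
#' @param e_a_wells,e_b_wells,e_ab_wells numeric vectors of per-well
#'   reporter scores for the two singles and the double.
#' @param z_threshold z cutoff for the additive call (default 2).
#' @return a classed list `interaction_call` with fields `e_a`, `e_b`,
#'   `e_ab`, `expected`, `deviation`, `se`, `z` and `class`.
#' @export
interaction_call <- function(e_a_wells, e_b_wells, e_ab_wells,
                             z_threshold = 2) {
  stopifnot(length(e_a_wells) >= 1, length(e_b_wells) >= 1,
            length(e_ab_wells) >= 1, z_threshold > 0)
  m <- function(x) mean(x)
  se2 <- function(x) if (length(x) >= 2) stats::var(x) / length(x) else NA_real_
  e_a <- m(e_a_wells); e_b <- m(e_b_wells); e_ab <- m(e_ab_wells)
  expected <- additive_expectation(e_a, e_b)
  deviation <- e_ab - expected
  se <- sqrt(se2(e_a_wells) + se2(e_b_wells) + se2(e_ab_wells))
  if (is.na(se) || se == 0) {
    z <- NA_real_
    cls <- "untested"
  } else {
    z <- deviation / se
    cls <- if (abs(z) <= z_threshold) "additive"
           else if (abs(e_ab) < abs(expected)) "buffering"
           else "synergistic"
  }
  structure(list(e_a = e_a, e_b = e_b, e_ab = e_ab, expected = expected,
                 deviation = deviation, se = se, z = z, class = cls),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf(paste0("<interaction_call> e_A = %.3f, e_B = %.3f, ",
                     "e_AB = %.3f, expected = %.3f, deviation = %.3f ",
                     "(z = %.2f) -> %s\n"),
              x$e_a, x$e_b, x$e_ab, x$expected, x$deviation, x$z, x$class))
  invisible(x)
}

#' Score all dual-sgRNA pairs in a well table
#'
#' Takes a long table of per-well reporter scores: each row is one well with
#' the two sgRNAs it carries (single knockdowns are paired with the
#' non-targeting label `nt_label`, in either slot). For every pair of
#' targeting sgRNAs, the matching single-knockdown wells are located and
#' [interaction_call()] is applied.
#'
#' @param wells data.frame with columns `sgRNA_A`, `sgRNA_B`, `score` (one
#'   row per well).
#' @param z_threshold z cutoff for the additive call.
#' @param nt_label label marking the non-targeting slot (default `"NT"`).
#' @return data.frame with one row per pair: `sgRNA_A`, `sgRNA_B`, `e_A`,
#'   `e_B`, `e_AB`, `expected`, `deviation`, `se`, `z`, `class`.
#' @export
score_interactions <- function(wells, z_threshold = 2, nt_label = "NT") {
  stopifnot(all(c("sgRNA_A", "sgRNA_B", "score") %in% names(wells)))
  a <- as.character(wells$sgRNA_A); b <- as.character(wells$sgRNA_B)
  # canonical orientation: singles as (sgRNA, NT)
  swap <- a == nt_label & b != nt_label
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  single_scores <- function(sg) wells$score[(a == sg & b == nt_label)]

  is_double <- a != nt_label & b != nt_label
  pairs <- unique(data.frame(
    A = pmin(a[is_double], b[is_double]),
    B = pmax(a[is_double], b[is_double]), stringsAsFactors = FALSE))
  if (nrow(pairs) == 0) return(data.frame())

  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pa <- pairs$A[i]; pb <- pairs$B[i]
    ab <- wells$score[is_double & pmin(a, b)[seq_along(a)] == pa &
                        pmax(a, b)[seq_along(a)] == pb]
    ea <- single_scores(pa); eb <- single_scores(pb)
    if (length(ea) == 0 || length(eb) == 0)
      stop(sprintf("missing single-knockdown wells for pair %s / %s", pa, pb))
    cl <- interaction_call(ea, eb, ab, z_threshold = z_threshold)
    data.frame(sgRNA_A = pa, sgRNA_B = pb, e_A = cl$e_a, e_B = cl$e_b,
               e_AB = cl$e_ab, expected = cl$expected,
               deviation = cl$deviation, se = cl$se, z = cl$z,
               class = cl$class, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
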