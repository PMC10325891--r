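#' Gating configuration
#'
#' Reproducible automatic rules standing in for the manually drawn gates of
#' an interactive analysis, each overridable by an explicit value:
#'
#' * viability: either a fraction in `(0, 1]` (retain that fraction of
#'   events with the highest FSC-A/SSC-A kernel-density estimate) or an
#'   explicit polygon (two-column matrix of FSC-A, SSC-A vertices).
#' * singlets: either a fraction in `(0, 1]` (central quantile band of the
#'   FSC-H/FSC-A ratio) or an explicit interval `c(lo, hi)` for the ratio.
#' * BFP: `"auto"` (threshold at the minimum-density valley between the two
#'   largest modes of log BFP) or an explicit linear threshold.
#'
#' @param viability fraction, polygon matrix, or `NULL` to skip.
#' @param singlet fraction, length-2 interval, or `NULL` to skip.
#' @param bfp_threshold `"auto"` or a positive number.
#' @param tail_fraction ratiometric tail fraction, in `(0, 0.5)`.
#' @return a classed list `gate_config`.
#' @export
gate_config <- function(viability = 0.90, singlet = 0.95,
                        bfp_threshold = "auto", tail_fraction = 0.15) {
  if (is.numeric(viability) && !is.matrix(viability))
    stopifnot(length(viability) == 1, viability > 0, viability <= 1)
  if (is.matrix(viability)) stopifnot(ncol(viability) == 2, nrow(viability) >= 3)
  if (is.numeric(singlet)) {
    stopifnot(length(singlet) %in% c(1, 2))
    if (length(singlet) == 1) stopifnot(singlet > 0, singlet <= 1)
    else stopifnot(singlet[1] < singlet[2])
  }
  if (is.numeric(bfp_threshold)) stopifnot(bfp_threshold > 0)
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  structure(list(viability = viability, singlet = singlet,
                 bfp_threshold = bfp_threshold, tail_fraction = tail_fraction),
            class = "gate_config")
}

# 2D kernel-density estimate evaluated at the data points (bilinear
# interpolation on a MASS::kde2d grid). The grid is fitted on an evenly
# spaced subsample to bound memory on large event tables; evaluation covers
# every point.
point_density_2d <- function(x, y, n_grid = 50, fit_max = 20000) {
  if (length(x) > fit_max) {
    idx <- unique(round(seq(1, length(x), length.out = fit_max)))
    kd <- MASS::kde2d(x[idx], y[idx], n = n_grid,
                      lims = c(range(x), range(y)))
  } else {
    kd <- MASS::kde2d(x, y, n = n_grid)
  }
  ix <- findInterval(x, kd$x, all.inside = TRUE)
  iy <- findInterval(y, kd$y, all.inside = TRUE)
  fx <- (x - kd$x[ix]) / diff(kd$x)[1]
  fy <- (y - kd$y[iy]) / diff(kd$y)[1]
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  kd$z[cbind(ix, iy)]         * (1 - fx) * (1 - fy) +
    kd$z[cbind(ix + 1, iy)]     * fx       * (1 - fy) +
    kd$z[cbind(ix, iy + 1)]     * (1 - fx) * fy +
    kd$z[cbind(ix + 1, iy + 1)] * fx       * fy
}

# ray-casting point-in-polygon test (polygon given as a 2-column matrix)
points_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Gate flow events: viability then singlets
#'
#' Applies the viability gate (FSC-A vs SSC-A) followed by the doublet gate
#' (FSC-H/FSC-A band); the order is fixed. Events with `FSC_A == 0` cannot
#' enter the ratio and are excluded up front with a warning count in the
#' report.
#'
#' @param events a flow-events data.frame (see [simulate_population()]).
#' @param config a [gate_config()].
#' @return a list with `events` (the gated table) and `report` (a data.frame
#'   of per-stage input size, output size and pass fraction).
#' @export
gate_events <- function(events, config = gate_config()) {
  report <- data.frame(stage = character(0), n_in = integer(0),
                       n_out = integer(0), fraction = numeric(0),
                       stringsAsFactors = FALSE)
  add <- function(stage, n_in, n_out) {
    rbind(report, data.frame(stage = stage, n_in = n_in, n_out = n_out,
                             fraction = if (n_in > 0) n_out / n_in else 0,
                             stringsAsFactors = FALSE))
  }
  if (nrow(events) == 0) {
    report <- add("viability", 0L, 0L)
    report <- add("singlet", 0L, 0L)
    return(list(events = events, report = report))
  }
  degenerate <- events$FSC_A <= 0
  if (any(degenerate)) {
    warning(sum(degenerate), " events with FSC_A <= 0 excluded")
    events <- events[!degenerate, , drop = FALSE]
  }

  n0 <- nrow(events)
  v <- config$viability
  if (is.null(v)) {
    keep <- rep(TRUE, n0)
  } else if (is.matrix(v)) {
    keep <- points_in_polygon(events$FSC_A, events$SSC_A, v)
  } else if (v >= 1) {
    keep <- rep(TRUE, n0)
  } else {
    # density estimated on the log scale, where the viable-cell mode is
    # compact and debris is diffuse (gates are drawn on log axes)
    dens <- point_density_2d(log10(events$FSC_A + 1),
                             log10(events$SSC_A + 1))
    keep <- dens >= stats::quantile(dens, 1 - v)
  }
  events <- events[keep, , drop = FALSE]
  report <- add("viability", n0, nrow(events))

  n1 <- nrow(events)
  s <- config$singlet
  ratio <- events$FSC_H / events$FSC_A
  if (is.null(s)) {
    keep <- rep(TRUE, n1)
  } else if (length(s) == 2) {
    keep <- ratio >= s[1] & ratio <= s[2]
  } else if (s >= 1) {
    keep <- rep(TRUE, n1)
  } else {
    band <- stats::quantile(ratio, c((1 - s) / 2, 1 - (1 - s) / 2))
    keep <- ratio >= band[1] & ratio <= band[2]
  }
  events <- events[keep, , drop = FALSE]
  report <- add("singlet", n1, nrow(events))

  list(events = events, report = report)
}

#' Split events into infected (BFP+) and uninfected (BFP-) populations
#'
#' With `threshold = "auto"`, the threshold is placed at the minimum-density
#' point between the two largest modes of the log-BFP kernel density; a
#' unimodal BFP distribution is rejected with advice to supply an explicit
#' threshold.
#'
#' @param events flow-events data.frame.
#' @param threshold `"auto"` or an explicit linear BFP threshold.
#' @return a list with `infected`, `uninfected` and the `threshold` used.
#' @export
split_by_bfp <- function(events, threshold = "auto") {
  if (identical(threshold, "auto")) {
    if (nrow(events) < 10)
      stop("too few events for automatic BFP threshold; supply one explicitly")
    lb <- log10(events$BFP + 1)
    d <- stats::density(lb, n = 512)
    up <- diff(d$y) > 0
    peaks <- which(diff(up) == -1) + 1
    if (length(peaks) < 2)
      stop("BFP distribution looks unimodal; supply an explicit threshold")
    top2 <- sort(peaks[order(d$y[peaks], decreasing = TRUE)][1:2])
    valley <- top2[1] + which.min(d$y[top2[1]:top2[2]]) - 1
    threshold <- 10^d$x[valley] - 1
  }
  pos <- events$BFP > threshold
  list(infected = events[pos, , drop = FALSE],
       uninfected = events[!pos, , drop = FALSE],
       threshold = threshold)
}

#' Signed pseudo-log transform
#'
#' `signed_log2(d, unit)` is `sign(d) * log2(1 + |d|/unit)`: odd, strictly
#' monotone, equal to `log2(d/unit)` asymptotically for `d >> unit`, and 0 at
#' `d = 0`, so depleting (negative-difference) phenotypes remain
#' representable. `signed_log2_inverse()` is its exact inverse.
#'
#' @param d numeric vector (fluorescence difference).
#' @param score numeric vector on the transformed scale.
#' @param unit positive fluorescence scale of the transform.
#' @return transformed (or back-transformed) numeric vector.
#' @export
signed_log2 <- function(d, unit = 1) {
  stopifnot(unit > 0)
  sign(d) * log2(1 + abs(d) / unit)
}

#' @rdname signed_log2
#' @export
signed_log2_inverse <- function(score, unit = 1) {
  stopifnot(unit > 0)
  sign(score) * unit * (2^abs(score) - 1)
}

#' Internally controlled reporter phenotype
#'
#' Computes the difference in mean GFP (`dGFP`) and mean mCherry
#' (`dmCherry`) between sgRNA-infected and uninfected cells co-cultured in
#' the same well, and the primary reporter score: the signed pseudo-log of
#' `dGFP - dmCherry`. Subtracting the mCherry difference cancels effects
#' acting equally on both cistrons (transcript abundance, IRES output),
#' isolating the change in near-cognate initiation.
#'
#' @param infected,uninfected flow-events data.frames (both non-empty).
#' @param unit fluorescence scale of the signed-log transform.
#' @return a classed list `reporter_phenotype` with `dGFP`, `dmCherry`,
#'   `difference`, `score` and event counts.
#' @export
reporter_phenotype <- function(infected, uninfected, unit = 1) {
  if (nrow(infected) == 0) stop("infected population is empty")
  if (nrow(uninfected) == 0) stop("uninfected population is empty")
  d_gfp <- mean(infected$GFP) - mean(uninfected$GFP)
  d_mch <- mean(infected$mCherry) - mean(uninfected$mCherry)
  d <- d_gfp - d_mch
  structure(list(dGFP = d_gfp, dmCherry = d_mch, difference = d,
                 score = signed_log2(d, unit), unit = unit,
                 n_infected = nrow(infected), n_uninfected = nrow(uninfected)),
            class = "reporter_phenotype")
}

#' @export
print.reporter_phenotype <- function(x, ...) {
  cat(sprintf(paste0("<reporter_phenotype> dGFP = %.4g, dmCherry = %.4g, ",
                     "score = %.4f (n = %d infected / %d uninfected)\n"),
              x$dGFP, x$dmCherry, x$score, x$n_infected, x$n_uninfected))
  invisible(x)
}

#' Population-level reporter diagnostics
#'
#' Computes the linear-scale CVs of GFP, mCherry and the GFP/mCherry ratio,
#' the Pearson correlation of the two channels, and the ratiometric tail
#' boundaries at the `tail_fraction` / `1 - tail_fraction` empirical
#' quantiles together with their percent separation
#' `(upper - lower)/lower * 100`.
#'
#' @param events flow-events data.frame with at least 3 events.
#' @param tail_fraction sorted tail fraction, in `(0, 0.5)`.
#' @return a list of diagnostics.
#' @export
population_diagnostics <- function(events, tail_fraction = 0.15) {
  if (nrow(events) < 3) stop("need at least 3 events for diagnostics")
  stopifnot(tail_fraction > 0, tail_fraction < 0.5)
  cv <- function(x) stats::sd(x) / mean(x)
  ratio <- events$GFP / events$mCherry
  qs <- stats::quantile(ratio, c(tail_fraction, 1 - tail_fraction),
                        names = FALSE)
  list(gfp_cv = cv(events$GFP),
       mcherry_cv = cv(events$mCherry),
       ratio_cv = cv(ratio),
       correlation = stats::cor(events$GFP, events$mCherry),
       ratio_boundaries = qs,
       boundary_separation_pct = 100 * (qs[2] - qs[1]) / qs[1],
       n_events = nrow(events))
}
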