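#' Low-rank embedding / light imputation of profile matrices
#'
#' Rank-`n_dims` truncated singular value decomposition of the
#' perturbation-by-gene z-score matrix. The rank-truncated reconstruction
#' acts as a light imputation step (drawing perturbations closer to their
#' relatives); the scaled left singular vectors provide the row embedding
#' used by the permissive clustering.
#'
#' @param mat numeric matrix (rows = perturbations, columns = genes).
#' @param n_dims embedding dimension, `<= min(dim(mat))` (default 20).
#' @return list with `embedding` (rows x `n_dims`, `U %*% diag(d)`),
#'   `smoothed` (the rank-`n_dims` reconstruction) and `d` (singular
#'   values).
#' @export
embed_profiles <- function(mat, n_dims = 20) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (any(!is.finite(mat))) stop("matrix entries must be finite")
  if (n_dims < 1 || n_dims > min(dim(mat)))
    stop(sprintf("n_dims must lie in [1, %d]", min(dim(mat))))
  sv <- svd(mat, nu = n_dims, nv = n_dims)
  d <- sv$d[seq_len(n_dims)]
  emb <- sv$u %*% diag(d, n_dims)
  rownames(emb) <- rownames(mat)
  smoothed <- emb %*% t(sv$v)
  dimnames(smoothed) <- dimnames(mat)
  list(embedding = emb, smoothed = smoothed, d = d)
}

#' Filter response genes by differential-response magnitude
#'
#' Keeps response genes (columns) whose profile across the perturbation
#' comparison set is both strong somewhere and consistently nonzero:
#' `max_i |z_ij| > max_abs_threshold` AND
#' `median_i |z_ij| > median_abs_threshold`, both strict.
#'
#' @param mat numeric matrix (rows = perturbations, columns = genes),
#'   non-empty.
#' @param max_abs_threshold default 1.
#' @param median_abs_threshold default 0.1.
#' @return the column-filtered matrix (retained names in `colnames`).
#' @export
filter_response_genes <- function(mat, max_abs_threshold = 1,
                                  median_abs_threshold = 0.1) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0 || ncol(mat) == 0) stop("empty matrix")
  az <- abs(mat)
  keep <- apply(az, 2, max) > max_abs_threshold &
    apply(az, 2, stats::median) > median_abs_threshold
  mat[, keep, drop = FALSE]
}

# canonical relabelling: clusters numbered by order of first appearance,
# making labels invariant to kmeans' arbitrary numbering
relabel_by_first_appearance <- function(labels) {
  match(labels, unique(labels))
}

#' Biaxial k-means clustering of a profile matrix
#'
#' k-means on the rows (perturbations) and, independently, on the columns
#' (response genes) of the matrix, each with `n_restarts` seeded restarts
#' keeping the lowest within-cluster sum of squares. Rows and columns are
#' canonically sorted by identifier before seeding so results do not depend
#' on input order; labels are renumbered by first appearance.
#'
#' @param mat numeric matrix with row/column names.
#' @param k_rows,k_cols cluster counts (defaults 5 and 3).
#' @param n_restarts random restarts (default 25).
#' @param seed RNG seed.
#' @return list with named `row_clusters` and `col_clusters` label vectors
#'   (in the input's row/column order), `row_inertia`, `col_inertia`, and
#'   the call parameters.
#' @export
kmeans_biaxial <- function(mat, k_rows = 5, k_cols = 3, n_restarts = 25,
                          seed = 1) {
  stopifnot(is.matrix(mat))
  if (k_rows > nrow(mat)) stop("k_rows exceeds number of rows")
  if (k_cols > ncol(mat)) stop("k_cols exceeds number of columns")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("r%04d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("c%04d", seq_len(ncol(mat)))

  run_axis <- function(x, k, tag) {
    ord <- order(rownames(x))
    x <- x[ord, , drop = FALSE]
    if (k == nrow(x)) {             # singleton limit (kmeans requires k < n)
      if (anyDuplicated(x) > 0)
        stop("k equals the number of rows but rows are not distinct")
      labels <- seq_len(nrow(x))
      names(labels) <- rownames(x)
      return(list(labels = labels, inertia = 0))
    }
    set.seed(derive_seed(seed, "kmeans", tag))
    km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
    labels <- relabel_by_first_appearance(km$cluster)
    names(labels) <- rownames(x)
    list(labels = labels, inertia = km$tot.withinss)
  }
  rows <- run_axis(mat, k_rows, "rows")
  cols <- run_axis(t(mat), k_cols, "cols")
  list(row_clusters = rows$labels[rownames(mat)],
       col_clusters = cols$labels[colnames(mat)],
       row_inertia = rows$inertia, col_inertia = cols$inertia,
       k_rows = k_rows, k_cols = k_cols, seed = seed)
}

#' Permissive agglomerative clustering of embedded perturbations
#'
#' Average-linkage hierarchical clustering on the correlation distance
#' (`1 - Pearson r`) between embedded row profiles, cut at a distance
#' threshold; singleton clusters are allowed. This is the permissive
#' complement to the stringent k-means partition: related perturbations
#' co-cluster at moderate thresholds without forcing every row into a
#' group.
#'
#' @param embedding numeric matrix of row coordinates (>= 2 rows).
#' @param threshold correlation-distance cut height (0 = all singletons).
#' @return named integer vector of cluster labels.
#' @export
permissive_cluster <- function(embedding, threshold = 0.5) {
  stopifnot(is.matrix(embedding), threshold >= 0)
  if (nrow(embedding) < 2) stop("need at least 2 rows to cluster")
  if (is.null(rownames(embedding)))
    rownames(embedding) <- sprintf("r%04d", seq_len(nrow(embedding)))
  cm <- suppressWarnings(stats::cor(t(embedding)))
  cm[!is.finite(cm)] <- 0      # constant rows: no correlation support
  d <- stats::as.dist(1 - cm)
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, h = threshold)
}
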