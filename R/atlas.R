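# PCA statistical atlases of ES shape and of contraction: construction via
# the Gram-matrix route, projection to mode scores, reconstruction, variance
# truncation and percentile mode-extreme shapes.

#' Build a PCA shape atlas
#'
#' Computes the mean vector and the eigen-decomposition of the sample
#' (n - 1 convention) covariance of a cohort of equal-length shape vectors
#' (vectorized mesh coordinates or contraction displacements, in mm). The
#' decomposition uses the Gram-matrix route, exact for n << p, and keeps all
#' modes with non-negligible variance.
#'
#' @param vectors n x p matrix, one subject per row.
#' @param kind Label recorded in the atlas (`"ES"`, `"ED"`, `"contraction"`).
#' @return Object of class `shape_atlas`: `mean` (p), `modes` (p x K,
#'   orthonormal columns), `eigenvalues` (variance per mode, mm^2),
#'   `n_subjects`, `kind`.
#' @export
build_atlas <- function(vectors, kind = "ES") {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2) stop("at least 2 subjects required")
  if (anyNA(vectors)) stop("shape vectors contain missing values")
  n <- nrow(vectors)
  mu <- colMeans(vectors)
  xc <- sweep(vectors, 2, mu)
  gram <- tcrossprod(xc) / (n - 1)
  eig <- eigen(gram, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10 & eig$values > 0
  lambda <- eig$values[pos]
  modes <- crossprod(xc, eig$vectors[, pos, drop = FALSE])
  modes <- sweep(modes, 2, sqrt((n - 1) * lambda), `/`)
  structure(
    list(mean = mu, modes = modes, eigenvalues = lambda,
         n_subjects = n, kind = kind),
    class = "shape_atlas"
  )
}

#' @method print shape_atlas
#' @export
print.shape_atlas <- function(x, ...) {
  cum <- cumsum(x$eigenvalues) / sum(x$eigenvalues)
  k95 <- which(cum >= 0.95)[1]
  cat(sprintf("%s shape atlas: %d subjects, %d modes (%d for 95%% variance)\n",
              x$kind, x$n_subjects, length(x$eigenvalues), k95))
  cat(sprintf("  total variance %.3g mm^2; leading shares: %s\n",
              sum(x$eigenvalues),
              paste(sprintf("%.1f%%", 100 * x$eigenvalues[
                seq_len(min(5, length(x$eigenvalues)))] /
                  sum(x$eigenvalues)), collapse = ", ")))
  invisible(x)
}

#' Project shape vectors onto atlas modes
#'
#' Mode scores are `c = t(modes) (x - mean)`, in mm (coefficient units);
#' optionally whitened by the per-mode standard deviation.
#'
#' @param atlas A `shape_atlas`.
#' @param vectors A single vector or an n x p matrix.
#' @param whiten Divide scores by `sqrt(eigenvalue)`.
#' @return n x K matrix of mode scores (columns `mode_1`, ...).
#' @export
project_atlas <- function(atlas, vectors, whiten = FALSE) {
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  if (ncol(vectors) != length(atlas$mean)) stop("dimension mismatch")
  scores <- sweep(vectors, 2, atlas$mean) %*% atlas$modes
  if (whiten) scores <- sweep(scores, 2, sqrt(atlas$eigenvalues), `/`)
  colnames(scores) <- paste0("mode_", seq_len(ncol(scores)))
  scores
}

#' @rdname project_atlas
#' @param object,newdata,... S3 method interface: `predict(atlas, vectors)`
#'   is equivalent to `project_atlas(atlas, vectors)`.
#' @export
predict.shape_atlas <- function(object, newdata, ...) {
  project_atlas(object, newdata, ...)
}

#' Reconstruct a shape vector from mode scores
#'
#' @param atlas A `shape_atlas`.
#' @param scores Score vector (or 1 x K matrix) from [project_atlas()].
#' @param k Number of leading modes to use (default: all scores provided).
#' @return Reconstructed shape vector `mean + sum_k score_k mode_k`.
#' @export
reconstruct_atlas <- function(atlas, scores, k = NULL) {
  scores <- as.numeric(scores)
  if (is.null(k)) k <- length(scores)
  if (k > ncol(atlas$modes)) stop("k exceeds the stored modes")
  use <- seq_len(k)
  atlas$mean + drop(atlas$modes[, use, drop = FALSE] %*% scores[use])
}

#' Number of modes needed for a variance fraction
#'
#' @param atlas A `shape_atlas`.
#' @param fraction Target cumulative variance share in (0, 1].
#' @return Smallest K whose cumulative eigenvalue share reaches `fraction`.
#' @export
modes_for_variance <- function(atlas, fraction = 0.95) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  cum <- cumsum(atlas$eigenvalues) / sum(atlas$eigenvalues)
  as.integer(which(cum >= fraction - 1e-12)[1])
}

#' Shapes at the percentile extremes of a discriminant direction
#'
#' Reconstructs the shapes at the empirical lower/upper percentiles of the
#' cohort score distribution along a (unit-normalized) direction in mode
#' space — the convention used to visualize risk-related modes (e.g. 5th
#' percentile = low-risk, 95th = high-risk representative).
#'
#' @param atlas A `shape_atlas`.
#' @param direction Direction in mode space (length <= number of modes).
#' @param scores Cohort mode-score matrix from [project_atlas()].
#' @param percentiles Two percentiles in (0, 100).
#' @return List with `low` and `high` shape vectors and the percentile
#'   projections `q`.
#' @export
mode_extremes <- function(atlas, direction, scores, percentiles = c(5, 95)) {
  k <- length(direction)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("degenerate direction")
  direction <- direction / nrm
  proj <- drop(scores[, seq_len(k), drop = FALSE] %*% direction)
  q <- stats::quantile(proj, percentiles / 100, names = FALSE)
  shape_at <- function(s) {
    atlas$mean + drop(atlas$modes[, seq_len(k), drop = FALSE] %*%
                        (direction * s))
  }
  list(low = shape_at(q[1]), high = shape_at(q[2]), q = q)
}

# Rebuild an lv_mesh from a shape vector using a topology prototype.
shape_vector_to_mesh <- function(vec, prototype) {
  prototype$nodes <- shape_vector_to_nodes(vec)
  colnames(prototype$nodes) <- c("x", "y", "z")
  class(prototype) <- "lv_mesh"
  prototype
}
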