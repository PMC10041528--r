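#' Fit a PCA embedding model
#'
#' Centred linear projection maximising variance, computed from the
#' eigendecomposition of the covariance of the input rows. No variance
#' scaling or whitening is applied to the SOAP features. Axis signs follow
#' a deterministic convention (the largest-magnitude loading of each axis
#' is positive), so refits are reproducible. When `variance_target` is
#' given, the number of retained components is the smallest `k` whose
#' cumulative explained-variance ratio reaches the target. Zero-variance
#' directions of rank-deficient data are reported with ratio 0.
#'
#' @param x numeric matrix (rows = observations) or a `soap_dataset`.
#' @param n_components number of components to retain.
#' @param variance_target alternatively, cumulative variance ratio in
#'   (0, 1] to reach (e.g. 0.80).
#' @return object of class `pca_model`: `center`, `rotation` (D x k),
#'   `explained_variance_ratio` (all D components), `cumulative_variance`
#'   (over all D), `n_components`.
#' @examples
#' m <- fit_pca(matrix(rnorm(200), 50, 4), n_components = 2)
#' sum(m$explained_variance_ratio)
#' @export
fit_pca <- function(x, n_components = NULL, variance_target = NULL) {
  if (inherits(x, "soap_dataset")) x <- x$X
  stopifnot(is.matrix(x), nrow(x) >= 2)
  D <- ncol(x)
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  # covariance eigendecomposition via crossprod: same spectrum as thin SVD
  cv <- crossprod(xc) / (nrow(x) - 1)
  e <- eigen(cv, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  ratio <- if (sum(ev) > 0) ev / sum(ev) else rep(0, D)
  cum <- cumsum(ratio)
  if (is.null(n_components)) {
    n_components <- if (is.null(variance_target)) D
                    else which(cum >= variance_target - 1e-12)[1]
    if (is.na(n_components)) n_components <- D
  }
  stopifnot(n_components >= 1, n_components <= D)
  rot <- e$vectors[, seq_len(n_components), drop = FALSE]
  # deterministic sign: largest |loading| positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(list(center = ctr, rotation = rot,
                 explained_variance = ev,
                 explained_variance_ratio = ratio,
                 cumulative_variance = cum,
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- x$n_components
  cat(sprintf("PCA model: %d components retained (%.1f%% cumulative variance)\n",
              k, 100 * x$cumulative_variance[k]))
  invisible(x)
}

#' Project rows with a fitted PCA model
#'
#' @param model a `pca_model`.
#' @param x matrix of rows (or `soap_dataset`) with the training dimension.
#' @return object of class `embedded_dataset`: `Y` (rows x k scores),
#'   `model`, and the row metadata when `x` is a `soap_dataset`.
#' @export
pca_transform <- function(model, x) {
  meta <- NULL
  if (inherits(x, "soap_dataset")) { meta <- x$meta; x <- x$X }
  if (is.null(dim(x))) x <- matrix(x, ncol = length(model$center))
  if (ncol(x) != length(model$center))
    stop("row dimension does not match the fitted model")
  Y <- sweep(x, 2, model$center) %*% model$rotation
  structure(list(Y = Y, model = model, meta = meta), class = "embedded_dataset")
}

#' Reconstruct rows from PCA scores
#'
#' Inverse projection onto the original feature space (exact when all
#' components are retained).
#'
#' @param model a `pca_model`.
#' @param scores matrix of scores (rows x k) or an `embedded_dataset`.
#' @return matrix in the original space.
#' @export
pca_inverse <- function(model, scores) {
  if (inherits(scores, "embedded_dataset")) scores <- scores$Y
  sweep(scores %*% t(model$rotation), 2, model$center, "+")
}

#' TwoNN intrinsic-dimension estimate
#'
#' Facco-style estimator: for each point the ratio `mu = r2/r1` of its
#' second to first nearest-neighbour distance follows a Pareto law with
#' shape equal to the intrinsic dimension; `d` is the slope of the
#' origin-constrained fit of `-log(1 - F(mu))` against `log mu` over the
#' empirical distribution, after discarding the largest `discard_fraction`
#' of the ratios (tail robustness). Exact duplicate points are dropped with
#' a warning.
#'
#' @param x numeric matrix of points (rows).
#' @param discard_fraction fraction of the largest ratios discarded.
#' @return list with `dimension`, `n_used`, `mu` (kept ratios).
#' @export
twonn_dimension <- function(x, discard_fraction = 0.10) {
  if (inherits(x, "embedded_dataset")) x <- x$Y
  stopifnot(is.matrix(x))
  n0 <- nrow(x)
  x <- unique(x)
  if (nrow(x) == 1L) stop("intrinsic dimension undefined: all points identical")
  if (nrow(x) < n0)
    warning(n0 - nrow(x), " duplicate points dropped")
  if (nrow(x) < 10) stop("need at least 10 distinct points")
  n <- nrow(x)
  r1 <- numeric(n); r2 <- numeric(n)
  # block-wise pairwise distances to cap memory at large n
  block <- max(1L, floor(2e7 / n))
  sq <- rowSums(x^2)
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(sq[s:e], sq, "+") - 2 * tcrossprod(x[s:e, , drop = FALSE], x)
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
    d2 <- pmax(d2, 0)
    for (i in seq_len(e - s + 1L)) {
      two <- sort.int(d2[i, ], partial = 2)[1:2]
      r1[s + i - 1L] <- sqrt(two[1]); r2[s + i - 1L] <- sqrt(two[2])
    }
  }
  mu <- sort(r2 / r1)
  m <- length(mu)
  keep_n <- max(2L, floor(m * (1 - discard_fraction)))
  Fhat <- seq_len(m) / (m + 1)
  lx <- log(mu[seq_len(keep_n)])
  ly <- -log(1 - Fhat[seq_len(keep_n)])
  d <- sum(lx * ly) / sum(lx^2)
  list(dimension = d, n_used = keep_n, mu = mu[seq_len(keep_n)])
}
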