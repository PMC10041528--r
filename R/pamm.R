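#' Farthest point sampling
#'
#' Greedy max-min subset selection: starting from a seeded random point,
#' iteratively add the point whose distance to the selected set is largest.
#' Deterministic given the seed.
#'
#' @param x numeric matrix of points (rows).
#' @param ngrid number of points to select (<= nrow(x)).
#' @param seed RNG seed for the starting point.
#' @param start optional starting row index (overrides the seeded draw).
#' @return integer vector of selected row indices (first = start).
#' @export
farthest_point_sampling <- function(x, ngrid, seed = 1L, start = NULL) {
  if (inherits(x, "embedded_dataset")) x <- x$Y
  n <- nrow(x)
  if (ngrid > n) stop("ngrid exceeds the number of points")
  if (is.null(start)) {
    set.seed(seed)
    start <- sample.int(n, 1L)
  }
  start <- as.integer(start)
  sel <- integer(ngrid)
  sel[1L] <- start
  mind <- rowSums(sweep(x, 2, x[start, ])^2)
  if (ngrid > 1L) {
    for (k in 2:ngrid) {
      nxt <- which.max(mind)
      sel[k] <- nxt
      d2 <- rowSums(sweep(x, 2, x[nxt, ])^2)
      mind <- pmin(mind, d2)
    }
  }
  sel
}

# nearest grid point for every sample, blockwise; ties -> lowest grid index
.nearest_grid <- function(x, grid) {
  n <- nrow(x); ng <- nrow(grid)
  out <- integer(n)
  gsq <- rowSums(grid^2)
  block <- max(1L, floor(4e6 / ng))
  for (s in seq(1, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- outer(rowSums(x[s:e, , drop = FALSE]^2), gsq, "+") -
      2 * tcrossprod(x[s:e, , drop = FALSE], grid)
    out[s:e] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Statistical inefficiency of an embedded trajectory dataset
#'
#' Effective-sample-size correction factor `g >= 1` for time-correlated
#' datasets: one descriptor row per (frame, surfactant) is not an
#' independent draw when consecutive frames are closer than the
#' decorrelation time. For each retained component the integrated
#' autocorrelation `g_j = 1 + 2 sum_t rho_j(t)` is estimated from the
#' per-surfactant time series (summed until the autocorrelation first
#' drops below 0.05), and the component estimates are combined weighted by
#' the embedded variance. The effective number of independent samples is
#' `n / g`.
#'
#' @param emb an `embedded_dataset` whose `meta` has `frame` and `center`.
#' @return scalar `g >= 1`.
#' @export
statistical_inefficiency <- function(emb) {
  stopifnot(inherits(emb, "embedded_dataset"), !is.null(emb$meta))
  meta <- emb$meta
  if (length(unique(meta$frame)) < 5) return(1)
  # per-surfactant time series; series may have different lengths when
  # several systems are pooled, so group by centre id
  ord <- order(meta$center, meta$frame)
  cid <- meta$center[ord]
  splits <- split(seq_along(cid), cid)
  g <- numeric(ncol(emb$Y))
  w <- numeric(ncol(emb$Y))
  for (j in seq_len(ncol(emb$Y))) {
    ser <- lapply(splits, function(ix) {
      s <- emb$Y[ord[ix], j]
      s - mean(s)
    })
    v <- mean(unlist(lapply(ser, function(s) mean(s^2))))
    w[j] <- stats::var(emb$Y[, j])
    gj <- 1
    maxlag <- max(lengths(ser)) - 2L
    for (lag in seq_len(max(1L, maxlag))) {
      num <- 0; den <- 0
      for (s in ser) {
        n <- length(s)
        if (n > lag + 1) {
          num <- num + sum(s[seq_len(n - lag)] * s[(1 + lag):n])
          den <- den + (n - lag)
        }
      }
      if (den == 0) break
      rho <- (num / den) / v
      if (!is.finite(rho) || rho < 0.05) break
      gj <- gj + 2 * rho
    }
    g[j] <- gj
  }
  max(1, sum(g * w) / sum(w))
}

#' Kernel density estimation on a farthest-point grid
#'
#' PAMM-style adaptive anisotropic KDE. Each grid point gets a bandwidth
#' matrix from the locally weighted covariance of the data around it; the
#' localisation window around grid point `i` is a Gaussian whose width is
#' the distance to the `ceiling(fs * n)`-th nearest data point, so the
#' dimensionless `fs` is the fraction of samples that localise the
#' anisotropic multivariate Gaussian bandwidth estimate. Each data point
#' kernel uses the bandwidth of its Voronoi grid centre, scaled by an
#' effective-sample-size Scott factor. Densities are normalised so that
#' the Voronoi-weighted sum over grid points equals 1. Singular local
#' covariances are regularised by diagonal loading.
#'
#' @param x data matrix (rows = points) or `embedded_dataset`.
#' @param grid_idx grid row indices, from [farthest_point_sampling()].
#' @param fs kernel localisation scaling (dimensionless, > 0).
#' @param inefficiency statistical inefficiency `g` of the samples
#'   (see [statistical_inefficiency()]); inflates the log-density error
#'   by `sqrt(g)`.
#' @return object of class `density_grid`: `grid` (coords), `grid_idx`,
#'   `density` (normalised), `raw_density`, `logerr`, `weight` (Voronoi
#'   counts), `assign` (per-point nearest grid index), `H` (per-grid
#'   bandwidth matrices), `fs`.
#' @export
kde_on_grid <- function(x, grid_idx, fs = 0.1, inefficiency = 1) {
  if (inherits(x, "embedded_dataset")) x <- x$Y
  stopifnot(fs > 0)
  n <- nrow(x); d <- ncol(x)
  grid <- x[grid_idx, , drop = FALSE]
  ng <- nrow(grid)
  assign <- .nearest_grid(x, grid)
  wcount <- tabulate(assign, nbins = ng)

  Cg <- cov(x)
  reg <- 1e-8 * sum(diag(Cg))
  m_loc <- min(n, max(8L, ceiling(fs * n))) # samples per localisation window

  H <- vector("list", ng)
  n_reg <- 0L
  xt <- t(x)
  for (i in seq_len(ng)) {
    d2 <- colSums((xt - grid[i, ])^2)
    s2 <- sort.int(d2, partial = m_loc)[m_loc] # m_loc-th NN distance^2
    w <- exp(-0.5 * d2 / max(s2, 1e-300))
    sw <- sum(w)
    neff <- sw^2 / sum(w^2)
    mu <- drop(crossprod(x, w)) / sw # weighted mean
    xc <- sweep(x, 2, mu)
    Cl <- crossprod(xc * (w / sw), xc) # sum_j w_j (x-mu)(x-mu)' / sum_j w_j
    ee <- eigen(Cl, symmetric = TRUE, only.values = TRUE)$values
    if (min(ee) < reg) { Cl <- Cl + diag(reg, d); n_reg <- n_reg + 1L }
    # Silverman-rule scaling of the localised covariance on the effective
    # localisation count
    H[[i]] <- Cl * (4 / (d + 2))^(2 / (d + 4)) * max(neff, 2)^(-2 / (d + 4))
  }
  if (n_reg > 0)
    message(n_reg, " singular local covariances regularised by diagonal loading")

  # KDE: every sample uses the bandwidth of its Voronoi grid centre
  f <- numeric(ng)
  for (c in which(wcount > 0L)) {
    U <- chol(H[[c]])
    ld <- 2 * sum(log(diag(U)))
    Xc <- x[assign == c, , drop = FALSE] %*% backsolve(U, diag(d))
    Gt <- grid %*% backsolve(U, diag(d))
    d2 <- outer(rowSums(Gt^2), rowSums(Xc^2), "+") - 2 * tcrossprod(Gt, Xc)
    f <- f + rowSums(exp(-0.5 * pmax(d2, 0))) *
      exp(-0.5 * (d * log(2 * pi) + ld))
  }
  f <- f / n
  # statistical error of log f: 1/sqrt(effective kernel-weighted sample count)
  neff_k <- n * f * (2 * pi)^(d / 2) *
    vapply(H, function(h) sqrt(max(det(h), 0)), numeric(1)) / inefficiency
  logerr <- 1 / sqrt(pmax(neff_k, 1))
  norm <- sum(f * wcount / n)
  structure(list(grid = grid, grid_idx = grid_idx, density = f / norm,
                 raw_density = f, logerr = logerr,
                 weight = wcount, assign = assign, H = H, fs = fs,
                 m_loc = m_loc),
            class = "density_grid")
}

#' Assign density modes (quick-shift) and merge insignificant basins
#'
#' Quick-shift ascent on the grid: every grid point links to the nearest
#' higher-density point among its `k` nearest grid neighbours; link-free
#' points are density peaks and their basins the preliminary clusters.
#' Basins are then merged into the neighbouring basin behind their highest
#' saddle when they are outliers - probability mass below
#' `merge_threshold` (default 1%) - or, when `z_merge > 0`, additionally
#' when the peak is not statistically distinguishable from that saddle,
#' i.e. `log f_peak - log f_saddle < z_merge * sqrt(err_peak^2 +
#' err_saddle^2)`, with the per-point statistical error of the KDE
#' log-density taken from the effective kernel sample count. Saddles are
#' the highest `min(f_i, f_j)` over neighbour-graph edges joining two
#' basins.
#'
#' @param grid a `density_grid` from [kde_on_grid()].
#' @param merge_threshold outlier-basin probability mass threshold.
#' @param z_merge optional significance (in standard errors) a peak must
#'   rise above its saddle to survive as its own cluster; 0 (default)
#'   disables the significance filter.
#' @param k number of nearest grid neighbours in the ascent graph;
#'   default `max(16, ngrid/50)`.
#' @return object of class `cluster_model`: `K`, `grid_labels` (1..K per
#'   grid point), `peaks` (grid row index of each cluster mode), `grid`
#'   (the `density_grid`), `merge_threshold`, `z_merge`.
#' @export
assign_modes <- function(grid, merge_threshold = 0.01, z_merge = 0, k = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  g <- grid$grid
  f <- grid$density
  ng <- nrow(g)
  if (is.null(k)) k <- max(16L, ceiling(ng / 50))
  k <- min(k, ng - 1L)

  gsq <- rowSums(g^2)
  d2 <- outer(gsq, gsq, "+") - 2 * tcrossprod(g)
  diag(d2) <- Inf

  parent <- integer(ng)
  nbr <- matrix(0L, ng, k)
  for (i in seq_len(ng)) {
    ord <- order(d2[i, ])[seq_len(k)]
    nbr[i, ] <- ord
    higher <- ord[f[ord] > f[i]]
    parent[i] <- if (length(higher)) higher[which.min(d2[i, higher])] else 0L
  }
  # follow links to roots
  root <- integer(ng)
  for (i in seq_len(ng)) {
    j <- i
    while (parent[j] != 0L) j <- parent[j]
    root[i] <- j
  }
  peaks <- sort(unique(root))
  lab <- match(root, peaks)
  K <- length(peaks)

  fraw <- grid$raw_density
  err <- grid$logerr
  mass <- function(lab, K) {
    m <- numeric(K)
    t <- tapply(grid$weight, lab, sum)
    m[as.integer(names(t))] <- t / sum(grid$weight)
    m
  }
  # neighbour-graph edge list, built once; saddles are recomputed per
  # merge round by vectorised grouping over edges
  e_i <- rep(seq_len(ng), times = k)
  e_j <- as.vector(nbr)
  e_f <- pmin(fraw[e_i], fraw[e_j])
  e_pt <- ifelse(fraw[e_i] < fraw[e_j], e_i, e_j) # lower endpoint = saddle pt

  # iterative merging of outlier / insignificant basins
  repeat {
    lab <- match(lab, sort(unique(lab)))
    K <- max(lab)
    peaks <- vapply(seq_len(K), function(c) {
      idx <- which(lab == c); idx[which.max(f[idx])]
    }, integer(1))
    if (K == 1L) break
    la <- lab[e_i]; lb <- lab[e_j]
    cross <- which(la != lb)
    sad <- matrix(0, K, K)
    sadpt <- matrix(0L, K, K)
    if (length(cross)) {
      cr <- cross[order(e_f[cross])] # ascending saddle height
      a <- pmin(la[cr], lb[cr]); b <- pmax(la[cr], lb[cr])
      sad[cbind(a, b)] <- e_f[cr]   # later (higher) writes win
      sadpt[cbind(a, b)] <- e_pt[cr]
      sad[lower.tri(sad)] <- t(sad)[lower.tri(sad)]
      sadpt[lower.tri(sadpt)] <- t(sadpt)[lower.tri(sadpt)]
    }
    m <- mass(lab, K)
    pk <- fraw[peaks]
    sad_max <- apply(sad, 1, max)
    tgt_of <- max.col(sad, ties.method = "first")
    spt <- sadpt[cbind(seq_len(K), tgt_of)]
    zval <- ifelse(sad_max > 0 & spt > 0,
                   (log(pk) - log(sad_max)) /
                     sqrt(err[peaks]^2 + err[pmax(spt, 1L)]^2),
                   Inf)
    if (z_merge <= 0) zval[] <- Inf
    insig <- which((zval < z_merge | m < merge_threshold) & sad_max > 0)
    insig <- setdiff(insig, which.max(pk)) # never merge the dominant mode
    if (length(insig) == 0L) break
    b <- if (any(is.finite(zval[insig]))) insig[which.min(zval[insig])]
         else insig[which.min(m[insig])]
    lab[lab == b] <- tgt_of[b]
  }
  lab <- match(lab, sort(unique(lab)))
  K <- max(lab)
  peaks <- vapply(seq_len(K), function(c) {
    idx <- which(lab == c); idx[which.max(f[idx])]
  }, integer(1))
  # order clusters by decreasing population mass for stable reporting
  ord <- order(-mass(lab, K))
  relab <- match(lab, ord)
  structure(list(K = K, grid_labels = relab, peaks = peaks[ord],
                 grid = grid, merge_threshold = merge_threshold,
                 z_merge = z_merge, k = k),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("PAMM cluster model: K = %d (ngrid = %d, fs = %.3g, merge = %.3g)\n",
              x$K, nrow(x$grid$grid), x$grid$fs, x$merge_threshold))
  invisible(x)
}

#' Classify points with a fitted cluster model
#'
#' Each point inherits the cluster of its nearest grid point (ties broken
#' by the lowest grid index).
#'
#' @param model a `cluster_model`.
#' @param x points to classify (matrix or `embedded_dataset`).
#' @return integer vector of cluster labels in 1..K.
#' @export
classify_points <- function(model, x) {
  if (inherits(x, "embedded_dataset")) x <- x$Y
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(model$grid$grid))
  if (ncol(x) != ncol(model$grid$grid)) stop("dimension mismatch with the cluster model")
  model$grid_labels[.nearest_grid(x, model$grid$grid)]
}

#' PAMM clustering pipeline
#'
#' Farthest-point grid, adaptive KDE, quick-shift mode assignment and
#' classification of every input point, in one call.
#'
#' @param x data matrix or `embedded_dataset`.
#' @param ngrid grid size.
#' @param fs kernel localisation scaling.
#' @param merge_threshold outlier-basin mass threshold.
#' @param z_merge saddle-significance threshold (standard errors).
#' @param seed seed for the farthest-point start.
#' @param k quick-shift neighbour count (default `max(16, ngrid/50)`).
#' @param inefficiency statistical inefficiency of the samples; `NULL`
#'   (default) estimates it with [statistical_inefficiency()] when time
#'   metadata is available, else 1 (i.i.d. samples).
#' @return list with `model` (`cluster_model`), `labels` (per input row),
#'   and `grid` (`density_grid`).
#' @export
pamm_cluster <- function(x, ngrid = 1500L, fs = 0.1, merge_threshold = 0.01,
                         z_merge = 0, seed = 1L, k = NULL,
                         inefficiency = NULL) {
  meta <- if (inherits(x, "embedded_dataset")) x$meta else NULL
  if (is.null(inefficiency)) {
    inefficiency <- if (inherits(x, "embedded_dataset") && !is.null(meta) &&
                          all(c("frame", "center") %in% names(meta)))
      statistical_inefficiency(x) else 1
  }
  if (inherits(x, "embedded_dataset")) x <- x$Y
  ngrid <- min(ngrid, nrow(x))
  gi <- farthest_point_sampling(x, ngrid, seed = seed)
  dg <- kde_on_grid(x, gi, fs = fs, inefficiency = inefficiency)
  model <- assign_modes(dg, merge_threshold = merge_threshold,
                        z_merge = z_merge, k = k)
  labels <- model$grid_labels[dg$assign]
  list(model = model, labels = labels, grid = dg, meta = meta)
}
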