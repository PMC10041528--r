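#' SOAP descriptor parameters
#'
#' Parameters of the Smooth Overlap of Atomic Positions power-spectrum
#' descriptor used on surfactant head centres. The defaults
#' (`n_max = 8`, `l_max = 8`, single species channel) give the
#' 324-component vector used throughout the micelle analysis.
#'
#' The neighbour density is a sum of Gaussians of width `sigma_atom`
#' centred on the neighbouring head positions (the centre itself is not
#' counted), expanded on `n_max` Loewdin-orthonormalised spherical
#' Gaussian-type radial functions times real spherical harmonics up to
#' degree `l_max`. With `species_policy = "single_channel"` all heads feed
#' one density channel regardless of species, matching the agnostic,
#' unsupervised character of the analysis; `"per_species"` keeps one
#' channel per species and crossed channel blocks.
#'
#' @param r_cut neighbour cutoff radius in `units`; default 3 nm = 30
#'   Angstrom, the micelle-scale setting.
#' @param n_max number of radial basis functions (>= 1).
#' @param l_max maximum spherical-harmonic degree (>= 0).
#' @param sigma_atom Gaussian smearing width of the neighbour density in
#'   `units`; default 0.35 nm = 3.5 Angstrom.
#' @param species_policy `"single_channel"` or `"per_species"`.
#' @param normalize logical; L2-normalise each power spectrum row.
#' @param units `"nm"` or `"angstrom"`; lengths are converted to nm
#'   internally.
#' @return object of class `soap_params`.
#' @examples
#' p <- soap_params(r_cut = 30, units = "angstrom")
#' soap_dim(p) # 324
#' @export
soap_params <- function(r_cut = NULL, n_max = 8L, l_max = 8L, sigma_atom = NULL,
                        species_policy = c("single_channel", "per_species"),
                        normalize = FALSE, units = c("nm", "angstrom")) {
  species_policy <- match.arg(species_policy)
  units <- match.arg(units)
  scale <- if (units == "angstrom") 0.1 else 1
  r_cut <- if (is.null(r_cut)) 3.0 else r_cut * scale
  sigma_atom <- if (is.null(sigma_atom)) 0.35 else sigma_atom * scale
  stopifnot(r_cut > 0, n_max >= 1, l_max >= 0, sigma_atom > 0)
  structure(list(r_cut = r_cut, n_max = as.integer(n_max),
                 l_max = as.integer(l_max), sigma_atom = sigma_atom,
                 species_policy = species_policy, normalize = normalize),
            class = "soap_params")
}

#' Length of the SOAP power-spectrum vector
#'
#' `D = (l_max + 1) * S * n_max * (S * n_max + 1) / 2` for `S` species
#' channels (non-redundant `n <= n'` pairs per degree `l`).
#'
#' @param params a [soap_params()].
#' @param n_species number of species present (ignored for the
#'   single-channel policy).
#' @return integer descriptor dimension.
#' @export
soap_dim <- function(params, n_species = 1L) {
  S <- if (params$species_policy == "single_channel") 1L else as.integer(n_species)
  t <- S * params$n_max
  as.integer((params$l_max + 1L) * t * (t + 1L) / 2L)
}

# ---- radial machinery -------------------------------------------------------

# GTO decay rates: basis k decays to 1e-3 at r_cut * k / n_max
.soap_alphas <- function(params) {
  rk <- params$r_cut * seq_len(params$n_max) / params$n_max
  -log(1e-3) / rk^2
}

# Loewdin orthonormalisation weights W (g_n = sum_k W[n,k] exp(-alpha_k r^2))
.soap_lowdin <- function(alphas) {
  p <- outer(alphas, alphas, "+")
  S <- 0.25 * sqrt(pi / p^3) # int_0^inf r^2 exp(-p r^2) dr
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), length(alphas)) %*% t(e$vectors)
}

# exp(-x) * i_l(x), modified spherical Bessel of the first kind, stable form
.isph_scaled <- function(x, l) {
  out <- numeric(length(x))
  small <- x < 1e-10
  if (any(!small))
    out[!small] <- besselI(x[!small], l + 0.5, expon.scaled = TRUE) *
      sqrt(pi / (2 * x[!small]))
  if (any(small)) out[small] <- if (l == 0L) exp(-x[small]) else 0
  out
}

# Radial integral table I_nl(R) on a fine R grid.
# c_nlm = sum_j Y_lm(u_j) I_nl(R_j) with
# I_nl(R) = 4 pi sum_k W[n,k] int r^2 g_k(r) exp(-a (r^2 + R^2)) i_l(2 a R r) dr,
# evaluated with the exp-scaled Bessel to avoid overflow.
.soap_table <- function(params) {
  key <- paste0("soap:", paste(unlist(params[c("r_cut", "n_max", "l_max", "sigma_atom")]),
                               collapse = "_"))
  if (!is.null(.mm_cache[[key]])) return(.mm_cache[[key]])

  a <- 1 / (2 * params$sigma_atom^2)
  alphas <- .soap_alphas(params)
  W <- .soap_lowdin(alphas)
  rmax <- params$r_cut + 4 * params$sigma_atom
  nq <- 200L
  gl <- pracma::gaussLegendre(nq, 0, rmax)
  rq <- gl$x; wq <- gl$w
  nR <- 1201L
  Rg <- seq(0, params$r_cut, length.out = nR)

  X <- 2 * a * outer(Rg, rq)                            # bessel argument
  E <- exp(-a * outer(Rg, rq, "-")^2) *
    matrix(wq * rq^2, nR, nq, byrow = TRUE)             # envelope * quadrature
  G <- exp(-outer(rq^2, alphas))                        # nq x n_max primitives

  TW <- matrix(0, nR, params$n_max * (params$l_max + 1L))
  for (l in 0:params$l_max) {
    Il <- matrix(.isph_scaled(as.vector(X), l), nR, nq)
    Tl <- (E * Il) %*% G                                # nR x n_max (primitives)
    TW[, l * params$n_max + seq_len(params$n_max)] <- 4 * pi * (Tl %*% t(W))
  }
  tab <- list(Rgrid = Rg, TW = TW, nR = nR)
  .mm_cache[[key]] <- tab
  tab
}

# ---- real spherical harmonics ----------------------------------------------

# Real spherical harmonics for unit vectors u (n x 3), all (l, m) up to lmax.
# Column order: l blocks, within a block m = -l..-1 (sine), 0, 1..l (cosine);
# column index = l^2 + l + m + 1.
.real_sph_harm <- function(u, lmax) {
  n <- nrow(u)
  ct <- u[, 3]
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- atan2(u[, 2], u[, 1])
  ncol_tot <- (lmax + 1L)^2
  Y <- matrix(0, n, ncol_tot)

  # associated Legendre P_l^m(ct) (no Condon-Shortley), upward recurrences
  P <- vector("list", lmax + 1L)
  for (l in 0:lmax) P[[l + 1L]] <- matrix(0, n, l + 1L)
  P[[1L]][, 1L] <- 1
  if (lmax >= 1) {
    for (m in 1:lmax) {
      # P_m^m = (2m-1)!! st^m
      P[[m + 1L]][, m + 1L] <- prod(seq(1, 2 * m - 1, by = 2)) * st^m
    }
    for (m in 0:(lmax - 1)) {
      P[[m + 2L]][, m + 1L] <- (2 * m + 1) * ct * P[[m + 1L]][, m + 1L]
      if (m + 2L <= lmax) {
        for (l in (m + 2L):lmax) {
          P[[l + 1L]][, m + 1L] <-
            ((2 * l - 1) * ct * P[[l]][, m + 1L] -
               (l + m - 1) * P[[l - 1L]][, m + 1L]) / (l - m)
        }
      }
    }
  }
  for (l in 0:lmax) {
    base <- l^2 + l + 1L
    Y[, base] <- sqrt((2 * l + 1) / (4 * pi)) * P[[l + 1L]][, 1L]
    if (l >= 1) {
      for (m in 1:l) {
        nlm <- sqrt((2 * l + 1) / (4 * pi) *
                      exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
        Y[, base + m] <- sqrt(2) * nlm * P[[l + 1L]][, m + 1L] * cos(m * phi)
        Y[, base - m] <- sqrt(2) * nlm * P[[l + 1L]][, m + 1L] * sin(m * phi)
      }
    }
  }
  Y
}

# ---- per-centre coefficients and spectra ------------------------------------

#' Density expansion coefficients around one centre
#'
#' Expands the Gaussian-smeared density of the neighbours (positions given
#' relative to the centre, which does not count itself) on the orthonormal
#' radial basis times real spherical harmonics. Neighbours at or beyond
#' `r_cut`, and any point closer than 1e-8 to the centre, are dropped.
#'
#' @param neighbors M x 3 matrix of neighbour positions relative to the
#'   centre (nm, already minimum-imaged).
#' @param params a [soap_params()].
#' @param species optional per-neighbour species labels (used by the
#'   `per_species` policy).
#' @return object of class `soap_coeffs`: list with `c` - per channel, a
#'   list over `l = 0..l_max` of `n_max x (2l+1)` coefficient matrices -
#'   plus `channels` and `params`.
#' @export
density_expansion_coefficients <- function(neighbors, params, species = NULL) {
  if (is.null(dim(neighbors))) neighbors <- matrix(neighbors, ncol = 3)
  tab <- .soap_table(params)
  R <- sqrt(rowSums(neighbors^2))
  keep <- R > 1e-8 & R < params$r_cut
  neighbors <- neighbors[keep, , drop = FALSE]
  R <- R[keep]
  if (params$species_policy == "per_species") {
    if (is.null(species)) stop("per_species policy requires neighbour species labels")
    species <- as.character(species)[keep]
    channels <- sort(unique(species))
    if (length(channels) == 0L) channels <- "X"
  } else {
    channels <- "all"
    species <- rep("all", length(R))
  }
  nmax <- params$n_max; lmax <- params$l_max

  empty <- lapply(0:lmax, function(l) matrix(0, nmax, 2 * l + 1))
  cc <- setNames(rep(list(empty), length(channels)), channels)

  if (length(R) > 0L) {
    u <- neighbors / R
    Y <- .real_sph_harm(u, lmax)
    # linear interpolation of the radial-integral table at the neighbour radii
    pos <- R / params$r_cut * (tab$nR - 1L) + 1
    i0 <- pmin(floor(pos), tab$nR - 1L)
    w <- pos - i0
    IW <- tab$TW[i0, , drop = FALSE] * (1 - w) + tab$TW[i0 + 1L, , drop = FALSE] * w
    for (ch in channels) {
      sel <- species == ch
      if (!any(sel)) next
      for (l in 0:lmax) {
        Il <- IW[sel, l * nmax + seq_len(nmax), drop = FALSE]
        Yl <- Y[sel, l^2 + seq_len(2 * l + 1), drop = FALSE]
        cc[[ch]][[l + 1L]] <- crossprod(Il, Yl)
      }
    }
  }
  structure(list(c = cc, channels = channels, params = params),
            class = "soap_coeffs")
}

#' SOAP partial power spectrum from expansion coefficients
#'
#' \eqn{p_{nn'l}^{Z_1 Z_2} = \pi \sqrt{8/(2l+1)} \sum_m c_{nlm}^{Z_1}
#' c_{n'lm}^{Z_2}}, keeping the non-redundant upper triangle over the
#' combined (channel, n) index with a sqrt(2) factor on off-diagonal pairs
#' (norm-preserving compression). Element order: degree `l` outermost, then
#' column-major upper-triangle pairs.
#'
#' @param coeffs a `soap_coeffs` object.
#' @return numeric power-spectrum vector.
#' @export
power_spectrum <- function(coeffs) {
  if (!inherits(coeffs, "soap_coeffs")) stop("coeffs must be a soap_coeffs object")
  params <- coeffs$params
  nmax <- params$n_max; lmax <- params$l_max
  S <- length(coeffs$channels)
  t <- S * nmax
  ut <- upper.tri(matrix(0, t, t), diag = TRUE)
  mult <- matrix(sqrt(2), t, t); diag(mult) <- 1
  out <- numeric((lmax + 1L) * t * (t + 1L) / 2L)
  k <- 0L
  npair <- t * (t + 1L) / 2L
  for (l in 0:lmax) {
    C <- do.call(rbind, lapply(coeffs$c, function(ch) ch[[l + 1L]]))
    P <- pi * sqrt(8 / (2 * l + 1)) * tcrossprod(C)
    out[k + seq_len(npair)] <- (P * mult)[ut]
    k <- k + npair
  }
  if (params$normalize) {
    nrm <- sqrt(sum(out^2))
    if (nrm > 0) out <- out / nrm
  }
  out
}

#' SOAP spectrum of a single neighbourhood
#'
#' Convenience wrapper: [density_expansion_coefficients()] followed by
#' [power_spectrum()].
#'
#' @inheritParams density_expansion_coefficients
#' @return numeric power-spectrum vector.
#' @export
soap_power_spectrum <- function(neighbors, params, species = NULL) {
  power_spectrum(density_expansion_coefficients(neighbors, params, species))
}

# spectra for all centres of one frame; centres are both the SOAP centres
# and the density sources (heads describing heads)
.soap_frame <- function(centers, box, params, species = NULL) {
  M <- nrow(centers)
  n_sp <- if (params$species_policy == "per_species") length(unique(species)) else 1L
  D <- soap_dim(params, n_sp)
  out <- matrix(0, M, D)
  dx <- outer(centers[, 1], centers[, 1], "-")
  dy <- outer(centers[, 2], centers[, 2], "-")
  dz <- outer(centers[, 3], centers[, 3], "-")
  if (!is.null(box) && is.finite(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
    dz <- dz - box * round(dz / box)
  }
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  for (i in seq_len(M)) {
    idx <- which(dist[i, ] < params$r_cut & dist[i, ] > 1e-8)
    rel <- cbind(dx[idx, i], dy[idx, i], dz[idx, i]) # neighbour minus centre
    out[i, ] <- soap_power_spectrum(rel, params,
                                    if (is.null(species)) NULL else species[idx])
  }
  out
}

# ---- head centres and datasets ----------------------------------------------

#' Extract surfactant head centres from a trajectory frame
#'
#' One centre per surfactant, the (equal-mass) centre of mass of its head
#' bead group. For the built-in five-bead model the head group is the
#' single bead 0, so centres equal the head bead positions. For external
#' trajectories a head map gives, per molecule, the 0-based head bead
#' indices and the species label.
#'
#' @param traj an `mcg_trajectory` (or anything with `frames`, `mol_id`,
#'   `role`, `species`).
#' @param frame frame index (1-based).
#' @param head_map optional data.frame with columns `molecule` (1-based id),
#'   `species`, `heads` (0-based indices within the molecule, ";"-separated).
#' @return list with `centers` (M x 3 matrix, nm) and `species` (length M).
#' @export
extract_head_centers <- function(traj, frame = 1L, head_map = NULL) {
  pos <- traj$frames[[frame]]
  if (is.null(head_map)) {
    sel <- which(traj$role == "head")
    mols <- traj$mol_id[sel]
    ord <- order(mols)
    list(centers = pos[sel[ord], , drop = FALSE],
         species = traj$species[mols[ord]])
  } else {
    mol_start <- match(unique(traj$mol_id), traj$mol_id)
    centers <- matrix(NA_real_, nrow(head_map), 3)
    for (i in seq_len(nrow(head_map))) {
      m <- head_map$molecule[i]
      idx0 <- as.integer(strsplit(as.character(head_map$heads[i]), ";")[[1]])
      if (length(idx0) == 0L || anyNA(idx0))
        stop("molecule ", m, " has an empty or invalid head group")
      beads <- mol_start[m] + idx0
      if (any(traj$mol_id[beads] != m)) stop("head indices out of range for molecule ", m)
      centers[i, ] <- colMeans(pos[beads, , drop = FALSE])
    }
    list(centers = centers, species = as.character(head_map$species))
  }
}

#' Build a SOAP dataset from a trajectory
#'
#' Computes the SOAP power spectrum centred on every surfactant head for
#' every selected frame. Rows are ordered frame-major, then centre index.
#'
#' @param traj an `mcg_trajectory` (or read via [read_trajectory()]).
#' @param params a [soap_params()].
#' @param head_map optional head map (see [extract_head_centers()]).
#' @param stride keep every `stride`-th frame.
#' @param window optional numeric `c(t_min, t_max)` time window in ns
#'   (inclusive), applied before `stride`.
#' @return object of class `soap_dataset`: list with `X` (rows x D matrix),
#'   `meta` (data.frame `frame`, `time`, `center`, `species`), `params`,
#'   and bookkeeping (`n_frames_used`, `stride`, `window`).
#' @export
build_soap_dataset <- function(traj, params, head_map = NULL,
                               stride = 1L, window = NULL) {
  nf <- length(traj$frames)
  counts <- vapply(traj$frames, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop("inconsistent particle count across frames")
  idx <- seq_len(nf)
  if (!is.null(window))
    idx <- idx[traj$times >= window[1] & traj$times <= window[2]]
  if (length(idx) == 0L) stop("frame window excludes all frames")
  idx <- idx[seq(1, length(idx), by = stride)]

  first <- extract_head_centers(traj, idx[1], head_map)
  M <- nrow(first$centers)
  n_sp <- if (params$species_policy == "per_species")
    length(unique(first$species)) else 1L
  D <- soap_dim(params, n_sp)
  X <- matrix(NA_real_, length(idx) * M, D)
  for (k in seq_along(idx)) {
    hc <- extract_head_centers(traj, idx[k], head_map)
    X[(k - 1L) * M + seq_len(M), ] <-
      .soap_frame(hc$centers, traj$box, params, hc$species)
  }
  meta <- data.frame(frame = rep(idx, each = M),
                     time = rep(traj$times[idx], each = M),
                     center = rep(seq_len(M), length(idx)),
                     species = rep(first$species, length(idx)),
                     stringsAsFactors = FALSE)
  structure(list(X = X, meta = meta, params = params,
                 n_frames_used = length(idx), stride = stride, window = window),
            class = "soap_dataset")
}

#' @export
print.soap_dataset <- function(x, ...) {
  cat(sprintf("SOAP dataset: %d rows (%d frames x %d centers), D = %d\n",
              nrow(x$X), x$n_frames_used, nrow(x$X) / x$n_frames_used, ncol(x$X)))
  invisible(x)
}
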