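.wrap_diff <- function(d, L) d - L * round(d / L)

#' Radial distribution function around a per-frame reference point
#'
#' Distance histogram from a single reference point per frame (e.g. the
#' micelle-core centre of mass) to a set of positions (e.g. surfactant
#' heads), normalised by shell volume and by the mean number density of the
#' selection in the box, averaged over frames. A uniform (ideal-gas)
#' selection therefore gives g(r) = 1.
#'
#' @param heads list of M x 3 position matrices (one per frame) or a single
#'   matrix.
#' @param core_reference per-frame reference point: frames x 3 matrix or a
#'   single length-3 vector.
#' @param box cubic box edge (nm); minimum-image convention applied.
#' @param breaks bin edges (nm); default 60 bins over (0, box/2).
#' @return object of class `rdf_result`: data.frame `r` (bin centres),
#'   `g`; plus `bin_width`, `n_frames`.
#' @export
radial_distribution <- function(heads, core_reference, box, breaks = NULL) {
  if (is.matrix(heads)) heads <- list(heads)
  if (is.null(dim(core_reference)))
    core_reference <- matrix(core_reference, length(heads), 3, byrow = TRUE)
  if (length(heads) == 0L || nrow(heads[[1]]) == 0L) stop("empty selection")
  if (is.null(breaks)) breaks <- seq(0, box / 2, length.out = 61)
  nb <- length(breaks) - 1L
  counts <- numeric(nb)
  M <- nrow(heads[[1]])
  for (k in seq_along(heads)) {
    d <- sqrt(rowSums(.wrap_diff(sweep(heads[[k]], 2, core_reference[k, ]), box)^2))
    h <- hist(d[d < max(breaks)], breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  counts <- counts / length(heads)
  vol <- 4 / 3 * pi * diff(breaks^3)
  rho <- M / box^3
  g <- counts / (vol * rho)
  structure(list(df = data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
                                 g = g),
                 bin_width = diff(breaks)[1], n_frames = length(heads)),
            class = "rdf_result")
}

#' Mean head contacts per surfactant couple
#'
#' Mean over frames of the number of A-B head pairs closer than `cutoff`
#' (minimum image), divided by the number of A-B couples.
#'
#' @param headsA,headsB lists of per-frame position matrices (or single
#'   matrices) of the two disjoint selections.
#' @param cutoff contact cutoff, nm (default 0.8 nm between head beads).
#' @param box cubic box edge, nm.
#' @return mean contacts per couple per frame (scalar).
#' @export
contact_count <- function(headsA, headsB, cutoff = 0.8, box) {
  if (is.matrix(headsA)) headsA <- list(headsA)
  if (is.matrix(headsB)) headsB <- list(headsB)
  stopifnot(length(headsA) == length(headsB))
  nA <- nrow(headsA[[1]]); nB <- nrow(headsB[[1]])
  if (nA * nB == 0L) stop("zero A-B couples")
  tot <- 0
  for (k in seq_along(headsA)) {
    dx <- .wrap_diff(outer(headsA[[k]][, 1], headsB[[k]][, 1], "-"), box)
    dy <- .wrap_diff(outer(headsA[[k]][, 2], headsB[[k]][, 2], "-"), box)
    dz <- .wrap_diff(outer(headsA[[k]][, 3], headsB[[k]][, 3], "-"), box)
    tot <- tot + sum(dx^2 + dy^2 + dz^2 < cutoff^2)
  }
  tot / (length(headsA) * nA * nB)
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_i m_i |r_i - r_{COM}|^2 / \sum_i m_i}}. Positions
#' must already be unwrapped across periodic boundaries (see
#' [unwrap_aggregate()]); when `box` is given, an aggregate spanning half
#' the box in any direction triggers an unwrap-first error.
#'
#' @param positions N x 3 matrix (nm).
#' @param masses per-particle masses (default equal).
#' @param box optional box edge for the wrapped-aggregate check.
#' @return gyration radius, nm.
#' @export
gyration_radius <- function(positions, masses = NULL, box = NULL) {
  stopifnot(is.matrix(positions), nrow(positions) >= 2)
  if (!is.null(box) &&
      any(apply(positions, 2, function(v) diff(range(v))) >= box / 2))
    stop("aggregate appears wrapped across the box; unwrap first")
  if (is.null(masses)) masses <- rep(1, nrow(positions))
  com <- colSums(positions * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(positions, 2, com)^2)) / sum(masses))
}

#' Unwrap an aggregate across periodic boundaries
#'
#' First unwraps each molecule by walking its bond graph (breadth-first)
#' under the minimum-image convention, then shifts every molecule by the
#' minimum image of its first bead relative to the first molecule. Valid
#' for aggregates smaller than half the box.
#'
#' @param positions N x 3 wrapped positions (nm).
#' @param bonds 2-column matrix of bonded bead pairs (1-based).
#' @param mol_id per-bead molecule id.
#' @param box cubic box edge (nm).
#' @return N x 3 unwrapped positions.
#' @export
unwrap_aggregate <- function(positions, bonds, mol_id, box) {
  pos <- positions
  adj <- vector("list", nrow(pos))
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  for (m in unique(mol_id)) {
    beads <- which(mol_id == m)
    seen <- logical(length(beads))
    names(seen) <- beads
    queue <- beads[1]
    seen[as.character(beads[1])] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj[[i]]) {
        if (!seen[as.character(j)]) {
          pos[j, ] <- pos[i, ] + .wrap_diff(pos[j, ] - pos[i, ], box)
          seen[as.character(j)] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  ref <- pos[which(mol_id == mol_id[1])[1], ]
  for (m in unique(mol_id)) {
    beads <- which(mol_id == m)
    shift <- .wrap_diff(pos[beads[1], ] - ref, box) - (pos[beads[1], ] - ref)
    pos[beads, ] <- sweep(pos[beads, , drop = FALSE], 2, shift, "+")
  }
  pos
}

#' Connected components of a distance graph
#'
#' Labels positions by the connected component of the graph joining pairs
#' closer than `cutoff` under minimum image; used, e.g., to check that a
#' micelle remains a single aggregate (head-distance graph, 1.2 nm cutoff).
#'
#' @param positions N x 3 matrix.
#' @param cutoff linking distance, nm.
#' @param box cubic box edge, nm.
#' @return integer component labels (1-based).
#' @export
aggregate_components <- function(positions, cutoff, box) {
  n <- nrow(positions)
  dx <- .wrap_diff(outer(positions[, 1], positions[, 1], "-"), box)
  dy <- .wrap_diff(outer(positions[, 2], positions[, 2], "-"), box)
  dz <- .wrap_diff(outer(positions[, 3], positions[, 3], "-"), box)
  adj <- (dx^2 + dy^2 + dz^2) < cutoff^2
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(adj[i, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Head-to-core RDF of an mCG trajectory
#'
#' Convenience wrapper computing [radial_distribution()] between the head
#' beads of one species and the per-frame centre of mass of all tail beads
#' (the micelle core).
#'
#' @param traj an `mcg_trajectory`.
#' @param species which head species to select (`"R"`, `"B"`, or `"all"`).
#' @param breaks bin edges (nm).
#' @return an `rdf_result`.
#' @export
rdf_head_core <- function(traj, species = "all", breaks = NULL) {
  sel_sp <- if (identical(species, "all")) unique(traj$species) else species
  head_idx <- which(traj$role == "head" & traj$species[traj$mol_id] %in% sel_sp)
  tail_idx <- which(traj$role != "head")
  heads <- lapply(traj$frames, function(p) p[head_idx, , drop = FALSE])
  core <- t(vapply(traj$frames, function(p) {
    up <- unwrap_aggregate(p, traj$bonds, traj$mol_id, traj$box)
    colMeans(up[tail_idx, , drop = FALSE]) %% traj$box
  }, numeric(3)))
  radial_distribution(heads, core, traj$box, breaks)
}
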