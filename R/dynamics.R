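#' Cluster label time series
#'
#' Arranges per-(frame, surfactant) cluster labels into the
#' frames x surfactants matrix that the interconversion analysis consumes.
#' Typically built from [pamm_cluster()] output, whose `meta` carries the
#' frame/centre/species bookkeeping of the SOAP dataset.
#'
#' @param labels integer cluster labels (1..K), one per (frame, centre) row.
#' @param meta data.frame with `frame`, `time`, `center`, `species` aligned
#'   with `labels` (as in a `soap_dataset`).
#' @param K number of clusters (default `max(labels)`).
#' @return object of class `label_series`: `labels` (frames x surfactants
#'   matrix), `times` (ns), `species` (per surfactant), `K`, `dt` (ns, lag
#'   between consecutive frames).
#' @export
label_series <- function(labels, meta, K = max(labels)) {
  stopifnot(length(labels) == nrow(meta))
  frames <- sort(unique(meta$frame))
  centers <- sort(unique(meta$center))
  mat <- matrix(NA_integer_, length(frames), length(centers))
  mat[cbind(match(meta$frame, frames), match(meta$center, centers))] <- labels
  if (anyNA(mat)) stop("incomplete label series: missing (frame, centre) cells")
  times <- meta$time[match(frames, meta$frame)]
  species <- meta$species[match(centers, meta$center)]
  dt <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  structure(list(labels = mat, times = times, species = species,
                 K = as.integer(K), dt = dt),
            class = "label_series")
}

.as_label_matrix <- function(series) {
  if (inherits(series, "label_series")) series$labels
  else as.matrix(series)
}

#' Transition counts between clusters
#'
#' `counts[i, j]` = number of (surfactant, consecutive-frame) events with
#' label `i` at `t` and `j` at `t + dt`; the diagonal counts residence
#' events. Total events = `n_surfactants * (n_frames - 1)`.
#'
#' @param series a `label_series` or a frames x surfactants label matrix.
#' @param K number of clusters.
#' @return K x K integer count matrix.
#' @export
transition_counts <- function(series, K = NULL) {
  m <- .as_label_matrix(series)
  if (is.null(K)) K <- if (inherits(series, "label_series")) series$K else max(m)
  if (nrow(m) < 2) stop("need at least 2 frames to count transitions")
  from <- m[-nrow(m), , drop = FALSE]
  to <- m[-1, , drop = FALSE]
  counts <- matrix(0L, K, K)
  t <- table(factor(from, levels = seq_len(K)), factor(to, levels = seq_len(K)))
  counts[] <- as.integer(t)
  counts
}

#' Conditional transition probability matrix
#'
#' Row-normalised counts: `P[i, j] = counts[i, j] / sum_j counts[i, j]`.
#' Rows with no outgoing events are returned as `NA` (never silently zero)
#' and reported via the `undefined_rows` attribute.
#'
#' @param counts K x K count matrix from [transition_counts()].
#' @return row-stochastic K x K matrix (defined rows sum to 1).
#' @export
conditional_transition_matrix <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts), length(counts) > 0)
  rs <- rowSums(counts)
  P <- counts / rs
  P[rs == 0, ] <- NA_real_
  attr(P, "undefined_rows") <- which(rs == 0)
  P
}

#' Cluster population percentages
#'
#' Fraction of all (frame, surfactant) cells belonging to each cluster,
#' i.e. the cluster distribution averaged along the analysed trajectory,
#' times 100.
#'
#' @inheritParams transition_counts
#' @return numeric vector of length K summing to 100.
#' @export
populations <- function(series, K = NULL) {
  m <- .as_label_matrix(series)
  if (is.null(K)) K <- if (inherits(series, "label_series")) series$K else max(m)
  100 * tabulate(m, nbins = K) / length(m)
}

#' Species composition of each cluster
#'
#' For each cluster, the percentage of its (frame, surfactant) member cells
#' contributed by each species, averaged over the analysed frames.
#'
#' @param series a `label_series` (species labels required).
#' @param species optional per-surfactant species vector when `series` is a
#'   plain matrix.
#' @return K x n_species matrix of percentages; rows sum to 100 (NA for
#'   empty clusters).
#' @export
cluster_composition <- function(series, species = NULL) {
  m <- .as_label_matrix(series)
  if (inherits(series, "label_series")) {
    species <- series$species
    K <- series$K
  } else {
    if (is.null(species)) stop("species labels required")
    K <- max(m)
  }
  if (length(species) != ncol(m)) stop("one species label per surfactant required")
  if (anyNA(species)) stop("unknown species label")
  sp_levels <- sort(unique(species))
  spm <- matrix(rep(species, each = nrow(m)), nrow(m), ncol(m))
  t <- table(factor(m, levels = seq_len(K)),
             factor(spm, levels = sp_levels))
  comp <- 100 * t / pmax(rowSums(t), 1)
  comp <- matrix(as.numeric(comp), K, length(sp_levels),
                 dimnames = list(cluster = seq_len(K), species = sp_levels))
  comp[rowSums(t) == 0, ] <- NA_real_
  comp
}

#' Build an interconversion diagram
#'
#' Bundles the population percentages, the conditional transition matrix
#' (at the series lag d*t*), the per-cluster species composition and the
#' raw transition counts, plus a per-pair stationary-flux imbalance
#' diagnostic `|pi_i P_ij - pi_j P_ji|` (reported, not asserted).
#'
#' @param series a `label_series`.
#' @return object of class `interconversion_diagram`.
#' @export
build_interconversion_diagram <- function(series) {
  stopifnot(inherits(series, "label_series"))
  counts <- transition_counts(series)
  P <- conditional_transition_matrix(counts)
  pop <- populations(series)
  comp <- cluster_composition(series)
  pi <- pop / 100
  flux <- abs(outer(pi, rep(1, series$K)) * P -
                t(outer(pi, rep(1, series$K)) * P))
  structure(list(populations = pop, transition_matrix = P,
                 composition = comp, counts = counts,
                 flux_imbalance = flux, K = series$K, dt = series$dt,
                 n_events = sum(counts)),
            class = "interconversion_diagram")
}

#' @export
print.interconversion_diagram <- function(x, ...) {
  cat(sprintf("Interconversion diagram: K = %d, lag = %.3g ns, %d events\n",
              x$K, x$dt, x$n_events))
  cat("populations [%]:", paste(sprintf("%.1f", x$populations), collapse = " / "), "\n")
  cat("conditional transition matrix (rows sum to 1):\n")
  print(round(x$transition_matrix, 3))
  cat("composition [% per species]:\n")
  print(round(x$composition, 1))
  invisible(x)
}

#' Serialise an interconversion diagram
#'
#' Writes a machine-readable JSON report and a DOT graph whose nodes carry
#' cluster populations and whose edges carry conditional transition
#' probabilities.
#'
#' @param diagram an `interconversion_diagram`.
#' @param json_file,dot_file output paths (`NULL` to skip either).
#' @param min_prob edges below this probability are omitted from the DOT
#'   graph.
#' @return invisibly, the report list.
#' @export
write_interconversion_diagram <- function(diagram, json_file = NULL,
                                          dot_file = NULL, min_prob = 0.005) {
  rep <- list(K = diagram$K, dt_ns = diagram$dt,
              populations_percent = diagram$populations,
              transition_matrix = diagram$transition_matrix,
              composition_percent = diagram$composition,
              counts = diagram$counts,
              n_events = diagram$n_events)
  if (!is.null(json_file))
    jsonlite::write_json(rep, json_file, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor", na = "null")
  if (!is.null(dot_file)) {
    lines <- c("digraph interconversion {")
    for (i in seq_len(diagram$K))
      lines <- c(lines, sprintf("  C%d [label=\"C%d\\n%.1f%%\"];",
                                i, i, diagram$populations[i]))
    for (i in seq_len(diagram$K)) for (j in seq_len(diagram$K)) {
      p <- diagram$transition_matrix[i, j]
      if (!is.na(p) && p >= min_prob)
        lines <- c(lines, sprintf("  C%d -> C%d [label=\"%.2f\"];", i, j, p))
    }
    lines <- c(lines, "}")
    writeLines(lines, dot_file)
  }
  invisible(rep)
}
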