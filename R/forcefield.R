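#' Lennard-Jones pair table for the minimalistic amphiphile model
#'
#' Builds the symmetric sigma/epsilon tables for the four bead types of the
#' two-species five-bead amphiphile model (`R` head, `B` head, `R` tail,
#' `B` tail). Three interaction regimes are predefined, matching the way the
#' homo- vs hetero-head interactions drive intermixing or segregation of the
#' two species on a micelle surface:
#'
#' * `"mixing"`: `eps_RR = eps_BB = eps_RB = 0.5` kJ/mol,
#' * `"segregating"`: `eps_RR = eps_BB = 4` kJ/mol with `eps_RB = 0.5`,
#' * `"intermediate"`: `eps_RR = 4`, `eps_BB = eps_RB = 0.5` kJ/mol.
#'
#' Tail beads are identical for both species (`sigma = 0.47` nm,
#' `eps = 5` kJ/mol intra- and inter-species), so amphiphilic cohesion is
#' carried by the strong tail-tail attraction of the implicit-solvent
#' model. Head-tail interactions default to the tail well depth
#' (`eps_head_tail = 5` kJ/mol), which keeps the corona compact against
#' the core without inverting it (head-head attraction stays weak); sigma
#' for unlike pairs follows the Lorentz arithmetic-mean rule. Every entry
#' can be overridden, so any published interaction matrix can be loaded
#' verbatim.
#'
#' @param regime one of `"mixing"`, `"segregating"`, `"intermediate"`, or
#'   `"custom"` (then `eps_RR`/`eps_BB` must be given).
#' @param sigma_R,sigma_B head bead diameters (nm). The size-asymmetric
#'   systems use `sigma_R = 0.7`, `sigma_B = 0.47` (ratio 1.49).
#' @param sigma_tail tail bead diameter (nm).
#' @param eps_RR,eps_BB,eps_RB head-head LJ well depths (kJ/mol);
#'   `NULL` entries take the regime defaults.
#' @param eps_tail tail-tail well depth (kJ/mol).
#' @param eps_head_tail head-tail well depth (kJ/mol).
#' @param r_cut truncation/shift radius (nm).
#' @return An object of class `pair_table`: list with `sigma` and `epsilon`
#'   4x4 matrices (bead types `R_head`, `B_head`, `R_tail`, `B_tail`) and
#'   `r_cut`.
#' @examples
#' pt <- mcg_pair_table("segregating")
#' pt$epsilon["R_head", "B_head"] # 0.5
#' @export
mcg_pair_table <- function(regime = c("mixing", "segregating", "intermediate", "custom"),
                           sigma_R = 0.7, sigma_B = 0.7, sigma_tail = 0.47,
                           eps_RR = NULL, eps_BB = NULL, eps_RB = 0.5,
                           eps_tail = 5, eps_head_tail = 5, r_cut = 1.2) {
  regime <- match.arg(regime)
  defaults <- switch(regime,
    mixing       = c(RR = 0.5, BB = 0.5),
    segregating  = c(RR = 4,   BB = 4),
    intermediate = c(RR = 4,   BB = 0.5),
    custom       = c(RR = NA,  BB = NA))
  if (is.null(eps_RR)) eps_RR <- defaults[["RR"]]
  if (is.null(eps_BB)) eps_BB <- defaults[["BB"]]
  stopifnot(is.finite(eps_RR), is.finite(eps_BB), is.finite(eps_RB))
  stopifnot(sigma_R > 0, sigma_B > 0, sigma_tail > 0, r_cut > max(sigma_R, sigma_B, sigma_tail))

  types <- c("R_head", "B_head", "R_tail", "B_tail")
  sig_self <- c(sigma_R, sigma_B, sigma_tail, sigma_tail)
  sigma <- outer(sig_self, sig_self, function(a, b) (a + b) / 2) # Lorentz rule
  dimnames(sigma) <- list(types, types)

  epsilon <- matrix(eps_head_tail, 4, 4, dimnames = list(types, types))
  epsilon["R_head", "R_head"] <- eps_RR
  epsilon["B_head", "B_head"] <- eps_BB
  epsilon["R_head", "B_head"] <- epsilon["B_head", "R_head"] <- eps_RB
  epsilon[3:4, 3:4] <- eps_tail
  stopifnot(all(epsilon >= 0))

  structure(list(sigma = sigma, epsilon = epsilon, r_cut = r_cut,
                 regime = regime, types = types),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("mCG Lennard-Jones pair table (regime:", x$regime, ")\n")
  cat("r_cut:", x$r_cut, "nm\n\nsigma [nm]:\n")
  print(round(x$sigma, 3))
  cat("\nepsilon [kJ/mol]:\n")
  print(round(x$epsilon, 3))
  invisible(x)
}

#' Truncated and shifted Lennard-Jones potential
#'
#' \eqn{u(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] -
#' 4\epsilon[(\sigma/r_c)^{12} - (\sigma/r_c)^6]} for \eqn{r < r_c} and
#' exactly 0 beyond, so the potential is continuous at the cutoff.
#' Vectorised over `r`.
#'
#' @param r distance(s), nm; must be positive.
#' @param sigma LJ diameter, nm.
#' @param epsilon LJ well depth, kJ/mol.
#' @param r_c cutoff, nm.
#' @return potential energy, kJ/mol.
#' @examples
#' lj_truncated_shifted(1.2, 0.7, 0.5, 1.2) # exactly 0 at the cutoff
#' @export
lj_truncated_shifted <- function(r, sigma, epsilon, r_c) {
  if (any(r <= 0)) stop("distance r must be positive")
  sr6 <- (sigma / r)^6
  src6 <- (sigma / r_c)^6
  u <- 4 * epsilon * (sr6^2 - sr6) - 4 * epsilon * (src6^2 - src6)
  u[r >= r_c] <- 0
  u
}
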