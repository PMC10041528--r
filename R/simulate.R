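#' Simulation configuration for the mCG Langevin simulator
#'
#' Collects the run parameters of the implicit-solvent NVT Langevin
#' dynamics. Defaults reproduce the micelle study conditions: cubic
#' 20 nm box, 300 K, 40 fs timestep, friction coupling time 0.1 ps, and
#' harmonic bonds with rest length 0.47 nm and stiffness
#' 1250 kJ mol^-1 nm^-2 (typical constants at this resolution; only the
#' bond functional form is fixed by the model).
#'
#' @param box cubic box edge L, nm; must exceed twice the LJ cutoff.
#' @param temperature target temperature, K.
#' @param dt integration timestep, ps (0.04 ps = 40 fs).
#' @param tau_t friction coupling time, ps; the Langevin friction is
#'   `gamma = 1/tau_t`, mass-independent.
#' @param bond_r0 harmonic bond rest length, nm.
#' @param bond_k harmonic bond stiffness, kJ mol^-1 nm^-2.
#' @param mass bead mass, amu; one value for all beads.
#' @param n_steps number of integration steps for [run_simulation()].
#' @param stride sampling stride, steps.
#' @param seed RNG seed used by [run_simulation()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(box = 20, temperature = 300, dt = 0.04, tau_t = 0.1,
                       bond_r0 = 0.47, bond_k = 1250, mass = 72,
                       n_steps = 25000L, stride = 2500L, seed = 1L) {
  stopifnot(box > 0, temperature >= 0, dt > 0, tau_t > 0,
            bond_r0 > 0, bond_k >= 0, mass > 0, n_steps >= 0, stride >= 0)
  structure(list(box = box, temperature = temperature, dt = dt, tau_t = tau_t,
                 bond_r0 = bond_r0, bond_k = bond_k, mass = mass,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# bead type ids per molecule: head first, then four tail beads
.mol_types <- function(species) {
  if (species == "R") c(1L, 3L, 3L, 3L, 3L) else c(2L, 4L, 4L, 4L, 4L)
}

.bead_roles <- c("head", "tail1", "tail2", "tail3", "tail4")

# evenly distributed unit vectors (Fibonacci sphere)
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a bicomponent five-bead amphiphile system
#'
#' Creates the initial state of `n_R` + `n_B` linear five-bead amphiphiles
#' (one head bead followed by four tail beads at the bond rest length) in a
#' periodic cubic box, with Maxwell-Boltzmann velocities at the configured
#' temperature.
#'
#' Two placement modes are available. `"random_dispersed"` scatters whole
#' molecules uniformly without overlaps, the starting point of a
#' self-assembly run. `"preassembled_micelle"` places all heads on a
#' spherical shell with the tails pointing inward, i.e. an already formed
#' micelle that only needs a short equilibration; this skips the very long
#' self-assembly phase. For the preassembled mode, `arrangement` controls
#' how the two species are distributed on the shell: `"mixed"` assigns
#' species at random, `"janus"` places them on opposite hemispheres
#' (the pre-demixed analogue, useful under segregating interaction regimes
#' whose equilibrium is compartmentalised and whose on-surface demixing is
#' otherwise very slow).
#'
#' @param n_R,n_B number of `R` and `B` molecules (not both zero).
#' @param pairs a [mcg_pair_table()].
#' @param config a [sim_config()].
#' @param mode placement mode, see Details.
#' @param arrangement species arrangement for the preassembled mode.
#' @param shell_radius head shell radius for the preassembled mode, nm;
#'   default scales with molecule count so heads are not overcrowded.
#' @param seed RNG seed.
#' @return object of class `mcg_state`: list with `positions` (N x 3 nm,
#'   wrapped), `velocities` (N x 3 nm/ps), `type` (bead type id 1..4),
#'   `mol_id`, `role`, `species` (per molecule), `bonds` (2-column matrix,
#'   1-based bead indices), `box`, `time` (ns).
#' @export
build_bicomponent_system <- function(n_R, n_B, pairs, config,
                                     mode = c("random_dispersed", "preassembled_micelle"),
                                     arrangement = c("mixed", "janus"),
                                     shell_radius = NULL, seed = config$seed) {
  mode <- match.arg(mode)
  arrangement <- match.arg(arrangement)
  stopifnot(n_R >= 0, n_B >= 0, n_R + n_B > 0)
  set.seed(seed)
  n_mol <- n_R + n_B
  L <- config$box
  r0 <- config$bond_r0
  ctr <- rep(L / 2, 3)

  if (mode == "random_dispersed") {
    species <- sample(rep(c("R", "B"), c(n_R, n_B)))
    pos <- matrix(NA_real_, n_mol * 5, 3)
    placed <- 0L
    for (m in seq_len(n_mol)) {
      ok <- FALSE
      for (attempt in seq_len(5000L)) {
        headp <- runif(3, 0, L)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        cand <- t(headp + outer(dir, 0:4) * r0)
        if (placed > 0L) {
          dmin <- min(.min_image_cross_dist(cand, pos[seq_len(placed), , drop = FALSE], L))
          if (dmin < 0.40) next
        }
        pos[placed + 1:5, ] <- cand %% L
        placed <- placed + 5L
        ok <- TRUE
        break
      }
      if (!ok) stop("box too small to place molecules without overlap")
    }
  } else {
    if (is.null(shell_radius))
      shell_radius <- max(2.2, sqrt(n_mol * 0.45 / (4 * pi)))
    u <- .fib_sphere(n_mol)
    if (arrangement == "janus") {
      ord <- order(u[, 3], decreasing = TRUE)
      species <- character(n_mol)
      species[ord[seq_len(n_R)]] <- "R"
      species[ord[-seq_len(n_R)]] <- "B"
      if (n_R == 0) species[] <- "B"
    } else {
      species <- sample(rep(c("R", "B"), c(n_R, n_B)))
    }
    pos <- matrix(NA_real_, n_mol * 5, 3)
    for (m in seq_len(n_mol)) {
      radii <- shell_radius - (0:4) * r0
      cand <- t(ctr + outer(u[m, ], radii))
      cand <- cand + matrix(rnorm(15, sd = 0.03), 5, 3)
      pos[(m - 1) * 5 + 1:5, ] <- cand %% L
    }
    if (min(shell_radius - 4 * r0) < 0)
      warning("tail beads cross the micelle centre; consider a larger shell_radius")
  }

  type <- unlist(lapply(species, .mol_types), use.names = FALSE)
  mol_id <- rep(seq_len(n_mol), each = 5L)
  role <- rep(.bead_roles, n_mol)
  bonds <- do.call(rbind, lapply(seq_len(n_mol), function(m) {
    b <- (m - 1L) * 5L
    cbind(b + 1:4, b + 2:5)
  }))
  sdv <- sqrt(kB_KJMOL * config$temperature / config$mass)
  vel <- matrix(rnorm(n_mol * 5 * 3, sd = sdv), ncol = 3)

  structure(list(positions = pos, velocities = vel, type = type,
                 mol_id = mol_id, role = role, species = species,
                 bonds = bonds, box = L, time = 0),
            class = "mcg_state")
}

# min-image distances between two position sets (na x nb), vectorised per dim
.min_image_cross_dist <- function(a, b, L) {
  dx <- outer(a[, 1], b[, 1], "-"); dx <- dx - L * round(dx / L)
  dy <- outer(a[, 2], b[, 2], "-"); dy <- dy - L * round(dy / L)
  dz <- outer(a[, 3], b[, 3], "-"); dz <- dz - L * round(dz / L)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' @export
print.mcg_state <- function(x, ...) {
  cat(sprintf("mCG system state: %d beads / %d molecules (%d R + %d B), box %.3g nm, t = %.4g ns\n",
              nrow(x$positions), length(x$species),
              sum(x$species == "R"), sum(x$species == "B"), x$box, x$time))
  invisible(x)
}

#' Forces and potential energy of an mCG state
#'
#' Sum of harmonic-bond forces and truncated-shifted LJ forces under the
#' minimum-image convention. LJ interactions between directly bonded (1-2)
#' beads are excluded; 1-3 and beyond are included. Bead pairs closer than
#' the 1e-6 nm overlap floor are clamped (with a warning).
#'
#' @param state an `mcg_state`.
#' @param pairs a [mcg_pair_table()].
#' @param config a [sim_config()].
#' @return list with `forces` (N x 3, kJ mol^-1 nm^-1) and `epot` (kJ/mol).
#' @export
compute_forces <- function(state, pairs, config) {
  res <- forces_cpp(state$positions, state$type, pairs$sigma, pairs$epsilon,
                    pairs$r_cut, state$box, state$bonds,
                    config$bond_r0, config$bond_k)
  if (res$n_clamped > 0)
    warning(sprintf("%d overlapping bead pairs clamped at the 1e-6 nm floor",
                    res$n_clamped))
  res[c("forces", "epot")]
}

#' Advance an mCG state by Langevin (BAOAB) steps
#'
#' BAOAB splitting of Langevin dynamics with mass-independent friction
#' `gamma = 1/tau_t` and thermal noise satisfying fluctuation-dissipation at
#' the configured temperature. Noise is drawn from R's RNG stream, so
#' `set.seed()` before the call makes the trajectory bitwise reproducible.
#' With `tau_t = Inf` the scheme reduces exactly to velocity Verlet (NVE).
#'
#' @param state an `mcg_state`.
#' @param pairs a [mcg_pair_table()].
#' @param config a [sim_config()].
#' @param n_steps number of steps to advance (default 1).
#' @return the advanced `mcg_state`.
#' @export
langevin_step <- function(state, pairs, config, n_steps = 1L) {
  gamma <- if (is.finite(config$tau_t)) 1 / config$tau_t else 0
  res <- run_md_cpp(state$positions, state$velocities, state$type,
                    pairs$sigma, pairs$epsilon, pairs$r_cut, state$box,
                    state$bonds, config$bond_r0, config$bond_k,
                    rep(config$mass, nrow(state$positions)),
                    config$dt, gamma, config$temperature,
                    as.integer(n_steps), 0L, state$time * 1e3)
  state$positions <- res$pos
  state$velocities <- res$vel
  state$time <- state$time + n_steps * config$dt * 1e-3
  state
}

#' Run an mCG Langevin simulation and sample a trajectory
#'
#' Optionally relaxes the input state (steepest descent), discards an
#' equilibration window, then integrates `n_steps` of BAOAB Langevin
#' dynamics sampling every `stride` steps. Potential energy and
#' instantaneous kinetic temperature are logged per sampled frame.
#'
#' @param state an `mcg_state` (see [build_bicomponent_system()]).
#' @param pairs a [mcg_pair_table()].
#' @param config a [sim_config()]; `n_steps`, `stride` and `seed` defaults
#'   are taken from it.
#' @param n_steps,stride production steps and sampling stride (steps).
#' @param equilibration steps run and discarded before production.
#' @param minimize_steps steepest-descent iterations before dynamics.
#' @param seed RNG seed for the thermal noise.
#' @return object of class `mcg_trajectory`: list with `frames` (list of
#'   N x 3 position matrices, nm, wrapped), `times` (ns), `log`
#'   (data.frame time/epot/temperature), the per-bead/molecule annotation
#'   of the state, `box`, and `final_state` for continuation runs.
#' @export
run_simulation <- function(state, pairs, config,
                           n_steps = config$n_steps, stride = config$stride,
                           equilibration = 0L, minimize_steps = 0L,
                           seed = config$seed) {
  set.seed(seed)
  gamma <- if (is.finite(config$tau_t)) 1 / config$tau_t else 0
  mass <- rep(config$mass, nrow(state$positions))

  if (minimize_steps > 0L) {
    mn <- minimize_cpp(state$positions, state$type, pairs$sigma, pairs$epsilon,
                       pairs$r_cut, state$box, state$bonds,
                       config$bond_r0, config$bond_k,
                       as.integer(minimize_steps), 0.02)
    state$positions <- mn$pos
  }
  if (equilibration > 0L) {
    eq <- run_md_cpp(state$positions, state$velocities, state$type,
                     pairs$sigma, pairs$epsilon, pairs$r_cut, state$box,
                     state$bonds, config$bond_r0, config$bond_k, mass,
                     config$dt, gamma, config$temperature,
                     as.integer(equilibration), 0L, state$time * 1e3)
    state$positions <- eq$pos
    state$velocities <- eq$vel
    state$time <- state$time + equilibration * config$dt * 1e-3
  }
  res <- run_md_cpp(state$positions, state$velocities, state$type,
                    pairs$sigma, pairs$epsilon, pairs$r_cut, state$box,
                    state$bonds, config$bond_r0, config$bond_k, mass,
                    config$dt, gamma, config$temperature,
                    as.integer(n_steps), as.integer(stride), state$time * 1e3)
  if (res$n_clamped > 0)
    warning(sprintf("%d overlapping bead pairs clamped during the run", res$n_clamped))

  final <- state
  final$positions <- res$pos
  final$velocities <- res$vel
  final$time <- state$time + n_steps * config$dt * 1e-3

  structure(list(frames = res$frames,
                 times = res$times * 1e-3,
                 log = data.frame(time = res$times * 1e-3,
                                  epot = res$epot,
                                  temperature = res$temp),
                 type = state$type, mol_id = state$mol_id, role = state$role,
                 species = state$species, bonds = state$bonds, box = state$box,
                 config = config, pairs = pairs,
                 final_state = final),
            class = "mcg_trajectory")
}

#' @export
print.mcg_trajectory <- function(x, ...) {
  cat(sprintf("mCG trajectory: %d frames x %d beads (%d molecules), t = %.4g..%.4g ns\n",
              length(x$frames), nrow(x$frames[[1]]), length(x$species),
              min(x$times), max(x$times)))
  cat(sprintf("mean T = %.1f K, mean Epot = %.1f kJ/mol\n",
              mean(x$log$temperature), mean(x$log$epot)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `mcg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)
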