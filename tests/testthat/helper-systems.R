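# Small builders shared across test files. Everything is generated in code;
# expensive shared fixtures (used by the acceptance suite) are cached in a
# session-local environment so they are simulated once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a state of n non-interacting beads (ideal Langevin gas)
make_free_state <- function(n, box = 20, temperature = 300, mass = 72, seed = 1) {
  set.seed(seed)
  sdv <- sqrt(micellemotifs:::kB_KJMOL * temperature / mass)
  structure(list(positions = matrix(runif(n * 3, 0, box), ncol = 3),
                 velocities = matrix(rnorm(n * 3, sd = sdv), ncol = 3),
                 type = rep(1L, n), mol_id = seq_len(n),
                 role = rep("head", n), species = rep("R", n),
                 bonds = matrix(integer(0), 0, 2), box = box, time = 0),
            class = "mcg_state")
}

ideal_pair_table <- function() {
  mcg_pair_table("custom", eps_RR = 0, eps_BB = 0, eps_RB = 0,
                 eps_tail = 0, eps_head_tail = 0)
}

# rotation matrix from an axis-angle pair (Rodrigues)
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# standard scaled-down micelle run used by several acceptance checks
simulate_micelle <- function(regime, sigma_B = 0.7, arrangement = "mixed",
                             seed = 1, frames = 60, stride = 2500L,
                             equilibration = 25000L) {
  pt <- mcg_pair_table(regime, sigma_B = sigma_B)
  sc <- sim_config()
  st <- build_bicomponent_system(100, 100, pt, sc,
                                 mode = "preassembled_micelle",
                                 arrangement = arrangement, seed = seed)
  run_simulation(st, pt, sc, n_steps = frames * stride, stride = stride,
                 equilibration = equilibration, minimize_steps = 200L,
                 seed = seed)
}

# Joint three-regime study-condition fixture (mixing / segregating /
# intermediate, equal head sizes): SOAP datasets, PCA trained on the
# pooled data of the compared micelles, then per-micelle PAMM clustering
# of the mixing system in that shared embedding.
fig1_fixture <- function() {
  if (!is.null(.fixture_env$fig1)) return(.fixture_env$fig1)
  sp <- soap_params(r_cut = 30, units = "angstrom")
  trs <- list(mixing = simulate_micelle("mixing", seed = 201, frames = 120),
              segregating = simulate_micelle("segregating", seed = 202, frames = 60),
              intermediate = simulate_micelle("intermediate", seed = 203, frames = 60))
  dss <- lapply(trs, build_soap_dataset, params = sp)
  Xall <- do.call(rbind, lapply(dss, function(d) d$X))
  pca <- fit_pca(Xall, n_components = 5)
  emb_mix <- pca_transform(pca, dss$mixing)
  cl_mix <- suppressMessages(pamm_cluster(emb_mix, ngrid = 1500, fs = 0.1,
                                          seed = 7))
  .fixture_env$fig1 <- list(datasets = dss, pca = pca,
                            emb_mixing = emb_mix, cluster_mixing = cl_mix)
  .fixture_env$fig1
}

# Size-asymmetric segregating fixture (sigma_R/sigma_B = 1.49, janus start)
sizeasym_fixture <- function() {
  if (!is.null(.fixture_env$sizeasym)) return(.fixture_env$sizeasym)
  sp <- soap_params(r_cut = 30, units = "angstrom")
  tr <- simulate_micelle("segregating", sigma_B = 0.47, arrangement = "janus",
                         seed = 204, frames = 80)
  ds <- build_soap_dataset(tr, sp)
  pca <- fit_pca(ds, n_components = 5)
  emb <- pca_transform(pca, ds)
  cl <- suppressMessages(pamm_cluster(emb, ngrid = 2500, fs = 0.2, seed = 8))
  .fixture_env$sizeasym <- list(dataset = ds, pca = pca, emb = emb, cluster = cl)
  .fixture_env$sizeasym
}
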