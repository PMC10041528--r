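test_that("bicomponent builder produces the right topology", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config()
  st <- build_bicomponent_system(100, 100, pt, sc, seed = 1)
  expect_equal(nrow(st$positions), 1000)
  expect_equal(nrow(st$bonds), 800)
  expect_equal(sum(st$species == "R"), 100)
  expect_equal(sum(st$role == "head"), 200)
  expect_true(all(st$positions >= 0 & st$positions < sc$box))
  # each molecule: 5 beads, linear 4-bond chain, head first
  expect_true(all(table(st$mol_id) == 5))
  expect_identical(st$role[st$mol_id == 1], c("head", paste0("tail", 1:4)))
})

test_that("a single dispersed molecule is a chain at rest length", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config(box = 10)
  st <- build_bicomponent_system(1, 0, pt, sc, mode = "random_dispersed", seed = 4)
  expect_equal(nrow(st$positions), 5)
  d <- sqrt(rowSums((st$positions[st$bonds[, 1], ] - st$positions[st$bonds[, 2], ])^2))
  expect_equal(d, rep(sc$bond_r0, 4), tolerance = 1e-10)
})

test_that("preassembled micelles put heads outside their own tails", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config()
  st <- build_bicomponent_system(100, 100, pt, sc,
                                 mode = "preassembled_micelle", seed = 2)
  ctr <- colMeans(st$positions)
  dh <- sqrt(rowSums(sweep(st$positions[st$role == "head", ], 2, ctr)^2))
  dt4 <- sqrt(rowSums(sweep(st$positions[st$role == "tail4", ], 2, ctr)^2))
  expect_true(all(dh > dt4))
})

test_that("janus arrangement splits species into hemispheres", {
  pt <- mcg_pair_table("segregating", sigma_B = 0.47)
  sc <- sim_config()
  st <- build_bicomponent_system(100, 100, pt, sc,
                                 mode = "preassembled_micelle",
                                 arrangement = "janus", seed = 3)
  heads <- st$positions[st$role == "head", ]
  z <- heads[, 3] - mean(heads[, 3])
  # R heads sit above B heads along the split axis
  expect_gt(mean(z[st$species == "R"]), mean(z[st$species == "B"]) + 2)
})

test_that("an overfull box raises a placement error", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config(box = 3)
  expect_error(build_bicomponent_system(300, 300, pt, sc,
                                        mode = "random_dispersed", seed = 1),
               "too small")
})

test_that("forces are the negative energy gradient and sum to zero", {
  pt <- mcg_pair_table("segregating", sigma_B = 0.47)
  sc <- sim_config(box = 6)
  set.seed(7)
  st <- build_bicomponent_system(2, 1, pt, sc, mode = "random_dispersed", seed = 3)
  f <- compute_forces(st, pt, sc)
  expect_lt(max(abs(colSums(f$forces))), 1e-9)
  h <- 1e-6
  for (i in c(1, 4, 9, 15)) {
    for (k in 1:3) {
      sp <- st; sp$positions[i, k] <- sp$positions[i, k] + h
      sm <- st; sm$positions[i, k] <- sm$positions[i, k] - h
      num <- -(compute_forces(sp, pt, sc)$epot -
                 compute_forces(sm, pt, sc)$epot) / (2 * h)
      expect_equal(f$forces[i, k], num,
                   tolerance = 1e-6 * max(1, abs(num)))
    }
  }
})

test_that("a bond at rest length exerts no force", {
  pt <- ideal_pair_table()
  sc <- sim_config(box = 10)
  st <- make_free_state(2, box = 10)
  st$positions <- rbind(c(5, 5, 5), c(5 + sc$bond_r0, 5, 5))
  st$bonds <- matrix(c(1L, 2L), 1, 2)
  f <- compute_forces(st, pt, sc)
  expect_equal(max(abs(f$forces)), 0, tolerance = 1e-12)
})

test_that("label swap symmetry: R<->B relabelling leaves forces unchanged", {
  sc <- sim_config(box = 8)
  pt <- mcg_pair_table("intermediate") # asymmetric homo-interactions
  st <- build_bicomponent_system(3, 3, pt, sc, mode = "random_dispersed", seed = 9)
  f1 <- compute_forces(st, pt, sc)
  # swap species labels AND swap the table parameters accordingly
  st2 <- st
  st2$type <- c(2L, 1L, 4L, 3L)[st$type]
  pt2 <- pt
  perm <- c(2, 1, 4, 3)
  pt2$sigma <- pt$sigma[perm, perm]
  pt2$epsilon <- pt$epsilon[perm, perm]
  f2 <- compute_forces(st2, pt2, sc)
  expect_equal(f1$forces, f2$forces, tolerance = 1e-12)
  expect_equal(f1$epot, f2$epot, tolerance = 1e-12)
})

test_that("zero temperature, zero force leaves the state frozen", {
  st <- make_free_state(10, temperature = 0)
  st$velocities[] <- 0
  sc <- sim_config(temperature = 0)
  st2 <- langevin_step(st, ideal_pair_table(), sc, n_steps = 100)
  expect_equal(st2$positions, st$positions, tolerance = 1e-14)
  expect_gt(st2$time, st$time)
})

test_that("Langevin thermostat equilibrates free particles to 300 K", {
  st <- make_free_state(10000, temperature = 300, seed = 5)
  sc <- sim_config()
  tr <- run_simulation(st, ideal_pair_table(), sc, n_steps = 10000,
                       stride = 100, seed = 5)
  mt <- mean(tr$log$temperature[-1])
  expect_lt(abs(mt - 300) / 300, 0.03)
})

test_that("same seed gives bitwise-identical trajectories", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config(box = 8)
  st <- build_bicomponent_system(5, 5, pt, sc, mode = "random_dispersed", seed = 6)
  tr1 <- run_simulation(st, pt, sc, n_steps = 500, stride = 100, seed = 42)
  tr2 <- run_simulation(st, pt, sc, n_steps = 500, stride = 100, seed = 42)
  expect_identical(tr1$frames, tr2$frames)
  expect_identical(tr1$log, tr2$log)
})

test_that("gamma -> 0 limit conserves energy (velocity-Verlet NVE)", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config(box = 8, dt = 0.005, tau_t = Inf)
  st <- build_bicomponent_system(2, 2, pt, sc, mode = "random_dispersed", seed = 8)
  # thermalise briefly, then switch the thermostat off
  st <- langevin_step(st, pt, sim_config(box = 8), n_steps = 2000)
  tr <- run_simulation(st, pt, sc, n_steps = 10000, stride = 100, seed = 1)
  n <- nrow(st$positions)
  etot <- tr$log$epot + 1.5 * n * micellemotifs:::kB_KJMOL * tr$log$temperature
  ref <- 1.5 * n * micellemotifs:::kB_KJMOL * 300 # kinetic energy scale
  drift <- abs(etot[length(etot)] - etot[1]) / ref
  expect_lt(drift, 1e-4)
})

test_that("n_steps = 0 returns a single-frame trajectory equal to the input", {
  st <- make_free_state(20)
  tr <- run_simulation(st, ideal_pair_table(), sim_config(),
                       n_steps = 0, stride = 100, seed = 1)
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$frames[[1]], st$positions, tolerance = 1e-14)
})

test_that("a preassembled micelle stays one connected aggregate", {
  tr <- simulate_micelle("mixing", seed = 31, frames = 4, stride = 2500,
                         equilibration = 10000)
  hp <- extract_head_centers(tr, n_frames(tr))
  comp <- aggregate_components(hp$centers, 1.2, tr$box)
  expect_equal(max(comp), 1)
})

test_that("thermostat holds 300 K on the interacting 1000-bead system", {
  # at the production 40 fs step the kinetic temperature carries a ~2-3%
  # O(dt^2) discretisation deficit from the stiff bond modes; the
  # thermostat invariant is checked at half that step, where the bias is
  # a quarter
  pt <- mcg_pair_table("mixing")
  sc20 <- sim_config(dt = 0.02)
  st <- build_bicomponent_system(100, 100, pt, sc20,
                                 mode = "preassembled_micelle", seed = 31)
  tr <- run_simulation(st, pt, sc20, n_steps = 30000, stride = 500,
                       equilibration = 10000, minimize_steps = 200, seed = 31)
  expect_lt(abs(mean(tr$log$temperature[-1]) - 300) / 300, 0.03)
})

test_that("segregating interactions raise same-species head neighbourhoods", {
  same_frac <- function(tr) {
    hp <- extract_head_centers(tr, n_frames(tr))
    d <- micellemotifs:::.min_image_cross_dist(hp$centers, hp$centers, tr$box)
    same <- outer(hp$species, hp$species, "==")
    close <- d < 1.0 & d > 1e-9
    sum(same & close) / sum(close)
  }
  # janus start for the segregating run: compartmentalisation is its
  # equilibrium, but demixing from a random arrangement is slower than a
  # short fixture can sample
  tr_seg <- simulate_micelle("segregating", seed = 32, frames = 8,
                             arrangement = "janus",
                             stride = 2500, equilibration = 25000)
  tr_mix <- simulate_micelle("mixing", seed = 32, frames = 8,
                             stride = 2500, equilibration = 25000)
  expect_gt(same_frac(tr_seg), same_frac(tr_mix))
})
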