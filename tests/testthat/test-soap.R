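soap_p <- soap_params(r_cut = 30, units = "angstrom")

test_that("descriptor dimension follows the species-channel formula", {
  expect_identical(soap_dim(soap_p), 324L)
  expect_identical(length(soap_power_spectrum(matrix(rnorm(9), 3, 3), soap_p)), 324L)
  # per-species channels: (l+1) * S n (S n + 1) / 2
  p2 <- soap_params(r_cut = 3, species_policy = "per_species")
  expect_identical(soap_dim(p2, 2L), as.integer(9 * 16 * 17 / 2))
  p3 <- soap_params(r_cut = 2, n_max = 4, l_max = 5)
  expect_identical(soap_dim(p3), as.integer(6 * 4 * 5 / 2))
})

test_that("angstrom parameters convert to nm internally", {
  expect_equal(soap_p$r_cut, 3.0)
  expect_equal(soap_p$sigma_atom, 0.35)
  expect_equal(soap_params(r_cut = 3.0)$r_cut, 3.0)
})

test_that("spectra are invariant under rotation, translation-free and permutation", {
  set.seed(11)
  nb <- matrix(rnorm(36, sd = 0.9), 12, 3)
  ref <- soap_power_spectrum(nb, soap_p)
  scale <- max(abs(ref))
  for (i in 1:5) {
    R <- rotation_matrix(rnorm(3), runif(1, 0, 2 * pi))
    rot <- soap_power_spectrum(nb %*% t(R), soap_p)
    expect_lt(max(abs(rot - ref)) / scale, 1e-8)
  }
  perm <- soap_power_spectrum(nb[sample(12), ], soap_p)
  expect_lt(max(abs(perm - ref)) / scale, 1e-8)
})

test_that("a single axial neighbour excites only m = 0 channels", {
  co <- density_expansion_coefficients(matrix(c(0, 0, 1.5), 1, 3), soap_p)
  for (l in 1:soap_p$l_max) {
    M <- co$c[[1]][[l + 1]]
    expect_equal(max(abs(M[, -(l + 1), drop = FALSE])), 0)
    expect_gt(max(abs(M[, l + 1])), 0)
  }
})

test_that("empty neighbourhoods give exactly zero coefficients and spectra", {
  co <- density_expansion_coefficients(matrix(numeric(0), 0, 3), soap_p)
  expect_true(all(vapply(co$c[[1]], function(m) all(m == 0), logical(1))))
  expect_identical(sum(abs(power_spectrum(co))), 0)
  # a neighbour beyond the cutoff is equivalent to no neighbour
  far <- soap_power_spectrum(matrix(c(0, 0, soap_p$r_cut + 1), 1, 3), soap_p)
  expect_identical(sum(abs(far)), 0)
})

test_that("expansion coefficients match a brute-force 3D quadrature", {
  # independent oracle: spherical product-grid integration of the smeared
  # density against each basis function
  params <- soap_params(r_cut = 2, n_max = 4, l_max = 4, sigma_atom = 0.3)
  quad_coeffs <- function(nb) {
    a <- 1 / (2 * params$sigma_atom^2)
    alphas <- micellemotifs:::.soap_alphas(params)
    W <- micellemotifs:::.soap_lowdin(alphas)
    glr <- pracma::gaussLegendre(120, 0, params$r_cut + 4 * params$sigma_atom)
    glc <- pracma::gaussLegendre(64, -1, 1)
    nphi <- 72
    phis <- (seq_len(nphi) - 1) * 2 * pi / nphi
    grid <- expand.grid(r = glr$x, ct = glc$x, phi = phis)
    st <- sqrt(1 - grid$ct^2)
    pts <- cbind(grid$r * st * cos(grid$phi),
                 grid$r * st * sin(grid$phi),
                 grid$r * grid$ct)
    wts <- rep(glr$w, times = 64 * nphi) *
      rep(rep(glc$w, each = 120), nphi) * (2 * pi / nphi) * grid$r^2
    rho <- rep(0, nrow(pts))
    for (j in seq_len(nrow(nb)))
      rho <- rho + exp(-a * ((pts[, 1] - nb[j, 1])^2 +
                               (pts[, 2] - nb[j, 2])^2 +
                               (pts[, 3] - nb[j, 3])^2))
    Y <- micellemotifs:::.real_sph_harm(pts / pmax(grid$r, 1e-12), params$l_max)
    G <- exp(-outer(grid$r^2, alphas)) %*% t(W)
    lapply(0:params$l_max, function(l)
      crossprod(G * (rho * wts), Y[, l^2 + seq_len(2 * l + 1), drop = FALSE]))
  }
  set.seed(42)
  nb <- matrix(runif(30, -1, 1), 10, 3)
  nb <- nb[sqrt(rowSums(nb^2)) < params$r_cut * 0.95, , drop = FALSE]
  impl <- density_expansion_coefficients(nb, params)$c[[1]]
  oracle <- quad_coeffs(nb)
  for (l in 0:params$l_max)
    expect_lt(max(abs(impl[[l + 1]] - oracle[[l + 1]])), 1e-4)
})

test_that("spectra vary smoothly with a neighbour displacement", {
  set.seed(3)
  nb <- matrix(rnorm(30, sd = 0.8), 10, 3)
  s0 <- soap_power_spectrum(nb, soap_p)
  deltas <- c(1e-3, 1e-4, 1e-5)
  changes <- vapply(deltas, function(d) {
    nb2 <- nb; nb2[1, 1] <- nb2[1, 1] + d
    max(abs(soap_power_spectrum(nb2, soap_p) - s0))
  }, numeric(1))
  # O(delta): change/delta stays bounded as delta -> 0
  rates <- changes / deltas
  expect_lt(max(rates) / min(rates), 1.5)
})

test_that("per-species channels reduce to single-channel blocks for one species", {
  p1 <- soap_params(r_cut = 2, n_max = 3, l_max = 2)
  p2 <- soap_params(r_cut = 2, n_max = 3, l_max = 2, species_policy = "per_species")
  set.seed(5)
  nb <- matrix(rnorm(15, sd = 0.5), 5, 3)
  s1 <- soap_power_spectrum(nb, p1)
  s2 <- soap_power_spectrum(nb, p2, species = rep("R", 5))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("head centres come from head-bead groups", {
  tr <- list(frames = list(rbind(c(0, 0, 0), c(1, 0, 0), c(4, 4, 4))),
             times = 0,
             mol_id = c(1L, 1L, 2L), role = c("head", "head", "head"),
             species = c("R", "B"), box = 10)
  hm <- data.frame(molecule = 1:2, species = c("R", "B"),
                   heads = c("0;1", "0"), stringsAsFactors = FALSE)
  hc <- extract_head_centers(tr, 1, head_map = hm)
  expect_equal(hc$centers[1, ], c(0.5, 0, 0))
  expect_equal(hc$centers[2, ], c(4, 4, 4))
  hm_bad <- data.frame(molecule = 1, species = "R", heads = "")
  expect_error(extract_head_centers(tr, 1, head_map = hm_bad), "head")
})

test_that("dataset bookkeeping: rows = frames x centers, frame-major", {
  pt <- mcg_pair_table("mixing")
  sc <- sim_config(box = 12)
  st <- build_bicomponent_system(4, 4, pt, sc, mode = "random_dispersed", seed = 13)
  tr <- run_simulation(st, pt, sc, n_steps = 400, stride = 100, seed = 13)
  p <- soap_params(r_cut = 2, n_max = 3, l_max = 3)
  ds <- build_soap_dataset(tr, p)
  expect_equal(nrow(ds$X), n_frames(tr) * 8)
  expect_equal(ds$meta$center[1:8], 1:8)
  expect_equal(ds$meta$frame[1:9], c(rep(1L, 8), 2L))
  # window excluding everything errors; duplicate frames give identical rows
  expect_error(build_soap_dataset(tr, p, window = c(100, 200)), "exclude")
  tr2 <- tr
  tr2$frames <- tr$frames[c(1, 1)]
  tr2$times <- tr$times[1] + c(0, 1)
  ds2 <- build_soap_dataset(tr2, p)
  expect_identical(ds2$X[1:8, ], ds2$X[9:16, ])
})
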