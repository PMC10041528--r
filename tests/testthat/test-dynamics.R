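# one surfactant, labels A,A,B,B,A (A=1, B=2): the worked example
.series_aabba <- matrix(c(1L, 1L, 2L, 2L, 1L), ncol = 1)

test_that("hand-enumerated transition counts and probabilities", {
  counts <- transition_counts(.series_aabba, K = 2)
  expect_identical(counts, matrix(c(1L, 1L, 1L, 1L), 2, 2))
  P <- conditional_transition_matrix(counts)
  expect_equal(P, matrix(0.5, 2, 2), ignore_attr = TRUE)
  expect_equal(rowSums(P), c(1, 1), tolerance = 1e-12)
})

test_that("constant labels give diagonal counts and an identity matrix", {
  m <- matrix(2L, 10, 7)
  counts <- transition_counts(m, K = 3)
  expect_equal(sum(counts), 7 * 9)
  expect_equal(counts[2, 2], 63L)
  expect_equal(sum(counts) - counts[2, 2], 0L)
  P <- conditional_transition_matrix(counts)
  expect_equal(P[2, ], c(0, 1, 0), ignore_attr = TRUE)
  expect_identical(attr(P, "undefined_rows"), c(1L, 3L))
  expect_true(all(is.na(P[1, ])))
})

test_that("counts equal brute-force enumeration on random label matrices", {
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(sample.int(3, 50 * 20, replace = TRUE), 50, 20)
    counts <- transition_counts(m, K = 3)
    brute <- matrix(0L, 3, 3)
    for (s in 1:20) for (t in 1:49) {
      i <- m[t, s]; j <- m[t + 1, s]
      brute[i, j] <- brute[i, j] + 1L
    }
    expect_identical(counts, brute)
    expect_equal(sum(counts), 20 * 49)
    P <- conditional_transition_matrix(counts)
    ok <- setdiff(1:3, attr(P, "undefined_rows"))
    expect_equal(rowSums(P)[ok], rep(1, length(ok)),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("populations average the label distribution over all cells", {
  expect_equal(populations(matrix(1L, 4, 5), K = 1), 100)
  m <- cbind(rep(1L, 10), rep(2L, 10))
  expect_equal(populations(m, K = 2), c(50, 50))
  expect_equal(sum(populations(matrix(sample.int(4, 200, TRUE), 20, 10), K = 4)), 100)
})

test_that("cluster composition matches direct counting", {
  m <- rbind(c(1L, 1L, 2L), c(1L, 2L, 2L))
  sp <- c("R", "B", "B")
  comp <- cluster_composition(m, species = sp)
  # cluster 1 cells: (f1,s1 R), (f1,s2 B), (f2,s1 R) -> 2/3 R
  expect_equal(comp[1, "R"], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(comp[2, "B"], 100, tolerance = 1e-12)
  expect_equal(rowSums(comp), c(100, 100), ignore_attr = TRUE)
  # all-R system: every cluster pure R
  comp_r <- cluster_composition(matrix(sample.int(2, 40, TRUE), 8, 5),
                                species = rep("R", 5))
  expect_true(all(comp_r[, "R"] == 100, na.rm = TRUE))
  expect_error(cluster_composition(m, species = c("R", NA, "B")), "species")
})

test_that("label_series assembles frames x surfactants with metadata", {
  meta <- data.frame(frame = rep(1:3, each = 2), time = rep(c(0, 10, 20), each = 2),
                     center = rep(1:2, 3), species = rep(c("R", "B"), 3))
  ser <- label_series(c(1L, 2L, 1L, 1L, 2L, 1L), meta)
  expect_identical(dim(ser$labels), c(3L, 2L))
  expect_identical(ser$labels[2, ], c(1L, 1L))
  expect_equal(ser$dt, 10)
  expect_identical(ser$species, c("R", "B"))
  dg <- build_interconversion_diagram(ser)
  expect_equal(sum(dg$populations), 100)
  expect_equal(dg$n_events, 2 * 2)
  expect_equal(dg$populations, populations(ser))
  expect_equal(dg$composition, cluster_composition(ser))
  expect_equal(dg$counts, transition_counts(ser))
})

test_that("frame order affects transitions but not populations/compositions", {
  set.seed(9)
  meta <- data.frame(frame = rep(1:30, each = 10), time = rep(1:30, each = 10),
                     center = rep(1:10, 30), species = rep(c("R", "B"), 150))
  labs <- sample.int(3, 300, replace = TRUE)
  ser <- label_series(labs, meta)
  perm <- sample(30)
  ser_shuf <- ser
  ser_shuf$labels <- ser$labels[perm, ]
  expect_equal(populations(ser_shuf), populations(ser))
  expect_equal(cluster_composition(ser_shuf), cluster_composition(ser))
  expect_false(identical(transition_counts(ser_shuf), transition_counts(ser)))
})

test_that("degenerate series are rejected", {
  expect_error(transition_counts(matrix(1L, 1, 5), K = 1), "2 frames")
  expect_error(conditional_transition_matrix(matrix(integer(0), 0, 0)))
})

test_that("diagram serialisation writes JSON and DOT", {
  meta <- data.frame(frame = rep(1:4, each = 3), time = rep(1:4, each = 3) * 10,
                     center = rep(1:3, 4), species = rep(c("R", "B", "R"), 4))
  ser <- label_series(sample.int(2, 12, replace = TRUE), meta, K = 2)
  dg <- build_interconversion_diagram(ser)
  jf <- tempfile(fileext = ".json"); df <- tempfile(fileext = ".dot")
  write_interconversion_diagram(dg, json_file = jf, dot_file = df)
  rep <- jsonlite::read_json(jf)
  expect_equal(rep$K, 2)
  expect_equal(sum(unlist(rep$populations_percent)), 100, tolerance = 1e-9)
  expect_true(any(grepl("digraph", readLines(df))))
})
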