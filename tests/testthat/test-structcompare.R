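random_cloud <- function(n, seed, scale = 10) {
  set.seed(seed)
  matrix(runif(n * 3, -scale, scale), ncol = 3)
}

rigid_copy <- function(cs, angle = 0.7, axis = c(0, 0, 1), shift = c(5, -2, 3),
                       id = "moved") {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  coordinate_set(id, cs$residue_index,
                 sweep(cs$xyz %*% t(R), 2, shift, `+`))
}

test_that("Kabsch superposition recovers rigid transforms exactly", {
  a <- coordinate_set("a", 1:10, random_cloud(10, 1))
  expect_equal(kabsch_superpose(a, a)$rmsd, 0, tolerance = 1e-10)

  b <- coordinate_set("b", 1:10, sweep(a$xyz, 2, c(5, 0, 0), `+`))
  sup <- kabsch_superpose(a, b)
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$translation, c(-5, 0, 0), tolerance = 1e-8)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)

  rot <- rigid_copy(a)
  expect_equal(kabsch_superpose(a, rot)$rmsd, 0, tolerance = 1e-8)
  expect_error(kabsch_superpose(a, b, cbind(1:2, 1:2)),
               class = "grlscreen_validation_error")
})

test_that("Kabsch RMSD matches a rotation grid-search oracle", {
  for (s in 1:3) {
    A <- random_cloud(10, 2000 + s)
    B <- random_cloud(10, 3000 + s)
    got <- kabsch_superpose(coordinate_set("a", 1:10, A),
                            coordinate_set("b", 1:10, B))$rmsd
    oracle <- oracle_grid_rmsd(A, B, step_deg = 12)
    expect_lte(got, oracle + 1e-9)       # optimal beats any grid rotation
    expect_lt(abs(got - oracle), 0.1)    # and the grid comes close
  }
})

test_that("Kabsch agrees with an independent superposition implementation", {
  A <- random_cloud(20, 7)
  B <- A + matrix(rnorm(60, 0, 1), ncol = 3)
  got <- kabsch_superpose(coordinate_set("a", 1:20, A),
                          coordinate_set("b", 1:20, B))$rmsd
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(A)), mobile = as.numeric(t(B)))
  ref <- bio3d::rmsd(as.numeric(t(A)), fit)
  expect_equal(got, ref, tolerance = 1e-4)
})

test_that("reflections are rejected by the determinant correction", {
  A <- random_cloud(12, 11)
  B <- A %*% diag(c(-1, 1, 1))  # mirror image
  sup <- kabsch_superpose(coordinate_set("a", 1:12, A),
                          coordinate_set("b", 1:12, B))
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  expect_gt(sup$rmsd, 0.5)
})

test_that("TM-score is exactly 1 for self-comparison", {
  b <- make_bundle(seed = 5)
  n <- length(b$residue_index)
  expect_identical(tm_score(b, b, cbind(1:n, 1:n), L_ref = n), 1)
  expect_equal(kabsch_superpose(b, b)$rmsd, 0, tolerance = 1e-10)
  expect_error(tm_score(b, b, L_ref = 15),
               class = "grlscreen_validation_error")
})

test_that("TM-score is invariant under rigid motion of either structure", {
  b <- make_bundle(seed = 6)
  noisy <- make_bundle(noise_sd = 1.5, seed = 7)
  base <- tm_score(b, noisy)
  expect_equal(tm_score(rigid_copy(b), noisy), base, tolerance = 1e-6)
  expect_equal(tm_score(b, rigid_copy(noisy)), base, tolerance = 1e-6)
})

test_that("TM-score decreases monotonically with bundle noise", {
  b <- make_bundle(seed = 8)
  scores <- vapply(c(0, 0.5, 2, 5, 10), function(sd) {
    tm_score(b, make_bundle(noise_sd = sd, seed = 9))
  }, numeric(1))
  expect_equal(scores[1], 1)
  expect_true(all(diff(scores) <= 0))
  expect_gte(scores[2], 0.5)   # 0.5 A noise: generally the same fold
  expect_lte(scores[5], 0.30)  # 10 A noise: random similarity
})

test_that("fold classification applies the published thresholds", {
  expect_equal(classify_fold(c(0, 0.30, 0.31, 0.49, 0.5, 1)),
               c("random", "random", "ambiguous", "ambiguous",
                 "same_fold", "same_fold"))
  expect_error(classify_fold(1.2))
})

test_that("pairwise matrices report both TM orientations and symmetric RMSD", {
  sets <- list(make_bundle(seed = 10, id = "ref"),
               make_bundle(noise_sd = 0.5, seed = 11, id = "close"),
               make_bundle(noise_sd = 10, seed = 12, id = "far"))
  sm <- pairwise_structure_matrix(sets)
  expect_equal(sm$rmsd, t(sm$rmsd))
  expect_equal(unname(diag(sm$tm)), rep(1, 3))
  long <- tidy(sm)
  self <- long[long$id1 == long$id2, ]
  expect_true(all(self$classification == "same_fold"))
  expect_equal(long$classification[long$id1 == "ref" & long$id2 == "close"],
               "same_fold")
  expect_equal(long$classification[long$id1 == "ref" & long$id2 == "far"],
               "random")
  p <- autoplot(sm)
  expect_s3_class(p, "ggplot")
})

test_that("model intake filters drop shallow or low-confidence models", {
  meta <- tibble::tibble(id = c("deep_good", "shallow", "low_tm", "edge"),
                         n_msa_seqs = c(120, 9, 80, 15),
                         estimated_tm = c(0.62, 0.70, 0.11, 0.17))
  kept <- filter_model_intake(meta)
  expect_setequal(kept$id, c("deep_good", "edge"))
})

test_that("structure comparison works end to end on compare_structures", {
  a <- make_bundle(seed = 13, id = "a")
  b <- make_bundle(noise_sd = 0.5, seed = 14, id = "b")
  cmp <- compare_structures(a, b)
  expect_equal(cmp$n_aligned, length(a$residue_index))
  expect_gt(cmp$tm_score, 0.5)
  expect_equal(cmp$classification, "same_fold")
  expect_lt(cmp$rmsd, 2)
})
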