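test_that("profile columns follow the pseudocount formula", {
  p0 <- build_profile(c("AC", "AC"), pseudocount = 0)
  expect_equal(unname(p0$prob["A", 1]), 1)
  expect_equal(unname(p0$prob["C", 2]), 1)
  expect_equal(colSums(p0$prob), rep(1, 2))

  p_mix <- build_profile(c("A", "C"), pseudocount = 0)
  expect_equal(unname(p_mix$prob["A", 1]), 0.5)
  expect_equal(unname(p_mix$prob["C", 1]), 0.5)

  # (2 + 20 * 1/20) / (2 + 20) = 3/22
  p20 <- build_profile(c("A", "A"), pseudocount = 20)
  expect_equal(unname(p20$prob["A", 1]), 3 / 22)
  expect_equal(unname(p20$prob["C", 1]), 1 / 22)
  expect_equal(sum(p20$prob[, 1]), 1)
})

test_that("majority-gap columns are dropped, normalisation conserved", {
  p <- build_profile(c("A-C", "A-C", "AAC", "A--"), pseudocount = 1)
  expect_equal(p$length, 2)  # middle column is 75% gaps
  expect_equal(p$kept_columns, c(1, 3))
  expect_equal(colSums(p$prob), rep(1, 2), tolerance = 1e-9)

  expect_error(build_profile(c("AC", "ACD")),
               class = "grlscreen_validation_error")
  expect_error(build_profile("AC"), class = "grlscreen_validation_error")
})

test_that("profile self-similarity and random cross-similarity calibrate", {
  fam <- make_family(n = 4, divergence = 0.15, seed = 2, prefix = "cal")
  p <- build_profile(fam$records, id = "cal")
  self <- align_profiles(p, p)
  expect_gte(self$normalized_similarity, 0.99)

  # unrelated random families stay low
  for (s in 1:5) {
    f1 <- make_family(n = 4, divergence = 0.15, seed = 100 + s, prefix = "u")
    f2 <- make_family(n = 4, divergence = 0.15, seed = 200 + s, prefix = "v")
    cross <- align_profiles(build_profile(f1$records, id = "u"),
                            build_profile(f2$records, id = "v"))
    expect_lte(cross$normalized_similarity, 0.2)
  }
})

test_that("overlapping halves of one family beat cross-family pairs", {
  fam <- make_family(n = 8, divergence = 0.2, seed = 33, prefix = "w")
  other <- make_family(n = 4, divergence = 0.2, seed = 44, prefix = "z")
  h1 <- build_profile(fam$records[1:5, ], id = "h1")
  h2 <- build_profile(fam$records[4:8, ], id = "h2")
  po <- build_profile(other$records, id = "other")
  within <- align_profiles(h1, h2)$normalized_similarity
  between <- max(align_profiles(h1, po)$normalized_similarity,
                 align_profiles(h2, po)$normalized_similarity)
  expect_gt(within, between)
})

test_that("the all-vs-all matrix is symmetric with unit diagonal", {
  fams <- lapply(1:3, function(s)
    make_family(n = 4, divergence = 0.2, seed = 50 + s,
                prefix = paste0("m", s)))
  profs <- lapply(seq_along(fams), function(i)
    build_profile(fams[[i]]$records, id = paste0("m", i)))
  M <- profile_similarity_matrix(profs)
  expect_equal(unclass(M), t(unclass(M)))
  expect_equal(unname(diag(M)), rep(1, 3))
  expect_true(all(M >= 0 & M <= 1))
  expect_error(profile_similarity_matrix(profs[1]),
               class = "grlscreen_validation_error")
})

test_that("clustering merges the two same-family profiles first", {
  fam <- make_family(n = 8, divergence = 0.15, seed = 8, prefix = "c")
  other <- make_family(n = 4, divergence = 0.15, seed = 9, prefix = "d")
  profs <- list(build_profile(fam$records[1:4, ], id = "c_a"),
                build_profile(fam$records[5:8, ], id = "c_b"),
                build_profile(other$records, id = "d"))
  M <- profile_similarity_matrix(profs)
  hc <- cluster_similarity(M)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("c_a", "c_b"))

  # identical profiles merge at zero distance
  M2 <- profile_similarity_matrix(list(profs[[1]],
                                       build_profile(fam$records[1:4, ],
                                                     id = "c_a2"),
                                       profs[[3]]))
  hc2 <- cluster_similarity(M2)
  expect_lt(hc2$height[1], 0.01)
})

test_that("a weak bridge family clusters between two distant families", {
  base <- make_family(n = 12, divergence = 0.35, topology = "two_clade",
                      seed = 77, prefix = "k")
  a <- base$records[base$records$clade == "A", ]
  b <- base$records[base$records$clade == "B", ]
  # bridge: half from each clade, similar to both
  bridge <- dplyr::bind_rows(a[1:3, ], b[1:3, ])
  profs <- list(build_profile(a, id = "animal_like"),
                build_profile(b, id = "plant_like"),
                build_profile(bridge, id = "bridge"))
  M <- profile_similarity_matrix(profs)
  expect_gt(M["animal_like", "bridge"], M["animal_like", "plant_like"])
  expect_gt(M["plant_like", "bridge"], M["animal_like", "plant_like"])
})
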