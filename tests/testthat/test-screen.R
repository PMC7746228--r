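test_that("reciprocal-hit criterion follows the top qualifying hit", {
  crit <- filter_criteria()
  hits <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s2"),
    evalue = c(1e-20, 1e-10), query_coverage = c(90, 80),
    subject_family = c("GRL", "other"))
  expect_true(check_reciprocal(hits, "q", crit))

  # an 'other' hit with the smallest E-value above a GRL hit fails
  hits2 <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s2"),
    evalue = c(1e-30, 1e-20), query_coverage = c(90, 90),
    subject_family = c("other", "GRL"))
  expect_false(check_reciprocal(hits2, "q", crit))

  # empty table: no significant similarity to other families
  expect_true(check_reciprocal(hits2[0, ], "q", crit))

  # hits that fail the E-value / coverage gates are ignored
  hits3 <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s2"),
    evalue = c(0.5, 1e-10), query_coverage = c(90, 50),
    subject_family = c("other", "other"))
  expect_true(check_reciprocal(hits3, "q", crit))

  # qualifying hits to unannotated families ('none') do not disqualify
  hits4 <- tibble::tibble(
    query_id = "q", subject_id = "s1", evalue = 1e-10,
    query_coverage = 80, subject_family = "none")
  expect_true(check_reciprocal(hits4, "q", crit))
})

test_that("hit qualification uses strict inequalities", {
  crit <- filter_criteria()
  # coverage exactly 50 and E-value exactly 0.05 do not qualify
  border <- tibble::tibble(
    query_id = "q", subject_id = c("s1", "s2"),
    evalue = c(0.05, 0.04), query_coverage = c(90, 50),
    subject_family = c("other", "other"))
  expect_true(check_reciprocal(border, "q", crit))
})

test_that("length criterion implements the slack band", {
  crit <- filter_criteria()  # 350-500 with slack 30
  expect_true(check_length(strrep("A", 440), crit))
  expect_false(check_length(1014, crit))
  expect_true(check_length(320, crit))
  expect_false(check_length(319, crit))
  expect_true(check_length(530, crit))
  expect_false(check_length(531, crit))
})

test_that("apply_filters combines the five criteria", {
  g <- make_grl_like(seed = 11)
  topo <- predict_topology(g$record)
  res <- apply_filters(g$record, topo$topology[[1]],
                       make_hit_table(g$record$id))
  expect_equal(res$n_passed, 5)
  expect_true(res$retained)

  # decoy with an extracellular N-terminus only: 4 of 5, still retained
  d <- make_decoy("n_out", seed = 11)
  dt <- predict_topology(d$record)
  dres <- apply_filters(d$record, dt$topology[[1]],
                        make_hit_table(d$record$id))
  expect_equal(dres$n_passed, 4)
  expect_true(dres$retained)
  expect_false(dres$c4_n_in)

  # three violated criteria: not retained
  gp <- make_decoy("gpcr_like", seed = 11)
  gt <- predict_topology(gp$record)
  gres <- apply_filters(gp$record, gt$topology[[1]],
                        make_hit_table(gp$record$id, top_family = "other"))
  expect_equal(gres$n_passed, 2)
  expect_false(gres$retained)
})

test_that("screen_collection preserves order and validates ids", {
  pos <- lapply(1:3, function(s) make_grl_like(seed = s)$record)
  dec <- lapply(1:3, function(s) make_decoy("gpcr_like", seed = s)$record)
  recs <- dplyr::bind_rows(c(pos, dec))
  topo <- predict_topology(recs)
  res <- screen_collection(recs, topo, make_hit_table(recs$id))
  expect_equal(res$protein_id, recs$id)
  expect_equal(sum(res$retained), 3)
  expect_false(any(res$retained[4:6]))

  expect_equal(nrow(screen_collection(recs[0, ], topo[0, ], NULL)), 0)
  expect_error(screen_collection(recs, topo[-1, ], NULL),
               class = "grlscreen_validation_error")
})

test_that("n_passed always equals the count of true criteria", {
  kinds <- c("short", "long", "six_tm", "n_out", "el_gt_il", "gpcr_like")
  for (s in 1:2) {
    recs <- dplyr::bind_rows(
      make_grl_like(seed = s)$record,
      dplyr::bind_rows(lapply(kinds, function(k) make_decoy(k, s)$record)))
    topo <- predict_topology(recs)
    res <- screen_collection(recs, topo, make_hit_table(recs$id))
    expect_equal(res$n_passed,
                 rowSums(res[, c("c1_reciprocal", "c2_length", "c3_seven_tm",
                                 "c4_n_in", "c5_il_gt_el")]))
  }
})

test_that("relaxing any single threshold never shrinks the retained set", {
  recs <- dplyr::bind_rows(
    make_grl_like(seed = 5)$record,
    make_decoy("short", 5)$record,
    make_decoy("el_gt_il", 5)$record,
    make_decoy("gpcr_like", 5)$record)
  topo <- predict_topology(recs)
  hits <- make_hit_table(recs$id)
  base <- screen_collection(recs, topo, hits, filter_criteria())
  relaxed <- list(
    filter_criteria(len_slack = 200),
    filter_criteria(evalue_max = 10),
    filter_criteria(coverage_min = 1),
    filter_criteria(min_criteria_passed = 3))
  for (crit in relaxed) {
    res <- screen_collection(recs, topo, hits, crit)
    expect_true(all(res$n_passed >= base$n_passed))
    expect_true(all(base$retained <= res$retained))
  }
})

test_that("retention at 5-of-5 is nested within retention at 4-of-5", {
  recs <- dplyr::bind_rows(lapply(1:2, function(s) {
    dplyr::bind_rows(make_grl_like(seed = s)$record,
                     make_decoy("n_out", s)$record)
  }))
  topo <- predict_topology(recs)
  hits <- make_hit_table(recs$id)
  at4 <- screen_collection(recs, topo, hits,
                           filter_criteria(min_criteria_passed = 4))
  at5 <- screen_collection(recs, topo, hits,
                           filter_criteria(min_criteria_passed = 5))
  expect_true(all(at5$retained <= at4$retained))
  expect_true(any(at4$retained & !at5$retained))  # the n_out decoys
})

test_that("screen summary and plots carry kingdom metadata", {
  recs <- dplyr::bind_rows(lapply(1:2, function(s) make_grl_like(seed = s)$record))
  recs$kingdom <- c("Fungi", "Protista")
  topo <- predict_topology(recs)
  res <- screen_collection(recs, topo, make_hit_table(recs$id))
  expect_equal(res$kingdom, recs$kingdom)
  gl <- glance(res)
  expect_equal(gl$n_retained, 2)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
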