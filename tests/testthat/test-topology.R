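test_that("windowed hydropathy matches hand-computed values", {
  recs <- tibble::tibble(
    id = c("polyL", "polyK", "polyX"),
    sequence = c(strrep("L", 19), strrep("K", 19), strrep("X", 19)))
  prof <- compute_hydropathy(recs, window = 19)
  expect_equal(prof$hydropathy[prof$id == "polyL"], rep(3.8, 19))
  expect_equal(prof$hydropathy[prof$id == "polyK"], rep(-3.9, 19))
  expect_equal(prof$hydropathy[prof$id == "polyX"], rep(0, 19))
  expect_error(compute_hydropathy(tibble::tibble(id = "s", sequence = "MKV"),
                                  window = 19),
               class = "grlscreen_validation_error")
  expect_error(compute_hydropathy(recs, window = 4),
               class = "grlscreen_validation_error")
})

test_that("hydropathy agrees with a direct per-position oracle", {
  for (s in 1:5) {
    seq <- random_protein(80, seed = s)
    got <- grlscreen:::hydropathy_vector(seq, 19)
    expect_equal(got, oracle_hydropathy(seq, 19), tolerance = 1e-12)
  }
})

test_that("TM segment calling matches the brute-force oracle", {
  # 7 poly-L stretches of 25 aa separated by 25-aa charged loops
  seq7 <- paste0(strrep("K", 25),
                 paste(rep(paste0(strrep("L", 25), strrep("K", 25)), 7),
                       collapse = ""))
  vals <- grlscreen:::hydropathy_vector(seq7, 19)
  got <- grlscreen:::segments_from_values(vals, 1.5, 15, 3)
  exp <- oracle_segments(vals, 1.5, 15, 3)
  expect_equal(got, exp)
  expect_equal(nrow(got), 7)
  # each segment contains its poly-L core midpoint
  cores <- 25 + 50 * (0:6) + 13
  expect_true(all(vapply(cores, function(p)
    any(got[, 1] <= p & got[, 2] >= p), logical(1))))

  # poly-E never crosses threshold
  valsE <- grlscreen:::hydropathy_vector(strrep("E", 100), 19)
  expect_equal(nrow(grlscreen:::segments_from_values(valsE, 1.5, 15, 3)), 0)

  # random profiles against the oracle
  for (s in 1:10) {
    set.seed(s)
    vals <- rnorm(150, mean = 0.8, sd = 1.5)
    expect_equal(grlscreen:::segments_from_values(vals, 1.5, 15, 3),
                 oracle_segments(vals, 1.5, 15, 3))
  }
})

test_that("run merging bridges short gaps", {
  vals <- c(rep(3, 18), rep(0, 2), rep(3, 18))
  got <- grlscreen:::segments_from_values(vals, 1.5, 15, merge_gap = 3)
  expect_equal(nrow(got), 1)  # merged (then trimmed to 30)
  expect_equal(got[1, 2] - got[1, 1] + 1, 30)
  got2 <- grlscreen:::segments_from_values(vals, 1.5, 15, merge_gap = 1)
  expect_equal(nrow(got2), 2)
})

test_that("positive-inside orientation follows the K/R count, ties inward", {
  mk <- function(n_kr_nterm, n_kr_cterm) {
    paste0(strrep("K", n_kr_nterm), strrep("G", 20 - n_kr_nterm),
           strrep("L", 21),
           strrep("K", n_kr_cterm), strrep("G", 20 - n_kr_cterm))
  }
  segs <- tibble::tibble(start = 21, end = 41)
  expect_equal(assign_orientation(mk(8, 1), segs)$n_term_side, "in")
  expect_equal(assign_orientation(mk(1, 8), segs)$n_term_side, "out")
  expect_equal(assign_orientation(mk(3, 3), segs)$n_term_side, "in")
  expect_error(assign_orientation(mk(3, 3), segs[0, ]),
               class = "grlscreen_validation_error")
})

test_that("loop totals sum by side, tails included", {
  topo <- fake_topology("t", paste0(strrep("K", 10), strrep("L", 21),
                                    strrep("E", 5), strrep("L", 21),
                                    strrep("K", 20)),
                        seg_start = c(11, 37), seg_end = c(31, 57))
  ll <- loop_length_summary(topo)
  expect_equal(ll$il_total, 30)
  expect_equal(ll$el_total, 5)
  sides <- topo$loops$side
  expect_true(all(sides[-1] != sides[-length(sides)]))  # strict alternation
})

test_that("generator loop totals are recovered by the topology module", {
  for (s in c(3, 17)) {
    g <- make_grl_like(seed = s)
    topo <- predict_topology(g$record)
    expect_equal(topo$n_tm, g$truth$n_tm)
    expect_equal(topo$n_term_side, g$truth$n_term_side)
    # predicted segments sit inside planted TM intervals, so loop totals
    # can differ only by boundary jitter
    expect_equal(topo$il_total, g$truth$il_total, tolerance = 0.15)
    expect_gt(topo$il_total, topo$el_total)
  }
})

test_that("hydropathy-stage prediction mirrors under sequence reversal", {
  for (s in 1:4) {
    g <- make_grl_like(seed = s, motif_in_tm7 = FALSE)
    fwd <- predict_topology(g$record)$topology[[1]]$segments
    rev_seq <- paste(rev(strsplit(g$record$sequence, "")[[1]]), collapse = "")
    rev_segs <- predict_topology(
      tibble::tibble(id = "r", sequence = rev_seq))$topology[[1]]$segments
    L <- nchar(g$record$sequence)
    mirrored <- tibble::tibble(start = rev(L - fwd$end + 1),
                               end = rev(L - fwd$start + 1))
    expect_equal(rev_segs$start, mirrored$start)
    expect_equal(rev_segs$end, mirrored$end)
  }
})

test_that("loop sides alternate and never overlap segments", {
  for (s in 1:5) {
    g <- make_grl_like(seed = s)
    topo <- predict_topology(g$record)$topology[[1]]
    sides <- topo$loops$side
    expect_true(all(sides[-1] != sides[-length(sides)]))
    feats <- tidy(topo)
    expect_true(all(diff(feats$start) > 0))
    expect_true(all(feats$end[-nrow(feats)] < feats$start[-1]))
  }
})

test_that("the re-entrant N-terminal drop removes an eighth segment", {
  seq8 <- paste0(strrep("K", 10),
                 paste(rep(paste0(strrep("I", 22), strrep("K", 12)), 8),
                       collapse = ""))
  plain <- predict_topology(tibble::tibble(id = "x", sequence = seq8))
  expect_equal(plain$n_tm, 8)
  dropped <- predict_topology(tibble::tibble(id = "x", sequence = seq8),
                              drop_nterm_reentrant = TRUE)
  expect_equal(dropped$n_tm, 7)
  expect_equal(dropped$topology[[1]]$segments$start[1],
               plain$topology[[1]]$segments$start[2])
})

test_that("the subthreshold-TM7 rescue recovers a weak final helix", {
  weak7 <- paste0(strrep("K", 12),
                  paste(rep(paste0(strrep("I", 22), strrep("K", 12)), 6),
                        collapse = ""),
                  strrep("A", 30), strrep("K", 12))
  rec <- tibble::tibble(id = "weak", sequence = weak7)
  plain <- predict_topology(rec)
  expect_equal(plain$n_tm, 6)
  rescued <- predict_topology(rec, rescue_tm7 = TRUE)
  expect_equal(rescued$n_tm, 7)
  expect_true(rescued$rescued)
  # the rescued segment is the C-terminal alanine stretch
  last <- rescued$topology[[1]]$segments[7, ]
  expect_gt(last$start, nchar(weak7) - 50)
})
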