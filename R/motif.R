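#' Definition of the diagnostic TM7 motif
#'
#' The nine-residue motif (T/S)Yhhhhh(Q/K/E)(F/L/M): four specific anchor
#' positions (1, 2, 8, 9) and a five-residue hydrophobic run (positions 3-7,
#' class `h`). A Y-to-F substitution at the second position is the one
#' conservative substitution recognised by default; the hydrophobic class is
#' the conventional set including the aromatics.
#'
#' @param hydrophobic Residues constituting class `h`.
#' @param conservative Named list of conservative residue sets per anchor
#'   (names `a1`..`a4`); only `a2 = "F"` by default.
#' @return A `motif_definition` object.
#' @export
grl_motif <- function(hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
                      conservative = list(a2 = "F")) {
  anchors <- list(a1 = c("T", "S"), a2 = "Y",
                  a3 = c("Q", "K", "E"), a4 = c("F", "L", "M"))
  cons <- list(a1 = character(), a2 = character(),
               a3 = character(), a4 = character())
  for (nm in names(conservative)) cons[[nm]] <- conservative[[nm]]
  if (any(purrr::map2_lgl(anchors, cons, ~ any(.y %in% .x)))) {
    abort_validation("conservative sets must be disjoint from anchor sets")
  }
  structure(list(anchors = anchors, conservative = cons,
                 anchor_pos = c(1L, 2L, 8L, 9L), h_pos = 3:7,
                 hydrophobic = hydrophobic, length = 9L),
            class = "motif_definition")
}

#' Score one nine-residue window against the TM7 motif
#'
#' `anchor_flags` marks exact anchor matches; `conservative_flags` marks
#' conservative-only matches (never both for the same position). With
#' `count_conservative`, `anchors_matched` counts exact plus conservative
#' matches, otherwise exact only. `X` never matches an anchor and never counts
#' as hydrophobic. `h_run_ok` records whether at least 4 of the 5 run
#' positions fall in class `h`; it does not enter `anchors_matched`.
#'
#' @param window A 9-character amino-acid string.
#' @param def A [grl_motif()] definition.
#' @param count_conservative Count conservative substitutions as matches?
#' @return One-row tibble: `window`, `anchors_matched`, `n_conservative`,
#'   `h_run_count`, `h_run_ok`, and per-anchor flag columns.
#' @export
score_motif_window <- function(window, def = grl_motif(),
                               count_conservative = FALSE) {
  if (nchar(window) != def$length) {
    abort_validation(sprintf("window must be %d residues", def$length))
  }
  chars <- strsplit(toupper(window), "")[[1]]
  if (any(!chars %in% AA21)) abort_validation("window has invalid letters")
  res <- chars[def$anchor_pos]
  anchor_flags <- purrr::map2_lgl(res, def$anchors, ~ .x %in% .y)
  conservative_flags <- purrr::map2_lgl(res, def$conservative, ~ .x %in% .y) &
    !anchor_flags
  matched <- anchor_flags | (count_conservative & conservative_flags)
  h_run <- chars[def$h_pos] %in% def$hydrophobic
  tibble(window = paste(chars, collapse = ""),
         anchors_matched = sum(matched),
         n_conservative = sum(conservative_flags),
         h_run_count = sum(h_run), h_run_ok = sum(h_run) >= 4,
         anchor1 = anchor_flags[1], anchor2 = anchor_flags[2],
         anchor3 = anchor_flags[3], anchor4 = anchor_flags[4],
         conservative2 = conservative_flags[2])
}

tm7_scan_range <- function(topo, seq_len, motif_len = 9L, margin = 10L) {
  seg <- topo$segments[nrow(topo$segments), ]
  mid <- floor((seg$start + seg$end) / 2)
  lo <- max(1L, mid - 5L)
  hi <- min(seq_len - motif_len + 1L, seg$end + margin)
  c(lo, hi)
}

#' Scan the TM7 region for the best motif window
#'
#' Scans every nine-mer whose start lies between (midpoint of the last TM
#' segment - 5) and (segment end + 10), returning the window with the most
#' matched anchors; ties break first toward more hydrophobic-run positions in
#' class `h`, then toward the leftmost start. When the search region is
#' shorter than nine residues a no-match sentinel (`anchors_matched = 0`,
#' `start = NA`) is returned.
#'
#' @param record One-row protein-record tibble.
#' @param topo The record's `topology_model` (at least one segment).
#' @param def A [grl_motif()] definition.
#' @param count_conservative Count conservative substitutions as matches?
#' @return One-row tibble: `protein_id`, `start`, plus the
#'   [score_motif_window()] columns.
#' @export
scan_tm7 <- function(record, topo, def = grl_motif(),
                     count_conservative = TRUE) {
  if (is.null(topo) || nrow(topo$segments) == 0) {
    abort_validation("scan_tm7 needs a topology with at least one TM segment")
  }
  sentinel <- tibble(protein_id = record$id, start = NA_integer_,
                     window = NA_character_, anchors_matched = 0L,
                     n_conservative = 0L, h_run_count = 0L, h_run_ok = FALSE)
  rng <- tm7_scan_range(topo, nchar(record$sequence), def$length)
  if (rng[2] < rng[1]) return(sentinel)
  starts <- rng[1]:rng[2]
  scored <- purrr::map_dfr(starts, function(s) {
    w <- substr(record$sequence, s, s + def$length - 1L)
    dplyr::mutate(score_motif_window(w, def, count_conservative), start = s)
  })
  best <- scored |>
    dplyr::arrange(dplyr::desc(.data$anchors_matched),
                   dplyr::desc(.data$h_run_count), .data$start) |>
    dplyr::slice(1)
  dplyr::bind_cols(tibble(protein_id = record$id),
                   dplyr::relocate(best, "start"))
}

#' Motif conservation table for a collection
#'
#' @param records Protein-record tibble.
#' @param topologies Output of [predict_topology()].
#' @param def A [grl_motif()] definition.
#' @param count_conservative Count conservative substitutions as matches?
#' @return A tibble, one row per protein in input order: `protein_id`,
#'   `start`, `window`, `anchors_matched`, `n_conservative`, `h_run_ok`.
#' @export
motif_conservation_table <- function(records, topologies, def = grl_motif(),
                                     count_conservative = TRUE) {
  records <- validate_protein_records(records)
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    topo <- topologies$topology[[match(records$id[i], topologies$id)]]
    scan_tm7(records[i, ], topo, def, count_conservative) |>
      dplyr::select("protein_id", "start", "window", "anchors_matched",
                    "n_conservative", "h_run_ok")
  })
}
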