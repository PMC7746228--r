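# Kyte-Doolittle hydropathy scale. X (and any unknown letter) scores 0.
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

kd_values <- function(sequence) {
  v <- KD_SCALE[strsplit(sequence, "")[[1]]]
  v[is.na(v)] <- 0
  unname(v)
}

#' Windowed Kyte-Doolittle hydropathy profiles
#'
#' Computes, for each protein, the mean hydropathy over a sliding window
#' centred on each residue. Positions within half a window of either end carry
#' the value of the nearest full-window centre. `X` contributes 0.
#'
#' @param records Protein-record tibble.
#' @param window Odd window width (default 19, the usual choice for membrane
#'   helix detection).
#' @return A tibble with columns `id`, `position`, `hydropathy`; the `window`
#'   used is stored as an attribute.
#' @export
compute_hydropathy <- function(records, window = 19) {
  records <- validate_protein_records(records)
  if (window %% 2 != 1 || window < 1) abort_validation("window must be odd and positive")
  out <- purrr::map2_dfr(records$id, records$sequence, function(id, s) {
    tibble(id = id, position = seq_len(nchar(s)),
           hydropathy = hydropathy_vector(s, window))
  })
  attr(out, "window") <- window
  out
}

hydropathy_vector <- function(sequence, window = 19) {
  n <- nchar(sequence)
  if (n < window) abort_validation("sequence shorter than hydropathy window")
  v <- kd_values(sequence)
  half <- (window - 1L) / 2L
  full <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
  if (half > 0) {
    full[seq_len(half)] <- full[half + 1L]
    full[(n - half + 1L):n] <- full[n - half]
  }
  full
}

# Maximal runs >= threshold; runs separated by <= merge_gap merged; runs
# shorter than min_len dropped; runs longer than 30 trimmed symmetrically.
segments_from_values <- function(values, threshold, min_len, merge_gap,
                                 max_len = 30L) {
  # rounding the margin makes threshold ties deterministic: windowed means
  # computed in different summation orders agree to well below 1e-6
  above <- round(values - threshold, 6) >= 0
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (nrow(runs) == 0) return(runs)
  merged <- runs[1, , drop = FALSE]
  for (k in seq_len(nrow(runs) - 1L)) {
    gap <- runs[k + 1L, 1L] - merged[nrow(merged), 2L] - 1L
    if (gap <= merge_gap) {
      merged[nrow(merged), 2L] <- runs[k + 1L, 2L]
    } else {
      merged <- rbind(merged, runs[k + 1L, ])
    }
  }
  lens <- merged[, 2L] - merged[, 1L] + 1L
  merged <- merged[lens >= min_len, , drop = FALSE]
  if (nrow(merged) > 0) {
    lens <- merged[, 2L] - merged[, 1L] + 1L
    over <- lens > max_len
    excess <- pmax(lens - max_len, 0L)
    merged[over, 1L] <- merged[over, 1L] + floor(excess[over] / 2)
    merged[over, 2L] <- merged[over, 1L] + max_len - 1L
  }
  unname(merged)
}

#' Predict transmembrane segments from a hydropathy profile
#'
#' Segments are maximal runs of windowed hydropathy at or above `threshold`;
#' runs separated by at most `merge_gap` residues are merged, runs shorter
#' than `min_len` are discarded, and runs longer than 30 residues are trimmed
#' symmetrically to 30.
#'
#' @param hydropathy Long tibble from [compute_hydropathy()].
#' @param threshold Hydropathy call threshold (default 1.5).
#' @param min_len Minimum segment length (default 15).
#' @param merge_gap Maximum gap bridged when merging runs (default 3).
#' @return A tibble `id`, `segment`, `start`, `end` (1-based closed).
#' @export
predict_tm_segments <- function(hydropathy, threshold = 1.5, min_len = 15,
                                merge_gap = 3) {
  hydropathy |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(g, key) {
      m <- segments_from_values(g$hydropathy[order(g$position)],
                                threshold, min_len, merge_gap)
      if (nrow(m) == 0) {
        return(tibble(segment = integer(), start = integer(), end = integer()))
      }
      tibble(segment = seq_len(nrow(m)), start = m[, 1], end = m[, 2])
    }) |>
    dplyr::ungroup()
}

loops_from_segments <- function(seq_len, segments) {
  # segments: matrix (start, end), sorted. Tails included when non-empty.
  bounds <- rbind(c(0L, segments[1, 1]),
                  if (nrow(segments) > 1)
                    cbind(segments[-nrow(segments), 2], segments[-1, 1]),
                  c(segments[nrow(segments), 2], seq_len + 1L))
  loops <- cbind(bounds[, 1] + 1L, bounds[, 2] - 1L)
  # loop index k sits after TM k-1 (k = 1 is the N tail); may be empty
  keep <- loops[, 2] >= loops[, 1]
  list(loops = loops, keep = keep)
}

#' Assign membrane orientation by the positive-inside rule
#'
#' For both candidate orientations the lysine + arginine count over loops
#' labelled inside is summed; the orientation with the larger sum wins, ties
#' going to an intracellular N-terminus. Loop sides then alternate from the
#' N-terminal side.
#'
#' @param sequence Amino-acid string.
#' @param segments Matrix or tibble of TM `start`, `end` (sorted, disjoint).
#' @param id Identifier stored in the model.
#' @return A `topology_model` object; see [tidy.topology_model()].
#' @export
assign_orientation <- function(sequence, segments, id = "protein") {
  segs <- as.matrix(segments[, c("start", "end")][TRUE, , drop = FALSE])
  storage.mode(segs) <- "integer"
  if (nrow(segs) == 0) abort_validation("orientation undefined with zero TM segments")
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  lp <- loops_from_segments(n, segs)
  loops <- lp$loops
  kr_per_loop <- vapply(seq_len(nrow(loops)), function(k) {
    if (loops[k, 2] < loops[k, 1]) return(0L)
    sum(chars[loops[k, 1]:loops[k, 2]] %in% c("K", "R"))
  }, integer(1))
  # loop k (1 = N tail) is on the N-terminal side if k is odd
  odd <- seq_len(nrow(loops)) %% 2 == 1
  kr_n_side <- sum(kr_per_loop[odd])
  kr_c_side <- sum(kr_per_loop[!odd])
  n_term_side <- if (kr_n_side >= kr_c_side) "in" else "out"
  sides <- rep(c(n_term_side, setdiff(c("in", "out"), n_term_side)),
               length.out = nrow(loops))
  structure(list(
    id = id, sequence = sequence, length = n,
    segments = tibble(segment = seq_len(nrow(segs)),
                      start = segs[, 1], end = segs[, 2]),
    loops = tibble(loop = seq_len(nrow(loops)),
                   start = loops[, 1], end = loops[, 2],
                   side = sides)[lp$keep, ],
    n_term_side = n_term_side),
    class = "topology_model")
}

#' Total intracellular and extracellular loop lengths
#'
#' N- and C-terminal tails count as loops.
#'
#' @param topo A `topology_model`.
#' @return A named list with `il_total` and `el_total` (residues).
#' @export
loop_length_summary <- function(topo) {
  stopifnot(inherits(topo, "topology_model"))
  len <- pmax(topo$loops$end - topo$loops$start + 1L, 0L)
  list(il_total = sum(len[topo$loops$side == "in"]),
       el_total = sum(len[topo$loops$side == "out"]))
}

#' Predict full membrane topology for a collection of proteins
#'
#' Runs hydropathy, TM-segment calling and positive-inside orientation per
#' protein. Two optional curation heuristics mirror the manual curation
#' applied to single-sequence predictors: `drop_nterm_reentrant` removes a
#' spurious N-terminal segment (a membrane re-entrant helix mispredicted as a
#' TM domain) when eight segments are found and the first lies within the
#' first 60 residues; `rescue_tm7` rescans C-terminal of segment six with the
#' threshold lowered by 0.5 when exactly six segments are found, recovering a
#' subthreshold final helix.
#'
#' @inheritParams compute_hydropathy
#' @inheritParams predict_tm_segments
#' @param drop_nterm_reentrant,rescue_tm7 Curation flags, off by default.
#' @return A tibble with one row per protein: `id`, `n_tm`, `n_term_side`,
#'   `il_total`, `el_total`, `rescued`, and a `topology` list-column of
#'   `topology_model` objects.
#' @export
predict_topology <- function(records, window = 19, threshold = 1.5,
                             min_len = 15, merge_gap = 3,
                             drop_nterm_reentrant = FALSE, rescue_tm7 = FALSE) {
  records <- validate_protein_records(records)
  purrr::map2_dfr(records$id, records$sequence, function(id, s) {
    vals <- hydropathy_vector(s, window)
    segs <- segments_from_values(vals, threshold, min_len, merge_gap)
    if (drop_nterm_reentrant && nrow(segs) == 8 && segs[1, 2] <= 60) {
      segs <- segs[-1, , drop = FALSE]
    }
    rescued <- FALSE
    if (rescue_tm7 && nrow(segs) == 6) {
      from <- segs[6, 2] + 1L
      if (from <= nchar(s)) {
        extra <- segments_from_values(vals[from:nchar(s)], threshold - 0.5,
                                      min_len, merge_gap)
        if (nrow(extra) > 0) {
          extra <- extra + from - 1L
          segs <- rbind(segs, extra)
          segs <- segs[order(segs[, 1]), , drop = FALSE]
          rescued <- TRUE
        }
      }
    }
    if (nrow(segs) == 0) {
      return(tibble(id = id, n_tm = 0L, n_term_side = NA_character_,
                    il_total = NA_integer_, el_total = NA_integer_,
                    rescued = rescued, topology = list(NULL)))
    }
    topo <- assign_orientation(s, tibble(start = segs[, 1], end = segs[, 2]),
                               id = id)
    ll <- loop_length_summary(topo)
    tibble(id = id, n_tm = nrow(segs), n_term_side = topo$n_term_side,
           il_total = ll$il_total, el_total = ll$el_total,
           rescued = rescued, topology = list(topo))
  })
}

#' @export
print.topology_model <- function(x, ...) {
  cat(sprintf("<topology_model> %s: %d aa, %d TM segment(s), N-terminus %s\n",
              x$id, x$length, nrow(x$segments), x$n_term_side))
  invisible(x)
}

#' Tidy a topology model into one row per feature
#'
#' @param x A `topology_model`.
#' @param ... Unused.
#' @return A tibble with `id`, `feature` (`TM`/`loop`), `index`, `start`,
#'   `end`, `side` (`NA` for TM segments).
#' @export
tidy.topology_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble(id = x$id, feature = "TM", index = x$segments$segment,
           start = x$segments$start, end = x$segments$end,
           side = NA_character_),
    tibble(id = x$id, feature = "loop", index = x$loops$loop,
           start = x$loops$start, end = x$loops$end, side = x$loops$side)
  ) |> dplyr::arrange(.data$start)
}

#' Plot a topology model over its hydropathy profile
#'
#' @param object A `topology_model`.
#' @param window Hydropathy window used for the background curve.
#' @param threshold Threshold line to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.topology_model <- function(object, window = 19, threshold = 1.5, ...) {
  prof <- tibble(position = seq_len(object$length),
                 hydropathy = hydropathy_vector(object$sequence, window))
  segs <- object$segments
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$position, y = .data$hydropathy)) +
    ggplot2::geom_rect(data = segs,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end),
                       ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
                       fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(title = object$id,
                  subtitle = sprintf("%d TM segments, N-terminus %s",
                                     nrow(segs), object$n_term_side),
                  x = "residue", y = "windowed hydropathy") +
    ggplot2::theme_minimal()
}
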