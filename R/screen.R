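#' Retention criteria for candidate screening
#'
#' Bundles the thresholds of the five retention criteria: (i) reciprocal hit
#' in the target family, (ii) length in the ~350-500 aa band (`len_slack`
#' implements the "approximately"), (iii) seven predicted TM domains,
#' (iv) intracellular N-terminus, (v) intracellular loop total exceeding the
#' extracellular total. Hits qualify when the E-value is below `evalue_max`
#' and query coverage exceeds `coverage_min`. A candidate is retained when at
#' least `min_criteria_passed` of the five criteria hold ("most or all").
#'
#' @param len_min,len_max,len_slack Length band (aa) and slack.
#' @param required_tm_count Required predicted TM segment count.
#' @param require_n_in,require_il_gt_el Flags for criteria (iv) and (v).
#' @param evalue_max,coverage_min Hit-qualification thresholds.
#' @param min_criteria_passed Retention threshold, 4 of 5 by default.
#' @return A `filter_criteria` object (a validated named list).
#' @export
filter_criteria <- function(len_min = 350, len_max = 500, len_slack = 30,
                            required_tm_count = 7, require_n_in = TRUE,
                            require_il_gt_el = TRUE, evalue_max = 0.05,
                            coverage_min = 50, min_criteria_passed = 4) {
  if (len_min >= len_max) abort_validation("len_min must be < len_max")
  if (coverage_min <= 0 || coverage_min > 100) {
    abort_validation("coverage_min must lie in (0, 100]")
  }
  if (min_criteria_passed < 1 || min_criteria_passed > 5) {
    abort_validation("min_criteria_passed must lie in 1..5")
  }
  structure(list(len_min = len_min, len_max = len_max, len_slack = len_slack,
                 required_tm_count = required_tm_count,
                 require_n_in = require_n_in,
                 require_il_gt_el = require_il_gt_el,
                 evalue_max = evalue_max, coverage_min = coverage_min,
                 min_criteria_passed = min_criteria_passed),
            class = "filter_criteria")
}

#' Reciprocal-hit criterion
#'
#' Among the query's hits with E-value below `evalue_max` and coverage above
#' `coverage_min`, the minimum-E-value hit must belong to the GRL or DUF3537
#' family, or no qualifying hit may belong to another family. An empty hit
#' list passes (no significant similarity to other protein families).
#'
#' @param hits Hit-table tibble (see [read_hit_table()]).
#' @param query_id Query protein id.
#' @param criteria A [filter_criteria()] object.
#' @return Logical scalar.
#' @export
check_reciprocal <- function(hits, query_id, criteria = filter_criteria()) {
  h <- dplyr::filter(as_tibble(hits), .data$query_id == !!query_id,
                     .data$evalue < criteria$evalue_max,
                     .data$query_coverage > criteria$coverage_min)
  if (nrow(h) == 0) return(TRUE)
  top <- h$subject_family[which.min(h$evalue)]
  if (!is.na(top) && top %in% c("GRL", "DUF3537")) return(TRUE)
  !any(!is.na(h$subject_family) & h$subject_family == "other")
}

#' Length-band criterion
#'
#' @param sequence Amino-acid string (or its length as an integer).
#' @param criteria A [filter_criteria()] object.
#' @return Logical scalar: length within `[len_min - len_slack,
#'   len_max + len_slack]`.
#' @export
check_length <- function(sequence, criteria = filter_criteria()) {
  len <- if (is.character(sequence)) nchar(sequence) else as.integer(sequence)
  len >= criteria$len_min - criteria$len_slack &
    len <= criteria$len_max + criteria$len_slack
}

#' Apply all five retention criteria to one candidate
#'
#' @param record One-row protein-record tibble.
#' @param topo The candidate's `topology_model` (or `NULL` when no TM segment
#'   was predicted).
#' @param hits Hit-table tibble (may be empty).
#' @param criteria A [filter_criteria()] object.
#' @return One-row tibble: per-criterion booleans `c1_reciprocal` ..
#'   `c5_il_gt_el`, `n_passed`, `retained`.
#' @export
apply_filters <- function(record, topo, hits = NULL,
                          criteria = filter_criteria()) {
  hits <- hits %||% tibble(query_id = character(), subject_id = character(),
                           evalue = numeric(), query_coverage = numeric(),
                           subject_family = character())
  c1 <- check_reciprocal(hits, record$id, criteria)
  c2 <- check_length(record$sequence, criteria)
  if (is.null(topo)) {
    c3 <- FALSE; c4 <- FALSE; c5 <- FALSE
  } else {
    ll <- loop_length_summary(topo)
    c3 <- nrow(topo$segments) == criteria$required_tm_count
    c4 <- if (criteria$require_n_in) topo$n_term_side == "in" else TRUE
    c5 <- if (criteria$require_il_gt_el) ll$il_total > ll$el_total else TRUE
  }
  n_passed <- sum(c(c1, c2, c3, c4, c5))
  tibble(protein_id = record$id, c1_reciprocal = c1, c2_length = c2,
         c3_seven_tm = c3, c4_n_in = c4, c5_il_gt_el = c5,
         n_passed = n_passed,
         retained = n_passed >= criteria$min_criteria_passed)
}

#' Screen a candidate collection
#'
#' Applies the five retention criteria to every record, in input order.
#'
#' @param records Protein-record tibble.
#' @param topologies Output of [predict_topology()] for the same records.
#' @param hit_table Hit-table tibble covering the collection (may be empty or
#'   `NULL`).
#' @param criteria A [filter_criteria()] object.
#' @return A `grl_screen` tibble, one row per record, with kingdom metadata
#'   carried through when present. See [glance.grl_screen()].
#' @export
screen_collection <- function(records, topologies, hit_table = NULL,
                              criteria = filter_criteria()) {
  records <- validate_protein_records(records)
  if (!setequal(records$id, topologies$id)) {
    abort_validation("record ids and topology ids do not match")
  }
  out <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    topo <- topologies$topology[[match(records$id[i], topologies$id)]]
    apply_filters(records[i, ], topo, hit_table, criteria)
  })
  if ("kingdom" %in% names(records)) {
    out$kingdom <- records$kingdom[match(out$protein_id, records$id)]
  }
  attr(out, "criteria") <- criteria
  class(out) <- c("grl_screen", class(out))
  out
}

#' Summarise a screening run
#'
#' @param x A `grl_screen` tibble.
#' @param ... Unused.
#' @return One-row tibble: candidate count, retained count, and per-criterion
#'   pass counts.
#' @export
glance.grl_screen <- function(x, ...) {
  tibble(n = nrow(x), n_retained = sum(x$retained),
         pass_c1 = sum(x$c1_reciprocal), pass_c2 = sum(x$c2_length),
         pass_c3 = sum(x$c3_seven_tm), pass_c4 = sum(x$c4_n_in),
         pass_c5 = sum(x$c5_il_gt_el))
}

#' @export
tidy.grl_screen <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(dplyr::starts_with("c"), names_to = "criterion",
                        values_to = "passed")
}

#' Criterion heatmap for a screening run
#'
#' @param object A `grl_screen` tibble.
#' @param ... Unused.
#' @return A ggplot object: candidates by criteria, pass/fail tiles.
#' @export
autoplot.grl_screen <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$criterion,
                                     y = .data$protein_id,
                                     fill = .data$passed)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2b8cbe",
                                          `FALSE` = "#fdbb84")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "passed") +
    ggplot2::theme_minimal()
}
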