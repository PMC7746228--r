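#' Intron positions in protein coordinates
#'
#' For each junction between consecutive exons, the cumulative CDS length `c`
#' at the junction gives the intron's protein-coordinate mark: phase
#' `c mod 3`; for phase 0 the mark sits at the boundary after residue `c/3`
#' (recorded as `residue_index = c/3`), otherwise inside residue
#' `floor(c/3) + 1`.
#'
#' @param gene_models Validated gene-model tibble (see [read_gene_models()]);
#'   may contain several genes.
#' @return A tibble: `protein_id`, `intron` (rank), `residue_index`, `phase`.
#'   Single-exon genes contribute no rows.
#' @export
intron_marks <- function(gene_models) {
  gene_models <- validate_gene_models(gene_models)
  gene_models |>
    dplyr::group_by(.data$gene_id, .data$protein_id) |>
    dplyr::group_modify(function(g, key) {
      lens <- g$exon_end - g$exon_start + 1L
      if (length(lens) < 2) {
        return(tibble(intron = integer(), residue_index = integer(),
                      phase = integer()))
      }
      cum <- cumsum(lens)[-length(lens)]
      phase <- cum %% 3L
      tibble(intron = seq_along(cum),
             residue_index = as.integer(ifelse(phase == 0L, cum / 3L,
                                               floor(cum / 3) + 1L)),
             phase = as.integer(phase))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("protein_id", "intron", "residue_index", "phase")
}

#' Project intron marks onto alignment columns
#'
#' Maps each mark's residue index to the column occupied by that residue in
#' the aligned sequence. Projection is monotone in the residue index.
#'
#' @param marks Output of [intron_marks()].
#' @param msa Aligned protein-record tibble containing every `protein_id`.
#' @return `marks` with an `alignment_column` added.
#' @export
project_to_alignment <- function(marks, msa) {
  msa <- as_tibble(msa)
  missing <- setdiff(unique(marks$protein_id), msa$id)
  if (length(missing) > 0) {
    abort_validation(paste("protein ids absent from alignment:",
                           paste(missing, collapse = ", ")))
  }
  col_of <- function(id, residue) {
    chars <- strsplit(msa$sequence[msa$id == id], "")[[1]]
    nongap <- which(!chars %in% c("-", "."))
    if (residue > length(nongap)) {
      abort_validation(sprintf("residue %d beyond degapped length of %s",
                               residue, id))
    }
    nongap[residue]
  }
  dplyr::mutate(marks,
                alignment_column = purrr::map2_int(
                  .data$protein_id, .data$residue_index,
                  ~ as.integer(col_of(.x, .y))))
}

#' Group intron marks by positional conservation
#'
#' Marks sharing phase and lying within `tolerance` alignment columns of one
#' another are grouped as a shared intron position. When a `grouping` (e.g.
#' kingdom per protein) is supplied, each group reports whether it is shared
#' within one grouping level and whether it bridges levels.
#'
#' @param marks Projected marks (with `alignment_column`).
#' @param grouping Optional named character vector: group label per
#'   `protein_id`.
#' @param tolerance Column tolerance for calling two marks the same position
#'   (default 0, with equal phase always required).
#' @return A tibble, one row per position group: `group`, `phase`,
#'   `column_min`, `column_max`, `n_marks`, `n_proteins`, `protein_ids`,
#'   and with `grouping`: `groupings`, `shared_within`, `shared_between`.
#' @export
conservation_groups <- function(marks, grouping = NULL, tolerance = 0) {
  marks <- as_tibble(marks)
  if (nrow(marks) == 0) {
    return(tibble(group = integer(), phase = integer(),
                  column_min = integer(), column_max = integer(),
                  n_marks = integer(), n_proteins = integer(),
                  protein_ids = character()))
  }
  if (!"alignment_column" %in% names(marks)) {
    abort_validation("marks must be projected to alignment columns first")
  }
  marks <- dplyr::arrange(marks, .data$phase, .data$alignment_column)
  grp <- integer(nrow(marks))
  gid <- 0L
  for (k in seq_len(nrow(marks))) {
    if (k == 1 || marks$phase[k] != marks$phase[k - 1] ||
        marks$alignment_column[k] - marks$alignment_column[k - 1] > tolerance) {
      gid <- gid + 1L
    }
    grp[k] <- gid
  }
  marks$group <- grp
  out <- marks |>
    dplyr::group_by(.data$group, .data$phase) |>
    dplyr::summarise(column_min = min(.data$alignment_column),
                     column_max = max(.data$alignment_column),
                     n_marks = dplyr::n(),
                     n_proteins = dplyr::n_distinct(.data$protein_id),
                     protein_ids = paste(sort(unique(.data$protein_id)),
                                         collapse = ","),
                     .groups = "drop")
  if (!is.null(grouping)) {
    labels <- marks |>
      dplyr::mutate(label = unname(grouping[.data$protein_id])) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        groupings = paste(sort(unique(.data$label)), collapse = ","),
        n_levels = dplyr::n_distinct(.data$label),
        n_proteins = dplyr::n_distinct(.data$protein_id),
        .groups = "drop")
    out <- out |>
      dplyr::left_join(dplyr::select(labels, "group", "groupings",
                                     "n_levels"), by = "group") |>
      dplyr::mutate(shared_within = .data$n_proteins > 1 & .data$n_levels == 1,
                    shared_between = .data$n_levels > 1) |>
      dplyr::select(-"n_levels")
  }
  out
}
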