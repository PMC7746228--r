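#' Construct a C-alpha coordinate set
#'
#' @param id Identifier.
#' @param residue_index Strictly increasing integer residue indices.
#' @param xyz Numeric n x 3 matrix of coordinates in Angstrom.
#' @return A `coordinate_set` object.
#' @export
coordinate_set <- function(id, residue_index, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) abort_validation("xyz must have 3 columns")
  if (length(residue_index) != nrow(xyz)) {
    abort_validation("residue_index and xyz disagree in length")
  }
  if (length(residue_index) < 3) {
    abort_validation("at least 3 residues required for superposition")
  }
  if (any(diff(residue_index) <= 0)) {
    abort_validation("residue_index must be strictly increasing")
  }
  structure(list(id = id, residue_index = as.integer(residue_index),
                 xyz = unname(xyz)),
            class = "coordinate_set")
}

#' @export
print.coordinate_set <- function(x, ...) {
  cat(sprintf("<coordinate_set> %s: %d residues\n", x$id,
              length(x$residue_index)))
  invisible(x)
}

#' @export
tidy.coordinate_set <- function(x, ...) {
  tibble(id = x$id, residue_index = x$residue_index,
         x = x$xyz[, 1], y = x$xyz[, 2], z = x$xyz[, 3])
}

default_correspondence <- function(a, b) {
  shared <- intersect(a$residue_index, b$residue_index)
  cbind(match(shared, a$residue_index), match(shared, b$residue_index))
}

#' Kabsch superposition
#'
#' Least-squares optimal rigid transform of `b` onto `a` over corresponding
#' residue pairs, via singular value decomposition with determinant-sign
#' correction (no reflections).
#'
#' @param a,b `coordinate_set` objects.
#' @param correspondence Two-column matrix of row indices (into `a` and `b`
#'   respectively); defaults to matching shared `residue_index` values.
#' @return A list: `rotation` (3 x 3), `translation` (length 3, applied to
#'   `b` after rotation), `rmsd` (Angstrom), `transformed` (all of `b`'s
#'   coordinates after the transform).
#' @export
kabsch_superpose <- function(a, b, correspondence = NULL) {
  corr <- correspondence %||% default_correspondence(a, b)
  if (nrow(corr) < 3) abort_validation("need at least 3 corresponding pairs")
  A <- a$xyz[corr[, 1], , drop = FALSE]
  B <- b$xyz[corr[, 2], , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- ca - as.numeric(R %*% cb)
  Bt <- sweep(B %*% t(R), 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((Bt - A)^2)))
  transformed <- sweep(b$xyz %*% t(R), 2, t_vec, `+`)
  list(rotation = R, translation = t_vec, rmsd = rmsd,
       transformed = transformed)
}

tm_d0 <- function(L_ref) max(0.5, 1.24 * (L_ref - 15)^(1 / 3) - 1.8)

#' TM-score between two coordinate sets
#'
#' Length-normalised structural similarity
#' `(1/L_ref) * sum_i 1 / (1 + (d_i/d0)^2)` with
#' `d0 = 1.24 (L_ref - 15)^(1/3) - 1.8` floored at 0.5 Angstrom. The score is
#' maximised over the standard iterative subset refinement: superpose on the
#' full correspondence, then re-superpose on pairs closer than `2 d0` until
#' the subset is stable (at most 20 iterations), keeping the best score seen.
#'
#' @inheritParams kabsch_superpose
#' @param L_ref Normalising reference length (at least 16); typically the
#'   length of the designated reference structure.
#' @return The TM-score in [0, 1].
#' @export
tm_score <- function(a, b, correspondence = NULL, L_ref = NULL) {
  corr <- correspondence %||% default_correspondence(a, b)
  L_ref <- L_ref %||% length(a$residue_index)
  if (L_ref < 16) abort_validation("L_ref must be at least 16")
  d0 <- tm_d0(L_ref)
  A <- a$xyz[corr[, 1], , drop = FALSE]
  B <- b$xyz[corr[, 2], , drop = FALSE]
  sub_a <- coordinate_set("a", seq_len(nrow(A)), A)
  sub_b <- coordinate_set("b", seq_len(nrow(B)), B)
  subset <- seq_len(nrow(A))
  best <- 0
  for (iter in seq_len(20)) {
    if (length(subset) < 3) break
    sup <- kabsch_superpose(sub_a, sub_b,
                            correspondence = cbind(subset, subset))
    d <- sqrt(rowSums((sup$transformed - A)^2))
    score <- sum(1 / (1 + (d / d0)^2)) / L_ref
    best <- max(best, score)
    new_subset <- which(d < 2 * d0)
    if (length(new_subset) == 0 || identical(new_subset, subset)) break
    subset <- new_subset
  }
  best
}

#' Classify a fold comparison from its TM-score
#'
#' TM-scores of at most 0.30 indicate random structural similarity; scores of
#' at least 0.5 indicate that the two structures adopt generally the same
#' fold; the band between is ambiguous.
#'
#' @param tm A TM-score in [0, 1] (vectorised).
#' @return A character vector: `"random"`, `"ambiguous"` or `"same_fold"`.
#' @export
classify_fold <- function(tm) {
  stopifnot(all(tm >= 0 & tm <= 1))
  dplyr::case_when(tm <= 0.30 ~ "random",
                   tm >= 0.5 ~ "same_fold",
                   TRUE ~ "ambiguous")
}

#' Compare two structures
#'
#' @inheritParams tm_score
#' @return One-row tibble: `id1`, `id2`, `n_aligned`, `rmsd`, `tm_score`,
#'   `classification`.
#' @export
compare_structures <- function(a, b, correspondence = NULL, L_ref = NULL) {
  corr <- correspondence %||% default_correspondence(a, b)
  sup <- kabsch_superpose(a, b, corr)
  tm <- tm_score(a, b, corr, L_ref %||% length(a$residue_index))
  tibble(id1 = a$id, id2 = b$id, n_aligned = nrow(corr), rmsd = sup$rmsd,
         tm_score = tm, classification = classify_fold(tm))
}

#' Pairwise structure comparison matrices
#'
#' Computes RMSD (symmetric) and TM-score for every ordered pair; the
#' TM-score of pair (i, j) is normalised by the length of structure i, so the
#' TM half-matrix may be asymmetric and both orientations are reported.
#'
#' @param sets List of `coordinate_set` objects.
#' @param correspondences Optional named list of two-column index matrices,
#'   names `"id1|id2"`; defaults to shared residue indices per pair.
#' @return A `structure_matrix`: list of matrices `tm` (row-normalised) and
#'   `rmsd`, plus `ids`.
#' @export
pairwise_structure_matrix <- function(sets, correspondences = NULL) {
  ids <- vapply(sets, `[[`, "", "id")
  n <- length(sets)
  tm <- matrix(1, n, n, dimnames = list(ids, ids))
  rmsd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      key <- paste(ids[i], ids[j], sep = "|")
      corr <- correspondences[[key]] %||%
        default_correspondence(sets[[i]], sets[[j]])
      if (j > i) {
        rmsd[i, j] <- kabsch_superpose(sets[[i]], sets[[j]], corr)$rmsd
        rmsd[j, i] <- rmsd[i, j]
      }
      tm[i, j] <- tm_score(sets[[i]], sets[[j]], corr,
                           L_ref = length(sets[[i]]$residue_index))
    }
  }
  structure(list(tm = tm, rmsd = rmsd, ids = ids),
            class = "structure_matrix")
}

#' @export
tidy.structure_matrix <- function(x, ...) {
  tm_long <- as_tibble(as.data.frame(as.table(x$tm))) |>
    setNames(c("id1", "id2", "tm_score"))
  rmsd_long <- as_tibble(as.data.frame(as.table(x$rmsd))) |>
    setNames(c("id1", "id2", "rmsd"))
  dplyr::left_join(tm_long, rmsd_long, by = c("id1", "id2")) |>
    dplyr::mutate(dplyr::across(c("id1", "id2"), as.character),
                  classification = classify_fold(.data$tm_score))
}

#' Two-half-matrix plot of structure comparisons
#'
#' Upper triangle: TM-score; lower triangle: RMSD. The two halves use
#' different colour scales, drawn as separate layers.
#'
#' @param object A `structure_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.structure_matrix <- function(object, ...) {
  long <- tidy(object)
  ord <- object$ids
  long <- long |>
    dplyr::mutate(i = match(.data$id1, ord), j = match(.data$id2, ord))
  up <- dplyr::filter(long, .data$j > .data$i)
  lo <- dplyr::filter(long, .data$j < .data$i)
  ggplot2::ggplot(up, ggplot2::aes(x = factor(.data$id2, ord),
                                   y = factor(.data$id1, rev(ord)))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$tm_score)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "TM-score") +
    ggplot2::geom_tile(data = lo, ggplot2::aes(color = .data$rmsd),
                       fill = "grey95", linewidth = 1.2) +
    ggplot2::scale_color_viridis_c(option = "magma", name = "RMSD") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Filter structure models on intake metadata
#'
#' Structure models built from very shallow alignments or with low estimated
#' accuracy are excluded before comparison: keep models whose seeding
#' alignment has at least `min_msa_seqs` sequences and whose estimated
#' TM-score is at least `min_estimated_tm`.
#'
#' @param meta Tibble with columns `id`, `n_msa_seqs`, `estimated_tm`.
#' @param min_msa_seqs Minimum alignment depth (default 15).
#' @param min_estimated_tm Minimum estimated TM-score (default 0.17).
#' @return The filtered tibble.
#' @export
filter_model_intake <- function(meta, min_msa_seqs = 15,
                                min_estimated_tm = 0.17) {
  dplyr::filter(as_tibble(meta), .data$n_msa_seqs >= min_msa_seqs,
                .data$estimated_tm >= min_estimated_tm)
}
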