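#' Build a pseudocounted sequence profile from an alignment
#'
#' Columns with more than 50% gaps are dropped. Within a retained column each
#' probability is `(count + pseudocount * background) / (n_nongap +
#' pseudocount)`, so every column sums to one. `X` is treated as missing.
#' This is a deliberately simple position-specific profile (no insert/delete
#' states), sufficient to build an all-vs-all similarity matrix over families.
#'
#' @param msa Aligned protein-record tibble (equal-length gapped sequences,
#'   `-` or `.` as gap) or a character vector of aligned sequences.
#' @param id Profile identifier.
#' @param pseudocount Total pseudocount mass added per column (default 1).
#' @param background Background amino-acid frequencies over [AA20] (uniform
#'   1/20 by default).
#' @return A `sequence_profile`: list with a 20 x L probability matrix
#'   `prob`, `length`, `n_sequences`, `kept_columns`.
#' @export
build_profile <- function(msa, id = "profile", pseudocount = 1,
                          background = rep(1 / 20, 20)) {
  seqs <- if (is.data.frame(msa)) msa$sequence else msa
  if (length(seqs) < 2) abort_validation("a profile needs at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1) {
    abort_validation("aligned sequences must have equal length")
  }
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-6)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  mat[mat == "."] <- "-"
  gap_frac <- colMeans(mat == "-")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) abort_validation("all columns are majority-gap")
  mat <- mat[, keep, drop = FALSE]
  prob <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    counts <- table(factor(col, levels = AA20))
    (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
  }, numeric(20))
  rownames(prob) <- AA20
  structure(list(id = id, prob = prob, length = ncol(prob),
                 n_sequences = length(seqs), kept_columns = keep,
                 background = background),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat(sprintf("<sequence_profile> %s: %d columns from %d sequences\n",
              x$id, x$length, x$n_sequences))
  invisible(x)
}

# Column-pair co-emission score in bits: log2 sum_a p1[a,i] p2[a,j] / bg[a].
profile_score_matrix <- function(p1, p2) {
  log2(t(p1$prob) %*% (p2$prob / p1$background))
}

# Smith-Waterman with affine gaps over a precomputed score matrix.
# Returns best score and the number of aligned column pairs on the optimal
# local path (traceback, ties resolved diagonal > up > left).
sw_affine <- function(S, gap_open, gap_extend) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in rows (left moves)
  F <- matrix(NEG, n + 1, m + 1)  # gap in cols (up moves)
  ptr <- matrix(0L, n + 1, m + 1) # 1 diag, 2 up, 3 left, 0 stop
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    Hi1 <- H[i, ]; Fi1 <- F[i, ]
    Fi <- pmax(Hi1 - gap_open, Fi1 - gap_extend)
    F[i + 1, ] <- Fi
    Hrow <- numeric(m + 1)
    Erow <- rep(NEG, m + 1)
    for (j in seq_len(m)) {
      Erow[j + 1] <- max(Hrow[j] - gap_open, Erow[j] - gap_extend)
      d <- Hi1[j] + S[i, j]
      h <- max(0, d, Fi[j + 1], Erow[j + 1])
      Hrow[j + 1] <- h
      ptr[i + 1, j + 1] <-
        if (h == 0) 0L else if (h == d) 1L else if (h == Fi[j + 1]) 2L else 3L
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
    H[i + 1, ] <- Hrow
    E[i + 1, ] <- Erow
  }
  aligned <- 0L
  i <- bi + 1L; j <- bj + 1L
  while (i > 1 && j > 1 && ptr[i, j] != 0L) {
    step <- ptr[i, j]
    if (step == 1L) { aligned <- aligned + 1L; i <- i - 1L; j <- j - 1L }
    else if (step == 2L) i <- i - 1L
    else j <- j - 1L
  }
  list(score = best, aligned_cols = aligned, end = c(bi, bj))
}

# Calibration constants for the logistic score -> similarity map (bits per
# effective column). Frozen; see the methods vignette.
PROFILE_SIM_MIDPOINT <- 1.5
PROFILE_SIM_SCALE <- 0.35
PROFILE_SIM_MIN_FRAC <- 0.5

#' Align two profiles and score their similarity
#'
#' Local (Smith-Waterman) alignment with affine gaps over column-pair
#' co-emission scores `log2 sum_a p1[i,a] p2[j,a] / bg[a]`. The raw score is
#' mapped to a similarity in [0, 1] by a logistic transform of bits per
#' effective aligned column, calibrated so that self-alignment of a typical
#' family profile exceeds 0.99 and alignment of unrelated random profiles
#' stays near zero. The effective column count is floored at half the shorter
#' profile length so that short spurious local hits cannot inflate the
#' similarity.
#'
#' @param p1,p2 `sequence_profile` objects.
#' @param gap_open,gap_extend Affine gap penalties in bits.
#' @return A list: `score` (bits), `aligned_cols`, `normalized_similarity`.
#' @export
align_profiles <- function(p1, p2, gap_open = 5, gap_extend = 0.5) {
  stopifnot(inherits(p1, "sequence_profile"), inherits(p2, "sequence_profile"))
  S <- profile_score_matrix(p1, p2)
  al <- sw_affine(S, gap_open, gap_extend)
  eff <- max(al$aligned_cols, PROFILE_SIM_MIN_FRAC * min(p1$length, p2$length))
  x <- al$score / eff
  sim <- stats::plogis((x - PROFILE_SIM_MIDPOINT) / PROFILE_SIM_SCALE)
  list(score = al$score, aligned_cols = al$aligned_cols,
       normalized_similarity = unname(sim))
}

#' All-vs-all profile similarity matrix
#'
#' @param profiles A list of `sequence_profile` objects.
#' @param ... Passed to [align_profiles()].
#' @return A `similarity_matrix`: symmetric numeric matrix in [0, 1] with
#'   unit diagonal, ids as dimnames.
#' @export
profile_similarity_matrix <- function(profiles, ...) {
  if (length(profiles) < 2) abort_validation("need at least 2 profiles")
  ids <- vapply(profiles, `[[`, "", "id")
  n <- length(profiles)
  M <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- align_profiles(profiles[[i]], profiles[[j]], ...)$normalized_similarity
      M[i, j] <- s
      M[j, i] <- s
    }
  }
  dimnames(M) <- list(ids, ids)
  structure(M, class = c("similarity_matrix", "matrix"))
}

#' Cluster a similarity matrix
#'
#' Average-linkage hierarchical clustering over distance `1 - similarity`.
#'
#' @param simmat A `similarity_matrix`.
#' @param method Linkage method for [stats::hclust()].
#' @return An `hclust` object; convert with [ape::as.phylo()] for newick
#'   output.
#' @export
cluster_similarity <- function(simmat, method = "average") {
  hclust(as.dist(1 - unclass(simmat)), method = method)
}

#' Tidy a similarity matrix into long form
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return A tibble `id1`, `id2`, `similarity` (all ordered pairs).
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame(as.table(m)), .name_repair = "minimal") |>
    setNames(c("id1", "id2", "similarity")) |>
    dplyr::mutate(dplyr::across(c("id1", "id2"), as.character))
}

#' Heatmap of a similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$id1, y = .data$id2,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
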