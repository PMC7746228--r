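#' Global pairwise alignment with percent identity
#'
#' Needleman-Wunsch global alignment with affine gaps under BLOSUM62
#' (delegated to Biostrings). Percent identity is computed over columns where
#' both sequences are non-gap: `100 * identical / both_non_gap`.
#'
#' @param r1,r2 One-row protein-record tibbles (or lists with `id`,
#'   `sequence`).
#' @param substitution_matrix Name of the substitution matrix (default
#'   `"BLOSUM62"`).
#' @param gap_open,gap_extend Gap penalties.
#' @return One-row tibble: `id1`, `id2`, `score`, `identity_pct`, `aligned1`,
#'   `aligned2`.
#' @export
global_align <- function(r1, r2, substitution_matrix = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (nchar(r1$sequence) == 0 || nchar(r2$sequence) == 0) {
    abort_validation("cannot align empty sequences")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(r1$sequence), Biostrings::AAString(r2$sequence),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  a1 <- as.character(Biostrings::alignedPattern(aln))
  a2 <- as.character(Biostrings::alignedSubject(aln))
  tibble(id1 = r1$id, id2 = r2$id, score = Biostrings::score(aln),
         identity_pct = aligned_identity(a1, a2),
         aligned1 = unname(a1), aligned2 = unname(a2))
}

aligned_identity <- function(a1, a2) {
  c1 <- strsplit(a1, "")[[1]]
  c2 <- strsplit(a2, "")[[1]]
  stopifnot(length(c1) == length(c2))
  both <- c1 != "-" & c2 != "-"
  if (!any(both)) return(0)
  100 * sum(c1[both] == c2[both]) / sum(both)
}

#' All-pairs percent-identity matrix
#'
#' @param records Protein-record tibble with at least 2 rows.
#' @param ... Passed to [global_align()].
#' @return A symmetric matrix of identities with 100 on the diagonal.
#' @export
identity_matrix <- function(records, ...) {
  records <- validate_protein_records(records)
  n <- nrow(records)
  if (n < 2) abort_validation("need at least 2 records")
  M <- diag(100, n)
  dimnames(M) <- list(records$id, records$id)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pid <- global_align(records[i, ], records[j, ], ...)$identity_pct
      M[i, j] <- pid
      M[j, i] <- pid
    }
  }
  M
}

#' Minimum pairwise identity in a collection
#'
#' @inheritParams identity_matrix
#' @return The minimum off-diagonal percent identity.
#' @export
min_identity <- function(records, ...) {
  M <- identity_matrix(records, ...)
  min(M[upper.tri(M)])
}

#' Identity matrix to evolutionary distances
#'
#' p-distance `1 - identity/100` by default; Poisson correction
#' `-log(1 - p)` optionally.
#'
#' @param id_matrix Output of [identity_matrix()].
#' @param correction `"p"` or `"poisson"`.
#' @return A symmetric distance matrix.
#' @export
identity_to_distance <- function(id_matrix, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  p <- 1 - id_matrix / 100
  d <- if (correction == "poisson") -log(pmax(1 - p, 1e-10)) else p
  diag(d) <- 0
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via ape); negative branch-length estimates are
#' clamped to zero. Exact on additive distance matrices.
#'
#' @param d Symmetric distance matrix over at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) abort_validation("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    abort_validation("distance matrix must be symmetric")
  }
  tree <- ape::nj(as.dist(d))
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

# ---- progressive MSA -------------------------------------------------------

block_freq <- function(block) {
  # block: character matrix (sequences x columns); gap columns give zeros
  vapply(seq_len(ncol(block)), function(j) {
    col <- block[, j]
    col <- col[col %in% AA20]
    if (length(col) == 0) return(numeric(20))
    as.numeric(table(factor(col, levels = AA20))) / length(col)
  }, numeric(20))
}

# Global NW over profile columns, linear gap; returns merged gapped blocks.
merge_blocks <- function(A, B, gap = 0.4) {
  fa <- block_freq(A); fb <- block_freq(B)
  n <- ncol(A); m <- ncol(B)
  S <- t(fa) %*% fb  # co-emission probability, in [0, 1]
  H <- matrix(0, n + 1, m + 1)
  H[, 1] <- -gap * (0:n)
  H[1, ] <- -gap * (0:m)
  ptr <- matrix(0L, n + 1, m + 1)
  ptr[, 1] <- 2L; ptr[1, ] <- 3L; ptr[1, 1] <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- H[i, j] + S[i, j]
      u <- H[i, j + 1] - gap
      l <- H[i + 1, j] - gap
      best <- max(d, u, l)
      H[i + 1, j + 1] <- best
      ptr[i + 1, j + 1] <- if (best == d) 1L else if (best == u) 2L else 3L
    }
  }
  # traceback
  path <- integer(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1 || j > 1) {
    step <- ptr[i, j]
    path <- c(step, path)
    if (step == 1L) { i <- i - 1L; j <- j - 1L }
    else if (step == 2L) i <- i - 1L
    else j <- j - 1L
  }
  out <- matrix("-", nrow(A) + nrow(B), length(path))
  rownames(out) <- c(rownames(A), rownames(B))
  ai <- 0L; bj <- 0L
  for (k in seq_along(path)) {
    if (path[k] != 3L) { ai <- ai + 1L; out[seq_len(nrow(A)), k] <- A[, ai] }
    if (path[k] != 2L) { bj <- bj + 1L; out[nrow(A) + seq_len(nrow(B)), k] <- B[, bj] }
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Profile-profile merges up a guide tree (average-linkage clustering of
#' p-distances from all-pairs global alignment by default). Every input
#' sequence is recoverable from the output by removing gaps. This is a
#' desk-scale progressive aligner, not a replacement for a production MSA
#' tool.
#'
#' @param records Protein-record tibble (at least 2 rows).
#' @param guide Optional guide: an `hclust` object, or a `phylo` tree (its
#'   cophenetic distances are clustered).
#' @param gap Linear gap penalty for the profile merge.
#' @return An aligned protein-record tibble (`id`, `sequence`) with
#'   equal-length gapped sequences, input order preserved.
#' @export
progressive_msa <- function(records, guide = NULL, gap = 0.4) {
  records <- validate_protein_records(records)
  n <- nrow(records)
  if (n < 2) abort_validation("need at least 2 records")
  blocks <- purrr::map(seq_len(n), function(i) {
    m <- matrix(strsplit(records$sequence[i], "")[[1]], nrow = 1)
    rownames(m) <- records$id[i]
    m
  })
  if (n == 2) {
    merged <- merge_blocks(blocks[[1]], blocks[[2]], gap)
  } else {
    hc <- if (is.null(guide)) {
      hclust(as.dist(identity_to_distance(identity_matrix(records))),
             method = "average")
    } else if (inherits(guide, "hclust")) {
      guide
    } else if (inherits(guide, "phylo")) {
      cd <- ape::cophenetic.phylo(guide)[records$id, records$id]
      hclust(as.dist(cd), method = "average")
    } else {
      abort_validation("guide must be NULL, an hclust, or a phylo tree")
    }
    node_blocks <- vector("list", n - 1)
    get_block <- function(k) if (k < 0) blocks[[-k]] else node_blocks[[k]]
    for (s in seq_len(n - 1)) {
      node_blocks[[s]] <- merge_blocks(get_block(hc$merge[s, 1]),
                                       get_block(hc$merge[s, 2]), gap)
    }
    merged <- node_blocks[[n - 1]]
  }
  aligned <- apply(merged, 1, paste, collapse = "")
  tibble(id = records$id,
         sequence = unname(aligned[records$id]))
}

#' Remove gaps from aligned sequences
#'
#' @param msa Aligned protein-record tibble.
#' @return The tibble with gaps stripped from `sequence`.
#' @export
degap <- function(msa) {
  dplyr::mutate(as_tibble(msa),
                sequence = gsub("[-.]", "", .data$sequence))
}
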