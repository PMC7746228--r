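# Independent oracle implementations used to cross-check the package code.
# These are written from the definitions, deliberately not sharing code with
# the implementation under test.

KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
        G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
        P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# windowed hydropathy by direct per-position averaging
oracle_hydropathy <- function(sequence, window) {
  chars <- strsplit(sequence, "")[[1]]
  v <- unname(KD[chars]); v[is.na(v)] <- 0
  n <- length(v); half <- (window - 1) / 2
  out <- vapply(seq_len(n), function(i) {
    lo <- i - half; hi <- i + half
    if (lo < 1) { lo <- 1; hi <- window }
    if (hi > n) { hi <- n; lo <- n - window + 1 }
    mean(v[lo:hi])
  }, numeric(1))
  out
}

# run detection / merge / drop / trim written independently
oracle_segments <- function(values, threshold, min_len, merge_gap) {
  above <- which(round(values - threshold, 6) >= 0)
  if (length(above) == 0) return(matrix(numeric(0), ncol = 2))
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  iv <- t(vapply(runs, range, numeric(2)))
  k <- 1
  while (k < nrow(iv)) {
    if (iv[k + 1, 1] - iv[k, 2] - 1 <= merge_gap) {
      iv[k, 2] <- iv[k + 1, 2]
      iv <- iv[-(k + 1), , drop = FALSE]
    } else k <- k + 1
  }
  iv <- iv[iv[, 2] - iv[, 1] + 1 >= min_len, , drop = FALSE]
  for (k in seq_len(nrow(iv))) {
    len <- iv[k, 2] - iv[k, 1] + 1
    if (len > 30) {
      iv[k, 1] <- iv[k, 1] + floor((len - 30) / 2)
      iv[k, 2] <- iv[k, 1] + 29
    }
  }
  unname(iv)
}

# brute-force motif scan over a start range, string operations only
oracle_motif_scan <- function(sequence, lo, hi, count_conservative = TRUE) {
  hset <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  best <- NULL
  for (s in lo:hi) {
    w <- strsplit(substr(sequence, s, s + 8), "")[[1]]
    cnt <- (w[1] %in% c("T", "S")) +
      (w[2] == "Y" || (count_conservative && w[2] == "F")) +
      (w[8] %in% c("Q", "K", "E")) +
      (w[9] %in% c("F", "L", "M"))
    h <- sum(w[3:7] %in% hset)
    if (is.null(best) || cnt > best$cnt || (cnt == best$cnt && h > best$h)) {
      best <- list(start = s, cnt = cnt, h = h)
    }
  }
  best
}

# exhaustive enumeration of global alignments with affine gaps
# (gap cost = open + extend * length, charged per gap run)
oracle_global_score <- function(s1, s2, submat, gap_open, gap_extend) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, score, state) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, score + submat[a[i], b[j]], 0L)
    }
    if (i <= length(a)) {
      pen <- if (state == 1L) gap_extend else gap_open + gap_extend
      recurse(i + 1, j, score - pen, 1L)
    }
    if (j <= length(b)) {
      pen <- if (state == 2L) gap_extend else gap_open + gap_extend
      recurse(i, j + 1, score - pen, 2L)
    }
  }
  recurse(1L, 1L, 0, 0L)
  best
}

# coarse grid search over rotations for the minimal RMSD after centering
oracle_grid_rmsd <- function(A, B, step_deg = 12) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  angles <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  half <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a1 in angles) for (a2 in half) for (a3 in angles) {
    Rz1 <- matrix(c(cos(a1), -sin(a1), 0, sin(a1), cos(a1), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(a2), 0, sin(a2), 0, 1, 0, -sin(a2), 0, cos(a2)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(a3), -sin(a3), 0, sin(a3), cos(a3), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    r <- sqrt(mean(rowSums((B %*% t(R) - A)^2)))
    if (r < best) best <- r
  }
  best
}

random_protein <- function(len, seed) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(seed)
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# a minimal hand-built topology model for motif-scanner tests
fake_topology <- function(id, sequence, seg_start, seg_end) {
  assign_orientation(sequence,
                     tibble::tibble(start = seg_start, end = seg_end),
                     id = id)
}
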