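# Seeded generators for every input class the pipeline consumes, with planted
# ground truth recorded for parameter-recovery tests. A single integer seed
# drives per-item substreams so adding one item never shifts another.

substream <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1000003) * 2017 + i * 7919) %% 2147483629L + 1L
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Residue pools. TM stretches are hydropathy-weighted; the last TM segment
# and the first residues of the following tail avoid every residue that could
# form a stray motif anchor (T/S/Y/F/L/M/Q/K/E), so the planted anchor count
# is the unique maximum over the scanned region.
TM_POOL <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8)
TM7_POOL <- c(I = 4.5, V = 4.2, A = 1.8, C = 2.5)
LOOP_IN_POOL <- c(K = 2, R = 2, D = 0.75, E = 0.75, N = 0.75, Q = 0.75,
                  S = 0.75, T = 0.75, G = 0.75, P = 0.75)
LOOP_OUT_POOL <- c(D = 1, E = 1, N = 1, Q = 1, S = 1, T = 1, G = 1, P = 1)
TAIL_HEAD_OUT_POOL <- c(D = 1, N = 1, G = 1, P = 1, H = 1)
TAIL_HEAD_IN_POOL <- c(R = 4, D = 1, N = 1, G = 1, P = 1)

r_res <- function(n, pool) {
  if (n <= 0) return(character(0))
  sample(names(pool), n, replace = TRUE, prob = pool)
}

# Distribute `delta` residues (possibly negative) across loops of one side,
# respecting per-loop bounds. Returns adjusted lengths or NULL if infeasible.
spread_delta <- function(lens, delta, lo, hi) {
  for (k in seq_along(lens)) {
    if (delta == 0) break
    room <- if (delta > 0) hi - lens[k] else lo - lens[k]
    take <- if (delta > 0) min(delta, room) else max(delta, room)
    lens[k] <- lens[k] + take
    delta <- delta - take
  }
  if (delta != 0) NULL else lens
}

generate_grl_once <- function(n_tm, tm_len_range, loop_in_range,
                              loop_out_range, total_len_range,
                              motif_anchors_conserved, motif_in_tm7,
                              n_term_side, id) {
  sides <- rep(c(n_term_side, setdiff(c("in", "out"), n_term_side)),
               length.out = n_tm + 1)
  tm_len <- sample(tm_len_range[1]:tm_len_range[2], n_tm, replace = TRUE)
  if (motif_in_tm7) {
    tm_len[n_tm] <- sample(26:30, 1)  # room for the motif's polar anchors
  }
  loop_len <- integer(n_tm + 1)
  for (k in seq_len(n_tm + 1)) {
    rng <- if (sides[k] == "in") loop_in_range else loop_out_range
    loop_len[k] <- sample(rng[1]:rng[2], 1)
  }
  if (!is.null(total_len_range)) {
    total <- sum(tm_len) + sum(loop_len)
    target <- min(max(total, total_len_range[1]), total_len_range[2])
    delta <- target - total
    if (delta != 0) {
      for (side in c("in", "out")) {
        idx <- which(sides == side)
        rng <- if (side == "in") loop_in_range else loop_out_range
        adj <- spread_delta(loop_len[idx], delta, rng[1], rng[2])
        if (!is.null(adj)) {
          delta <- delta - (sum(adj) - sum(loop_len[idx]))
          loop_len[idx] <- adj
        }
        if (delta == 0) break
      }
      if (delta != 0) abort_validation("infeasible length constraints")
    }
  }

  chars <- character(0)
  tm_start <- integer(n_tm); tm_end <- integer(n_tm)
  loop_rows <- list()
  motif_start_abs <- NA_integer_
  conserved_pos <- integer(0)
  for (k in seq_len(n_tm + 1)) {
    lstart <- length(chars) + 1L
    pool <- if (sides[k] == "in") LOOP_IN_POOL else LOOP_OUT_POOL
    if (k == n_tm + 1 && motif_in_tm7) {
      head_pool <- if (sides[k] == "in") TAIL_HEAD_IN_POOL else TAIL_HEAD_OUT_POOL
      nh <- min(loop_len[k], 18L)
      chars <- c(chars, r_res(nh, head_pool), r_res(loop_len[k] - nh, pool))
    } else {
      chars <- c(chars, r_res(loop_len[k], pool))
    }
    loop_rows[[k]] <- tibble(loop = k, start = lstart,
                             end = length(chars), side = sides[k])
    if (k <= n_tm) {
      tm_start[k] <- length(chars) + 1L
      pool_tm <- if (k == n_tm && motif_in_tm7) TM7_POOL else TM_POOL
      seg <- r_res(tm_len[k], pool_tm)
      if (k == n_tm && motif_in_tm7) {
        t7 <- tm_len[k]
        mstart <- t7 - 14L  # motif ends 6 residues before the segment end
        conserved_pos <- sort(sample(1:4, motif_anchors_conserved))
        anchor_res <- c(
          if (1 %in% conserved_pos) sample(c("T", "S"), 1) else "I",
          if (2 %in% conserved_pos) "Y" else "I",
          if (3 %in% conserved_pos) sample(c("Q", "K", "E"), 1) else "I",
          if (4 %in% conserved_pos) sample(c("L", "M"), 1) else "I")
        motif <- c(anchor_res[1], anchor_res[2],
                   sample(c("I", "V"), 5, replace = TRUE),
                   anchor_res[3], anchor_res[4])
        seg[mstart:(mstart + 8L)] <- motif
        motif_start_abs <- length(chars) + mstart
      }
      chars <- c(chars, seg)
      tm_end[k] <- length(chars)
    }
  }
  list(
    record = tibble(id = id, sequence = paste(chars, collapse = "")),
    truth = list(
      n_tm = n_tm,
      tm_intervals = tibble(segment = seq_len(n_tm),
                            start = tm_start, end = tm_end),
      loops = dplyr::bind_rows(loop_rows),
      n_term_side = n_term_side,
      motif_start = motif_start_abs,
      anchors_conserved = if (motif_in_tm7) motif_anchors_conserved else 0L,
      conserved_positions = conserved_pos,
      il_total = sum(loop_len[sides == "in"]),
      el_total = sum(loop_len[sides == "out"])))
}

#' Generate a GRL-like seven-TM protein with planted ground truth
#'
#' Emits a protein whose architecture realises the screening criteria by
#' construction: `n_tm` hydrophobic membrane segments, charged loops with the
#' positive-inside K/R bias on the designated intracellular side,
#' intracellular loop totals exceeding extracellular ones, total length in
#' the target band, and (optionally) the nine-residue TM7 motif planted with
#' exactly `motif_anchors_conserved` matching anchors. The generated record
#' is self-validated against the topology and motif modules; the construction
#' is resampled (deterministically under the seed) until the planted truth is
#' recovered, so generator output is guaranteed consistent.
#'
#' @param n_tm Number of TM segments (default 7).
#' @param tm_len_range TM segment length range; the default (21, 28) makes
#'   every planted helix recoverable at the topology module's default window,
#'   threshold and minimum length.
#' @param loop_in_range,loop_out_range Loop length ranges by side (residues);
#'   inside loops are longer in expectation.
#' @param total_len_range Target band for total length (aa).
#' @param motif_anchors_conserved Planted anchor-conservation count, 0-4.
#' @param motif_in_tm7 Plant the motif in the last TM segment?
#' @param n_term_side Side of the N-terminus, `"in"` or `"out"`.
#' @param seed Integer seed; output is bitwise reproducible.
#' @param id Record identifier.
#' @return A list with `record` (one-row protein tibble) and `truth` (planted
#'   TM intervals, loop sides, motif start, anchor count, loop totals).
#' @export
make_grl_like <- function(n_tm = 7, tm_len_range = c(21, 28),
                          loop_in_range = c(20, 80),
                          loop_out_range = c(9, 20),
                          total_len_range = c(350, 500),
                          motif_anchors_conserved = 4, motif_in_tm7 = TRUE,
                          n_term_side = c("in", "out"), seed = 1,
                          id = NULL) {
  n_term_side <- match.arg(n_term_side)
  stopifnot(motif_anchors_conserved %in% 0:4)
  id <- id %||% sprintf("grl_s%d", seed)
  for (attempt in seq_len(50)) {
    out <- with_seed(substream(seed, attempt), {
      generate_grl_once(n_tm, tm_len_range, loop_in_range, loop_out_range,
                        total_len_range, motif_anchors_conserved,
                        motif_in_tm7, n_term_side, id)
    })
    topo_tbl <- predict_topology(out$record)
    ok <- topo_tbl$n_tm[1] == n_tm &&
      identical(topo_tbl$n_term_side[1], n_term_side)
    if (ok && motif_in_tm7) {
      m <- scan_tm7(out$record, topo_tbl$topology[[1]],
                    count_conservative = TRUE)
      ok <- m$anchors_matched == motif_anchors_conserved &&
        (motif_anchors_conserved == 0 ||
           identical(m$start, out$truth$motif_start))
    }
    if (ok) {
      out$truth$seed <- seed
      out$truth$attempts <- attempt
      return(out)
    }
  }
  abort_validation("generator failed to realise planted truth in 50 attempts")
}

DECOY_KINDS <- c("short", "long", "six_tm", "n_out", "el_gt_il", "gpcr_like")

decoy_expected <- list(
  short     = c(c1 = TRUE, c2 = FALSE, c3 = TRUE, c4 = TRUE, c5 = TRUE),
  long      = c(c1 = TRUE, c2 = FALSE, c3 = TRUE, c4 = TRUE, c5 = TRUE),
  six_tm    = c(c1 = TRUE, c2 = TRUE, c3 = FALSE, c4 = TRUE, c5 = TRUE),
  n_out     = c(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = FALSE, c5 = TRUE),
  el_gt_il  = c(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = TRUE, c5 = FALSE),
  gpcr_like = c(c1 = TRUE, c2 = TRUE, c3 = TRUE, c4 = FALSE, c5 = FALSE))

#' Generate a decoy protein violating named screening criteria
#'
#' Each decoy kind violates an exact set of retention criteria and passes the
#' rest: `short`/`long` fail the length band only; `six_tm` fails the TM
#' count only; `n_out` fails the intracellular N-terminus only; `el_gt_il`
#' fails the loop-balance criterion only; `gpcr_like` (the opposite-topology
#' contrast) fails both orientation criteria. The decoy is self-validated
#' against the screen (with a qualifying in-family hit supplied for the
#' reciprocal criterion) and resampled deterministically until the failure
#' pattern is exact.
#'
#' @param kind One of `"short"`, `"long"`, `"six_tm"`, `"n_out"`,
#'   `"el_gt_il"`, `"gpcr_like"`.
#' @param seed Integer seed.
#' @param id Record identifier.
#' @return A list with `record`, `truth` (including `kind` and the expected
#'   per-criterion pattern).
#' @export
make_decoy <- function(kind, seed = 1, id = NULL) {
  if (length(kind) == 0) abort_validation("decoy kind must be supplied")
  kind <- match.arg(kind, DECOY_KINDS)
  id <- id %||% sprintf("decoy_%s_s%d", kind, seed)
  args <- switch(kind,
    short = list(tm_len_range = c(21, 23), loop_in_range = c(11, 16),
                 loop_out_range = c(8, 10), total_len_range = NULL),
    long = list(loop_in_range = c(60, 110), total_len_range = c(560, 690)),
    six_tm = list(n_tm = 6),
    n_out = list(n_term_side = "out"),
    el_gt_il = list(loop_in_range = c(5, 15), loop_out_range = c(35, 75)),
    gpcr_like = list(n_term_side = "out", loop_in_range = c(5, 15),
                     loop_out_range = c(35, 75)))
  expected <- decoy_expected[[kind]]
  for (attempt in seq_len(50)) {
    gen_args <- c(args, list(seed = substream(seed, 100 + attempt), id = id,
                             motif_anchors_conserved = 4, motif_in_tm7 = TRUE))
    gen <- try(do.call(generate_decoy_base, gen_args), silent = TRUE)
    if (inherits(gen, "try-error")) next
    topo_tbl <- predict_topology(gen$record)
    res <- apply_filters(gen$record, topo_tbl$topology[[1]],
                         make_hit_table(id))
    got <- c(c1 = res$c1_reciprocal, c2 = res$c2_length, c3 = res$c3_seven_tm,
             c4 = res$c4_n_in, c5 = res$c5_il_gt_el)
    if (identical(unname(got), unname(expected))) {
      gen$truth$kind <- kind
      gen$truth$expected_criteria <- expected
      gen$truth$seed <- seed
      return(gen)
    }
  }
  abort_validation(sprintf("decoy '%s' failed self-validation in 50 attempts",
                           kind))
}

# decoys reuse the architecture generator without its own retry loop
generate_decoy_base <- function(seed, id, n_tm = 7,
                                tm_len_range = c(21, 28),
                                loop_in_range = c(20, 80),
                                loop_out_range = c(9, 20),
                                total_len_range = c(350, 500),
                                motif_anchors_conserved = 4,
                                motif_in_tm7 = TRUE, n_term_side = "in") {
  with_seed(seed, {
    generate_grl_once(n_tm, tm_len_range, loop_in_range, loop_out_range,
                      total_len_range, motif_anchors_conserved, motif_in_tm7,
                      n_term_side, id)
  })
}

#' Minimal qualifying hit table for synthetic candidates
#'
#' One strong in-family hit per query: E-value 1e-20, coverage 90, subject
#' family `GRL` (configurable), satisfying the reciprocal criterion.
#'
#' @param ids Query ids.
#' @param top_family Family of the top hit.
#' @return A hit-table tibble.
#' @export
make_hit_table <- function(ids, top_family = "GRL") {
  tibble(query_id = ids, subject_id = "family_ref",
         evalue = 1e-20, query_coverage = 90,
         subject_family = top_family)
}

HYDRO_SET <- c("I", "V", "L", "F", "M", "A", "C")
POLAR_SET <- c("D", "E", "N", "Q", "S", "T", "G", "P", "K", "R", "H")

mutate_sequence <- function(sequence, rate, indel_rate = 0) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- runif(length(chars)) < rate
  for (i in which(hit)) {
    pool <- if (chars[i] %in% HYDRO_SET) HYDRO_SET else POLAR_SET
    chars[i] <- sample(setdiff(pool, chars[i]), 1)
  }
  if (indel_rate > 0) {
    n_events <- stats::rbinom(1, length(chars), indel_rate)
    for (e in seq_len(n_events)) {
      pos <- sample(length(chars), 1)
      if (runif(1) < 0.5 && length(chars) > 10) {
        del <- sample(1:3, 1)
        chars <- chars[-(pos:min(pos + del - 1, length(chars)))]
      } else {
        ins <- r_res(sample(1:3, 1), LOOP_OUT_POOL)
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Generate a diverged protein family with recorded identities
#'
#' Mutates a generated ancestor along a star or two-clade topology.
#' Substitutions stay within hydrophobic or polar residue categories so the
#' membrane architecture is preserved; optional small indels. Realised
#' pairwise identities are recorded in the truth (positional when ungapped,
#' alignment-based when indels are on).
#'
#' @param n Number of family members.
#' @param divergence Per-site substitution probability from the root (for
#'   `two_clade`, clade roots diverge at this rate and leaves at a quarter of
#'   it within clades).
#' @param indel_rate Per-site indel event probability (default 0).
#' @param topology `"star"` or `"two_clade"`.
#' @param seed Integer seed.
#' @param prefix Id prefix for members.
#' @param ancestor Optional ancestor record; generated if missing.
#' @return A list with `records` (tibble, with `clade` for `two_clade`) and
#'   `truth` (realised identity matrix, clades, ancestor).
#' @export
make_family <- function(n = 6, divergence = 0.2, indel_rate = 0,
                        topology = c("star", "two_clade"), seed = 1,
                        prefix = "fam", ancestor = NULL) {
  topology <- match.arg(topology)
  if (is.null(ancestor)) {
    ancestor <- make_grl_like(seed = substream(seed, 1),
                              id = paste0(prefix, "_anc"))$record
  }
  clades <- NULL
  if (topology == "star") {
    seqs <- vapply(seq_len(n), function(i) {
      with_seed(substream(seed, 10 + i),
                mutate_sequence(ancestor$sequence, divergence, indel_rate))
    }, "")
    ids <- sprintf("%s_%d", prefix, seq_len(n))
  } else {
    roots <- vapply(1:2, function(cl) {
      with_seed(substream(seed, 200 + cl),
                mutate_sequence(ancestor$sequence, divergence, indel_rate))
    }, "")
    clades <- rep(c("A", "B"), length.out = n)
    seqs <- vapply(seq_len(n), function(i) {
      with_seed(substream(seed, 300 + i),
                mutate_sequence(roots[(i - 1) %% 2 + 1], divergence / 4,
                                indel_rate))
    }, "")
    ids <- sprintf("%s_%s%d", prefix, clades, ceiling(seq_len(n) / 2))
  }
  records <- tibble(id = ids, sequence = seqs)
  if (!is.null(clades)) records$clade <- clades
  ident <- if (indel_rate == 0) {
    M <- diag(100, n); dimnames(M) <- list(ids, ids)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- strsplit(seqs[i], "")[[1]]; b <- strsplit(seqs[j], "")[[1]]
      M[i, j] <- M[j, i] <- 100 * mean(a == b)
    }
    M
  } else {
    identity_matrix(records)
  }
  list(records = records,
       truth = list(realized_identity = ident, clades = clades,
                    divergence = divergence, ancestor = ancestor))
}

#' Generate a gene model consistent with a protein record
#'
#' Places introns at the stated codon positions and phases: an intron with
#' phase 0 follows the given codon's last nucleotide; phases 1 and 2 fall
#' inside the codon.
#'
#' @param record One-row protein-record tibble.
#' @param intron_positions Tibble or data frame with columns `codon`,
#'   `phase`; may be empty for an intron-free gene.
#' @param gene_id Gene identifier (defaults to `<id>_gene`).
#' @return A validated gene-model tibble (one row per exon).
#' @export
make_gene_model <- function(record, intron_positions = NULL, gene_id = NULL) {
  len_nt <- 3L * nchar(record$sequence)
  gene_id <- gene_id %||% paste0(record$id, "_gene")
  ip <- as_tibble(intron_positions %||%
                    tibble(codon = integer(), phase = integer()))
  if (nrow(ip) > 0) {
    cuts <- ifelse(ip$phase == 0L, 3L * ip$codon,
                   3L * (ip$codon - 1L) + ip$phase)
    cuts <- as.integer(cuts)
    if (any(cuts <= 0) || any(cuts >= len_nt) || any(diff(cuts) <= 0)) {
      abort_validation("intron positions must be increasing and inside the CDS")
    }
  } else {
    cuts <- integer(0)
  }
  bounds <- c(0L, cuts, len_nt)
  validate_gene_models(tibble(
    gene_id = gene_id, protein_id = record$id, strand = "+",
    exon_start = bounds[-length(bounds)] + 1L,
    exon_end = bounds[-1]))
}

#' Generate an idealised seven-helix coordinate bundle
#'
#' Helices are ideal alpha-helices (1.5 Angstrom rise and 100 degrees of
#' twist per residue around a 2.3 Angstrom helical radius) placed on a ring;
#' with `antiparallel` alternate helices run in opposite directions, the
#' packing arrangement characteristic of this receptor fold. Per-atom
#' Gaussian noise of standard deviation `noise_sd` perturbs the coordinates.
#'
#' @param n_helices Number of helices (default 7).
#' @param residues_per_helix Residues per helix (scalar or vector recycled
#'   over helices).
#' @param rise,twist,helix_radius Helix geometry (Angstrom, degrees,
#'   Angstrom).
#' @param ring_radius Radius of the helix-centre ring (Angstrom).
#' @param antiparallel Alternate helix directions?
#' @param noise_sd Gaussian perturbation per coordinate (Angstrom).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @param id Identifier.
#' @return A `coordinate_set` with sequential residue indices.
#' @export
make_bundle <- function(n_helices = 7, residues_per_helix = 25, rise = 1.5,
                        twist = 100, helix_radius = 2.3, ring_radius = 12,
                        antiparallel = TRUE, noise_sd = 0, seed = 1,
                        id = NULL) {
  rph <- rep(residues_per_helix, length.out = n_helices)
  id <- id %||% sprintf("bundle_s%d", seed)
  coords <- purrr::map(seq_len(n_helices), function(k) {
    i <- seq_len(rph[k]) - 1
    theta <- 2 * pi * (k - 1) / n_helices
    phase <- i * twist * pi / 180
    z <- i * rise
    if (antiparallel && k %% 2 == 0) z <- rev(z)
    cbind(ring_radius * cos(theta) + helix_radius * cos(phase),
          ring_radius * sin(theta) + helix_radius * sin(phase),
          z)
  })
  xyz <- do.call(rbind, coords)
  if (noise_sd > 0) {
    xyz <- xyz + with_seed(seed, matrix(rnorm(length(xyz), 0, noise_sd),
                                        ncol = 3))
  }
  coordinate_set(id, seq_len(nrow(xyz)), xyz)
}
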