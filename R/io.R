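#' Validate a tibble of protein records
#'
#' A protein-record table has one row per protein with columns `id` and
#' `sequence`, plus optional `species`, `kingdom` and `accession` metadata.
#' Sequences are uppercase strings over the 20 standard amino acids plus `X`.
#'
#' @param records A data frame with at least `id` and `sequence` columns.
#' @return The validated records as a tibble (invisibly unchanged).
#' @export
validate_protein_records <- function(records) {
  records <- as_tibble(records)
  if (!all(c("id", "sequence") %in% names(records))) {
    abort_validation("protein records need `id` and `sequence` columns")
  }
  if (nrow(records) == 0) return(records)
  if (anyDuplicated(records$id)) {
    abort_validation("duplicate protein ids in collection")
  }
  if (any(is.na(records$sequence)) || any(nchar(records$sequence) == 0)) {
    abort_validation("empty protein sequence")
  }
  bad <- stringr::str_detect(records$sequence,
                             paste0("[^", paste(AA21, collapse = ""), "]"))
  if (any(bad)) {
    abort_validation(sprintf(
      "sequence for %s contains letters outside the 20 amino acids + X",
      paste(records$id[bad], collapse = ", ")))
  }
  if ("kingdom" %in% names(records)) {
    ok <- is.na(records$kingdom) |
      records$kingdom %in% c("Fungi", "Protista", "Plantae", "Animalia")
    if (!all(ok)) abort_validation("kingdom must be Fungi/Protista/Plantae/Animalia")
  }
  records
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on input. Letters outside the 20 standard amino
#' acids plus `X` are rejected, as are duplicate identifiers and empty files.
#' The identifier is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort_format("empty FASTA file")
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) abort_format("FASTA file must start with a '>' header")
  grp <- cumsum(is_hdr)
  ids <- vapply(strsplit(sub("^>", "", lines[is_hdr]), "\\s+"), `[`, "", 1)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), paste, "", collapse = "")
  if (length(seqs) != length(ids)) abort_format("FASTA record with no sequence")
  recs <- tibble(id = ids,
                 sequence = toupper(gsub("\\s", "", unname(seqs))))
  validate_protein_records(recs)
}

#' Write protein records to FASTA
#'
#' @param records A protein-record tibble (see [validate_protein_records()]).
#' @param path Output path.
#' @param width Line-wrap width, 60 columns by default.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  records <- validate_protein_records(records)
  chunks <- purrr::map2(records$id, records$sequence, function(id, s) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    c(paste0(">", id), body)
  })
  readr::write_lines(unlist(chunks), path)
  invisible(path)
}

#' Read a homology hit table
#'
#' A tab-separated table with columns `query_id`, `subject_id`, `evalue`,
#' `query_coverage` and optionally `subject_family` (one of `GRL`, `DUF3537`,
#' `other`, `none`). Carries precomputed database-search results consumed by
#' the reciprocal-hit retention criterion.
#'
#' @param path Path to the TSV file.
#' @return A tibble, row order preserved.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("query_id", "subject_id", "evalue", "query_coverage")
  if (!all(need %in% names(tbl))) {
    abort_format(paste("hit table missing column(s):",
                       paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  ev <- suppressWarnings(as.numeric(tbl$evalue))
  cov <- suppressWarnings(as.numeric(tbl$query_coverage))
  if (any(is.na(ev)) || any(is.na(cov))) {
    abort_format("malformed numeric field in hit table")
  }
  tbl$evalue <- ev
  tbl$query_coverage <- cov
  if (!"subject_family" %in% names(tbl)) tbl$subject_family <- NA_character_
  validate_hit_table(tbl)
}

#' @rdname read_hit_table
#' @param hits A hit-table data frame to validate.
#' @export
validate_hit_table <- function(hits) {
  hits <- as_tibble(hits)
  if (any(hits$evalue < 0)) abort_validation("evalue must be >= 0")
  if (any(hits$query_coverage < 0 | hits$query_coverage > 100)) {
    abort_validation("query_coverage must lie in [0, 100]")
  }
  fam_ok <- is.na(hits$subject_family) |
    hits$subject_family %in% c("GRL", "DUF3537", "other", "none")
  if (!all(fam_ok)) abort_validation("subject_family must be GRL/DUF3537/other/none")
  hits
}

#' Read gene models from an exon table
#'
#' The exon-table format is a TSV with columns `gene_id`, `protein_id`,
#' `strand`, `exon_start`, `exon_end`: one row per exon, 1-based closed
#' coordinates on the coding sequence. Minus-strand models are normalised to
#' CDS orientation (exons ordered 5' to 3' of the mRNA) at parse time.
#' The summed exon length must be divisible by 3 (complete CDS).
#'
#' @param path Path to the exon-table TSV.
#' @return A tibble with one row per exon, ordered along the CDS, with an
#'   `exon_rank` column added.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "protein_id", "strand", "exon_start", "exon_end")
  if (!all(need %in% names(tbl))) {
    abort_format(paste("exon table missing column(s):",
                       paste(setdiff(need, names(tbl)), collapse = ", ")))
  }
  validate_gene_models(tbl)
}

#' @rdname read_gene_models
#' @param models A gene-model data frame to validate/normalise.
#' @export
validate_gene_models <- function(models) {
  models <- as_tibble(models)
  if (!all(models$strand %in% c("+", "-"))) {
    abort_validation("strand must be '+' or '-'")
  }
  if (any(models$exon_end < models$exon_start)) {
    abort_validation("exon_end < exon_start")
  }
  out <- models |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      g <- if (g$strand[1] == "-") dplyr::arrange(g, dplyr::desc(.data$exon_start))
           else dplyr::arrange(g, .data$exon_start)
      ov <- nrow(g) > 1 &&
        any(g$exon_start[-1] <= g$exon_end[-nrow(g)] &
              g$exon_end[-1] >= g$exon_start[-nrow(g)])
      if (g$strand[1] == "+" && ov) {
        abort_validation(paste("overlapping exons in", key$gene_id))
      }
      len <- sum(g$exon_end - g$exon_start + 1)
      if (len %% 3 != 0) {
        abort_validation(paste("CDS length of", key$gene_id,
                               "is not divisible by 3"))
      }
      g$exon_rank <- seq_len(nrow(g))
      g
    }) |>
    dplyr::ungroup()
  out
}

#' Read C-alpha coordinates from a PDB file
#'
#' Keeps C-alpha atoms of the first chain and first alternate location only.
#'
#' @param path Path to a PDB file.
#' @param id Identifier for the coordinate set; defaults to the file stem.
#' @return A `coordinate_set` object (see [coordinate_set()]).
#' @export
read_coordinates <- function(path, id = NULL) {
  if (!file.exists(path)) abort_format(paste("no such file:", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) abort_format("no C-alpha atoms in PDB file")
  ca <- ca[ca$chain == ca$chain[1], , drop = FALSE]
  alt <- ca$alt
  ca <- ca[is.na(alt) | alt == "" | alt == alt[!is.na(alt) & alt != ""][1] |
             !duplicated(ca$resno), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  coordinate_set(id %||% sub("\\.[^.]*$", "", basename(path)),
                 residue_index = ca$resno,
                 xyz = cbind(ca$x, ca$y, ca$z))
}

#' Write C-alpha coordinates as a PDB file
#'
#' @param coords A `coordinate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(coords, path) {
  stopifnot(inherits(coords, "coordinate_set"))
  n <- length(coords$residue_index)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), coords$residue_index,
    coords$xyz[, 1], coords$xyz[, 2], coords$xyz[, 3])
  readr::write_lines(c(lines, "END"), path)
  invisible(path)
}

#' Write a phylogenetic tree in newick format
#'
#' @param tree An `ape::phylo` tree with at least 2 leaves.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) abort_validation("tree must be an ape 'phylo'")
  if (length(tree$tip.label) < 2) {
    abort_validation("degenerate tree: at least 2 leaves required")
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a screening report as TSV
#'
#' @param results A tibble of screening results, one row per candidate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  readr::write_tsv(as_tibble(results), path)
  invisible(path)
}

#' Load the packaged candidate-GRL inventory
#'
#' A transcription of the published inventory of candidate GRL proteins in
#' unicellular eukaryotes: 17 proteins with kingdom, phylum, species,
#' provisional protein name and accession. Sequences themselves are not
#' distributed with the package; pair the inventory with a FASTA file of the
#' corresponding records where available.
#'
#' @return A tibble with columns `kingdom`, `phylum`, `species`, `protein`,
#'   `accession`, `trimmed`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_candidates.tsv", package = "grlscreen")
  readr::read_tsv(path, show_col_types = FALSE)
}

# 1-based closed interval -> 0-based half-open, and back. Internal arithmetic
# uses 0-based half-open; everything user-facing is 1-based closed.
to_zero_based <- function(start, end) list(start = start - 1L, end = end)
to_one_based <- function(start, end) list(start = start + 1L, end = end)
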