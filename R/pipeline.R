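#' Run the full candidate screening pipeline
#'
#' Orchestrates topology prediction, five-criteria screening, TM7 motif
#' scanning and, when the inputs are present, profile similarity, identity /
#' distance-tree and intron-conservation stages. Every stage writes a TSV
#' artifact into `out_dir`; the consolidated summary is computed by re-reading
#' those files, so every summary number is traceable to a stage file. Output
#' is a pure function of (inputs, config, seed).
#'
#' @param config A named list (or path to a JSON file) with elements:
#'   `records` (protein-record tibble or FASTA path; required), `hit_table`
#'   (tibble or TSV path), `gene_models` (tibble or exon-table path), `msa`
#'   (aligned tibble or FASTA path), `family_msas` (named list of aligned
#'   tibbles/paths, for the profile matrix), `structures` (list of
#'   `coordinate_set`s or PDB paths), `criteria` (argument list for
#'   [filter_criteria()]), `topology` (argument list for
#'   [predict_topology()]), `grouping` (named vector for intron
#'   conservation), `seed` (integer).
#' @param out_dir Output directory for stage artifacts.
#' @return A `grl_pipeline` list: stage tibbles, file paths, and `summary`.
#' @export
run_screening_pipeline <- function(config, out_dir = tempfile("grlrun")) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  records <- stage("input", {
    if (is.character(config$records)) read_fasta(config$records)
    else validate_protein_records(config$records)
  })
  hit_table <- stage("input", {
    ht <- config$hit_table
    if (is.character(ht)) read_hit_table(ht)
    else if (!is.null(ht)) validate_hit_table(ht)
    else NULL
  })

  files <- list()
  topo_args <- config$topology %||% list()
  topologies <- stage("topology", {
    do.call(predict_topology, c(list(records = records), topo_args))
  })
  files$topology <- file.path(out_dir, "topology.tsv")
  readr::write_tsv(dplyr::select(topologies, -"topology"), files$topology)

  criteria <- stage("screen", {
    do.call(filter_criteria, config$criteria %||% list())
  })
  screen <- stage("screen", {
    screen_collection(records, topologies, hit_table, criteria)
  })
  files$screen <- file.path(out_dir, "screen.tsv")
  write_report(screen, files$screen)

  motif <- stage("motif", {
    ok <- topologies$id[topologies$n_tm > 0]
    motif_conservation_table(records[records$id %in% ok, ], topologies)
  })
  files$motif <- file.path(out_dir, "motif.tsv")
  readr::write_tsv(motif, files$motif)

  simmat <- NULL
  if (!is.null(config$family_msas)) {
    simmat <- stage("profile-matrix", {
      profiles <- purrr::imap(config$family_msas, function(m, nm) {
        msa <- if (is.character(m)) read_fasta(m) else as_tibble(m)
        build_profile(msa, id = nm)
      })
      profile_similarity_matrix(unname(profiles))
    })
    files$similarity <- file.path(out_dir, "profile_similarity.tsv")
    readr::write_tsv(tidy(simmat), files$similarity)
    if (length(config$family_msas) >= 3) {
      files$profile_dendrogram <- file.path(out_dir, "profile_clusters.nwk")
      write_newick(ape::as.phylo(cluster_similarity(simmat)),
                   files$profile_dendrogram)
    }
  }

  tree <- NULL
  id_mat <- NULL
  if (nrow(records) >= 3) {
    id_mat <- stage("tree", identity_matrix(records))
    files$identity <- file.path(out_dir, "identity_matrix.tsv")
    readr::write_tsv(as_tibble(as.data.frame(id_mat), rownames = "id"),
                     files$identity)
    tree <- stage("tree", nj_tree(identity_to_distance(id_mat)))
    files$tree <- file.path(out_dir, "nj_tree.nwk")
    write_newick(tree, files$tree)
  }

  introns <- NULL
  if (!is.null(config$gene_models)) {
    introns <- stage("introns", {
      gm <- config$gene_models
      gm <- if (is.character(gm)) read_gene_models(gm) else validate_gene_models(gm)
      marks <- intron_marks(gm)
      msa <- config$msa
      if (!is.null(msa)) {
        msa <- if (is.character(msa)) read_fasta(msa) else as_tibble(msa)
        marks <- project_to_alignment(marks, msa)
      }
      marks
    })
    files$introns <- file.path(out_dir, "intron_marks.tsv")
    readr::write_tsv(introns, files$introns)
    if ("alignment_column" %in% names(introns)) {
      grouping <- config$grouping
      if (!is.null(grouping)) grouping <- unlist(grouping)
      groups <- conservation_groups(introns, grouping = grouping,
                                    tolerance = config$intron_tolerance %||% 0)
      files$intron_groups <- file.path(out_dir, "intron_groups.tsv")
      readr::write_tsv(groups, files$intron_groups)
    }
  }

  structures <- NULL
  if (!is.null(config$structures)) {
    structures <- stage("structcomp", {
      sets <- purrr::map(config$structures, function(s) {
        if (is.character(s)) read_coordinates(s) else s
      })
      pairwise_structure_matrix(sets)
    })
    files$structures <- file.path(out_dir, "structure_matrix.tsv")
    readr::write_tsv(tidy(structures), files$structures)
  }

  # summary recomputed from the stage files themselves
  screen_back <- readr::read_tsv(files$screen, show_col_types = FALSE)
  motif_back <- readr::read_tsv(files$motif, show_col_types = FALSE)
  summary <- list(
    seed = seed,
    n_candidates = nrow(screen_back),
    n_retained = sum(screen_back$retained),
    criterion_failures = as.list(colSums(
      !screen_back[, c("c1_reciprocal", "c2_length", "c3_seven_tm",
                       "c4_n_in", "c5_il_gt_el")])),
    max_anchors_matched = if (nrow(motif_back) > 0)
      max(motif_back$anchors_matched) else NA_integer_,
    thresholds = unclass(criteria))
  if ("kingdom" %in% names(screen_back)) {
    summary$retained_by_kingdom <- as.list(table(
      screen_back$kingdom[screen_back$retained]))
  }
  files$summary <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, files$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  structure(list(records = records, topologies = topologies, screen = screen,
                 motif = motif, similarity = simmat, identity = id_mat,
                 tree = tree, introns = introns, structures = structures,
                 summary = summary, files = files, out_dir = out_dir),
            class = "grl_pipeline")
}

#' @export
print.grl_pipeline <- function(x, ...) {
  cat(sprintf("<grl_pipeline> %d candidates, %d retained; artifacts in %s\n",
              x$summary$n_candidates, x$summary$n_retained, x$out_dir))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `grl_pipeline` object.
#' @param ... Unused.
#' @return A one-row tibble of headline counts.
#' @export
glance.grl_pipeline <- function(x, ...) {
  tibble(n_candidates = x$summary$n_candidates,
         n_retained = x$summary$n_retained,
         max_anchors_matched = x$summary$max_anchors_matched,
         seed = x$summary$seed)
}

#' @export
tidy.grl_pipeline <- function(x, ...) as_tibble(x$screen)
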