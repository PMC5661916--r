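#' Run the full small-RNA analysis pipeline
#'
#' Orchestrates the stage sequence clean -> classify -> known miRNA -> novel
#' miRNA -> differential expression (-> targets -> enrichment when a
#' transcript set and annotation maps are supplied), writing each stage's
#' table into `out_dir` together with an archived copy of the configuration
#' and a provenance log of output file hashes. Re-running with identical
#' inputs reproduces identical outputs.
#'
#' @param inputs A list with components: `fastq` (named vector of FASTQ
#'   paths, names are library ids) or `tags` (tag-count data.frame or TSV
#'   path for pre-cleaned libraries); `adapter3`, `adapter5` (for FASTQ
#'   input); `genome` (FASTA path or named vector); `known` (data.frame from
#'   [mirna_reference()] or list(fasta, coords)); `ncrna` (named list of
#'   FASTA paths or of named vectors); optional `transcripts` (named vector
#'   or FASTA path, names taken as gene ids), `go_map`, `kegg_map`
#'   (annotation TSV paths or `annotation_map` objects); optional
#'   `clean_reads` (named totals, required for tag-count input).
#' @param out_dir Output directory.
#' @param config [default_config()] list.
#' @param comparisons List of `c(treatment, control)` library pairs; default
#'   pairs each `<X>3` with `<X>0`.
#' @param engine Folding engine for novel-miRNA prediction.
#' @return Invisibly, a list with every stage result (`stats`, `tags`,
#'   `assignments`, `category_table`, `known_hits`, `known_expr`,
#'   `novel`, `novel_expr`, `de`, `targets`, `enrichment`, `paths`).
#' @export
run_pipeline <- function(inputs, out_dir, config = default_config(),
                         comparisons = NULL, engine = rnafold_engine()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("genome", "known", "ncrna")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0L) {
    stop("pipeline configuration invalid: missing input '", missing[[1L]], "'")
  }
  if (is.null(inputs$fastq) && is.null(inputs$tags)) {
    stop("pipeline configuration invalid: need either 'fastq' or 'tags' input")
  }
  write_config(config, file.path(out_dir, "run_config.txt"))

  # --- stage 1: clean / ingest -------------------------------------------
  if (!is.null(inputs$fastq)) {
    cleaned <- lapply(names(inputs$fastq), function(lib) {
      clean_reads(inputs$fastq[[lib]], adapter3 = inputs$adapter3,
                  adapter5 = inputs$adapter5, lib_id = lib, config = config)
    })
    stats <- do.call(rbind, lapply(cleaned, `[[`, "stats"))
    tags <- merge_tag_counts(lapply(cleaned, `[[`, "tags"))
    clean_totals <- stats::setNames(stats$clean_reads, stats$library_id)
  } else {
    tags <- if (is.character(inputs$tags)) read_tag_counts(inputs$tags) else inputs$tags
    stats <- NULL
    clean_totals <- if (!is.null(inputs$clean_reads)) {
      unlist(inputs$clean_reads)
    } else {
      vapply(setdiff(names(tags), "sequence"), function(l) sum(tags[[l]]),
             0)
    }
  }
  libs <- setdiff(names(tags), "sequence")
  lendist <- do.call(rbind, lapply(libs, function(l) {
    d <- length_distribution(tags, l); if (nrow(d) > 0L) d$library_id <- l; d
  }))
  shared <- if (length(libs) >= 2L) common_specific(tags) else NULL

  # --- stage 2: ncRNA/repeat classification ------------------------------
  ncrna_sets <- lapply(inputs$ncrna, function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x) else x
  })
  assignments <- match_ncrna(tags$sequence, ncrna_sets)
  unann <- assignments$sequence[assignments$category == "unann"]

  # --- stage 3: known miRNAs ---------------------------------------------
  known_ref <- if (is.data.frame(inputs$known)) inputs$known else
    read_mirna_reference(inputs$known$fasta, inputs$known$coords)
  known_hits <- match_known(unann, known_ref,
                            min_overlap = config$min_mature_overlap)
  known_expr <- expression_counts(known_hits, tags)

  # --- stage 4: novel miRNAs ---------------------------------------------
  genome <- if (is.character(inputs$genome) && length(inputs$genome) == 1L &&
                file.exists(inputs$genome)) read_fasta(inputs$genome) else inputs$genome
  params <- mireap_params(
    min_mirna_len = config$min_mirna_len, max_mirna_len = config$max_mirna_len,
    min_ref_len = config$min_ref_len, max_ref_len = config$max_ref_len,
    max_copy_number = config$max_copy_number,
    max_precursor_mfe = config$max_precursor_mfe, max_space = config$max_space,
    min_pairs = config$min_pairs, max_bulge = config$max_bulge,
    max_asymmetry = config$max_asymmetry, flank_len = config$flank_len)
  novel_input <- setdiff(unann, known_hits$tag)
  novel <- call_novel(novel_input, genome, params = params, engine = engine)
  novel_expr <- data.frame(mirna_id = novel$novel_id, stringsAsFactors = FALSE)
  tag_row <- match(novel$tag, tags$sequence)
  for (lib in libs) novel_expr[[lib]] <- tags[[lib]][tag_row]

  mirna_tags <- unique(c(known_hits$tag, novel$tag))
  cat_table <- category_table(assignments, tags, mirna_tags = mirna_tags)

  # --- stage 5: differential expression ----------------------------------
  if (is.null(comparisons)) {
    treat <- libs[endsWith(libs, "3")]
    comparisons <- lapply(treat, function(t) c(t, sub("3$", "0", t)))
    comparisons <- Filter(function(p) p[[2L]] %in% libs, comparisons)
  }
  de <- list()
  for (cmp in comparisons) {
    key <- paste0(cmp[[1L]], "_vs_", cmp[[2L]])
    de[[paste0("known_", key)]] <-
      diff_expression(known_expr, cmp[[1L]], cmp[[2L]], clean_totals, config)
    if (nrow(novel_expr) > 0L) {
      de[[paste0("novel_", key)]] <-
        diff_expression(novel_expr, cmp[[1L]], cmp[[2L]], clean_totals, config)
    }
  }

  # --- stage 6: targets + enrichment (optional) --------------------------
  targets <- NULL; enrichment <- NULL
  if (!is.null(inputs$transcripts)) {
    tx <- if (is.character(inputs$transcripts) &&
              length(inputs$transcripts) == 1L &&
              file.exists(inputs$transcripts)) {
      read_fasta(inputs$transcripts)
    } else inputs$transcripts
    de_ids <- unique(unlist(lapply(de, function(d)
      d$mirna_id[d$significant != "ns"])))
    de_seqs <- c(
      stats::setNames(known_ref$mature, known_ref$mirna_id)[
        intersect(de_ids, known_ref$mirna_id)],
      stats::setNames(novel$tag, novel$novel_id)[
        intersect(de_ids, novel$novel_id)])
    de_seqs <- de_seqs[!is.na(de_seqs)]
    if (length(de_seqs) > 0L) {
      targets <- predict_targets(de_seqs, tx, config)
      cand <- unique(targets$transcript_id)
      enrichment <- list()
      if (!is.null(inputs$go_map)) {
        go <- if (inherits(inputs$go_map, "annotation_map")) inputs$go_map
          else read_annotation_map(inputs$go_map)
        enrichment$GO <- enrich(cand, go, mode = "GO",
                                alpha = config$enrich_alpha)
      }
      if (!is.null(inputs$kegg_map)) {
        kegg <- if (inherits(inputs$kegg_map, "annotation_map")) inputs$kegg_map
          else read_annotation_map(inputs$kegg_map)
        enrichment$KEGG <- enrich(cand, kegg, mode = "KEGG",
                                  alpha = config$enrich_alpha)
      }
    }
  }

  # --- outputs + provenance ----------------------------------------------
  wr <- function(obj, name) {
    if (is.null(obj) || (is.data.frame(obj) && nrow(obj) == 0L)) return(NULL)
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wr(stats, "library_stats.tsv"), wr(tags, "tag_counts.tsv"),
    wr(lendist, "length_distribution.tsv"), wr(shared, "common_specific.tsv"),
    wr(assignments, "category_assignments.tsv"),
    wr(cat_table, "category_table.tsv"),
    wr(known_hits, "known_hits.tsv"), wr(known_expr, "known_expression.tsv"),
    wr(novel[setdiff(names(novel), "structure_file")], "novel_mirnas.tsv"),
    wr(novel_expr, "novel_expression.tsv"),
    unlist(lapply(names(de), function(k) wr(de[[k]], paste0("de_", k, ".tsv")))),
    wr(targets, "targets.tsv"),
    if (!is.null(enrichment$GO)) wr(enrichment$GO, "enrichment_go.tsv"),
    if (!is.null(enrichment$KEGG)) wr(enrichment$KEGG, "enrichment_kegg.tsv"))
  log <- data.frame(file = basename(paths),
                    md5 = unname(tools::md5sum(paths)),
                    stringsAsFactors = FALSE)
  utils::write.table(log, file.path(out_dir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(stats = stats, tags = tags, length_distribution = lendist,
                 common_specific = shared, assignments = assignments,
                 category_table = cat_table, known_hits = known_hits,
                 known_expr = known_expr, novel = novel,
                 novel_expr = novel_expr, de = de, targets = targets,
                 enrichment = enrichment, clean_reads = clean_totals,
                 paths = paths))
}
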