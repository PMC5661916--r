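#' Default run configuration
#'
#' Every numeric threshold of the pipeline with its default value. Hairpin
#' prediction defaults follow the conventional Mireap-style parameter block
#' (precursor free energy at most -18 kcal/mol, at least 16 duplex pairs,
#' bulge and asymmetry at most 4, miRNA/miRNA* space at most 300 nt, 20 nt
#' precursor flank, at most 20 genomic copies); cleaning, differential
#' expression and target-scoring defaults are documented on the functions
#' that consume them.
#'
#' @param ... Named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    # cleaning
    min_tag_len = 18, max_tag_len = 30,
    quality_threshold = 20, max_low_quality_bases = 1,
    polya_frac = 0.8, polya_run = 10,
    adapter5_max_mismatch = 1, adapter3_seed_len = 8,
    # classification
    classify_max_mismatch = 0,
    # known miRNA matching
    min_mature_overlap = 16,
    # hairpin (novel miRNA) prediction
    min_mirna_len = 18, max_mirna_len = 25,
    min_ref_len = 20, max_ref_len = 23,
    max_copy_number = 20, max_precursor_mfe = -18,
    max_space = 300, min_pairs = 16,
    max_bulge = 4, max_asymmetry = 4, flank_len = 20,
    # differential expression
    rpm_floor = 0.01, lfc_threshold = 1, p_threshold = 0.05,
    # target prediction
    target_max_score = 4, target_mismatch = 1, target_wobble = 0.5,
    target_gap = 2, target_core_start = 2, target_core_end = 13,
    target_nogap_start = 10, target_nogap_end = 11,
    # enrichment
    enrich_alpha = 0.05,
    # reproducibility
    seed = 42
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown configuration key: ", unknown[[1L]])
    }
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "run_config")
}

#' Write a configuration to a flat key-value text file
#'
#' The full parameter set (defaults plus overrides) is always written out so
#' that an archived copy of the file fully determines a run.
#'
#' @param config A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  vals <- vapply(config, function(v) format(v, digits = 15, scientific = FALSE), "")
  writeLines(paste0(names(config), " = ", vals), path)
  invisible(path)
}

#' Read a configuration file written by [write_config()]
#'
#' @param path Path to a flat key-value file.
#' @return A `run_config` list; round-trips losslessly through
#'   [write_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([^=\\s]+)\\s*=\\s*(.*)$", lines,
                                  perl = TRUE))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) stop("malformed config line ", bad[[1L]], ": ", lines[bad[[1L]]])
  keys <- vapply(kv, `[[`, "", 2L)
  vals <- vapply(kv, `[[`, "", 3L)
  num <- suppressWarnings(as.numeric(vals))
  parsed <- ifelse(is.na(num), vals, num)
  cfg <- stats::setNames(as.list(as.numeric(parsed[!is.na(num)])), keys[!is.na(num)])
  if (any(is.na(num))) cfg[keys[is.na(num)]] <- vals[is.na(num)]
  do.call(default_config, cfg)
}
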