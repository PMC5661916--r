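#' Clean raw small-RNA reads and collapse them to unique tags
#'
#' Applies the standard small-RNA cleaning cascade in a fixed order so that
#' every removed read is attributed to exactly one filter:
#' low quality, 5' adapter contamination, missing 3' adapter, 3' adapter
#' trimming, empty insert, poly-A insert, insert length out of range.
#' Survivors are collapsed to unique tags with per-library counts.
#'
#' A read is low quality when it contains any N or more than
#' `max_low_quality_bases` bases below `quality_threshold` (Phred). The 5'
#' adapter is searched anywhere in the read with up to
#' `adapter5_max_mismatch` mismatches. The 3' adapter is located by the exact
#' leftmost occurrence of its first `adapter3_seed_len` bases; reads without
#' it are dropped unless `require_adapter = FALSE`, in which case the whole
#' read is taken as the insert (useful for re-cleaning already-trimmed tags,
#' which is a no-op). A poly-A insert has an A fraction of at least
#' `polya_frac` or an A run of at least `polya_run` nt.
#'
#' @param reads data.frame from [read_fastq()] (columns `sequence`,
#'   `quality`), or a path to a FASTQ file.
#' @param adapter3 3' adapter sequence (required unless
#'   `require_adapter = FALSE`).
#' @param adapter5 5' adapter sequence, or `NULL` to skip that filter.
#' @param lib_id Library identifier used as the count column name.
#' @param config A [default_config()] list.
#' @param require_adapter Drop reads without the 3' adapter (default TRUE).
#' @return A list with `tags` (data.frame `sequence` + count column named
#'   `lib_id`) and `stats` (one-row data.frame of raw/clean/removal counts).
#' @export
clean_reads <- function(reads, adapter3, adapter5 = NULL, lib_id = "lib",
                        config = default_config(), require_adapter = TRUE) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_fastq(reads)
  if (require_adapter && (is.null(adapter3) || !nzchar(adapter3))) {
    stop("configuration error: empty 3' adapter sequence")
  }
  if (!is.null(adapter5) && !nzchar(adapter5)) {
    stop("configuration error: empty 5' adapter sequence")
  }
  seqs <- reads$sequence
  n_raw <- length(seqs)
  removed <- c(low_quality = 0L, contam_5prime = 0L, no_3prime = 0L,
               no_insert = 0L, polyA = 0L, length_out_of_range = 0L)
  alive <- rep(TRUE, n_raw)

  # 1. low quality: any N, or >max_low_quality_bases below the Phred cutoff
  if (n_raw > 0L && !is.null(reads$quality) && any(nzchar(reads$quality))) {
    qual <- Biostrings::PhredQuality(reads$quality)
    low_per_read <- sum(methods::as(qual, "IntegerList") < config$quality_threshold)
    bad_q <- low_per_read > config$max_low_quality_bases | grepl("N", seqs, fixed = TRUE)
  } else {
    bad_q <- grepl("N", seqs, fixed = TRUE)
  }
  removed[["low_quality"]] <- sum(alive & bad_q)
  alive <- alive & !bad_q

  # 2. 5' adapter contamination anywhere in the read
  if (!is.null(adapter5) && any(alive)) {
    hits <- Biostrings::vcountPattern(
      adapter5, Biostrings::DNAStringSet(seqs),
      max.mismatch = config$adapter5_max_mismatch
    ) > 0L
    removed[["contam_5prime"]] <- sum(alive & hits)
    alive <- alive & !hits
  }

  # 3-4. locate and trim the 3' adapter
  if (require_adapter) {
    seed <- substr(adapter3, 1L, config$adapter3_seed_len)
    pos <- regexpr(seed, seqs, fixed = TRUE)
    miss <- pos < 0L
    removed[["no_3prime"]] <- sum(alive & miss)
    alive <- alive & !miss
    insert <- substr(seqs, 1L, pmax(pos - 1L, 0L))
  } else {
    insert <- seqs
  }

  # 5. empty insert (adapter dimer)
  empty <- !nzchar(insert)
  removed[["no_insert"]] <- sum(alive & empty)
  alive <- alive & !empty

  # 6. poly-A insert
  len <- nchar(insert)
  n_a <- nchar(gsub("[^A]", "", insert))
  polya <- (len > 0L & n_a / pmax(len, 1L) >= config$polya_frac) |
    grepl(strrep("A", config$polya_run), insert, fixed = TRUE)
  removed[["polyA"]] <- sum(alive & polya)
  alive <- alive & !polya

  # 7. insert length
  bad_len <- len < config$min_tag_len | len > config$max_tag_len
  removed[["length_out_of_range"]] <- sum(alive & bad_len)
  alive <- alive & !bad_len

  kept <- insert[alive]
  counts <- table(kept)
  tags <- data.frame(sequence = names(counts), stringsAsFactors = FALSE)
  tags[[lib_id]] <- as.integer(counts)
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  stats <- data.frame(library_id = lib_id, raw_reads = n_raw,
                      clean_reads = length(kept), t(removed),
                      stringsAsFactors = FALSE)
  stopifnot(stats$clean_reads + sum(removed) == n_raw)
  list(tags = tags, stats = stats)
}

#' Merge per-library tag tables into one tag-count table
#'
#' @param tag_list List of per-library tag data.frames from [clean_reads()].
#' @return data.frame with `sequence` plus one count column per library
#'   (absent tags have count 0).
#' @export
merge_tag_counts <- function(tag_list) {
  stopifnot(length(tag_list) >= 1L)
  merged <- Reduce(function(a, b) merge(a, b, by = "sequence", all = TRUE), tag_list)
  for (col in setdiff(names(merged), "sequence")) {
    merged[[col]][is.na(merged[[col]])] <- 0L
  }
  merged[order(merged$sequence), , drop = FALSE] -> merged
  rownames(merged) <- NULL
  merged
}

#' Length distribution of a cleaned library
#'
#' @param tags Tag-count data.frame.
#' @param lib_id Library column to summarize.
#' @return data.frame with `length`, `unique_count` (distinct tags) and
#'   `total_count` (reads).
#' @export
length_distribution <- function(tags, lib_id) {
  stopifnot(lib_id %in% names(tags))
  present <- tags[[lib_id]] > 0L
  if (!any(present)) {
    return(data.frame(length = integer(0), unique_count = integer(0),
                      total_count = integer(0)))
  }
  len <- nchar(tags$sequence[present])
  cnt <- tags[[lib_id]][present]
  agg <- stats::aggregate(cbind(unique_count = rep(1L, length(len)),
                                total_count = cnt),
                          by = list(length = len), FUN = sum)
  agg[order(agg$length), , drop = FALSE]
}

#' Shared and library-specific tags for every library pair
#'
#' For each pair of libraries, partitions the union of their tags into a
#' shared class and two exclusive classes (presence means count > 0).
#'
#' @param tags Tag-count data.frame with at least two library columns.
#' @return data.frame with `lib_a`, `lib_b`, `class` (`shared`, `a_only`,
#'   `b_only`), `unique_count` and `total_count` (reads of the class summed
#'   over the pair).
#' @export
common_specific <- function(tags) {
  libs <- setdiff(names(tags), "sequence")
  if (length(libs) < 2L) stop("common/specific analysis needs at least 2 libraries")
  out <- list()
  for (i in seq_len(length(libs) - 1L)) {
    for (j in seq(i + 1L, length(libs))) {
      a <- tags[[libs[i]]] > 0L
      b <- tags[[libs[j]]] > 0L
      cls <- ifelse(a & b, "shared", ifelse(a, "a_only", ifelse(b, "b_only", NA)))
      keep <- !is.na(cls)
      totals <- tags[[libs[i]]] + tags[[libs[j]]]
      agg <- data.frame(
        lib_a = libs[i], lib_b = libs[j],
        class = c("shared", "a_only", "b_only"),
        unique_count = vapply(c("shared", "a_only", "b_only"),
                              function(k) sum(cls[keep] == k), 0L),
        total_count = vapply(c("shared", "a_only", "b_only"),
                             function(k) sum(totals[keep][cls[keep] == k]), 0L),
        stringsAsFactors = FALSE
      )
      out[[length(out) + 1L]] <- agg
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
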