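# Exact substring matching of many short tags against a set of reference
# sequences. Tags are grouped by width (preprocessed dictionaries require a
# constant width for exact matching); references are concatenated with N
# spacers so one scan per width group suffices; N never matches a tag base.

# Returns data.frame(tag, ref_id, start, end, strand) with coordinates
# 1-based inclusive on the forward strand of the named reference.
exact_matches <- function(tags, refs, both_strands = TRUE) {
  stopifnot(is.character(tags), is.character(refs), !is.null(names(refs)))
  if (length(refs) == 0L) stop("empty reference set")
  tags <- unique(tags)
  empty <- data.frame(tag = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(tags) == 0L) return(empty)

  sep <- strrep("N", max(nchar(tags)) + 1L)
  widths <- nchar(refs)
  offsets <- cumsum(c(0L, widths + nchar(sep)))[seq_along(refs)]
  subj_fwd <- Biostrings::DNAString(paste(refs, collapse = sep))
  subj_rev <- if (both_strands) {
    Biostrings::DNAString(paste(revcomp(refs), collapse = sep))
  } else NULL

  scan_one <- function(subject, strand) {
    res <- list()
    for (w in unique(nchar(tags))) {
      grp <- tags[nchar(tags) == w]
      pd <- Biostrings::PDict(grp)
      m <- Biostrings::matchPDict(pd, subject)
      starts <- Biostrings::startIndex(m)
      hit <- which(lengths(starts) > 0L)
      if (length(hit) == 0L) next
      tag_rep <- rep(grp[hit], lengths(starts)[hit])
      st <- unlist(starts[hit], use.names = FALSE)
      ref_idx <- findInterval(st, offsets + 1L)
      loc_start <- st - offsets[ref_idx]
      loc_end <- loc_start + w - 1L
      if (strand == "-") {
        # positions on the reverse-complement string -> forward coordinates
        fw_start <- widths[ref_idx] - loc_end + 1L
        fw_end <- widths[ref_idx] - loc_start + 1L
        loc_start <- fw_start
        loc_end <- fw_end
      }
      res[[length(res) + 1L]] <- data.frame(
        tag = tag_rep, ref_id = names(refs)[ref_idx],
        start = loc_start, end = loc_end, strand = strand,
        stringsAsFactors = FALSE
      )
    }
    res
  }

  parts <- scan_one(subj_fwd, "+")
  if (both_strands) parts <- c(parts, scan_one(subj_rev, "-"))
  if (length(parts) == 0L) return(empty)
  out <- do.call(rbind, parts)
  out <- out[order(out$tag, out$ref_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
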