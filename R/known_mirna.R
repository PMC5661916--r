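#' Identify known miRNAs by the two-stage precursor/mature criterion
#'
#' Stage 1: the tag must be an exact (0-mismatch) substring of a known
#' precursor. Stage 2: the tag's interval on the precursor must overlap the
#' annotated mature interval by at least `min_overlap` nt, so offset isoforms
#' of the mature are accepted while loop- or star-only matches are not.
#' Overlap is computed on precursor coordinates, which makes "allowing
#' offsets" well defined.
#'
#' @param tags Character vector of tag sequences (or tag-count data.frame).
#' @param reference data.frame from [mirna_reference()].
#' @param min_overlap Minimum tag/mature overlap in nt (default 16).
#' @return data.frame with `tag`, `mirna_id`, `position` (1-based tag start
#'   on the precursor), `overlap` and `offset` (tag start minus mature
#'   start).
#' @export
match_known <- function(tags, reference, min_overlap = 16L) {
  if (is.data.frame(tags)) tags <- tags$sequence
  bad <- reference$mature != substr(reference$precursor,
                                    reference$mature_start,
                                    reference$mature_end)
  if (any(bad)) {
    stop("reference validation error: mature not on precursor for ",
         reference$mirna_id[which(bad)[1L]])
  }
  prec <- stats::setNames(reference$precursor, reference$mirna_id)
  hits <- exact_matches(tags, prec, both_strands = FALSE)
  if (nrow(hits) == 0L) {
    return(data.frame(tag = character(0), mirna_id = character(0),
                      position = integer(0), overlap = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  }
  ref_row <- match(hits$ref_id, reference$mirna_id)
  ms <- reference$mature_start[ref_row]
  me <- reference$mature_end[ref_row]
  overlap <- pmax(0L, pmin(hits$end, me) - pmax(hits$start, ms) + 1L)
  keep <- overlap >= min_overlap
  out <- data.frame(tag = hits$tag[keep], mirna_id = hits$ref_id[keep],
                    position = hits$start[keep], overlap = overlap[keep],
                    offset = hits$start[keep] - ms[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Accumulate per-miRNA expression from known-miRNA hits
#'
#' The raw count of a miRNA in a library is the sum of the counts of all its
#' hit tags in that library. A tag hitting several miRNAs contributes its
#' full count to each by default (`multi = "full"`); `multi = "fraction"`
#' splits the count evenly across the k miRNAs it hits.
#'
#' @param hits data.frame from [match_known()].
#' @param tags Tag-count data.frame.
#' @param multi Multi-mapping policy, `"full"` or `"fraction"`.
#' @return data.frame with `mirna_id` plus one count column per library.
#' @export
expression_counts <- function(hits, tags, multi = c("full", "fraction")) {
  multi <- match.arg(multi)
  libs <- setdiff(names(tags), "sequence")
  pairs <- unique(hits[, c("tag", "mirna_id")])
  if (nrow(pairs) == 0L) {
    out <- data.frame(mirna_id = character(0), stringsAsFactors = FALSE)
    for (lib in libs) out[[lib]] <- numeric(0)
    return(out)
  }
  w <- if (multi == "fraction") {
    1 / table(pairs$tag)[pairs$tag]
  } else rep(1, nrow(pairs))
  row <- match(pairs$tag, tags$sequence)
  out <- data.frame(mirna_id = sort(unique(pairs$mirna_id)),
                    stringsAsFactors = FALSE)
  for (lib in libs) {
    contrib <- tags[[lib]][row] * as.numeric(w)
    s <- tapply(contrib, pairs$mirna_id, sum, default = 0)
    out[[lib]] <- as.numeric(s[out$mirna_id])
  }
  rownames(out) <- NULL
  out
}

#' Base-composition bias of identified miRNA tags
#'
#' Summarizes (i) the first-base composition per tag length and (ii) the base
#' composition at every position over all tags. Plant mature miRNAs typically
#' show a U bias at the first position of 21/22-nt tags and an A bias around
#' the cleavage-site positions 10-11.
#'
#' @param tag_seqs Character vector of identified miRNA tag sequences.
#' @return A list with `first_base` (data.frame `length`, `base`,
#'   `proportion`) and `by_position` (data.frame `position`, `base`,
#'   `proportion`); proportions at each length/position sum to 1.
#' @export
base_bias <- function(tag_seqs) {
  if (length(tag_seqs) == 0L) stop("base_bias needs at least one tag")
  bases <- c("A", "C", "G", "T")
  first <- substr(tag_seqs, 1L, 1L)
  len <- nchar(tag_seqs)
  fb <- do.call(rbind, lapply(sort(unique(len)), function(L) {
    tab <- table(factor(first[len == L], levels = bases))
    data.frame(length = L, base = bases,
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  maxlen <- max(len)
  bp <- do.call(rbind, lapply(seq_len(maxlen), function(p) {
    ch <- substr(tag_seqs[len >= p], p, p)
    tab <- table(factor(ch, levels = bases))
    data.frame(position = p, base = bases,
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }))
  list(first_base = fb, by_position = bp)
}
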