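#' Hairpin-prediction parameter block
#'
#' The eleven numeric criteria of Mireap-style novel miRNA prediction. A
#' candidate precursor is accepted only if its MFE is at most
#' `max_precursor_mfe` (kcal/mol), the miRNA/miRNA* duplex has at least
#' `min_pairs` base pairs, at most `max_bulge` consecutive unpaired bases on
#' either strand, at most `max_asymmetry` difference in unpaired bases
#' between the two strands, and at most `max_space` nt between the mature and
#' star inner ends. `min_ref_len`/`max_ref_len` bound the mature length used
#' for the reported annotation; `flank_len` is the genomic flank added when
#' excising candidate windows; `max_copy_number` caps genomic multi-mapping.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters.
#' @export
mireap_params <- function(...) {
  p <- list(
    min_mirna_len = 18L, max_mirna_len = 25L,
    min_ref_len = 20L, max_ref_len = 23L,
    max_copy_number = 20L, max_precursor_mfe = -18,
    max_space = 300L, min_pairs = 16L,
    max_bulge = 4L, max_asymmetry = 4L, flank_len = 20L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown) > 0L) stop("unknown hairpin parameter: ", unknown[[1L]])
  p[names(overrides)] <- overrides
  if (p$max_precursor_mfe >= 0) stop("max_precursor_mfe must be negative")
  stopifnot(p$min_mirna_len > 0, p$min_pairs > 0, p$flank_len >= 0)
  p
}

#' Map tags to exact genomic loci, capped by copy number
#'
#' @param tags Character vector of tag sequences.
#' @param reference Named character vector of reference sequences.
#' @param max_copy_number Tags with more loci than this (both strands
#'   combined) are discarded and reported via the `discarded` attribute.
#' @return data.frame `tag`, `ref_id`, `start`, `end`, `strand` (forward
#'   coordinates, 1-based inclusive), with attribute `discarded` naming the
#'   over-mapped tags.
#' @export
map_tags <- function(tags, reference, max_copy_number = 20L) {
  if (length(reference) == 0L) stop("empty reference")
  hits <- exact_matches(tags, reference, both_strands = TRUE)
  n_loci <- table(hits$tag)
  over <- names(n_loci)[n_loci > max_copy_number]
  out <- hits[!hits$tag %in% over, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- over
  out
}

#' Excise candidate precursor windows around a mapped tag
#'
#' For a tag mapped at one locus, two precursor hypotheses are generated: the
#' tag sitting on the 5' arm (window extends downstream far enough to hold
#' the star plus loop) and on the 3' arm (window extends upstream), each with
#' `flank_len` nt on the tag's outer side. The maximal inward extension is
#' `max_space + tag length + flank_len`. Windows are truncated at reference
#' edges. Minus-strand loci are excised from the reverse-complement so the
#' tag always reads 5' to 3' inside its window.
#'
#' @param locus One-row data.frame (or list) with `ref_id`, `start`, `end`,
#'   `strand` as produced by [map_tags()].
#' @param reference Named character vector of reference sequences.
#' @param params [mireap_params()] list.
#' @return data.frame with `arm` (`"5p"`/`"3p"`), `window` (sequence),
#'   `win_start`, `win_end` (forward reference coordinates), and
#'   `mature_start`, `mature_end` (tag position inside the window, 1-based).
#' @export
excise_precursor <- function(locus, reference, params = mireap_params()) {
  ref <- reference[[locus$ref_id]]
  L <- nchar(ref)
  tag_len <- locus$end - locus$start + 1L
  reach <- params$max_space + tag_len + params$flank_len
  if (locus$strand == "+") {
    local_seq <- ref
    s <- locus$start; e <- locus$end
  } else {
    local_seq <- revcomp(ref)
    s <- L - locus$end + 1L; e <- L - locus$start + 1L
  }
  mk <- function(ws, we, arm) {
    ws <- max(1L, ws); we <- min(L, we)
    if (locus$strand == "+") {
      fs <- ws; fe <- we
    } else {
      fs <- L - we + 1L; fe <- L - ws + 1L
    }
    data.frame(arm = arm, window = substr(local_seq, ws, we),
               win_start = fs, win_end = fe,
               mature_start = s - ws + 1L, mature_end = e - ws + 1L,
               stringsAsFactors = FALSE)
  }
  rbind(mk(s - params$flank_len, e + reach, "5p"),
        mk(s - reach, e + params$flank_len, "3p"))
}

#' miRNA/miRNA* duplex metrics from a folded precursor
#'
#' Given the dot-bracket structure of a candidate precursor and the mature
#' interval on it, locates the star as the set of pairing partners of the
#' mature extended by the canonical 2-nt 3' overhang, and computes the duplex
#' statistics the acceptance criteria are tested on: the number of paired
#' mature bases, the longest unpaired run (bulge) on either strand inside the
#' duplex, the strand asymmetry in unpaired bases, and the space between the
#' mature and star inner ends.
#'
#' @param structure Dot-bracket string of the precursor window.
#' @param mature_start,mature_end Mature interval on the window, 1-based.
#' @return A list with `star_start`, `star_end`, `n_pairs`, `max_bulge`,
#'   `asymmetry`, `space`; or with `reason` (`"no duplex"` or `"overlap"`)
#'   when no valid duplex exists.
#' @export
duplex_metrics <- function(structure, mature_start, mature_end) {
  pt <- pair_table(structure)
  n <- length(pt)
  stopifnot(mature_start >= 1L, mature_end <= n, mature_start <= mature_end)
  mpos <- mature_start:mature_end
  partners <- pt[mpos]
  # only pairs reaching outside the mature count toward the duplex
  outside <- !is.na(partners) & (partners < mature_start | partners > mature_end)
  if (!any(outside)) return(list(reason = "no duplex"))
  pvals <- partners[outside]
  s1 <- min(pvals); s2 <- max(pvals)
  star_start <- s1
  star_end <- min(n, s2 + 2L)  # 2-nt 3' overhang on the star
  if (star_start <= mature_end && star_end >= mature_start) {
    return(list(reason = "overlap"))
  }
  n_pairs <- sum(outside)
  # duplex spans: between outermost paired bases on each strand
  mp <- mpos[outside]
  mspan <- seq(min(mp), max(mp))
  sspan <- seq(s1, s2)
  m_unpaired <- !mspan %in% mp
  s_unpaired <- !sspan %in% pvals
  run_max <- function(x) if (!any(x)) 0L else max(rle(x)$lengths[rle(x)$values])
  max_bulge <- max(run_max(m_unpaired), run_max(s_unpaired))
  asymmetry <- abs(sum(m_unpaired) - sum(s_unpaired))
  space <- if (mature_end < s1) s1 - mature_end - 1L else mature_start - s2 - 1L
  list(star_start = star_start, star_end = star_end, n_pairs = n_pairs,
       max_bulge = max_bulge, asymmetry = asymmetry, space = space)
}

# Conjunctive acceptance over the five numeric criteria.
passes_hairpin_criteria <- function(mfe, metrics, params) {
  if (!is.null(metrics$reason)) return(FALSE)
  mfe <= params$max_precursor_mfe &&
    metrics$n_pairs >= params$min_pairs &&
    metrics$max_bulge <= params$max_bulge &&
    metrics$asymmetry <= params$max_asymmetry &&
    metrics$space >= 0L && metrics$space <= params$max_space
}

#' Predict novel miRNAs from unannotated tags
#'
#' For each eligible tag (length within `min_mirna_len`..`max_mirna_len`),
#' maps it to the reference (copy-number capped), excises both precursor
#' hypotheses at every locus, folds the windows, computes the duplex metrics,
#' and accepts candidates that satisfy all five numeric criteria. One best
#' candidate is kept per tag: lowest MFE, ties broken by shorter precursor,
#' then leftmost locus.
#'
#' @param tags Character vector of candidate tag sequences (post
#'   classification, post known-miRNA identification).
#' @param reference Named character vector of reference sequences.
#' @param params [mireap_params()] list.
#' @param engine Folding engine (default [rnafold_engine()]).
#' @return data.frame of accepted candidates: `novel_id`, `tag`, `ref_id`,
#'   `strand`, `precursor_start`, `precursor_end`, `arm`, `precursor`,
#'   `structure`, `mfe`, `mature_start`, `mature_end`, `star_start`,
#'   `star_end`, `n_pairs`, `max_bulge`, `asymmetry`, `space`. Attribute
#'   `discarded` carries tags dropped by the copy-number cap.
#' @export
call_novel <- function(tags, reference, params = mireap_params(),
                       engine = rnafold_engine()) {
  if (is.data.frame(tags)) tags <- tags$sequence
  tags <- unique(tags)
  eligible <- tags[nchar(tags) >= params$min_mirna_len &
                     nchar(tags) <= params$max_mirna_len]
  empty <- data.frame(
    novel_id = character(0), tag = character(0), ref_id = character(0),
    strand = character(0), precursor_start = integer(0),
    precursor_end = integer(0), arm = character(0), precursor = character(0),
    structure = character(0), mfe = numeric(0), mature_start = integer(0),
    mature_end = integer(0), star_start = integer(0), star_end = integer(0),
    n_pairs = integer(0), max_bulge = integer(0), asymmetry = integer(0),
    space = integer(0), stringsAsFactors = FALSE
  )
  loci <- map_tags(eligible, reference, params$max_copy_number)
  if (nrow(loci) == 0L) {
    attr(empty, "discarded") <- attr(loci, "discarded")
    return(empty)
  }
  wins <- do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    w <- excise_precursor(loci[i, ], reference, params)
    w$tag <- loci$tag[i]; w$ref_id <- loci$ref_id[i]; w$strand <- loci$strand[i]
    w
  }))
  folded <- fold(wins$window, engine = engine)
  wins$structure <- folded$structure
  wins$mfe <- folded$mfe

  rows <- lapply(seq_len(nrow(wins)), function(i) {
    met <- duplex_metrics(wins$structure[i], wins$mature_start[i], wins$mature_end[i])
    if (!passes_hairpin_criteria(wins$mfe[i], met, params)) return(NULL)
    data.frame(
      tag = wins$tag[i], ref_id = wins$ref_id[i], strand = wins$strand[i],
      precursor_start = wins$win_start[i], precursor_end = wins$win_end[i],
      arm = wins$arm[i], precursor = wins$window[i],
      structure = wins$structure[i], mfe = wins$mfe[i],
      mature_start = wins$mature_start[i], mature_end = wins$mature_end[i],
      star_start = met$star_start, star_end = met$star_end,
      n_pairs = met$n_pairs, max_bulge = met$max_bulge,
      asymmetry = met$asymmetry, space = met$space,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    attr(empty, "discarded") <- attr(loci, "discarded")
    return(empty)
  }
  cand <- do.call(rbind, rows)
  # one best candidate per tag: lowest mfe, then shortest precursor, then leftmost
  ord <- order(match(cand$tag, eligible), cand$mfe,
               cand$precursor_end - cand$precursor_start,
               cand$ref_id, cand$precursor_start)
  cand <- cand[ord, , drop = FALSE]
  cand <- cand[!duplicated(cand$tag), , drop = FALSE]
  cand$novel_id <- paste0("novel_mir_", seq_len(nrow(cand)))
  cand <- cand[, c("novel_id", setdiff(names(cand), "novel_id"))]
  rownames(cand) <- NULL
  attr(cand, "discarded") <- attr(loci, "discarded")
  cand
}
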