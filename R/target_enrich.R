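#' Predict plant miRNA target sites by complementarity penalty scoring
#'
#' Scans each transcript for sites where the miRNA:mRNA duplex penalty is at
#' most `target_max_score` under the classic plant scheme: each mismatch
#' costs `target_mismatch` (1.0), each G:U wobble `target_wobble` (0.5), each
#' 1-nt gap `target_gap` (2.0); penalties are doubled at miRNA positions
#' `target_core_start`..`target_core_end` (2-13, the seed/cleavage core), and
#' no gap is allowed at positions `target_nogap_start`..`target_nogap_end`
#' (10-11). Ungapped sites and sites with a single 1-nt bulge on either
#' strand are considered; all qualifying sites are reported.
#'
#' Positions are counted 5' to 3' along the miRNA; the site interval is
#' reported 1-based on the transcript.
#'
#' @param mirnas Named character vector of mature miRNA sequences (>= 18 nt).
#' @param transcripts Named character vector of transcript sequences.
#' @param config [default_config()] list carrying the scoring parameters.
#' @return data.frame `mirna_id`, `transcript_id`, `start`, `end` (site on
#'   transcript), `score`, `gap` (`"none"`, `"transcript"`, `"mirna"`),
#'   `alignment` (`|` pair, `o` wobble, `.` mismatch, `-` gap, 5'->3' along
#'   the miRNA).
#' @export
predict_targets <- function(mirnas, transcripts, config = default_config()) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  if (any(nchar(mirnas) < 18L)) {
    stop("miRNA shorter than 18 nt: ",
         names(mirnas)[which(nchar(mirnas) < 18L)[1L]])
  }
  out <- list()
  for (mi in names(mirnas)) {
    for (tx in names(transcripts)) {
      hits <- scan_target_sites(mirnas[[mi]], transcripts[[tx]], config)
      if (nrow(hits) > 0L) {
        hits$mirna_id <- mi
        hits$transcript_id <- tx
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0), score = numeric(0),
                      gap = character(0), alignment = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[, c("mirna_id", "transcript_id", "start", "end", "score",
                 "gap", "alignment")]
  res <- res[order(res$mirna_id, res$transcript_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Pairing state of miRNA base m against transcript base t (both 5'->3' as
# stored): 0 = Watson-Crick pair, 1 = G:U wobble, 2 = mismatch.
pair_state <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
    (m == "G" & t == "C") | (m == "C" & t == "G")
  wob <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, 0L, ifelse(wob, 1L, 2L))
}

# Scan one transcript for sites of one miRNA; vectorized over site starts for
# each alignment topology (ungapped, one transcript bulge, one miRNA bulge).
scan_target_sites <- function(mirna, transcript, config) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  mch <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  tch <- strsplit(transcript, "", fixed = TRUE)[[1L]]
  mult <- ifelse(seq_len(L) >= config$target_core_start &
                   seq_len(L) <= config$target_core_end, 2, 1)
  nogap <- seq(config$target_nogap_start, config$target_nogap_end)
  hits <- list()

  add_hits <- function(starts, scores, wlen, gap_kind, state_fun) {
    ok <- which(scores <= config$target_max_score)
    for (i in ok) {
      s <- starts[i]
      aln <- state_fun(s)
      hits[[length(hits) + 1L]] <<- data.frame(
        start = s, end = s + wlen - 1L, score = scores[i], gap = gap_kind,
        alignment = aln, stringsAsFactors = FALSE
      )
    }
  }

  # penalty matrix for a given mapping of miRNA position i -> window offset
  # off[i] (window position = start + off[i]); returns per-start score vector
  score_topology <- function(off, wlen, gap_pen, gap_positions) {
    starts <- seq_len(max(0L, Tn - wlen + 1L))
    if (length(starts) == 0L) return(list(starts = integer(0), scores = numeric(0)))
    pen <- matrix(0, nrow = L, ncol = length(starts))
    for (i in seq_len(L)) {
      if (is.na(off[i])) { pen[i, ] <- gap_pen[i]; next }
      tpos <- starts + off[i]
      st <- pair_state(mch[i], tch[tpos])
      pen[i, ] <- ifelse(st == 0L, 0, ifelse(st == 1L, config$target_wobble,
                                             config$target_mismatch)) * mult[i]
    }
    extra <- if (length(gap_positions) > 0L) sum(gap_pen[gap_positions]) else 0
    list(starts = starts, scores = colSums(pen) +
           if (all(!is.na(off))) extra else 0)
  }

  aln_string <- function(off, s, gap_marks = integer(0)) {
    chars <- character(L)
    for (i in seq_len(L)) {
      if (is.na(off[i])) { chars[i] <- "-"; next }
      st <- pair_state(mch[i], tch[s + off[i]])
      chars[i] <- c("|", "o", ".")[st + 1L]
    }
    paste(chars, collapse = "")
  }

  # miRNA position i pairs antiparallel: window offset wlen - i for ungapped
  gap_cost <- config$target_gap * mult

  # ungapped
  off0 <- (L - seq_len(L))
  sc <- score_topology(off0, L, gap_cost, integer(0))
  add_hits(sc$starts, sc$scores, L, "none", function(s) aln_string(off0, s))

  # one transcript bulge between miRNA positions g and g+1 (extra transcript
  # base opposite no miRNA base); gap attributed to position g
  for (g in seq_len(L - 1L)) {
    if (g %in% nogap) next
    wlen <- L + 1L
    off <- ifelse(seq_len(L) <= g, wlen - seq_len(L), wlen - seq_len(L) - 1L)
    starts <- seq_len(max(0L, Tn - wlen + 1L))
    if (length(starts) == 0L) next
    scg <- score_topology(off, wlen, gap_cost, integer(0))
    scg$scores <- scg$scores + gap_cost[g]
    add_hits(scg$starts, scg$scores, wlen, "transcript",
             function(s) aln_string(off, s))
  }

  # one miRNA bulge: miRNA position g unpaired
  for (g in seq(2L, L - 1L)) {
    if (g %in% nogap) next
    wlen <- L - 1L
    off <- ifelse(seq_len(L) < g, wlen - seq_len(L),
                  ifelse(seq_len(L) == g, NA_integer_, wlen - seq_len(L) + 1L))
    scg <- score_topology(off, wlen, gap_cost, integer(0))
    add_hits(scg$starts, scg$scores, wlen, "mirna",
             function(s) aln_string(off, s))
  }

  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), score = numeric(0),
                      gap = character(0), alignment = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  # keep the best variant per site start
  res <- res[order(res$start, res$score), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing at least `m` annotated candidates when drawing
#' `n` genes from a background of `N` genes of which `M` carry the term:
#' P(X >= m) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n), evaluated via
#' the stable distribution-function implementation.
#'
#' @param N Background size (genes with annotation).
#' @param M Genes annotated to the term.
#' @param n Candidate genes within the background.
#' @param m Candidate genes annotated to the term.
#' @return P(X >= m) in \[0, 1\]; `m = 0` gives exactly 1.
#' @export
hypergeom_p <- function(N, M, n, m) {
  if (any(m > pmin(n, M)) || any(pmin(n, M) > N) || any(c(N, M, n, m) < 0)) {
    stop("hypergeometric bounds violated: need 0 <= m <= min(n, M) <= N")
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' GO/KEGG term enrichment of target gene candidates
#'
#' Tests every term annotated to at least one candidate gene with the
#' upper-tail hypergeometric probability against the full annotated
#' background, then corrects for multiple testing: Bonferroni over the
#' tested terms in GO mode, Benjamini-Hochberg FDR in KEGG mode. Terms with
#' corrected value below `alpha` are flagged significant.
#'
#' @param candidate_genes Character vector of candidate gene ids. Genes
#'   absent from the background are dropped with a warning.
#' @param annotation An `annotation_map` (see [read_annotation_map()]).
#' @param mode `"GO"` (Bonferroni) or `"KEGG"` (BH FDR).
#' @param alpha Significance threshold on the corrected value (default 0.05).
#' @return data.frame `term_id`, `term_name`, `N`, `M`, `n`, `m`, `p_raw`,
#'   `p_corrected`, `significant`, sorted by corrected value.
#' @export
enrich <- function(candidate_genes, annotation, mode = c("GO", "KEGG"),
                   alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(annotation, "annotation_map"))
  candidate_genes <- unique(candidate_genes)
  known <- candidate_genes %in% names(annotation$genes)
  if (any(!known)) {
    warning(sum(!known), " candidate gene(s) absent from the annotated ",
            "background were dropped")
  }
  cand <- candidate_genes[known]
  N <- annotation$background_size
  n <- length(cand)
  term_of_gene <- annotation$genes
  all_terms <- table(unlist(term_of_gene, use.names = FALSE))
  cand_terms <- table(unlist(term_of_gene[cand], use.names = FALSE))
  terms <- names(cand_terms)
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      N = integer(0), M = integer(0), n = integer(0),
                      m = integer(0), p_raw = numeric(0),
                      p_corrected = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  M <- as.integer(all_terms[terms])
  m <- as.integer(cand_terms[terms])
  p_raw <- hypergeom_p(N, M, n, m)
  p_corr <- if (mode == "GO") {
    pmin(1, p_raw * length(terms))
  } else {
    stats::p.adjust(p_raw, method = "BH")
  }
  nm <- annotation$term_names[terms]
  out <- data.frame(term_id = terms,
                    term_name = ifelse(is.na(nm), terms, nm),
                    N = N, M = M, n = n, m = m,
                    p_raw = p_raw, p_corrected = p_corr,
                    significant = p_corr < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_corrected, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
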