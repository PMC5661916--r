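# independent brute-force rescorer used as the oracle for site scanning
brute_scan <- function(mirna, transcript, cfg = default_config()) {
  L <- nchar(mirna)
  mch <- strsplit(mirna, "")[[1]]
  tch <- strsplit(transcript, "")[[1]]
  mult <- ifelse(seq_len(L) >= cfg$target_core_start &
                   seq_len(L) <= cfg$target_core_end, 2, 1)
  state <- function(m, t) {
    if ((m == "A" && t == "T") || (m == "T" && t == "A") ||
        (m == "G" && t == "C") || (m == "C" && t == "G")) 0
    else if ((m == "G" && t == "T") || (m == "T" && t == "G")) 0.5
    else 1
  }
  nogap <- seq(cfg$target_nogap_start, cfg$target_nogap_end)
  out <- list()
  score_map <- function(offsets, wlen, gap_at) {
    for (s in seq_len(length(tch) - wlen + 1)) {
      sc <- 0
      for (i in seq_len(L)) {
        sc <- sc + if (is.na(offsets[i])) cfg$target_gap * mult[i] else {
          st <- state(mch[i], tch[s + offsets[i]])
          (if (st == 0.5) cfg$target_wobble else st * cfg$target_mismatch) * mult[i]
        }
      }
      if (!is.null(gap_at)) sc <- sc + cfg$target_gap * mult[gap_at]
      if (sc <= cfg$target_max_score) {
        out[[length(out) + 1]] <<- data.frame(start = s, score = sc)
      }
    }
  }
  score_map((L - seq_len(L)), L, NULL)
  for (g in seq_len(L - 1)) {
    if (g %in% nogap) next
    score_map(ifelse(seq_len(L) <= g, L + 1 - seq_len(L), L - seq_len(L)),
              L + 1, g)
  }
  for (g in seq(2, L - 1)) {
    if (g %in% nogap) next
    score_map(ifelse(seq_len(L) < g, L - 1 - seq_len(L),
                     ifelse(seq_len(L) == g, NA, L - seq_len(L))),
              L - 1, NULL)
  }
  if (length(out) == 0) return(data.frame(start = integer(0), score = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$score), ]
  df[!duplicated(df$start), ]
}

test_that("a perfect reverse-complement site scores zero", {
  set.seed(71)
  mirna <- c(m1 = paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
                        collapse = ""))
  site <- revcomp(mirna)
  tx <- c(t1 = paste0(strrep("CA", 20), site, strrep("AC", 20)))
  hits <- predict_targets(mirna, tx)
  # the perfect site itself scores exactly zero at the planted position;
  # overlapping single-bulge variants of the same site may also qualify
  best <- hits[hits$score == 0, ]
  expect_equal(nrow(best), 1L)
  expect_equal(best$start, 41L)
  expect_equal(best$alignment, strrep("|", 21))
  expect_true(all(hits$score <= default_config()$target_max_score))
  expect_error(predict_targets(c(short = "ACGTACGTACGT"), tx), "shorter than 18")
})

test_that("penalty arithmetic: core doubling, wobbles, and the score cutoff", {
  mirna <- c(m = "ATCGGATCGGATCGGATCGGA")  # 21 nt
  site <- revcomp(mirna)
  L <- 21L
  # three mismatches at miRNA positions 5, 7, 9 (core): 3 x 1.0 x 2 = 6 > 4
  flip <- function(site, mpos, base) {
    tpos <- L - mpos + 1L
    substr(site, tpos, tpos) <- base
    site
  }
  # m[5]=G, m[7]=T, m[9]=G: flip to bases that are neither WC nor wobble
  bad <- flip(flip(flip(site, 5L, "A"), 7L, "C"), 9L, "A")
  tx_bad <- c(t1 = paste0(strrep("CA", 10), bad, strrep("AC", 10)))
  expect_equal(nrow(predict_targets(mirna, tx_bad)), 0L)

  # wobble at position 15 (G:U) + mismatch at 16, outside the core: 0.5 + 1.0
  m2 <- c(m = "ATCGGATCGGATCGGATCGGA")
  s2 <- revcomp(m2)
  # position 15 is G (m2[15]=G); complement C -> change transcript base to T => G:T wobble
  stopifnot(substr(m2, 15, 15) == "G", substr(m2, 16, 16) == "A")
  s2 <- flip(s2, 15L, "T")
  s2 <- flip(s2, 16L, "G")  # m=A vs t=G: mismatch
  tx2 <- c(t1 = paste0(strrep("CA", 10), s2, strrep("AC", 10)))
  h2 <- predict_targets(m2, tx2)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$score, 1.5)
  expect_equal(substr(h2$alignment, 15, 16), "o.")
})

test_that("the scanner agrees with the brute-force rescorer", {
  set.seed(72)
  mirna <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
  # transcript with a planted near-perfect site plus random background
  site <- revcomp(mirna)
  substr(site, 3, 3) <- "A"
  tx <- paste0(paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                     collapse = ""),
               site,
               paste(sample(c("A", "C", "G", "T"), 130, replace = TRUE),
                     collapse = ""))
  mine <- predict_targets(c(m = mirna), c(t = tx))
  oracle <- brute_scan(mirna, tx)
  expect_equal(mine$start, oracle$start)
  expect_equal(mine$score, oracle$score)
})

test_that("hypergeometric tail equals direct summation of the formula", {
  expect_equal(hypergeom_p(10, 4, 3, 2), 1 / 3)
  expect_equal(hypergeom_p(10, 4, 3, 0), 1)
  expect_equal(hypergeom_p(12, 12, 5, 5), 1)
  expect_error(hypergeom_p(10, 4, 3, 4), "bounds")
  set.seed(73)
  for (i in 1:50) {
    N <- sample(5:30, 1); M <- sample(0:N, 1); n <- sample(0:N, 1)
    m <- sample(0:min(n, M), 1)
    direct <- if (m == 0) 1 else
      1 - sum(choose(M, 0:(m - 1)) * choose(N - M, n - (0:(m - 1))) /
                choose(N, n))
    expect_equal(hypergeom_p(N, M, n, m), direct, tolerance = 1e-12)
  }
})

test_that("enrichment corrections behave and the planted term is recovered", {
  # one term carried by every gene: never significant
  am <- annotation_map(c("g1", "g2", "g3"), rep("GO:1", 3))
  e <- enrich(c("g1", "g2"), am, mode = "GO")
  expect_equal(e$p_corrected, 1)
  expect_false(e$significant)

  # corrected values never fall below raw; BH is monotone
  ann <- make_annotation(74, n_genes = 150L, n_terms = 40L)
  go <- enrich(ann$candidates, ann$annotation, mode = "GO")
  expect_true(all(go$p_corrected >= go$p_raw - 1e-12))
  kegg <- enrich(ann$candidates, ann$annotation, mode = "KEGG")
  expect_true(all(diff(kegg$p_corrected) >= -1e-12))
  # planted term is the unique significant one in GO mode
  expect_equal(go$term_id[go$significant], ann$planted_term)
  expect_equal(kegg$term_id[kegg$p_corrected == min(kegg$p_corrected)][1],
               ann$planted_term)
  # m <= min(n, M) invariant on every row
  expect_true(all(go$m <= pmin(go$n, go$M)))
  expect_warning(enrich(c(ann$candidates, "ghost_gene"), ann$annotation),
                 "absent from the annotated")
})
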