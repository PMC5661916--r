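test_that("tag mapping reports exact loci and enforces the copy-number cap", {
  set.seed(51)
  tag <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = "")
  bg <- function(n) paste(sample(c("A", "C"), n, replace = TRUE,
                                 prob = c(0.3, 0.7)), collapse = "")
  one <- c(chr1 = paste0(bg(100), tag, bg(100)))
  m <- map_tags(tag, one, max_copy_number = 20L)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 101L)
  expect_equal(m$end, 121L)
  expect_equal(m$strand, "+")
  # minus-strand locus: reverse complement planted
  two <- c(chr1 = paste0(bg(50), revcomp(tag), bg(50)))
  m2 <- map_tags(tag, two, max_copy_number = 20L)
  expect_equal(m2$strand, "-")
  expect_equal(m2$start, 51L)
  expect_identical(unname(revcomp(substr(two, m2$start, m2$end))), tag)
  # 21 copies with cap 20 -> discarded
  many <- c(chr1 = paste(c(rep(c(tag, bg(30)), 21)), collapse = ""))
  m3 <- map_tags(tag, many, max_copy_number = 20L)
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "discarded"), tag)
  expect_equal(nrow(map_tags(tag, many, max_copy_number = 21L)), 21L)
  expect_error(map_tags(tag, character(0)), "empty reference")

  # 50 planted single-locus tags recovered at their coordinates
  set.seed(52)
  tags <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE), collapse = ""), "")
  starts <- integer(50); pos <- 0L; pieces <- character(0)
  for (i in 1:50) {
    gap <- bg(40); pieces <- c(pieces, gap, tags[i])
    starts[i] <- pos + 41L; pos <- pos + 40L + 22L
  }
  genome <- c(chr1 = paste(pieces, collapse = ""))
  mm <- map_tags(tags, genome, 20L)
  mm <- mm[order(match(mm$tag, tags)), ]
  expect_equal(nrow(mm), 50L)
  expect_equal(mm$start, starts)
})

test_that("excised windows follow the flank/space arithmetic and truncate at edges", {
  p <- mireap_params()
  reach <- p$max_space + 21L + p$flank_len
  ref <- c(chr1 = strrep("ACGT", 300))  # 1200 nt
  locus <- data.frame(ref_id = "chr1", start = 500L, end = 520L, strand = "+")
  w <- excise_precursor(locus, ref, p)
  expect_equal(nrow(w), 2L)
  w5 <- w[w$arm == "5p", ]; w3 <- w[w$arm == "3p", ]
  expect_equal(w5$win_start, 500L - p$flank_len)
  expect_equal(w5$win_end, 520L + reach)
  expect_equal(w3$win_start, 500L - reach)
  expect_equal(w3$win_end, 520L + p$flank_len)
  expect_equal(nchar(w5$window), w5$win_end - w5$win_start + 1L)
  # mature sits where the coordinates say
  expect_equal(substr(w5$window, w5$mature_start, w5$mature_end),
               unname(substr(ref, 500, 520)))
  # edge truncation: no out-of-bounds coordinates
  locus2 <- data.frame(ref_id = "chr1", start = 3L, end = 23L, strand = "+")
  w2 <- excise_precursor(locus2, ref, p)
  expect_true(all(w2$win_start >= 1L))
  expect_true(all(w2$win_end <= nchar(ref)))
})

test_that("duplex metrics match hand-constructed structures", {
  # perfect 21-bp stem, 10-nt loop: mature 1..21 pairs 32..52
  db <- paste0(strrep("(", 21), strrep(".", 10), strrep(")", 21))
  m <- duplex_metrics(db, 1L, 21L)
  expect_equal(m$n_pairs, 21L)
  expect_equal(m$max_bulge, 0L)
  expect_equal(m$asymmetry, 0L)
  expect_equal(m$space, 10L)
  expect_equal(m$star_start, 32L)
  expect_equal(m$star_end, 52L)  # overhang clipped at the sequence end

  # 3-nt interior loop on the mature strand only: ((((((...((((((((((((((( loop )))))))))))))))))))))
  db2 <- paste0(strrep("(", 6), "...", strrep("(", 15),
                strrep(".", 8), strrep(")", 21))
  m2 <- duplex_metrics(db2, 1L, 24L)
  expect_equal(m2$n_pairs, 21L)
  expect_equal(m2$max_bulge, 3L)
  expect_equal(m2$asymmetry, 3L)

  # fully unpaired mature -> no duplex
  db3 <- paste0(strrep(".", 25), "((((....))))")
  expect_equal(duplex_metrics(db3, 1L, 20L)$reason, "no duplex")
  expect_error(pair_table("(()"), "unbalanced")
})

test_that("the MFE acceptance boundary is sharp at the threshold", {
  set.seed(53)
  mature <- "GATCGGTAGCTTGCAGCTGAC"
  hp <- paste0(mature, "CACACACACA", revcomp(mature))
  genome <- c(chr1 = paste0(strrep("CA", 30), hp, strrep("CA", 30)))
  p <- mireap_params()
  at <- call_novel(mature, genome, p, engine = fixed_mfe_engine(-18.0))
  expect_equal(nrow(at), 1L)     # -18.0 passes (threshold inclusive)
  above <- call_novel(mature, genome, p, engine = fixed_mfe_engine(-17.5))
  expect_equal(nrow(above), 0L)  # -17.5 rejected
})

test_that("the minimum-pairs criterion rejects 15-pair duplexes and accepts 16", {
  ref <- shared_reference()
  hp_pairs <- ref$hairpins[ref$hairpins$label == "pairs", ][1, ]
  p <- mireap_params()
  # its best duplex has exactly 15 pairs: rejected at 16, accepted at 15
  expect_equal(nrow(call_novel(hp_pairs$mature, ref$genome, p)), 0L)
  relaxed <- mireap_params(min_pairs = 15L)
  expect_gte(nrow(call_novel(hp_pairs$mature, ref$genome, relaxed)), 1L)
})

test_that("accepted candidates re-verify all criteria; calls are deterministic and monotone", {
  ref <- shared_reference()
  p <- mireap_params()
  called <- call_novel(ref$hairpins$mature, ref$genome, p)
  # every accepted candidate re-verifies the five numeric criteria
  for (i in seq_len(nrow(called))) {
    met <- duplex_metrics(called$structure[i], called$mature_start[i],
                          called$mature_end[i])
    expect_lte(called$mfe[i], p$max_precursor_mfe)
    expect_gte(met$n_pairs, p$min_pairs)
    expect_lte(met$max_bulge, p$max_bulge)
    expect_lte(met$asymmetry, p$max_asymmetry)
    expect_lte(met$space, p$max_space)
    # mature substring integrity
    expect_identical(substr(called$precursor[i], called$mature_start[i],
                            called$mature_end[i]), called$tag[i])
  }
  # determinism
  again <- call_novel(ref$hairpins$mature, ref$genome, p)
  expect_identical(called, again)
  # monotonicity: relaxing every threshold never shrinks the accepted set
  relaxed <- mireap_params(max_precursor_mfe = -15, min_pairs = 14L,
                           max_bulge = 6L, max_asymmetry = 6L,
                           max_space = 320L)
  more <- call_novel(ref$hairpins$mature, ref$genome, relaxed)
  expect_true(all(called$tag %in% more$tag))
})
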