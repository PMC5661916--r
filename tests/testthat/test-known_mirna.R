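test_that("two-stage matching enforces the 16-nt mature overlap sharply", {
  ref <- tiny_known_ref()  # mature at 30..50 (21 nt) on an 80 nt precursor
  prec <- ref$precursor
  sub <- function(s, e) substr(prec, s, e)

  exact <- match_known(sub(30, 50), ref)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$overlap, 21L)
  expect_equal(exact$offset, 0L)
  expect_equal(exact$position, 30L)

  # brute-force overlap oracle over all 21-nt windows of the precursor
  for (s in c(34L, 35L, 36L, 25L, 26L)) {
    tag <- sub(s, s + 20L)
    want <- max(0L, min(s + 20L, 50L) - max(s, 30L) + 1L)
    hit <- match_known(tag, ref)
    if (want >= 16L) {
      expect_equal(hit$overlap[hit$position == s], want)
    } else {
      expect_false(s %in% hit$position)
    }
  }
  # shifted +4 => overlap 17 passes; +6 => overlap 15 fails
  expect_equal(nrow(match_known(sub(34, 54), ref)), 1L)
  expect_equal(nrow(match_known(sub(36, 56), ref)), 0L)
  # loop-only tag (no mature overlap)
  expect_equal(nrow(match_known(sub(55, 75), ref)), 0L)
  # tag not on the precursor at all
  expect_equal(nrow(match_known("AAAACCCCGGGGTTTTACGATG", ref)), 0L)

  bad <- ref; bad$mature <- chartr("A", "C", paste0("A", substr(bad$mature, 2, 21)))
  expect_error(match_known(sub(30, 50), bad), "validation error")
})

test_that("expression accumulation is additive and matches a brute-force rescan", {
  ref <- rbind(tiny_known_ref(),
               within(tiny_known_ref(), mirna_id <- "mir_twin"))
  prec <- ref$precursor[1]
  t1 <- substr(prec, 30, 50); t2 <- substr(prec, 32, 52)
  tags <- data.frame(sequence = c(t1, t2), F0 = c(3L, 4L), F3 = c(10L, 0L))
  hits <- match_known(tags$sequence, ref[1, ])
  expr <- expression_counts(hits, tags)
  expect_equal(expr$F0, 7)
  expect_equal(expr$F3, 10)
  one <- expression_counts(match_known(t1, ref[1, ]),
                           data.frame(sequence = t1, F0 = 10L))
  expect_equal(one$F0, 10)

  # multi-mapping: identical precursors -> full counting doubles, fractional splits
  hits2 <- match_known(tags$sequence, ref)
  full <- expression_counts(hits2, tags, multi = "full")
  expect_equal(full$F0, c(7, 7))
  frac <- expression_counts(hits2, tags, multi = "fraction")
  expect_equal(frac$F0, c(3.5, 3.5))
  expect_equal(sum(frac$F0), sum(tags$F0))

  # brute-force rescan oracle on a random tag set
  set.seed(41)
  rnd <- vapply(1:30, function(i) {
    s <- sample(1:60, 1)
    substr(prec, s, s + sample(17:21, 1))
  }, "")
  tags3 <- data.frame(sequence = unique(rnd),
                      F0 = seq_along(unique(rnd)))
  hits3 <- match_known(tags3$sequence, ref[1, ])
  expr3 <- expression_counts(hits3, tags3)
  brute <- 0L
  for (i in seq_len(nrow(tags3))) {
    tg <- tags3$sequence[i]
    p <- regexpr(tg, prec, fixed = TRUE)
    if (p > 0) {
      ov <- max(0L, min(p + nchar(tg) - 1L, 50L) - max(p, 30L) + 1L)
      if (ov >= 16L) brute <- brute + tags3$F0[i]
    }
  }
  expect_equal(if (nrow(expr3) > 0) expr3$F0 else 0L, brute)
})

test_that("base bias recovers planted first-base composition", {
  expect_error(base_bias(character(0)), "at least one")
  one <- base_bias("TAAAGGCTGACCTGAAACGGT")
  expect_equal(one$first_base$proportion[one$first_base$base == "T"], 1)
  two <- base_bias(c("TAAAGGCTGACCTGAAACGGT", "AAAAGGCTGACCTGAAACGGT"))
  fb <- two$first_base
  expect_equal(fb$proportion[fb$base %in% c("T", "A")], c(0.5, 0.5))

  set.seed(42)
  n <- 400
  first <- sample(c("T", "A", "G", "C"), n, replace = TRUE,
                  prob = c(0.9, 0.04, 0.03, 0.03))
  tags <- vapply(first, function(f)
    paste0(f, paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                    collapse = "")), "")
  bb <- base_bias(tags)
  u21 <- bb$first_base$proportion[bb$first_base$length == 21 &
                                    bb$first_base$base == "T"]
  expect_equal(u21, 0.9, tolerance = 0.05)
  # proportions sum to 1 at every position
  sums <- tapply(bb$by_position$proportion, bb$by_position$position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
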