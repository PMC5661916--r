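test_that("generators are deterministic for a fixed seed", {
  expect_identical(make_known_reference(91), make_known_reference(91))
  ncr <- make_ncrna_reference(92)
  expect_identical(ncr, make_ncrna_reference(92))
  known <- make_known_reference(91, n = 8L)
  a <- make_libraries(93, known, NULL, ncr, depth = 20000)
  b <- make_libraries(93, known, NULL, ncr, depth = 20000)
  expect_identical(a$tags, b$tags)
  r1 <- make_reference(94, n_pass = 1L, n_fail = 0L)
  r2 <- make_reference(94, n_pass = 1L, n_fail = 0L)
  expect_identical(r1$genome, r2$genome)
  # minimal case: the single planted hairpin is called by the module itself
  expect_equal(nrow(call_novel(r1$hairpins$mature, r1$genome)), 1L)
})

test_that("failing hairpins violate exactly their labeled criterion", {
  ref <- shared_reference()
  p <- mireap_params()
  fails <- ref$hairpins[ref$hairpins$label != "pass", ]
  for (i in seq_len(nrow(fails))) {
    hp <- fails[i, ]
    # excise the planted window exactly as the caller would and fold it
    locus <- data.frame(ref_id = "chr1", start = hp$mature_start,
                        end = hp$mature_end, strand = "+")
    w <- excise_precursor(locus, ref$genome, p)
    w5 <- w[w$arm == "5p", ]
    f <- fold(w5$window)
    met <- duplex_metrics(f$structure, w5$mature_start, w5$mature_end)
    flags <- c(mfe = f$mfe <= p$max_precursor_mfe,
               pairs = met$n_pairs >= p$min_pairs,
               bulge = met$max_bulge <= p$max_bulge,
               asymmetry = met$asymmetry <= p$max_asymmetry,
               space = met$space >= 0 && met$space <= p$max_space)
    expect_false(flags[[hp$label]],
                 label = paste0(hp$hairpin_id, " violates ", hp$label))
    expect_true(all(flags[setdiff(names(flags), hp$label)]),
                label = paste0(hp$hairpin_id, " passes the rest"))
    if (hp$label == "pairs") expect_equal(met$n_pairs, p$min_pairs - 1L)
  }
})

test_that("library generator bookkeeping is exact and fractions are recovered", {
  known <- make_known_reference(95, n = 20L)
  ncrna <- make_ncrna_reference(96)
  libs <- make_libraries(97, known, NULL, ncrna, depth = 2e5,
                         contaminant_fractions = c(rRNA = 0.10, tRNA = 0.015))
  # per-library tag counts sum to the clean depth
  for (lib in libs$libraries) {
    expect_equal(sum(libs$tags[[lib]]), unname(libs$clean_reads[[lib]]))
  }
  # planted 10% rRNA recovered within 0.5% by classification
  a <- match_ncrna(libs$tags$sequence, ncrna)
  rr <- a$sequence[a$category == "rRNA"]
  frac <- sum(libs$tags$F0[libs$tags$sequence %in% rr]) / sum(libs$tags$F0)
  expect_equal(frac, 0.10, tolerance = 0.05)
  expect_lt(abs(frac - 0.10), 0.005)
  # prescribing a fold change for an unplanted id errors
  expect_error(
    make_libraries(97, known, NULL, ncrna, depth = 1e4,
                   lfc_f = c(ghost = 2)),
    "unplanted")
})

test_that("intended fold changes are recovered within 0.15 at depth 1e6", {
  known <- make_known_reference(98, n = 20L)
  ncrna <- make_ncrna_reference(96)
  libs <- make_libraries(99, known, NULL, ncrna, depth = 1e6)
  ent <- libs$entities
  de <- ent[ent$lfc_f != 0, ]
  est <- fold_change(normalize_rpm(de$count_F3, libs$clean_reads[["F3"]]),
                     normalize_rpm(de$count_F0, libs$clean_reads[["F0"]]))
  expect_true(all(abs(est - de$lfc_f) <= 0.15))
})
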