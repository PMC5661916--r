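ad3 <- "TGGAATTCTCGGGTGCCAAGG"
ad5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

mk_read <- function(insert, qual_prefix = "") {
  s <- substr(paste0(insert, ad3, strrep("A", 50)), 1, 50)
  q <- paste0(qual_prefix, strrep("I", 50 - nchar(qual_prefix)))
  list(sequence = s, quality = q)
}

test_that("cleaning attributes every removal once and conserves read counts", {
  good <- "ACGTGGCTAGCTAGCTAGCTG"  # 21 nt
  reads <- rbind(
    data.frame(mk_read(good)),                       # clean
    data.frame(mk_read(good)),                       # duplicate -> count 2
    data.frame(mk_read("GGCTAGGTCAGTCGATGCAGT")),    # clean, different tag
    data.frame(sequence = substr(strrep(ad3, 3), 1, 50),
               quality = strrep("I", 50)),           # adapter dimer -> no_insert
    data.frame(mk_read(strrep("A", 22))),            # polyA
    data.frame(mk_read("GGCTAGCTAGCT")),             # 12 nt -> length
    data.frame(mk_read(good, qual_prefix = "###")),  # low quality
    data.frame(sequence = substr(paste0(ad5, good, ad3, strrep("A", 50)), 1, 50),
               quality = strrep("I", 50)),           # 5' contaminant
    data.frame(sequence = strrep("G", 50),
               quality = strrep("I", 50))            # no 3' adapter
  )
  reads$id <- sprintf("r%d", seq_len(nrow(reads)))
  out <- clean_reads(reads, ad3, ad5, lib_id = "F0")
  st <- out$stats
  expect_equal(st$raw_reads, 9L)
  expect_equal(st$clean_reads, 3L)
  expect_equal(st$no_insert, 1L)
  expect_equal(st$polyA, 1L)
  expect_equal(st$length_out_of_range, 1L)
  expect_equal(st$low_quality, 1L)
  expect_equal(st$contam_5prime, 1L)
  expect_equal(st$no_3prime, 1L)
  # conservation: raw = clean + sum of removals
  rem <- c("low_quality", "contam_5prime", "no_3prime", "no_insert",
           "polyA", "length_out_of_range")
  expect_equal(st$clean_reads + sum(unlist(st[rem])), st$raw_reads)
  # collapsing conservation
  expect_equal(sum(out$tags$F0), st$clean_reads)
  expect_equal(out$tags$F0[out$tags$sequence == good], 2L)
  expect_error(clean_reads(reads, "", lib_id = "x"), "configuration error")
})

test_that("planted artifact reads are recovered exactly by the cleaning stats", {
  known <- make_known_reference(21, n = 10L)
  ncrna <- make_ncrna_reference(22)
  dir <- withr::local_tempdir()
  libs <- make_libraries(23, known, NULL, ncrna, depth = 10000,
                         format = "fastq", out_dir = dir)
  out <- clean_reads(libs$fastq[["F0"]], libs$adapter3, libs$adapter5,
                     lib_id = "F0")
  expect_equal(out$stats$clean_reads, unname(libs$clean_reads[["F0"]]))
  expect_equal(out$stats$no_insert, unname(libs$artifacts[["no_insert"]]))
  expect_equal(out$stats$polyA, unname(libs$artifacts[["polyA"]]))
  expect_equal(out$stats$length_out_of_range, unname(libs$artifacts[["short"]]))
  expect_equal(out$stats$low_quality, unname(libs$artifacts[["low_quality"]]))
  expect_equal(out$stats$contam_5prime, unname(libs$artifacts[["contam_5prime"]]))
  # collapsed counts equal the drawn per-entity counts
  truth <- libs$entities
  row <- match(out$tags$sequence, truth$sequence)
  expect_true(all(!is.na(row)))
  expect_equal(out$tags$F0, truth$count_F0[row])
})

test_that("cleaning already-clean tags changes nothing", {
  set.seed(3)
  tags <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(18:30, 1), replace = TRUE),
          collapse = ""), "")
  tags <- unique(tags[!grepl("AAAAAAAAAA", tags)])
  reads <- data.frame(id = seq_along(tags), sequence = tags,
                      quality = strrep("I", nchar(tags)))
  out <- clean_reads(reads, adapter3 = NULL, lib_id = "L",
                     require_adapter = FALSE)
  expect_equal(sort(out$tags$sequence), sort(tags))
  expect_equal(out$stats$clean_reads, length(tags))
  # second pass over the cleaned tags is the identity
  reads2 <- data.frame(id = seq_len(nrow(out$tags)),
                       sequence = out$tags$sequence,
                       quality = strrep("I", nchar(out$tags$sequence)))
  out2 <- clean_reads(reads2, adapter3 = NULL, lib_id = "L",
                      require_adapter = FALSE)
  expect_equal(out2$tags$sequence, out$tags$sequence)
})

test_that("length distribution sums to library unique and total counts", {
  tags <- data.frame(sequence = c("ACGTGGCTAGCTAGCTAGCTG"), L1 = 5L)
  expect_equal(length_distribution(tags, "L1"),
               data.frame(length = 21L, unique_count = 1L, total_count = 5L))
  empty <- data.frame(sequence = character(0), L1 = integer(0))
  expect_equal(nrow(length_distribution(empty, "L1")), 0L)

  set.seed(4)
  lens <- sample(18:30, 300, replace = TRUE,
                 prob = c(1, 1, 2, 20, 3, 2, 40, 2, 1, 1, 1, 1, 1))
  seqs <- unique(vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), ""))
  tags <- data.frame(sequence = seqs, L1 = rpois(length(seqs), 5) + 1L)
  d <- length_distribution(tags, "L1")
  expect_equal(sum(d$unique_count), nrow(tags))
  expect_equal(sum(d$total_count), sum(tags$L1))
  # planted modes: 24 nt most abundant, then 21 nt
  ord <- d$length[order(-d$unique_count)]
  expect_equal(ord[1:2], c(24L, 21L))
})

test_that("common/specific classes partition the union of tags", {
  two <- function(a, b) {
    u <- sort(unique(c(a, b)))
    data.frame(sequence = u, A = as.integer(u %in% a), B = as.integer(u %in% b))
  }
  same <- two(c("ACGTACGTACGTACGTAA", "CCGTACGTACGTACGTAA"),
              c("ACGTACGTACGTACGTAA", "CCGTACGTACGTACGTAA"))
  cs <- common_specific(same)
  expect_equal(cs$unique_count[cs$class == "shared"], 2L)
  expect_equal(sum(cs$unique_count[cs$class != "shared"]), 0L)

  disjoint <- two("ACGTACGTACGTACGTAA", "CCGTACGTACGTACGTAA")
  cs <- common_specific(disjoint)
  expect_equal(cs$unique_count[cs$class == "shared"], 0L)
  expect_equal(sum(cs$unique_count), 2L)

  set.seed(5)
  pool <- unique(vapply(1:150, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""), ""))
  shared <- pool[1:60]; a_only <- pool[61:80]; b_only <- pool[81:100]
  tags <- two(c(shared, a_only), c(shared, b_only))
  cs <- common_specific(tags)
  expect_equal(cs$unique_count, c(60L, 20L, 20L),
               ignore_attr = TRUE)
  expect_equal(sum(cs$unique_count), 100L)
  expect_error(common_specific(data.frame(sequence = "A", L = 1L)),
               "at least 2")
})
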