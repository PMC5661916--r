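# Seeded generators for every input the pipeline consumes, with ground-truth
# bookkeeping so recovery tests can compare pipeline output against what was
# planted. Sequence design notes:
#  - the genome background is drawn over {A, C} only (C-rich): A/C sequence
#    cannot base-pair with itself, so planted hairpins dominate the folded
#    structure of any excised window and pass/fail labels stay exact;
#  - deliberately unpaired duplex positions (bulge/asymmetry designs) are
#    A/C-only for the same reason;
#  - every planted construct is verified with the package's own folding and
#    duplex code (rejection sampling with bounded retries), so ground truth
#    holds under the actual thermodynamic engine, not just by construction.

rand_chars <- function(n, alphabet, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# background that cannot pair with itself; C-rich to limit pairing with the
# A/U-rich arms of weak planted hairpins
rand_background <- function(n) rand_chars(n, c("A", "C"), c(0.3, 0.7))

# random tag rejected for poly-A content, adapter seed and N
rand_tag <- function(len, alphabet = c("A", "C", "G", "T"), avoid = character(0),
                     max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    s <- rand_chars(len, alphabet)
    n_a <- nchar(gsub("[^A]", "", s))
    if (n_a / len >= 0.6) next
    if (grepl("AAAAAAAA", s, fixed = TRUE)) next
    if (any(vapply(avoid, function(a) grepl(a, s, fixed = TRUE), TRUE))) next
    return(s)
  }
  stop("could not draw a tag satisfying the constraints")
}

# Assemble one hairpin unit for a given label. Returns list(seq, mature,
# mature_offset) where mature_offset is the 0-based offset of the mature
# inside the unit. Labels: "pass" or the single criterion a failing hairpin
# violates: "mfe", "pairs", "bulge", "asymmetry", "space".
hairpin_unit <- function(label, avoid) {
  loop <- rand_background(10L)
  if (label == "pass") {
    m <- rand_tag(21L, avoid = avoid)
    list(seq = paste0(m, loop, revcomp(m)), mature = m, mature_offset = 0L)
  } else if (label == "pairs") {
    m <- paste0(rand_tag(15L, avoid = avoid), rand_chars(7L, c("A", "C"), c(0.3, 0.7)))
    list(seq = paste0(m, loop, revcomp(substr(m, 1L, 15L))),
         mature = m, mature_offset = 0L)
  } else if (label == "mfe") {
    m <- paste0(rand_tag(16L, alphabet = c("A", "T"), avoid = avoid),
                rand_chars(6L, c("A", "C"), c(0.3, 0.7)))
    list(seq = paste0(m, loop, revcomp(substr(m, 1L, 16L))),
         mature = m, mature_offset = 0L)
  } else if (label == "bulge") {
    m <- rand_tag(22L, avoid = avoid)
    substr(m, 9L, 13L) <- rand_chars(5L, c("A", "C"), c(0.3, 0.7))
    arm3 <- paste0(revcomp(substr(m, 14L, 22L)),
                   rand_chars(5L, c("A", "C"), c(0.3, 0.7)),
                   revcomp(substr(m, 1L, 8L)))
    list(seq = paste0(m, loop, arm3), mature = m, mature_offset = 0L)
  } else if (label == "asymmetry") {
    m <- rand_tag(22L, avoid = avoid)
    substr(m, 8L, 8L) <- rand_chars(1L, c("A", "C"))
    substr(m, 12L, 15L) <- rand_chars(4L, c("A", "C"), c(0.3, 0.7))
    arm3 <- paste0(revcomp(substr(m, 16L, 22L)),
                   revcomp(substr(m, 9L, 11L)),
                   revcomp(substr(m, 1L, 7L)))
    list(seq = paste0(m, loop, arm3), mature = m, mature_offset = 0L)
  } else if (label == "space") {
    m <- rand_tag(21L, avoid = avoid)
    list(seq = paste0(m, rand_background(310L), revcomp(m)),
         mature = m, mature_offset = 0L)
  } else stop("unknown hairpin label: ", label)
}

# criterion vector for one folded candidate; metrics may carry a reject reason
criterion_flags <- function(mfe, met, params) {
  if (!is.null(met$reason)) {
    return(c(mfe = FALSE, pairs = FALSE, bulge = FALSE,
             asymmetry = FALSE, space = FALSE))
  }
  c(mfe = mfe <= params$max_precursor_mfe,
    pairs = met$n_pairs >= params$min_pairs,
    bulge = met$max_bulge <= params$max_bulge,
    asymmetry = met$asymmetry <= params$max_asymmetry,
    space = met$space >= 0L && met$space <= params$max_space)
}

# quick unit-level screen: fold the unit with short background pads and check
# that the label's criterion pattern holds (exactly one violated for fails)
unit_matches_label <- function(unit, label, params, engine) {
  pad <- rand_background(20L)
  seqs <- paste0(pad, unit$seq, pad)
  f <- fold(seqs, engine = engine)
  ms <- 20L + unit$mature_offset + 1L
  me <- ms + nchar(unit$mature) - 1L
  met <- duplex_metrics(f$structure, ms, me)
  fl <- criterion_flags(f$mfe, met, params)
  if (label == "pass") {
    return(all(fl) && f$mfe <= params$max_precursor_mfe - 2)
  }
  if (!is.null(met$reason)) return(FALSE)
  if (label == "pairs" && met$n_pairs != params$min_pairs - 1L) return(FALSE)
  !fl[[label]] && all(fl[setdiff(names(fl), label)])
}

#' Generate a reference genome with planted hairpins
#'
#' Plants `n_pass` hairpins that satisfy every hairpin criterion with margin
#' and `n_fail` hairpins that each violate exactly one named criterion
#' (cycled over mfe, pairs, bulge, asymmetry, space), separated by
#' low-structure background. Every plant is verified by running the
#' package's own hairpin caller on the assembled genome; units whose outcome
#' disagrees with their label are redrawn (bounded retries).
#'
#' @param seed Integer seed; fully determines the output.
#' @param n_pass,n_fail Numbers of criterion-passing and single-criterion-
#'   failing hairpins.
#' @param params [mireap_params()] list.
#' @param engine Folding engine.
#' @param spacer Background length between hairpins (default 400 nt, wide
#'   enough that no excised window spans two plants).
#' @return A list with `genome` (named character vector, one sequence named
#'   `chr1`) and `hairpins` (data.frame `hairpin_id`, `label`, `mature`,
#'   `mature_start`, `mature_end`, `unit_start`, `unit_end`).
#' @export
make_reference <- function(seed, n_pass = 20L, n_fail = 10L,
                           params = mireap_params(),
                           engine = rnafold_engine(), spacer = 400L) {
  set.seed(seed)
  fail_labels <- rep(c("mfe", "pairs", "bulge", "asymmetry", "space"),
                     length.out = n_fail)
  labels <- c(rep("pass", n_pass), fail_labels)
  adapter_seed <- substr(default_adapter3(), 1L, 8L)

  draw_unit <- function(label, avoid) {
    for (try in seq_len(50L)) {
      u <- hairpin_unit(label, avoid = c(adapter_seed, avoid))
      if (unit_matches_label(u, label, params, engine)) return(u)
    }
    stop("could not construct a '", label, "' hairpin within the retry budget")
  }

  units <- vector("list", length(labels))
  matures <- character(0)
  for (i in seq_along(labels)) {
    units[[i]] <- draw_unit(labels[i], matures)
    matures <- c(matures, units[[i]]$mature)
  }

  assemble <- function(units) {
    pieces <- character(0)
    pos <- 0L
    info <- list()
    for (i in seq_along(units)) {
      gap <- rand_background(spacer)
      pieces <- c(pieces, gap)
      pos <- pos + spacer
      u <- units[[i]]
      info[[i]] <- data.frame(
        hairpin_id = sprintf("hp_%02d", i), label = labels[i],
        mature = u$mature,
        mature_start = pos + u$mature_offset + 1L,
        mature_end = pos + u$mature_offset + nchar(u$mature),
        unit_start = pos + 1L, unit_end = pos + nchar(u$seq),
        stringsAsFactors = FALSE
      )
      pieces <- c(pieces, u$seq)
      pos <- pos + nchar(u$seq)
    }
    pieces <- c(pieces, rand_background(spacer))
    list(genome = c(chr1 = paste(pieces, collapse = "")),
         hairpins = do.call(rbind, info))
  }

  # genome-level verification loop: outcomes must match labels exactly
  for (round in seq_len(20L)) {
    built <- assemble(units)
    called <- call_novel(built$hairpins$mature, built$genome,
                         params = params, engine = engine)
    ok_call <- built$hairpins$mature %in% called$tag
    want <- labels == "pass"
    wrong <- which(ok_call != want)
    if (length(wrong) == 0L) return(built)
    for (i in wrong) units[[i]] <- draw_unit(labels[i], matures)
  }
  stop("planted-hairpin verification did not converge")
}

default_adapter3 <- function() "TGGAATTCTCGGGTGCCAAGG"
default_adapter5 <- function() "GTTCAGAGTTCTACAGTCCGACGATC"

#' Generate a miRBase-style known-miRNA reference
#'
#' @param seed Integer seed.
#' @param n Number of miRNAs.
#' @return data.frame as from [mirna_reference()] (ids `kmir_01`, ...).
#' @export
make_known_reference <- function(seed, n = 30L) {
  set.seed(seed)
  adapter_seed <- substr(default_adapter3(), 1L, 8L)
  matures <- character(0)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    len <- sample(20:22, 1L)
    m <- rand_tag(len, avoid = c(adapter_seed, matures))
    matures <- c(matures, m)
    prec <- paste0(rand_tag(15L, avoid = adapter_seed), m,
                   rand_tag(40L, avoid = adapter_seed))
    rows[[i]] <- data.frame(mirna_id = sprintf("kmir_%02d", i),
                            precursor = prec, mature_start = 16L,
                            mature_end = 15L + len, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  mirna_reference(df$mirna_id, df$precursor, df$mature_start, df$mature_end)
}

#' Generate non-coding RNA / repeat reference sets
#'
#' @param seed Integer seed.
#' @return Named list of named character vectors, keyed by category.
#' @export
make_ncrna_reference <- function(seed) {
  set.seed(seed)
  mk <- function(prefix, n, len_range) {
    seqs <- vapply(seq_len(n), function(i) {
      rand_chars(sample(len_range[1]:len_range[2], 1L), c("A", "C", "G", "T"))
    }, "")
    stats::setNames(seqs, paste0(prefix, "_", seq_len(n)))
  }
  list(rRNA = mk("rrna", 3L, c(500L, 1500L)),
       tRNA = mk("trna", 5L, c(72L, 90L)),
       snRNA = mk("snrna", 3L, c(100L, 180L)),
       snoRNA = mk("snorna", 3L, c(80L, 150L)),
       srpRNA = mk("srprna", 1L, c(280L, 320L)),
       "repeat" = mk("rep", 2L, c(300L, 600L)))
}

#' Generate a gene-to-term annotation map with one planted enriched term
#'
#' Builds a random flat annotation over `n_genes` genes and `n_terms` terms,
#' then plants one term that is strongly over-represented in a designated
#' candidate gene set (most candidates carry it; few background genes do).
#'
#' @param seed Integer seed.
#' @param n_genes,n_terms Background sizes.
#' @param n_candidates Size of the candidate set.
#' @param prefix Term-id prefix (`"GO"` or `"ko"`).
#' @return list with `annotation` (an `annotation_map`), `map` (the flat
#'   data.frame), `candidates` (gene ids) and `planted_term`.
#' @export
make_annotation <- function(seed, n_genes = 200L, n_terms = 50L,
                            n_candidates = 20L, prefix = "GO") {
  set.seed(seed)
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  terms <- sprintf("%s:%07d", prefix, seq_len(n_terms))
  planted <- terms[n_terms]
  free_terms <- terms[-n_terms]
  gene_v <- character(0); term_v <- character(0)
  for (g in genes) {
    k <- sample(1:4, 1L)
    gene_v <- c(gene_v, rep(g, k))
    term_v <- c(term_v, sample(free_terms, k))
  }
  candidates <- sample(genes, n_candidates)
  carriers <- c(sample(candidates, round(0.6 * n_candidates)),
                sample(setdiff(genes, candidates), 4L))
  gene_v <- c(gene_v, carriers)
  term_v <- c(term_v, rep(planted, length(carriers)))
  names_v <- paste0("term ", sub("^.*:", "", term_v))
  map <- unique(data.frame(gene_id = gene_v, term_id = term_v,
                           term_name = names_v, stringsAsFactors = FALSE))
  list(annotation = annotation_map(map$gene_id, map$term_id, map$term_name),
       map = map, candidates = candidates, planted_term = planted)
}

# default intended log2 fold changes for the two comparisons: applied to the
# first known miRNAs; ids 5-8 are perturbed in both cultivars
default_lfc_f <- function(known_ids) {
  ids <- known_ids[seq_len(min(8L, length(known_ids)))]
  stats::setNames(c(2, 1.8, 1.6, 1.5, 2, 1.6, -1.5, -2)[seq_along(ids)], ids)
}
default_lfc_r <- function(known_ids) {
  idx <- intersect(5:12, seq_along(known_ids))
  stats::setNames(c(2, 1.6, 1.8, 1.5, 1.7, -1.5, -2.2, -1.6)[seq_along(idx)],
                  known_ids[idx])
}

#' Generate the four tag-count libraries (two cultivars x two timepoints)
#'
#' Draws per-library counts for every planted entity (known miRNAs, novel
#' hairpin matures, ncRNA-derived contaminant tags and unannotated filler
#' tags) from a multinomial around prescribed proportions. Treated libraries
#' (`F3`, `R3`) scale the selected miRNAs by 2^(intended log2 fold change).
#' With `format = "fastq"`, reads (insert + 3' adapter, padded) are written
#' with planted artifact reads (adapter dimers, poly-A, short fragments,
#' low-quality, 5'-contaminated) at the stated rates.
#'
#' @param seed Integer seed.
#' @param known Known-miRNA reference from [make_known_reference()].
#' @param novel_hairpins Hairpin truth data.frame from [make_reference()].
#' @param ncrna Reference list from [make_ncrna_reference()].
#' @param depth Raw reads per library (default 1e6).
#' @param known_frac,novel_frac Clean-read fraction carried by known miRNA
#'   and novel-mature tags.
#' @param contaminant_fractions Named clean-read fractions per ncRNA
#'   category.
#' @param artifact_fractions Named raw-read fractions of planted artifacts
#'   (`no_insert`, `polyA`, `short`, `low_quality`, `contam_5prime`).
#' @param lfc_f,lfc_r Named log2 fold-change vectors (entity id -> lfc) for
#'   the F3/F0 and R3/R0 comparisons; defaults perturb the first known
#'   miRNAs. Prescribing an unplanted id is an error.
#' @param format `"counts"` (tag-count table only) or `"fastq"` (also write
#'   four FASTQ files under `out_dir`).
#' @param out_dir Directory for FASTQ output (required for
#'   `format = "fastq"`).
#' @param n_filler Number of unannotated filler tags.
#' @return list with `tags` (tag-count data.frame), `entities` (per-entity
#'   truth: id, sequence, category, intended lfc, exact drawn counts),
#'   `clean_reads`, `artifacts` (per-library planted artifact counts),
#'   `libraries`, and `fastq` (paths, when written).
#' @export
make_libraries <- function(seed, known, novel_hairpins, ncrna, depth = 1e6,
                           known_frac = 0.09, novel_frac = 0.01,
                           contaminant_fractions = c(
                             rRNA = 0.05, tRNA = 0.015, snRNA = 5e-4,
                             snoRNA = 5e-4, srpRNA = 5e-5, "repeat" = 5e-5),
                           artifact_fractions = c(
                             no_insert = 0.003, polyA = 0.002, short = 0.002,
                             low_quality = 0.002, contam_5prime = 0.001),
                           lfc_f = NULL, lfc_r = NULL,
                           format = c("counts", "fastq"), out_dir = NULL,
                           n_filler = 1500L) {
  format <- match.arg(format)
  set.seed(seed)
  libs <- c("F0", "F3", "R0", "R3")
  adapter3 <- default_adapter3()
  adapter5 <- default_adapter5()
  seed8 <- substr(adapter3, 1L, 8L)

  # --- entity table -------------------------------------------------------
  ent <- list()
  ent[[1]] <- data.frame(id = known$mirna_id, sequence = known$mature,
                         category = "miRNA_known", stringsAsFactors = FALSE)
  if (!is.null(novel_hairpins) && nrow(novel_hairpins) > 0L) {
    keep <- novel_hairpins$label == "pass"
    ent[[2]] <- data.frame(id = novel_hairpins$hairpin_id[keep],
                           sequence = novel_hairpins$mature[keep],
                           category = "miRNA_novel", stringsAsFactors = FALSE)
  }
  for (cat in names(contaminant_fractions)) {
    refs <- ncrna[[cat]]
    if (is.null(refs)) next
    n_tags <- if (contaminant_fractions[[cat]] >= 0.01) 50L else 10L
    rows <- lapply(seq_len(n_tags), function(i) {
      r <- refs[[sample(length(refs), 1L)]]
      len <- sample(19:25, 1L)
      s <- sample(nchar(r) - len, 1L)
      data.frame(id = sprintf("%s_tag_%03d", cat, i),
                 sequence = substr(r, s, s + len - 1L),
                 category = cat, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    ok <- !grepl(seed8, df$sequence, fixed = TRUE) &
      nchar(gsub("[^A]", "", df$sequence)) / nchar(df$sequence) < 0.8 &
      !grepl("AAAAAAAAAA", df$sequence, fixed = TRUE)
    ent[[length(ent) + 1L]] <- df[ok, , drop = FALSE]
  }
  len_probs <- stats::setNames(
    c(2, 3, 4, 14, 6, 5, 30, 5, 3, 2, 1, 0.5, 0.5), 18:30)
  filler_len <- as.integer(sample(names(len_probs), n_filler, replace = TRUE,
                                  prob = len_probs))
  filler <- vapply(filler_len, function(L) rand_tag(L, avoid = seed8), "")
  ent[[length(ent) + 1L]] <- data.frame(
    id = sprintf("unann_%04d", seq_len(n_filler)), sequence = filler,
    category = "unann", stringsAsFactors = FALSE)
  entities <- do.call(rbind, ent)
  entities <- entities[!duplicated(entities$sequence), , drop = FALSE]
  rownames(entities) <- NULL

  # --- proportions --------------------------------------------------------
  prop_for <- function(idx, total) {
    w <- exp(stats::rnorm(length(idx), 0, 1))
    w / sum(w) * total
  }
  base <- numeric(nrow(entities))
  base[entities$category == "miRNA_known"] <-
    prop_for(which(entities$category == "miRNA_known"), known_frac)
  if (any(entities$category == "miRNA_novel")) {
    base[entities$category == "miRNA_novel"] <-
      prop_for(which(entities$category == "miRNA_novel"), novel_frac)
  }
  for (cat in names(contaminant_fractions)) {
    idx <- which(entities$category == cat)
    if (length(idx) > 0L) base[idx] <- prop_for(idx, contaminant_fractions[[cat]])
  }
  rest <- 1 - sum(base)
  stopifnot(rest > 0)
  idx <- which(entities$category == "unann")
  base[idx] <- prop_for(idx, rest)

  if (is.null(lfc_f)) lfc_f <- default_lfc_f(known$mirna_id)
  if (is.null(lfc_r)) lfc_r <- default_lfc_r(known$mirna_id)
  missing_f <- setdiff(names(lfc_f), entities$id)
  missing_r <- setdiff(names(lfc_r), entities$id)
  if (length(missing_f) + length(missing_r) > 0L) {
    stop("fold change prescribed for unplanted entity: ",
         c(missing_f, missing_r)[[1L]])
  }
  entities$lfc_f <- unname(lfc_f[match(entities$id, names(lfc_f))])
  entities$lfc_r <- unname(lfc_r[match(entities$id, names(lfc_r))])
  entities$lfc_f[is.na(entities$lfc_f)] <- 0
  entities$lfc_r[is.na(entities$lfc_r)] <- 0

  # the unannotated background absorbs the mass shift of the perturbed
  # miRNAs, so planted proportions realize the intended fold changes exactly
  scale_props <- function(base, lfc) {
    p <- base * 2^lfc
    absorb <- entities$category == "unann" & lfc == 0
    delta <- sum(p) - sum(base)
    stopifnot(sum(p[absorb]) > delta)
    p[absorb] <- p[absorb] * (sum(p[absorb]) - delta) / sum(p[absorb])
    p / sum(p)
  }
  props <- list(F0 = base / sum(base), F3 = scale_props(base, entities$lfc_f),
                R0 = base / sum(base), R3 = scale_props(base, entities$lfc_r))

  # --- counts -------------------------------------------------------------
  n_artifact <- round(depth * artifact_fractions)
  clean_depth <- depth - sum(n_artifact)
  counts <- lapply(libs, function(lib) {
    as.integer(stats::rmultinom(1L, clean_depth, props[[lib]]))
  })
  names(counts) <- libs
  for (lib in libs) entities[[paste0("count_", lib)]] <- counts[[lib]]

  tags <- data.frame(sequence = entities$sequence, stringsAsFactors = FALSE)
  for (lib in libs) tags[[lib]] <- counts[[lib]]
  keep <- rowSums(as.matrix(tags[libs])) > 0L
  tags <- tags[keep, , drop = FALSE]
  tags <- tags[order(tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL

  out <- list(tags = tags, entities = entities,
              clean_reads = stats::setNames(rep(clean_depth, 4L), libs),
              artifacts = n_artifact, libraries = libs,
              adapter3 = adapter3, adapter5 = adapter5,
              lfc_f = lfc_f, lfc_r = lfc_r, depth = depth, seed = seed)

  # --- FASTQ materialization ---------------------------------------------
  if (format == "fastq") {
    stopifnot(!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    read_len <- 50L
    build_read <- function(insert) {
      substr(paste0(insert, adapter3, strrep("A", read_len)), 1L, read_len)
    }
    paths <- character(0)
    for (lib in libs) {
      inserts <- rep(entities$sequence, counts[[lib]])
      seqs <- vapply(unique(entities$sequence), build_read, "")
      reads <- unname(seqs[match(inserts, unique(entities$sequence))])
      quals <- rep(strrep("I", read_len), length(reads))
      # artifacts
      art_seq <- character(0); art_qual <- character(0)
      rep_art <- function(n, f) vapply(seq_len(max(n, 0L)), function(i) f(), "")
      art_seq <- c(art_seq, rep_art(n_artifact[["no_insert"]], function()
        substr(strrep(adapter3, 4L), 1L, read_len)))
      art_seq <- c(art_seq, rep_art(n_artifact[["polyA"]], function()
        build_read(strrep("A", sample(20:26, 1L)))))
      art_seq <- c(art_seq, rep_art(n_artifact[["short"]], function()
        build_read(rand_tag(sample(10:15, 1L), avoid = seed8))))
      art_qual <- c(art_qual, rep(strrep("I", read_len), length(art_seq)))
      lowq <- rep_art(n_artifact[["low_quality"]], function()
        build_read(rand_tag(21L, avoid = seed8)))
      art_seq <- c(art_seq, lowq)
      art_qual <- c(art_qual, rep(paste0("###", strrep("I", read_len - 3L)),
                                  length(lowq)))
      c5 <- rep_art(n_artifact[["contam_5prime"]], function()
        substr(paste0(adapter5, rand_tag(21L, avoid = seed8), adapter3,
                      strrep("A", read_len)), 1L, read_len))
      art_seq <- c(art_seq, c5)
      art_qual <- c(art_qual, rep(strrep("I", read_len), length(c5)))

      all_seq <- c(reads, art_seq)
      all_qual <- c(quals, art_qual)
      ord <- sample(length(all_seq))
      df <- data.frame(id = sprintf("%s_r%07d", lib, seq_along(all_seq)),
                       sequence = all_seq[ord], quality = all_qual[ord],
                       stringsAsFactors = FALSE)
      p <- file.path(out_dir, paste0(lib, ".fastq"))
      write_fastq(df, p)
      paths <- c(paths, p)
    }
    out$fastq <- stats::setNames(paths, libs)
  }
  out
}

#' Generate a synthetic qPCR Ct table from known fold changes
#'
#' @param seed Integer seed.
#' @param folds Named vector of true expression folds relative to the
#'   calibrator (the calibrator itself should be 1).
#' @param calibrator Calibrator sample name (must be in `names(folds)`).
#' @param reps Technical replicates per well group.
#' @param sd Gaussian Ct noise (cycles).
#' @return list with `ct` (data.frame `sample`, `role`, `ct`) and `folds`.
#' @export
make_ct_table <- function(seed, folds, calibrator, reps = 3L, sd = 0.1) {
  set.seed(seed)
  stopifnot(calibrator %in% names(folds))
  rows <- list()
  for (s in names(folds)) {
    shift <- stats::runif(1, -1, 1)  # sample-loading shift, cancels in dCt
    ddct_true <- -log2(folds[[s]] / folds[[calibrator]])
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, role = "target",
      ct = 25 + shift + ddct_true + stats::rnorm(reps, 0, sd),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s, role = "reference",
      ct = 18 + shift + stats::rnorm(reps, 0, sd),
      stringsAsFactors = FALSE)
  }
  list(ct = do.call(rbind, rows), folds = folds, calibrator = calibrator)
}

#' Generate a complete synthetic study into a directory
#'
#' Emits every input the pipeline needs: a genome with planted hairpins,
#' known-miRNA and ncRNA reference FASTA files, GO/KEGG annotation maps, the
#' four libraries (tag-count table, or FASTQ when `format = "fastq"`), and a
#' machine-readable `truth.json` with the ground-truth bookkeeping.
#'
#' @param seed Integer seed; fully determines all output.
#' @param out_dir Output directory (created if needed).
#' @param depth Raw reads per library.
#' @param format `"counts"` or `"fastq"`; see [make_libraries()].
#' @param n_pass,n_fail Planted hairpin counts; see [make_reference()].
#' @param engine Folding engine used to verify planted hairpins.
#' @return Invisibly, a list with all generator outputs (`reference`,
#'   `known`, `ncrna`, `go`, `kegg`, `libraries`) and the file paths.
#' @export
simulate_run <- function(seed, out_dir, depth = 1e6,
                         format = c("counts", "fastq"),
                         n_pass = 20L, n_fail = 10L,
                         engine = rnafold_engine()) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(seed, n_pass = n_pass, n_fail = n_fail, engine = engine)
  known <- make_known_reference(seed + 1L)
  ncrna <- make_ncrna_reference(seed + 2L)
  go <- make_annotation(seed + 3L, prefix = "GO")
  kegg <- make_annotation(seed + 4L, n_terms = 30L, prefix = "ko")
  libs <- make_libraries(seed + 5L, known, ref$hairpins, ncrna, depth = depth,
                         format = format,
                         out_dir = file.path(out_dir, "libs"))

  paths <- list()
  paths$genome <- file.path(out_dir, "genome.fa")
  write_fasta(ref$genome, paths$genome)
  paths$known_fa <- file.path(out_dir, "known_precursors.fa")
  write_fasta(stats::setNames(known$precursor, known$mirna_id), paths$known_fa)
  paths$known_coords <- file.path(out_dir, "known_coords.tsv")
  utils::write.table(known[, c("mirna_id", "mature_start", "mature_end")],
                     paths$known_coords, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dir.create(file.path(out_dir, "ncrna"), showWarnings = FALSE)
  paths$ncrna <- vapply(names(ncrna), function(cat) {
    p <- file.path(out_dir, "ncrna", paste0(cat, ".fa"))
    write_fasta(ncrna[[cat]], p)
    p
  }, "")
  paths$go_map <- file.path(out_dir, "go_map.tsv")
  utils::write.table(go$map, paths$go_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$kegg_map <- file.path(out_dir, "kegg_map.tsv")
  utils::write.table(kegg$map, paths$kegg_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths$tags <- file.path(out_dir, "tag_counts.tsv")
  write_tag_counts(libs$tags, paths$tags)
  truth <- list(seed = seed, depth = depth,
                hairpins = ref$hairpins,
                known_ids = known$mirna_id,
                lfc_f = as.list(libs$lfc_f), lfc_r = as.list(libs$lfc_r),
                clean_reads = as.list(libs$clean_reads),
                artifacts = as.list(libs$artifacts),
                planted_go_term = go$planted_term,
                planted_kegg_term = kegg$planted_term)
  paths$truth <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(list(reference = ref, known = known, ncrna = ncrna, go = go,
                 kegg = kegg, libraries = libs, paths = paths))
}
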