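#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and mapped onto a single canonical alphabet so
#' that downstream exact matching never has to deal with mixed U/T content.
#' The package stores sequences as DNA internally and converts to RNA only at
#' the folding boundary.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"` (default) rewrites U to T; `"RNA"` rewrites T to U.
#' @return Named character vector of sequences (names are record ids). An
#'   empty file returns an empty vector with a warning.
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("FASTA file '", path, "' contains no records")
    return(stats::setNames(character(0), character(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id in '", path, "': ", dup[[1L]])
  }
  seqs <- normalize_alphabet(as.character(set), alphabet)
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad)) {
    stop("sequence '", ids[which(bad)[1L]], "' contains characters outside ACGTUN")
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyNA(seqs))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Map sequences onto one alphabet (uppercase; U<->T).
normalize_alphabet <- function(seqs, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  seqs <- toupper(seqs)
  if (alphabet == "DNA") chartr("U", "T", seqs) else chartr("T", "U", seqs)
}

#' Read a FASTQ file (4-line records, Sanger qualities)
#'
#' @param path Path to a FASTQ file.
#' @param alphabet Alphabet policy as in [read_fasta()].
#' @return A data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record at line ", (n %/% 4L) * 4L + 1L, " of '", path, "'")
  }
  if (n == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE))
  }
  heads <- lines[seq(1L, n, by = 4L)]
  seqs  <- lines[seq(2L, n, by = 4L)]
  plus  <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad_head <- which(!startsWith(heads, "@"))
  if (length(bad_head) > 0L) {
    stop("malformed FASTQ header at line ", (bad_head[[1L]] - 1L) * 4L + 1L)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0L) {
    stop("malformed FASTQ separator at line ", (bad_plus[[1L]] - 1L) * 4L + 3L)
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len) > 0L) {
    stop("sequence/quality length mismatch at line ",
         (bad_len[[1L]] - 1L) * 4L + 2L)
  }
  data.frame(
    id = sub("\\s.*$", "", substring(heads, 2L)),
    sequence = normalize_alphabet(seqs, alphabet),
    quality = quals,
    stringsAsFactors = FALSE
  )
}

#' Write a FASTQ file
#'
#' @param reads data.frame with columns `id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)),
            all(nchar(reads$sequence) == nchar(reads$quality)))
  out <- character(4L * nrow(reads))
  out[seq(1L, length(out), by = 4L)] <- paste0("@", reads$id)
  out[seq(2L, length(out), by = 4L)] <- reads$sequence
  out[seq(3L, length(out), by = 4L)] <- "+"
  out[seq(4L, length(out), by = 4L)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

#' Read a tag-count table
#'
#' A tag-count table is the pipeline's central currency: one row per unique
#' cleaned small-RNA sequence, one integer count column per library.
#'
#' @param path TSV with a `sequence` column followed by library columns.
#' @return data.frame with `sequence` plus one integer column per library.
#' @export
read_tag_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot("sequence" %in% names(df))
  for (col in setdiff(names(df), "sequence")) df[[col]] <- as.integer(df[[col]])
  df
}

#' Write a tag-count table
#' @param tags data.frame as returned by [read_tag_counts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_counts <- function(tags, path) {
  utils::write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-term annotation map (GO or KEGG)
#'
#' Input is a TSV of `gene_id <tab> term_id [<tab> term_name]`. The background
#' size N used by the enrichment test is the number of distinct annotated
#' genes.
#'
#' @param path Path to the TSV (no header).
#' @return An object of class `annotation_map`: a list with `genes` (named
#'   list of term-id character vectors), `term_names` (named character
#'   vector), and `background_size`.
#' @export
read_annotation_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2L)
  if (length(bad) > 0L) {
    stop("malformed annotation line ", bad[[1L]], " in '", path,
         "': expected gene_id<TAB>term_id")
  }
  gene <- vapply(parts, `[[`, "", 1L)
  term <- vapply(parts, `[[`, "", 2L)
  name <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, "")
  annotation_map(gene, term, name)
}

#' Construct an annotation map from parallel vectors
#'
#' @param gene,term Character vectors (one entry per gene-term pair).
#' @param term_name Optional term labels parallel to `term`.
#' @return An `annotation_map` object; see [read_annotation_map()].
#' @export
annotation_map <- function(gene, term, term_name = NULL) {
  stopifnot(length(gene) == length(term))
  genes <- lapply(split(term, gene), unique)
  nm <- character(0)
  if (!is.null(term_name)) {
    keep <- !is.na(term_name) & !duplicated(term)
    nm <- stats::setNames(term_name[keep], term[keep])
    nm <- nm[!is.na(nm)]
  }
  structure(
    list(genes = genes, term_names = nm, background_size = length(genes)),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("annotation_map:", x$background_size, "genes,",
      length(unique(unlist(x$genes, use.names = FALSE))), "terms\n")
  invisible(x)
}

#' Assemble a known-miRNA reference (miRBase-style)
#'
#' Each record carries a precursor sequence and the 1-based inclusive
#' coordinates of the mature miRNA on that precursor. Validation enforces that
#' the stated mature sequence is the precursor substring at those coordinates
#' and that mature length is within 18-30 nt.
#'
#' @param mirna_id Character vector of ids.
#' @param precursor Character vector of precursor sequences (DNA alphabet).
#' @param mature_start,mature_end Integer vectors, 1-based inclusive.
#' @return data.frame with columns `mirna_id`, `precursor`, `mature_start`,
#'   `mature_end`, `mature`.
#' @export
mirna_reference <- function(mirna_id, precursor, mature_start, mature_end) {
  precursor <- normalize_alphabet(precursor, "DNA")
  stopifnot(length(mirna_id) == length(precursor),
            !anyDuplicated(mirna_id))
  mature_start <- as.integer(mature_start)
  mature_end <- as.integer(mature_end)
  ok <- mature_start >= 1L & mature_end <= nchar(precursor) &
    mature_end >= mature_start
  if (!all(ok)) {
    stop("mature coordinates outside precursor for: ",
         paste(mirna_id[!ok], collapse = ", "))
  }
  mature <- substr(precursor, mature_start, mature_end)
  len_ok <- nchar(mature) >= 18L & nchar(mature) <= 30L
  if (!all(len_ok)) {
    stop("mature length outside 18-30 nt for: ",
         paste(mirna_id[!len_ok], collapse = ", "))
  }
  data.frame(mirna_id = mirna_id, precursor = precursor,
             mature_start = mature_start, mature_end = mature_end,
             mature = mature, stringsAsFactors = FALSE)
}

#' Read a known-miRNA reference from precursor FASTA plus coordinates TSV
#'
#' @param precursor_fasta FASTA of precursors (ids are miRNA ids).
#' @param coords_tsv TSV with header `mirna_id, mature_start, mature_end`.
#' @return data.frame as from [mirna_reference()].
#' @export
read_mirna_reference <- function(precursor_fasta, coords_tsv) {
  prec <- read_fasta(precursor_fasta, "DNA")
  coords <- utils::read.delim(coords_tsv, stringsAsFactors = FALSE)
  missing <- setdiff(coords$mirna_id, names(prec))
  if (length(missing) > 0L) {
    stop("coordinates reference unknown precursor id: ", missing[[1L]])
  }
  mirna_reference(coords$mirna_id, unname(prec[coords$mirna_id]),
                  coords$mature_start, coords$mature_end)
}

#' Reverse complement of DNA sequences
#' @param seqs Character vector (DNA alphabet).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}
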