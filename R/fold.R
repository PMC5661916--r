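#' RNA secondary structure prediction (pluggable engine)
#'
#' The pipeline treats folding as a contract: a function taking RNA sequences
#' and returning their minimum-free-energy dot-bracket structures and MFE in
#' kcal/mol. The default engine shells out to the ViennaRNA `RNAfold`
#' executable; tests that only exercise threshold logic inject stub engines
#' so they are independent of engine version.
#'
#' @param sequences Character vector of sequences (DNA or RNA alphabet; DNA
#'   is converted to RNA at this boundary).
#' @param engine A folding engine function, e.g. [rnafold_engine()].
#' @return data.frame with `sequence` (as supplied), `structure`
#'   (dot-bracket) and `mfe` (kcal/mol, <= 0).
#' @export
fold <- function(sequences, engine = rnafold_engine()) {
  if (length(sequences) == 0L) {
    return(data.frame(sequence = character(0), structure = character(0),
                      mfe = numeric(0), stringsAsFactors = FALSE))
  }
  rna <- normalize_alphabet(sequences, "RNA")
  res <- engine(rna)
  stopifnot(is.data.frame(res), nrow(res) == length(sequences),
            all(c("structure", "mfe") %in% names(res)))
  bad <- which(nchar(res$structure) != nchar(sequences))
  if (length(bad) > 0L) stop("engine returned structure of wrong length for record ", bad[[1L]])
  # balanced dot-bracket check
  for (i in seq_along(res$structure)) pair_table(res$structure[[i]])
  data.frame(sequence = sequences, structure = res$structure, mfe = res$mfe,
             stringsAsFactors = FALSE)
}

#' Default folding engine backed by the RNAfold executable
#'
#' @param path Path to the RNAfold binary (found on `PATH` by default).
#' @return A function(sequences) -> data.frame(structure, mfe).
#' @export
rnafold_engine <- function(path = Sys.which("RNAfold")) {
  if (!nzchar(path)) {
    stop("folding engine unavailable: RNAfold not found on PATH; install ",
         "ViennaRNA or pass a custom engine function to fold()")
  }
  force(path)
  function(sequences) {
    input <- paste0(">s", seq_along(sequences), "\n", sequences, collapse = "\n")
    out <- system2(path, c("--noPS"), input = input, stdout = TRUE, stderr = FALSE)
    # records: >id / sequence / structure ( mfe )
    struct_lines <- out[seq(3L, length(out), by = 3L)]
    m <- regmatches(struct_lines,
                    regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", struct_lines))
    bad <- which(lengths(m) != 3L)
    if (length(bad) > 0L) stop("unparseable RNAfold output: ", struct_lines[bad[[1L]]])
    data.frame(structure = vapply(m, `[[`, "", 2L),
               mfe = as.numeric(vapply(m, `[[`, "", 3L)),
               stringsAsFactors = FALSE)
  }
}

#' Pairing partners of a dot-bracket structure
#'
#' @param structure A dot-bracket string.
#' @return Integer vector the length of the structure; `pt[i]` is the
#'   1-based partner of position i, or NA when unpaired. Errors on
#'   unbalanced brackets.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c(".", "(", ")"))
  if (length(bad) > 0L) stop("invalid dot-bracket character at position ", bad[[1L]])
  pt <- rep(NA_integer_, length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket: unmatched ')' at ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket: unmatched '(' at ", stack[1L])
  pt
}
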