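#' Default category precedence for small-RNA annotation
#'
#' When a tag matches references from several categories it is assigned to
#' the first matching category in this order, mirroring the
#' remove-before-miRNA-matching convention of small-RNA annotation.
#' @return Character vector of category names, highest precedence first.
#' @export
category_precedence <- function() {
  c("rRNA", "scRNA", "snoRNA", "snRNA", "srpRNA", "tRNA", "repeat")
}

#' Annotate tags against non-coding RNA and repeat references
#'
#' A tag hits a category when it is an exact substring (both strands) of any
#' reference sequence in that category's set. Tags hitting several categories
#' are assigned by the precedence order; tags hitting none are left
#' unassigned (category `unann`) for downstream miRNA identification.
#'
#' @param tags Character vector of tag sequences, or a tag-count data.frame.
#' @param reference_sets Named list of named character vectors, keyed by
#'   category (e.g. `rRNA`, `tRNA`, ...).
#' @param precedence Category order; defaults to [category_precedence()]
#'   restricted to the configured sets.
#' @return data.frame with `sequence`, `category` (`unann` when unmatched)
#'   and `evidence` (id of the first reference hit, NA for `unann`).
#' @export
match_ncrna <- function(tags, reference_sets,
                        precedence = category_precedence()) {
  if (is.data.frame(tags)) tags <- tags$sequence
  cats <- precedence[precedence %in% names(reference_sets)]
  extra <- setdiff(names(reference_sets), precedence)
  cats <- c(cats, extra)
  assignment <- rep("unann", length(tags))
  evidence <- rep(NA_character_, length(tags))
  for (cat in cats) {
    refs <- reference_sets[[cat]]
    if (length(refs) == 0L) {
      warning("empty reference set for category '", cat, "'; skipped")
      next
    }
    open <- assignment == "unann"
    if (!any(open)) break
    hits <- exact_matches(tags[open], refs, both_strands = TRUE)
    if (nrow(hits) == 0L) next
    first <- hits[!duplicated(hits$tag), , drop = FALSE]
    hit_ref <- stats::setNames(first$ref_id, first$tag)
    sel <- open & tags %in% first$tag
    assignment[sel] <- cat
    evidence[sel] <- unname(hit_ref[tags[sel]])
  }
  data.frame(sequence = tags, category = assignment, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Per-library category summary table
#'
#' Builds the category-by-library summary of unique tag counts and total read
#' counts with percentages. Unique percentages are taken against the number
#' of distinct clean tags in the library; total percentages against its clean
#' read count. Tags identified as known or novel miRNAs are promoted from
#' `unann` to `miRNA`.
#'
#' @param assignments data.frame from [match_ncrna()].
#' @param tags Tag-count data.frame (same sequences).
#' @param mirna_tags Optional character vector of tag sequences identified as
#'   miRNAs; these override an `unann` assignment.
#' @param categories Row order; defaults to miRNA, the ncRNA categories, and
#'   `unann`.
#' @return data.frame with `category` and, per library, `<lib>_unique`,
#'   `<lib>_unique_pct`, `<lib>_total`, `<lib>_total_pct`.
#' @export
category_table <- function(assignments, tags, mirna_tags = character(0),
                           categories = NULL) {
  stopifnot(identical(sort(assignments$sequence), sort(tags$sequence)))
  cat_of <- assignments$category[match(tags$sequence, assignments$sequence)]
  cat_of[tags$sequence %in% mirna_tags & cat_of == "unann"] <- "miRNA"
  if (is.null(categories)) {
    categories <- unique(c("miRNA", category_precedence(), "unann"))
  }
  cat_of <- factor(cat_of, levels = categories)
  libs <- setdiff(names(tags), "sequence")
  out <- data.frame(category = categories, stringsAsFactors = FALSE)
  for (lib in libs) {
    present <- tags[[lib]] > 0L
    uniq <- tapply(present, cat_of, sum, default = 0L)
    tot <- tapply(tags[[lib]] * present, cat_of, sum, default = 0L)
    clean <- sum(tags[[lib]])
    n_uniq <- sum(present)
    out[[paste0(lib, "_unique")]] <- as.integer(uniq)
    out[[paste0(lib, "_unique_pct")]] <- round(100 * uniq / max(n_uniq, 1L), 2)
    out[[paste0(lib, "_total")]] <- as.integer(tot)
    out[[paste0(lib, "_total_pct")]] <- round(100 * tot / max(clean, 1L), 2)
  }
  rownames(out) <- NULL
  out
}
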