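# Worked-example tables from a published sugarcane cold-response small-RNA
# study, shipped as fixtures: per-miRNA standardized (RPM) expression in the
# four libraries F0/F3/R0/R3 with the printed fold-change columns, and the
# per-library category/read accounting. The table-reproduction mode
# re-derives the printed derived columns from the printed inputs and flags
# the handful of rows whose printed values are internally inconsistent.

#' Printed differential-expression tables (worked example)
#'
#' @param which `"known"` or `"novel"`.
#' @return data.frame with `mirna_id`, `sequence`, the four `_std` columns,
#'   printed fold changes `fc_f`, `fc_r` and significance marks `sig_f`,
#'   `sig_r` (`"**"`, `"*"` or empty; NA std means not expressed/absent).
#' @export
printed_de_table <- function(which = c("known", "novel")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_de_table.tsv"),
                      package = "coldsmRNA", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c(sig_f = "character",
                                         sig_r = "character"))
  df$sig_f[is.na(df$sig_f)] <- ""
  df$sig_r[is.na(df$sig_r)] <- ""
  df
}

#' Printed per-library category accounting (worked example)
#'
#' @return data.frame with one row per small-RNA category plus `clean_reads`
#'   and `raw_reads` rows; unique and total counts per library.
#' @export
printed_category_table <- function() {
  path <- system.file("extdata", "category_counts.tsv",
                      package = "coldsmRNA", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Recompute fold-change columns from printed standardized expression
#'
#' Re-derives every printed log2 fold change from the printed 2-decimal RPM
#' values using the 0.01 floor, and flags rows where the recomputed value
#' disagrees with the printed one at 2 decimals. Known printed anomalies are
#' flagged, not "fixed".
#'
#' @param table A data.frame in the layout of [printed_de_table()], which is
#'   used when `table` is a `"known"`/`"novel"` keyword.
#' @param floor Ratio floor (default 0.01).
#' @return The table with added `fc_f_recomputed`, `fc_r_recomputed`,
#'   `match_f`, `match_r` (NA where the printed column is NA); attribute
#'   `mismatches` lists the flagged ids.
#' @export
reproduce_tables <- function(table = "known", floor = 0.01) {
  if (is.character(table) && length(table) == 1L) {
    table <- printed_de_table(table)
  }
  need <- c("F0_std", "F3_std", "R0_std", "R3_std", "fc_f", "fc_r")
  if (!all(need %in% names(table))) {
    stop("malformed table: expected columns ", paste(need, collapse = ", "))
  }
  rc_f <- ifelse(is.na(table$F0_std) | is.na(table$F3_std), NA,
                 fold_change(table$F3_std, table$F0_std, floor = floor))
  rc_r <- ifelse(is.na(table$R0_std) | is.na(table$R3_std), NA,
                 fold_change(table$R3_std, table$R0_std, floor = floor))
  table$fc_f_recomputed <- rc_f
  table$fc_r_recomputed <- rc_r
  table$match_f <- ifelse(is.na(table$fc_f) | is.na(rc_f), NA,
                          abs(table$fc_f - rc_f) < 0.005)
  table$match_r <- ifelse(is.na(table$fc_r) | is.na(rc_r), NA,
                          abs(table$fc_r - rc_r) < 0.005)
  mism <- table$mirna_id[(!is.na(table$match_f) & !table$match_f) |
                           (!is.na(table$match_r) & !table$match_r)]
  attr(table, "mismatches") <- mism
  table
}

#' Differential-expression counts from printed fold-change columns
#'
#' Applies the |log2fc| >= 1 filter together with the printed significance
#' marks to one printed table and reports the per-comparison counts and the
#' up/down partition, plus the ids shared (and co-directional) between the
#' two cultivar comparisons.
#'
#' @param table `"known"`, `"novel"`, or a data.frame in that layout.
#' @param lfc_threshold Absolute fold-change threshold (default 1).
#' @return list with `f` and `r` (each `c(n, up, down)`), `common_up` and
#'   `common_down` (shared significant ids by direction).
#' @export
printed_de_counts <- function(table = "known", lfc_threshold = 1) {
  if (is.character(table) && length(table) == 1L) {
    table <- printed_de_table(table)
  }
  pick <- function(fc, sig) {
    ok <- !is.na(fc) & abs(fc) >= lfc_threshold & sig %in% c("*", "**")
    list(n = sum(ok), up = sum(ok & fc > 0), down = sum(ok & fc < 0),
         up_ids = table$mirna_id[ok & fc > 0],
         down_ids = table$mirna_id[ok & fc < 0])
  }
  f <- pick(table$fc_f, table$sig_f)
  r <- pick(table$fc_r, table$sig_r)
  list(f = c(n = f$n, up = f$up, down = f$down),
       r = c(n = r$n, up = r$up, down = r$down),
       common_up = intersect(f$up_ids, r$up_ids),
       common_down = intersect(f$down_ids, r$down_ids))
}

#' Category-table arithmetic from printed counts
#'
#' Recomputes, for one library, the per-category percentage of clean reads
#' and the raw-to-clean removal fraction from the printed counts.
#'
#' @param lib Library id (`"F0"`, `"F3"`, `"R0"`, `"R3"`).
#' @param table Printed category table (default the shipped fixture).
#' @return list with `category_pct` (named vector, percent of clean reads
#'   per category) and `removed_pct` (percent of raw reads removed by
#'   cleaning).
#' @export
printed_category_arithmetic <- function(lib = "F0",
                                        table = printed_category_table()) {
  tot_col <- paste0(lib, "_total")
  cats <- setdiff(table$category, c("clean_reads", "raw_reads"))
  clean <- table[[tot_col]][table$category == "clean_reads"]
  raw <- table[[tot_col]][table$category == "raw_reads"]
  pct <- round(100 * table[[tot_col]][match(cats, table$category)] / clean, 2)
  list(category_pct = stats::setNames(pct, cats),
       removed_pct = round(100 * (raw - clean) / raw, 2))
}
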