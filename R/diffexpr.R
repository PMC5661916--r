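#' Reads-per-million normalization
#'
#' Normalized expression = raw count / total clean reads x 1,000,000. For
#' reporting and for every ratio, values are floored at `floor` (default
#' 0.01) so that a miRNA absent from one library yields a finite fold
#' change; published tables print exactly this floor for absent miRNAs.
#'
#' @param counts Numeric vector of raw counts.
#' @param clean_reads Library clean-read total (> 0).
#' @param floor Reporting/ratio floor (default 0.01).
#' @param digits Decimals for the reported value (default 2).
#' @return Numeric vector of floored, rounded RPM values.
#' @export
normalize_rpm <- function(counts, clean_reads, floor = 0.01, digits = 2) {
  if (length(clean_reads) != 1L || is.na(clean_reads) || clean_reads <= 0) {
    stop("clean_reads must be a single positive count")
  }
  stopifnot(all(counts >= 0))
  pmax(round(counts / clean_reads * 1e6, digits), floor)
}

#' Log2 fold change of normalized expression
#'
#' Fold change = log2(treatment / control), with both inputs floored at
#' `floor` so zero expression never produces an infinite ratio.
#'
#' @param treatment,control Normalized (RPM) expression values.
#' @param floor Ratio floor (default 0.01).
#' @param digits Decimals for the reported value (default 2).
#' @return Numeric vector of log2 fold changes.
#' @export
fold_change <- function(treatment, control, floor = 0.01, digits = 2) {
  round(log2(pmax(treatment, floor) / pmax(control, floor)), digits)
}

#' Replicate-free significance test for two count libraries
#'
#' Two-sided test for a difference in relative abundance of one tag between
#' two libraries without replicates, following the Audic-Claverie approach:
#' conditional on the count x in the first library, the count y in the second
#' is distributed as p(y|x) = (n2/n1)^y (x+y)! / (x! y! (1+n2/n1)^(x+y+1)),
#' which is the negative binomial with size x+1 and success probability
#' n1/(n1+n2). The two-sided p-value is twice the smaller tail mass at y,
#' capped at 1. Both counts zero returns p = 1 by convention.
#'
#' @param x,y Raw counts in the control and treatment libraries.
#' @param n1,n2 Clean-read totals of the two libraries.
#' @return Two-sided p-value in (0, 1]. Vectorized over `x`, `y`.
#' @export
ac_test <- function(x, y, n1, n2) {
  stopifnot(all(x >= 0), all(y >= 0), n1 > 0, n2 > 0)
  k <- max(length(x), length(y))
  x <- rep_len(x, k); y <- rep_len(y, k)
  prob <- n1 / (n1 + n2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = prob, lower.tail = FALSE)
  p <- pmin(1, 2 * pmin(lower, upper))
  p[x == 0 & y == 0] <- 1
  p
}

#' Build differential-expression records for one comparison
#'
#' Combines RPM normalization, the 0.01-floored log2 fold change and the
#' replicate-free count test into per-miRNA records for a
#' treatment-vs-control library pair.
#'
#' @param expr data.frame with `mirna_id` and raw count columns.
#' @param treatment,control Column names of the treatment and control
#'   libraries.
#' @param clean_reads Named numeric vector of clean-read totals (names
#'   include both libraries).
#' @param config [default_config()] list (floor and thresholds).
#' @return data.frame `mirna_id`, `<control>_std`, `<treatment>_std`
#'   (floored RPM), `log2fc`, `p_value`, `significant` (`"**"`, `"*"` or
#'   `"ns"`), `direction` (`"up"`, `"down"`, `"none"`).
#' @export
diff_expression <- function(expr, treatment, control, clean_reads,
                            config = default_config()) {
  stopifnot(all(c(treatment, control) %in% names(expr)),
            all(c(treatment, control) %in% names(clean_reads)))
  std_t <- normalize_rpm(expr[[treatment]], clean_reads[[treatment]],
                         floor = config$rpm_floor)
  std_c <- normalize_rpm(expr[[control]], clean_reads[[control]],
                         floor = config$rpm_floor)
  lfc <- fold_change(std_t, std_c, floor = config$rpm_floor)
  p <- ac_test(expr[[control]], expr[[treatment]],
               clean_reads[[control]], clean_reads[[treatment]])
  out <- data.frame(mirna_id = expr$mirna_id, stringsAsFactors = FALSE)
  out[[paste0(control, "_std")]] <- std_c
  out[[paste0(treatment, "_std")]] <- std_t
  out$log2fc <- lfc
  out$p_value <- p
  de_filter(out, lfc_threshold = config$lfc_threshold,
            p_threshold = config$p_threshold)
}

#' Apply the differential-expression filter
#'
#' A record is significant when |log2fc| >= `lfc_threshold` and p-value <=
#' `p_threshold`; significant records are marked `"**"` (p < 0.01) or `"*"`,
#' others `"ns"`. The up/down partition is reported in the `summary`
#' attribute.
#'
#' @param records data.frame with `log2fc` and `p_value` columns.
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1,
#'   inclusive).
#' @param p_threshold p-value threshold (default 0.05, inclusive).
#' @return `records` with added `significant` and `direction` columns and a
#'   `summary` attribute `c(n, up, down)`.
#' @export
de_filter <- function(records, lfc_threshold = 1, p_threshold = 0.05) {
  sig <- !is.na(records$log2fc) & abs(records$log2fc) >= lfc_threshold &
    records$p_value <= p_threshold
  records$significant <- ifelse(sig,
                                ifelse(records$p_value < 0.01, "**", "*"),
                                "ns")
  records$direction <- ifelse(!sig, "none",
                              ifelse(records$log2fc > 0, "up", "down"))
  attr(records, "summary") <- c(n = sum(sig),
                                up = sum(sig & records$log2fc > 0),
                                down = sum(sig & records$log2fc < 0))
  records
}
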