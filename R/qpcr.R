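#' Relative expression by the comparative Ct method
#'
#' Computes 2^-ddCt relative quantification from a table of technical
#' replicate Ct values for a target gene and a reference gene: per sample,
#' dCt = mean(Ct_target) - mean(Ct_reference); ddCt = dCt_sample -
#' dCt_calibrator; relative expression = 2^-ddCt (so the calibrator is 1 by
#' construction). Amplification efficiency is fixed at 2, the method's
#' assumption. The per-sample standard error is propagated from the
#' replicate standard deviations: SE(dCt) = sqrt(sd_t^2/n_t + sd_r^2/n_r),
#' SE(ddCt) adds the calibrator's dCt uncertainty in quadrature, and
#' SE(expr) = ln(2) * expr * SE(ddCt). The calibrator row reports SE 0 since
#' its relative expression is 1 by construction.
#'
#' @param ct data.frame with columns `sample`, `role` (`"target"` or
#'   `"reference"`) and `ct` (one row per replicate well), Ct in (0, 45).
#' @param calibrator Sample id used as the calibrator.
#' @return data.frame `sample`, `dct`, `ddct`, `expression`, `se`.
#' @export
ddct <- function(ct, calibrator) {
  stopifnot(all(c("sample", "role", "ct") %in% names(ct)),
            all(ct$role %in% c("target", "reference")),
            all(ct$ct > 0 & ct$ct < 45))
  samples <- unique(ct$sample)
  if (!calibrator %in% samples) stop("calibrator sample '", calibrator, "' not present")
  per <- lapply(samples, function(s) {
    tgt <- ct$ct[ct$sample == s & ct$role == "target"]
    ref <- ct$ct[ct$sample == s & ct$role == "reference"]
    if (length(ref) == 0L) stop("missing reference wells for sample '", s, "'")
    if (length(tgt) == 0L) stop("missing target wells for sample '", s, "'")
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    list(dct = mean(tgt) - mean(ref),
         se = sqrt(sd0(tgt)^2 / length(tgt) + sd0(ref)^2 / length(ref)))
  })
  names(per) <- samples
  dct <- vapply(per, `[[`, 0, "dct")
  se_dct <- vapply(per, `[[`, 0, "se")
  dd <- dct - dct[[calibrator]]
  expr <- 2^(-dd)
  se_dd <- sqrt(se_dct^2 + se_dct[[calibrator]]^2)
  se_dd[samples == calibrator] <- 0
  data.frame(sample = samples, dct = unname(dct), ddct = unname(dd),
             expression = unname(expr),
             se = unname(log(2) * expr * se_dd),
             stringsAsFactors = FALSE)
}
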