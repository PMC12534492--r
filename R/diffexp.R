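#' @importFrom stats pt p.adjust
NULL

#' Resolve a two-group contrast against the sample design
#'
#' Selectors are `(cell_type, treatment)` pairs; `NA` in either slot means
#' "any". The fold-change convention downstream is group B minus group A.
#'
#' @param design sample design `data.frame`.
#' @param group_A,group_B character vectors like
#'   `c(cell_type = "beta", treatment = "control")`.
#' @return list with sample id vectors `A`, `B` and a `label` string.
#' @export
resolveContrast <- function(design, group_A, group_B) {
  pick <- function(sel) .selectSamples(
    design,
    cell_type = if ("cell_type" %in% names(sel)) sel[["cell_type"]] else NA,
    treatment = if ("treatment" %in% names(sel)) sel[["treatment"]] else NA)
  A <- pick(group_A); B <- pick(group_B)
  if (length(intersect(A, B)))
    stop("contrast groups overlap: ", paste(intersect(A, B), collapse = ", "))
  if (length(A) < 2L || length(B) < 2L)
    stop("each contrast group needs >= 2 samples (got ", length(A), " and ",
         length(B), ")")
  lab <- function(sel) paste(sel[!is.na(sel)], collapse = ".")
  list(A = A, B = B, label = paste0(lab(group_B), "-vs-", lab(group_A)))
}

#' Two-group differential expression on log2 intensities
#'
#' Per feature with at least `min_valid` observed values in each group:
#' the log2 fold change is mean(B) - mean(A) of the log2 intensities, the
#' p-value comes from Welch's unequal-variance t-test, and
#' Benjamini-Hochberg adjustment is applied across all tested features of
#' the contrast. Features failing the validity filter are reported with
#' missing statistics and excluded from the adjustment. A degenerate zero
#' test statistic (identical group means) yields p = 1 so that exact
#' equality never appears significant.
#'
#' @param x a log2-scale [IntensityExperiment-class] with a sample design.
#' @param contrast a contrast from [resolveContrast()], or a list with
#'   sample-id vectors `A` and `B`.
#' @param min_valid minimum observed values per group (default 2).
#' @return `data.frame` with columns `feature_id`, `log2fc`, `t`, `p_raw`,
#'   `p_adj`, `n_A`, `n_B`, `tested`; the contrast label is attached as
#'   attribute `"contrast"`.
#' @export
differentialExpression <- function(x, contrast, min_valid = 2L) {
  stopifnot(is(x, "IntensityExperiment"))
  if (intensityScale(x) != "log2")
    stop("differential expression expects a log2-scaled matrix; ",
         "use log2Transform() first")
  A <- contrast$A; B <- contrast$B
  bad <- setdiff(c(A, B), colnames(x))
  if (length(bad)) stop("unknown samples: ", paste(bad, collapse = ", "))
  if (length(intersect(A, B))) stop("contrast groups overlap")
  va <- assay(x, "intensity")[, A, drop = FALSE]
  vb <- assay(x, "intensity")[, B, drop = FALSE]
  nA <- rowSums(!is.na(va)); nB <- rowSums(!is.na(vb))
  mA <- rowMeans(va, na.rm = TRUE); mB <- rowMeans(vb, na.rm = TRUE)
  sA2 <- apply(va, 1, stats::var, na.rm = TRUE)
  sB2 <- apply(vb, 1, stats::var, na.rm = TRUE)
  tested <- nA >= min_valid & nB >= min_valid

  log2fc <- ifelse(tested, mB - mA, NA_real_)
  se2 <- sA2 / nA + sB2 / nB
  tstat <- ifelse(tested & se2 > 0, (mB - mA) / sqrt(se2), NA_real_)
  df <- se2^2 / ((sA2 / nA)^2 / (nA - 1) + (sB2 / nB)^2 / (nB - 1))
  p <- 2 * pt(-abs(tstat), df)
  # zero variance in both groups: identical means -> p = 1, else minimal p
  degenerate <- tested & se2 == 0
  p[degenerate & log2fc == 0] <- 1
  p[degenerate & log2fc != 0] <- 1e-300
  tstat[degenerate] <- ifelse(log2fc[degenerate] == 0, 0, Inf)
  p[tested & !is.na(tstat) & tstat == 0] <- 1
  p <- pmax(p, 1e-300)
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  out <- data.frame(feature_id = rownames(x), log2fc = log2fc, t = tstat,
                    p_raw = p, p_adj = padj, n_A = as.integer(nA),
                    n_B = as.integer(nB), tested = tested,
                    row.names = NULL)
  attr(out, "contrast") <- contrast$label
  out
}

#' Volcano-style regulation calls
#'
#' `up` when adjusted p < `p_thresh` and log2 FC > `fc_thresh`; `down` when
#' adjusted p < `p_thresh` and log2 FC < -`fc_thresh`; otherwise `ns`
#' (including untested features). Defaults are the conventional
#' significance thresholds adj. p < 0.05 and |log2 FC| > 1.
#'
#' @param records output of [differentialExpression()] (or any table with
#'   `p_adj` and `log2fc`).
#' @param p_thresh,fc_thresh thresholds.
#' @return factor of labels `up`/`down`/`ns`, one per record.
#' @export
classifyRegulation <- function(records, p_thresh = 0.05, fc_thresh = 1.0) {
  sig <- !is.na(records$p_adj) & records$p_adj < p_thresh
  lab <- rep("ns", nrow(records))
  lab[sig & records$log2fc > fc_thresh] <- "up"
  lab[sig & records$log2fc < -fc_thresh] <- "down"
  factor(lab, levels = c("down", "ns", "up"))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Input validation plus the standard step-up procedure (as implemented by
#' [stats::p.adjust()]): adjusted values are monotone after sorting and
#' capped at 1.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as input.
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}
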