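#' @importFrom stats oneway.test kmeans
NULL

#' One-way ANOVA across all (cell type x treatment) groups
#'
#' Per feature, a one-way analysis of variance over every design group
#' (six groups for 3 cell types x 2 treatments), with Benjamini-Hochberg
#' adjustment across tested features and the fraction of features with
#' adjusted p below the threshold reported. Features with fewer than two
#' observed values in any group are excluded from testing and counted
#' (complete-observations policy).
#'
#' @param x a log2-scale [IntensityExperiment-class].
#' @param design sample design `data.frame`.
#' @param p_thresh significance threshold on adjusted p (default 0.05).
#' @return list with `table` (`data.frame`: `feature_id`, `F`, `p_raw`,
#'   `p_adj`, `significant`, `tested`), `fraction_significant` (among
#'   tested features) and `n_excluded`.
#' @export
anovaAcrossGroups <- function(x, design, p_thresh = 0.05) {
  stopifnot(is(x, "IntensityExperiment"))
  if (intensityScale(x) != "log2")
    stop("ANOVA expects a log2-scaled matrix")
  smp <- intersect(colnames(x), rownames(design))
  v <- assay(x, "intensity")[, smp, drop = FALSE]
  grp <- factor(.groupKey(design[smp, , drop = FALSE]))
  if (nlevels(grp) < 2L)
    stop("need >= 2 design groups for ANOVA")
  n_per_grp <- t(apply(!is.na(v), 1, function(ok) tapply(ok, grp, sum)))
  tested <- apply(n_per_grp >= 2L, 1, all)

  Fv <- rep(NA_real_, nrow(v)); p <- rep(NA_real_, nrow(v))
  for (i in which(tested)) {
    ok <- !is.na(v[i, ])
    ft <- oneway.test(v[i, ok] ~ grp[ok], var.equal = TRUE)
    Fv[i] <- unname(ft$statistic)
    p[i] <- ft$p.value
  }
  p[tested & !is.na(Fv) & Fv == 0] <- 1
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  tab <- data.frame(feature_id = rownames(v), F = Fv, p_raw = p,
                    p_adj = padj,
                    significant = !is.na(padj) & padj < p_thresh,
                    tested = tested, row.names = NULL)
  .msg("anovaAcrossGroups: ", sum(tab$significant), "/", sum(tested),
       " tested features significant at adj. p < ", p_thresh)
  list(table = tab,
       fraction_significant = mean(tab$significant[tested]),
       n_excluded = sum(!tested))
}

#' k-means clustering of significant features into response categories
#'
#' Features (typically the ANOVA-significant ones) are summarized as
#' per-group mean profiles of their z-scored log2 intensities (one value
#' per cell type x treatment group) and clustered with k-means into `k`
#' categories (default 6). 25 random restarts under a fixed seed keep the
#' result reproducible and near-deterministic.
#'
#' @param x a complete log2-scale [IntensityExperiment-class] restricted to
#'   the features to cluster.
#' @param design sample design `data.frame`.
#' @param k number of clusters (default 6); must not exceed the feature
#'   count.
#' @param seed integer seed.
#' @param nstart random restarts (default 25).
#' @return list with `assignment` (`data.frame`: `feature_id`, `cluster`),
#'   `centers` (k x groups matrix of cluster mean profiles), `profiles`
#'   (features x groups matrix clustered on), `withinss` (total
#'   within-cluster sum of squares).
#' @export
kmeansResponseClusters <- function(x, design, k = 6L, seed = 1L,
                                   nstart = 25L) {
  stopifnot(is(x, "IntensityExperiment"))
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of features (", nrow(x), ")")
  z <- zscoreFeatures(x)
  smp <- intersect(colnames(z), rownames(design))
  v <- assay(z, "intensity")[, smp, drop = FALSE]
  grp <- factor(.groupKey(design[smp, , drop = FALSE]),
                levels = unique(.groupKey(design[smp, , drop = FALSE])))
  prof <- t(apply(v, 1, function(row) tapply(row, grp, mean)))
  colnames(prof) <- levels(grp)
  km <- withr::with_seed(seed, kmeans(prof, centers = k, nstart = nstart,
                                      iter.max = 100L))
  list(assignment = data.frame(feature_id = rownames(prof),
                               cluster = unname(km$cluster),
                               row.names = NULL),
       centers = km$centers, profiles = prof,
       withinss = km$tot.withinss)
}

#' Pairwise enrichment tables across cell types and treatments
#'
#' Runs [differentialExpression()] and [classifyRegulation()] for every
#' cell-type pair within each treatment and for control-vs-treated within
#' each cell type, and summarizes which features respond to treatment in
#' all cell types (shared) versus exactly one (cell-type-specific).
#'
#' @param x a log2-scale [IntensityExperiment-class].
#' @param design sample design `data.frame`.
#' @param p_thresh,fc_thresh volcano thresholds passed to
#'   [classifyRegulation()].
#' @param min_valid minimum observed values per group.
#' @return list with `tables` (named list of DE tables, each with a
#'   `regulation` column), and `treatment_summary` (`data.frame` per
#'   feature: number of cell types where treatment-regulated, shared /
#'   specific flags).
#' @export
pairwiseEnrichmentTables <- function(x, design, p_thresh = 0.05,
                                     fc_thresh = 1.0, min_valid = 2L) {
  cts <- unique(design$cell_type)
  trs <- unique(design$treatment)
  tables <- list()
  run <- function(gA, gB) {
    de <- differentialExpression(x, resolveContrast(design, gA, gB),
                                 min_valid = min_valid)
    de$regulation <- classifyRegulation(de, p_thresh, fc_thresh)
    de
  }
  for (tr in trs) {
    if (length(cts) >= 2) {
      prs <- utils::combn(cts, 2)
      for (j in seq_len(ncol(prs))) {
        de <- run(c(cell_type = prs[1, j], treatment = tr),
                  c(cell_type = prs[2, j], treatment = tr))
        tables[[attr(de, "contrast")]] <- de
      }
    }
  }
  treat_tabs <- list()
  if (length(trs) == 2) {
    for (ct in cts) {
      de <- run(c(cell_type = ct, treatment = trs[1]),
                c(cell_type = ct, treatment = trs[2]))
      tables[[attr(de, "contrast")]] <- de
      treat_tabs[[ct]] <- de
    }
  }
  treatment_summary <- NULL
  if (length(treat_tabs)) {
    reg <- vapply(treat_tabs, function(de)
      de$regulation != "ns", logical(nrow(treat_tabs[[1]])))
    if (is.null(dim(reg))) reg <- matrix(reg, nrow = 1)
    n_reg <- rowSums(reg)
    treatment_summary <- data.frame(
      feature_id = treat_tabs[[1]]$feature_id,
      n_celltypes_regulated = n_reg,
      shared = n_reg == length(cts),
      specific = n_reg == 1L)
    for (ct in names(treat_tabs))
      treatment_summary[[paste0("regulated_", ct)]] <- reg[, ct]
  }
  list(tables = tables, treatment_summary = treatment_summary)
}
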