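#' @importFrom stats cor lm coef var complete.cases
NULL

#' Match proteome and transcriptome features through an identifier map
#'
#' Restricts both matrices to features linked by the mapping, keeping only
#' one-to-one pairs (genes mapping to several protein groups, or vice
#' versa, are dropped and logged, never guessed) and returning both objects
#' in identical row order.
#'
#' @param proteome,transcriptome [IntensityExperiment-class] objects.
#' @param map `data.frame` with columns `gene_id`, `protein_group`.
#' @return list with `proteome`, `transcriptome` (row-matched) and
#'   `n_matched`.
#' @export
matchFeatures <- function(proteome, transcriptome, map) {
  m <- map[map$gene_id %in% rownames(transcriptome) &
             map$protein_group %in% rownames(proteome), , drop = FALSE]
  g_multi <- unique(m$gene_id[duplicated(m$gene_id)])
  p_multi <- unique(m$protein_group[duplicated(m$protein_group)])
  if (length(g_multi) || length(p_multi))
    .msg("matchFeatures: dropping ", length(g_multi), " genes / ",
         length(p_multi), " protein groups with ambiguous mapping")
  m <- m[!(m$gene_id %in% g_multi) & !(m$protein_group %in% p_multi), ,
         drop = FALSE]
  if (!nrow(m))
    stop("no overlapping features between proteome and transcriptome")
  .msg("matchFeatures: ", nrow(m), " one-to-one matched features")
  list(proteome = proteome[m$protein_group, ],
       transcriptome = transcriptome[m$gene_id, ],
       n_matched = nrow(m))
}

#' Left-shifted Gaussian imputation of missing values
#'
#' For each feature with at least two observed values, missing cells are
#' drawn from \eqn{N(\bar{x} - d \cdot s,\; (w \cdot s)^2)} where
#' \eqn{\bar{x}} and \eqn{s} are that feature's observed mean and standard
#' deviation and, by default, the downshift is \eqn{d = 3} and the width
#' \eqn{w = 0.3}. This places imputed values in the left tail of the
#' feature's distribution, the standard model for abundance-dependent
#' non-detection. Only missing cells are altered; observed values pass
#' through bit-identically. Features with fewer than two observed values
#' cannot provide \eqn{\bar{x}, s} and are dropped with a warning.
#'
#' @param x a log2-scale [IntensityExperiment-class].
#' @param downshift mean shift in feature standard deviations (default 3).
#' @param width imputation-distribution sd as a fraction of the feature sd
#'   (default 0.3).
#' @param seed integer seed; imputation is deterministic under it.
#' @return a complete [IntensityExperiment-class].
#' @export
imputeGaussian <- function(x, downshift = 3, width = 0.3, seed = 1L) {
  stopifnot(is(x, "IntensityExperiment"))
  if (intensityScale(x) != "log2")
    stop("imputation expects a log2-scaled matrix")
  if (width <= 0 || downshift < 0)
    stop("width must be > 0 and downshift >= 0")
  v <- assay(x, "intensity")
  nobs <- rowSums(!is.na(v))
  if (any(nobs < 2L)) {
    warning(sum(nobs < 2L),
            " feature(s) with < 2 observed values dropped before imputation")
    x <- x[nobs >= 2L, ]
    v <- assay(x, "intensity")
  }
  miss <- is.na(v)
  if (!any(miss)) return(x)
  mu <- rowMeans(v, na.rm = TRUE)
  s <- apply(v, 1, sd, na.rm = TRUE)
  idx <- which(miss, arr.ind = TRUE)
  withr::with_seed(seed, {
    v[miss] <- rnorm(nrow(idx),
                     mean = mu[idx[, 1]] - downshift * s[idx[, 1]],
                     sd = width * s[idx[, 1]])
  })
  assay(x, "intensity") <- v
  x
}

#' Z-score each feature across samples
#'
#' Subtracts the feature mean and divides by the feature standard
#' deviation; requires a complete matrix (impute first) and positive
#' per-feature variance.
#'
#' @param x a complete [IntensityExperiment-class].
#' @return `x` with each feature row at mean 0, sd 1.
#' @export
zscoreFeatures <- function(x) {
  stopifnot(is(x, "IntensityExperiment"))
  v <- assay(x, "intensity")
  if (any(is.na(v)))
    stop("z-scoring requires a complete matrix; impute missing values first")
  s <- apply(v, 1, sd)
  if (any(s == 0))
    stop("zero-variance feature(s): ",
         paste(utils::head(rownames(v)[s == 0], 5), collapse = ", "))
  assay(x, "intensity") <- (v - rowMeans(v)) / s
  x
}

#' All-vs-all cross-omics replicate correlations
#'
#' Within each (cell type, treatment) group, every pairing of one proteomics
#' replicate with one transcriptomics replicate (e.g. 3 x 3 = 9 pairings
#' for triplicates) is compared over the matched features: Pearson r and a
#' simple linear regression (transcriptome on proteome) computed on log2
#' values, using features observed in both members of the pairing
#' (complete-pairs policy; no imputed values enter these correlations).
#'
#' @param matched output of [matchFeatures()], both members log2-scaled.
#' @param design shared sample design `data.frame`.
#' @return `data.frame` with one row per pairing: `cell_type`, `treatment`,
#'   `proteome_sample`, `transcriptome_sample`, `pearson_r`, `r_squared`,
#'   `slope`, `intercept`, `n_features`.
#' @export
crossOmicsCorrelations <- function(matched, design) {
  vp <- assay(matched$proteome, "intensity")
  vt <- assay(matched$transcriptome, "intensity")
  groups <- unique(design[, c("cell_type", "treatment")])
  out <- list()
  for (i in seq_len(nrow(groups))) {
    smp <- .selectSamples(design, groups$cell_type[i], groups$treatment[i])
    smp <- intersect(smp, intersect(colnames(vp), colnames(vt)))
    if (length(smp) < 1L) {
      warning("group ", groups$cell_type[i], "/", groups$treatment[i],
              " has no replicates on both sides; skipped")
      next
    }
    for (sp in smp) for (st in smp) {
      xy <- cbind(vp[, sp], vt[, st])
      ok <- complete.cases(xy)
      fit <- lm(xy[ok, 2] ~ xy[ok, 1])
      r <- cor(xy[ok, 1], xy[ok, 2])
      out[[length(out) + 1L]] <- data.frame(
        cell_type = groups$cell_type[i], treatment = groups$treatment[i],
        proteome_sample = sp, transcriptome_sample = st,
        pearson_r = r, r_squared = r^2,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        n_features = sum(ok))
    }
  }
  do.call(rbind, out)
}

#' Compare correlation distributions between two conditions
#'
#' Two-sided independent Student's t-test (equal variances) on the
#' per-pairing Pearson r values of two groups, e.g. control vs treated
#' pairings of one cell type. Identical constant groups return p = 1 by
#' convention.
#'
#' @param results table from [crossOmicsCorrelations()].
#' @param groupX,groupY selectors `c(cell_type = ..., treatment = ...)`
#'   (`NA` or omitted slot = any).
#' @return list with `t`, `p`, `mean_X`, `mean_Y`, `n_X`, `n_Y`.
#' @export
compareConditionCorrelations <- function(results, groupX, groupY) {
  pick <- function(sel) {
    keep <- rep(TRUE, nrow(results))
    if ("cell_type" %in% names(sel) && !is.na(sel[["cell_type"]]))
      keep <- keep & results$cell_type == sel[["cell_type"]]
    if ("treatment" %in% names(sel) && !is.na(sel[["treatment"]]))
      keep <- keep & results$treatment == sel[["treatment"]]
    results$pearson_r[keep]
  }
  rx <- pick(groupX); ry <- pick(groupY)
  if (length(rx) < 2L || length(ry) < 2L)
    stop("each group needs >= 2 correlation values")
  if (sd(rx) == 0 && sd(ry) == 0) {
    # degenerate: constant groups; equality -> no evidence of difference
    return(list(t = if (mean(rx) == mean(ry)) 0 else Inf,
                p = if (mean(rx) == mean(ry)) 1 else 0,
                mean_X = mean(rx), mean_Y = mean(ry),
                n_X = length(rx), n_Y = length(ry)))
  }
  tt <- stats::t.test(rx, ry, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_X = mean(rx), mean_Y = mean(ry),
       n_X = length(rx), n_Y = length(ry))
}

#' Within-group replicate reproducibility and CVs
#'
#' For each (cell type, treatment) group: all pairwise replicate
#' R-squared values on log2 intensities (complete pairs), and per-feature
#' coefficients of variation computed on LINEAR-scale values across the
#' group's replicates (sd/mean; CV on log scale is meaningless). Groups
#' with a single replicate yield missing values.
#'
#' @param x an [IntensityExperiment-class] (either scale; converted
#'   internally as needed).
#' @param design sample design `data.frame`.
#' @return list with `pairwise` (`data.frame`: group, sample pair, r2),
#'   `cv` (features x groups matrix of CVs), `mean_r2`, `mean_cv`.
#' @export
replicateReproducibility <- function(x, design) {
  v <- assay(x, "intensity")
  lin <- if (intensityScale(x) == "linear") v else 2^v
  lg <- if (intensityScale(x) == "log2") v else {
    tmp <- v; tmp[!is.na(tmp) & tmp == 0] <- NA_real_; log2(tmp)
  }
  groups <- unique(design[, c("cell_type", "treatment")])
  pw <- list(); cvs <- list()
  for (i in seq_len(nrow(groups))) {
    smp <- intersect(.selectSamples(design, groups$cell_type[i],
                                    groups$treatment[i]), colnames(v))
    key <- paste(groups$cell_type[i], groups$treatment[i], sep = ".")
    gl <- lin[, smp, drop = FALSE]
    if (length(smp) >= 2L) {
      cvs[[key]] <- apply(gl, 1, sd, na.rm = TRUE) /
        rowMeans(gl, na.rm = TRUE)
      prs <- utils::combn(smp, 2)
      for (j in seq_len(ncol(prs))) {
        a <- lg[, prs[1, j]]; b <- lg[, prs[2, j]]
        ok <- !is.na(a) & !is.na(b)
        pw[[length(pw) + 1L]] <- data.frame(
          cell_type = groups$cell_type[i], treatment = groups$treatment[i],
          sample_1 = prs[1, j], sample_2 = prs[2, j],
          r_squared = cor(a[ok], b[ok])^2, n_features = sum(ok))
      }
    } else {
      cvs[[key]] <- rep(NA_real_, nrow(v))
    }
  }
  pw <- if (length(pw)) do.call(rbind, pw) else NULL
  cv <- do.call(cbind, cvs)
  rownames(cv) <- rownames(v)
  list(pairwise = pw, cv = cv,
       mean_r2 = if (!is.null(pw)) mean(pw$r_squared) else NA_real_,
       mean_cv = mean(cv, na.rm = TRUE))
}

#' Sample-sample correlation matrix ordered by single-linkage clustering
#'
#' Applies the heatmap recipe: on an imputed, z-scored matrix, compute the
#' Pearson correlation between every pair of samples, then order samples by
#' single-linkage agglomerative clustering of the Euclidean distances
#' between sample profiles.
#'
#' @param x a complete, z-scored [IntensityExperiment-class] (apply
#'   [imputeGaussian()] then [zscoreFeatures()] first).
#' @return list with `r` (symmetric sample x sample Pearson matrix, unit
#'   diagonal), `order` (sample ids in dendrogram order), `hclust` (the
#'   [stats::hclust] tree).
#' @export
sampleCorrelationMap <- function(x) {
  v <- assay(x, "intensity")
  if (any(is.na(v)))
    stop("correlation map requires a complete matrix; impute first")
  r <- cor(v)
  diag(r) <- 1
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"),
                      method = "single")
  list(r = r, order = colnames(v)[hc$order], hclust = hc)
}
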