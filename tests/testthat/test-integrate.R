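test_that("feature matching keeps one-to-one pairs in shared order", {
  m <- matrix(1:20, 10, 2,
              dimnames = list(sprintf("P%02d", 1:10), c("s1", "s2")))
  prot <- IntensityExperiment(m)
  g <- m; rownames(g) <- sprintf("G%02d", 1:10)
  trans <- IntensityExperiment(g)
  map <- data.frame(gene_id = sprintf("G%02d", 1:10),
                    protein_group = sprintf("P%02d", 1:10))
  out <- matchFeatures(prot, trans, map)
  expect_identical(out$n_matched, 10L)
  expect_identical(rownames(out$proteome), sprintf("P%02d", 1:10))

  # ambiguous mappings are dropped, not guessed
  map2 <- rbind(map, data.frame(gene_id = "G01", protein_group = "P05"))
  out2 <- matchFeatures(prot, trans, map2)
  expect_false(any(c("P01", "P05") %in% rownames(out2$proteome)))
  expect_identical(out2$n_matched, 8L)

  bad <- data.frame(gene_id = "GX", protein_group = "PX")
  expect_error(matchFeatures(prot, trans, bad), "no overlapping")

  sim <- simulateOmicsPair(SimulationConfig(n_proteins = 500, seed = 2))
  mt <- matchFeatures(sim$proteome, sim$transcriptome, sim$map)
  expect_identical(mt$n_matched, 500L)
})

test_that("imputation draws from the left-shifted feature distribution", {
  n_miss <- 1e5
  v <- matrix(c(19, 20, 21, rep(NA, n_miss)), 1,
              dimnames = list("F1", sprintf("s%d", 1:(n_miss + 3))))
  x <- IntensityExperiment(2^v, scale = "linear") |> log2Transform()
  imp <- imputeGaussian(x, seed = 7)
  iv <- SummarizedExperiment::assay(imp)[1, -(1:3)]
  # observed mean 20, sd 1: imputed ~ N(17, 0.3)
  expect_lt(abs(mean(iv) - 17), 0.01)
  expect_lt(abs(sd(iv) - 0.3), 0.01)
  # observed cells bit-identical
  expect_identical(SummarizedExperiment::assay(imp)[1, 1:3],
                   SummarizedExperiment::assay(x)[1, 1:3])
  # deterministic under seed
  expect_identical(SummarizedExperiment::assay(imputeGaussian(x, seed = 7)),
                   SummarizedExperiment::assay(imp))
})

test_that("imputation leaves complete data alone and handles degenerate sd", {
  v <- matrix(rnorm(20, 20), 4, 5,
              dimnames = list(paste0("F", 1:4), paste0("s", 1:5)))
  x <- log2IE(v)
  expect_identical(SummarizedExperiment::assay(imputeGaussian(x, seed = 1)),
                   SummarizedExperiment::assay(x))
  v2 <- rbind(F1 = c(5, 5, 5, NA, NA), F2 = c(NA, 1, 2, 3, NA))
  colnames(v2) <- paste0("s", 1:5)
  imp <- imputeGaussian(log2IE(v2), seed = 2)
  expect_identical(unname(SummarizedExperiment::assay(imp)[1, 4:5]), c(5, 5))
  # only missing cells altered
  expect_identical(SummarizedExperiment::assay(imp)[2, 2:4],
                   SummarizedExperiment::assay(log2IE(v2))[2, 2:4])
  v3 <- rbind(F1 = c(1, NA), F2 = c(1, 2))
  colnames(v3) <- c("s1", "s2")
  expect_warning(imputeGaussian(log2IE(v3), seed = 1), "dropped")
})

test_that("z-scoring centers, scales, and is idempotent", {
  v <- matrix(rnorm(50, 10, 4), 5, 10,
              dimnames = list(paste0("F", 1:5), paste0("s", 1:10)))
  z <- zscoreFeatures(log2IE(v))
  zv <- SummarizedExperiment::assay(z)
  expect_lt(max(abs(rowMeans(zv))), 1e-10)
  expect_lt(max(abs(apply(zv, 1, sd) - 1)), 1e-10)
  z2 <- zscoreFeatures(z)
  expect_equal(SummarizedExperiment::assay(z2), zv, tolerance = 1e-12)
  vc <- v; vc[1, ] <- 3
  expect_error(zscoreFeatures(log2IE(vc)), "F1")
})

test_that("cross-omics correlations recognize exact and affine agreement", {
  withr::with_seed(8, v <- matrix(rnorm(4481 * 2, 20, 2), 4481, 2))
  dimnames(v) <- list(sprintf("P%04d", 1:4481), c("beta_control_1",
                                                  "beta_control_2"))
  d <- data.frame(cell_type = "beta", treatment = "control",
                  replicate = 1:2, row.names = colnames(v))
  prot <- log2IE(v)
  # transcriptome = 2 * proteome + 1 exactly
  t2 <- v * 2 + 1
  trans <- log2IE(t2)
  out <- crossOmicsCorrelations(list(proteome = prot, transcriptome = trans),
                                d)
  expect_identical(nrow(out), 4L)  # 2x2 pairings in one group
  self <- out[out$proteome_sample == out$transcriptome_sample, ]
  expect_equal(self$pearson_r, c(1, 1))
  expect_equal(self$r_squared, c(1, 1))
  expect_equal(self$slope, c(2, 2))
  expect_equal(self$intercept, c(1, 1))
  expect_equal(out$r_squared, out$pearson_r^2, tolerance = 1e-12)

  # independent features: |r| small
  withr::with_seed(9, tn <- matrix(rnorm(4481 * 2, 10, 2), 4481, 2,
                                   dimnames = dimnames(v)))
  out0 <- crossOmicsCorrelations(list(proteome = prot,
                                      transcriptome = log2IE(tn)), d)
  expect_true(all(abs(out0$pearson_r) < 3 / sqrt(4481) + 0.02))
})

test_that("condition comparison t-test behaves at both extremes", {
  res <- data.frame(cell_type = rep(c("a", "a"), each = 3),
                    treatment = rep(c("control", "IFNg"), each = 3),
                    pearson_r = c(0.9, 0.9, 0.9, 0.5, 0.5, 0.5))
  out <- compareConditionCorrelations(res, c(treatment = "control"),
                                      c(treatment = "IFNg"))
  expect_lt(out$p, 0.05)
  res2 <- res; res2$pearson_r <- rep(c(0.8, 0.85, 0.9), 2)
  out2 <- compareConditionCorrelations(res2, c(treatment = "control"),
                                       c(treatment = "IFNg"))
  expect_equal(out2$p, 1)
  expect_equal(out2$t, 0)
  # agrees with the classical pooled t-test on non-degenerate data
  res3 <- res; res3$pearson_r <- c(0.91, 0.88, 0.93, 0.55, 0.62, 0.49)
  out3 <- compareConditionCorrelations(res3, c(treatment = "control"),
                                       c(treatment = "IFNg"))
  oracle <- stats::t.test(res3$pearson_r[1:3], res3$pearson_r[4:6],
                          var.equal = TRUE)
  expect_equal(out3$p, oracle$p.value)
  expect_error(compareConditionCorrelations(res[1:3, ],
                                            c(treatment = "control"),
                                            c(treatment = "IFNg")), ">= 2")
})

test_that("treatment shifts in mRNA-protein coupling are detectable", {
  mk <- function(r, seed) simulateOmicsPair(SimulationConfig(
    n_proteins = 1500, cell_types = "beta", n_replicates = 3,
    frac_celltype_markers = 0, frac_treatment_responsive = 0,
    mrna_protein_r = r, missing_rate = 0, seed = seed))
  hi <- mk(0.7, 23); lo <- mk(0.3, 24)
  d <- sampleDesign(hi$proteome)
  cc_hi <- crossOmicsCorrelations(
    matchFeatures(log2Transform(hi$proteome), log2Transform(hi$transcriptome),
                  hi$map), d)
  cc_lo <- crossOmicsCorrelations(
    matchFeatures(log2Transform(lo$proteome), log2Transform(lo$transcriptome),
                  lo$map), d)
  res <- rbind(cc_hi[cc_hi$treatment == "control", ],
               cc_lo[cc_lo$treatment == "IFNg", ])
  out <- compareConditionCorrelations(res, c(treatment = "control"),
                                      c(treatment = "IFNg"))
  expect_lt(out$p, 0.05)
  expect_gt(out$mean_X, out$mean_Y)
})

test_that("replicate reproducibility summaries respect exact duplicates", {
  withr::with_seed(11, v <- matrix(2^rnorm(60, 20, 2), 20, 3))
  v <- cbind(v, v[, 3])  # duplicated replicate
  dimnames(v) <- list(sprintf("F%02d", 1:20), sprintf("s%d", 1:4))
  d <- data.frame(cell_type = "beta", treatment = "control", replicate = 1:4,
                  row.names = colnames(v))
  rr <- replicateReproducibility(IntensityExperiment(v), d)
  pair34 <- rr$pairwise[rr$pairwise$sample_1 == "s3" &
                          rr$pairwise$sample_2 == "s4", ]
  expect_equal(pair34$r_squared, 1)
  v2 <- v[, c(3, 4)]
  d2 <- d[3:4, ]
  rr2 <- replicateReproducibility(IntensityExperiment(v2), d2)
  expect_true(all(rr2$cv == 0))
  # single replicate: undefined, reported missing
  rr1 <- replicateReproducibility(IntensityExperiment(v[, 1, drop = FALSE]),
                                  d[1, , drop = FALSE])
  expect_true(all(is.na(rr1$cv)))
  expect_null(rr1$pairwise)
})

test_that("sample correlation map is symmetric and orders like samples together", {
  sim <- simulateOmicsPair(SimulationConfig(
    n_proteins = 800, frac_celltype_markers = 0.4, marker_log2fc = 3,
    frac_treatment_responsive = 0, missing_rate = 0.05, seed = 19))
  x <- zscoreFeatures(suppressWarnings(
    imputeGaussian(log2Transform(sim$proteome), seed = 4)))
  out <- sampleCorrelationMap(x)
  expect_equal(out$r, t(out$r), tolerance = 1e-12)
  expect_true(all(diag(out$r) == 1))
  # cell types form contiguous blocks in the ordering
  ct <- sampleDesign(sim$proteome)[out$order, "cell_type"]
  expect_identical(sum(ct[-1] != ct[-length(ct)]), 2L)

  # two identical samples: r = 1 and adjacent
  v <- SummarizedExperiment::assay(x)[, 1:4]
  v[, 2] <- v[, 1]
  dup <- IntensityExperiment(2^v) |> log2Transform()
  out2 <- sampleCorrelationMap(dup)
  expect_equal(out2$r[1, 2], 1)
  expect_equal(abs(diff(match(colnames(v)[1:2], out2$order))), 1)
})
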