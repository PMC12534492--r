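test_that("identical configs give bit-identical simulated data", {
  cfg <- SimulationConfig(n_proteins = 150, n_phosphosites = 40, seed = 42)
  a <- simulateOmicsPair(cfg)
  b <- simulateOmicsPair(cfg)
  expect_identical(SummarizedExperiment::assay(a$proteome),
                   SummarizedExperiment::assay(b$proteome))
  expect_identical(SummarizedExperiment::assay(a$transcriptome),
                   SummarizedExperiment::assay(b$transcriptome))
  expect_identical(a$truth, b$truth)
  pa <- simulatePhosphoExperiment(cfg)
  pb <- simulatePhosphoExperiment(cfg)
  expect_identical(intensities(pa$report), intensities(pb$report))
  expect_identical(as.data.frame(pa$truth$sites), as.data.frame(pb$truth$sites))
})

test_that("a no-effect configuration yields all-null ground truth", {
  cfg <- SimulationConfig(n_proteins = 300, frac_celltype_markers = 0,
                          frac_treatment_responsive = 0, missing_rate = 0,
                          seed = 3)
  sim <- simulateOmicsPair(cfg)
  expect_true(all(sim$truth$marker_effect == 0))
  expect_true(all(sim$truth$treatment_effect == 0))
  expect_true(all(is.na(sim$truth$archetype)))
  expect_false(anyNA(SummarizedExperiment::assay(sim$proteome)))
  # group means differ only by replicate noise
  v <- SummarizedExperiment::assay(log2Transform(sim$proteome))
  d <- sampleDesign(sim$proteome)
  gm <- sapply(split(rownames(d), paste(d$cell_type, d$treatment)),
               function(s) rowMeans(v[, s, drop = FALSE]))
  sd_group_mean <- sqrt(log(1 + 0.093^2)) / log(2) / sqrt(3)
  expect_lt(max(apply(gm, 1, function(z) diff(range(z)))),
            10 * sd_group_mean)
})

test_that("replicate noise is calibrated to the target CVs", {
  cfg <- SimulationConfig(n_proteins = 2000, n_replicates = 50,
                          cell_types = "beta", missing_rate = 0,
                          frac_celltype_markers = 0,
                          frac_treatment_responsive = 0, seed = 4)
  sim <- simulateOmicsPair(cfg)
  d <- sampleDesign(sim$proteome)
  cv_p <- replicateReproducibility(sim$proteome, d)$mean_cv
  cv_t <- replicateReproducibility(sim$transcriptome, d)$mean_cv
  expect_lt(abs(cv_p - 0.093) / 0.093, 0.10)
  expect_lt(abs(cv_t - 0.218) / 0.218, 0.10)
})

test_that("matched transcripts and proteins correlate at the target level", {
  sim <- simulateOmicsPair(SimulationConfig(
    n_proteins = 5000, missing_rate = 0, frac_celltype_markers = 0,
    frac_treatment_responsive = 0, mrna_protein_r = 0.6, seed = 9))
  lp <- SummarizedExperiment::assay(log2Transform(sim$proteome))
  lt <- SummarizedExperiment::assay(log2Transform(sim$transcriptome))
  r <- cor(lp[, 1], lt[, 1])
  expect_lt(abs(r - 0.6), 0.05)
})

test_that("left-censored missingness hits its rate and removes low values", {
  cfg <- SimulationConfig(n_proteins = 5000, n_replicates = 10,
                          cell_types = "beta", missing_rate = 0, seed = 8)
  sim <- simulateOmicsPair(cfg)
  x <- sim$proteome  # 5000 x 20 = 1e5 cells
  out <- applyMissingness(x, missing_rate = 0.2, seed = 21)
  v0 <- SummarizedExperiment::assay(x)
  v1 <- SummarizedExperiment::assay(out)
  frac <- mean(is.na(v1))
  expect_lt(abs(frac - 0.2), 0.01)
  removed <- log2(v0[is.na(v1)])
  retained <- log2(v0[!is.na(v1)])
  expect_lt(mean(removed), mean(retained))
  # untouched at rate 0, deterministic under seed
  expect_identical(SummarizedExperiment::assay(
    applyMissingness(x, 0, seed = 1)), v0)
  expect_identical(v1, SummarizedExperiment::assay(
    applyMissingness(x, 0.2, seed = 21)))
  expect_error(applyMissingness(x, 1.5, seed = 1), "missing_rate")
})

test_that("phosphosite effect classes obey their defining constraints", {
  cfg <- SimulationConfig(n_proteins = 400, n_phosphosites = 100,
                          missing_rate = 0, seed = 6)
  ph <- simulatePhosphoExperiment(cfg)
  tr <- ph$truth$sites
  expect_identical(nrow(tr), 100L)
  # protein-driven: identical injected phospho and protein FC
  pd <- tr[tr$class == "protein_driven", ]
  expect_true(all(pd$phospho_log2fc == pd$protein_log2fc))
  expect_true(all(pd$corrected_log2fc == 0))
  expect_true(all(abs(pd$phospho_log2fc) == 2))
  # stoichiometry: parent protein unchanged
  st <- tr[tr$class == "stoichiometry", ]
  expect_true(all(st$protein_log2fc == 0))
  expect_true(all(st$corrected_log2fc == st$phospho_log2fc))
  # 1-4 precursors per site bounds the report
  m <- nrow(precursorData(ph$report))
  expect_gte(m, 100L); expect_lte(m, 400L)
  expect_identical(sum(tr$n_precursors), m)

  # all-stoichiometry config forces a null proteome
  cfg2 <- SimulationConfig(n_proteins = 200, n_phosphosites = 50,
                           frac_stoichiometry_sites = 1,
                           frac_protein_driven_sites = 0, seed = 7)
  tr2 <- simulatePhosphoExperiment(cfg2)$truth$sites
  expect_true(all(tr2$protein_log2fc == 0))
})

test_that("injected fold changes are recovered at large replicate numbers", {
  cfg <- SimulationConfig(n_proteins = 500, n_replicates = 40,
                          cell_types = "beta", missing_rate = 0,
                          frac_celltype_markers = 0,
                          frac_treatment_responsive = 0.3,
                          treatment_log2fc = 2, seed = 10)
  sim <- simulateOmicsPair(cfg)
  v <- SummarizedExperiment::assay(log2Transform(sim$proteome))
  d <- sampleDesign(sim$proteome)
  fc_hat <- rowMeans(v[, d$treatment == "IFNg"]) -
    rowMeans(v[, d$treatment == "control"])
  fc_true <- sim$truth$treatment_effect[, "beta"]
  resp <- fc_true != 0
  # bound for the max over ~500 independent N(0, se) estimates: 6 se
  se <- sqrt(log(1 + 0.093^2)) / log(2) * sqrt(2 / 40)
  expect_lt(max(abs(fc_hat[resp] - fc_true[resp])), 6 * se)
  expect_lt(max(abs(fc_hat[!resp])), 6 * se)
})
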