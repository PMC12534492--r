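#' @importFrom stats plogis rnorm runif uniroot sd setNames
NULL

# treatment-response archetypes over the given cell types: each single cell
# type up, shared up, shared down, then pairwise combinations; signs are
# multipliers of the configured treatment effect size
.responseArchetypes <- function(cell_types, n) {
  k <- length(cell_types)
  pats <- list()
  for (i in seq_len(k)) {
    v <- setNames(numeric(k), cell_types); v[i] <- 1
    pats[[paste0(cell_types[i], "_only")]] <- v
  }
  pats[["all_up"]] <- setNames(rep(1, k), cell_types)
  pats[["all_down"]] <- setNames(rep(-1, k), cell_types)
  if (k >= 2) {
    cmb <- utils::combn(k, 2)
    for (j in seq_len(ncol(cmb))) {
      v <- setNames(numeric(k), cell_types); v[cmb[, j]] <- 1
      pats[[paste(cell_types[cmb[, j]], collapse = "+")]] <- v
    }
  }
  pats[seq_len(min(n, length(pats)))]
}

#' Simulate a matched proteome/transcriptome pair with known ground truth
#'
#' Generates linear-scale intensity matrices for a cell-types x treatments x
#' replicates design. Baseline log2 abundances are log-normal with a wide
#' (~5 orders of magnitude) dynamic range; matched transcript and protein
#' abundances share a latent log-abundance mixed to reach the target
#' mRNA-protein correlation. A fraction of features carries a cell-type
#' marker effect, and a fraction responds to treatment following one of the
#' configured response archetypes; both effects act on both omics layers.
#' Replicate noise is calibrated so realized within-group CVs on the linear
#' scale match the configured targets, and left-censored missingness is
#' applied at the configured rate.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with elements `proteome` and `transcriptome`
#'   ([IntensityExperiment-class], linear scale), `map` (`data.frame` with
#'   `gene_id`, `protein_group`), and `truth`: a list with the sample
#'   `design`, `marker_effect` and `treatment_effect` matrices (features x
#'   cell types, log2 units), the per-feature `archetype` label (`NA` for
#'   non-responsive features) and `expected_log2` mean matrices per omics.
#' @examples
#' sim <- simulateOmicsPair(SimulationConfig(n_proteins = 100, seed = 3))
#' sim$proteome
#' @export
simulateOmicsPair <- function(config) {
  validObject(config)
  design <- .makeDesign(config@cell_types, config@treatments,
                        config@n_replicates)
  n <- config@n_proteins
  prot_ids <- sprintf("P%05d", seq_len(n))
  gene_ids <- sprintf("ENSG%07d", seq_len(n))

  sd_p <- .cvToLog2Sd(config@target_cv_proteomics)
  sd_t <- .cvToLog2Sd(config@target_cv_transcriptomics)
  a_p <- 2.5; a_t <- 2.0            # log2 sd of baseline abundances
  # inflate the latent sharing so the noise-attenuated feature-wise
  # correlation lands on the requested target
  r_lat <- min(config@mrna_protein_r *
                 sqrt((1 + (sd_p / a_p)^2) * (1 + (sd_t / a_t)^2)), 0.999)

  out <- withr::with_seed(.subSeed(config@seed, 101L), {
    z <- rnorm(n)
    base_p <- 20 + a_p * (sqrt(r_lat) * z + sqrt(1 - r_lat) * rnorm(n))
    base_t <- 10 + a_t * (sqrt(r_lat) * z + sqrt(1 - r_lat) * rnorm(n))

    k <- length(config@cell_types)
    marker_effect <- matrix(0, n, k,
                            dimnames = list(prot_ids, config@cell_types))
    n_mark <- round(config@frac_celltype_markers * n)
    mark_idx <- if (n_mark > 0) sample.int(n, n_mark) else integer()
    mark_ct <- sample.int(k, n_mark, replace = TRUE)
    marker_effect[cbind(mark_idx, mark_ct)] <- config@marker_log2fc

    treatment_effect <- matrix(0, n, k,
                               dimnames = list(prot_ids, config@cell_types))
    pats <- .responseArchetypes(config@cell_types,
                                config@n_response_archetypes)
    n_resp <- round(config@frac_treatment_responsive * n)
    resp_idx <- if (n_resp > 0) sample.int(n, n_resp) else integer()
    archetype <- rep(NA_character_, n)
    if (n_resp > 0) {
      pat_of <- sample(names(pats), n_resp, replace = TRUE)
      archetype[resp_idx] <- pat_of
      for (j in seq_along(resp_idx))
        treatment_effect[resp_idx[j], ] <-
          pats[[pat_of[j]]] * config@treatment_log2fc
    }

    treated <- design$treatment != config@treatments[1]
    ct_idx <- match(design$cell_type, config@cell_types)
    mean_p <- base_p + marker_effect[, ct_idx, drop = FALSE] +
      sweep(treatment_effect[, ct_idx, drop = FALSE], 2, treated, `*`)
    mean_t <- base_t + marker_effect[, ct_idx, drop = FALSE] +
      sweep(treatment_effect[, ct_idx, drop = FALSE], 2, treated, `*`)
    colnames(mean_p) <- colnames(mean_t) <- rownames(design)

    vals_p <- 2^(mean_p + matrix(rnorm(n * nrow(design), 0, sd_p),
                                 n, nrow(design)))
    vals_t <- 2^(mean_t + matrix(rnorm(n * nrow(design), 0, sd_t),
                                 n, nrow(design)))
    rownames(vals_p) <- prot_ids
    rownames(vals_t) <- gene_ids
    rownames(mean_t) <- gene_ids
    list(vals_p = vals_p, vals_t = vals_t, mean_p = mean_p, mean_t = mean_t,
         marker_effect = marker_effect, treatment_effect = treatment_effect,
         archetype = archetype)
  })

  vals_p <- .censorMatrix(out$vals_p, config@missing_rate,
                          config@censoring_steepness,
                          .subSeed(config@seed, 102L), log_scale = FALSE)
  vals_t <- .censorMatrix(out$vals_t, config@missing_rate,
                          config@censoring_steepness,
                          .subSeed(config@seed, 103L), log_scale = FALSE)

  truth <- list(design = design,
                marker_effect = out$marker_effect,
                treatment_effect = out$treatment_effect,
                archetype = setNames(out$archetype, prot_ids),
                expected_log2 = list(proteome = out$mean_p,
                                     transcriptome = out$mean_t))
  .msg("simulateOmicsPair: ", n, " features x ", nrow(design), " samples; ",
       sum(!is.na(truth$archetype)), " treatment-responsive, ",
       sum(rowSums(out$marker_effect != 0) > 0), " cell-type markers")
  list(proteome = IntensityExperiment(vals_p, design, scale = "linear"),
       transcriptome = IntensityExperiment(vals_t, design, scale = "linear"),
       map = data.frame(gene_id = gene_ids, protein_group = prot_ids),
       truth = truth)
}

#' Simulate a precursor-level phosphoproteomics experiment
#'
#' Generates a [PhosphoReport-class] plus the matched (unenriched) proteome
#' for the same design, with three planted phosphosite classes:
#' \describe{
#'   \item{stoichiometry}{the phosphosite changes with treatment while the
#'     parent protein does not (true corrected log2 FC = injected FC);}
#'   \item{protein_driven}{phosphosite and parent protein carry the same
#'     injected log2 FC (true corrected FC = 0);}
#'   \item{null}{no effect on either level.}
#' }
#' Each phosphosite is reported by 1-4 precursors whose intensities are the
#' site abundance scaled by a fixed per-precursor ionization-efficiency
#' offset, so collapse-by-sum recovers the site profile. A configured
#' fraction of precursors receives a localization probability below the
#' class-I cutoff of 0.75 to exercise filtering; whether each site retains
#' at least one confident precursor is recorded in the ground truth.
#'
#' @param config a [SimulationConfig-class]; `n_proteins` must be at least
#'   the number of effect-carrying phosphosites so each gets its own parent.
#' @return list with `report` ([PhosphoReport-class]), `proteome`
#'   ([IntensityExperiment-class], linear), and `truth`: a list with the
#'   sample `design`, a `sites` [S4Vectors::DataFrame] (site id, parent
#'   protein group, class, injected phospho/protein/corrected log2 FC,
#'   precursor counts, class-I flag) and a `precursors` DataFrame mapping
#'   precursor ids to site ids and localization probabilities.
#' @export
simulatePhosphoExperiment <- function(config) {
  validObject(config)
  design <- .makeDesign(config@cell_types, config@treatments,
                        config@n_replicates)
  ns <- config@n_phosphosites
  np <- config@n_proteins
  n_st <- round(config@frac_stoichiometry_sites * ns)
  n_pd <- round(config@frac_protein_driven_sites * ns)
  if (np < n_st + n_pd)
    stop("n_proteins too small: each effect-carrying phosphosite needs ",
         "its own parent protein")
  sd_noise <- .cvToLog2Sd(config@target_cv_proteomics)
  prot_ids <- sprintf("P%05d", seq_len(np))

  res <- withr::with_seed(.subSeed(config@seed, 201L), {
    site_class <- sample(c(rep("stoichiometry", n_st),
                           rep("protein_driven", n_pd),
                           rep("null", ns - n_st - n_pd)))
    is_eff <- site_class != "null"
    parent <- integer(ns)
    if (np >= ns) {
      parent <- sample.int(np, ns)
    } else {
      parent[is_eff] <- sample.int(np, sum(is_eff))
      parent[!is_eff] <- sample(setdiff(seq_len(np), parent[is_eff]),
                                sum(!is_eff), replace = TRUE)
    }
    sgn <- sample(c(-1, 1), ns, replace = TRUE)
    phospho_fc <- ifelse(is_eff, sgn * config@treatment_log2fc, 0)
    protein_fc_site <- ifelse(site_class == "protein_driven", phospho_fc, 0)

    protein_fc <- setNames(numeric(np), prot_ids)
    protein_fc[parent[site_class == "protein_driven"]] <-
      phospho_fc[site_class == "protein_driven"]

    # phosphosite identities: one site per (parent, position, residue)
    residue <- sample(c("S", "T", "Y"), ns, replace = TRUE,
                      prob = c(0.80, 0.15, 0.05))
    position <- integer(ns)
    repeat {
      position <- sample.int(600, ns, replace = TRUE)
      if (!anyDuplicated(paste(parent, position))) break
    }
    site_id <- paste0(prot_ids[parent], "_", residue, position)

    treated <- design$treatment != config@treatments[1]
    nsmp <- nrow(design)

    # matched (unenriched) proteome
    prot_base <- rnorm(np, 20, 2.5)
    prot_mean <- outer(prot_base, rep(1, nsmp)) +
      outer(protein_fc, as.numeric(treated))
    prot_vals <- 2^(prot_mean + matrix(rnorm(np * nsmp, 0, sd_noise),
                                       np, nsmp))
    dimnames(prot_vals) <- list(prot_ids, rownames(design))

    # precursor-level phospho report
    site_base <- rnorm(ns, 19, 2.5)
    n_prec <- sample.int(4, ns, replace = TRUE)
    site_of <- rep(seq_len(ns), n_prec)
    m <- length(site_of)
    eff_offset <- rnorm(m, -1, 0.8)       # log2 ionization efficiency
    low_loc <- runif(m) < config@frac_low_localization
    loc_prob <- ifelse(low_loc, runif(m, 0.20, 0.74), runif(m, 0.75, 1.0))
    site_mean <- outer(site_base, rep(1, nsmp)) +
      outer(phospho_fc, as.numeric(treated))
    prec_vals <- 2^(site_mean[site_of, , drop = FALSE] + eff_offset +
                    matrix(rnorm(m * nsmp, 0, sd_noise), m, nsmp))
    colnames(prec_vals) <- rownames(design)

    list(site_class = site_class, parent = parent, site_id = site_id,
         residue = residue, position = position, phospho_fc = phospho_fc,
         protein_fc_site = protein_fc_site, prot_vals = prot_vals,
         site_of = site_of, loc_prob = loc_prob, prec_vals = prec_vals,
         n_prec = n_prec)
  })

  prot_vals <- .censorMatrix(res$prot_vals, config@missing_rate,
                             config@censoring_steepness,
                             .subSeed(config@seed, 202L), log_scale = FALSE)
  prec_vals <- .censorMatrix(res$prec_vals, config@missing_rate,
                             config@censoring_steepness,
                             .subSeed(config@seed, 203L), log_scale = FALSE)

  m <- length(res$site_of)
  prec_ids <- sprintf("PREC%06d", seq_len(m))
  report <- PhosphoReport(
    precursor_id = prec_ids,
    protein_group = prot_ids[res$parent[res$site_of]],
    positions = as.list(res$position[res$site_of]),
    residues = as.list(res$residue[res$site_of]),
    localization_probs = as.list(res$loc_prob),
    multiplicity = rep(1L, m),
    intensities = prec_vals
  )

  class_I <- tapply(res$loc_prob >= 0.75, res$site_of, any)
  truth_sites <- DataFrame(
    site_id = res$site_id,
    protein_group = prot_ids[res$parent],
    class = res$site_class,
    phospho_log2fc = res$phospho_fc,
    protein_log2fc = res$protein_fc_site,
    corrected_log2fc = res$phospho_fc - res$protein_fc_site,
    n_precursors = res$n_prec,
    is_class_I = as.logical(class_I[as.character(seq_len(config@n_phosphosites))])
  )
  truth_prec <- DataFrame(precursor_id = prec_ids,
                          site_id = res$site_id[res$site_of],
                          localization_prob = res$loc_prob)
  .msg("simulatePhosphoExperiment: ", config@n_phosphosites, " sites (",
       sum(truth_sites$is_class_I), " class I) via ", m, " precursors")
  list(report = report,
       proteome = IntensityExperiment(prot_vals, design, scale = "linear"),
       truth = list(design = design, sites = truth_sites,
                    precursors = truth_prec))
}

.censorMatrix <- function(m, missing_rate, steepness, seed,
                          log_scale = FALSE) {
  if (missing_rate < 0 || missing_rate > 1)
    stop("missing_rate must lie in [0, 1]")
  if (missing_rate == 0) return(m)
  if (missing_rate == 1) { m[] <- NA_real_; return(m) }
  l <- if (log_scale) m else log2(pmax(m, .Machine$double.xmin))
  obs <- !is.na(l)
  # pick the logistic midpoint so the expected dropout rate matches
  f <- function(q) mean(plogis(steepness * (q - l[obs]))) - missing_rate
  rng <- range(l[obs])
  q <- uniroot(f, lower = rng[1] - 60 / steepness,
               upper = rng[2] + 60 / steepness)$root
  p <- plogis(steepness * (q - l))
  withr::with_seed(seed, {
    drop <- matrix(runif(length(m)) < p, nrow(m), ncol(m))
  })
  m[drop & obs] <- NA_real_
  m
}

#' Apply left-censored (intensity-dependent) missingness
#'
#' Removes cells at an expected overall rate `missing_rate`, with the
#' dropout probability decreasing logistically in log2 intensity (steepness
#' per log2 unit), emulating the missing-not-at-random pattern of
#' low-abundance non-detection in DIA data. The logistic midpoint is
#' calibrated so the expected missing fraction equals `missing_rate`.
#' Deterministic under a fixed seed.
#'
#' @param x an [IntensityExperiment-class] (complete or partially observed).
#' @param missing_rate target expected fraction of missing cells, in \[0,1\].
#' @param censoring_steepness logistic steepness (> 0) per log2 unit.
#' @param seed integer seed.
#' @return `x` with cells set to `NA`.
#' @export
applyMissingness <- function(x, missing_rate, censoring_steepness = 0.8,
                             seed = 1L) {
  stopifnot(is(x, "IntensityExperiment"))
  v <- assay(x, "intensity")
  assay(x, "intensity") <- .censorMatrix(
    v, missing_rate, censoring_steepness, seed,
    log_scale = intensityScale(x) == "log2")
  x
}
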