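#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IntegerList CharacterList NumericList
#' @import SummarizedExperiment
NULL

#' IntensityExperiment: a features x samples abundance matrix
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"intensity"` assay (protein groups, phosphosites or genes in rows,
#' samples in columns) together with the scale the values live on. Missing
#' values are encoded as `NA`. The experimental design (cell type, treatment,
#' replicate) lives in `colData`.
#'
#' @slot intensityScale either `"linear"` (raw intensities, non-negative) or
#'   `"log2"`.
#' @export
setClass("IntensityExperiment",
  contains = "SummarizedExperiment",
  representation(intensityScale = "character"),
  prototype(intensityScale = "linear")
)

setValidity("IntensityExperiment", function(object) {
  msg <- character()
  if (length(object@intensityScale) != 1L ||
      !object@intensityScale %in% c("linear", "log2"))
    msg <- c(msg, "intensityScale must be \"linear\" or \"log2\"")
  if (!"intensity" %in% assayNames(object))
    msg <- c(msg, "assay \"intensity\" is required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if ("intensity" %in% assayNames(object) &&
      identical(object@intensityScale, "linear")) {
    v <- assay(object, "intensity")
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, "linear-scale intensities must be >= 0 where present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityExperiment
#'
#' @param values numeric matrix (features x samples) with dimnames; `NA`
#'   marks missing values.
#' @param design optional `data.frame` with columns `cell_type`, `treatment`,
#'   `replicate` and either rownames or a `sample_id` column matching
#'   `colnames(values)`. Every sample column must have exactly one design row.
#' @param scale `"linear"` or `"log2"`.
#' @return An [IntensityExperiment-class] object.
#' @examples
#' m <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' ie <- IntensityExperiment(m)
#' intensityScale(ie)
#' @export
IntensityExperiment <- function(values, design = NULL,
                                scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("values must have feature rownames and sample colnames")
  if (nrow(values) == 0L && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (ncol(values) == 0L && is.null(colnames(values)))
    colnames(values) <- character(0)
  storage.mode(values) <- "double"
  cd <- if (is.null(design)) {
    DataFrame(row.names = colnames(values))
  } else {
    .resolveDesign(design, colnames(values))
  }
  new("IntensityExperiment",
      SummarizedExperiment(assays = list(intensity = values), colData = cd),
      intensityScale = scale)
}

.resolveDesign <- function(design, sample_ids) {
  design <- as.data.frame(design)
  if ("sample_id" %in% colnames(design)) {
    rownames(design) <- design$sample_id
    design$sample_id <- NULL
  }
  missing_cols <- setdiff(c("cell_type", "treatment", "replicate"),
                          colnames(design))
  if (length(missing_cols))
    stop("design lacks column(s): ", paste(missing_cols, collapse = ", "))
  unmatched <- setdiff(sample_ids, rownames(design))
  if (length(unmatched))
    stop("samples without a design row: ", paste(unmatched, collapse = ", "))
  DataFrame(design[sample_ids, , drop = FALSE])
}

#' PhosphoReport: precursor-level phosphopeptide quantifications
#'
#' One row per precursor, carrying its protein-group assignment, candidate
#' phosphosite positions with residues and localization probabilities, the
#' count of phospho groups (multiplicity), and per-sample intensities (linear
#' scale, `NA` = missing).
#'
#' @slot precursors a [S4Vectors::DataFrame] with columns `precursor_id`,
#'   `protein_group`, `positions` (`IntegerList`, 1-based protein
#'   coordinates, strictly increasing within a record), `residues`
#'   (`CharacterList` of S/T/Y), `localization_probs` (`NumericList` in
#'   \[0,1\]) and `multiplicity`.
#' @slot intensities numeric matrix, one row per precursor, one column per
#'   sample.
#' @export
setClass("PhosphoReport",
  representation(precursors = "DataFrame", intensities = "matrix")
)

setValidity("PhosphoReport", function(object) {
  pc <- object@precursors
  msg <- character()
  need <- c("precursor_id", "protein_group", "positions", "residues",
            "localization_probs", "multiplicity")
  absent <- setdiff(need, colnames(pc))
  if (length(absent))
    return(paste("precursors lacks column(s):", paste(absent, collapse = ", ")))
  if (nrow(pc) != nrow(object@intensities))
    msg <- c(msg, "precursors and intensities disagree on row count")
  if (anyDuplicated(pc$precursor_id))
    msg <- c(msg, "precursor ids must be unique")
  pr <- unlist(pc$localization_probs)
  if (length(pr) && (any(pr < 0) || any(pr > 1)))
    msg <- c(msg, "localization probabilities must lie in [0, 1]")
  npos <- lengths(pc$positions)
  if (!all(npos == lengths(pc$residues)) ||
      !all(npos == lengths(pc$localization_probs)))
    msg <- c(msg, "positions, residues and localization_probs must have equal lengths per record")
  inc <- vapply(pc$positions, function(p) all(diff(p) > 0), logical(1))
  if (!all(inc))
    msg <- c(msg, "positions must be strictly increasing within a record")
  res <- unlist(pc$residues)
  if (length(res) && !all(res %in% c("S", "T", "Y")))
    msg <- c(msg, "residues must be S, T or Y")
  if (length(msg)) msg else TRUE
})

#' Construct a PhosphoReport
#'
#' @param precursor_id character vector of unique precursor ids.
#' @param protein_group character vector of protein-group accessions
#'   (";"-separated groups allowed; the leading accession is used for
#'   protein matching downstream).
#' @param positions list (or `IntegerList`) of 1-based site positions.
#' @param residues list (or `CharacterList`) of S/T/Y residues.
#' @param localization_probs list (or `NumericList`) of probabilities.
#' @param multiplicity integer count of phospho groups per precursor.
#' @param intensities numeric matrix of per-sample intensities (linear).
#' @return A [PhosphoReport-class] object.
#' @export
PhosphoReport <- function(precursor_id, protein_group, positions, residues,
                          localization_probs, multiplicity, intensities) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (nrow(intensities)) rownames(intensities) <- as.character(precursor_id)
  pc <- DataFrame(
    precursor_id = as.character(precursor_id),
    protein_group = as.character(protein_group),
    positions = IntegerList(positions),
    residues = CharacterList(residues),
    localization_probs = NumericList(localization_probs),
    multiplicity = as.integer(multiplicity)
  )
  new("PhosphoReport", precursors = pc, intensities = intensities)
}

#' SimulationConfig: parameters for the synthetic-data generator
#'
#' Holds the study design and effect structure the generator emulates:
#' cell types x treatments x replicates, fractions and sizes of cell-type
#' marker and treatment effects, phosphosite effect classes (stoichiometry
#' change vs protein-driven), replicate noise calibrated to target
#' coefficients of variation, mRNA-protein coupling, and left-censored
#' missingness.
#'
#' Default CV targets (9.3\% proteomics, 21.8\% transcriptomics) match
#' replicate variability typical of sorted-islet DIA proteomes and bulk
#' RNA-seq at this depth.
#'
#' @export
setClass("SimulationConfig",
  representation(
    n_proteins = "integer", n_phosphosites = "integer",
    cell_types = "character", treatments = "character",
    n_replicates = "integer",
    frac_celltype_markers = "numeric", marker_log2fc = "numeric",
    frac_treatment_responsive = "numeric", treatment_log2fc = "numeric",
    n_response_archetypes = "integer",
    frac_stoichiometry_sites = "numeric", frac_protein_driven_sites = "numeric",
    frac_low_localization = "numeric",
    target_cv_proteomics = "numeric", target_cv_transcriptomics = "numeric",
    mrna_protein_r = "numeric",
    missing_rate = "numeric", censoring_steepness = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chkFrac <- function(nm) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      paste0(nm, " must be a single value in [0, 1]")
    else character()
  }
  for (nm in c("frac_celltype_markers", "frac_treatment_responsive",
               "frac_stoichiometry_sites", "frac_protein_driven_sites",
               "frac_low_localization", "missing_rate"))
    msg <- c(msg, chkFrac(nm))
  for (nm in c("n_proteins", "n_phosphosites"))
    if (slot(object, nm) < 1L) msg <- c(msg, paste0(nm, " must be positive"))
  if (object@n_replicates < 2L)
    msg <- c(msg, "n_replicates must be >= 2")
  if (object@frac_stoichiometry_sites + object@frac_protein_driven_sites > 1)
    msg <- c(msg,
      "frac_stoichiometry_sites + frac_protein_driven_sites must be <= 1")
  for (nm in c("target_cv_proteomics", "target_cv_transcriptomics"))
    if (slot(object, nm) <= 0) msg <- c(msg, paste0(nm, " must be > 0"))
  if (object@mrna_protein_r < 0 || object@mrna_protein_r > 1)
    msg <- c(msg, "mrna_protein_r must lie in [0, 1]")
  if (object@censoring_steepness <= 0)
    msg <- c(msg, "censoring_steepness must be > 0")
  if (length(object@cell_types) < 1L || anyDuplicated(object@cell_types))
    msg <- c(msg, "cell_types must be non-empty and unique")
  if (length(object@treatments) != 2L || anyDuplicated(object@treatments))
    msg <- c(msg, "treatments must be two distinct labels (reference first)")
  if (length(msg)) msg else TRUE
})

#' Create a simulation configuration
#'
#' @param n_proteins,n_phosphosites feature counts.
#' @param cell_types,treatments group labels; the first treatment is the
#'   reference (untreated) condition.
#' @param n_replicates biological replicates per (cell type, treatment) group.
#' @param frac_celltype_markers fraction of features carrying a cell-type
#'   marker effect of `marker_log2fc` log2 units in one cell type.
#' @param frac_treatment_responsive fraction of features responding to
#'   treatment with `treatment_log2fc` log2 units, following one of
#'   `n_response_archetypes` response patterns (single-cell-type, shared up,
#'   shared down, pairwise).
#' @param n_response_archetypes number of distinct treatment-response
#'   patterns planted (default 6).
#' @param marker_log2fc,treatment_log2fc effect sizes in log2 units.
#' @param frac_stoichiometry_sites fraction of phosphosites whose treatment
#'   change is phosphorylation-only (parent protein unchanged).
#' @param frac_protein_driven_sites fraction of phosphosites whose change
#'   exactly tracks the parent protein (corrected fold change 0).
#' @param frac_low_localization fraction of precursors drawn with a
#'   localization probability below the class-I cutoff.
#' @param target_cv_proteomics,target_cv_transcriptomics within-group
#'   coefficient of variation (linear scale) the replicate noise is
#'   calibrated to.
#' @param mrna_protein_r target Pearson correlation of log2 abundances
#'   between matched transcripts and proteins.
#' @param missing_rate expected fraction of missing cells after
#'   left-censored dropout.
#' @param censoring_steepness logistic steepness of the dropout probability
#'   per log2-intensity unit.
#' @param seed integer master seed; all generator randomness derives from it.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(n_proteins = 200, n_phosphosites = 50, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(n_proteins = 2000L, n_phosphosites = 500L,
                             cell_types = c("alpha", "beta", "delta"),
                             treatments = c("control", "IFNg"),
                             n_replicates = 3L,
                             frac_celltype_markers = 0.2,
                             marker_log2fc = 2,
                             frac_treatment_responsive = 0.15,
                             treatment_log2fc = 2,
                             n_response_archetypes = 6L,
                             frac_stoichiometry_sites = 0.3,
                             frac_protein_driven_sites = 0.3,
                             frac_low_localization = 0.1,
                             target_cv_proteomics = 0.093,
                             target_cv_transcriptomics = 0.218,
                             mrna_protein_r = 0.6,
                             missing_rate = 0.1,
                             censoring_steepness = 0.8,
                             seed = 1L) {
  new("SimulationConfig",
      n_proteins = as.integer(n_proteins),
      n_phosphosites = as.integer(n_phosphosites),
      cell_types = cell_types, treatments = treatments,
      n_replicates = as.integer(n_replicates),
      frac_celltype_markers = frac_celltype_markers,
      marker_log2fc = marker_log2fc,
      frac_treatment_responsive = frac_treatment_responsive,
      treatment_log2fc = treatment_log2fc,
      n_response_archetypes = as.integer(n_response_archetypes),
      frac_stoichiometry_sites = frac_stoichiometry_sites,
      frac_protein_driven_sites = frac_protein_driven_sites,
      frac_low_localization = frac_low_localization,
      target_cv_proteomics = target_cv_proteomics,
      target_cv_transcriptomics = target_cv_transcriptomics,
      mrna_protein_r = mrna_protein_r,
      missing_rate = missing_rate,
      censoring_steepness = censoring_steepness,
      seed = as.integer(seed))
}
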