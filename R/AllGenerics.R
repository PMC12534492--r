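#' Scale of an intensity matrix
#'
#' @param x an [IntensityExperiment-class].
#' @return `"linear"` or `"log2"`.
#' @export
setGeneric("intensityScale", function(x) standardGeneric("intensityScale"))

#' @rdname intensityScale
#' @export
setMethod("intensityScale", "IntensityExperiment",
          function(x) x@intensityScale)

#' Sample design of an experiment
#'
#' @param x an [IntensityExperiment-class].
#' @return `data.frame` with columns `cell_type`, `treatment`, `replicate`,
#'   one row per sample (rownames = sample ids).
#' @export
setGeneric("sampleDesign", function(x) standardGeneric("sampleDesign"))

#' @rdname sampleDesign
#' @export
setMethod("sampleDesign", "IntensityExperiment", function(x) {
  as.data.frame(colData(x))
})

#' Intensity values
#'
#' @param x an [IntensityExperiment-class] or [PhosphoReport-class].
#' @return numeric matrix of intensities (`NA` = missing).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname intensities
#' @export
setMethod("intensities", "IntensityExperiment",
          function(x) assay(x, "intensity"))

#' @rdname intensities
#' @export
setMethod("intensities", "PhosphoReport", function(x) x@intensities)

#' Precursor annotation of a PhosphoReport
#'
#' @param x a [PhosphoReport-class].
#' @return the precursor [S4Vectors::DataFrame].
#' @export
setGeneric("precursorData", function(x) standardGeneric("precursorData"))

#' @rdname precursorData
#' @export
setMethod("precursorData", "PhosphoReport", function(x) x@precursors)

#' Log2-transform a linear intensity matrix
#'
#' Replaces present values by their log2; zeros are treated according to the
#' zero policy (by default they become missing, since DIA exports encode
#' non-detection as 0 or blank depending on settings). Applying the
#' transform to an already log2-scaled object is an error.
#'
#' @param x an [IntensityExperiment-class] on linear scale.
#' @param zero_as_missing replace zeros by `NA` before transforming
#'   (default `TRUE`).
#' @return the log2-scaled [IntensityExperiment-class].
#' @examples
#' m <- matrix(c(8, 1, 0, 4), 2, 2,
#'             dimnames = list(c("P1", "P2"), c("s1", "s2")))
#' assay(log2Transform(IntensityExperiment(m)))
#' @export
setGeneric("log2Transform",
           function(x, zero_as_missing = TRUE) standardGeneric("log2Transform"))

#' @rdname log2Transform
#' @export
setMethod("log2Transform", "IntensityExperiment",
          function(x, zero_as_missing = TRUE) {
  if (intensityScale(x) == "log2")
    stop("matrix is already log2-scaled")
  v <- assay(x, "intensity")
  if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
  if (any(v == 0, na.rm = TRUE))
    stop("zero intensities present with zero_as_missing = FALSE; log2 undefined")
  assay(x, "intensity") <- log2(v)
  x@intensityScale <- "log2"
  validObject(x)
  x
})

setMethod("show", "IntensityExperiment", function(object) {
  v <- assay(object, "intensity")
  cat("IntensityExperiment:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  scale:", intensityScale(object),
      sprintf(" | missing: %.1f%%\n", 100 * mean(is.na(v))))
  if (ncol(colData(object)))
    cat("  design:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

setMethod("show", "PhosphoReport", function(object) {
  cat("PhosphoReport:", nrow(object@precursors), "precursors x",
      ncol(object@intensities), "samples\n")
  cat("  protein groups:", length(unique(object@precursors$protein_group)),
      "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  design:", length(object@cell_types), "cell types x",
      length(object@treatments), "treatments x", object@n_replicates,
      "replicates\n")
  cat("  features:", object@n_proteins, "proteins,", object@n_phosphosites,
      "phosphosites\n")
  cat(sprintf("  target CVs: %.3f (proteome) / %.3f (transcriptome); missing rate %.2f\n",
      object@target_cv_proteomics, object@target_cv_transcriptomics,
      object@missing_rate))
  cat("  seed:", object@seed, "\n")
})
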