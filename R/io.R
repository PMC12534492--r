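#' @importFrom utils read.delim write.table
NULL

.readTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, na.strings = c("", "NA", "NaN"))
}

#' Read a protein-group intensity matrix (pg_matrix TSV dialect)
#'
#' Expects a tab-separated table whose first column (`Protein.Group`) holds
#' the protein-group accession and whose remaining columns are samples.
#' Empty cells, `NA`/`NaN` and (by default) zeros become the missing marker;
#' the result is on linear scale.
#'
#' @param path TSV file path.
#' @param design optional sample design `data.frame` (see
#'   [IntensityExperiment()]); sample columns must match its rows.
#' @param feature_col name of the feature-id column (default
#'   `"Protein.Group"`).
#' @param zero_as_missing treat intensity 0 as missing (default `TRUE`).
#' @return an [IntensityExperiment-class], linear scale.
#' @export
readProteinMatrix <- function(path, design = NULL,
                              feature_col = "Protein.Group",
                              zero_as_missing = TRUE) {
  tab <- .readTSV(path)
  if (!feature_col %in% colnames(tab))
    stop("missing feature column '", feature_col, "' in ", path)
  ids <- as.character(tab[[feature_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature ids: ", paste(dup, collapse = ", "))
  v <- as.matrix(tab[, setdiff(colnames(tab), feature_col), drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
  x <- IntensityExperiment(v, design = design, scale = "linear")
  .msg("read ", nrow(x), " features x ", ncol(x), " samples from ", path,
       sprintf(" (%.1f%% missing)", 100 * mean(is.na(v))))
  x
}

#' Read a transcript abundance matrix
#'
#' Same dialect as [readProteinMatrix()] with the feature column named
#' `gene_id`.
#' @inheritParams readProteinMatrix
#' @return an [IntensityExperiment-class], linear scale.
#' @export
readTranscriptMatrix <- function(path, design = NULL,
                                 zero_as_missing = TRUE) {
  readProteinMatrix(path, design = design, feature_col = "gene_id",
                    zero_as_missing = zero_as_missing)
}

#' Write an intensity matrix as TSV
#'
#' Emits the same dialect [readProteinMatrix()] reads, so generated data
#' round-trips through the pipeline entry points at full float precision.
#' Missing values are written as empty cells.
#'
#' @param x an [IntensityExperiment-class].
#' @param path output path.
#' @param feature_col header of the feature-id column.
#' @export
writeIntensityMatrix <- function(x, path, feature_col = "Protein.Group") {
  v <- assay(x, "intensity")
  out <- data.frame(id = rownames(v), format(v, digits = 17, trim = TRUE,
                                             scientific = FALSE),
                    check.names = FALSE)
  out[-1][is.na(v)] <- ""
  colnames(out)[1] <- feature_col
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' TSV with columns `sample_id`, `cell_type`, `treatment`, `replicate`.
#' @param path TSV file path.
#' @return `data.frame` with sample ids as rownames.
#' @export
readSampleDesign <- function(path) {
  d <- .readTSV(path)
  need <- c("sample_id", "cell_type", "treatment", "replicate")
  absent <- setdiff(need, colnames(d))
  if (length(absent))
    stop("design lacks column(s): ", paste(absent, collapse = ", "))
  rownames(d) <- d$sample_id
  d$sample_id <- NULL
  d
}

#' Write a sample design table
#' @param design `data.frame` with rownames = sample ids and columns
#'   `cell_type`, `treatment`, `replicate`.
#' @param path output path.
#' @export
writeSampleDesign <- function(design, path) {
  out <- cbind(sample_id = rownames(design), as.data.frame(design))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-to-protein identifier mapping
#'
#' Two-column TSV (`gene_id`, `protein_group`). The mapping is applied as
#' given: features absent from it are dropped from integration, never
#' invented.
#' @param path TSV file path.
#' @return `data.frame` with columns `gene_id`, `protein_group`.
#' @export
readGeneProteinMap <- function(path) {
  m <- .readTSV(path)
  absent <- setdiff(c("gene_id", "protein_group"), colnames(m))
  if (length(absent))
    stop("mapping lacks column(s): ", paste(absent, collapse = ", "))
  m[, c("gene_id", "protein_group")]
}

#' Read a precursor-level phosphopeptide report
#'
#' Long TSV with columns `precursor_id`, `protein_group`, `positions`
#' (";"-separated 1-based integers), `residues` (";"-separated S/T/Y),
#' `localization_probs` (";"-separated floats in \[0,1\]), `multiplicity`,
#' followed by one intensity column per sample.
#'
#' @param path TSV file path.
#' @param zero_as_missing treat intensity 0 as missing (default `TRUE`).
#' @return a [PhosphoReport-class].
#' @export
readPhosphoReport <- function(path, zero_as_missing = TRUE) {
  tab <- .readTSV(path)
  meta_cols <- c("precursor_id", "protein_group", "positions", "residues",
                 "localization_probs", "multiplicity")
  absent <- setdiff(meta_cols, colnames(tab))
  if (length(absent))
    stop("phospho report lacks column(s): ", paste(absent, collapse = ", "))
  splitNum <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                 as.numeric)
  probs <- splitNum(tab$localization_probs)
  for (i in seq_along(probs)) {
    p <- probs[[i]]
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
      stop("localization probability outside [0, 1] at row ", i)
  }
  smp <- setdiff(colnames(tab), meta_cols)
  v <- as.matrix(tab[, smp, drop = FALSE])
  storage.mode(v) <- "double"
  if (zero_as_missing) v[!is.na(v) & v == 0] <- NA_real_
  rep <- PhosphoReport(
    precursor_id = tab$precursor_id,
    protein_group = tab$protein_group,
    positions = lapply(splitNum(tab$positions), as.integer),
    residues = strsplit(as.character(tab$residues), ";", fixed = TRUE),
    localization_probs = probs,
    multiplicity = tab$multiplicity,
    intensities = v
  )
  .msg("read phospho report: ", nrow(tab), " precursors x ", length(smp),
       " samples from ", path)
  rep
}

#' Write a precursor-level phosphopeptide report as TSV
#' @param report a [PhosphoReport-class].
#' @param path output path.
#' @export
writePhosphoReport <- function(report, path) {
  pc <- precursorData(report)
  v <- intensities(report)
  joinNum <- function(l) vapply(l, function(z)
    paste(format(z, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = ";"), character(1))
  out <- data.frame(
    precursor_id = pc$precursor_id,
    protein_group = pc$protein_group,
    positions = vapply(pc$positions, paste, character(1), collapse = ";"),
    residues = vapply(pc$residues, paste, character(1), collapse = ";"),
    localization_probs = joinNum(as.list(pc$localization_probs)),
    multiplicity = pc$multiplicity,
    format(v, digits = 17, trim = TRUE, scientific = FALSE),
    check.names = FALSE
  )
  out[-(1:6)][is.na(v)] <- ""
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
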