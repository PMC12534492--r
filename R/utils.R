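#' @importFrom withr with_seed
NULL

# derive a deterministic sub-seed for a pipeline stage, kept within the
# 32-bit integer range
.subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

.msg <- function(...) {
  if (isTRUE(getOption("phosphonorm.verbose", TRUE))) message(...)
}

# log2-scale replicate noise sd that yields a given linear-scale CV under a
# log-normal model: CV^2 = exp(sigma_ln^2) - 1
.cvToLog2Sd <- function(cv) sqrt(log(1 + cv^2)) / log(2)

# sample labels "<cell>_<treat>_<rep>" and matching design data.frame
.makeDesign <- function(cell_types, treatments, n_replicates) {
  d <- expand.grid(replicate = seq_len(n_replicates),
                   treatment = treatments, cell_type = cell_types,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c("cell_type", "treatment", "replicate")]
  rownames(d) <- paste(d$cell_type, d$treatment, d$replicate, sep = "_")
  d
}

# resolve a (cell_type, treatment) selector against a design; NA in a slot
# means "any"
.selectSamples <- function(design, cell_type = NA, treatment = NA) {
  keep <- rep(TRUE, nrow(design))
  if (!is.na(cell_type)) keep <- keep & design$cell_type == cell_type
  if (!is.na(treatment)) keep <- keep & design$treatment == treatment
  rownames(design)[keep]
}

# leading accession of a ";"-separated protein group string
.leadingAccession <- function(x) sub(";.*$", "", x)

.groupKey <- function(design) paste(design$cell_type, design$treatment, sep = ".")
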