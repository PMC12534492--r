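options(phosphonorm.verbose = FALSE)

# log2-scale IntensityExperiment straight from a matrix
log2IE <- function(v) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("F%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
  ie <- IntensityExperiment(2^v, scale = "linear")
  log2Transform(ie)
}

# two-group design over the columns of a matrix: first half A, second half B
twoGroupDesign <- function(n_per_group, cell_type = "beta") {
  d <- data.frame(
    cell_type = cell_type,
    treatment = rep(c("control", "IFNg"), each = n_per_group),
    replicate = rep(seq_len(n_per_group), 2))
  rownames(d) <- paste(d$cell_type, d$treatment, d$replicate, sep = "_")
  d
}

# rank-based AUC: probability that a value drawn from `pos` exceeds one
# drawn from `neg`
rankAUC <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
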