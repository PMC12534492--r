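#' Proteome-corrected phosphosite fold change
#'
#' Subtracts the parent protein's log2 fold change from the phosphosite's.
#' A corrected fold change of 0 means the phosphorylation stoichiometry did
#' not change between conditions even though the site's abundance did (e.g.
#' phospho log2 FC 2 on a protein with log2 FC 2 corrects to 0).
#'
#' @param log2fc_phospho,log2fc_protein finite log2 fold changes.
#' @return `log2fc_phospho - log2fc_protein`.
#' @examples
#' correctFoldChange(2, 2)    # 0: pure protein-driven change
#' correctFoldChange(1.5, 0.5)
#' @export
correctFoldChange <- function(log2fc_phospho, log2fc_protein) {
  if (any(!is.finite(log2fc_phospho)) || any(!is.finite(log2fc_protein)))
    stop("fold changes must be finite")
  log2fc_phospho - log2fc_protein
}

#' Damping ratio of a corrected phosphosite fold change
#'
#' The ratio of corrected to original log2 fold change, clamped to \[0,1\].
#' The clamping encodes the boundary behaviour of the p-value dampening:
#' protein regulation at least as strong as the phospho regulation (ratio
#' <= 0) must force a dampened p-value of 1, and a correction that would
#' *increase* apparent regulation (ratio > 1) must never make the p-value
#' more significant. An unregulated site (original fold change 0) gets
#' ratio 1: there is nothing to dampen.
#'
#' @param log2fc_original original (phospho-level) log2 fold change.
#' @param log2fc_corrected proteome-corrected log2 fold change.
#' @return damping ratio in \[0,1\] (vectorized).
#' @export
dampingRatio <- function(log2fc_original, log2fc_corrected) {
  if (any(!is.finite(log2fc_original)) || any(!is.finite(log2fc_corrected)))
    stop("fold changes must be finite")
  r <- ifelse(log2fc_original == 0, 1, log2fc_corrected / log2fc_original)
  pmin(pmax(r, 0), 1)
}

#' Exponential p-value dampening
#'
#' Conservatively weakens a phosphosite p-value as a function of how much
#' of its fold change survives proteome correction:
#' \deqn{p' = 10^{\log_{10}(p_{ptm}) \cdot r_{FC}}}
#' with \eqn{r_{FC} \in [0,1]} the damping ratio. At \eqn{r_{FC} = 1} the
#' p-value is unchanged; at \eqn{r_{FC} = 0} (protein regulation as strong
#' as or stronger than the phospho regulation) it becomes exactly 1.
#' Because the transform is exponential on the logged p-value, each 0.1
#' drop in \eqn{r_{FC}} costs a tenth of the p-value's orders of magnitude.
#'
#' @param p_ptm raw phosphosite p-value in (0, 1]; exact zeros are floored
#'   at 1e-300 with a warning.
#' @param r_fc damping ratio in \[0,1\], see [dampingRatio()].
#' @return dampened p-value in \[`p_ptm`, 1\] (vectorized).
#' @examples
#' dampenPValue(0.001, 0)    # 1
#' dampenPValue(0.01, 0.5)   # 0.1
#' @export
dampenPValue <- function(p_ptm, r_fc) {
  if (any(is.na(p_ptm)) || any(p_ptm < 0) || any(p_ptm > 1))
    stop("p_ptm must lie in [0, 1]")
  if (any(is.na(r_fc)) || any(r_fc < 0) || any(r_fc > 1))
    stop("r_fc must lie in [0, 1]")
  if (any(p_ptm == 0)) {
    warning("p_ptm of 0 floored at 1e-300 before dampening")
    p_ptm <- pmax(p_ptm, 1e-300)
  }
  10^(log10(p_ptm) * r_fc)
}

#' Proteome normalization of a phosphosite differential-expression table
#'
#' Joins each phosphosite's differential-expression record to its parent
#' protein group's record from the unenriched proteome (matched on the
#' leading accession of the protein group), subtracts the protein log2 fold
#' change, derives the damping ratio and dampens the phosphosite p-value.
#' Sites whose parent protein was not tested in the proteome keep their raw
#' fold change and p-value with `matched = FALSE` and ratio 1 — flagged,
#' not dropped. Benjamini-Hochberg adjustment is re-applied across the
#' dampened p-values of all tested sites so downstream significance calls
#' reflect the corrected evidence.
#'
#' @param phospho_de [differentialExpression()] table for the collapsed
#'   phosphosite matrix.
#' @param protein_de [differentialExpression()] table for the matched
#'   proteome, same contrast.
#' @param site_to_protein `data.frame` with columns `site_id`,
#'   `protein_group` mapping each phosphosite to its parent protein group.
#'   Defaults to parsing the site id (`<protein_group>_<residue><pos>`).
#' @return `data.frame` with columns `site_id`, `protein_group`,
#'   `log2fc_phospho`, `log2fc_protein`, `log2fc_corrected`, `r_fc`,
#'   `p_ptm`, `p_dampened`, `p_adj`, `matched`.
#' @export
normalizePhosphoDataset <- function(phospho_de, protein_de,
                                    site_to_protein = NULL) {
  ca <- attr(phospho_de, "contrast"); cb <- attr(protein_de, "contrast")
  if (!is.null(ca) && !is.null(cb) && !identical(ca, cb))
    stop("contrast mismatch between phospho ('", ca, "') and proteome ('",
         cb, "') tables")
  if (is.null(site_to_protein)) {
    site_to_protein <- data.frame(
      site_id = phospho_de$feature_id,
      protein_group = sub("_[STY][0-9]+$", "", phospho_de$feature_id))
  }
  pg <- site_to_protein$protein_group[
    match(phospho_de$feature_id, site_to_protein$site_id)]
  prot_idx <- match(.leadingAccession(pg),
                    .leadingAccession(protein_de$feature_id))
  prot_tested <- !is.na(prot_idx) & protein_de$tested[prot_idx] %in% TRUE
  fc_prot <- ifelse(prot_tested, protein_de$log2fc[prot_idx], NA_real_)

  tested <- phospho_de$tested
  matched <- tested & prot_tested
  fc_ph <- phospho_de$log2fc
  fc_corr <- ifelse(matched, fc_ph - fc_prot, fc_ph)
  r <- rep(1, nrow(phospho_de))
  r[matched] <- dampingRatio(fc_ph[matched], fc_corr[matched])
  p_damp <- rep(NA_real_, nrow(phospho_de))
  p_damp[tested] <- dampenPValue(phospho_de$p_raw[tested], r[tested])
  p_adj <- rep(NA_real_, nrow(phospho_de))
  p_adj[tested] <- p.adjust(p_damp[tested], method = "BH")

  out <- data.frame(
    site_id = phospho_de$feature_id,
    protein_group = pg,
    log2fc_phospho = fc_ph,
    log2fc_protein = fc_prot,
    log2fc_corrected = ifelse(tested, fc_corr, NA_real_),
    r_fc = ifelse(tested, r, NA_real_),
    p_ptm = phospho_de$p_raw,
    p_dampened = p_damp,
    p_adj = p_adj,
    matched = matched,
    row.names = NULL
  )
  attr(out, "contrast") <- ca
  attr(out, "r_fc_policy") <-
    "ratio clamped to [0,1]; r = 1 when original log2 FC = 0"
  .msg("normalizePhosphoDataset: ", sum(matched), "/", sum(tested),
       " tested sites matched to a proteome record")
  out
}
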