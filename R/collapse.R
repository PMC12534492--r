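#' Collapse precursor records to a class-I phosphosite matrix
#'
#' A precursor contributes to the site (protein group, position, residue)
#' exactly when that site's localization probability is at or above the
#' cutoff (default 0.75, the class-I criterion); the decision is per site,
#' so a multiply-phosphorylated precursor may support one confident site and
#' fail another. Site intensity per sample is the sum of the contributing
#' precursors' intensities; missing precursor values are ignored and a site
#' with no observed contributor in a sample stays missing. Summation is the
#' linear-aggregation default of the Perseus peptide-collapse workflow and
#' preserves intensity mass.
#'
#' @param report a [PhosphoReport-class] (linear-scale intensities).
#' @param loc_cutoff localization probability cutoff in \[0,1\].
#' @return list with `sites` (an [IntensityExperiment-class], linear, rows
#'   keyed `<protein_group>_<residue><position>`) and `provenance`
#'   (`data.frame` mapping each site to its contributing precursor ids,
#'   one row per (site, precursor) assignment).
#' @examples
#' rep <- PhosphoReport("p1", "P1", list(12L), list("S"), list(0.99), 1L,
#'                      matrix(100, 1, 1, dimnames = list("p1", "s1")))
#' collapseToSites(rep)$sites
#' @export
collapseToSites <- function(report, loc_cutoff = 0.75) {
  stopifnot(is(report, "PhosphoReport"))
  if (loc_cutoff < 0 || loc_cutoff > 1)
    stop("loc_cutoff must lie in [0, 1]")
  pc <- precursorData(report)
  v <- intensities(report)
  # expand to one row per (precursor, candidate site), then filter
  npos <- lengths(pc$positions)
  prec_row <- rep(seq_len(nrow(pc)), npos)
  pos <- unlist(pc$positions, use.names = FALSE)
  res <- unlist(pc$residues, use.names = FALSE)
  prob <- unlist(pc$localization_probs, use.names = FALSE)
  keep <- which(prob >= loc_cutoff)
  empty <- function() IntensityExperiment(
    matrix(numeric(0), 0, ncol(v),
           dimnames = list(character(0), colnames(v))), scale = "linear")
  if (!length(keep)) {
    return(list(sites = empty(),
                provenance = data.frame(site_id = character(0),
                                        precursor_id = character(0))))
  }
  prec_row <- prec_row[keep]
  site_id <- paste0(pc$protein_group[prec_row], "_", res[keep], pos[keep])
  f <- factor(site_id, levels = sort(unique(site_id)))
  agg <- rowsum(ifelse(is.na(v[prec_row, , drop = FALSE]), 0,
                       v[prec_row, , drop = FALSE]), f)
  nobs <- rowsum((!is.na(v[prec_row, , drop = FALSE])) * 1, f)
  agg[nobs == 0] <- NA_real_
  prov <- data.frame(site_id = as.character(f),
                     precursor_id = pc$precursor_id[prec_row])
  prov <- prov[order(prov$site_id, prov$precursor_id), , drop = FALSE]
  rownames(prov) <- NULL
  .msg("collapseToSites: ", nrow(agg), " class-I sites from ", nrow(pc),
       " precursors (cutoff ", loc_cutoff, ")")
  list(sites = IntensityExperiment(agg, scale = "linear"), provenance = prov)
}

#' Identification counts for a collapsed phosphosite matrix
#'
#' @param sites an [IntensityExperiment-class] of collapsed sites.
#' @param report the source [PhosphoReport-class].
#' @return list with `n_sites_total`, `n_precursors_total` (distinct
#'   precursor ids in the report), `per_sample` (`data.frame` of quantified
#'   site and precursor counts per sample).
#' @export
countIdentifications <- function(sites, report) {
  sv <- intensities(sites)
  pv <- intensities(report)
  list(
    n_sites_total = nrow(sv),
    n_precursors_total = length(unique(precursorData(report)$precursor_id)),
    per_sample = data.frame(
      sample_id = colnames(sv),
      n_sites = as.integer(colSums(!is.na(sv))),
      n_precursors = as.integer(colSums(!is.na(pv))[colnames(sv)])
    )
  )
}
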