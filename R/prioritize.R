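#' Default frequency thresholds
#'
#' Minor-allele-frequency filter thresholds by inheritance mode (strict
#' "<"): 0.01 for autosomal recessive, 0.001 for autosomal dominant.
#' X-linked uses the dominant threshold. \code{vus_af} is the ultra-rare
#' cutoff (0.01\% = 1e-4) required of a possibly-solved candidate.
#'
#' @return named list of thresholds.
#' @export
defaultThresholds <- function() {
  list(AR = 0.01, AD = 0.001, XL = 0.001, vus_af = 1e-4)
}

#' Match gene panels to a proband
#'
#' Returns the panels whose HPO terms intersect the proband's positive
#' terms, ordered by descending overlap count with ties broken by panel id.
#' If no panel overlaps, falls back to the panel mapped from the proband's
#' diagnostic category.
#'
#' @param hpoPositive character vector of the proband's positive HPO terms.
#' @param category the proband's diagnostic category.
#' @param panels panel data.frame (see \code{\link{defaultPanels}}).
#' @return character vector of matched panel ids, best first.
#' @export
matchPanels <- function(hpoPositive, category, panels) {
  if (nrow(panels) == 0) validationError("panel set is empty")
  perPanel <- unique(panels[, c("panel_id", "hpo_terms")])
  overlap <- vapply(strsplit(perPanel$hpo_terms, ";", fixed = TRUE),
                    function(terms) length(intersect(terms, hpoPositive)),
                    integer(1))
  hit <- overlap > 0
  if (!any(hit)) {
    fallback <- categoryPanelId(category)
    if (is.na(category) || !fallback %in% perPanel$panel_id)
      validationError("no panel resolvable: no HPO overlap and unknown category '",
                      category, "'")
    return(fallback)
  }
  ids <- perPanel$panel_id[hit]
  ids[order(-overlap[hit], ids)]
}

#' Inheritance-specific frequency filter
#'
#' A variant passes iff its maximum allele frequency across catalogs is
#' strictly below the threshold for the gene's inheritance mode (0.01 AR,
#' 0.001 AD/XL). Unobserved (NA or absent) frequencies count as 0 and pass.
#'
#' @param afs numeric vector of per-catalog allele frequencies.
#' @param mode inheritance mode, one of \code{"AR"}, \code{"AD"},
#'   \code{"XL"}.
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return logical.
#' @examples
#' mafPass(0.005, "AR")   # TRUE
#' mafPass(0.005, "AD")   # FALSE
#' mafPass(0.01,  "AR")   # FALSE (strict)
#' @export
mafPass <- function(afs, mode, thresholds = defaultThresholds()) {
  if (!mode %in% c("AR", "AD", "XL"))
    validationError("inheritance mode must be AR, AD or XL")
  afs <- afs[!is.na(afs)]
  if (length(afs) && (any(afs < 0) || any(afs > 1)))
    validationError("allele frequencies must lie in [0, 1]")
  maxAf <- if (length(afs)) max(afs) else 0
  maxAf < thresholds[[mode]]
}

#' Zygosity consistency of a candidate gene group
#'
#' Recessive genes require a biallelic genotype (one homozygote or at
#' least two heterozygous variants, assumed in trans); dominant genes need
#' one variant; X-linked genes require hemizygosity in males and follow
#' the dominant rule in females.
#'
#' @param zygosities character vector of zygosities (\code{"het"},
#'   \code{"hom"}, \code{"hemi"}) of the variants in one gene.
#' @param mode inheritance mode.
#' @param sex \code{"M"} or \code{"F"} (used for XL genes).
#' @return logical; an empty group returns \code{FALSE}.
#' @export
zygosityConsistent <- function(zygosities, mode, sex = NA_character_) {
  if (length(zygosities) == 0) return(FALSE)
  switch(mode,
    AR = any(zygosities == "hom") || sum(zygosities == "het") >= 2,
    AD = length(zygosities) >= 1,
    XL = if (identical(sex, "M")) any(zygosities == "hemi")
         else length(zygosities) >= 1,
    validationError("inheritance mode must be AR, AD or XL"))
}

#' Prioritize a proband's variants
#'
#' Applies the three-stage reduction: restrict to genes of the proband's
#' matched panels, apply the inheritance-specific frequency filter, group
#' by gene, and retain only zygosity-consistent groups. Output ordering is
#' deterministic (gene symbol, then position within gene). Unphased
#' compound heterozygotes are assumed in trans and flagged
#' \code{"phase unconfirmed"}.
#'
#' @param proband one-row data.frame with columns \code{proband_id},
#'   \code{category}, \code{sex}, \code{hpo_pos} (semicolon-separated).
#' @param variants data.frame of the proband's variants (columns
#'   \code{id}, \code{gene}, \code{pos}, \code{zygosity} and \code{af_*}
#'   frequency columns).
#' @param panels panel data.frame.
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return data.frame of candidate groups: \code{proband_id}, \code{gene},
#'   \code{mode}, \code{variant_ids} (semicolon-separated, position
#'   order), \code{n_variants}, \code{phase_note}.
#' @export
prioritizeVariants <- function(proband, variants, panels,
                               thresholds = defaultThresholds()) {
  stopifnot(nrow(proband) == 1)
  hpo <- strsplit(proband$hpo_pos, ";", fixed = TRUE)[[1]]
  ids <- matchPanels(hpo[nzchar(hpo)], proband$category, panels)
  panelGenes <- unique(panels[panels$panel_id %in% ids, c("gene", "mode")])
  empty <- data.frame(proband_id = character(), gene = character(),
                      mode = character(), variant_ids = character(),
                      n_variants = integer(), phase_note = character(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0) return(empty)
  variants <- variants[variants$gene %in% panelGenes$gene, , drop = FALSE]
  if (nrow(variants) == 0) return(empty)
  afCols <- grep("^af_", names(variants), value = TRUE)
  out <- empty
  for (g in sort(unique(variants$gene))) {
    mode <- panelGenes$mode[match(g, panelGenes$gene)]
    vg <- variants[variants$gene == g, , drop = FALSE]
    keep <- vapply(seq_len(nrow(vg)), function(i)
      mafPass(as.numeric(vg[i, afCols]), mode, thresholds), logical(1))
    vg <- vg[keep, , drop = FALSE]
    if (nrow(vg) == 0) next
    if (!zygosityConsistent(vg$zygosity, mode, proband$sex)) next
    vg <- vg[order(vg$pos), , drop = FALSE]
    phase <- if (mode == "AR" && sum(vg$zygosity == "het") >= 2 &&
                 !any(vg$zygosity == "hom")) "phase unconfirmed" else ""
    out <- rbind(out, data.frame(
      proband_id = proband$proband_id, gene = g, mode = mode,
      variant_ids = paste(vg$id, collapse = ";"),
      n_variants = nrow(vg), phase_note = phase,
      stringsAsFactors = FALSE))
  }
  out
}

#' Extended-analysis flag
#'
#' TRUE iff prioritization returned no candidate group, in which case the
#' proband is flagged for extended analyses (structural/copy-number,
#' mitochondrial, repeat-expansion, de novo) outside this package's scope
#' except for the DMD exon-interval engine.
#'
#' @param candidates the result of \code{\link{prioritizeVariants}}.
#' @return logical.
#' @export
flagExtendedAnalysis <- function(candidates) {
  nrow(candidates) == 0
}
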