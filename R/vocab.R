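## Controlled vocabularies for the synthetic cohort: diagnostic categories,
## countries, a small per-category HPO term map, and per-category causal-gene
## mixtures. The four major categories and their weights follow the reported
## cohort composition; the remaining categories are a curated tail, each
## under 7% of the cohort.

#' Diagnostic category vocabulary
#'
#' The controlled set of clinical diagnostic categories recognised by the
#' cohort simulator and the prioritization/outcome machinery.
#'
#' @return character vector of category labels.
#' @export
nmdCategories <- function() {
  c("LGMD", "PN", "CM/CMD", "DMD/BMD",
    "SMA", "FSHD", "myotonic_dystrophy", "mitochondrial",
    "channelopathy", "MND", "NMJ_disorder", "metabolic_myopathy", "other")
}

defaultCategoryWeights <- function() {
  c("LGMD" = 0.181, "PN" = 0.155, "CM/CMD" = 0.094, "DMD/BMD" = 0.086,
    "SMA" = 0.065, "FSHD" = 0.060, "myotonic_dystrophy" = 0.060,
    "mitochondrial" = 0.065, "channelopathy" = 0.050, "MND" = 0.050,
    "NMJ_disorder" = 0.040, "metabolic_myopathy" = 0.050, "other" = 0.044)
}

defaultCountryWeights <- function() {
  c("India" = 0.60, "Brazil" = 0.16, "South Africa" = 0.12,
    "Turkey" = 0.10, "Zambia" = 0.02)
}

## p_solved / p_possibly_solved per category. The four majors are fixed by
## the reported in-depth yields; the pooled tail value (0.29, 0.135) is
## derived so the cohort-wide expected combined rate under the default
## category weights equals the reported overall 56%.
defaultYields <- function() {
  tail <- c(0.29, 0.135)
  y <- rbind(
    "LGMD"    = c(0.44, 0.16),
    "PN"      = c(0.46, 0.15),
    "CM/CMD"  = c(0.53, 0.19),
    "DMD/BMD" = c(0.98, 0.00))
  for (cat in setdiff(nmdCategories(), rownames(y)))
    y <- rbind(y, matrix(tail, 1, dimnames = list(cat)))
  colnames(y) <- c("p_solved", "p_possibly_solved")
  y
}

## Small packaged category -> HPO term vocabulary (>= 3 terms/category).
## Real ontology traversal is deliberately out of scope; these are literal
## term sets used for panel alignment.
categoryHpoTerms <- function() {
  list(
    "LGMD"               = c("HP:0008997", "HP:0003701", "HP:0003560", "HP:0003236"),
    "PN"                 = c("HP:0009830", "HP:0002460", "HP:0001284", "HP:0003477"),
    "CM/CMD"             = c("HP:0001252", "HP:0001270", "HP:0003198", "HP:0003560"),
    "DMD/BMD"            = c("HP:0003391", "HP:0008981", "HP:0003236", "HP:0003560"),
    "SMA"                = c("HP:0002380", "HP:0003202", "HP:0001252"),
    "FSHD"               = c("HP:0003691", "HP:0010628", "HP:0001324"),
    "myotonic_dystrophy" = c("HP:0002486", "HP:0000508", "HP:0003202"),
    "mitochondrial"      = c("HP:0003198", "HP:0000508", "HP:0001251"),
    "channelopathy"      = c("HP:0003768", "HP:0002486", "HP:0001324"),
    "MND"                = c("HP:0002380", "HP:0002493", "HP:0003202"),
    "NMJ_disorder"       = c("HP:0003473", "HP:0000508", "HP:0001324"),
    "metabolic_myopathy" = c("HP:0003546", "HP:0002913", "HP:0003236"),
    "other"              = c("HP:0001324", "HP:0003202", "HP:0001252"))
}

## Per-category causal-gene mixtures: gene, inheritance mode, mixture weight,
## and an optional mechanism label (used for PMP22, where deletion,
## duplication and point mutation are tracked as distinct mechanisms).
defaultGeneMix <- function() {
  mk <- function(cat, gene, mode, weight, mechanism = NA_character_)
    data.frame(category = cat, gene = gene, mode = mode, weight = weight,
               mechanism = mechanism, stringsAsFactors = FALSE)
  rbind(
    mk("PN", c("GJB1", "PMP22", "MFN2", "MPZ", "PRX", "SH3TC2", "NEFL",
               "HSPB1", "IGHMBP2", "GDAP1"),
       c("XL", "AD", "AD", "AD", "AR", "AR", "AD", "AD", "AR", "AR"),
       c(0.35, 0.17, 0.10, 0.08, 0.07, 0.07, 0.05, 0.05, 0.03, 0.03),
       c(NA, "duplication", NA, NA, NA, NA, NA, NA, NA, NA)),
    mk("LGMD", c("DYSF", "CAPN3", "GNE", "SGCA", "FKRP", "ANO5", "CAV3",
                 "TTN", "COL6A1"),
       c("AR", "AR", "AR", "AR", "AR", "AR", "AD", "AR", "AD"),
       c(0.27, 0.24, 0.08, 0.08, 0.08, 0.07, 0.06, 0.06, 0.06)),
    mk("CM/CMD", c("STAC3", "RYR1", "LAMA2", "NEB", "COL6A2", "COL6A3",
                   "ACTA1", "TPM3", "SELENON"),
       c("AR", "AR", "AR", "AR", "AR", "AR", "AD", "AD", "AR"),
       c(0.35, 0.20, 0.12, 0.08, 0.07, 0.06, 0.05, 0.04, 0.03)),
    mk("DMD/BMD", "DMD", "XL", 1),
    mk("SMA", "SMN1", "AR", 1),
    mk("FSHD", "SMCHD1", "AD", 1),
    mk("myotonic_dystrophy", c("DMPK", "CNBP"), c("AD", "AD"), c(0.8, 0.2)),
    mk("mitochondrial", c("POLG", "TWNK", "TYMP"), c("AR", "AD", "AR"),
       c(0.5, 0.25, 0.25)),
    mk("channelopathy", c("SCN4A", "CLCN1"), c("AD", "AR"), c(0.5, 0.5)),
    mk("MND", c("SOD1", "ALS2"), c("AD", "AR"), c(0.5, 0.5)),
    mk("NMJ_disorder", c("CHRNE", "RAPSN", "DOK7"), c("AR", "AR", "AR"),
       c(0.6, 0.2, 0.2)),
    mk("metabolic_myopathy", c("GAA", "PYGM", "CPT2"), c("AR", "AR", "AR"),
       c(0.5, 0.3, 0.2)),
    mk("other", c("COL6A1", "RYR1"), c("AD", "AR"), c(0.5, 0.5)))
}

## Genes on the X chromosome (zygosity "hemi" is only legal here).
X_LINKED_GENES <- c("GJB1", "DMD", "ATP7A", "AIFM1")

geneChrom <- function(gene) {
  ifelse(gene %in% X_LINKED_GENES, "X",
         as.character(1 + (abs(vapply(gene, function(g)
           sum(utf8ToInt(g)), numeric(1))) %% 22)))
}

#' Default gene panels
#'
#' One panel per diagnostic category, built from the per-category causal
#' gene mixtures and the packaged category HPO vocabulary. Panels mirror the
#' expert-review panel model: each entry is a gene with an inheritance mode,
#' and each panel carries the HPO terms it aligns to.
#'
#' @return a data.frame with columns \code{panel_id}, \code{name},
#'   \code{gene}, \code{mode} and a semicolon-separated \code{hpo_terms}
#'   column (constant within a panel).
#' @export
defaultPanels <- function() {
  mix <- defaultGeneMix()
  hpo <- categoryHpoTerms()
  do.call(rbind, lapply(split(mix, mix$category), function(m) {
    cat <- m$category[1]
    data.frame(panel_id = paste0("panel_", gsub("[^A-Za-z0-9]", "_", cat)),
               name = cat, gene = m$gene, mode = m$mode,
               hpo_terms = paste(hpo[[cat]], collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

## Map category -> panel_id for the no-HPO-overlap fallback.
categoryPanelId <- function(category) {
  paste0("panel_", gsub("[^A-Za-z0-9]", "_", category))
}
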