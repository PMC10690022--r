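#' @import methods
NULL

#' CohortConfig: parameters of the synthetic NMD cohort generator
#'
#' An S4 container for every tunable of the synthetic-cohort model: the
#' diagnostic-category mixture, sex ratio, age model, per-category
#' diagnostic-yield probabilities, per-category causal-gene mixtures, the
#' per-country dystrophinopathy variant-type mixtures, the intron
#' breakpoint-weight map, the decoy-variant load and the novel-variant
#' fraction. Defaults encode the reported composition of the multinational
#' cohort the simulator emulates (see \code{\link{cohortConfig}}).
#'
#' @slot seed integer master seed; per-proband substreams are derived from it.
#' @slot categoryWeights named probability vector over \code{\link{nmdCategories}}.
#' @slot countryWeights named probability vector over recruiting countries.
#' @slot maleFraction probability a proband is male.
#' @slot ageModel named numeric: \code{paediatric_fraction} (weight of the
#'   under-18 component), \code{paediatric_max} (upper age of the uniform
#'   paediatric component), \code{adult_shape}, \code{adult_scale} (gamma
#'   component shifted to start at \code{paediatric_max}).
#' @slot yields matrix (category x 2) of \code{p_solved},
#'   \code{p_possibly_solved}.
#' @slot geneMix data.frame of (category, gene, mode, weight, mechanism).
#' @slot dmdCountryTypeMix matrix (country x 4) of probabilities over
#'   (deletion, nonsense, duplication, splice).
#' @slot dmdBreakpointWeights named probability vector over intron indices
#'   "0".."78" (0 = the 5' flank, i.e. a deletion starting at exon 1).
#' @slot dmdSpanGeomProb success probability of the truncated geometric
#'   distribution of exon-interval spans.
#' @slot noiseVariantsPerProband nonnegative integer decoy load.
#' @slot novelFraction probability a planted causal variant is novel.
#' @export
setClass("CohortConfig", representation(
  seed = "numeric",
  categoryWeights = "numeric",
  countryWeights = "numeric",
  maleFraction = "numeric",
  ageModel = "numeric",
  yields = "matrix",
  geneMix = "data.frame",
  dmdCountryTypeMix = "matrix",
  dmdBreakpointWeights = "numeric",
  dmdSpanGeomProb = "numeric",
  noiseVariantsPerProband = "numeric",
  novelFraction = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  chk <- function(expr) tryCatch({ expr; NULL }, error = function(e) conditionMessage(e))
  for (m in list(chk(checkProbabilityMap(object@categoryWeights, "category_weights")),
                 chk(checkProbabilityMap(object@countryWeights, "country_weights")),
                 chk(checkProbabilityMap(object@dmdBreakpointWeights, "dmd_breakpoint_weights"))))
    if (!is.null(m)) msg <- c(msg, m)
  if (!all(names(object@categoryWeights) %in% nmdCategories()))
    msg <- c(msg, "category_weights has labels outside the controlled category vocabulary")
  if (object@maleFraction < 0 || object@maleFraction > 1)
    msg <- c(msg, "male_fraction outside [0, 1]")
  if (any(object@yields < 0) || any(rowSums(object@yields) > 1 + 1e-9))
    msg <- c(msg, "per_category_yield rows must be nonnegative with p_solved + p_possibly_solved <= 1")
  for (r in rownames(object@dmdCountryTypeMix)) {
    m <- chk(checkProbabilityMap(
      stats::setNames(object@dmdCountryTypeMix[r, ], colnames(object@dmdCountryTypeMix)),
      paste0("dmd_country_type_mix[", r, "]")))
    if (!is.null(m)) msg <- c(msg, m)
  }
  for (cat in unique(object@geneMix$category)) {
    w <- object@geneMix$weight[object@geneMix$category == cat]
    if (abs(sum(w) - 1) > 1e-9)
      msg <- c(msg, paste0("per_category_gene_mix[", cat, "] does not sum to 1"))
  }
  if (object@noiseVariantsPerProband < 0)
    msg <- c(msg, "noise_variants_per_proband must be nonnegative")
  if (object@novelFraction < 0 || object@novelFraction > 1)
    msg <- c(msg, "novel_fraction outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' DmdExonModel: the 79-exon coding model of the dystrophin muscle transcript
#'
#' Ordered coding-exon lengths (nucleotides) of the full-length Dp427m
#' dystrophin transcript. All reading-frame arithmetic (the frame rule,
#' exon-skipping amenability) is performed on these lengths modulo 3.
#'
#' @slot exon integer vector 1..79.
#' @slot codingLength positive integer coding length of each exon.
#' @slot source transcript identifier string.
#' @export
setClass("DmdExonModel", representation(
  exon = "integer", codingLength = "integer", source = "character"))

setValidity("DmdExonModel", function(object) {
  msg <- character()
  if (!identical(object@exon, 1:79))
    msg <- c(msg, "exon model must contain exactly exons 1..79 in order")
  if (any(object@codingLength <= 0))
    msg <- c(msg, "all coding lengths must be > 0")
  if (sum(object@codingLength) %% 3 != 0)
    msg <- c(msg, "total coding length must be divisible by 3 (complete CDS)")
  if (length(msg)) msg else TRUE
})

#' @describeIn DmdExonModel-class number of exons (always 79 for a valid model)
#' @param object a \code{DmdExonModel}.
#' @export
exonCount <- function(object) length(object@exon)

#' Coding-exon lengths of a DmdExonModel
#' @param object a \code{DmdExonModel}.
#' @return named integer vector of per-exon coding lengths.
#' @export
exonLengths <- function(object) stats::setNames(object@codingLength, object@exon)

#' Category weights of a CohortConfig
#' @param object a \code{CohortConfig}.
#' @return named probability vector.
#' @export
categoryWeights <- function(object) object@categoryWeights

#' Per-category yield probabilities of a CohortConfig
#' @param object a \code{CohortConfig}.
#' @return matrix with columns p_solved, p_possibly_solved.
#' @export
categoryYields <- function(object) object@yields

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig (seed ", object@seed, ")\n", sep = "")
  cat("  categories: ", length(object@categoryWeights),
      " (LGMD ", format(100 * object@categoryWeights["LGMD"]), "%, PN ",
      format(100 * object@categoryWeights["PN"]), "%, ...)\n", sep = "")
  cat("  male fraction: ", object@maleFraction, "\n", sep = "")
  cat("  novel fraction: ", object@novelFraction, "\n", sep = "")
  cat("  decoy variants/proband: ", object@noiseVariantsPerProband, "\n", sep = "")
  cat("  DMD country mixes: ", paste(rownames(object@dmdCountryTypeMix), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "DmdExonModel", function(object) {
  cat("DmdExonModel: ", exonCount(object), " coding exons, total ",
      sum(object@codingLength), " nt [", object@source, "]\n", sep = "")
})
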