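#' Construct a cohort configuration
#'
#' Builds a \code{\linkS4class{CohortConfig}}. Defaults encode the reported
#' structure of the multinational NMD cohort the simulator emulates:
#' category mixture LGMD 18.1\%, PN 15.5\%, CM/CMD 9.4\%, DMD/BMD 8.6\%
#' (remaining categories each under 7\%); 65\% male; ages with median 26
#' years and 35\% aged 18 or under; per-category diagnostic yields
#' (p_solved, p_possibly_solved) of PN (0.46, 0.15), LGMD (0.44, 0.16),
#' CM/CMD (0.53, 0.19), DMD/BMD (0.98, 0) with a pooled (0.29, 0.135) for
#' the tail categories; 29\% of planted causal variants novel; per-country
#' dystrophinopathy variant-type mixtures of India 60:3:0:1 and South
#' Africa 24:8:7:1 (deletion:nonsense:duplication:splice) plus Brazil 1:1
#' deletion:nonsense; and deletion/duplication breakpoint weights
#' concentrated on introns 44-50 with a secondary 5' hotspot over introns
#' 9-20.
#'
#' @param seed integer master seed.
#' @param categoryWeights named probability vector over
#'   \code{\link{nmdCategories}}.
#' @param countryWeights named probability vector over countries.
#' @param maleFraction probability a proband is male.
#' @param ageModel named numeric vector, see
#'   \code{\linkS4class{CohortConfig}}.
#' @param yields matrix (category x 2: p_solved, p_possibly_solved).
#' @param geneMix data.frame (category, gene, mode, weight, mechanism).
#' @param dmdCountryTypeMix matrix (country x type probabilities).
#' @param dmdBreakpointWeights named probability vector over introns
#'   "0".."78".
#' @param dmdSpanGeomProb geometric success probability of exon spans.
#' @param noiseVariantsPerProband decoy variants added per proband.
#' @param novelFraction probability a planted causal variant is novel.
#' @return a validated \code{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(seed = 1)
#' categoryWeights(cfg)[["LGMD"]]
#' @export
cohortConfig <- function(seed = 1L,
                         categoryWeights = defaultCategoryWeights(),
                         countryWeights = defaultCountryWeights(),
                         maleFraction = 0.65,
                         ageModel = defaultAgeModel(),
                         yields = defaultYields(),
                         geneMix = defaultGeneMix(),
                         dmdCountryTypeMix = defaultDmdCountryTypeMix(),
                         dmdBreakpointWeights = defaultDmdBreakpointWeights(),
                         dmdSpanGeomProb = 0.35,
                         noiseVariantsPerProband = 6L,
                         novelFraction = 0.29) {
  new("CohortConfig",
      seed = as.numeric(seed),
      categoryWeights = categoryWeights,
      countryWeights = countryWeights,
      maleFraction = maleFraction,
      ageModel = ageModel,
      yields = yields,
      geneMix = geneMix,
      dmdCountryTypeMix = dmdCountryTypeMix,
      dmdBreakpointWeights = dmdBreakpointWeights,
      dmdSpanGeomProb = dmdSpanGeomProb,
      noiseVariantsPerProband = as.numeric(noiseVariantsPerProband),
      novelFraction = novelFraction)
}

#' Default age model
#'
#' Two-component mixture: a paediatric component, uniform on [0, 18] with
#' weight 0.35 (so 35\% of the cohort is 18 or under), and an adult
#' component, 18 + Gamma(shape 2, scale 8.8). The scale is chosen so the
#' adult component puts probability 0.15/0.65 below age 26, which places
#' the overall cohort median at 26 years.
#'
#' @return named numeric vector of age-model parameters.
#' @export
defaultAgeModel <- function() {
  c(paediatric_fraction = 0.35, paediatric_max = 18,
    adult_shape = 2, adult_scale = 8.8)
}

#' Default per-country dystrophinopathy variant-type mixtures
#'
#' Probabilities over (deletion, nonsense, duplication, splice) per country:
#' India 60/64, 3/64, 0, 1/64; South Africa 24/40, 8/40, 7/40, 1/40;
#' Brazil 1/2, 1/2, 0, 0.
#'
#' @return matrix of per-country type probabilities.
#' @export
defaultDmdCountryTypeMix <- function() {
  m <- rbind(
    "India"        = c(60, 3, 0, 1) / 64,
    "South Africa" = c(24, 8, 7, 1) / 40,
    "Brazil"       = c(1, 1, 0, 0) / 2)
  colnames(m) <- c("deletion", "nonsense", "duplication", "splice")
  m
}

#' Default DMD breakpoint weights
#'
#' Probability that the left breakpoint of a deletion/duplication falls in
#' each intron (index 0 denotes the 5' flank, i.e. the interval starts at
#' exon 1). Mass is concentrated on the distal hotspot introns 44-50 (0.68
#' total, with intron 45 the single most likely) and a proximal 5' hotspot
#' over introns 9-20 (0.18 total); the remaining introns share 0.14.
#'
#' @return named probability vector over "0".."78".
#' @export
defaultDmdBreakpointWeights <- function() {
  w <- stats::setNames(rep(0, 79), as.character(0:78))
  w[as.character(c(44, 45, 46, 47, 48, 49, 50))] <-
    c(0.05, 0.29, 0.10, 0.03, 0.15, 0.03, 0.03)
  w[as.character(9:20)] <- 0.18 / 12
  rest <- names(w)[w == 0]
  w[rest] <- 0.14 / length(rest)
  w / sum(w)
}
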