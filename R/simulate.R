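## Synthetic cohort generation with planted ground truth. One master seed;
## each proband draws from its own deterministic substream, so enlarging
## the cohort never reshuffles earlier probands.

sampleCategorical <- function(p) names(p)[sample.int(length(p), 1, prob = p)]

drawAge <- function(am) {
  if (stats::runif(1) < am[["paediatric_fraction"]])
    stats::runif(1, 0, am[["paediatric_max"]])
  else
    am[["paediatric_max"]] + stats::rgamma(1, shape = am[["adult_shape"]],
                                           scale = am[["adult_scale"]])
}

#' Generate a synthetic NMD cohort with planted truth
#'
#' Draws \code{n} probands (category, country, sex, age, positive/negative
#' HPO terms, relatives) from the configured distributions, together with
#' a planted ground-truth record per proband: the intended diagnostic
#' outcome (drawn from the per-category yield probabilities), the causal
#' gene and inheritance mode (from the per-category gene mixture), and a
#' novelty flag. Deterministic for a fixed config seed.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param n number of probands.
#' @param modality \code{"WES"} forces whole-exome modality for all
#'   probands; \code{"auto"} assigns MLPA to DMD/BMD probands and WES
#'   elsewhere.
#' @return list with \code{probands} and \code{truth} data.frames.
#' @examples
#' sim <- simulateCohort(cohortConfig(seed = 7), n = 50)
#' table(sim$truth$outcome)
#' @export
simulateCohort <- function(config, n, modality = c("auto", "WES")) {
  methods::validObject(config)
  modality <- match.arg(modality)
  hpo <- categoryHpoTerms()
  allTerms <- unlist(hpo, use.names = FALSE)
  mixByCat <- split(config@geneMix, config@geneMix$category)
  id <- sprintf("P%05d", seq_len(n))
  category <- country <- sex <- hpoPos <- hpoNeg <- rel <-
    outcome <- gene <- mode <- mech <- character(n)
  age <- numeric(n)
  novel <- logical(n)
  for (i in seq_len(n)) {
    set.seed(substreamSeed(config@seed, i))
    category[i] <- sampleCategorical(config@categoryWeights)
    country[i] <- sampleCategorical(config@countryWeights)
    sex[i] <- if (stats::runif(1) < config@maleFraction) "M" else "F"
    age[i] <- roundHalfUp(drawAge(config@ageModel), 1)
    terms <- hpo[[category[i]]]
    pos <- sample(terms, sample(2:min(3, length(terms)), 1))
    hpoPos[i] <- paste(pos, collapse = ";")
    hpoNeg[i] <- paste(sample(setdiff(allTerms, terms), 2), collapse = ";")
    nRel <- stats::rpois(1, 0.7)
    rel[i] <- if (nRel > 0)
      paste(sample(c("sibling", "parent", "child"), nRel, replace = TRUE),
            sample(c("affected", "unaffected"), nRel, replace = TRUE,
                   prob = c(0.3, 0.7)), sep = ":", collapse = ";")
      else ""
    y <- config@yields[category[i], ]
    u <- stats::runif(1)
    outcome[i] <- if (u < y[["p_solved"]]) "solved"
      else if (u < y[["p_solved"]] + y[["p_possibly_solved"]]) "possibly_solved"
      else "unsolved"
    mix <- mixByCat[[category[i]]]
    gi <- sample.int(nrow(mix), 1, prob = mix$weight)
    if (outcome[i] == "unsolved") {
      gene[i] <- NA; mode[i] <- NA; mech[i] <- NA; novel[i] <- NA
    } else {
      gene[i] <- mix$gene[gi]; mode[i] <- mix$mode[gi]
      mech[i] <- mix$mechanism[gi]
      novel[i] <- stats::runif(1) < config@novelFraction
    }
  }
  list(probands = data.frame(
         proband_id = id, country = country, category = category, sex = sex,
         age = age, hpo_pos = hpoPos, hpo_neg = hpoNeg, relatives = rel,
         modality = if (modality == "WES") rep("WES", n)
           else ifelse(category == "DMD/BMD", "MLPA", "WES"),
         stringsAsFactors = FALSE),
       truth = data.frame(
         proband_id = id, outcome = outcome, causal_gene = gene,
         mode = mode, mechanism = mech, novel = novel,
         causal_variant_ids = "", stringsAsFactors = FALSE))
}

## consequence vocabulary for decoys and planted point variants
CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice",
                  "inframe_indel", "exonic_deletion", "exonic_duplication",
                  "other")

plantHgvs <- function(consequence, pos) {
  switch(consequence,
    missense = sprintf("c.%dA>G", pos),
    nonsense = sprintf("c.%dC>T", pos),
    frameshift = sprintf("c.%ddel", pos),
    splice = sprintf("c.%d+1G>A", pos),
    inframe_indel = sprintf("c.%d_%ddel", pos, pos + 2),
    exonic_deletion = sprintf("c.%d_%ddel", pos, pos + 300),
    exonic_duplication = sprintf("c.%d_%ddup", pos, pos + 300),
    sprintf("c.%dG>C", pos))
}

## Evidence templates planted on causal variants. Solved probands get a
## P- or LP-supporting set (PM2 is added downstream from the frequency);
## possibly-solved get a VUS-supporting set.
plantEvidence <- function(outcome) {
  if (outcome == "solved") {
    if (stats::runif(1) < 0.5) "PVS1;PS3" else "PS1;PM1"
  } else {
    "PP3"
  }
}

plantZygosity <- function(mode, sex) {
  switch(mode,
    AR = if (stats::runif(1) < 0.6) "hom" else "cmphet",
    AD = "het",
    XL = if (identical(sex, "M")) "hemi" else "het")
}

#' Generate variant observations for one proband
#'
#' Plants causal variant(s) consistent with the proband's truth record --
#' pathogenic/likely-pathogenic evidence for solved probands, an
#' ultra-rare (< 0.01\% frequency) in-silico-supported VUS for possibly
#' solved, nothing for unsolved -- with zygosity matching the inheritance
#' mode (homozygous or two heterozygous variants for recessive genes,
#' hemizygous for X-linked males). Adds the configured number of decoy
#' variants with frequencies drawn log-uniformly over [1e-6, 0.05] so that
#' both MAF filter thresholds are exercised; decoys carry no in-silico
#' support.
#'
#' @param proband one-row proband data.frame.
#' @param truth the matching one-row truth data.frame.
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param probandIndex integer index used to derive the variant substream
#'   seed (taken from the proband id when omitted).
#' @return list with \code{variants} (data.frame) and \code{truth} (the
#'   truth row with \code{causal_variant_ids} filled in).
#' @export
simulateVariants <- function(proband, truth, config, probandIndex = NULL) {
  stopifnot(nrow(proband) == 1, nrow(truth) == 1)
  if (!identical(proband$proband_id, truth$proband_id))
    validationError("truth record does not match proband ",
                    proband$proband_id)
  if (is.null(probandIndex))
    probandIndex <- as.integer(sub("^P", "", proband$proband_id))
  set.seed(substreamSeed(config@seed + 1, probandIndex))
  mix <- config@geneMix
  rows <- list()
  vcount <- 0
  addVariant <- function(gene, consequence, zygosity, af, evidence,
                         insilico, mechanism = NA_character_, pos = NULL) {
    vcount <<- vcount + 1
    ## causal variants get a cohort-unique position so their gene+HGVS
    ## novelty keys never collide; decoys draw freely
    if (is.null(pos)) pos <- sample.int(5000, 1)
    if (!is.na(mechanism) && mechanism == "duplication")
      consequence <- "exonic_duplication"
    data.frame(
      id = sprintf("%s_v%02d", proband$proband_id, vcount),
      proband_id = proband$proband_id, gene = gene,
      transcript = paste0("TX_", gene), hgvs_c = plantHgvs(consequence, pos),
      consequence = consequence, zygosity = zygosity,
      chrom = geneChrom(gene), pos = pos,
      af_gnomad = af[1], af_local = af[2],
      insilico_support = insilico, acmg_evidence = evidence,
      stringsAsFactors = FALSE)
  }
  causalIds <- character()
  if (truth$outcome != "unsolved") {
    zyg <- plantZygosity(truth$mode, proband$sex)
    ev <- plantEvidence(truth$outcome)
    insil <- TRUE
    ## causal allele frequency: ultra-rare, often absent from catalogs
    drawAf <- function() {
      a <- if (stats::runif(1) < 0.5) NA_real_
        else 10^stats::runif(1, -6, -4.05)
      c(a, NA_real_)
    }
    nVar <- if (zyg == "cmphet") 2 else 1
    for (k in seq_len(nVar)) {
      rows[[length(rows) + 1]] <- addVariant(
        truth$causal_gene,
        consequence = sample(c("missense", "nonsense", "frameshift",
                               "splice"), 1),
        zygosity = if (zyg == "cmphet") "het" else zyg,
        af = drawAf(), evidence = ev, insilico = insil,
        mechanism = truth$mechanism, pos = 10000 + 10 * probandIndex + k)
      causalIds <- c(causalIds, rows[[length(rows)]]$id)
    }
  }
  nNoise <- config@noiseVariantsPerProband
  for (k in seq_len(nNoise)) {
    g <- mix$gene[sample.int(nrow(mix), 1)]
    rows[[length(rows) + 1]] <- addVariant(
      g, consequence = sample(CONSEQUENCES[1:5], 1),
      zygosity = if (g %in% X_LINKED_GENES && identical(proband$sex, "M"))
        "hemi" else "het",
      af = c(10^stats::runif(1, -6, log10(0.05)), NA_real_),
      evidence = "", insilico = FALSE)
  }
  variants <- if (length(rows)) do.call(rbind, rows) else NULL
  truth$causal_variant_ids <- paste(causalIds, collapse = ";")
  list(variants = variants, truth = truth)
}

#' Generate variants for a whole cohort
#'
#' Applies \code{\link{simulateVariants}} to every proband, returning the
#' combined variant table and the truth table with causal variant ids
#' resolved.
#'
#' @param sim result of \code{\link{simulateCohort}}.
#' @param config the same \code{\linkS4class{CohortConfig}}.
#' @return list with \code{probands}, \code{variants}, \code{truth}.
#' @export
simulateCohortVariants <- function(sim, config) {
  out <- vector("list", nrow(sim$probands))
  tr <- vector("list", nrow(sim$probands))
  for (i in seq_len(nrow(sim$probands))) {
    r <- simulateVariants(sim$probands[i, , drop = FALSE],
                          sim$truth[i, , drop = FALSE], config, i)
    out[[i]] <- r$variants
    tr[[i]] <- r$truth
  }
  list(probands = sim$probands,
       variants = do.call(rbind, Filter(Negate(is.null), out)),
       truth = do.call(rbind, tr))
}

#' Build synthetic reference catalogs for novelty determination
#'
#' Constructs a known-variant catalog containing the keys of every
#' non-novel planted causal variant (plus all decoy variants observed in
#' population catalogs), so that \code{\link{isNovel}} recovers exactly
#' the planted novelty flags.
#'
#' @param variants cohort variant table.
#' @param truth cohort truth table (with \code{causal_variant_ids}).
#' @return data.frame with columns \code{catalog}, \code{gene},
#'   \code{hgvs_c}, \code{af}.
#' @export
simulateCatalogs <- function(variants, truth) {
  known <- list()
  knownIds <- unlist(strsplit(
    truth$causal_variant_ids[!is.na(truth$novel) & !truth$novel], ";"))
  novelIds <- unlist(strsplit(
    truth$causal_variant_ids[!is.na(truth$novel) & truth$novel], ";"))
  ## the generator's contract: keys planted as novel are absent from every
  ## catalog, including by chance key collision with a decoy
  novelKeys <- with(variants[variants$id %in% novelIds, , drop = FALSE],
                    variantKey(gene, hgvs_c))
  causal <- variants[variants$id %in% knownIds, , drop = FALSE]
  causal <- causal[!variantKey(causal$gene, causal$hgvs_c) %in% novelKeys, ,
                   drop = FALSE]
  if (nrow(causal))
    known[[1]] <- data.frame(catalog = "synthetic_clinvar",
                             gene = causal$gene, hgvs_c = causal$hgvs_c,
                             af = causal$af_gnomad,
                             stringsAsFactors = FALSE)
  seen <- variants[!is.na(variants$af_gnomad) &
                     !variants$id %in% c(knownIds, novelIds), , drop = FALSE]
  seen <- seen[!variantKey(seen$gene, seen$hgvs_c) %in% novelKeys, ,
               drop = FALSE]
  if (nrow(seen))
    known[[2]] <- data.frame(catalog = "synthetic_gnomad",
                             gene = seen$gene, hgvs_c = seen$hgvs_c,
                             af = seen$af_gnomad, stringsAsFactors = FALSE)
  do.call(rbind, Filter(Negate(is.null), known))
}

#' Generate a synthetic dystrophinopathy structural-variant cohort
#'
#' Draws per-country variant types from the configured type mixtures, and
#' for deletions/duplications draws the left breakpoint intron from the
#' configured breakpoint-weight map (concentrated on the distal 45-48
#' hotspot and the proximal 5' region) and the exon span from a truncated
#' geometric distribution. Nonsense variants are placed uniformly on
#' exons 4-72, splice variants uniformly on introns 1-78.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param n number of patients.
#' @param countries country labels to draw from (must appear in the
#'   configured type mixture); sampled uniformly unless \code{weights}
#'   given.
#' @param weights optional sampling weights over \code{countries}.
#' @param seed optional seed overriding the config master seed.
#' @return data.frame with columns \code{sample_id}, \code{country},
#'   \code{kind}, \code{first_exon}, \code{last_exon}, \code{locus}.
#' @export
simulateDmdCohort <- function(config, n,
                              countries = c("India", "South Africa"),
                              weights = NULL, seed = NULL) {
  missing <- setdiff(countries, rownames(config@dmdCountryTypeMix))
  if (length(missing))
    configError("dmd_country_type_mix has no entry for: ",
                paste(missing, collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(countries))
  bw <- config@dmdBreakpointWeights
  introns <- as.integer(names(bw))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(substreamSeed(if (is.null(seed)) config@seed + 2 else seed, i))
    country <- countries[sample.int(length(countries), 1, prob = weights)]
    typeP <- config@dmdCountryTypeMix[country, ]
    kind <- sampleCategorical(typeP)
    if (kind %in% c("deletion", "duplication")) {
      L <- introns[sample.int(length(bw), 1, prob = bw)]
      firstExon <- L + 1L
      maxSpan <- min(12L, 79L - L)
      span <- min(1L + stats::rgeom(1, config@dmdSpanGeomProb), maxSpan)
      rows[[i]] <- data.frame(sample_id = sprintf("D%05d", i),
                              country = country, kind = kind,
                              first_exon = firstExon,
                              last_exon = firstExon + span - 1L,
                              locus = NA_character_,
                              stringsAsFactors = FALSE)
    } else {
      locus <- if (kind == "nonsense")
        paste0("exon", sample(4:72, 1)) else paste0("intron", sample(1:78, 1))
      rows[[i]] <- data.frame(sample_id = sprintf("D%05d", i),
                              country = country, kind = kind,
                              first_exon = NA_integer_,
                              last_exon = NA_integer_, locus = locus,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Analytic hotspot probability of the structural-variant generator
#'
#' Computes, by exact enumeration over the finite support of the
#' breakpoint and span distributions, the probability that a generated
#' deletion/duplication has at least one breakpoint within the given
#' intron window. Used as the analytic reference for the empirical
#' hotspot fraction.
#'
#' @param config a \code{\linkS4class{CohortConfig}}.
#' @param hotspotIntrons intron window (default 45-48).
#' @return probability.
#' @export
dmdHotspotProbability <- function(config, hotspotIntrons = 45:48) {
  bw <- config@dmdBreakpointWeights
  introns <- as.integer(names(bw))
  p <- 0
  for (j in seq_along(bw)) {
    L <- introns[j]
    maxSpan <- min(12L, 79L - L)
    spanP <- stats::dgeom(0:(maxSpan - 2), config@dmdSpanGeomProb)
    spanP <- c(spanP, 1 - sum(spanP))          # spans 1..maxSpan, capped tail
    for (s in seq_len(maxSpan)) {
      lastExon <- L + s
      right <- if (lastExon >= 79L) NA_integer_ else lastExon
      hit <- (L %in% hotspotIntrons) ||
        (!is.na(right) && right %in% hotspotIntrons)
      if (hit) p <- p + bw[j] * spanP[s]
    }
  }
  unname(p)
}
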