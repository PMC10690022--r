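#' Classify every variant's ACMG class
#'
#' Parses each variant's evidence-code string, augments it with frequency
#' evidence derived from its catalog allele frequencies, and combines the
#' result into a five-tier class.
#'
#' @param variants variant data.frame with an \code{acmg_evidence} column
#'   (semicolon-separated codes) and \code{af_*} frequency columns.
#' @return the data.frame with an added \code{acmg_class} column.
#' @export
classifyVariants <- function(variants) {
  afCols <- grep("^af_", names(variants), value = TRUE)
  variants$acmg_class <- vapply(seq_len(nrow(variants)), function(i) {
    codes <- strsplit(variants$acmg_evidence[i], ";", fixed = TRUE)[[1]]
    codes <- codes[nzchar(codes)]
    codes <- assignFrequencyEvidence(codes, as.numeric(variants[i, afCols]))
    combineAcmg(codes)
  }, character(1))
  variants
}

#' Diagnostic outcome of one proband
#'
#' Applies the study outcome rules to a proband's prioritized candidate
#' groups. \strong{Solved}: some group has all variants classed
#' Pathogenic/Likely pathogenic and fits the phenotype (the group is
#' already zygosity-consistent, i.e. biallelic for recessive genes).
#' \strong{Possibly solved}: not solved, but some phenotype-fitting group
#' has at least one VUS while every variant in the group is ultra-rare
#' (maximum allele frequency < 0.01\%), has in-silico support, and no
#' variant is benign-side. Otherwise \strong{unsolved}. All qualifying
#' groups are reported, P/LP groups first.
#'
#' @param proband one-row proband data.frame.
#' @param candidates result of \code{\link{prioritizeVariants}} for this
#'   proband.
#' @param variants the proband's variants, already passed through
#'   \code{\link{classifyVariants}}.
#' @param phenotypeFit logical vector, one entry per candidate group
#'   (default all TRUE: prioritization already restricted to
#'   phenotype-matched panel genes).
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return one-row data.frame: \code{proband_id}, \code{outcome},
#'   \code{causal_gene}, \code{causal_variants}, \code{variant_classes},
#'   \code{n_qualifying_groups}, \code{extended_analysis}, \code{notes}.
#' @export
classifyOutcome <- function(proband, candidates, variants,
                            phenotypeFit = rep(TRUE, nrow(candidates)),
                            thresholds = defaultThresholds()) {
  stopifnot(nrow(proband) == 1, length(phenotypeFit) == nrow(candidates))
  if (nrow(candidates) > 0 && is.null(variants$acmg_class))
    validationError("variants must carry an acmg_class column (run classifyVariants)")
  afCols <- grep("^af_", names(variants), value = TRUE)
  ## Within a candidate gene group, outcomes are judged on the qualifying
  ## subset of its variants (a passing decoy sharing the gene must not
  ## spoil a clean diagnostic pair): solved needs a zygosity-consistent
  ## subset of P/LP variants; possibly-solved needs a zygosity-consistent
  ## subset of ultra-rare, in-silico-supported P/LP/VUS variants with at
  ## least one VUS.
  groupInfo <- lapply(seq_len(nrow(candidates)), function(k) {
    ids <- strsplit(candidates$variant_ids[k], ";", fixed = TRUE)[[1]]
    vg <- variants[match(ids, variants$id), , drop = FALSE]
    if (any(is.na(vg$acmg_class)))
      validationError("candidate variant without an ACMG class in gene ",
                      candidates$gene[k])
    mode <- candidates$mode[k]
    maxAf <- vapply(seq_len(nrow(vg)), function(i) {
      a <- as.numeric(vg[i, afCols]); a <- a[!is.na(a)]
      if (length(a)) max(a) else 0
    }, numeric(1))
    plpSel <- vg$acmg_class %in% c("Pathogenic", "Likely pathogenic")
    solved <- phenotypeFit[k] &&
      zygosityConsistent(vg$zygosity[plpSel], mode, proband$sex)
    strongSel <- vg$acmg_class %in% c("Pathogenic", "Likely pathogenic", "VUS") &
      maxAf < thresholds$vus_af & as.logical(vg$insilico_support)
    possibly <- phenotypeFit[k] && !solved &&
      any(vg$acmg_class[strongSel] == "VUS") &&
      zygosityConsistent(vg$zygosity[strongSel], mode, proband$sex)
    sel <- if (solved) plpSel else if (possibly) strongSel else rep(FALSE, nrow(vg))
    list(ids = ids[sel], classes = vg$acmg_class[sel],
         solved = solved, possibly = possibly)
  })
  solvedIdx <- which(vapply(groupInfo, `[[`, logical(1), "solved"))
  possIdx <- which(vapply(groupInfo, `[[`, logical(1), "possibly"))
  if (length(solvedIdx)) {
    outcome <- "solved"; use <- c(solvedIdx, possIdx)
  } else if (length(possIdx)) {
    outcome <- "possibly_solved"; use <- possIdx
  } else {
    outcome <- "unsolved"; use <- integer()
  }
  data.frame(
    proband_id = proband$proband_id,
    outcome = outcome,
    causal_gene = if (length(use)) candidates$gene[use[1]] else NA_character_,
    causal_variants = if (length(use))
      paste(unlist(lapply(groupInfo[use], `[[`, "ids")), collapse = ";")
      else "",
    variant_classes = if (length(use))
      paste(unlist(lapply(groupInfo[use], `[[`, "classes")), collapse = ";")
      else "",
    n_qualifying_groups = length(use),
    extended_analysis = flagExtendedAnalysis(candidates),
    notes = if (length(use)) paste(candidates$phase_note[use], collapse = ";") else "",
    stringsAsFactors = FALSE)
}

#' Classify a whole cohort end to end
#'
#' Runs prioritization and outcome classification for every proband, and
#' determines novelty of each causal variant against the supplied
#' catalogs.
#'
#' @param probands proband data.frame (one row per proband).
#' @param variants variant data.frame for the whole cohort (with
#'   \code{proband_id}).
#' @param panels panel data.frame.
#' @param catalogs optional data.frame of known variants (columns
#'   \code{gene}, \code{hgvs_c}) for novelty determination.
#' @param thresholds see \code{\link{defaultThresholds}}.
#' @return list with \code{outcomes} (one row per proband, with
#'   \code{category}, \code{country}, \code{sex}, \code{modality} joined
#'   in) and \code{causal} (one row per causal variant: gene, hgvs_c,
#'   class, mechanism label, novelty flag).
#' @export
classifyCohort <- function(probands, variants, panels = defaultPanels(),
                           catalogs = NULL, thresholds = defaultThresholds()) {
  variants <- classifyVariants(variants)
  byProband <- split(seq_len(nrow(variants)), variants$proband_id)
  rows <- vector("list", nrow(probands))
  causal <- vector("list", nrow(probands))
  for (i in seq_len(nrow(probands))) {
    pb <- probands[i, , drop = FALSE]
    pv <- variants[byProband[[pb$proband_id]], , drop = FALSE]
    if (is.null(pv)) pv <- variants[0, , drop = FALSE]
    cand <- prioritizeVariants(pb, pv, panels, thresholds)
    rows[[i]] <- classifyOutcome(pb, cand, pv, thresholds = thresholds)
    if (nzchar(rows[[i]]$causal_variants)) {
      ids <- strsplit(rows[[i]]$causal_variants, ";", fixed = TRUE)[[1]]
      vg <- pv[match(ids, pv$id), , drop = FALSE]
      causal[[i]] <- data.frame(
        proband_id = pb$proband_id, category = pb$category,
        gene = vg$gene, hgvs_c = vg$hgvs_c,
        consequence = vg$consequence, acmg_class = vg$acmg_class,
        novel = if (!is.null(catalogs))
          vapply(seq_len(nrow(vg)), function(j)
            isNovel(vg$gene[j], vg$hgvs_c[j], catalogs), logical(1))
          else NA,
        stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, rows)
  keep <- intersect(c("proband_id", "category", "country", "sex", "age",
                      "modality"), names(probands))
  outcomes <- merge(probands[, keep], outcomes, by = "proband_id", sort = FALSE)
  outcomes <- outcomes[match(probands$proband_id, outcomes$proband_id), ]
  rownames(outcomes) <- NULL
  list(outcomes = outcomes,
       causal = if (length(cc <- Filter(Negate(is.null), causal)))
         do.call(rbind, cc) else NULL)
}
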