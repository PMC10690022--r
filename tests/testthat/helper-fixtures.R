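## Small in-code fixtures shared across test files.

## a one-row proband
makeProband <- function(id = "P00001", category = "LGMD", sex = "F",
                        hpo = "HP:0008997;HP:0003701") {
  data.frame(proband_id = id, country = "India", category = category,
             sex = sex, age = 30, hpo_pos = hpo, hpo_neg = "HP:0000508",
             relatives = "", modality = "WES", stringsAsFactors = FALSE)
}

## a variant row compatible with the prioritization/outcome machinery
makeVariant <- function(id, gene, zygosity = "het", af = NA_real_,
                        evidence = "", insilico = FALSE, pos = 100,
                        consequence = "missense",
                        hgvs = sprintf("c.%dA>G", pos)) {
  data.frame(id = id, proband_id = sub("_v.*$", "", id), gene = gene,
             transcript = paste0("TX_", gene), hgvs_c = hgvs,
             consequence = consequence, zygosity = zygosity,
             chrom = "1", pos = pos, af_gnomad = af, af_local = NA_real_,
             insilico_support = insilico, acmg_evidence = evidence,
             stringsAsFactors = FALSE)
}

## a two-panel toy panel set with controllable HPO terms
makePanels <- function() {
  rbind(
    data.frame(panel_id = "panel_LGMD", name = "LGMD",
               gene = c("DYSF", "CAPN3", "CAV3"), mode = c("AR", "AR", "AD"),
               hpo_terms = "HP:0008997;HP:0003701", stringsAsFactors = FALSE),
    data.frame(panel_id = "panel_PN", name = "PN",
               gene = c("GJB1", "MFN2"), mode = c("XL", "AD"),
               hpo_terms = "HP:0009830;HP:0002460", stringsAsFactors = FALSE))
}

## class ordering used by monotonicity checks (benign low, pathogenic high)
classRank <- function(cls) {
  match(cls, c("Benign", "Likely benign", "VUS",
               "Likely pathogenic", "Pathogenic"))
}

## independent re-statement of the ACMG combining algebra as boolean
## expressions over strength counts (dual route to the packaged rule table)
oracleAcmg <- function(codes) {
  nPVS <- sum(codes == "PVS1"); nPS <- sum(grepl("^PS", codes))
  nPM <- sum(grepl("^PM", codes)); nPP <- sum(grepl("^PP", codes))
  nBA <- sum(codes == "BA1"); nBS <- sum(grepl("^BS", codes))
  nBP <- sum(grepl("^BP", codes))
  path <- (nPVS >= 1 && (nPS >= 1 || nPM >= 2 || (nPM >= 1 && nPP >= 1) ||
                           nPP >= 2)) ||
    nPS >= 2 ||
    (nPS >= 1 && (nPM >= 3 || (nPM >= 2 && nPP >= 2) ||
                    (nPM >= 1 && nPP >= 4)))
  lp <- (nPVS >= 1 && nPM >= 1) || (nPS >= 1 && nPM >= 1) ||
    (nPS >= 1 && nPP >= 2) || nPM >= 3 || (nPM >= 2 && nPP >= 2) ||
    (nPM >= 1 && nPP >= 4)
  ben <- nBA >= 1 || nBS >= 2
  lb <- (nBS >= 1 && nBP >= 1) || nBP >= 2
  pSide <- if (path) "Pathogenic" else if (lp) "Likely pathogenic" else NA
  bSide <- if (ben) "Benign" else if (lb) "Likely benign" else NA
  if (!is.na(pSide) && !is.na(bSide)) "VUS"
  else if (!is.na(pSide)) pSide
  else if (!is.na(bSide)) bSide
  else "VUS"
}

## two-sided Fisher p for a 2x2 table by direct hypergeometric summation
oracleFisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1.0)
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- stats::dhyper(ks, r1, r2, c1)
  pObs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(pk[pk <= pObs * (1 + 1e-7)])
}

## reading-frame oracle: lay out one entry per coding nucleotide and count
## what survives the deletion
makeFrameOracle <- function(model) {
  len <- exonLengths(model)
  exonOf <- rep(1:79, times = len)
  function(a, b) {
    if (a == 1 || b == 79) return("inapplicable")
    kept <- sum(!(exonOf %in% a:b))
    if (kept %% 3 == 0) "in_frame" else "out_of_frame"
  }
}
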