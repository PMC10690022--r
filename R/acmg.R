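## ACMG evidence codes and the combining engine. The combining algebra is
## shipped as a packaged, versioned rule table (inst/extdata/
## acmg_combining_rules.csv) rather than hard-coded logic, so tests can
## enumerate it exhaustively.

ACMG_CODES <- c("PVS1",
                paste0("PS", 1:4),
                paste0("PM", 1:6),
                paste0("PP", 1:5),
                "BA1",
                paste0("BS", 1:4),
                paste0("BP", 1:7))

#' Valid ACMG evidence codes
#' @return character vector of the 28 recognised evidence codes.
#' @export
acmgCodes <- function() ACMG_CODES

.acmgRuleCache <- new.env(parent = emptyenv())

#' The packaged ACMG combining-rule table
#'
#' Each row is a firing rule: a class plus the minimum number of codes
#' required in each strength category (PVS/PS/PM/PP/BA/BS/BP).
#'
#' @return data.frame of combining rules.
#' @export
acmgRuleTable <- function() {
  if (is.null(.acmgRuleCache$rules))
    .acmgRuleCache$rules <- utils::read.csv(
      extdataPath("acmg_combining_rules.csv"), comment.char = "#",
      stringsAsFactors = FALSE)
  .acmgRuleCache$rules
}

acmgStrengthCounts <- function(codes) {
  c(pvs = sum(codes == "PVS1"),
    ps = sum(grepl("^PS", codes)),
    pm = sum(grepl("^PM", codes)),
    pp = sum(grepl("^PP", codes)),
    ba = sum(codes == "BA1"),
    bs = sum(grepl("^BS", codes)),
    bp = sum(grepl("^BP", codes)))
}

#' Combine ACMG evidence codes into a variant class
#'
#' Applies the packaged combining-rule table: the strongest
#' pathogenic-side class whose rule fires, or the strongest benign-side
#' class, is returned. If rules fire on both sides the evidence conflicts
#' and the class is VUS; an empty evidence set is VUS.
#'
#' @param codes character vector of evidence codes (subset of
#'   \code{\link{acmgCodes}}); duplicates are ignored.
#' @return one of \code{"Pathogenic"}, \code{"Likely pathogenic"},
#'   \code{"VUS"}, \code{"Likely benign"}, \code{"Benign"}.
#' @examples
#' combineAcmg(c("PVS1", "PS1"))   # Pathogenic
#' combineAcmg(c("PVS1", "PM2"))   # Likely pathogenic
#' combineAcmg("BA1")              # Benign
#' combineAcmg(character())        # VUS
#' @export
combineAcmg <- function(codes) {
  codes <- unique(codes[nzchar(codes)])
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad))
    validationError("unknown ACMG evidence code(s): ", paste(bad, collapse = ", "))
  n <- acmgStrengthCounts(codes)
  rules <- acmgRuleTable()
  fires <- rules$min_pvs <= n["pvs"] & rules$min_ps <= n["ps"] &
    rules$min_pm <= n["pm"] & rules$min_pp <= n["pp"] &
    rules$min_ba <= n["ba"] & rules$min_bs <= n["bs"] &
    rules$min_bp <= n["bp"]
  fired <- rules$class[fires]
  pathSide <- if ("Pathogenic" %in% fired) "Pathogenic"
    else if ("Likely pathogenic" %in% fired) "Likely pathogenic" else NA
  benSide <- if ("Benign" %in% fired) "Benign"
    else if ("Likely benign" %in% fired) "Likely benign" else NA
  if (!is.na(pathSide) && !is.na(benSide)) return("VUS")
  if (!is.na(pathSide)) return(pathSide)
  if (!is.na(benSide)) return(benSide)
  "VUS"
}

#' Map observed allele frequencies onto frequency evidence codes
#'
#' Adds PM2 (absent/ultra-rare: maximum frequency across catalogs below
#' \code{pm2}, or unobserved), BS1 (too common: above \code{bs1}) and BA1
#' (stand-alone benign: above \code{ba1}) to an evidence set, leaving all
#' other codes untouched.
#'
#' @param codes existing evidence codes.
#' @param afs numeric vector of per-catalog allele frequencies (may be
#'   empty or NA = unobserved).
#' @param pm2,bs1,ba1 frequency cutoffs.
#' @return augmented character vector of evidence codes.
#' @export
assignFrequencyEvidence <- function(codes, afs, pm2 = 1e-4, bs1 = 0.01, ba1 = 0.05) {
  afs <- afs[!is.na(afs)]
  if (length(afs) && (any(afs < 0) || any(afs > 1)))
    validationError("allele frequencies must lie in [0, 1]")
  maxAf <- if (length(afs)) max(afs) else 0
  add <- character()
  if (maxAf < pm2) add <- c(add, "PM2")
  if (maxAf > bs1) add <- c(add, "BS1")
  if (maxAf > ba1) add <- c(add, "BA1")
  unique(c(codes, add))
}

#' Variant novelty against reference catalogs
#'
#' A variant is novel iff its key (gene symbol + whitespace-stripped
#' HGVS c. description) is absent from every supplied catalog.
#'
#' @param gene gene symbol (case sensitive).
#' @param hgvsC HGVS c. string.
#' @param catalogs data.frame with columns \code{gene} and \code{hgvs_c}
#'   (and optionally \code{catalog}), or a list of such data.frames.
#' @return logical.
#' @export
isNovel <- function(gene, hgvsC, catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  if (length(catalogs) == 0) {
    warning("no catalogs supplied; novelty is vacuously TRUE")
    return(TRUE)
  }
  key <- variantKey(gene, hgvsC)
  for (cat in catalogs) {
    if (key %in% variantKey(cat$gene, cat$hgvs_c)) return(FALSE)
  }
  TRUE
}

## gene + normalized (whitespace-stripped) HGVS.c, the novelty key
variantKey <- function(gene, hgvsC) {
  paste0(gene, "|", gsub("[[:space:]]+", "", hgvsC))
}
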