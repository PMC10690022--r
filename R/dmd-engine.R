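#' Load the packaged dystrophin exon model
#'
#' Reads the packaged coding-exon length table of the full-length muscle
#' dystrophin transcript (Dp427m, 79 exons) into a
#' \code{\linkS4class{DmdExonModel}}.
#'
#' @return a validated \code{DmdExonModel}.
#' @examples
#' model <- dmdExonModel()
#' exonLengths(model)[c("45", "51", "52", "53")]
#' @export
dmdExonModel <- function() {
  tab <- readPackagedTsv("dmd_exon_lengths.tsv")
  new("DmdExonModel", exon = as.integer(tab$exon),
      codingLength = as.integer(tab$coding_length),
      source = "NM_004006.2 (Dp427m)")
}

checkExonInterval <- function(firstExon, lastExon) {
  if (any(firstExon < 1) || any(lastExon > 79) || any(firstExon > lastExon))
    validationError("exon interval must satisfy 1 <= first_exon <= last_exon <= 79")
}

#' Reading-frame status of a DMD exon-interval variant
#'
#' Applies the dystrophin reading-frame rule: a deletion (or tandem
#' duplication) of exons \code{firstExon..lastExon} is in frame iff the sum
#' of the coding lengths of the affected exons is divisible by 3. Intervals
#' touching the initial (1) or terminal (79) exon are "inapplicable": the
#' rule does not apply at the transcript ends.
#'
#' @param firstExon,lastExon 1-based inclusive exon interval.
#' @param model a \code{\linkS4class{DmdExonModel}}.
#' @return one of \code{"in_frame"}, \code{"out_of_frame"},
#'   \code{"inapplicable"}.
#' @examples
#' model <- dmdExonModel()
#' frameStatus(52, 52, model)   # out_of_frame
#' frameStatus(45, 47, model)   # in_frame
#' @export
frameStatus <- function(firstExon, lastExon, model) {
  checkExonInterval(firstExon, lastExon)
  if (firstExon == 1L || lastExon == 79L) return("inapplicable")
  len <- sum(model@codingLength[firstExon:lastExon])
  if (len %% 3 == 0) "in_frame" else "out_of_frame"
}

#' Predicted severity of a DMD variant
#'
#' Frame-preserving deletions/duplications predict the milder Becker
#' phenotype; frameshifting ones, and truncating point variants (nonsense,
#' small frameshift), predict Duchenne. Intervals where the frame rule is
#' inapplicable are indeterminate.
#'
#' @param kind one of \code{"deletion"}, \code{"duplication"},
#'   \code{"nonsense"}, \code{"splice"}, \code{"small_frameshift"}.
#' @param firstExon,lastExon exon interval (required for
#'   deletion/duplication; ignored otherwise).
#' @param model a \code{\linkS4class{DmdExonModel}}.
#' @return one of \code{"DMD_like"}, \code{"BMD_like"},
#'   \code{"indeterminate"}.
#' @export
predictSeverity <- function(kind, firstExon = NA, lastExon = NA, model = dmdExonModel()) {
  if (kind %in% c("nonsense", "small_frameshift")) return("DMD_like")
  if (kind == "splice") return("indeterminate")
  if (!kind %in% c("deletion", "duplication"))
    validationError("unknown DMD variant kind: ", kind)
  switch(frameStatus(firstExon, lastExon, model),
         out_of_frame = "DMD_like",
         in_frame = "BMD_like",
         inapplicable = "indeterminate")
}

#' Single-exon skipping amenability
#'
#' An out-of-frame deletion is amenable to skipping of \code{exon} iff the
#' exon is immediately adjacent to the deleted interval, the enlarged
#' interval does not touch exon 1 or 79, and removing the enlarged interval
#' restores the reading frame. In-frame or frame-rule-inapplicable
#' deletions are not amenable by definition (returns \code{FALSE}).
#'
#' @param firstExon,lastExon deleted exon interval.
#' @param exon candidate exon to skip (1..79).
#' @param model a \code{\linkS4class{DmdExonModel}}.
#' @return logical.
#' @examples
#' model <- dmdExonModel()
#' skipAmenable(52, 52, 51, model)   # TRUE
#' skipAmenable(52, 52, 45, model)   # FALSE (not adjacent)
#' @export
skipAmenable <- function(firstExon, lastExon, exon, model) {
  checkExonInterval(firstExon, lastExon)
  if (exon < 1 || exon > 79) validationError("exon must be in 1..79")
  if (frameStatus(firstExon, lastExon, model) != "out_of_frame") return(FALSE)
  if (exon != firstExon - 1 && exon != lastExon + 1) return(FALSE)
  lo <- min(firstExon, exon); hi <- max(lastExon, exon)
  identical(frameStatus(lo, hi, model), "in_frame")
}

#' Therapy-relevant skippable exons for a deletion
#'
#' Evaluates \code{\link{skipAmenable}} for each licensed antisense
#' oligonucleotide target exon (45, 51, 53) and each trial-stage target
#' (44), returning the amenable subsets in ascending order.
#'
#' @param firstExon,lastExon deleted exon interval.
#' @param model a \code{\linkS4class{DmdExonModel}}.
#' @param licensed,trial integer vectors of therapy target exons.
#' @return list with elements \code{licensed} and \code{trial}.
#' @examples
#' amenableTherapyExons(52, 52, dmdExonModel())$licensed   # 51 53
#' @export
amenableTherapyExons <- function(firstExon, lastExon, model,
                                 licensed = c(45L, 51L, 53L), trial = 44L) {
  ok <- function(exons) sort(exons[vapply(exons, function(e)
    skipAmenable(firstExon, lastExon, e, model), logical(1))])
  list(licensed = ok(licensed), trial = ok(trial))
}

#' Breakpoint introns of an exon-interval variant
#'
#' Places both breakpoints of an exon-level deletion/duplication in the
#' immediately flanking introns: intron \code{firstExon - 1} and intron
#' \code{lastExon} (intron i lies between exons i and i+1). A boundary at
#' the gene start or end yields the sentinel \code{"5prime"} /
#' \code{"3prime"} instead of an intron index.
#'
#' @param firstExon,lastExon exon interval.
#' @return character vector of length 2 (intron indices as characters, or
#'   sentinels).
#' @examples
#' breakpointIntrons(46, 50)   # "45" "50"
#' breakpointIntrons(1, 3)     # "5prime" "3"
#' @export
breakpointIntrons <- function(firstExon, lastExon) {
  checkExonInterval(firstExon, lastExon)
  left <- if (firstExon == 1) "5prime" else as.character(firstExon - 1)
  right <- if (lastExon == 79) "3prime" else as.character(lastExon)
  c(left, right)
}

#' Intron breakpoint hotspot summary
#'
#' Tabulates, over the deletion/duplication variants of a cohort, how many
#' variants touch each intron with a breakpoint (a variant counts once per
#' intron it touches), and the fraction of variants with at least one
#' breakpoint within the distal hotspot introns 45-48.
#'
#' @param sv data.frame with columns \code{kind}, \code{first_exon},
#'   \code{last_exon} (point variants are ignored).
#' @param hotspotIntrons integer vector defining the hotspot window.
#' @return list with \code{counts} (data.frame intron, n, proportion,
#'   percent display-rounded), \code{n_deldup}, and
#'   \code{fraction_hotspot}.
#' @export
hotspotSummary <- function(sv, hotspotIntrons = 45:48) {
  sv <- sv[sv$kind %in% c("deletion", "duplication"), , drop = FALSE]
  if (nrow(sv) == 0) {
    warning("no deletion/duplication variants; empty hotspot summary")
    return(list(counts = data.frame(intron = character(), n = integer(),
                                    proportion = numeric(), percent = numeric()),
                n_deldup = 0L, fraction_hotspot = NA_real_))
  }
  bps <- mapply(function(a, b) unique(breakpointIntrons(a, b)),
                sv$first_exon, sv$last_exon, SIMPLIFY = FALSE)
  tab <- table(unlist(bps))
  introns <- names(tab)
  num <- suppressWarnings(as.numeric(introns))
  ord <- order(is.na(num), num)
  counts <- data.frame(intron = introns[ord], n = as.integer(tab[ord]),
                       stringsAsFactors = FALSE)
  counts$proportion <- counts$n / nrow(sv)
  counts$percent <- roundHalfUp(100 * counts$proportion)
  inHot <- vapply(bps, function(b) any(b %in% as.character(hotspotIntrons)),
                  logical(1))
  list(counts = counts, n_deldup = nrow(sv),
       fraction_hotspot = mean(inHot))
}

#' Country-by-type contingency table of DMD variants
#'
#' @param sv data.frame with columns \code{country} and \code{kind}.
#' @return integer matrix, rows = countries, columns = (deletion, nonsense,
#'   duplication, splice).
#' @export
variantTypeTable <- function(sv) {
  types <- c("deletion", "nonsense", "duplication", "splice")
  if (nrow(sv) == 0)
    return(matrix(integer(), 0, 4, dimnames = list(NULL, types)))
  bad <- setdiff(unique(sv$kind), types)
  if (length(bad)) validationError("unknown DMD variant type(s): ",
                                   paste(bad, collapse = ", "))
  tab <- table(factor(sv$country), factor(sv$kind, levels = types))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), types))
  m
}

#' Per-patient DMD report
#'
#' Convenience wrapper producing frame status, predicted severity and
#' therapy-amenable exons for each structural-variant record.
#'
#' @param sv data.frame with columns \code{sample_id}, \code{country},
#'   \code{kind}, \code{first_exon}, \code{last_exon}.
#' @param model a \code{\linkS4class{DmdExonModel}}.
#' @return data.frame with appended \code{frame}, \code{severity},
#'   \code{amenable_licensed}, \code{amenable_trial} columns.
#' @export
dmdReport <- function(sv, model = dmdExonModel()) {
  res <- sv
  res$frame <- NA_character_
  res$severity <- NA_character_
  res$amenable_licensed <- ""
  res$amenable_trial <- ""
  for (i in seq_len(nrow(sv))) {
    k <- sv$kind[i]
    if (k %in% c("deletion", "duplication")) {
      res$frame[i] <- frameStatus(sv$first_exon[i], sv$last_exon[i], model)
      res$severity[i] <- predictSeverity(k, sv$first_exon[i], sv$last_exon[i], model)
      if (k == "deletion" && res$frame[i] == "out_of_frame") {
        am <- amenableTherapyExons(sv$first_exon[i], sv$last_exon[i], model)
        res$amenable_licensed[i] <- paste(am$licensed, collapse = ";")
        res$amenable_trial[i] <- paste(am$trial, collapse = ";")
      }
    } else {
      res$frame[i] <- "inapplicable"
      res$severity[i] <- predictSeverity(k, model = model)
    }
  }
  res
}
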