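#' Diagnostic yield table
#'
#' Tabulates solved / possibly-solved / unsolved counts by the requested
#' grouping keys, with unrounded percentages recomputed from the counts, a
#' combined solved+possibly-solved column, and display percentages rounded
#' half-up to integers in the style of cohort reports.
#'
#' @param outcomes outcome data.frame (from \code{\link{classifyCohort}},
#'   or any data.frame with an \code{outcome} column).
#' @param by character vector of grouping columns (empty = whole cohort).
#' @return data.frame of per-group counts and percentages.
#' @export
yieldTable <- function(outcomes, by = character()) {
  if (nrow(outcomes) == 0) validationError("outcomes is empty")
  bad <- setdiff(by, names(outcomes))
  if (length(bad))
    validationError("unknown grouping key(s): ", paste(bad, collapse = ", "))
  groups <- if (length(by)) split(outcomes, outcomes[, by, drop = FALSE], drop = TRUE)
    else list(cohort = outcomes)
  rows <- lapply(names(groups), function(g) {
    o <- groups[[g]]
    n <- nrow(o)
    ns <- sum(o$outcome == "solved")
    np <- sum(o$outcome == "possibly_solved")
    nu <- sum(o$outcome == "unsolved")
    cbind(
      if (length(by)) stats::setNames(as.data.frame(
        as.list(strsplit(g, ".", fixed = TRUE)[[1]]),
        col.names = by, stringsAsFactors = FALSE), by)
      else data.frame(group = "cohort", stringsAsFactors = FALSE),
      data.frame(n = n, solved = ns, possibly_solved = np, unsolved = nu,
                 pct_solved = 100 * ns / n,
                 pct_possibly_solved = 100 * np / n,
                 pct_combined = 100 * (ns + np) / n,
                 pct_solved_display = roundHalfUp(100 * ns / n),
                 pct_combined_display = roundHalfUp(100 * (ns + np) / n)))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Causal-gene frequency table
#'
#' Counts solved/possibly-solved probands per causal gene, with PMP22
#' deletion, duplication and point mutation tracked as distinct mechanism
#' labels ("PMP22 del", "PMP22 dup", "PMP22 pm"). Percentages are relative
#' to all probands in \code{outcomes}.
#'
#' @param outcomes outcome data.frame (denominator).
#' @param causal causal-variant data.frame (from
#'   \code{\link{classifyCohort}}).
#' @return data.frame (gene label, count, percent), sorted descending.
#' @export
geneFrequency <- function(outcomes, causal) {
  if (is.null(causal) || nrow(causal) == 0)
    return(data.frame(gene = character(), n = integer(), percent = numeric()))
  lab <- causal$gene
  mech <- ifelse(causal$consequence == "exonic_duplication", "dup",
          ifelse(causal$consequence == "exonic_deletion", "del", "pm"))
  lab[lab == "PMP22"] <- paste("PMP22", mech[lab == "PMP22"])
  perProband <- unique(data.frame(proband_id = causal$proband_id, gene = lab,
                                  stringsAsFactors = FALSE))
  tab <- sort(table(perProband$gene), decreasing = TRUE)
  data.frame(gene = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / nrow(outcomes),
             stringsAsFactors = FALSE)
}

#' Novel-variant fraction
#'
#' The proportion of causal variants flagged novel, overall and per
#' diagnostic category.
#'
#' @param causal causal-variant data.frame with \code{novel} and
#'   \code{category} columns.
#' @return list with \code{overall} (proportion, NA with a warning if
#'   there are no causal variants) and \code{by_category} (data.frame).
#' @export
novelFraction <- function(causal) {
  if (is.null(causal) || nrow(causal) == 0 || all(is.na(causal$novel))) {
    warning("no causal variants with novelty flags; fraction undefined")
    return(list(overall = NA_real_,
                by_category = data.frame(category = character(),
                                         n = integer(), novel = integer(),
                                         fraction = numeric())))
  }
  causal <- causal[!is.na(causal$novel), , drop = FALSE]
  byCat <- do.call(rbind, lapply(split(causal, causal$category), function(x)
    data.frame(category = x$category[1], n = nrow(x),
               novel = sum(x$novel), fraction = mean(x$novel),
               stringsAsFactors = FALSE)))
  rownames(byCat) <- NULL
  list(overall = mean(causal$novel), by_category = byCat)
}
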