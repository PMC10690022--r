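## Readers and writers for the interchange formats: a minimal VCF for
## variant observations, TSV for phenotypes and panels, JSON for truth and
## manifests, plus the packaged study-table fixtures.

VCF_INFO_KEYS <- c("GENE", "TX", "HGVSC", "CSQ", "ZYG", "AF_GNOMAD",
                   "AF_LOCAL", "INSILICO", "ACMG_EV")

#' Write variant observations as minimal VCF
#'
#' Variant observations are encoded one per VCF record; all
#' package-specific fields travel in INFO keys (GENE, TX, HGVSC, CSQ, ZYG,
#' AF_GNOMAD, AF_LOCAL, INSILICO, ACMG_EV). Coordinates are 1-based with
#' literal REF/ALT placeholders, as this minimal profile carries
#' annotation-level records rather than raw calls.
#'
#' @param variants variant data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeVariantsVcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=nmdx",
           sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
                   VCF_INFO_KEYS, VCF_INFO_KEYS),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  fmtAf <- function(x) ifelse(is.na(x), ".", format(x, digits = 17,
                                                    scientific = TRUE))
  info <- paste0("GENE=", variants$gene,
                 ";TX=", variants$transcript,
                 ";HGVSC=", variants$hgvs_c,
                 ";CSQ=", variants$consequence,
                 ";ZYG=", variants$zygosity,
                 ";AF_GNOMAD=", fmtAf(variants$af_gnomad),
                 ";AF_LOCAL=", fmtAf(variants$af_local),
                 ";INSILICO=", as.integer(variants$insilico_support),
                 ";ACMG_EV=", ifelse(nzchar(variants$acmg_evidence),
                                     gsub(";", "|", variants$acmg_evidence,
                                          fixed = TRUE), "."))
  rec <- paste(variants$chrom, variants$pos, variants$id, "N", "A", ".",
               "PASS", info, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

parseInfo <- function(info) {
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  stats::setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "",
                         character(1)),
                  vapply(kv, `[[`, character(1), 1))
}

#' Read variant observations from minimal VCF
#'
#' Parses the minimal profile written by \code{\link{writeVariantsVcf}}.
#' Round-trips losslessly for the supported INFO keys. Malformed records
#' are collected into an \code{errors} attribute (and reported with a
#' warning) rather than silently dropped; a file whose records lack the
#' mandatory GENE key is a format error.
#'
#' @param path VCF file path.
#' @return variant data.frame; malformed lines in
#'   \code{attr(, "errors")}.
#' @export
readVariantsVcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  rows <- vector("list", length(body))
  errs <- character()
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) { errs <- c(errs, sprintf("line %d: too few columns", i)); next }
    info <- parseInfo(f[8])
    if (!"GENE" %in% names(info))
      validationError("format error: missing mandatory INFO key GENE at record ", i)
    num <- function(x) if (is.na(x) || x == ".") NA_real_ else as.numeric(x)
    afG <- num(info["AF_GNOMAD"]); afL <- num(info["AF_LOCAL"])
    if (!is.na(afG) && (afG < 0 || afG > 1)) {
      errs <- c(errs, sprintf("line %d: AF_GNOMAD out of range", i)); next
    }
    rows[[i]] <- data.frame(
      id = f[3],
      proband_id = sub("_v[0-9]+$", "", f[3]),
      gene = unname(info["GENE"]), transcript = unname(info["TX"]),
      hgvs_c = unname(info["HGVSC"]), consequence = unname(info["CSQ"]),
      zygosity = unname(info["ZYG"]), chrom = f[1], pos = as.integer(f[2]),
      af_gnomad = afG, af_local = afL,
      insilico_support = info["INSILICO"] == "1",
      acmg_evidence = if (info["ACMG_EV"] == ".") ""
        else gsub("|", ";", info["ACMG_EV"], fixed = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  if (length(errs)) {
    warning(length(errs), " malformed VCF record(s) skipped")
    attr(out, "errors") <- errs
  }
  out
}

#' Write / read phenotype tables
#'
#' Phenotypes travel as 1-based human-readable TSV with one row per
#' proband.
#'
#' @param probands proband data.frame.
#' @param path file path.
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
writePhenotypes <- function(probands, path) {
  utils::write.table(probands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(hpo_pos = "character",
                                         hpo_neg = "character"))
  mandatory <- c("proband_id", "category", "sex", "age", "hpo_pos", "hpo_neg")
  miss <- setdiff(mandatory, names(df))
  if (length(miss))
    validationError("phenotype file missing mandatory column(s): ",
                    paste(miss, collapse = ", "))
  df
}

#' Write / read gene panel tables
#' @param panels panel data.frame (see \code{\link{defaultPanels}}).
#' @param path file path.
#' @return \code{path} (writer) or the data.frame (reader).
#' @export
writePanels <- function(panels, path) {
  utils::write.table(panels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writePanels
#' @export
readPanels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("panel_id", "gene", "mode", "hpo_terms"), names(df))
  if (length(miss))
    validationError("panel file missing column(s): ",
                    paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$mode), c("AR", "AD", "XL"))
  if (length(bad))
    validationError("panel file has unknown inheritance mode(s): ",
                    paste(bad, collapse = ", "))
  df
}

#' Load a packaged study-table fixture
#'
#' Returns one of the packaged reference tables transcribed from a large
#' multinational NMD cohort study: the novel-variant tables of the
#' peripheral-neuropathy (\code{"pn_novel"}, 22 rows), CM/CMD
#' (\code{"cm_cmd_novel"}, 21 rows) and LGMD plus DMD/BMD
#' (\code{"lgmd_dmd_novel"}, 17 rows) cohorts, or the per-country
#' dystrophinopathy variant-type counts (\code{"dmd_counts"}). Gene
#' symbols and variant strings are kept exactly as printed in the source
#' tables (including probable typos), with a \code{note} column.
#'
#' @param id fixture identifier.
#' @return data.frame.
#' @examples
#' nrow(loadFixture("pn_novel"))    # 22
#' loadFixture("dmd_counts")
#' @export
loadFixture <- function(id = c("pn_novel", "cm_cmd_novel", "lgmd_dmd_novel",
                               "dmd_counts")) {
  id <- match.arg(id)
  file <- switch(id,
                 pn_novel = "novel_variants_pn.tsv",
                 cm_cmd_novel = "novel_variants_cm_cmd.tsv",
                 lgmd_dmd_novel = "novel_variants_lgmd_dmd.tsv",
                 dmd_counts = "dmd_country_type_counts.tsv")
  tab <- readPackagedTsv(file)
  expected <- c(pn_novel = 22L, cm_cmd_novel = 21L, lgmd_dmd_novel = 17L,
                dmd_counts = 2L)
  if (nrow(tab) != expected[[id]])
    stop("packaging error: fixture ", id, " has ", nrow(tab),
         " rows, expected ", expected[[id]])
  tab
}

#' Write outcomes as JSON lines
#' @param outcomes outcome data.frame.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeOutcomesJsonl <- function(outcomes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(outcomes)))
    writeLines(jsonlite::toJSON(as.list(outcomes[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  invisible(path)
}

#' @rdname writeOutcomesJsonl
#' @export
readOutcomesJsonl <- function(path) {
  rows <- lapply(readLines(path), function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    as.data.frame(x, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
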