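#' Round half up
#'
#' Rounds to the nearest integer (or given number of digits) with exact
#' halves rounded away from zero toward the larger magnitude, matching the
#' "60 (94\%)" style of percentage reporting in clinical cohort papers.
#' Base \code{round()} uses banker's rounding, which does not.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(c(0.5, 1.5, 2.5))   # 1 2 3
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Derive a per-record substream seed from a master seed so that record i's
## draws are unaffected by cohort size. Kept below 2^31 - 1.
substreamSeed <- function(seed, i) {
  (abs(as.numeric(seed)) + 7919 * as.numeric(i)) %% 2147483647
}

## stop() with a class so callers/tests can distinguish configuration errors
configError <- function(...) {
  stop(errorCondition(paste0(...), class = c("nmdx_config_error", "error")))
}

validationError <- function(...) {
  stop(errorCondition(paste0(...), class = c("nmdx_validation_error", "error")))
}

checkProbabilityMap <- function(p, what, tol = 1e-9) {
  if (is.null(names(p)) || any(!nzchar(names(p))))
    configError(what, " must be a named numeric vector")
  if (any(p < 0) || any(p > 1))
    configError(what, " has entries outside [0, 1]")
  if (abs(sum(p) - 1) > tol)
    configError(what, " does not sum to 1 (sum = ", format(sum(p), digits = 12), ")")
  invisible(TRUE)
}

extdataPath <- function(file) {
  p <- system.file("extdata", file, package = "nmdx")
  if (!nzchar(p)) stop("packaged data file not found: ", file)
  p
}

readPackagedTsv <- function(file) {
  utils::read.delim(extdataPath(file), comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
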