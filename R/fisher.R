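#' Exact Fisher test for r x c contingency tables
#'
#' Implements the exact conditional test of independence from first
#' principles. Under the null, conditional on both margins, the probability
#' of a table T is the multivariate hypergeometric mass
#' \deqn{P(T) = \frac{\prod_i r_i!\; \prod_j c_j!}{N!\; \prod_{ij} t_{ij}!}.}
#' The two-sided p-value uses the probability-mass criterion: the sum of
#' P(T') over all tables T' with the observed margins whose probability
#' does not exceed that of the observed table. \code{method = "exact"}
#' enumerates all margin-consistent tables by recursive traversal with a
#' log-factorial cache; \code{method = "montecarlo"} draws \code{B} tables
#' from the margin-conditional null (Patefield's algorithm via
#' \code{\link[stats]{r2dtable}}) and returns the add-one estimator
#' \eqn{(1 + \#\{P(T_b) \le P(T_{obs})\}) / (B + 1)}.
#'
#' @param tab nonnegative integer matrix (at least 2 x 2).
#' @param method \code{"exact"} or \code{"montecarlo"}.
#' @param B number of Monte-Carlo draws.
#' @param seed optional integer seed for the Monte-Carlo method.
#' @param maxTotal grand-total bound above which exact enumeration refuses
#'   to run (use the Monte-Carlo method instead).
#' @return the p-value (numeric scalar in [0, 1]).
#' @examples
#' fisherExactRC(matrix(c(1, 1, 1, 1), 2))        # 1
#' tab <- rbind(India = c(60, 3, 0, 1), SA = c(24, 8, 7, 1))
#' fisherExactRC(tab) < 0.001
#' @export
fisherExactRC <- function(tab, method = c("exact", "montecarlo"),
                          B = 10000L, seed = NULL, maxTotal = 200L) {
  method <- match.arg(method)
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    validationError("contingency table must be at least 2 x 2")
  if (any(tab < 0) || any(tab != floor(tab)))
    validationError("contingency table must contain nonnegative integers")
  N <- sum(tab)
  if (N == 0) validationError("contingency table has grand total 0")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("table has a zero row/column margin; p = 1")
    return(1.0)
  }
  lf <- lgamma(seq_len(N + 1))          # lf[k+1] = log(k!)
  lfact <- function(k) lf[k + 1]
  const <- sum(lfact(rs)) + sum(lfact(cs)) - lfact(N)
  logp <- function(m) const - sum(lfact(m))
  lpObs <- logp(tab)
  tol <- 1e-7
  if (method == "montecarlo") {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::r2dtable(B, rs, cs)
    lps <- vapply(sims, logp, numeric(1))
    return((1 + sum(lps <= lpObs + tol)) / (B + 1))
  }
  if (N > maxTotal)
    stop("grand total ", N, " exceeds the exact enumeration bound (",
         maxTotal, "); use method = \"montecarlo\"")
  r <- nrow(tab); cc <- ncol(tab)
  psum <- 0
  cur <- matrix(0L, r, cc)
  ## fill rows top to bottom, within a row left to right; the last cell of
  ## each row and the whole last row are forced by the margins
  recurse <- function(i, j, rowLeft, colLeft) {
    if (i == r) {
      if (any(colLeft < 0)) return()
      cur[r, ] <<- colLeft
      lp <- logp(cur)
      if (lp <= lpObs + tol) psum <<- psum + exp(lp)
      return()
    }
    if (j == cc) {
      if (rowLeft > colLeft[cc]) return()
      cur[i, cc] <<- rowLeft
      colLeft[cc] <- colLeft[cc] - rowLeft
      recurse(i + 1, 1, rs[i + 1], colLeft)
      return()
    }
    hi <- min(rowLeft, colLeft[j])
    for (v in 0:hi) {
      cur[i, j] <<- v
      cl <- colLeft; cl[j] <- cl[j] - v
      recurse(i, j + 1, rowLeft - v, cl)
    }
  }
  recurse(1, 1, rs[1], cs)
  min(1, psum)
}

#' Pearson chi-square statistic (diagnostic)
#'
#' The plain chi-square statistic without continuity correction, provided
#' purely as a cross-check diagnostic alongside \code{\link{fisherExactRC}};
#' it is not used for inference.
#'
#' @param tab nonnegative integer matrix.
#' @return list with \code{statistic} and \code{df}.
#' @export
chisqStat <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}
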