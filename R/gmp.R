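## The generalized mean p-value and its Bayes-factor interpretation.

# validate a vector of constituent p-values; optionally clip exact zeros up to
# `floor` instead of rejecting them
.check_pvalues <- function(p, floor = NULL) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("p must be a non-empty numeric vector of p-values")
  if (anyNA(p) || any(!is.finite(p)))
    stop("p-values must be finite and non-missing")
  if (any(p > 1)) stop("p-values must not exceed 1")
  if (!is.null(floor)) {
    stopifnot(is.numeric(floor), length(floor) == 1L, floor > 0, floor <= 1)
    p <- pmax(p, floor)
  }
  if (any(p <= 0))
    stop("p-values must be strictly positive; a p-value of 0 makes the GMP ",
         "undefined for r < 0 (use the 'floor' argument to clip instead)")
  p
}

# exponents within this distance of 0 are treated as the geometric mean:
# 1/r amplifies rounding noise beyond any useful precision closer to zero
.GMP_R_GEOMETRIC <- 1e-8

#' Generalized mean p-value
#'
#' Computes the generalized mean \eqn{M_{r,K}(p_1,\dots,p_K) =
#' ((p_1^r + \dots + p_K^r)/K)^{1/r}} of a vector of p-values.  The family
#' interpolates the minimum (\eqn{r \to -\infty}), harmonic mean
#' (\eqn{r = -1}), geometric mean (\eqn{r \to 0}), arithmetic mean
#' (\eqn{r = 1}) and maximum (\eqn{r \to \infty}).  `r = 0` (or any value
#' within 1e-8 of it) is treated as the geometric-mean sentinel and
#' `r = -Inf` / `r = Inf` return the minimum / maximum.
#'
#' The power mean is evaluated through a log-sum-exp so that exponents as
#' extreme as `r = -10` with p-values near `1e-300` neither overflow nor
#' underflow.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param r the GMP exponent; any extended real.
#' @param floor optional positive value; p-values of exactly 0 are clipped up
#'   to it instead of raising an error.
#' @return The generalized mean, a single number in `[min(p), max(p)]`.
#' @seealso [gclt_threshold()] and [rra_threshold()] for significance
#'   thresholds; [mean_bayes_factor()] for the model-averaging
#'   interpretation.
#' @examples
#' compute_gmp(c(0.2, 0.4), r = 1)            # arithmetic mean, 0.3
#' compute_gmp(c(0.01, 0.04, 0.25, 0.81), -1) # harmonic mean
#' compute_gmp(c(0.2, 0.4), r = -Inf)         # minimum
#' @export
compute_gmp <- function(p, r, floor = NULL) {
  p <- .check_pvalues(p, floor)
  stopifnot(is.numeric(r), length(r) == 1L, !is.na(r))
  if (is.infinite(r)) return(if (r < 0) min(p) else max(p))
  if (abs(r) < .GMP_R_GEOMETRIC) return(exp(mean(log(p))))
  lp <- r * log(p)
  m <- max(lp)
  exp((m + log(mean(exp(lp - m)))) / r)
}

# row-wise GMP over a matrix of p-values (replicates x tests); same
# conventions as compute_gmp, used by the simulation harness
.gmp_rows <- function(P, r) {
  if (is.infinite(r)) {
    idx <- max.col(if (r < 0) -P else P, ties.method = "first")
    return(P[cbind(seq_len(nrow(P)), idx)])
  }
  L <- log(P)
  if (abs(r) < .GMP_R_GEOMETRIC) return(exp(rowMeans(L)))
  L <- r * L
  m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  exp((m + log(rowMeans(exp(L - m)))) / r)
}

#' Tail index of the GMP summands
#'
#' Under the null, \eqn{p^r} is Pareto with tail index \eqn{\lambda = -1/r}
#' for \eqn{r < 0} and bounded (index \eqn{\infty}) for \eqn{r > 0}.  The
#' tail index selects the extremal stable limit law of the sum
#' \eqn{\sum p_i^r}; for distributional purposes any \eqn{\lambda > 2}
#' behaves as \eqn{\lambda = 2} (the Normal case).
#'
#' @param r nonzero GMP exponent.
#' @return The tail index, possibly `Inf`.
#' @export
tail_index <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, !is.na(r))
  if (r == 0)
    stop("the geometric mean (r = 0) has no tail index; use Fisher's method")
  if (r < 0) -1 / r else Inf
}

#' Moments of a power of a uniform p-value
#'
#' Mean and variance of \eqn{X = p^r} for \eqn{p \sim U(0,1)}: the mean is
#' \eqn{1/(1+r)} when \eqn{r > -1} and infinite otherwise; the variance is
#' \eqn{r^2/((1+r)^2(1+2r))} when \eqn{r > -1/2} and infinite otherwise.
#' These moments supply the centering and scaling constants of the GCLT
#' thresholds in the light-tailed regime.
#'
#' @param r finite nonzero GMP exponent.
#' @return A list with components `mean` and `variance` (either may be
#'   `Inf`).
#' @export
power_moments <- function(r) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r != 0)
  list(mean = if (r > -1) 1 / (1 + r) else Inf,
       variance = if (r > -1 / 2) r^2 / ((1 + r)^2 * (1 + 2 * r)) else Inf)
}

#' Model-averaged Bayes factor for a vector of p-values
#'
#' When each p-value follows a Beta(\eqn{\xi}, \eqn{\zeta}) distribution
#' under its alternative (with \eqn{0 < \xi \le 1 \le \zeta}, so the density
#' is non-increasing), the likelihood ratio of test \eqn{i} is
#' \eqn{BF_i = p_i^{\xi-1}(1-p_i)^{\zeta-1} / B(\xi,\zeta)} and the mean
#' Bayes factor over mutually exclusive alternatives is their average.  With
#' \eqn{\zeta = 1} and \eqn{\xi = 1 + r} this equals
#' \eqn{(1+r) M_{r,K}^r}, linking GMPs with \eqn{-1 < r < 0} to
#' model-averaged likelihood ratios.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param xi Beta shape under the alternative, in (0, 1].
#' @param zeta second Beta shape, at least 1.
#' @return The mean Bayes factor, a nonnegative number.
#' @examples
#' mean_bayes_factor(c(0.01, 0.04), xi = 0.5)  # 3.75
#' @export
mean_bayes_factor <- function(p, xi, zeta = 1) {
  p <- .check_pvalues(p)
  stopifnot(xi > 0, xi <= 1, zeta >= 1)
  mean(p^(xi - 1) * (1 - p)^(zeta - 1)) / beta(xi, zeta)
}

#' Bound on the mean Bayes factor from a smaller-exponent GMP
#'
#' For exponents \eqn{r_\star < r < 0} the power-mean inequality gives
#' \eqn{\overline{BF} \le (1+r) M_{r_\star,K}^r}: a GMP computed at a more
#' negative exponent upper-bounds the model-averaged Bayes factor with
#' hyper-parameter \eqn{\xi = 1 + r}.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param r_star the exponent at which the GMP is computed; `r_star < r`.
#' @param r the Bayes-factor exponent, in (-1, 0).
#' @return The upper bound \eqn{(1+r) M_{r_\star,K}^r}.
#' @export
bf_bound <- function(p, r_star, r) {
  p <- .check_pvalues(p)
  stopifnot(is.numeric(r_star), is.numeric(r), length(r_star) == 1L,
            length(r) == 1L)
  if (!(r_star < r && r < 0))
    stop("bf_bound requires r_star < r < 0")
  (1 + r) * compute_gmp(p, r_star)^r
}

#' Read p-values from a text or TSV file
#'
#' Reads one p-value per line from a plain text file, or a named column from
#' a tab-separated file with a header.
#'
#' @param file path to the input file.
#' @param column optional column name; if supplied the file is parsed as TSV
#'   with a header row.
#' @param floor optional positive value; zeros are clipped up to it.
#' @return A validated numeric vector of p-values.
#' @export
read_pvalues <- function(file, column = NULL, floor = NULL) {
  if (is.null(column)) {
    p <- scan(file, what = numeric(), quiet = TRUE, comment.char = "#")
  } else {
    tab <- utils::read.delim(file, check.names = FALSE)
    if (!column %in% names(tab))
      stop("column '", column, "' not found in ", file)
    p <- tab[[column]]
  }
  .check_pvalues(p, floor)
}
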