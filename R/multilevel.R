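## Multilevel (closed testing) procedures: rejecting subsets of the K
## p-values while controlling the strong-sense family-wise error rate.
## A subset R is significant when its own GMP falls below a deflated
## threshold f_|R| * Psi_{r,|R|}(eps); the factor f is chosen so that
## significance of the subset implies significance of the full set even if
## every complement p-value equals 1 (consonance), via the partition
## identity K pbar_r^r = |R| pbar_{r,R}^r + |R'| pbar_{r,R'}^r.

.psi_for <- function(method, r, m, eps) {
  switch(method,
         gclt = gclt_threshold(r, m, eps)$psi,
         rra = rra_threshold(r, m, eps)$psi,
         stop("unknown threshold method: ", method))
}

#' Closed-testing deflation factor for a subset of p-values
#'
#' The factor \eqn{f_{|R|} \le 1} by which the size-\eqn{|R|} significance
#' threshold is multiplied when testing a subset of \eqn{|R|} of the `K`
#' p-values.  For \eqn{r < 0} the factor is
#' \deqn{f_{|R|} = \min\{1, [\Psi_{r,K}(\epsilon)^r /
#'   ((|R|/K)\,\Psi_{r,|R|}(\epsilon)^r)]^{1/r}\},}
#' the (slightly stronger, hence still consonant) form obtained by bounding
#' the complement contribution by its worst case; when \eqn{r < -1} both
#' the GCLT and RRA threshold families satisfy
#' \eqn{\Psi_{r,K}/\Psi_{r,|R|} = (|R|/K)^{1+1/r}} and the factor collapses
#' to exactly \eqn{|R|/K}.  For \eqn{r > 0} the general form
#' \eqn{f = \min\{1, [(\Psi_{r,K}^r - (1 - |R|/K)) /
#' ((|R|/K)\Psi_{r,|R|}^r)]^{1/r}\}} applies, and subsets smaller than
#' \eqn{K(1 - \Psi_{r,K}(\epsilon)^r)} can never be significant: no subset
#' GMP is small enough to offset complement p-values of 1, and the factor
#' is reported as `NA` (not rejectable).
#'
#' @param r nonzero finite GMP exponent.
#' @param subset_size the subset cardinality \eqn{|R|}, between 1 and `K`.
#' @param K total number of p-values.
#' @param eps target family-wise error rate.
#' @param method threshold family, `"gclt"` or `"rra"`.
#' @return The factor in (0, 1], or `NA_real_` when the subset cannot be
#'   rejected (only possible for `r > 0`).
#' @examples
#' ctp_factor(-2, subset_size = 10, K = 100)   # exactly |R|/K = 0.1
#' @export
ctp_factor <- function(r, subset_size, K, eps = 0.05,
                       method = c("gclt", "rra")) {
  method <- match.arg(method)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            subset_size >= 1, subset_size <= K, subset_size == round(subset_size))
  if (r == 0)
    stop("no closed testing procedure is defined for the geometric mean (r = 0)")
  m <- subset_size
  if (m == K) return(1)
  if (r < -1) return(m / K)
  psi_K <- .psi_for(method, r, K, eps)
  psi_m <- .psi_for(method, r, m, eps)
  if (r < 0) {
    f <- (psi_K^r / ((m / K) * psi_m^r))^(1 / r)
    return(min(1, f))
  }
  if (r > 0 && method == "rra")
    stop("no worst-case multilevel construction is available for r > 0")
  num <- psi_K^r - (1 - m / K)
  if (num <= 0) return(NA_real_)   # not rejectable at this subset size
  min(1, (num / ((m / K) * psi_m^r))^(1 / r))
}

#' Subset significance threshold for the multilevel test
#'
#' The threshold against which the subset GMP \eqn{\bar p_{r,R}} is
#' compared: \eqn{f_{|R|} \Psi_{r,|R|}(\epsilon)} in general.  Two closed
#' forms are available for heavy tails: with `small_eps = TRUE` and
#' \eqn{r \le -1}, the small-epsilon GCLT form
#' \eqn{|R|^{-1/r} \epsilon / K}; and with `method = "rra"` and
#' \eqn{r < -1}, \eqn{(|R|/K)^{-1/r} \Psi_{RRA,r,K}(\epsilon)}.  For
#' singletons with \eqn{r < -1} the RRA form is more stringent than the
#' Bonferroni per-test threshold by exactly the factor \eqn{(r+1)/r}: the
#' price of being able to reject statements about groups of p-values, not
#' only individuals.
#'
#' @inheritParams ctp_factor
#' @param small_eps if `TRUE`, use the small-epsilon closed form (requires
#'   \eqn{r \le -1}; ignores `method`).
#' @return The subset threshold, or `NA_real_` when not rejectable.
#' @examples
#' subset_threshold(-1, 10, 1000, 0.05, small_eps = TRUE)   # 5e-4
#' @export
subset_threshold <- function(r, subset_size, K, eps = 0.05,
                             method = c("gclt", "rra"), small_eps = FALSE) {
  method <- match.arg(method)
  m <- subset_size
  if (small_eps) {
    if (r > -1)
      stop("the small-epsilon subset threshold requires r <= -1")
    stopifnot(m >= 1, m <= K)
    return(m^(-1 / r) * eps / K)
  }
  f <- ctp_factor(r, m, K, eps, method)
  if (is.na(f)) return(NA_real_)
  f * .psi_for(method, r, m, eps)
}

#' Multilevel test of a subset of p-values
#'
#' Tests the partial null hypothesis that none of the p-values indexed by
#' `subset` is significant, while controlling the strong-sense family-wise
#' error rate at `eps` across all such subset claims.  Computes the GMP of
#' the subset and compares it with [subset_threshold()].  Rejecting a
#' subset implies the grand null would be rejected even with every
#' complement p-value replaced by 1.
#'
#' @param p numeric vector of all `K` p-values.
#' @param subset integer indices of the subset to test.
#' @inheritParams ctp_factor
#' @inheritParams subset_threshold
#' @return An object of class `ctp_decision` with fields `subset_size`,
#'   `K`, `r`, `eps`, `method`, `factor`, `subset_gmp`, `subset_threshold`
#'   and `reject` (`factor` and `subset_threshold` are `NA` and `reject`
#'   is `FALSE` when the subset size is not rejectable).
#' @examples
#' p <- c(4e-5, runif(999, 0.01, 1))
#' multilevel_reject(p, subset = 1, r = -1, eps = 0.05, small_eps = TRUE)
#' @export
multilevel_reject <- function(p, subset, r, eps = 0.05,
                              method = c("gclt", "rra"), small_eps = FALSE) {
  method <- match.arg(method)
  p <- .check_pvalues(p)
  K <- length(p)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be non-empty")
  if (anyDuplicated(subset) || any(subset < 1L) || any(subset > K))
    stop("subset must be distinct indices in 1..K")
  m <- length(subset)
  thr <- subset_threshold(r, m, K, eps, method, small_eps)
  gmp_sub <- compute_gmp(p[subset], r)
  f <- if (small_eps) NA_real_ else ctp_factor(r, m, K, eps, method)
  structure(list(subset_size = m, K = K, r = r, eps = eps, method = method,
                 small_eps = small_eps, factor = f, subset_gmp = gmp_sub,
                 subset_threshold = thr,
                 reject = !is.na(thr) && gmp_sub <= thr),
            class = "ctp_decision")
}

#' @export
print.ctp_decision <- function(x, ...) {
  cat(sprintf("Multilevel GMP test (r = %g, %s%s) of a subset of %d / %d p-values\n",
              x$r, toupper(x$method),
              if (isTRUE(x$small_eps)) ", small-eps form" else "",
              x$subset_size, x$K))
  if (is.na(x$subset_threshold)) {
    cat("  subset size not rejectable at this r (threshold undefined)\n")
  } else {
    cat(sprintf("  subset GMP = %.6g vs threshold %.6g -> %s\n",
                x$subset_gmp, x$subset_threshold,
                if (x$reject) "REJECT subset null" else "do not reject"))
  }
  invisible(x)
}
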