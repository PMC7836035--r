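## Significance thresholds for the GMP: GCLT (independence, extremal stable
## quantiles), the small-epsilon simplification, and the worst-case RRA
## bounds of Vovk and Wang; plus the inverse maps between the two families
## and the classical comparator tests.

.check_eps <- function(eps) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0, eps < 1)
  if (eps > 0.2)
    warning("GCLT tail approximations degrade for eps > 0.2; ",
            "thresholds may be poorly calibrated")
  invisible(eps)
}

.threshold_result <- function(method, r, K, eps, psi) {
  structure(list(method = method, r = r, K = K, eps = eps,
                 psi = min(max(psi, 0), 1)),
            class = "gmp_threshold")
}

#' @export
print.gmp_threshold <- function(x, ...) {
  cat(sprintf("GMP significance threshold [%s]\n", x$method))
  cat(sprintf("  r = %g, K = %d, target level eps = %g\n", x$r, x$K, x$eps))
  cat(sprintf("  psi = %.6g  (reject when M_{r,K} <= psi)\n", x$psi))
  invisible(x)
}

#' GCLT centering and scaling coefficients
#'
#' Coefficients \eqn{a_{r,K}} (centering) and \eqn{b_{r,K}} (scaling) such
#' that \eqn{(\sum p_i^r - a_{r,K}) / b_{r,K}} converges to the extremal
#' stable law \eqn{S_{\lambda,1}} with \eqn{\lambda = \min(-1/r, 2)} under
#' independence.  The regimes are: \eqn{r < -1} (very heavy tails,
#' \eqn{a = 0}); \eqn{r = -1} (the harmonic case, \eqn{a = K \log K},
#' \eqn{b = (\pi/2) K}); \eqn{-1 < r < -1/2} (heavy tails with finite
#' mean); \eqn{r = -1/2} (the boundary, \eqn{b = \sqrt{K \log K}}); and
#' \eqn{r > -1/2} including all positive `r` (finite variance, the plain
#' CLT with \eqn{b = \sqrt{K V[X] / 2}}).  The constant
#' \eqn{C_{r,K} = b_{r,K} / K^{\max(1/2, -r)}} in the heavy-tailed regimes
#' is \eqn{[(2/\pi)\Gamma(-1/r)\sin(-\pi/(2r))]^r}.
#'
#' @param r finite nonzero GMP exponent.
#' @param K number of constituent p-values, at least 2.
#' @return A list with components `a`, `b`, `C`, `lambda` and `log_b`
#'   (`b` may overflow to `Inf` for extreme `r`; `log_b` never does).
#' @export
gclt_coefficients <- function(r, K) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r), r != 0,
            is.numeric(K), length(K) == 1L, K >= 1, K == round(K))
  # log of (2/pi) Gamma(-1/r) sin(-pi/(2r)), the lambda-tail constant
  log_inner <- function(r) {
    log(2 / pi) + lgamma(-1 / r) + log(sin(-pi / (2 * r)))
  }
  if (r < -1) {
    lam <- -1 / r
    logC <- r * log_inner(r)
    a <- 0
    log_b <- logC - r * log(K)
  } else if (r == -1) {
    lam <- 1
    logC <- log(pi / 2)
    a <- K * log(K)
    log_b <- logC + log(K)
  } else if (r < -1 / 2) {
    lam <- -1 / r
    logC <- r * log_inner(r)
    a <- K / (1 + r)
    log_b <- logC - r * log(K)
  } else if (r == -1 / 2) {
    lam <- 2
    logC <- 0.5 * log(log(K))
    a <- K / (1 + r)
    log_b <- logC + 0.5 * log(K)
  } else {
    lam <- 2
    vx <- power_moments(r)$variance
    logC <- 0.5 * log(vx / 2)
    a <- K / (1 + r)
    log_b <- logC + 0.5 * log(K)
  }
  list(a = a, b = exp(log_b), C = exp(logC), lambda = lam, log_b = log_b)
}

#' GCLT significance threshold for the GMP
#'
#' The threshold \eqn{\Psi_{GCLT,r,K}(\epsilon)} below which the GMP is
#' declared significant, derived from the limiting extremal stable
#' distribution of \eqn{\sum p_i^r} under independence:
#' \deqn{\Psi = [(a_{r,K} + b_{r,K} q) / K]^{1/r}}
#' where \eqn{q} is the upper \eqn{1-\epsilon} stable quantile for
#' \eqn{r < 0} (tail index \eqn{\min(-1/r, 2)}) and the lower
#' \eqn{\epsilon} quantile of Normal(0, 2) for \eqn{r > 0}.  For
#' \eqn{-1/2 \le r < 0} the construction coincides with the plain central
#' limit theorem.  The geometric mean (`r = 0`) is not covered; Fisher's
#' method is exact there.
#'
#' @inheritParams gclt_coefficients
#' @param eps target false positive rate, in (0, 1); a warning is issued
#'   above 0.2 where the tail approximation degrades.
#' @return An object of class `gmp_threshold` with fields `method`, `r`,
#'   `K`, `eps` and `psi`.
#' @examples
#' gclt_threshold(-1, 1000, 0.05)   # harmonic mean p-value threshold
#' gclt_threshold(1, 1000, 0.01)$psi
#' @export
gclt_threshold <- function(r, K, eps) {
  .check_eps(eps)
  if (is.numeric(r) && length(r) == 1L && is.finite(r) && r == 0)
    stop("no GCLT threshold at r = 0: use Fisher's method (fisher_test)")
  co <- gclt_coefficients(r, K)
  if (r > 0) {
    q <- qnorm(eps, 0, sqrt(2))
    arg <- (co$a + co$b * q) / K
    if (arg <= 0)
      stop("threshold argument non-positive: eps = ", eps,
           " is too extreme for r = ", r, ", K = ", K)
    psi <- arg^(1 / r)
  } else if (r < -1) {
    # a = 0; work in logs so that arbitrarily negative r cannot overflow
    logq <- .exstable_logq_upper(eps, co$lambda)
    psi <- exp((co$log_b + logq - log(K)) / r)
  } else {
    q <- .exstable_q_upper(eps, co$lambda)
    arg <- (co$a + co$b * q) / K
    if (arg <= 0)
      stop("threshold argument non-positive for r = ", r, ", eps = ", eps)
    psi <- arg^(1 / r)
  }
  .threshold_result("GCLT", r, K, eps, psi)
}

#' Small-epsilon GCLT threshold
#'
#' The closed-form limit \eqn{\Psi = \epsilon K^{-(1+1/r)}} of the GCLT
#' threshold as \eqn{\epsilon \to 0}, valid for \eqn{r < -1/2} by the
#' theory of regularly varying tails.  At \eqn{r = -1} it is exactly
#' \eqn{\epsilon}, the direct-interpretation property of the harmonic mean
#' p-value; as \eqn{r \to -\infty} it approaches the Bonferroni per-test
#' threshold \eqn{\epsilon / K}.  Refused for \eqn{r \ge -1/2}, where both
#' the heavy-tail and the small-epsilon characterizations break down.
#'
#' @inheritParams gclt_threshold
#' @return An object of class `gmp_threshold`.
#' @export
small_eps_threshold <- function(r, K, eps) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  if (r >= -1 / 2)
    stop("the small-epsilon approximation is unreliable for r >= -1/2 ",
         "(the summands are no longer heavy-tailed); use gclt_threshold")
  .check_eps(eps)
  stopifnot(K >= 2, K == round(K))
  .threshold_result("GCLT_SMALL_EPS", r, K, eps, eps * K^(-(1 + 1 / r)))
}

# slope m of the RRA threshold map psi = m * eps
.rra_slope <- function(r, K) {
  if (r < -1) {
    ((r + 1) / r) * K^(-(1 + 1 / r))
  } else if (r == -1) {
    1 / log(K)
  } else if (r == 0) {
    exp(-1)
  } else {
    # (r+1)^(-1/r); -> 1/e as r -> 0, = 1/2 at r = 1
    exp(-log1p(r) / r)
  }
}

#' Worst-case (robust risk analysis) threshold for the GMP
#'
#' Significance thresholds valid under arbitrary dependence between the
#' p-values, after Vovk and Wang: \eqn{\Psi = \frac{r+1}{r}\epsilon
#' K^{-(1+1/r)}} for \eqn{r < -1}; \eqn{\Psi = \epsilon / \log K} for the
#' harmonic mean (\eqn{r = -1}); and \eqn{\Psi = \epsilon (r+1)^{-1/r}}
#' for \eqn{r > -1}, giving the familiar multipliers \eqn{e} at
#' \eqn{r \to 0} (geometric mean) and 2 at \eqn{r = 1} (arithmetic mean).
#' These bounds are precise: for every \eqn{\epsilon} some dependence
#' structure attains them.
#'
#' @inheritParams gclt_threshold
#' @return An object of class `gmp_threshold`.
#' @examples
#' rra_threshold(-1, 1000, 0.05)    # eps / log K
#' @export
rra_threshold <- function(r, K, eps) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L, K >= 1, K == round(K),
            is.numeric(eps), length(eps) == 1L, eps > 0, eps < 1)
  .threshold_result("RRA", r, K, eps, .rra_slope(r, K) * eps)
}

#' False positive rate of a threshold under independence
#'
#' Inverts the GCLT threshold map: returns the level \eqn{\epsilon} at
#' which `gclt_threshold(r, K, eps)` equals `t`.  Applied to an RRA
#' threshold this gives the (conservative) false positive rate the
#' worst-case procedure actually attains when the p-values are
#' independent.
#'
#' @param t a threshold in (0, 1).
#' @inheritParams gclt_threshold
#' @return The implied false positive rate.
#' @export
fpr_under_independence <- function(t, r, K) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0, t < 1)
  co <- gclt_coefficients(r, K)
  if (r > 0) {
    q <- (K * t^r - co$a) / co$b
    return(pnorm(q, 0, sqrt(2)))
  }
  if (r < -1) {
    logq <- log(K) + r * log(t) - co$log_b   # a = 0
    return(.exstable_sf_logx(logq, co$lambda))
  }
  q <- (K * t^r - co$a) / co$b
  .exstable_sf(q, co$lambda)
}

#' Worst-case false positive rate of a threshold
#'
#' Inverts the RRA threshold map, which is linear in \eqn{\epsilon}:
#' assuming the RRA bounds are precise, a test that rejects when the GMP
#' falls below `t` has worst-case false positive rate `min(1, t / m)`
#' where `m` is the epsilon-slope of the RRA threshold.  Applied to a GCLT
#' threshold this quantifies its inflation under adversarial dependence.
#'
#' @inheritParams fpr_under_independence
#' @return The worst-case false positive rate, capped at 1.
#' @examples
#' psi <- gclt_threshold(1, 1000, 0.01)$psi
#' fpr_worst_case(psi, 1, 1000)         # 0.96: the arithmetic mean GMP
#' @export
fpr_worst_case <- function(t, r, K) {
  stopifnot(is.numeric(t), length(t) == 1L, t > 0, t < 1)
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r))
  min(1, t / .rra_slope(r, K))
}

#' Exponent of the tightest worst-case bound below the harmonic mean
#'
#' The RRA threshold for the harmonic mean p-value is derived as the
#' tightest bound over exponents \eqn{r < -1}, attained at
#' \eqn{r = \log K / (1 - \log K)}; for \eqn{K = 1000} this is \eqn{-1.17}.
#' GMPs at this exponent behave most like the harmonic mean while keeping
#' the very-heavy-tail robustness of \eqn{r < -1}.
#'
#' @param K number of tests.
#' @return The exponent, a number slightly below -1 for large `K`.
#' @export
tightest_exponent <- function(K) {
  stopifnot(K >= 2)
  log(K) / (1 - log(K))
}

.combined_result <- function(method, K, eps, statistic, threshold, reject,
                             p_combined = NA_real_) {
  structure(list(method = method, K = K, eps = eps, statistic = statistic,
                 threshold = threshold, reject = reject,
                 p_combined = p_combined),
            class = "combined_test")
}

#' @export
print.combined_test <- function(x, ...) {
  cat(sprintf("%s combined test on K = %d p-values (eps = %g)\n",
              x$method, x$K, x$eps))
  cat(sprintf("  statistic = %.6g, threshold = %.6g -> %s\n",
              x$statistic, x$threshold,
              if (x$reject) "REJECT grand null" else "do not reject"))
  if (!is.na(x$p_combined))
    cat(sprintf("  combined p-value = %.6g\n", x$p_combined))
  invisible(x)
}

#' Classical comparator tests for the grand null
#'
#' Reference procedures against which the GMP is compared: Bonferroni
#' (reject when \eqn{\min p \le \epsilon/K}; valid under arbitrary
#' dependence), Sidak (\eqn{\min p \le 1 - (1-\epsilon)^{1/K}}; exact
#' under independence), Simes (\eqn{\min_i K p_{(i)}/i \le \epsilon};
#' valid under positive dependence) and Fisher (\eqn{-2\sum \log p_i}
#' against chi-squared with \eqn{2K} degrees of freedom; independence
#' only).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param eps target false positive rate.
#' @return An object of class `combined_test` with the test statistic, the
#'   rejection threshold on its scale, the decision and (where defined) a
#'   combined p-value.
#' @examples
#' simes_test(c(0.01, 0.04, 0.05), eps = 0.05)
#' fisher_test(c(0.05, 0.05))
#' @export
bonferroni_test <- function(p, eps = 0.05) {
  p <- .check_pvalues(p); .check_level(eps)
  K <- length(p); s <- min(p)
  .combined_result("Bonferroni", K, eps, s, eps / K, s <= eps / K,
                   min(1, K * s))
}

#' @rdname bonferroni_test
#' @export
sidak_test <- function(p, eps = 0.05) {
  p <- .check_pvalues(p); .check_level(eps)
  K <- length(p); s <- min(p)
  thr <- -expm1(log1p(-eps) / K)       # 1 - (1 - eps)^(1/K)
  .combined_result("Sidak", K, eps, s, thr, s <= thr, -expm1(K * log1p(-s)))
}

#' @rdname bonferroni_test
#' @export
simes_test <- function(p, eps = 0.05) {
  p <- .check_pvalues(p); .check_level(eps)
  K <- length(p)
  s <- min(K * sort(p) / seq_len(K))
  .combined_result("Simes", K, eps, s, eps, s <= eps, min(1, s))
}

#' @rdname bonferroni_test
#' @export
fisher_test <- function(p, eps = 0.05) {
  p <- .check_pvalues(p); .check_level(eps)
  K <- length(p)
  stat <- -2 * sum(log(p))
  pc <- pchisq(stat, df = 2 * K, lower.tail = FALSE)
  .combined_result("Fisher", K, eps, stat, qchisq(eps, 2 * K, lower.tail = FALSE),
                   pc <= eps, pc)
}

.check_level <- function(eps) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0, eps < 1)
}
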