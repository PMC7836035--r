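test_that("GCLT coefficients reproduce the tabulated regimes", {
  co <- gclt_coefficients(-1, 1000)
  expect_equal(co$a, 1000 * log(1000))
  expect_equal(co$b, pi / 2 * 1000)
  expect_equal(co$lambda, 1)

  co <- gclt_coefficients(1, 1000)
  expect_equal(co$a, 500)
  expect_equal(co$b, sqrt(1000 / 24))
  expect_equal(co$b, 6.45497, tolerance = 1e-5)

  # r = -2: C = [(2/pi) Gamma(1/2) sin(pi/4)]^-2 = pi/2 exactly
  co <- gclt_coefficients(-2, 100)
  expect_equal(co$a, 0)
  expect_equal(co$C, pi / 2, tolerance = 1e-12)
  expect_equal(co$b, pi / 2 * 100^2)
  expect_equal(co$lambda, 0.5)

  expect_equal(gclt_coefficients(-0.5, 100)$C, sqrt(log(100)))
  expect_error(gclt_coefficients(0, 100))
})

test_that("GCLT thresholds match closed-form and spec values", {
  expect_equal(gclt_threshold(1, 1000, 0.01)$psi,
               (500 + sqrt(1000 / 24) * sqrt(2) * qnorm(0.01)) / 1000,
               tolerance = 1e-12)
  expect_equal(gclt_threshold(1, 1000, 0.01)$psi, 0.47876, tolerance = 1e-5)
  # psi strictly increasing in eps
  for (r in c(-2, -1, -0.6, -0.25, 1)) {
    psis <- vapply(c(0.001, 0.01, 0.05, 0.1),
                   function(e) gclt_threshold(r, 1000, e)$psi, numeric(1))
    expect_true(all(diff(psis) > 0), label = paste("r =", r))
  }
  expect_warning(gclt_threshold(-1, 100, 0.3), "degrade")
  expect_error(gclt_threshold(0, 100, 0.05), "Fisher")
})

test_that("the lambda clamp makes -1/2 < r < 0 a plain CLT construction", {
  r <- -0.25; K <- 1000; eps <- 0.05
  vx <- power_moments(r)$variance
  clt <- ((K / (1 + r) + sqrt(K * vx) * qnorm(1 - eps)) / K)^(1 / r)
  expect_equal(gclt_threshold(r, K, eps)$psi, clt, tolerance = 1e-10)
})

test_that("small-epsilon thresholds follow eps * K^-(1+1/r)", {
  expect_equal(small_eps_threshold(-1, 50, 0.037)$psi, 0.037)
  expect_equal(small_eps_threshold(-1, 5000, 0.037)$psi, 0.037)
  expect_equal(small_eps_threshold(-2, 100, 0.005)$psi, 0.0005)
  expect_equal(small_eps_threshold(-1e6, 1000, 0.05)$psi,
               0.05 * 1000^(-(1 - 1e-6)), tolerance = 1e-12)
  expect_equal(small_eps_threshold(-1e6, 1000, 0.05)$psi, 5e-5,
               tolerance = 1e-4)
  expect_error(small_eps_threshold(-0.5, 100, 0.05), "r >= -1/2")
  expect_error(small_eps_threshold(1, 100, 0.05), "r >= -1/2")
})

test_that("RRA thresholds reproduce the worst-case table", {
  expect_equal(rra_threshold(-1, 1000, 0.05)$psi, 0.05 / log(1000))
  expect_equal(rra_threshold(-1, 1000, 0.05)$psi, 0.0072382, tolerance = 1e-5)
  expect_equal(rra_threshold(1, 10, 0.05)$psi, 0.025)
  expect_equal(rra_threshold(1, 99999, 0.05)$psi, 0.025)  # K-free for r > -1
  expect_equal(rra_threshold(-2, 100, 0.01)$psi, 0.5 * 0.01 * 100^(-0.5))
  # geometric-mean limit: multiplier e
  expect_equal(rra_threshold(1e-9, 100, 0.05)$psi, 0.05 / exp(1),
               tolerance = 1e-6)
  # two-fold gap at r = -2, independent of K and eps
  for (K in c(10, 100, 1000)) {
    for (eps in c(0.001, 0.01, 0.05)) {
      expect_equal(small_eps_threshold(-2, K, eps)$psi /
                     rra_threshold(-2, K, eps)$psi, 2)
    }
  }
})

test_that("RRA is more stringent than GCLT for r <= -1", {
  for (r in c(-10, -2, -1.5, -1)) {
    for (eps in c(0.01, 0.05)) {
      expect_lte(rra_threshold(r, 1000, eps)$psi,
                 gclt_threshold(r, 1000, eps)$psi)
    }
  }
})

test_that("GCLT threshold converges to the small-eps form as eps -> 0", {
  for (r in c(-2, -1)) {
    ratios <- vapply(c(1e-3, 1e-4, 1e-6), function(e) {
      gclt_threshold(r, 1000, e)$psi / small_eps_threshold(r, 1000, e)$psi
    }, numeric(1))
    expect_true(all(abs(ratios - 1) < 0.05))
    expect_lt(abs(ratios[3] - 1), 1e-3)
  }
})

test_that("extreme negative exponents recover Sidak and Bonferroni", {
  K <- 1000; eps <- 0.05
  sidak <- -expm1(log1p(-eps) / K)
  expect_equal(gclt_threshold(-1e6, K, eps)$psi / sidak, 1, tolerance = 1e-3)
  expect_equal(rra_threshold(-1e6, K, eps)$psi / (eps / K), 1,
               tolerance = 1e-3)
})

test_that("fpr_under_independence inverts the GCLT map", {
  for (r in c(-2, -1.25, -1, -0.75, -0.25, 1)) {
    for (eps in c(0.005, 0.03)) {
      t <- gclt_threshold(r, 1000, eps)$psi
      expect_equal(fpr_under_independence(t, r, 1000), eps,
                   tolerance = 1e-6, label = sprintf("r=%g eps=%g", r, eps))
    }
  }
  # RRA thresholds are conservative under independence ...
  expect_lt(fpr_under_independence(rra_threshold(-1, 1000, 0.01)$psi, -1, 1000),
            0.01)
  # ... but approach the target as r -> -infinity
  f10 <- fpr_under_independence(rra_threshold(-10, 1000, 0.01)$psi, -10, 1000)
  expect_lt(abs(f10 - 0.01) / 0.01, 0.15)
})

test_that("fpr_worst_case inverts the RRA map and reproduces the inflation figures", {
  for (r in c(-3, -1, 0.5)) {
    t <- rra_threshold(r, 1000, 0.02)$psi
    expect_equal(fpr_worst_case(t, r, 1000), 0.02, tolerance = 1e-12)
  }
  expect_equal(fpr_worst_case(gclt_threshold(1, 1000, 0.01)$psi, 1, 1000),
               0.96, tolerance = 0.005)
  hmp_fold <- fpr_worst_case(gclt_threshold(-1, 1000, 0.01)$psi, -1, 1000) / 0.01
  expect_equal(hmp_fold, 6.2, tolerance = 0.01)
  expect_equal(fpr_worst_case(0.9, 1, 1000), 1)  # capped
})

test_that("tightest_exponent matches log K / (1 - log K)", {
  expect_equal(tightest_exponent(1000), log(1000) / (1 - log(1000)))
  expect_equal(round(tightest_exponent(1000), 2), -1.17)
})

test_that("comparator tests match brute-force calculations", {
  s <- simes_test(c(0.01, 0.04, 0.05), eps = 0.05)
  expect_equal(s$statistic, 0.03)
  expect_true(s$reject)
  set.seed(31)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    expect_equal(simes_test(p)$statistic, simes_brute(p))
  }

  f <- fisher_test(c(0.05, 0.05))
  expect_equal(f$statistic, -4 * log(0.05))
  expect_equal(f$statistic, 11.9829, tolerance = 1e-4)
  expect_equal(f$p_combined, pchisq(-4 * log(0.05), 4, lower.tail = FALSE))
  # closed form for 4 df: exp(-x/2) (1 + x/2)
  expect_equal(f$p_combined, exp(2 * log(0.05)) * (1 - 2 * log(0.05)),
               tolerance = 1e-12)
  expect_equal(f$p_combined, 0.017479, tolerance = 1e-4)

  b <- bonferroni_test(runif(1000), eps = 0.05)
  expect_equal(b$threshold, 5e-5)
  sk <- sidak_test(c(0.001, 0.5), eps = 0.05)
  expect_equal(sk$threshold, 1 - 0.95^(1 / 2))
  expect_true(sk$reject)
})

test_that("GCLT rejection rates calibrate against a Monte-Carlo oracle (desk scale)", {
  set.seed(32)
  res <- gmp_null_rejection_rates(rs = c(-2, -1, 1), K = 200, nrep = 2e4,
                                  epss = 0.05,
                                  threshold_fun = function(r, eps) {
                                    gclt_threshold(r, 200, eps)$psi
                                  })
  for (i in seq_len(nrow(res))) {
    expect_lt(abs(res$rate[i] - res$eps[i]),
              4 * binom_mcse(res$eps[i], 2e4),
              label = sprintf("r=%g", res$r[i]))
  }
})
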