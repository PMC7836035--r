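test_that("method_spec validates the family / exponent pairing", {
  expect_error(method_spec("gmp_gclt"), "exponent")
  expect_error(method_spec("simes", r = -1), "only meaningful")
  m <- method_spec("gmp_rra", r = -2, eps = 0.01)
  expect_equal(m$family, "gmp_rra")
  expect_equal(m$eps, 0.01)
})

test_that("every method calibrates near its nominal level under independence", {
  set.seed(61)
  K <- 500; n <- 3000
  sc <- scenario_spec("null", K = K)
  model <- dependence_model(K = K, rho = 0)
  specs <- list(method_spec("gmp_gclt", r = -1),
                method_spec("gmp_gclt", r = -2),
                method_spec("bonferroni"),
                method_spec("sidak"),
                method_spec("simes"),
                method_spec("fisher"))
  for (ms in specs) {
    res <- estimate_rejection_rate(ms, sc, model, n_sims = n)
    expect_lt(abs(res$rate - 0.05), 4 * binom_mcse(0.05, n),
              label = res$method)
    expect_equal(res$mcse, sqrt(res$rate * (1 - res$rate) / n))
  }
})

test_that("needle power under independence matches the noncentral closed form", {
  # Bonferroni rejects iff some p <= eps/K; with one noncentral test
  # (ncp = 18) the exact power is 1 - (1-s)(1-eps/K)^(K-1)
  set.seed(62)
  K <- 1000; n <- 2000
  cutoff <- qchisq(1 - 0.05 / K, 2)
  s <- pchisq(cutoff, 2, ncp = 18, lower.tail = FALSE)
  exact <- 1 - (1 - s) * (1 - 0.05 / K)^(K - 1)
  res <- estimate_rejection_rate(method_spec("bonferroni"),
                                 scenario_spec("needle"),
                                 dependence_model(K = K, rho = 0),
                                 n_sims = n)
  expect_lt(abs(res$rate - exact), 4 * binom_mcse(exact, n))
})

test_that("the sweep is deterministic and tidily structured", {
  a <- gmp_sweep(r_grid = c(-1, 1), rho_grid = c(0, 0.5),
                 scenarios = c("null", "needle"), comparators = "bonferroni",
                 n_sims = 300, K = 100, seed = 99)
  b <- gmp_sweep(r_grid = c(-1, 1), rho_grid = c(0, 0.5),
                 scenarios = c("null", "needle"), comparators = "bonferroni",
                 n_sims = 300, K = 100, seed = 99)
  expect_identical(a, b)
  # 2 scenarios x 2 rho x (2 r x 2 threshold families + 1 comparator)
  expect_equal(nrow(a), 2 * 2 * (2 * 2 + 1))
  expect_setequal(unique(a$scenario), c("null", "needle"))
  expect_true(all(a$rate >= 0 & a$rate <= 1))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  gmp_sweep(r_grid = -1, rho_grid = 0, scenarios = "null",
            comparators = character(0), n_sims = 100, K = 50, seed = 7,
            file = f1)
  gmp_sweep(r_grid = -1, rho_grid = 0, scenarios = "null",
            comparators = character(0), n_sims = 100, K = 50, seed = 7,
            file = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty sweep returns an empty table without error", {
  res <- gmp_sweep(r_grid = -1, rho_grid = 0, scenarios = "null",
                   n_sims = 0, K = 50, seed = 1)
  expect_s3_class(res, "data.frame")
  expect_equal(nrow(res), 0)
})

test_that("ROC curves are monotone and calibrated at independence", {
  set.seed(63)
  K <- 300; n <- 3000
  roc <- roc_curve(method_spec("gmp_gclt", r = -1),
                   scenario_spec("mixture", K = K),
                   dependence_model(K = K, rho = 0), n_sims = n)
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$power) >= 0))
  i05 <- which(roc$eps == 0.05)
  expect_lt(abs(roc$fpr[i05] - 0.05), 4 * binom_mcse(0.05, n))
})

test_that("at rho = 1 the replicate statistic is the single shared p-value", {
  set.seed(64)
  model <- dependence_model(K = 50, rho = 1)
  s <- sample_null_deviances(model, 20)
  stat <- gmpcomb:::.row_statistics(s$pvalues, method_spec("gmp_gclt", r = -1))
  expect_equal(stat, s$pvalues[, 1], tolerance = 1e-10)
})

test_that("inherent power equals actual power when the threshold is calibrated", {
  set.seed(65)
  K <- 300; n <- 4000
  ip <- inherent_power(method_spec("gmp_gclt", r = -1),
                       scenario_spec("mixture", K = K),
                       dependence_model(K = K, rho = 0), n_sims = n)
  # under independence the GCLT threshold is (nearly) the true eps-quantile
  expect_lt(abs(ip$actual - ip$inherent), 4 * sqrt(2) * binom_mcse(0.5, n))
})

test_that("under dependence, conservative tests fall short of inherent power", {
  set.seed(66)
  K <- 300; n <- 4000
  ip <- inherent_power(method_spec("simes"),
                       scenario_spec("mixture", K = K),
                       dependence_model(K = K, rho = 0.4), n_sims = n)
  # Simes is conservative at rho = 0.4, so actual < inherent
  expect_lt(ip$actual, ip$inherent)
})

test_that("the HMP is inherently at least as powerful as Simes under a signal mixture", {
  set.seed(67)
  K <- 300; n <- 4000
  model <- dependence_model(K = K, rho = 0)
  sc <- scenario_spec("mixture", K = K)
  hmp <- inherent_power(method_spec("gmp_gclt", r = -1), sc, model, n_sims = n)
  sim <- inherent_power(method_spec("simes"), sc, model, n_sims = n)
  expect_gt(hmp$inherent, sim$inherent - 3 * binom_mcse(0.5, n))
})
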