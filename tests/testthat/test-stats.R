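# Oracles (pbOracle, wilcoxOracle, aucOracle, friedmanPermOracle) are
# defined in helper-oracles.R.

test_that("Shapiro-Wilk wrapper distinguishes normal from skewed samples", {
  pnorm_ok <- 0L; pexp_low <- 0L
  for (s in 1:20) {
    set.seed(s)
    if (shapiroWilk(rnorm(100))$p > 0.05) pnorm_ok <- pnorm_ok + 1L
    if (shapiroWilk(rexp(100))$p < 0.05) pexp_low <- pexp_low + 1L
  }
  expect_gte(pnorm_ok, 18L)
  expect_gte(pexp_low, 19L)
  expect_error(shapiroWilk(c(1, 2)), "n")
  expect_error(shapiroWilk(rep(1, 10)))
})

test_that("Spearman rho equals the Pearson-on-midranks oracle", {
  x <- 1:10
  expect_equal(spearmanRho(x, x * 2 + 3)$rho, 1)
  expect_equal(spearmanRho(x, -x^3)$rho, -1)
  set.seed(4)
  for (k in 1:20) {
    xx <- sample(1:4, 8, replace = TRUE)    # ties on purpose
    yy <- sample(1:5, 8, replace = TRUE)
    if (sd(xx) == 0 || sd(yy) == 0) next
    got <- spearmanRho(xx, yy)$rho
    expect_equal(got, cor(rank(xx), rank(yy)), tolerance = 1e-12)
  }
  deg <- spearmanRho(rep(1, 6), 1:6)
  expect_true(deg$degenerate && is.na(deg$rho))
  # invariance under strictly monotone transforms
  set.seed(5); a <- runif(12); b <- runif(12)
  expect_equal(spearmanRho(exp(a), b)$rho, spearmanRho(a, b)$rho)
})

test_that("Friedman matches the exhaustive permutation null", {
  m_id <- matrix(rep(1:5, 3), 5, 3)
  out <- friedmanTest(m_id)
  expect_equal(out$chi2, 0)
  expect_equal(out$p, 1)

  set.seed(6)
  for (k in 1:3) {    # n = 5, k = 3: 6^5 within-block permutations
    m <- matrix(rnorm(15), 5, 3)
    expect_equal(friedmanTest(m, "exact")$p, friedmanPermOracle(m),
                 tolerance = 1e-12)
  }
  for (k in 1:5) {    # smaller blocks with ties
    m <- matrix(sample(1:3, 12, replace = TRUE), 4, 3)
    expect_equal(friedmanTest(m, "exact")$p, friedmanPermOracle(m),
                 tolerance = 1e-12)
  }
  # strong separation
  m <- matrix(rnorm(30), 10, 3)
  m[, 2] <- m[, 2] + 50; m[, 3] <- m[, 3] + 100
  expect_lt(friedmanTest(m, "chisq")$p, 0.001)
  expect_error(friedmanTest(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)),
               "incomplete")
})

test_that("Wilcoxon post-hocs match exact sign enumeration", {
  m <- cbind(a = rnorm(10), b = rnorm(10))
  m[, 2] <- m[, 1]
  out <- wilcoxonPairwiseBonferroni(m)
  expect_equal(out$p, 1)
  expect_true(out$degenerate)

  set.seed(7)
  for (k in 1:20) {
    n <- sample(6:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- wilcoxonPairwiseBonferroni(cbind(x, y))
    expect_equal(got$p, wilcoxOracle(x - y), tolerance = 1e-12)
  }
  # Bonferroni multiplicity over the four planimetric measures
  m4 <- matrix(rnorm(48), 12, 4)
  out <- wilcoxonPairwiseBonferroni(m4)
  expect_equal(nrow(out), 6L)
  expect_equal(out$p_adj, pmin(1, out$p * 6))
})

test_that("Passing-Bablok matches the shifted-median enumeration oracle", {
  x <- as.numeric(1:10)
  pb <- passingBablok(x, x, use_zscores = FALSE)
  expect_equal(pb$slope, 1)
  expect_equal(pb$intercept, 0)
  pb2 <- passingBablok(x, 2 * x + 1, use_zscores = FALSE)
  expect_equal(pb2$slope, 2)
  expect_equal(pb2$intercept, 1)
  expect_false(pb$proportional_bias || pb$constant_bias)

  set.seed(8)
  for (k in 1:20) {
    n <- sample(10:14, 1)
    xx <- rnorm(n); yy <- 1.4 * xx + rnorm(n, 0, 0.4)
    got <- passingBablok(xx, yy, use_zscores = FALSE)
    want <- pbOracle(xx, yy)
    expect_equal(got$slope, want$slope, tolerance = 1e-12)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-12)
    expect_true(got$slope_ci[1] <= got$slope &&
                got$slope <= got$slope_ci[2])
  }
})

test_that("Passing-Bablok is scale-equivariant and z-score invariant", {
  set.seed(9)
  x <- rnorm(15); y <- x + rnorm(15, 0, 0.3)
  raw <- passingBablok(x, y, use_zscores = FALSE)
  scaled <- passingBablok(3 * x, 3 * y, use_zscores = FALSE)
  expect_equal(raw$slope, scaled$slope, tolerance = 1e-12)
  z1 <- passingBablok(x, y, use_zscores = TRUE)
  z2 <- passingBablok(5 * x - 2, 0.1 * y + 7, use_zscores = TRUE)
  expect_equal(z1$slope, z2$slope, tolerance = 1e-9)
  expect_error(passingBablok(x[1:5], y[1:5]), "10")
})

test_that("AUC equals concordant-pair counting and is rank-invariant", {
  sep <- c(rnorm(20, 10), rnorm(20, -10))
  lab <- rep(c(TRUE, FALSE), each = 20)
  expect_equal(rocAUC(sep, lab)$auc, 1)

  set.seed(10)
  for (k in 1:20) {
    s <- sample(1:6, 8, replace = TRUE)   # ties included
    l <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_equal(rocAUC(s, l)$auc, aucOracle(s, l), tolerance = 1e-12)
    expect_equal(rocAUC(exp(s), l)$auc, rocAUC(s, l)$auc)
  }
  # label-independent scores stay near 1/2
  set.seed(11)
  s <- rnorm(2000); l <- rbinom(2000, 1, 0.5) > 0
  expect_gt(rocAUC(s, l)$auc, 0.47)
  expect_lt(rocAUC(s, l)$auc, 0.53)
  expect_error(rocAUC(1:5, rep(TRUE, 5)), "classes")
})

test_that("dichotomized ROC skips empty classes with a warning", {
  set.seed(12)
  vpi <- runif(30); cov <- runif(30, 0, 20)   # nothing above 25 or 50
  expect_warning(rocDichotomized(vpi, cov, cuts = 50), "empty")
  out <- suppressWarnings(rocDichotomized(vpi, cov))
  expect_true("cut_10" %in% names(out))
  expect_false("cut_50" %in% names(out))
  # percentile splits always have both classes
  out2 <- rocDichotomized(vpi, cov, cuts = c(25, 50),
                          percentile_split = TRUE)
  expect_length(out2, 2L)
})

test_that("correlation sample-size formula reproduces known values", {
  expect_identical(sampleSizeCorrelation(0.66, 0.05, 0.2), 15L)
  expect_identical(sampleSizeCorrelation(0.5, 0.05, 0.2), 29L)
  expect_identical(sampleSizeCorrelation(0.9999), 3L)
  expect_error(sampleSizeCorrelation(0), "r")
  expect_error(sampleSizeCorrelation(1), "r")
})

test_that("segmented regression recovers a two-regime growth law", {
  # noiseless two-segment data: exact recovery
  x <- seq(5, 95, length.out = 60)
  y <- 0.2 + 0.015 * x + 0.015 * pmax(x - 32.5, 0)
  bp <- contributionBreakpoint(data.frame(plani_tot = x, vpi = y))
  expect_false(bp$single_line)
  expect_equal(bp$breakpoint, 32.5, tolerance = 1)
  expect_equal(bp$slope_ratio, 2, tolerance = 0.02)

  # a pure line is flagged as such
  line <- contributionBreakpoint(
    data.frame(plani_tot = x, vpi = 0.1 + 0.02 * x))
  expect_true(line$single_line)
  expect_true(is.na(line$breakpoint))

  # noisy simulated cohort
  d <- simulateGrowthRegimes(150, seed = 3)
  fit <- contributionBreakpoint(d)
  expect_equal(fit$breakpoint, 32.5, tolerance = 4)
  expect_equal(fit$slope_ratio, 2, tolerance = 0.3)

  # dark/light contribution fits are reported alongside
  d$plani_dark <- d$plani_tot * 0.5 + rnorm(150, 0, 2)
  d$plani_light <- d$plani_tot - d$plani_dark
  fit2 <- contributionBreakpoint(d)
  expect_true(is.numeric(fit2$dark_light_slope_ratio))

  expect_error(contributionBreakpoint(data.frame(plani_tot = 1:5,
                                                 vpi = 1:5)), "20")
})

test_that("bootstrap breakpoint interval covers a strong true break", {
  d <- simulateGrowthRegimes(200, noise_sd = 0.05, seed = 5)
  fit <- contributionBreakpoint(d, n_boot = 60, seed = 9)
  expect_true(fit$breakpoint_ci[1] <= 32.5 && 32.5 <= fit$breakpoint_ci[2])
})
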