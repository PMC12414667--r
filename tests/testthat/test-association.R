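# Association engine: OLS carrier effects, Fisher's exact test, Firth
# logistic regression, test selection, meta-analysis.

test_that("OLS carrier beta equals the two-group mean difference", {
  r <- ols_carrier_beta(c(2.0, 2.2, 2.4, 1.6), c(0, 0, 0, 1))
  expect_equal(r$beta, -0.6)
  expect_identical(r$n_carriers, 1L)
  # property over random cases
  set.seed(101)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- rnorm(n)
    carrier <- rbinom(n, 1, 0.2)
    if (sum(carrier) == 0) carrier[1] <- 1
    r <- ols_carrier_beta(y, carrier)
    expect_equal(r$beta, mean(y[carrier == 1]) - mean(y[carrier == 0]),
                 tolerance = 1e-12)
  }
})

test_that("OLS handles constant responses and matches lm with covariates", {
  r <- ols_carrier_beta(rep(2.2, 10), c(1, 1, rep(0, 8)))
  expect_equal(r$beta, 0)
  set.seed(7)
  n <- 200
  covs <- cbind(age = rnorm(n, 55, 8), male = rbinom(n, 1, 0.5),
                matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("pc", 1:3))))
  carrier <- as.numeric(seq_len(n) %in% sample(n, 1))
  y <- rnorm(n) + 0.1 * covs[, "age"] / 10
  r <- ols_carrier_beta(y, carrier, covs)
  ref <- summary(lm(y ~ carrier + covs))$coefficients["carrier", ]
  expect_equal(r$beta, unname(ref[1]), tolerance = 1e-10)
  expect_equal(r$se, unname(ref[2]), tolerance = 1e-10)
  expect_equal(r$p_value, unname(ref[4]), tolerance = 1e-10)
})

test_that("OLS error conditions: no carriers, zero residual df, collinearity", {
  expect_error(ols_carrier_beta(c(1, 2, 3), c(0, 0, 0)), "carrier")
  expect_error(ols_carrier_beta(c(1, 2), c(0, 1)), "degrees of freedom")
  set.seed(1)
  y <- rnorm(20); carrier <- c(1, rep(0, 19))
  covs <- cbind(a = rnorm(20))
  covs <- cbind(covs, b = 2 * covs[, "a"])   # collinear pair
  expect_warning(r <- ols_carrier_beta(y, carrier, covs), "collinear")
  expect_true(is.finite(r$beta))
})

test_that("Fisher exact p follows the stated two-sided convention", {
  r <- fisher_carrier_enrichment(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r <- fisher_carrier_enrichment(1, 0, 1, 99)
  expect_identical(r$odds_ratio, Inf)
  expect_equal(r$p_value, 2 / 101, tolerance = 1e-12)
  expect_error(fisher_carrier_enrichment(0, 0, 0, 0), "all-zero")
  expect_error(fisher_carrier_enrichment(0, 0, 3, 4), "carrier")
  expect_error(fisher_carrier_enrichment(1, -1, 3, 4), "non-negative")
})

test_that("Fisher p equals the independent exact oracle on small tables", {
  # stats::fisher.test is an independent implementation of the same
  # sum-of-probabilities convention
  for (n in c(5, 12, 25)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b < 1) next
      p1 <- fisher_carrier_enrichment(a, b, cc, d)$p_value
      p2 <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
      expect_equal(p1, p2, tolerance = 1e-12)
    }
  }
})

test_that("Haldane-Anscombe correction applies to display ORs only", {
  r <- fisher_carrier_enrichment(2, 0, 1, 97)
  expect_identical(r$odds_ratio, Inf)
  expect_equal(r$odds_ratio_ha, (2.5 * 97.5) / (0.5 * 1.5))
  # p-value is computed from the raw counts, not the corrected ones
  expect_equal(r$p_value,
               stats::fisher.test(matrix(c(2, 1, 0, 97), 2))$p.value,
               tolerance = 1e-12)
})

test_that("Firth fit matches a direct penalized-likelihood maximizer", {
  set.seed(4)
  x <- rnorm(40)
  y <- rbinom(40, 1, plogis(0.3 + 0.8 * x))
  f <- suppressWarnings(firth_logistic(y, x))
  negpll <- function(b) {
    X <- cbind(1, x); p <- plogis(drop(X %*% b))
    I <- crossprod(X * sqrt(p * (1 - p)))
    -(sum(y * log(p) + (1 - y) * log(1 - p)) +
        0.5 * determinant(I)$modulus)
  }
  o <- optim(c(0, 0), negpll, control = list(reltol = 1e-15, maxit = 1e4))
  expect_equal(f$beta, o$par[2], tolerance = 1e-5)
})

test_that("Firth yields finite estimates under complete separation", {
  y <- c(0, 0, 0, 1, 1, 1)
  x <- c(0, 0, 0, 1, 1, 1)
  f <- suppressWarnings(firth_logistic(y, x))
  expect_true(is.finite(f$beta))
  expect_gt(f$beta, 0)
  # ordinary ML diverges here
  ml <- suppressWarnings(coef(glm(y ~ x, family = binomial)))[2]
  expect_gt(abs(ml), 10)
})

test_that("Firth is near-null on independent data", {
  set.seed(12)
  n <- 400
  y <- rbinom(n, 1, 0.3)
  carrier <- rbinom(n, 1, 0.3)
  f <- firth_logistic(y, carrier)
  expect_lt(abs(f$beta), 0.5)
  expect_gt(f$p_value, 0.001)
})

test_that("test selection implements the 10-events-per-variable rule", {
  expect_identical(select_test(3, 12), "fisher")
  expect_identical(select_test(200, 12), c("fisher", "firth"))
  expect_identical(select_test(0, 12), "fisher")
  expect_identical(select_test(120, 12), c("fisher", "firth"))
  expect_identical(select_test(119, 12), "fisher")
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  one <- data.frame(beta = -0.3, se = 0.12)
  m <- meta_fixed_effect(one)
  expect_equal(m$beta, -0.3)
  expect_equal(m$se, 0.12)
  m <- meta_fixed_effect(data.frame(beta = c(-0.2, -0.2), se = c(0.1, 0.1)))
  expect_equal(m$beta, -0.2)
  expect_equal(m$se, 1 / sqrt(200), tolerance = 1e-12)
  m <- meta_fixed_effect(data.frame(beta = c(-0.3, 0.3), se = c(0.1, 0.1)))
  expect_equal(m$beta, 0)
  expect_error(meta_fixed_effect(data.frame(beta = 1, se = Inf)), "finite")
})

test_that("pooled se never exceeds the smallest component se", {
  set.seed(33)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    df <- data.frame(beta = rnorm(k), se = runif(k, 0.05, 0.5))
    m <- meta_fixed_effect(df)
    expect_lte(m$se, min(df$se) + 1e-12)
  }
})

test_that("meta-analysis agrees with an established implementation", {
  skip_if_not_installed("metafor")
  set.seed(9)
  df <- data.frame(beta = rnorm(4, -0.2, 0.1), se = runif(4, 0.05, 0.2))
  m <- meta_fixed_effect(df)
  ref <- metafor::rma(yi = df$beta, sei = df$se, method = "FE")
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(m$se, ref$se, tolerance = 1e-8)
  expect_equal(m$p_value, ref$pval, tolerance = 1e-8)
})

test_that("Stouffer combination strengthens concordant evidence", {
  s <- meta_stouffer(c(0.04, 0.04), c(-1, -1))
  expect_lt(s$p_value, 0.04)
  s2 <- meta_stouffer(c(0.04, 0.04), c(-1, 1))
  expect_gt(s2$p_value, 0.5)
  expect_error(meta_stouffer(numeric(0), numeric(0)), "usable|length")
})
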