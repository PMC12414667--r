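# Per-variant association statistics: OLS carrier effects on quantitative labs,
# Fisher's exact test for binary phenotype enrichment, Firth-penalized logistic
# regression, the test-selection rule, and fixed-effect meta-analysis.

.assoc_result <- function(beta = NA_real_, se = NA_real_,
                          odds_ratio = NA_real_, p_value = NA_real_,
                          n_carriers = NA_integer_, n_events = NA_integer_,
                          method = NA_character_, kind = NA_character_) {
  data.frame(beta = beta, se = se, odds_ratio = odds_ratio, p_value = p_value,
             n_carriers = n_carriers, n_events = n_events, method = method,
             kind = kind, stringsAsFactors = FALSE)
}

#' Carrier effect on a quantitative lab by ordinary least squares
#'
#' Fits `y ~ carrier + covariates` and returns the carrier coefficient, its
#' standard error and the two-sided p-value from the t statistic. Collinear
#' covariate columns are dropped with a warning (the carrier term itself must
#' be estimable). Without covariates the estimate equals the carrier-minus-
#' non-carrier mean difference.
#'
#' @param y Numeric response (lab values); missing values are dropped.
#' @param carrier 0/1 (or logical) carrier indicator.
#' @param covariates Optional numeric matrix/data.frame of covariates
#'   (e.g. age, sex indicator, genetic PCs).
#' @return One-row `data.frame` (beta, se, p_value, n_carriers, method).
#' @examples
#' ols_carrier_beta(c(2.0, 2.2, 2.4, 1.6), c(0, 0, 0, 1))  # beta = -0.6
#' @export
ols_carrier_beta <- function(y, carrier, covariates = NULL) {
  carrier <- as.numeric(carrier)
  stopifnot(length(y) == length(carrier))
  keep <- !is.na(y) & !is.na(carrier)
  y <- y[keep]; carrier <- carrier[keep]
  if (sum(carrier != 0) < 1) stop("need at least one carrier with non-missing y")
  dat <- data.frame(.y = y, .carrier = carrier)
  if (!is.null(covariates)) {
    cv <- as.data.frame(as.matrix(covariates)[keep, , drop = FALSE])
    names(cv) <- make.names(names(cv), unique = TRUE)
    dat <- cbind(dat, cv)
  }
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  dropped <- names(cf)[is.na(cf)]
  if (length(dropped)) {
    if (".carrier" %in% dropped) stop("carrier coefficient is not estimable")
    warning("dropped collinear covariates: ",
            paste(dropped, collapse = ", "))
  }
  if (fit$df.residual <= 0) stop("zero residual degrees of freedom")
  sm <- suppressWarnings(summary(fit))$coefficients
  row <- sm[".carrier", ]
  .assoc_result(beta = unname(row[1]), se = unname(row[2]),
                p_value = unname(row[4]),
                n_carriers = as.integer(sum(carrier != 0)),
                method = "ols", kind = "quantitative")
}

# Two-sided Fisher p for a 2x2 table by summing hypergeometric point
# probabilities <= that of the observed table (with the conventional
# 1 + 1e-7 relative tolerance for floating-point ties).
.fisher_p2 <- function(a, b, c, d) {
  k <- a + b                 # carriers drawn
  m <- a + c                 # phenotype-positive in population
  n <- b + d                 # phenotype-negative
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Carrier-phenotype enrichment by Fisher's exact test
#'
#' Two-sided exact test on the 2x2 table of carrier status against a binary
#' phenotype. The two-sided p-value is the sum of hypergeometric probabilities
#' of all tables (with the observed margins) at most as probable as the
#' observed one; two-sided exact conventions differ, so this one is stated
#' explicitly. The odds ratio is the raw cross-product `ad/bc`, reported as
#' infinite when `bc = 0`; `odds_ratio_ha` carries the Haldane-Anscombe
#' 0.5-corrected value for display only (never used for p-values).
#'
#' @param a Carriers with the phenotype.
#' @param b Carriers without the phenotype.
#' @param c Non-carriers with the phenotype.
#' @param d Non-carriers without the phenotype.
#' @return One-row `data.frame` (odds_ratio, odds_ratio_ha, p_value,
#'   n_carriers, n_events, method).
#' @examples
#' fisher_carrier_enrichment(1, 0, 1, 99)  # OR = Inf, p ~= 0.0198
#' @export
fisher_carrier_enrichment <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all-zero table")
  if (a + b < 1) stop("need at least one carrier")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  res <- .assoc_result(odds_ratio = or, p_value = .fisher_p2(a, b, c, d),
                       n_carriers = as.integer(a + b),
                       n_events = as.integer(a + c),
                       method = "fisher", kind = "binary")
  res$odds_ratio_ha <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  res
}

# Penalized log-likelihood and Firth ingredients for logistic regression.
.firth_pieces <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  w <- pmax(p * (1 - p), 1e-12)
  XW <- X * sqrt(w)
  I <- crossprod(XW)
  ch <- chol(I)
  # hat values of W^1/2 X (X'WX)^-1 X' W^1/2
  h <- colSums(forwardsolve(t(ch), t(XW))^2)
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  list(p = p, I = I, ch = ch, h = h,
       pll = ll + sum(log(diag(ch))),     # + 1/2 log det I
       score = drop(crossprod(X, y - p + h * (0.5 - p))))
}

.firth_fit <- function(X, y, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pc <- .firth_pieces(X, y, beta)
  for (it in seq_len(maxit)) {
    step <- backsolve(pc$ch, forwardsolve(t(pc$ch), pc$score))
    # step-halving on the penalized log-likelihood
    lam <- 1
    repeat {
      cand <- beta + lam * step
      pc2 <- try(.firth_pieces(X, y, cand), silent = TRUE)
      ok <- !inherits(pc2, "try-error") && is.finite(pc2$pll)
      if (ok && pc2$pll >= pc$pll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) { cand <- beta; pc2 <- pc; break }
    }
    moved <- max(abs(cand - beta))
    beta <- cand; pc <- pc2
    if (moved < tol && max(abs(pc$score)) < 1e-6) {
      return(list(beta = beta, pll = pc$pll, I = pc$I, converged = TRUE,
                  iterations = it))
    }
  }
  list(beta = beta, pll = pc$pll, I = pc$I, converged = FALSE,
       iterations = maxit)
}

#' Firth-penalized logistic regression for a carrier effect
#'
#' Maximizes the Jeffreys-penalized likelihood (log-likelihood plus half the
#' log-determinant of the Fisher information), which yields finite carrier
#' estimates even under complete separation. The p-value is a penalized
#' likelihood-ratio test comparing against the model without the carrier term.
#' The pipeline runs this only for phenotype/variant combinations with at
#' least 10 events per variable (see [select_test()]); calling it below that
#' regime emits a warning rather than an error so that degenerate examples
#' remain analysable.
#'
#' @param y Binary response (0/1 or logical).
#' @param carrier 0/1 carrier indicator.
#' @param covariates Optional covariate matrix/data.frame.
#' @param maxit,tol Newton iteration controls.
#' @return One-row `data.frame` (beta = carrier log-odds, se, odds_ratio,
#'   p_value, n_carriers, n_events, method).
#' @export
firth_logistic <- function(y, carrier, covariates = NULL,
                           maxit = 100, tol = 1e-10) {
  y <- as.numeric(y); carrier <- as.numeric(carrier)
  keep <- !is.na(y) & !is.na(carrier)
  y <- y[keep]; carrier <- carrier[keep]
  X <- cbind(`(Intercept)` = 1, carrier = carrier)
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(covariates)[keep, , drop = FALSE])
  }
  n_events <- sum(y == 1)
  epv <- n_events / (ncol(X) - 1)
  if (epv < 10) {
    warning("fewer than 10 events per variable; Fisher's exact test is the ",
            "intended method in this regime")
  }
  full <- .firth_fit(X, y, maxit = maxit, tol = tol)
  if (!full$converged) {
    stop("Firth fit did not converge after ", maxit,
         " iterations (max score ", format(max(abs(full$beta))), ")")
  }
  red <- .firth_fit(X[, colnames(X) != "carrier", drop = FALSE], y,
                    maxit = maxit, tol = tol)
  lr <- max(0, 2 * (full$pll - red$pll))
  se <- sqrt(diag(solve(full$I)))[["carrier"]]
  b <- full$beta[[which(colnames(X) == "carrier")]]
  .assoc_result(beta = b, se = se, odds_ratio = exp(b),
                p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                n_carriers = as.integer(sum(carrier != 0)),
                n_events = as.integer(n_events),
                method = "firth", kind = "binary")
}

#' Choose the association test(s) for a binary phenotype
#'
#' Fisher's exact test always feeds the score pipeline; Firth-corrected
#' logistic regression is additionally run (for reporting) when there are at
#' least 10 events per variable.
#'
#' @param n_events Number of events (phenotype-positive individuals).
#' @param n_variables Number of model variables (carrier + covariates).
#' @return Character vector: `"fisher"` or `c("fisher", "firth")`.
#' @export
select_test <- function(n_events, n_variables) {
  stopifnot(n_events >= 0, n_variables >= 1)
  if (n_events > 0 && n_events / n_variables >= 10) c("fisher", "firth")
  else "fisher"
}

#' Fixed-effect (inverse-variance) meta-analysis across strata
#'
#' Pools per-stratum estimates with weights `1/se^2`; the pooled standard
#' error is `(sum(se^-2))^-1/2` and the two-sided p-value is normal. Strata
#' with non-finite beta or se (e.g. infinite odds ratios) are dropped; if all
#' are dropped an error is raised. A single usable stratum is returned
#' unchanged (with `method = "meta"`).
#'
#' @param results `data.frame` with columns `beta` and `se` (one row per
#'   stratum), e.g. rows from [ols_carrier_beta()].
#' @return One-row `data.frame` with pooled `beta`, `se`, `p_value`, the
#'   number of pooled strata `k`, and a heterogeneity note (Cochran's Q).
#' @examples
#' meta_fixed_effect(data.frame(beta = c(-0.2, -0.2), se = c(0.1, 0.1)))
#' @export
meta_fixed_effect <- function(results) {
  stopifnot(is.data.frame(results), all(c("beta", "se") %in% names(results)))
  ok <- is.finite(results$beta) & is.finite(results$se) & results$se > 0
  if (!any(ok)) stop("no stratum with finite beta and se")
  b <- results$beta[ok]; se <- results$se[ok]
  w <- 1 / se^2
  pooled <- sum(w * b) / sum(w)
  pooled_se <- sqrt(1 / sum(w))
  z <- pooled / pooled_se
  q <- sum(w * (b - pooled)^2)
  out <- .assoc_result(beta = pooled, se = pooled_se,
                       p_value = 2 * stats::pnorm(-abs(z)),
                       method = "meta")
  out$k <- sum(ok)
  out$heterogeneity_q <- q
  out$heterogeneity_p <- if (sum(ok) > 1) {
    stats::pchisq(q, df = sum(ok) - 1, lower.tail = FALSE)
  } else NA_real_
  out
}

#' Stouffer weighted-Z combination of signed p-values
#'
#' Used for binary-phenotype meta-analysis when odds ratios are infinite and
#' log-OR pooling is impossible: each stratum contributes a Z value
#' `sign * qnorm(1 - p/2)` and strata are combined with the given weights
#' (default: square root of the carrier count).
#'
#' @param p Per-stratum two-sided p-values.
#' @param sign Per-stratum effect directions (+1/-1).
#' @param weights Per-stratum weights (default equal).
#' @return One-row `data.frame` with the combined `p_value` and `method`.
#' @export
meta_stouffer <- function(p, sign, weights = rep(1, length(p))) {
  stopifnot(length(p) == length(sign), length(p) == length(weights))
  ok <- is.finite(p) & p > 0 & p <= 1
  if (!any(ok)) stop("no usable p-values")
  z <- sign[ok] * stats::qnorm(1 - p[ok] / 2)
  zc <- sum(weights[ok] * z) / sqrt(sum(weights[ok]^2))
  out <- .assoc_result(p_value = 2 * stats::pnorm(-abs(zc)),
                       method = "stouffer", kind = "binary")
  out$z <- zc
  out
}
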