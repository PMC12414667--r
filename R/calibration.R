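# Empirical null calibration: resample synonymous-variant sub-scores, set the
# detection threshold at a target percentile, and measure classifier
# performance.

# Run expr with a private RNG stream; the caller's RNG state is untouched.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Build the empirical null score distribution
#'
#' Resamples sub-scores of synonymous variants to form `B` null ADH1 scores
#' and sets the detection threshold at the target percentile. In the default
#' `"independent"` mode each draw sums components sampled independently (with
#' replacement) from the per-component empirical distributions of the
#' synonymous set; `"joint"` mode resamples whole sub-score rows, preserving
#' the observed between-component correlation. The threshold is the lower
#' empirical order statistic (no interpolation): the mass of draws at or below
#' it is exactly `ceiling(percentile/100 * B) / B`, which is reproducible
#' across numeric stacks.
#'
#' @param synonymous_subscores `data.frame`/matrix of per-component sub-score
#'   values, one row per synonymous (variant, stratum) pair.
#' @param B Number of null draws (default 10,000; at least 1,000).
#' @param percentile Target percentile for the threshold (default 98).
#' @param seed Seed for the resampling (mandatory; the draw is deterministic
#'   given the seed).
#' @param mode `"independent"` (default) or `"joint"` resampling.
#' @return Object of class `"adh1_null"`: list with `draws`, `B`,
#'   `percentile`, `threshold`, `seed`, `mode`, `n_synonymous`.
#' @export
build_null <- function(synonymous_subscores, B = 10000, percentile = 98,
                       seed = 1, mode = c("independent", "joint")) {
  mode <- match.arg(mode)
  S <- as.matrix(synonymous_subscores)
  if (nrow(S) == 0) stop("empty synonymous sub-score set")
  if (nrow(S) < 10) {
    warning("fewer than 10 synonymous variants; null distribution will be coarse")
  }
  if (B < 1000) warning("B < 1000 gives an unstable percentile estimate")
  stopifnot(percentile > 0, percentile <= 100, !is.null(seed))
  draws <- .with_seed(seed, {
    if (mode == "independent") {
      out <- numeric(B)
      for (j in seq_len(ncol(S))) {
        out <- out + S[sample.int(nrow(S), B, replace = TRUE), j]
      }
      out
    } else {
      rowSums(S[sample.int(nrow(S), B, replace = TRUE), , drop = FALSE])
    }
  })
  sorted <- sort(draws)
  threshold <- sorted[ceiling(percentile / 100 * B)]
  structure(list(draws = draws, B = as.integer(B), percentile = percentile,
                 threshold = threshold, seed = seed, mode = mode,
                 n_synonymous = nrow(S)),
            class = "adh1_null")
}

#' @export
print.adh1_null <- function(x, ...) {
  cat(sprintf(
    "Empirical null: %d draws (%s resampling of %d synonymous sub-score rows)\n",
    x$B, x$mode, x$n_synonymous))
  cat(sprintf("  threshold at percentile %g: %.4g (fraction of draws <= threshold: %.4f)\n",
              x$percentile, x$threshold, mean(x$draws <= x$threshold)))
  invisible(x)
}

#' Sensitivity and specificity at a score threshold
#'
#' Sensitivity is the fraction of positives scoring strictly above the
#' threshold; specificity is the fraction of negatives scoring at or below
#' it. A metric whose class is absent is missing (`NA`), not zero.
#'
#' @param scores Numeric scores.
#' @param labels Character vector, `"positive"` or `"negative"`.
#' @param threshold Score threshold.
#' @return List of class `"adh1_performance"`: `sensitivity`, `specificity`,
#'   `n_positives`, `n_negatives`, `threshold`, and the confusion counts
#'   `tp`, `fn`, `tn`, `fp`.
#' @export
sens_spec <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("positive", "negative")))
  pos <- labels == "positive"
  neg <- labels == "negative"
  tp <- sum(scores[pos] > threshold); fn <- sum(pos) - tp
  tn <- sum(scores[neg] <= threshold); fp <- sum(neg) - tn
  structure(list(
    sensitivity = if (any(pos)) tp / sum(pos) else NA_real_,
    specificity = if (any(neg)) tn / sum(neg) else NA_real_,
    n_positives = sum(pos), n_negatives = sum(neg),
    threshold = threshold, tp = tp, fn = fn, tn = tn, fp = fp),
    class = "adh1_performance")
}

#' @export
print.adh1_performance <- function(x, ...) {
  cat(sprintf("sensitivity %.3f (%d positives), specificity %.3f (%d negatives) at threshold %.3g\n",
              x$sensitivity, x$n_positives, x$specificity, x$n_negatives,
              x$threshold))
  invisible(x)
}

#' Resolve the detection threshold (fixed vs. empirical)
#'
#' In `"fixed"` mode returns the reference threshold 1.5 (or the supplied
#' value) verbatim, bypassing the null; in `"empirical"` mode returns the
#' calibrated threshold from a [build_null()] object. The provenance (mode
#' and value) is recorded in the result so run manifests can report it.
#'
#' @param mode `"fixed"` or `"empirical"`.
#' @param null An `"adh1_null"` object (required for `"empirical"`).
#' @param fixed_value Threshold used in `"fixed"` mode (default 1.5).
#' @return List with `threshold` and `mode`.
#' @export
resolve_threshold <- function(mode = c("empirical", "fixed"), null = NULL,
                              fixed_value = 1.5) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    list(threshold = fixed_value, mode = "fixed")
  } else {
    if (!inherits(null, "adh1_null")) {
      stop("empirical mode requires a build_null() result")
    }
    list(threshold = null$threshold, mode = "empirical")
  }
}
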