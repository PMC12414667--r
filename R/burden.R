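# Carrier frequency, lab and diagnosis-code penetrance, excess symptom
# burden, allelic-series summaries, and cross-cohort concordance.

#' Carrier frequency per 100,000 cohort members
#'
#' Exact ratio `n_carriers / cohort_n * 100000`, computed on integer counts.
#' Note that published aggregate frequencies sometimes use a different
#' denominator than the full cohort; this function always reports the exact
#' ratio of its inputs.
#'
#' @param n_carriers Number of carriers (>= 0).
#' @param cohort_n Cohort size (> 0).
#' @return Frequency per 100,000.
#' @examples
#' carrier_frequency(10, 433793)   # 2.31 per 100k
#' @export
carrier_frequency <- function(n_carriers, cohort_n) {
  stopifnot(cohort_n > 0)
  if (any(n_carriers < 0)) stop("negative carrier count")
  n_carriers / cohort_n * 1e5
}

#' Laboratory penetrance among carriers
#'
#' Fraction of carrier lab values strictly beyond a normal limit in the
#' stated direction (e.g. calcium below the LLN, phosphate above the ULN).
#'
#' @param carrier_values Numeric lab values (mM), one per carrier.
#' @param limit Normal limit.
#' @param direction `"below"` or `"above"`.
#' @return Fraction in `[0, 1]`; `NA` if no non-missing values.
#' @examples
#' lab_penetrance(c(2.13, 2.07, 1.96, 2.39), 2.2, "below")
#' @export
lab_penetrance <- function(carrier_values, limit,
                           direction = c("below", "above")) {
  direction <- match.arg(direction)
  v <- carrier_values[!is.na(carrier_values)]
  if (length(v) == 0) return(NA_real_)
  n <- if (direction == "below") sum(v < limit) else sum(v > limit)
  n / length(v)
}

#' Diagnosis-code penetrance among evaluable carriers
#'
#' Fraction of evaluable carriers (those with adequate record coverage, e.g.
#' both in-patient and primary-care records) with at least one phecode in the
#' directly ADH1-suggestive categories (calcium/phosphorus disorder and
#' hypoparathyroidism by default).
#'
#' @param carrier_phenotypes Phenotype rows for carriers (from
#'   [build_phenotypes()]), with the `dx_*` columns and `record_coverage`.
#' @param categories Category labels counted as directly suggestive.
#' @param evaluable Optional logical overriding the `record_coverage` column.
#' @return Fraction in `[0, 1]`; `NA` when no carrier is evaluable.
#' @export
dx_penetrance <- function(carrier_phenotypes,
                          categories = ADH1_DIRECT_DX_CATEGORIES,
                          evaluable = NULL) {
  if (is.null(evaluable)) {
    evaluable <- as.logical(carrier_phenotypes$record_coverage)
  }
  stopifnot(length(evaluable) == nrow(carrier_phenotypes))
  if (!any(evaluable)) return(NA_real_)
  cols <- paste0("dx_", categories)
  miss <- setdiff(cols, names(carrier_phenotypes))
  if (length(miss)) stop("missing category columns: ",
                         paste(miss, collapse = ", "))
  flagged <- Reduce(`|`, carrier_phenotypes[cols])
  sum(flagged & evaluable) / sum(evaluable)
}

#' Excess symptom burden over the cohort baseline
#'
#' `expected = n_carriers * baseline_rate`; `excess = max(0, observed -
#' expected)`, scaled per 100,000 cohort members. The headline excess floors
#' at zero; the signed value is kept in `excess_raw` for diagnostics.
#'
#' @param observed_affected Carriers with at least one ADH1-relevant
#'   diagnosis (<= `n_carriers`).
#' @param n_carriers Number of carriers.
#' @param baseline_rate Baseline rate of the phenotype among non-carriers,
#'   in `[0, 1]`.
#' @param cohort_n Cohort size.
#' @return List of class `"adh1_burden"`: `n_carriers`, `cohort_n`,
#'   `frequency_per_100k`, `observed_affected`, `expected_affected`,
#'   `excess`, `excess_raw`, `excess_per_100k`.
#' @examples
#' excess_burden(20, 60, 0.10, 433793)  # expected 6, excess 14
#' @export
excess_burden <- function(observed_affected, n_carriers, baseline_rate,
                          cohort_n) {
  stopifnot(baseline_rate >= 0, baseline_rate <= 1, cohort_n > 0,
            n_carriers >= 0)
  if (observed_affected > n_carriers) {
    stop("observed_affected exceeds n_carriers")
  }
  expected <- n_carriers * baseline_rate
  raw <- observed_affected - expected
  excess <- max(0, raw)
  structure(list(
    n_carriers = n_carriers, cohort_n = cohort_n,
    frequency_per_100k = carrier_frequency(n_carriers, cohort_n),
    observed_affected = observed_affected, expected_affected = expected,
    excess = excess, excess_raw = raw,
    excess_per_100k = excess / cohort_n * 1e5),
    class = "adh1_burden")
}

#' @export
print.adh1_burden <- function(x, ...) {
  cat(sprintf(
    "carriers %d/%d (%.3g per 100k); affected %d observed vs %.2f expected -> excess %.2f (%.3g per 100k)\n",
    x$n_carriers, x$cohort_n, x$frequency_per_100k, x$observed_affected,
    x$expected_affected, x$excess, x$excess_per_100k))
  invisible(x)
}

#' Allelic-series summary: effect size versus frequency by variant class
#'
#' Per-class median calcium effect, effect range, frequency range and variant
#' count -- the boxplot-ready table for the allelic series (common
#' calcium-associated variation at one end, rare familial gain-of-function
#' variants at the other). Empty classes are omitted with a warning.
#'
#' @param variants `data.frame` with columns `class` (label), `variant_id`,
#'   `beta` (calcium effect, mM) and `maf`.
#' @param class_order Optional ordering of class labels in the output.
#' @return `data.frame` with one row per non-empty class: `class`, `n`,
#'   `median_beta`, `min_beta`, `max_beta`, `min_maf`, `max_maf`.
#' @export
allelic_series_summary <- function(variants, class_order = NULL) {
  stopifnot(all(c("class", "variant_id", "beta", "maf") %in% names(variants)))
  classes <- if (is.null(class_order)) unique(variants$class) else class_order
  empty <- setdiff(classes, variants$class)
  if (length(empty)) {
    warning("empty classes omitted: ", paste(empty, collapse = ", "))
    classes <- setdiff(classes, empty)
  }
  rows <- lapply(classes, function(cl) {
    sub <- variants[variants$class == cl & !is.na(variants$beta), ,
                    drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(class = cl, n = nrow(sub),
               median_beta = stats::median(sub$beta),
               min_beta = min(sub$beta), max_beta = max(sub$beta),
               min_maf = suppressWarnings(min(sub$maf, na.rm = TRUE)),
               max_maf = suppressWarnings(max(sub$maf, na.rm = TRUE)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Cross-cohort concordance of above-threshold calls
#'
#' Counts variants above threshold in cohort A only, cohort B only, and both
#' (over the harmonized shared variant ID space), and -- when per-cohort
#' calcium effects are supplied for a third cohort -- the fraction of shared
#' variants whose calcium effect has the same sign there.
#'
#' @param scores_a,scores_b `data.frame`s with `variant_id` and `score`.
#' @param threshold Score threshold applied to both cohorts.
#' @param beta_a Optional named numeric: calcium betas in cohort A (names =
#'   variant IDs).
#' @param beta_third Optional named numeric: calcium betas in a third
#'   validation cohort.
#' @return List: `n_shared`, `above_a_only`, `above_b_only`, `above_both`,
#'   `shared_above_both` (IDs), `sign_concordance` (`NA` without betas).
#' @export
cross_cohort_concordance <- function(scores_a, scores_b, threshold,
                                     beta_a = NULL, beta_third = NULL) {
  shared <- intersect(scores_a$variant_id, scores_b$variant_id)
  sa <- stats::setNames(scores_a$score, scores_a$variant_id)[shared]
  sb <- stats::setNames(scores_b$score, scores_b$variant_id)[shared]
  above_a <- sa > threshold
  above_b <- sb > threshold
  conc <- NA_real_
  if (!is.null(beta_a) && !is.null(beta_third)) {
    ids <- intersect(names(beta_a), names(beta_third))
    ids <- intersect(ids, shared)
    ok <- is.finite(beta_a[ids]) & is.finite(beta_third[ids]) &
      beta_a[ids] != 0 & beta_third[ids] != 0
    if (any(ok)) {
      conc <- mean(sign(beta_a[ids][ok]) == sign(beta_third[ids][ok]))
    }
  }
  list(n_shared = length(shared),
       above_a_only = sum(above_a & !above_b),
       above_b_only = sum(!above_a & above_b),
       above_both = sum(above_a & above_b),
       shared_above_both = shared[above_a & above_b],
       sign_concordance = conc)
}
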