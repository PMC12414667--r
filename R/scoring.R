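# The ADH1 variant score: weighted, direction-constrained sub-scores summed
# per (variant, stratum); the variant-level score is the maximum over strata.

#' Sub-score weights and constants for the ADH1 score
#'
#' Defaults: 3 for serum calcium, 1 for serum phosphate (only about half of
#' affected carriers are hyperphosphatemic), 1 for each ADH1-associated
#' diagnosis category and 1 for medications, 0.5 for location in a known
#' gain-of-function hotspot (residues 116-136 and 819-837), 0.2 for the
#' in-silico pathogenicity consensus, with nominal significance alpha = 0.05.
#'
#' @param calcium,phosphate,dx_category,medication,hotspot,insilico
#'   Component weights (all >= 0).
#' @param nominal_alpha Significance level gating the association components.
#' @param hotspot_ranges Two-column matrix of inclusive 1-based protein
#'   residue ranges.
#' @return List of class `"adh1_weights"`.
#' @export
score_weights <- function(calcium = 3, phosphate = 1, dx_category = 1,
                          medication = 1, hotspot = 0.5, insilico = 0.2,
                          nominal_alpha = 0.05,
                          hotspot_ranges = rbind(c(116, 136), c(819, 837))) {
  w <- list(calcium = calcium, phosphate = phosphate,
            dx_category = dx_category, medication = medication,
            hotspot = hotspot, insilico = insilico,
            nominal_alpha = nominal_alpha,
            hotspot_ranges = hotspot_ranges)
  stopifnot(all(unlist(w[1:6]) >= 0), nominal_alpha > 0, nominal_alpha < 1,
            is.matrix(hotspot_ranges), ncol(hotspot_ranges) == 2,
            all(hotspot_ranges[, 1] <= hotspot_ranges[, 2]))
  structure(w, class = "adh1_weights")
}

#' Is a protein position inside a known gain-of-function hotspot?
#'
#' @param protein_position 1-based residue index (vectorized).
#' @param ranges Inclusive residue ranges (default 116-136 and 819-837).
#' @return Logical vector.
#' @examples
#' hotspot_flag(c(104, 124, 137, 819))
#' @export
hotspot_flag <- function(protein_position,
                         ranges = score_weights()$hotspot_ranges) {
  stopifnot(all(is.na(protein_position) | protein_position >= 1))
  out <- rep(FALSE, length(protein_position))
  for (i in seq_len(nrow(ranges))) {
    out <- out | (!is.na(protein_position) &
                    protein_position >= ranges[i, 1] &
                    protein_position <= ranges[i, 2])
  }
  out
}

# Shared grading of an association-driven component: binary (weight iff
# p <= alpha and the direction is right) or graded
# (weight * min(1, log10(p)/log10(alpha)), direction-gated).
.grade_component <- function(weight, p, direction_ok, grading) {
  if (is.na(p) || !direction_ok) return(0)
  if (grading == "binary") {
    if (p <= 1 && p > 0 && p <= attr(grading, "alpha")) weight else 0
  } else {
    weight * min(1, log10(max(p, 1e-300)) / log10(attr(grading, "alpha")))
  }
}

.grading <- function(grading, alpha) {
  grading <- match.arg(grading, c("binary", "graded"))
  attr(grading, "alpha") <- alpha
  grading
}

#' Serum-calcium sub-score
#'
#' Fires (value `w_calcium`) iff the carrier association with serum calcium is
#' nominally significant *and* in the gain-of-function direction (beta < 0,
#' i.e. carriers have lower calcium). In graded mode the component is
#' `w * min(1, log10(p)/log10(alpha))`, still direction-gated.
#'
#' @param beta,p_value Carrier effect (mM) and p-value from
#'   [ols_carrier_beta()].
#' @param weights [score_weights()].
#' @param grading `"binary"` (default) or `"graded"`.
#' @return Component value.
#' @export
calcium_subscore <- function(beta, p_value, weights = score_weights(),
                             grading = "binary") {
  g <- .grading(grading, weights$nominal_alpha)
  if (is.na(beta)) return(0)
  .grade_component(weights$calcium, p_value, beta < 0, g)
}

#' Serum-phosphate sub-score
#'
#' As [calcium_subscore()] but the gain-of-function direction is beta > 0
#' (carriers have higher phosphate).
#'
#' @inheritParams calcium_subscore
#' @export
phosphate_subscore <- function(beta, p_value, weights = score_weights(),
                               grading = "binary") {
  g <- .grading(grading, weights$nominal_alpha)
  if (is.na(beta)) return(0)
  .grade_component(weights$phosphate, p_value, beta > 0, g)
}

#' Diagnosis-category and medication sub-scores
#'
#' A diagnosis category scores `w_dx_category` iff at least one carrier has a
#' phecode in that category *and* the category's Fisher enrichment p-value is
#' at most alpha; the medication component behaves the same with "at least one
#' carrier counts an ADH1-associated medication".
#'
#' @param carrier_any Named logical: does any carrier have the category
#'   phenotype? (names = category labels; one element `medication` allowed or
#'   supplied separately).
#' @param enrichment_p Named numeric of Fisher p-values, same names.
#' @param med_any,med_p Medication presence flag and enrichment p.
#' @param weights [score_weights()].
#' @param grading `"binary"` or `"graded"`.
#' @return List with `dx` (named numeric per category), `medication`
#'   (single value).
#' @export
dx_medication_subscores <- function(carrier_any, enrichment_p,
                                    med_any = FALSE, med_p = NA_real_,
                                    weights = score_weights(),
                                    grading = "binary") {
  g <- .grading(grading, weights$nominal_alpha)
  stopifnot(identical(names(carrier_any), names(enrichment_p)))
  dx <- vapply(names(carrier_any), function(cat) {
    .grade_component(weights$dx_category, enrichment_p[[cat]],
                     isTRUE(carrier_any[[cat]]), g)
  }, numeric(1))
  med <- .grade_component(weights$medication, med_p, isTRUE(med_any), g)
  list(dx = dx, medication = med)
}

#' In-silico pathogenicity sub-score
#'
#' Fires iff a strict majority of the in-silico predictor ensemble calls the
#' variant deleterious (fraction > 0.5). Missing input scores 0.
#'
#' @param fraction_deleterious Fraction of ensemble predictors calling the
#'   variant deleterious, in `[0, 1]`.
#' @param weights [score_weights()].
#' @return Component value.
#' @export
insilico_subscore <- function(fraction_deleterious,
                              weights = score_weights()) {
  if (is.na(fraction_deleterious)) return(0)
  stopifnot(fraction_deleterious >= 0, fraction_deleterious <= 1)
  if (fraction_deleterious > 0.5) weights$insilico else 0
}

.SCORE_COMPONENTS <- function(categories) {
  c("calcium", "phosphate", paste0("dx_", categories),
    "medication", "hotspot", "insilico")
}

.parse_carriers <- function(x) {
  if (is.na(x) || x == "") character(0)
  else strsplit(x, ",", fixed = TRUE)[[1L]]
}

#' ADH1 score for a single variant (reference path)
#'
#' Computes the per-stratum sub-score vector and the variant-level score
#' (maximum over strata) for one variant, calling the individual association
#' operations directly. [adh1_scan()] computes the same quantities for all
#' variants through an algebraically equivalent batch path; the two agree
#' exactly and are cross-checked in the test suite.
#'
#' @param variant One-row `data.frame` with `variant_id`, `consequence`,
#'   `protein_position`, `carriers` (comma-separated individual IDs) and
#'   `insilico_fraction_deleterious`.
#' @param phenotypes Phenotype table from [build_phenotypes()].
#' @param weights [score_weights()].
#' @param maf_cutoff Strata where the realized MAF (carriers / 2n) is at or
#'   above this are not scored (default 0.01).
#' @param grading `"binary"` or `"graded"` sub-score grading.
#' @return List with `subscores` (`data.frame`, one row per scored stratum)
#'   and `variant_score` (max total across strata).
#' @export
adh1_score <- function(variant, phenotypes, weights = score_weights(),
                       maf_cutoff = 0.01, grading = "binary") {
  stopifnot(nrow(variant) == 1)
  carriers <- .parse_carriers(variant$carriers)
  if (length(carriers) == 0) stop("variant has no carriers in any stratum")
  categories <- names(adh1_phecode_categories())
  comp_names <- .SCORE_COMPONENTS(categories)
  is_carrier <- phenotypes$individual_id %in% carriers
  rows <- NULL
  for (st in unique(phenotypes$stratum[is_carrier])) {
    ph <- phenotypes[phenotypes$stratum == st, , drop = FALSE]
    carr <- ph$individual_id %in% carriers
    k <- sum(carr)
    maf <- k / (2 * nrow(ph))
    if (maf >= maf_cutoff) next
    covs <- cbind(age = ph$age, male = as.numeric(ph$sex == "male"),
                  as.matrix(ph[, grep("^pc[0-9]+$", names(ph)), drop = FALSE]))
    ca <- tryCatch(ols_carrier_beta(ph$calcium, carr, covs),
                   error = function(e) .assoc_result())
    pho <- tryCatch(ols_carrier_beta(ph$phosphate, carr, covs),
                    error = function(e) .assoc_result())
    carrier_any <- enr_p <- stats::setNames(vector("list", length(categories)),
                                            categories)
    for (cat in categories) {
      flag <- ph[[paste0("dx_", cat)]]
      a <- sum(flag & carr); b <- k - a
      cc <- sum(flag & !carr); d <- sum(!carr) - cc
      carrier_any[[cat]] <- a >= 1
      enr_p[[cat]] <- if (a >= 1) fisher_carrier_enrichment(a, b, cc, d)$p_value
                      else NA_real_
    }
    am <- sum(ph$med_user & carr)
    med_p <- if (am >= 1) {
      fisher_carrier_enrichment(am, k - am, sum(ph$med_user & !carr),
                                sum(!carr) - sum(ph$med_user & !carr))$p_value
    } else NA_real_
    dxmed <- dx_medication_subscores(
      stats::setNames(unlist(carrier_any), categories),
      stats::setNames(unlist(enr_p), categories),
      med_any = am >= 1, med_p = med_p, weights = weights, grading = grading)
    comp <- c(
      calcium = calcium_subscore(ca$beta, ca$p_value, weights, grading),
      phosphate = phosphate_subscore(pho$beta, pho$p_value, weights, grading),
      stats::setNames(dxmed$dx, paste0("dx_", categories)),
      medication = dxmed$medication,
      hotspot = if (hotspot_flag(variant$protein_position,
                                 weights$hotspot_ranges)) weights$hotspot else 0,
      insilico = insilico_subscore(variant$insilico_fraction_deleterious,
                                   weights))
    row <- data.frame(variant_id = variant$variant_id, stratum = st,
                      n_carriers = k, maf = maf,
                      calcium_beta = ca$beta, calcium_p = ca$p_value,
                      phosphate_beta = pho$beta, phosphate_p = pho$p_value,
                      stringsAsFactors = FALSE)
    for (nm in comp_names) row[[paste0("s_", nm)]] <- unname(comp[[nm]])
    row$total <- sum(comp)
    rows <- rbind(rows, row)
  }
  if (is.null(rows)) {
    return(list(subscores = NULL, variant_score = NA_real_))
  }
  list(subscores = rows, variant_score = max(rows$total))
}

# Per-stratum precomputation shared by all variants: covariate QR, lab
# residuals and binary phenotype flags (Frisch-Waugh-Lovell batch OLS).
.stratum_context <- function(ph, categories) {
  covs <- cbind(intercept = 1, age = ph$age,
                male = as.numeric(ph$sex == "male"),
                as.matrix(ph[, grep("^pc[0-9]+$", names(ph)), drop = FALSE]))
  ctx <- list(ids = ph$individual_id, n = nrow(ph))
  for (lab in c("calcium", "phosphate")) {
    y <- ph[[lab]]
    ok <- which(!is.na(y))
    if (length(ok) > ncol(covs) + 1) {
      qr_ <- qr(covs[ok, , drop = FALSE])
      Q <- qr.Q(qr_)
      e <- y[ok] - Q %*% crossprod(Q, y[ok])
      ctx[[lab]] <- list(ok = ok, Q = Q, e = drop(e), rss = sum(e^2),
                         df = length(ok) - qr_$rank - 1L,
                         pos = stats::setNames(seq_along(ok), ph$individual_id[ok]))
    } else ctx[[lab]] <- NULL
  }
  flags <- do.call(cbind, c(
    lapply(categories, function(cat) as.logical(ph[[paste0("dx_", cat)]])),
    list(as.logical(ph$med_user))))
  colnames(flags) <- c(categories, "medication")
  ctx$flags <- flags
  ctx$flag_totals <- colSums(flags)
  ctx
}

# Exact OLS carrier beta/p against the precomputed stratum context.
.batch_ols <- function(ctx_lab, carrier_ids) {
  if (is.null(ctx_lab)) return(c(beta = NA_real_, p = NA_real_))
  pos <- ctx_lab$pos[carrier_ids]
  pos <- pos[!is.na(pos)]
  k <- length(pos)
  if (k == 0 || ctx_lab$df <= 0) return(c(beta = NA_real_, p = NA_real_))
  qx <- colSums(ctx_lab$Q[pos, , drop = FALSE])
  exx <- k - sum(qx^2)
  if (exx <= 1e-10) return(c(beta = NA_real_, p = NA_real_))
  beta <- sum(ctx_lab$e[pos]) / exx
  s2 <- (ctx_lab$rss - beta^2 * exx) / ctx_lab$df
  if (s2 <= 0) return(c(beta = beta, p = 0))
  tval <- beta / sqrt(s2 / exx)
  c(beta = beta, p = 2 * stats::pt(-abs(tval), ctx_lab$df))
}

#' Score every variant in a cohort: the ADH1 scan
#'
#' The central fitting function. For each variant and each ancestry stratum
#' with at least one carrier (and realized MAF below `maf_cutoff`), computes
#' the direction-constrained sub-scores against the cohort phenotypes, sums
#' them into the per-stratum ADH1 score, takes the variant-level score as the
#' maximum over strata, calibrates the detection threshold on the empirical
#' null built by resampling synonymous-variant sub-scores (or uses the fixed
#' threshold 1.5), and reports candidate gain-of-function calls. Missense,
#' nonsense and frameshift variants are candidates; synonymous variants are
#' scored too (they form the null); variants already annotated as known
#' ADH1/FHH1 are scored but excluded from novel calls.
#'
#' @param variants Variant table: `variant_id`, `consequence`,
#'   `protein_position`, `carriers` (comma-separated individual IDs),
#'   `insilico_fraction_deleterious`, `known_status`
#'   (`known_adh1`/`known_fhh1`/`novel`).
#' @param individuals Raw individual table (see [build_phenotypes()]), or
#'   `NULL` if `phenotypes` is given.
#' @param phenotypes Optional prebuilt phenotype table.
#' @param phecode_map,policy,labs Passed to [build_phenotypes()] when
#'   `phenotypes` is `NULL`.
#' @param weights [score_weights()].
#' @param maf_cutoff Rare-variant MAF filter (default 0.01).
#' @param threshold `"empirical"` (calibrated on the synonymous null) or
#'   `"fixed"` (use `fixed_threshold` verbatim).
#' @param fixed_threshold Fixed threshold value (default 1.5).
#' @param B,percentile,null_resampling Null-calibration controls, see
#'   [build_null()].
#' @param grading `"binary"` (default) or `"graded"` sub-scores.
#' @param seed Seed for the null resampling (required for the empirical
#'   threshold).
#' @return Object of class `"adh1_scan"`: list with `scores` (per
#'   variant-stratum sub-scores and totals), `variant_scores` (per-variant
#'   maxima, candidate flags and calls), `null` ([build_null()] object or
#'   `NULL`), `threshold`, `threshold_mode`, `performance` (sensitivity /
#'   specificity against known-ADH1 positives and synonymous negatives, when
#'   both present), `weights`, `grading`, `strata`, `n_individuals`.
#' @seealso [adh1_score()] for the single-variant reference path;
#'   [build_null()]; [sens_spec()].
#' @export
adh1_scan <- function(variants, individuals = NULL, phenotypes = NULL,
                      phecode_map = adh1_phecode_map(), labs = NULL,
                      policy = "mean", weights = score_weights(),
                      maf_cutoff = 0.01,
                      threshold = c("empirical", "fixed"),
                      fixed_threshold = 1.5, B = 10000, percentile = 98,
                      null_resampling = c("independent", "joint"),
                      grading = c("binary", "graded"), seed = 1) {
  threshold <- match.arg(threshold)
  null_resampling <- match.arg(null_resampling)
  grading <- match.arg(grading)
  stopifnot(is.data.frame(variants))
  req <- c("variant_id", "consequence", "protein_position", "carriers",
           "insilico_fraction_deleterious", "known_status")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(variants$variant_id)) stop("duplicate variant IDs")
  if (is.null(phenotypes)) {
    if (is.null(individuals)) stop("supply individuals or phenotypes")
    phenotypes <- build_phenotypes(individuals, phecode_map = phecode_map,
                                   labs = labs, policy = policy)
  }
  categories <- names(adh1_phecode_categories())
  comp_names <- .SCORE_COMPONENTS(categories)
  strata <- sort(unique(phenotypes$stratum))
  ctx <- lapply(stats::setNames(strata, strata), function(st) {
    .stratum_context(phenotypes[phenotypes$stratum == st, , drop = FALSE],
                     categories)
  })
  id2stratum <- stats::setNames(phenotypes$stratum, phenotypes$individual_id)

  scored <- variants$consequence %in% c("missense", "nonsense", "frameshift",
                                        "synonymous")
  rows <- vector("list", nrow(variants))
  for (i in which(scored)) {
    v <- variants[i, ]
    carriers <- .parse_carriers(v$carriers)
    if (length(carriers) == 0) next
    hs <- hotspot_flag(v$protein_position, weights$hotspot_ranges)
    ins <- insilico_subscore(v$insilico_fraction_deleterious, weights)
    by_st <- split(carriers, id2stratum[carriers])
    g <- .grading(grading, weights$nominal_alpha)
    vrows <- NULL
    for (st in names(by_st)) {
      if (is.na(st)) next
      cx <- ctx[[st]]
      ids <- by_st[[st]]
      k <- length(ids)
      maf <- k / (2 * cx$n)
      if (maf >= maf_cutoff) next
      ca <- .batch_ols(cx$calcium, ids)
      pho <- .batch_ols(cx$phosphate, ids)
      carr_rows <- match(ids, cx$ids)
      a_vec <- colSums(cx$flags[carr_rows, , drop = FALSE])
      comp <- stats::setNames(numeric(length(comp_names)), comp_names)
      comp["calcium"] <- calcium_subscore(ca[["beta"]], ca[["p"]],
                                          weights, grading)
      comp["phosphate"] <- phosphate_subscore(pho[["beta"]], pho[["p"]],
                                              weights, grading)
      for (j in seq_along(categories)) {
        a <- a_vec[[j]]
        if (a >= 1) {
          tot <- cx$flag_totals[[j]]
          p <- .fisher_p2(a, k - a, tot - a, cx$n - k - (tot - a))
          comp[paste0("dx_", categories[j])] <-
            .grade_component(weights$dx_category, p, TRUE, g)
        }
      }
      am <- a_vec[["medication"]]
      if (am >= 1) {
        tot <- cx$flag_totals[["medication"]]
        p <- .fisher_p2(am, k - am, tot - am, cx$n - k - (tot - am))
        comp["medication"] <- .grade_component(weights$medication, p, TRUE, g)
      }
      comp["hotspot"] <- if (hs) weights$hotspot else 0
      comp["insilico"] <- ins
      row <- data.frame(variant_id = v$variant_id, stratum = st,
                        consequence = v$consequence,
                        known_status = v$known_status,
                        n_carriers = k, maf = maf,
                        calcium_beta = ca[["beta"]], calcium_p = ca[["p"]],
                        phosphate_beta = pho[["beta"]],
                        phosphate_p = pho[["p"]],
                        stringsAsFactors = FALSE)
      for (nm in comp_names) row[[paste0("s_", nm)]] <- comp[[nm]]
      row$total <- sum(comp)
      vrows <- rbind(vrows, row)
    }
    rows[[i]] <- vrows
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(scores) || nrow(scores) == 0) {
    stop("no variant could be scored (no carriers under the MAF cutoff?)")
  }

  agg <- scores[order(scores$variant_id, -scores$total), ]
  vs <- agg[!duplicated(agg$variant_id),
            c("variant_id", "consequence", "known_status")]
  vs$score <- tapply(scores$total, scores$variant_id, max)[vs$variant_id]
  vs <- vs[order(match(vs$variant_id, variants$variant_id)), ]
  rownames(vs) <- NULL

  syn <- scores[scores$consequence == "synonymous", , drop = FALSE]
  null <- NULL
  if (threshold == "empirical") {
    if (nrow(syn) == 0) stop("empirical threshold requested but no ",
                             "synonymous variants were scored")
    null <- build_null(syn[, paste0("s_", comp_names), drop = FALSE],
                       B = B, percentile = percentile, seed = seed,
                       mode = null_resampling)
  }
  thr <- resolve_threshold(mode = threshold, null = null,
                           fixed_value = fixed_threshold)

  vs$candidate <- vs$consequence %in% c("missense", "nonsense", "frameshift") &
    vs$known_status == "novel"
  vs$above_threshold <- vs$score > thr$threshold

  performance <- NULL
  pos <- vs$known_status == "known_adh1"
  neg <- vs$consequence == "synonymous"
  if (any(pos) || any(neg)) {
    labels <- rep(NA_character_, nrow(vs))
    labels[pos] <- "positive"; labels[neg] <- "negative"
    keep <- !is.na(labels)
    performance <- sens_spec(vs$score[keep], labels[keep], thr$threshold)
  }

  structure(list(scores = scores, variant_scores = vs, null = null,
                 threshold = thr$threshold, threshold_mode = thr$mode,
                 performance = performance, weights = weights,
                 grading = grading, maf_cutoff = maf_cutoff,
                 strata = strata,
                 n_individuals = nrow(phenotypes),
                 component_names = comp_names,
                 call = match.call()),
            class = "adh1_scan")
}

#' @export
print.adh1_scan <- function(x, ...) {
  cat("ADH1 variant scan\n")
  cat(sprintf("  %d variants scored (%d variant-stratum pairs) in %d strat%s, n = %d individuals\n",
              nrow(x$variant_scores), nrow(x$scores), length(x$strata),
              if (length(x$strata) == 1) "um" else "a", x$n_individuals))
  cat(sprintf("  threshold: %.3g (%s), grading: %s\n",
              x$threshold, x$threshold_mode, x$grading))
  calls <- sum(x$variant_scores$candidate & x$variant_scores$above_threshold)
  cat(sprintf("  candidate calls above threshold: %d\n", calls))
  invisible(x)
}

#' @export
summary.adh1_scan <- function(object, ...) {
  vs <- object$variant_scores
  by_cons <- table(vs$consequence)
  perf <- object$performance
  top <- vs[vs$candidate & vs$above_threshold, ]
  top <- top[order(-top$score), c("variant_id", "consequence", "score")]
  out <- list(n_variants = nrow(vs), by_consequence = by_cons,
              threshold = object$threshold,
              threshold_mode = object$threshold_mode,
              mean_score_synonymous =
                mean(vs$score[vs$consequence == "synonymous"]),
              mean_score_known_adh1 =
                mean(vs$score[vs$known_status == "known_adh1"]),
              performance = perf,
              calls = utils::head(top, 10), n_calls = nrow(top))
  class(out) <- "summary.adh1_scan"
  out
}

#' @export
print.summary.adh1_scan <- function(x, ...) {
  cat("ADH1 variant scan summary\n")
  cat("  variants by consequence:\n")
  print(x$by_consequence)
  cat(sprintf("  threshold %.3g (%s)\n", x$threshold, x$threshold_mode))
  if (!is.na(x$mean_score_synonymous)) {
    cat(sprintf("  mean score synonymous: %.3g", x$mean_score_synonymous))
    if (!is.na(x$mean_score_known_adh1)) {
      cat(sprintf("; known ADH1: %.3g", x$mean_score_known_adh1))
    }
    cat("\n")
  }
  if (!is.null(x$performance)) {
    cat(sprintf("  sensitivity %.3g (n=%d), specificity %.3g (n=%d)\n",
                x$performance$sensitivity, x$performance$n_positives,
                x$performance$specificity, x$performance$n_negatives))
  }
  cat(sprintf("  %d candidate call(s) above threshold", x$n_calls))
  if (x$n_calls > 0) {
    cat("; top:\n")
    print(x$calls, row.names = FALSE)
  } else cat("\n")
  invisible(x)
}

#' @export
coef.adh1_scan <- function(object, ...) {
  stats::setNames(object$variant_scores$score,
                  object$variant_scores$variant_id)
}

#' Classify variant scores against the calibrated threshold
#'
#' @param object An [adh1_scan()] fit.
#' @param newdata Optional `data.frame` of sub-score rows (the `s_*` component
#'   columns, or a `total`/`score` column); defaults to the fitted variants.
#' @param type `"call"` (logical above-threshold) or `"score"`.
#' @param ... Unused.
#' @return Named vector of scores or above-threshold calls.
#' @export
predict.adh1_scan <- function(object, newdata = NULL,
                              type = c("call", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    sc <- coef(object)
  } else {
    comp_cols <- paste0("s_", object$component_names)
    sc <- if (all(comp_cols %in% names(newdata))) {
      rowSums(newdata[, comp_cols, drop = FALSE])
    } else if ("total" %in% names(newdata)) newdata$total
    else if ("score" %in% names(newdata)) newdata$score
    else stop("newdata must carry the s_* component columns or a total/score column")
    if ("variant_id" %in% names(newdata)) names(sc) <- newdata$variant_id
  }
  if (type == "score") sc else sc > object$threshold
}

#' Plot the score distribution of a scan
#'
#' Histogram of variant-level ADH1 scores with the calibrated threshold;
#' synonymous (null) variants drawn separately from candidate classes.
#'
#' @param x An [adh1_scan()] fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.adh1_scan <- function(x, ...) {
  vs <- x$variant_scores
  syn <- vs$score[vs$consequence == "synonymous"]
  oth <- vs$score[vs$consequence != "synonymous"]
  brk <- pretty(range(vs$score, x$threshold, finite = TRUE), n = 30)
  h_all <- graphics::hist(oth, breaks = brk, plot = FALSE)
  h_syn <- graphics::hist(syn, breaks = brk, plot = FALSE)
  ymax <- max(h_all$counts, h_syn$counts, 1)
  graphics::plot(h_all, col = grDevices::adjustcolor("firebrick", 0.6),
                 border = NA, ylim = c(0, ymax),
                 main = "ADH1 variant scores",
                 xlab = "ADH1 score (a.u.)", ...)
  if (length(syn)) {
    graphics::plot(h_syn, col = grDevices::adjustcolor("grey40", 0.5),
                   border = NA, add = TRUE)
  }
  graphics::abline(v = x$threshold, lty = 2, lwd = 2)
  graphics::legend("topright", bty = "n",
                   fill = c(grDevices::adjustcolor("firebrick", 0.6),
                            grDevices::adjustcolor("grey40", 0.5)),
                   legend = c("missense/nonsense/frameshift", "synonymous"))
  invisible(x)
}
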