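# Burden and allelic-series estimation.

test_that("carrier frequency is the exact scaled ratio", {
  expect_identical(carrier_frequency(0, 1000), 0)
  expect_identical(round(carrier_frequency(10, 433793), 2), 2.31)
  expect_identical(round(carrier_frequency(16, 229987), 2), 6.96)
  expect_identical(carrier_frequency(3, 100000), 3)
  expect_error(carrier_frequency(-1, 100), "negative")
  expect_error(carrier_frequency(1, 0))
})

test_that("lab penetrance reproduces the published carrier fractions", {
  expect_identical(lab_penetrance(KNOWN_CARRIER_CALCIUM, 2.2, "below"), 0.6)
  expect_identical(lab_penetrance(KNOWN_CARRIER_PHOSPHATE, 1.45, "above"),
                   0.4)
  expect_identical(lab_penetrance(c(2.5, 2.6), 2.2, "below"), 0)
  expect_identical(lab_penetrance(numeric(0), 2.2, "below"), NA_real_)
  # strictly beyond: a value at the limit does not count
  expect_identical(lab_penetrance(c(2.2), 2.2, "below"), 0)
  expect_identical(lab_penetrance(c(1.45), 1.45, "above"), 0)
})

test_that("diagnosis penetrance counts evaluable carriers only", {
  mk <- function(direct, coverage) {
    data.frame(dx_calcium_phosphorus = direct,
               dx_hypoparathyroidism = FALSE,
               record_coverage = coverage)
  }
  expect_equal(dx_penetrance(mk(c(TRUE, rep(FALSE, 5)), rep(1, 6))),
               1 / 6, tolerance = 1e-12)
  expect_equal(dx_penetrance(mk(c(rep(TRUE, 4), rep(FALSE, 5)), rep(1, 9))),
               4 / 9, tolerance = 1e-12)
  expect_identical(dx_penetrance(mk(rep(FALSE, 4), rep(1, 4))), 0)
  # carriers without record coverage are not evaluable
  expect_equal(dx_penetrance(mk(c(TRUE, TRUE, FALSE, FALSE),
                                c(1, 0, 1, 0))), 0.5)
  expect_identical(dx_penetrance(mk(c(TRUE, TRUE), c(0, 0))), NA_real_)
  expect_error(dx_penetrance(data.frame(record_coverage = 1)), "missing")
})

test_that("excess burden arithmetic is exact and floors at zero", {
  e <- excess_burden(14, 20, 0, 433793)
  expect_identical(e$excess, 14)
  expect_equal(e$excess_per_100k, 14 / 433793 * 1e5)
  e <- excess_burden(20, 60, 0.10, 1e5)
  expect_equal(e$expected_affected, 6, tolerance = 1e-12)
  expect_equal(e$excess, 14, tolerance = 1e-12)
  e <- excess_burden(6, 60, 0.10, 1e5)
  expect_equal(e$excess, 0, tolerance = 1e-12)
  e <- excess_burden(2, 60, 0.10, 1e5)
  expect_equal(e$excess, 0, tolerance = 1e-12)
  expect_equal(e$excess_raw, -4, tolerance = 1e-12)
  expect_error(excess_burden(61, 60, 0.1, 1e5), "exceeds")
  expect_error(excess_burden(1, 60, 1.1, 1e5))
})

test_that("allelic series medians are ordered by rarity class", {
  v <- data.frame(class = c("common", "intermediate", "known"),
                  variant_id = c("a", "b", "c"),
                  beta = c(-0.01, -0.1, -0.4),
                  maf = c(0.1, 1e-4, 2e-6))
  s <- allelic_series_summary(v, class_order = c("common", "intermediate",
                                                 "known"))
  expect_identical(s$median_beta, c(-0.01, -0.1, -0.4))
  expect_true(all(diff(s$median_beta) < 0))
  single <- allelic_series_summary(v[1, ])
  expect_identical(nrow(single), 1L)
  expect_warning(allelic_series_summary(v, class_order = c("common", "x")),
                 "empty")
})

test_that("the generator's allelic architecture is recovered from the scan", {
  co <- test_cohort()
  scan <- test_scan()
  sc <- scan$scores
  beta <- tapply(sc$calcium_beta, sc$variant_id, function(x) x[1])
  df <- data.frame(variant_id = names(beta), beta = as.numeric(beta),
                   maf = as.numeric(tapply(sc$maf, sc$variant_id, max)))
  df$class <- co$truth$class_label[match(df$variant_id,
                                         co$truth$variant_id)]
  s <- allelic_series_summary(df[!is.na(df$beta), ],
                              class_order = c("neutral", "gof_intermediate",
                                              "gof_known"))
  expect_true(all(diff(s$median_beta) < 0))  # more negative with rarity class
  # and the loss-of-function class sits on the other side
  lof <- allelic_series_summary(df[df$class == "lof" & !is.na(df$beta), ])
  expect_gt(lof$median_beta, s$median_beta[s$class == "gof_known"])
})

test_that("dx penetrance lags lab penetrance for gain-of-function classes", {
  co <- test_cohort()
  phen <- test_phenotypes()
  gof <- co$truth$variant_id[co$truth$class_label %in%
                               c("gof_known", "gof_intermediate")]
  ids <- unique(unlist(strsplit(
    co$variants$carriers[co$variants$variant_id %in% gof], ",")))
  carr <- phen[phen$individual_id %in% ids, ]
  lab_p <- lab_penetrance(carr$calcium, 2.2, "below")
  dx_p <- dx_penetrance(carr, evaluable = rep(TRUE, nrow(carr)))
  expect_lte(dx_p, lab_p)
})

test_that("cross-cohort concordance counts shared calls correctly", {
  a <- data.frame(variant_id = c("v1", "v2", "v3"), score = c(2, 0.5, 3))
  r <- cross_cohort_concordance(a, a, 1.5)
  expect_identical(r$above_both, 2L + 0L)
  expect_identical(r$above_a_only, 0L)
  expect_identical(sort(r$shared_above_both), c("v1", "v3"))
  b <- data.frame(variant_id = c("x1"), score = 2)
  r2 <- cross_cohort_concordance(a, b, 1.5)
  expect_identical(r2$n_shared, 0L)
  b3 <- data.frame(variant_id = c("v1", "v2", "v3"), score = c(2, 2, 0.1))
  r3 <- cross_cohort_concordance(
    a, b3, 1.5,
    beta_a = c(v1 = -0.3, v2 = -0.2, v3 = -0.1),
    beta_third = c(v1 = -0.1, v2 = 0.2, v3 = -0.2))
  expect_identical(r3$above_both, 1L)
  expect_identical(r3$above_a_only, 1L)
  expect_identical(r3$above_b_only, 1L)
  expect_equal(r3$sign_concordance, 2 / 3)
})

test_that("two cohorts from the same truth enrich shared gain-of-function calls", {
  vc <- sim_variant_classes()
  vc$n_variants <- c(4L, 4L, 4L, 20L, 40L)
  vc$carrier_max <- pmin(vc$carrier_max, 30L)
  mk <- function(seed) {
    co <- simulate_biobank(sim_config(n_individuals = 3000,
                                      variant_classes = vc, seed = seed))
    list(co = co, scan = adh1_scan(co$variants, co$individuals, seed = 2,
                                   threshold = "fixed"))
  }
  a <- mk(101); b <- mk(102)
  # same architecture; variant IDs are positional, classes align via truth
  sa <- data.frame(variant_id = a$scan$variant_scores$variant_id,
                   score = a$scan$variant_scores$score)
  sb <- data.frame(variant_id = b$scan$variant_scores$variant_id,
                   score = b$scan$variant_scores$score)
  r <- cross_cohort_concordance(sa, sb, 1.5)
  shared_gof <- intersect(
    r$shared_above_both,
    a$co$truth$variant_id[a$co$truth$class_label == "gof_known"])
  shared_neutral <- intersect(
    r$shared_above_both,
    a$co$truth$variant_id[a$co$truth$class_label %in%
                            c("neutral", "synonymous")])
  n_gof <- sum(a$co$truth$class_label == "gof_known")
  n_neu <- sum(a$co$truth$class_label %in% c("neutral", "synonymous"))
  expect_gt(length(shared_gof) / n_gof, length(shared_neutral) / n_neu)
})
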