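# ADH1 score: sub-score grading, additivity, the scan, and its invariances.

test_that("hotspot membership uses inclusive boundaries", {
  expect_identical(hotspot_flag(c(104, 116, 124, 136, 137)),
                   c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(hotspot_flag(c(818, 819, 837, 838)),
                   c(FALSE, TRUE, TRUE, FALSE))
})

test_that("calcium sub-score requires significance and the GoF direction", {
  w <- score_weights()
  expect_equal(calcium_subscore(-0.24, 9.1e-3, w), 3)
  expect_equal(calcium_subscore(-0.01, 0.90, w), 0)
  expect_equal(calcium_subscore(0.30, 0.001, w), 0)   # wrong direction
  expect_equal(calcium_subscore(NA, NA, w), 0)
})

test_that("phosphate sub-score requires the opposite direction", {
  w <- score_weights()
  expect_equal(phosphate_subscore(0.35, 2.2e-2, w), 1)
  expect_equal(phosphate_subscore(0.05, 0.64, w), 0)
  expect_equal(phosphate_subscore(-0.21, 0.001, w), 0)
})

test_that("in-silico sub-score fires on a strict majority only", {
  w <- score_weights()
  expect_equal(insilico_subscore(0.9, w), 0.2)
  expect_equal(insilico_subscore(0.5, w), 0)
  expect_equal(insilico_subscore(0.0, w), 0)
  expect_equal(insilico_subscore(NA, w), 0)
})

test_that("diagnosis/medication sub-scores need a carrier and enrichment", {
  w <- score_weights()
  cats <- names(adh1_phecode_categories())
  any_c <- setNames(c(TRUE, rep(FALSE, 4)), cats)
  ps <- setNames(c(2.4e-3, rep(NA_real_, 4)), cats)
  r <- dx_medication_subscores(any_c, ps, med_any = TRUE, med_p = 0.01, w)
  expect_equal(unname(r$dx[cats[1]]), 1)
  expect_equal(sum(r$dx), 1)
  expect_equal(r$medication, 1)
  # significant enrichment without a carrier cannot fire
  none <- setNames(rep(FALSE, 5), cats)
  ps2 <- setNames(rep(0.001, 5), cats)
  r2 <- dx_medication_subscores(none, ps2, med_any = FALSE, med_p = 0.001, w)
  expect_equal(sum(r2$dx), 0)
  expect_equal(r2$medication, 0)
})

test_that("every component firing reaches the maximal total 10.7", {
  w <- score_weights()
  cats <- names(adh1_phecode_categories())
  dxm <- dx_medication_subscores(setNames(rep(TRUE, 5), cats),
                                 setNames(rep(0.001, 5), cats),
                                 med_any = TRUE, med_p = 0.001, w)
  total <- calcium_subscore(-0.4, 1e-5, w) +
    phosphate_subscore(0.4, 1e-3, w) + sum(dxm$dx) + dxm$medication +
    w$hotspot + insilico_subscore(0.9, w)
  expect_equal(total, 10.7)
})

test_that("graded mode scales with -log10(p), gated by direction", {
  w <- score_weights()
  expect_equal(calcium_subscore(-0.2, 0.05, w, grading = "graded"), 3)
  expect_equal(calcium_subscore(-0.2, 1e-8, w, grading = "graded"), 3)
  mid <- calcium_subscore(-0.2, 0.5, w, grading = "graded")
  expect_gt(mid, 0); expect_lt(mid, 3)
  expect_equal(calcium_subscore(-0.2, 1, w, grading = "graded"), 0)
  expect_equal(calcium_subscore(0.2, 1e-8, w, grading = "graded"), 0)
  # monotone in p
  ps <- c(0.9, 0.5, 0.2, 0.06)
  vals <- vapply(ps, function(p) calcium_subscore(-1, p, w, "graded"),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("invalid weights are rejected", {
  expect_error(score_weights(calcium = -1))
  expect_error(score_weights(nominal_alpha = 0))
  expect_error(score_weights(hotspot_ranges = rbind(c(136, 116))))
})

test_that("scan totals are the exact sum of components", {
  scan <- test_scan()
  comp <- scan$scores[, paste0("s_", scan$component_names)]
  expect_identical(scan$scores$total, unname(rowSums(comp)))
  # variant score is the max across strata
  agg <- tapply(scan$scores$total, scan$scores$variant_id, max)
  expect_equal(unname(agg[scan$variant_scores$variant_id]),
               scan$variant_scores$score)
})

test_that("binary components take only the values {0, weight}", {
  scan <- test_scan()
  w <- scan$weights
  expected <- c(calcium = w$calcium, phosphate = w$phosphate,
                setNames(rep(w$dx_category, 5),
                         paste0("dx_", names(adh1_phecode_categories()))),
                medication = w$medication, hotspot = w$hotspot,
                insilico = w$insilico)
  for (nm in scan$component_names) {
    vals <- scan$scores[[paste0("s_", nm)]]
    expect_true(all(vals %in% c(0, expected[[nm]])), info = nm)
  }
  # hence adding a firing component can never decrease the total
  expect_true(all(as.matrix(
    scan$scores[, paste0("s_", scan$component_names)]) >= 0))
})

test_that("single-variant reference path agrees with the batch scan", {
  co <- test_cohort()
  scan <- test_scan()
  phen <- test_phenotypes()
  some <- c(which(co$variants$known_status == "known_adh1")[1:2],
            which(co$variants$consequence == "synonymous")[1:2],
            which(co$truth$class_label == "gof_intermediate")[1:2])
  for (i in some) {
    ref <- adh1_score(co$variants[i, ], phen)
    got <- scan$scores[scan$scores$variant_id == co$variants$variant_id[i], ]
    if (is.null(ref$subscores)) {
      expect_identical(nrow(got), 0L)  # filtered identically
      next
    }
    expect_identical(nrow(got), nrow(ref$subscores))
    for (nm in paste0("s_", scan$component_names)) {
      expect_equal(got[[nm]], ref$subscores[[nm]], tolerance = 1e-12,
                   info = nm)
    }
    expect_equal(got$total, ref$subscores$total, tolerance = 1e-12)
    expect_equal(max(got$total), ref$variant_score)
  }
})

test_that("scoring is invariant to individual relabeling and stratum order", {
  vc <- sim_variant_classes()
  vc$n_variants <- c(2L, 2L, 2L, 5L, 15L)
  vc$carrier_max <- pmin(vc$carrier_max, 40L)
  co <- simulate_biobank(sim_config(n_individuals = 800,
                                    strata = c("s1", "s2"),
                                    variant_classes = vc, seed = 77))
  scan1 <- adh1_scan(co$variants, co$individuals, seed = 3)

  # relabel every individual and shuffle both tables
  relabel <- setNames(sprintf("Z%06d", rev(seq_len(nrow(co$individuals)))),
                      co$individuals$individual_id)
  ind2 <- co$individuals
  ind2$individual_id <- unname(relabel[ind2$individual_id])
  ind2 <- ind2[order(ind2$individual_id), ]
  ind2$stratum <- factor(ind2$stratum, levels = c("s2", "s1"))
  ind2$stratum <- as.character(ind2$stratum)
  var2 <- co$variants
  var2$carriers <- vapply(strsplit(var2$carriers, ","), function(ids) {
    paste(sort(unname(relabel[ids])), collapse = ",")
  }, character(1))
  scan2 <- adh1_scan(var2, ind2, seed = 3)

  s1 <- scan1$scores[order(scan1$scores$variant_id, scan1$scores$stratum), ]
  s2 <- scan2$scores[order(scan2$scores$variant_id, scan2$scores$stratum), ]
  expect_equal(s1$total, s2$total, tolerance = 1e-12)
  expect_equal(s1$calcium_beta, s2$calcium_beta, tolerance = 1e-10)
  expect_identical(scan1$threshold, scan2$threshold)
})

test_that("variants without carriers are rejected by the reference path", {
  co <- test_cohort()
  v <- co$variants[1, ]
  v$carriers <- ""
  expect_error(adh1_score(v, test_phenotypes()), "no carriers")
})

test_that("known variants are scored but never called as novel candidates", {
  scan <- test_scan()
  vs <- scan$variant_scores
  expect_true(all(!vs$candidate[vs$known_status != "novel"]))
  expect_true(all(vs$known_status[vs$candidate] == "novel"))
  expect_true(all(!vs$candidate[vs$consequence == "synonymous"]))
  # known ADH1 variants still received scores
  expect_true(all(is.finite(vs$score[vs$known_status == "known_adh1"])))
})

test_that("gain-of-function variants separate widely from synonymous", {
  scan <- test_scan()
  vs <- scan$variant_scores
  m_gof <- mean(vs$score[vs$known_status == "known_adh1"])
  m_syn <- mean(vs$score[vs$consequence == "synonymous"])
  expect_gt(m_gof - m_syn, 1.5)   # wide margin, not exact means
})
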