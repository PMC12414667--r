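# Synthetic biobank generator: cohorts with a known ground-truth allelic
# series, so every downstream stage is testable without external data.

.ADH1_ICD_POOL <- data.frame(
  code = c("E83.51", "E20.9", "R20.2", "R29.0", "G40.9"),
  weight = c(0.45, 0.20, 0.15, 0.10, 0.10),
  stringsAsFactors = FALSE)

.BACKGROUND_ICD <- c("I10", "E11.9", "E78.0", "J45.9", "K21.9", "M54.5",
                     "F32.9")

.ADH1_MED_STRINGS <- c(
  "calcitriol 0.25mcg capsule", "alfacalcidol 1mcg", "calcichew d3 tablet",
  "colecalciferol 800iu tablet", "cholecalciferol 20000iu",
  "calcium carbonate 1.25g chewable", "calcium citrate 950mg",
  "teriparatide 20mcg injection")

.BACKGROUND_MED_STRINGS <- c(
  "aspirin 75mg", "atorvastatin 20mg tablet", "metformin 500mg",
  "omeprazole 20mg capsule", "salbutamol 100mcg inhaler",
  "paracetamol 500mg")

#' Default variant-class architecture for the simulator
#'
#' One row per simulated variant class. Known gain-of-function variants carry
#' large negative calcium shifts at very low carrier counts; intermediate
#' gain-of-function variants have smaller shifts at higher carrier counts;
#' loss-of-function variants shift calcium upward; neutral missense and
#' synonymous variants have exactly zero effect. Shift magnitudes are drawn
#' as `-|N(mean, sd)|` (gain-of-function) or `+|N(mean, sd)|`
#' (loss-of-function) per variant, so the configured sign is always honoured.
#'
#' @return `data.frame` with columns `class_label`, `n_variants`,
#'   `carrier_min`, `carrier_max`, `calcium_shift_mean`, `calcium_shift_sd`,
#'   `phosphate_shift_mean`, `phosphate_shift_sd`, `phosphate_co_elevation`,
#'   `diagnosis_penetrance`, `hotspot_fraction`, `insilico_deleterious_prob`,
#'   `consequence`.
#' @export
sim_variant_classes <- function() {
  data.frame(
    class_label = c("gof_known", "gof_intermediate", "lof", "neutral",
                    "synonymous"),
    n_variants = c(5L, 9L, 10L, 50L, 100L),
    carrier_min = c(1L, 1L, 1L, 1L, 1L),
    carrier_max = c(4L, 120L, 40L, 120L, 120L),
    calcium_shift_mean = c(-0.29, -0.06, 0.10, 0, 0),
    calcium_shift_sd = c(0.15, 0.04, 0.05, 0, 0),
    phosphate_shift_mean = c(0.35, 0.08, -0.05, 0, 0),
    phosphate_shift_sd = c(0.10, 0.04, 0.03, 0, 0),
    phosphate_co_elevation = c(0.5, 0.5, 0.5, 0, 0),
    diagnosis_penetrance = c(0.30, 0.15, 0, 0, 0),
    hotspot_fraction = c(0.40, 0.10, 0.10, 0.04, 0.04),
    insilico_deleterious_prob = c(0.90, 0.60, 0.70, 0.20, 0.05),
    consequence = c("missense", "missense", "missense", "missense",
                    "synonymous"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic biobank. Defaults
#' emulate a single-ancestry biobank stratum with UK-scale serum calcium
#' (2.37 +/- 0.095 mM) and phosphate (1.16 +/- 0.16 mM) marginals; see the
#' methods vignette for the rationale behind each default.
#'
#' @param n_individuals Individuals per stratum.
#' @param strata Stratum labels.
#' @param variant_classes Class table, see [sim_variant_classes()]. Optional
#'   per-class list-columns `shifts` and `carrier_counts` pin per-variant
#'   calcium shifts / carrier counts explicitly (recycled to `n_variants`).
#' @param lab_baseline Named list: `calcium_mean`, `calcium_sd`,
#'   `phosphate_mean`, `phosphate_sd` (mM; sds must be positive).
#' @param covariate_model Additive covariate effects on the labs (per year of
#'   age centred at 55, male indicator, and the first two genetic PCs).
#' @param diagnosis Named list: `dx_given_hypocalcemia_noncarrier`,
#'   `background_dx_rate` (per ADH1 code), `background_icd_rate` (per
#'   unrelated code), `med_given_dx`, `background_med_rate`,
#'   `background_other_med_rate`, `record_coverage`.
#' @param n_measurements Lab measurements per individual (1 = single
#'   measurement; more exercises measurement averaging).
#' @param measurement_sd Within-person measurement SD in mM (an assumption;
#'   not an observed quantity).
#' @param homozygotes Allow homozygous carriers (off by default; carriers are
#'   heterozygous only).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Validated list of class `"adh1_sim_config"`.
#' @export
sim_config <- function(n_individuals = 20000L,
                       strata = "pop1",
                       variant_classes = sim_variant_classes(),
                       lab_baseline = list(calcium_mean = 2.37,
                                           calcium_sd = 0.095,
                                           phosphate_mean = 1.16,
                                           phosphate_sd = 0.16),
                       covariate_model = list(
                         calcium = c(age = -3e-4, male = -0.02,
                                     pc1 = 0.003, pc2 = -0.003),
                         phosphate = c(age = 5e-4, male = -0.08,
                                       pc1 = 0.003, pc2 = 0.003)),
                       diagnosis = list(
                         dx_given_hypocalcemia_noncarrier = 0.10,
                         background_dx_rate = 0.005,
                         background_icd_rate = 0.05,
                         med_given_dx = 0.70,
                         background_med_rate = 0.02,
                         background_other_med_rate = 0.30,
                         record_coverage = 0.60),
                       n_measurements = 1L,
                       measurement_sd = 0.03,
                       homozygotes = FALSE,
                       seed = 1L) {
  vc <- variant_classes
  stopifnot(is.data.frame(vc), n_individuals >= 0, length(strata) >= 1,
            n_measurements >= 1, measurement_sd >= 0)
  if (lab_baseline$calcium_sd <= 0 || lab_baseline$phosphate_sd <= 0) {
    stop("lab baseline sds must be positive")
  }
  if (any(vc$calcium_shift_sd < 0) || any(vc$phosphate_shift_sd < 0)) {
    stop("shift sds must be non-negative")
  }
  if (any(vc$carrier_min < 1) || any(vc$carrier_max < vc$carrier_min)) {
    stop("carrier_count_range must be positive and ordered")
  }
  total_n <- n_individuals * length(strata)
  if (any(vc$n_variants > 0 & vc$carrier_max > total_n)) {
    stop("carrier_count_range exceeds the number of individuals")
  }
  gof <- grepl("^gof", vc$class_label)
  lof <- vc$class_label == "lof"
  nul <- vc$class_label %in% c("neutral", "synonymous")
  if (any(vc$calcium_shift_mean[gof] > 0) ||
      any(vc$calcium_shift_mean[lof] < 0) ||
      any(vc$calcium_shift_mean[nul] != 0)) {
    stop("calcium shift signs inconsistent with class labels ",
         "(gof negative, lof positive, neutral/synonymous zero)")
  }
  probs <- c(vc$diagnosis_penetrance, vc$hotspot_fraction,
             vc$insilico_deleterious_prob, vc$phosphate_co_elevation,
             unlist(diagnosis))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(list(n_individuals = as.integer(n_individuals), strata = strata,
                 variant_classes = vc, lab_baseline = lab_baseline,
                 covariate_model = covariate_model, diagnosis = diagnosis,
                 n_measurements = as.integer(n_measurements),
                 measurement_sd = measurement_sd, homozygotes = homozygotes,
                 seed = as.integer(seed)),
            class = "adh1_sim_config")
}

# log-uniform integer carrier counts (site-frequency-like skew toward rare)
.draw_carrier_counts <- function(n, lo, hi) {
  if (lo == hi) return(rep.int(lo, n))
  pmin(hi, pmax(lo, round(exp(stats::runif(n, log(lo), log(hi + 0.999))))))
}

.draw_positions <- function(n, hotspot_fraction, ranges) {
  hot <- unlist(apply(ranges, 1, function(r) r[1]:r[2], simplify = FALSE))
  cold <- setdiff(seq_len(CASR_PROTEIN_LENGTH), hot)
  in_hot <- stats::runif(n) < hotspot_fraction
  pos <- integer(n)
  pos[in_hot] <- sample(hot, sum(in_hot), replace = TRUE)
  pos[!in_hot] <- sample(cold, sum(!in_hot), replace = TRUE)
  pos
}

# accumulate ";"-joined string fields column-wise (avoids per-row loops)
.join_codes <- function(...) {
  s <- do.call(paste, c(list(...), sep = ";"))
  s <- gsub(";{2,}", ";", s)
  gsub("^;|;$", "", s)
}

#' Generate a synthetic biobank cohort
#'
#' Draws a cohort of individuals across ancestry strata and a set of variants
#' with the configured allelic architecture. Carriers are sampled without
#' replacement per variant (heterozygous by default); carrier labs are
#' baseline + covariate effects + class shift + Gaussian noise; diagnosis
#' codes are threshold-driven (assigned with the class penetrance only when
#' the realized calcium is below the LLN, plus a small background rate
#' otherwise), so diagnosis lags hypocalcemia as in real cohorts; medications
#' are assigned to a configurable fraction of diagnosed individuals;
#' synonymous and neutral variants have all effects exactly zero. The output
#' is deterministic for a fixed seed.
#'
#' @param config An [sim_config()] object.
#' @return List of class `"adh1_cohort"`: `variants` (variant table with
#'   comma-separated carrier IDs), `individuals` (individual table),
#'   `labs` (long-format repeated measurements, or `NULL` when
#'   `n_measurements == 1`), `truth` (variant_id, class_label,
#'   calcium_shift), `config`.
#' @export
simulate_biobank <- function(config = sim_config()) {
  stopifnot(inherits(config, "adh1_sim_config"))
  .with_seed(config$seed, .simulate_biobank_impl(config))
}

.simulate_biobank_impl <- function(config) {
  n_str <- length(config$strata)
  n <- config$n_individuals * n_str
  ids <- sprintf("I%06d", seq_len(n))
  stratum <- rep(config$strata, each = config$n_individuals)

  age <- if (n) round(stats::runif(n, 40, 70)) else numeric(0)
  sex <- if (n) ifelse(stats::runif(n) < 0.54, "female", "male") else character(0)
  pcs <- matrix(stats::rnorm(n * 10), nrow = n, ncol = 10,
                dimnames = list(NULL, paste0("pc", 1:10)))

  lb <- config$lab_baseline
  cm <- config$covariate_model
  male <- as.numeric(sex == "male")
  ca_mean <- lb$calcium_mean + cm$calcium[["age"]] * (age - 55) +
    cm$calcium[["male"]] * male +
    cm$calcium[["pc1"]] * pcs[, 1] + cm$calcium[["pc2"]] * pcs[, 2]
  ph_mean <- lb$phosphate_mean + cm$phosphate[["age"]] * (age - 55) +
    cm$phosphate[["male"]] * male +
    cm$phosphate[["pc1"]] * pcs[, 1] + cm$phosphate[["pc2"]] * pcs[, 2]

  # variants
  vc <- config$variant_classes
  ranges <- score_weights()$hotspot_ranges
  vrows <- list(); trows <- list()
  ca_shift <- numeric(n); ph_shift <- numeric(n)
  pen <- numeric(n)                       # per-individual dx penetrance
  vi <- 0L
  for (ci in seq_len(nrow(vc))) {
    cl <- vc[ci, ]
    if (cl$n_variants == 0) next
    m <- cl$n_variants
    shifts <- if (!is.null(vc$shifts) && !is.null(vc$shifts[[ci]])) {
      rep_len(vc$shifts[[ci]], m)
    } else if (grepl("^gof", cl$class_label)) {
      -abs(stats::rnorm(m, abs(cl$calcium_shift_mean), cl$calcium_shift_sd))
    } else if (cl$class_label == "lof") {
      abs(stats::rnorm(m, abs(cl$calcium_shift_mean), cl$calcium_shift_sd))
    } else rep(0, m)
    counts <- if (!is.null(vc$carrier_counts) &&
                  !is.null(vc$carrier_counts[[ci]])) {
      rep_len(vc$carrier_counts[[ci]], m)
    } else .draw_carrier_counts(m, cl$carrier_min, cl$carrier_max)
    ph_shifts <- if (cl$phosphate_shift_mean == 0) rep(0, m) else {
      sign(cl$phosphate_shift_mean) *
        abs(stats::rnorm(m, abs(cl$phosphate_shift_mean),
                         cl$phosphate_shift_sd))
    }
    positions <- .draw_positions(m, cl$hotspot_fraction, ranges)
    deleterious <- stats::runif(m) < cl$insilico_deleterious_prob
    insilico <- ifelse(deleterious, stats::runif(m, 0.55, 1),
                       stats::runif(m, 0, 0.45))
    known <- if (cl$class_label == "gof_known") "known_adh1"
             else if (cl$class_label == "lof") "known_fhh1" else "novel"
    for (j in seq_len(m)) {
      vi <- vi + 1L
      k <- counts[j]
      carr <- sample.int(n, k)
      # heterozygous by default; optional homozygotes get a doubled shift
      dosage <- rep(1, k)
      if (isTRUE(config$homozygotes)) {
        dosage[stats::runif(k) < 0.05] <- 2
      }
      ca_shift[carr] <- ca_shift[carr] + shifts[j] * dosage
      if (ph_shifts[j] != 0 && cl$phosphate_co_elevation > 0) {
        co <- carr[stats::runif(k) < cl$phosphate_co_elevation]
        ph_shift[co] <- ph_shift[co] + ph_shifts[j]
      }
      if (cl$diagnosis_penetrance > 0) {
        pen[carr] <- pmax(pen[carr], cl$diagnosis_penetrance)
      }
      vrows[[vi]] <- data.frame(
        variant_id = sprintf("var%04d", vi),
        consequence = cl$consequence,
        protein_position = positions[j],
        carriers = paste(ids[sort(carr)], collapse = ","),
        hom_carriers = paste(ids[sort(carr[dosage == 2])], collapse = ","),
        n_carriers = k,
        insilico_fraction_deleterious = insilico[j],
        known_status = known,
        stringsAsFactors = FALSE)
      trows[[vi]] <- data.frame(
        variant_id = sprintf("var%04d", vi),
        class_label = cl$class_label,
        calcium_shift = shifts[j],
        stringsAsFactors = FALSE)
    }
  }
  variants <- if (vi) do.call(rbind, vrows) else data.frame(
    variant_id = character(0), consequence = character(0),
    protein_position = integer(0), carriers = character(0),
    hom_carriers = character(0), n_carriers = integer(0),
    insilico_fraction_deleterious = numeric(0),
    known_status = character(0), stringsAsFactors = FALSE)
  truth <- if (vi) do.call(rbind, trows) else data.frame(
    variant_id = character(0), class_label = character(0),
    calcium_shift = numeric(0), stringsAsFactors = FALSE)

  # realized labs (latent per-person values; measurement noise layered below)
  calcium <- ca_mean + ca_shift + stats::rnorm(n, 0, lb$calcium_sd)
  phosphate <- ph_mean + ph_shift + stats::rnorm(n, 0, lb$phosphate_sd)
  cystatin <- stats::rlnorm(n, log(0.9), 0.15)

  labs <- NULL
  if (config$n_measurements > 1 && n > 0) {
    reps <- config$n_measurements
    labs <- data.frame(
      individual_id = rep(ids, each = reps * 2),
      lab = rep(rep(c("calcium", "phosphate"), each = reps), times = n),
      value = as.vector(rbind(
        matrix(rep(calcium, each = reps) +
                 stats::rnorm(n * reps, 0, config$measurement_sd),
               nrow = reps),
        matrix(rep(phosphate, each = reps) +
                 stats::rnorm(n * reps, 0, config$measurement_sd),
               nrow = reps))),
      stringsAsFactors = FALSE)
  }

  # threshold-driven diagnosis codes with incomplete penetrance
  dg <- config$diagnosis
  lln <- adh1_lab_limits[["calcium_lln"]]
  hypo <- calcium < lln
  p_dx <- ifelse(pen > 0, pen, dg$dx_given_hypocalcemia_noncarrier)
  diagnosed <- hypo & (stats::runif(n) < p_dx)
  adh1_code <- character(n)
  idx_dx <- which(diagnosed)
  for (i in idx_dx) {
    k <- 1L + (stats::runif(1) < 0.5)
    adh1_code[i] <- paste(sample(.ADH1_ICD_POOL$code, k,
                                 prob = .ADH1_ICD_POOL$weight),
                          collapse = ";")
  }
  bg_adh1 <- !diagnosed & (stats::runif(n) < dg$background_dx_rate)
  adh1_code[bg_adh1] <- sample(.ADH1_ICD_POOL$code, sum(bg_adh1),
                               replace = TRUE,
                               prob = .ADH1_ICD_POOL$weight)
  bg_codes <- matrix("", nrow = n, ncol = length(.BACKGROUND_ICD))
  for (j in seq_along(.BACKGROUND_ICD)) {
    bg_codes[stats::runif(n) < dg$background_icd_rate, j] <- .BACKGROUND_ICD[j]
  }
  icd <- .join_codes(adh1_code,
                     do.call(paste, c(as.data.frame(bg_codes), sep = ";")))

  # medications
  med <- character(n)
  on_adh1_med <- (diagnosed | bg_adh1) & (stats::runif(n) < dg$med_given_dx)
  bg_adh1_med <- !on_adh1_med & (stats::runif(n) < dg$background_med_rate)
  take <- which(on_adh1_med | bg_adh1_med)
  if (length(take)) {
    med[take] <- .ADH1_MED_STRINGS[
      sample.int(length(.ADH1_MED_STRINGS), length(take), replace = TRUE)]
  }
  bg_med <- stats::runif(n) < dg$background_other_med_rate
  med2 <- ifelse(bg_med, .BACKGROUND_MED_STRINGS[
    sample.int(length(.BACKGROUND_MED_STRINGS), n, replace = TRUE)], "")
  meds <- .join_codes(med, med2)

  individuals <- data.frame(
    individual_id = ids, stratum = stratum, age = age, sex = sex,
    pcs, calcium = calcium, phosphate = phosphate, cystatin_c = cystatin,
    icd10_codes = icd, medications = meds,
    record_coverage = if (n) as.integer(stats::runif(n) < dg$record_coverage)
                      else integer(0),
    stringsAsFactors = FALSE)

  structure(list(variants = variants, individuals = individuals, labs = labs,
                 truth = truth, config = config),
            class = "adh1_cohort")
}

#' @export
print.adh1_cohort <- function(x, ...) {
  cat(sprintf("Synthetic biobank cohort: %d individuals (%d strat%s), %d variants\n",
              nrow(x$individuals), length(x$config$strata),
              if (length(x$config$strata) == 1) "um" else "a",
              nrow(x$variants)))
  if (nrow(x$truth)) print(table(x$truth$class_label))
  invisible(x)
}
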