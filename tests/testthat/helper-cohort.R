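# Shared fixtures, built in code once per run.

.cohort_cache <- new.env(parent = emptyenv())

# Default single-stratum cohort used across test files.
test_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    .cohort_cache$co <- simulate_biobank(sim_config(n_individuals = 4000,
                                                    seed = 11))
  }
  .cohort_cache$co
}

test_scan <- function() {
  if (is.null(.cohort_cache$scan)) {
    co <- test_cohort()
    .cohort_cache$scan <- adh1_scan(co$variants, co$individuals, seed = 3)
  }
  .cohort_cache$scan
}

test_phenotypes <- function() {
  if (is.null(.cohort_cache$phen)) {
    .cohort_cache$phen <- build_phenotypes(test_cohort()$individuals)
  }
  .cohort_cache$phen
}

# Carrier calcium and phosphate values of the ten previously reported
# ADH1-variant heterozygotes (mM), used for penetrance checks.
KNOWN_CARRIER_CALCIUM <- c(2.13, 2.07, 2.07, 2.19, 2.19, 2.20, 1.96, 2.39,
                           2.22, 2.36)
KNOWN_CARRIER_PHOSPHATE <- c(1.46, 1.44, 1.70, 1.51, 1.27, 1.23, 1.57, 1.04,
                             1.37, 1.29)

# Published per-stratum carrier calcium effects (mM) and carrier counts for
# previously established ADH1 variants (gain-of-function direction only).
KNOWN_GOF_BETAS <- c(-0.24, -0.24, -0.19, -0.43, -0.10,
                     -0.18, -0.23, -0.65, -0.23, -0.29, -0.34, -0.36)
KNOWN_GOF_CARRIERS <- c(1L, 3L, 2L, 1L, 2L,
                        1L, 1L, 1L, 1L, 2L, 1L, 1L)
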