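# Readers/writers for the fixture formats (TSV and VCF), relatedness
# exclusion, run configuration, and the end-to-end pipeline.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

.VARIANT_REQUIRED <- c("variant_id", "consequence", "protein_position",
                       "carriers", "insilico_fraction_deleterious",
                       "known_status")

#' Read a variant table (TSV or VCF)
#'
#' TSV tables must carry the documented schema columns. VCF input (the
#' fixture dialect written by [write_cohort()]) carries the annotations in
#' INFO fields `CSQ` (consequence), `PPOS` (1-based protein position),
#' `INSILICO`, `KNOWN` and `CARRIERS` (pipe-separated individual IDs).
#' Coordinates are 1-based (VCF convention); ref/alt alleles are normalized
#' to uppercase; duplicate variant IDs are rejected.
#'
#' @param path Path to a `.tsv` or `.vcf` file.
#' @return Variant `data.frame` with the schema columns.
#' @export
read_variant_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    info <- function(el) vcfR::extract.info(v, element = el)
    out <- data.frame(
      variant_id = fix$ID,
      consequence = info("CSQ"),
      protein_position = suppressWarnings(as.integer(info("PPOS"))),
      carriers = gsub("|", ",", info("CARRIERS"), fixed = TRUE),
      n_carriers = NA_integer_,
      insilico_fraction_deleterious =
        suppressWarnings(as.numeric(info("INSILICO"))),
      known_status = info("KNOWN"),
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = toupper(fix$REF), alt = toupper(fix$ALT),
      stringsAsFactors = FALSE)
    out$carriers[is.na(out$carriers)] <- ""
    out$n_carriers <- vapply(out$carriers, function(x) {
      if (x == "") 0L else length(strsplit(x, ",", fixed = TRUE)[[1L]])
    }, integer(1), USE.NAMES = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = NA)
    out$carriers <- as.character(out$carriers)
    out$carriers[is.na(out$carriers)] <- ""
    if ("hom_carriers" %in% names(out)) {
      out$hom_carriers <- as.character(out$hom_carriers)
      out$hom_carriers[is.na(out$hom_carriers)] <- ""
    }
    if (all(c("ref", "alt") %in% names(out))) {
      out$ref <- toupper(out$ref); out$alt <- toupper(out$alt)
    }
  }
  miss <- setdiff(.VARIANT_REQUIRED, names(out))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(out$variant_id)) {
    stop("duplicate variant IDs: ",
         paste(unique(out$variant_id[duplicated(out$variant_id)]),
               collapse = ", "))
  }
  bad <- which(out$consequence %in% c("missense", "nonsense", "frameshift") &
                 (is.na(out$protein_position) | out$protein_position < 1))
  if (length(bad)) {
    stop("missing/invalid protein_position for protein-coding rows: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Read an individual table (TSV)
#'
#' @param path Path to the TSV written by [write_cohort()] (columns
#'   `individual_id`, `stratum`, `age`, `sex`, `pc1`..`pc10`, `calcium`,
#'   `phosphate`, `cystatin_c`, `icd10_codes`, `medications`,
#'   `record_coverage`).
#' @return `data.frame`.
#' @export
read_individual_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "stratum", "age", "sex")
  miss <- setdiff(req, names(out))
  if (length(miss)) stop("individual table missing columns: ",
                         paste(miss, collapse = ", "))
  for (col in c("icd10_codes", "medications")) {
    if (col %in% names(out)) {
      out[[col]] <- as.character(out[[col]])
      out[[col]][is.na(out[[col]])] <- ""
    }
  }
  out
}

# Minimal VCFv4.2 writer for the fixture dialect.
.write_variant_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=3,length=198295559>",
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=PPOS,Number=1,Type=Integer,Description=\"1-based protein position\">",
    "##INFO=<ID=INSILICO,Number=1,Type=Float,Description=\"Fraction of in-silico predictors calling deleterious\">",
    "##INFO=<ID=KNOWN,Number=1,Type=String,Description=\"known_adh1, known_fhh1 or novel\">",
    "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Pipe-separated carrier individual IDs\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  n <- nrow(variants)
  lines <- hdr
  if (n) {
    alleles <- c("A", "C", "G", "T")
    ref <- alleles[(seq_len(n) - 1L) %% 4L + 1L]
    alt <- alleles[seq_len(n) %% 4L + 1L]
    info <- sprintf(
      "CSQ=%s;PPOS=%d;INSILICO=%.6g;KNOWN=%s;CARRIERS=%s",
      variants$consequence, variants$protein_position,
      variants$insilico_fraction_deleterious, variants$known_status,
      gsub(",", "|", variants$carriers, fixed = TRUE))
    info[variants$carriers == ""] <- sub(";CARRIERS=$", "",
                                         info[variants$carriers == ""])
    lines <- c(lines, paste("3", 121902530L + 3L * seq_len(n),
                            variants$variant_id, ref, alt, ".", "PASS",
                            info, sep = "\t"))
  }
  writeLines(lines, path)
  path
}

#' Write a cohort fixture directory
#'
#' Writes `variants.tsv`, `variants.vcf`, `individuals.tsv`, `truth.tsv`,
#' `labs.tsv` (when repeated measurements were simulated), `config.yaml` and
#' a `schema.json` documenting the column names of each file. The TSV tables
#' round-trip losslessly through [read_variant_table()] /
#' [read_individual_table()]; an empty cohort produces header-only files.
#'
#' @param cohort An [simulate_biobank()] result (or a compatible list with
#'   `variants`, `individuals`, `truth`).
#' @param directory Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0) {
    stop("cannot write to directory: ", directory)
  }
  paths <- c(
    variants = .write_tsv(cohort$variants,
                          file.path(directory, "variants.tsv")),
    variants_vcf = .write_variant_vcf(cohort$variants,
                                      file.path(directory, "variants.vcf")),
    individuals = .write_tsv(cohort$individuals,
                             file.path(directory, "individuals.tsv")),
    truth = .write_tsv(cohort$truth, file.path(directory, "truth.tsv")))
  if (!is.null(cohort$labs)) {
    paths["labs"] <- .write_tsv(cohort$labs, file.path(directory, "labs.tsv"))
  }
  if (!is.null(cohort$config)) {
    cfg <- unclass(cohort$config)
    cfg$variant_classes <- as.list(cohort$config$variant_classes)
    yaml::write_yaml(cfg, file.path(directory, "config.yaml"))
    paths["config"] <- file.path(directory, "config.yaml")
  }
  schema <- list(
    variants.tsv = names(cohort$variants),
    individuals.tsv = names(cohort$individuals),
    truth.tsv = names(cohort$truth))
  if (!is.null(cohort$labs)) schema$labs.tsv <- names(cohort$labs)
  jsonlite::write_json(schema, file.path(directory, "schema.json"),
                       pretty = TRUE)
  paths["schema"] <- file.path(directory, "schema.json")
  invisible(paths)
}

#' Read a cohort fixture directory back into memory
#'
#' @param directory Directory written by [write_cohort()].
#' @return List with `variants`, `individuals`, `truth`, `labs` (or `NULL`).
#' @export
read_cohort <- function(directory) {
  labs_path <- file.path(directory, "labs.tsv")
  list(
    variants = read_variant_table(file.path(directory, "variants.tsv")),
    individuals = read_individual_table(file.path(directory,
                                                  "individuals.tsv")),
    truth = utils::read.delim(file.path(directory, "truth.tsv"),
                              stringsAsFactors = FALSE),
    labs = if (file.exists(labs_path)) {
      utils::read.delim(labs_path, stringsAsFactors = FALSE)
    } else NULL)
}

#' Exclude close relatives by kinship
#'
#' Greedy removal on the relatedness graph of pairs with kinship above the
#' cutoff (default 0.0884, the KING threshold between 2nd- and 3rd-degree
#' relatives): repeatedly remove the individual with the most above-cutoff
#' partners (ties broken by lexicographically smallest ID) until no retained
#' pair exceeds the cutoff. Deterministic.
#'
#' @param pairs `data.frame` with columns `id1`, `id2`, `kinship`.
#' @param cutoff Kinship cutoff (default 0.0884).
#' @param ids Optional universe of individual IDs; defaults to the IDs seen
#'   in `pairs`.
#' @return Character vector of retained IDs (sorted).
#' @export
exclude_relatives <- function(pairs, cutoff = 0.0884, ids = NULL) {
  stopifnot(all(c("id1", "id2", "kinship") %in% names(pairs)))
  if (any(pairs$id1 == pairs$id2)) stop("self-pairs are not allowed")
  if (is.null(ids)) ids <- sort(unique(c(pairs$id1, pairs$id2)))
  edges <- pairs[pairs$kinship > cutoff, c("id1", "id2"), drop = FALSE]
  removed <- character(0)
  while (nrow(edges) > 0) {
    deg <- sort(table(c(edges$id1, edges$id2)), decreasing = TRUE)
    top <- names(deg)[deg == max(deg)]
    victim <- sort(top)[1L]
    removed <- c(removed, victim)
    edges <- edges[edges$id1 != victim & edges$id2 != victim, , drop = FALSE]
  }
  sort(setdiff(ids, removed))
}

#' Run configuration for the pipeline
#'
#' Validated bundle of paths, constants and mode flags. Unknown keys are
#' rejected up front so a typo fails before any stage runs.
#'
#' @param input_dir Cohort fixture directory (see [write_cohort()]), or
#'   `NULL` when tables are passed to [run_pipeline()] directly.
#' @param output_dir Run directory for stage outputs and the manifest.
#' @param kinship_path Optional kinship pair TSV for relatedness exclusion.
#' @param lln,uln Lab limits (mM).
#' @param maf_cutoff Rare-variant MAF filter (default 0.01).
#' @param alpha Nominal significance for sub-scores (default 0.05).
#' @param weights [score_weights()].
#' @param threshold_mode `"empirical"` or `"fixed"`.
#' @param fixed_threshold Threshold used in fixed mode (default 1.5).
#' @param B,percentile,null_resampling Null-calibration controls.
#' @param grading Sub-score grading mode.
#' @param measurement_policy `"mean"` or `"first"`.
#' @param kinship_cutoff KING kinship cutoff (default 0.0884).
#' @param seed Seed for all stochastic stages (mandatory).
#' @return List of class `"adh1_run_config"`.
#' @export
run_config <- function(input_dir = NULL, output_dir = tempfile("adh1_run_"),
                       kinship_path = NULL,
                       lln = 2.2, uln = 1.45, maf_cutoff = 0.01,
                       alpha = 0.05, weights = score_weights(),
                       threshold_mode = "empirical", fixed_threshold = 1.5,
                       B = 10000, percentile = 98,
                       null_resampling = "independent",
                       grading = "binary", measurement_policy = "mean",
                       kinship_cutoff = 0.0884, seed = 1) {
  stopifnot(lln > 0, uln > 0, maf_cutoff > 0, alpha > 0, alpha < 1,
            B >= 1, percentile > 0, percentile <= 100, kinship_cutoff > 0,
            !is.null(seed))
  weights$nominal_alpha <- alpha
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 kinship_path = kinship_path, lln = lln, uln = uln,
                 maf_cutoff = maf_cutoff, alpha = alpha, weights = weights,
                 threshold_mode = match.arg(threshold_mode,
                                            c("empirical", "fixed")),
                 fixed_threshold = fixed_threshold, B = B,
                 percentile = percentile,
                 null_resampling = match.arg(null_resampling,
                                             c("independent", "joint")),
                 grading = match.arg(grading, c("binary", "graded")),
                 measurement_policy = match.arg(measurement_policy,
                                                c("mean", "first")),
                 kinship_cutoff = kinship_cutoff, seed = seed),
            class = "adh1_run_config")
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; unknown keys raise an error
#' before any stage runs.
#'
#' @param path YAML file.
#' @return An `"adh1_run_config"` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Run the full scoring pipeline
#'
#' Executes phenotype construction, relatedness exclusion (when a kinship
#' table is given), the variant scan with per-stratum association sub-scores,
#' null calibration, and the burden / allelic-series stage, writing every
#' stage output plus a manifest (config echo, seed, package version, row
#' counts in/out per filter, and md5 checksums of each output) into the run
#' directory. Re-running with the same inputs, config and seed reproduces
#' identical checksums.
#'
#' @param config An [run_config()] object or path to its YAML form.
#' @param cohort Optional in-memory cohort (overrides `config$input_dir`).
#' @return The run directory path, invisibly; the manifest is
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "adh1_run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(cohort)) {
    if (is.null(config$input_dir)) stop("no input: set input_dir or pass cohort")
    cohort <- stage("read", read_cohort(config$input_dir))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(n_individuals_in = nrow(cohort$individuals),
              n_variants_in = nrow(cohort$variants))

  individuals <- cohort$individuals
  if (!is.null(config$kinship_path)) {
    pairs <- utils::read.delim(config$kinship_path,
                               stringsAsFactors = FALSE)
    keep <- stage("relatedness",
                  exclude_relatives(pairs, cutoff = config$kinship_cutoff,
                                    ids = individuals$individual_id))
    individuals <- individuals[individuals$individual_id %in% keep, ,
                               drop = FALSE]
  }
  log$n_individuals_retained <- nrow(individuals)

  phen <- stage("phenotype_mapping",
                build_phenotypes(individuals, labs = cohort$labs,
                                 policy = config$measurement_policy,
                                 lln = config$lln, uln = config$uln))
  .write_tsv(phen, file.path(config$output_dir, "phenotypes.tsv"))

  scan <- stage("scoring", adh1_scan(
    cohort$variants, phenotypes = phen, weights = config$weights,
    maf_cutoff = config$maf_cutoff, threshold = config$threshold_mode,
    fixed_threshold = config$fixed_threshold, B = config$B,
    percentile = config$percentile,
    null_resampling = config$null_resampling, grading = config$grading,
    seed = config$seed))
  .write_tsv(scan$scores, file.path(config$output_dir, "scores.tsv"))
  .write_tsv(scan$variant_scores,
             file.path(config$output_dir, "variant_scores.tsv"))
  if (!is.null(scan$null)) {
    .write_tsv(data.frame(draw = scan$null$draws),
               file.path(config$output_dir, "null_draws.tsv"))
  }
  log$n_variants_scored <- nrow(scan$variant_scores)
  log$n_calls <- sum(scan$variant_scores$candidate &
                       scan$variant_scores$above_threshold)

  burden <- stage("burden_allelic",
                  .pipeline_burden(scan, phen, cohort$variants,
                                   cohort$truth))
  jsonlite::write_json(burden$report,
                       file.path(config$output_dir, "burden.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(burden$allelic_series)) {
    .write_tsv(burden$allelic_series,
               file.path(config$output_dir, "allelic_series.tsv"))
  }

  perf <- list(threshold = scan$threshold,
               threshold_mode = scan$threshold_mode)
  if (!is.null(scan$performance)) {
    perf <- c(perf, unclass(scan$performance))
  }
  jsonlite::write_json(perf, file.path(config$output_dir, "performance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  outputs <- sort(setdiff(list.files(config$output_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("adh1score")),
    seed = config$seed,
    config = unclass(config)[names(config) != "weights"],
    weights = unclass(config$weights),
    record_counts = log,
    checksums = as.list(tools::md5sum(file.path(config$output_dir, outputs))))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$output_dir)
}

# Burden / allelic-series stage shared by run_pipeline.
.pipeline_burden <- function(scan, phen, variants, truth = NULL) {
  vs <- scan$variant_scores
  cohort_n <- nrow(phen)
  called <- vs$variant_id[vs$candidate & vs$above_threshold]
  sc <- scan$scores
  carrier_map <- stats::setNames(
    lapply(variants$carriers, .parse_carriers), variants$variant_id)
  carrier_ids <- function(vids) unique(unlist(carrier_map[vids]))
  all_scored_carriers <- carrier_ids(vs$variant_id)
  called_carriers <- carrier_ids(called)
  baseline_ids <- setdiff(phen$individual_id, all_scored_carriers)
  base <- phen[phen$individual_id %in% baseline_ids, , drop = FALSE]
  baseline_rate <- if (nrow(base)) mean(base$any_adh1_dx) else 0
  carr <- phen[phen$individual_id %in% called_carriers, , drop = FALSE]
  report <- list(
    cohort_n = cohort_n,
    n_called_variants = length(called),
    n_called_carriers = nrow(carr),
    carrier_frequency_per_100k = carrier_frequency(nrow(carr), cohort_n),
    hypocalcemia_penetrance = lab_penetrance(carr$calcium, 2.2, "below"),
    hyperphosphatemia_penetrance = lab_penetrance(carr$phosphate, 1.45,
                                                  "above"),
    dx_penetrance = if (nrow(carr)) dx_penetrance(carr) else NA,
    baseline_any_adh1_dx_rate = baseline_rate)
  if (nrow(carr)) {
    eb <- excess_burden(sum(carr$any_adh1_dx), nrow(carr), baseline_rate,
                        cohort_n)
    report$excess_burden <- unclass(eb)
  }
  allelic <- NULL
  if (!is.null(truth) && nrow(truth)) {
    beta <- tapply(sc$calcium_beta, sc$variant_id,
                   function(x) x[which.max(abs(x))])
    maf <- tapply(sc$maf, sc$variant_id, max)
    av <- data.frame(variant_id = names(beta),
                     beta = as.numeric(beta), maf = as.numeric(maf),
                     stringsAsFactors = FALSE)
    av$class <- truth$class_label[match(av$variant_id, truth$variant_id)]
    av <- av[!is.na(av$class) & !is.na(av$beta), , drop = FALSE]
    if (nrow(av)) allelic <- allelic_series_summary(av)
  }
  list(report = report, allelic_series = allelic)
}
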