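# Phenotype construction: ICD-10 -> phecodes, medication counting, eGFR,
# lab flagging, measurement collapsing, and the per-individual phenotype table.

.normalize_icd <- function(x) gsub(".", "", toupper(trimws(x)), fixed = TRUE)

#' Map ICD-10 codes to phecodes
#'
#' Codes are normalized (uppercased, dots stripped) and matched against the map
#' on the longest available prefix, trying the full normalized code first and
#' backing off to 4- and then 3-character prefixes. Phecode granularity varies,
#' so prefix back-off gives deterministic behaviour on truncated codes. Codes
#' that already are phecodes present in the map pass through unchanged, which
#' makes the mapping idempotent. Unmapped codes are dropped with one warning.
#'
#' @param icd10_codes Character vector (a set) of ICD-10 codes; may be empty.
#' @param phecode_map `data.frame` with columns `icd10` and `phecode`
#'   (see [adh1_phecode_map()] for the bundled subset).
#' @return Sorted character vector of unique phecodes.
#' @examples
#' map_icd_to_phecodes(c("E20", "E83.51"), adh1_phecode_map())
#' @export
map_icd_to_phecodes <- function(icd10_codes, phecode_map) {
  stopifnot(is.data.frame(phecode_map))
  if (!all(c("icd10", "phecode") %in% names(phecode_map))) {
    stop("phecode_map must have columns 'icd10' and 'phecode'")
  }
  bad <- which(is.na(phecode_map$icd10) | phecode_map$icd10 == "" |
                 is.na(phecode_map$phecode) | phecode_map$phecode == "")
  if (length(bad)) {
    stop("malformed phecode map rows: ", paste(bad, collapse = ", "))
  }
  if (length(icd10_codes) == 0) return(character(0))

  keys <- .normalize_icd(phecode_map$icd10)
  lookup <- stats::setNames(phecode_map$phecode, keys)
  known_phecodes <- unique(phecode_map$phecode)

  codes <- unique(icd10_codes[!is.na(icd10_codes) & icd10_codes != ""])
  out <- character(0)
  unmapped <- character(0)
  for (code in codes) {
    if (code %in% known_phecodes) {       # already a phecode: pass through
      out <- c(out, code)
      next
    }
    norm <- .normalize_icd(code)
    lens <- unique(pmin(nchar(norm), c(nchar(norm), 4L, 3L)))
    hit <- NA_character_
    for (l in sort(lens, decreasing = TRUE)) {
      if (l < 3L) break
      cand <- substr(norm, 1L, l)
      if (!is.na(lookup[cand])) { hit <- lookup[[cand]]; break }
    }
    if (is.na(hit)) unmapped <- c(unmapped, code) else out <- c(out, hit)
  }
  if (length(unmapped)) {
    warning("unmapped ICD-10 codes ignored: ", paste(unmapped, collapse = ", "))
  }
  sort(unique(out))
}

#' Count ADH1-associated medications in free-text strings
#'
#' Case-insensitive substring match of each medication string against the
#' keyword list; each string counts at most once. `"PTH"` is matched as a
#' whole word only, so e.g. "naturopathy" does not fire.
#'
#' @param medication_strings Character vector of free-text prescriptions.
#' @param keywords Keyword list; defaults to [adh1_medication_keywords()].
#' @return Integer count of matching strings.
#' @examples
#' count_adh1_medications(c("Calcitriol 0.25mcg", "aspirin"))
#' @export
count_adh1_medications <- function(medication_strings,
                                   keywords = adh1_medication_keywords()) {
  stopifnot(length(keywords) > 0)
  if (length(medication_strings) == 0) return(0L)
  s <- tolower(medication_strings)
  word_only <- tolower(keywords) == "pth"
  hit <- rep(FALSE, length(s))
  for (i in seq_along(keywords)) {
    kw <- tolower(keywords[i])
    hit <- hit | if (word_only[i]) {
      grepl(paste0("\\b", kw, "\\b"), s)
    } else {
      grepl(kw, s, fixed = TRUE)
    }
  }
  sum(hit)
}

#' Estimated GFR from cystatin C (CKD-EPI 2012)
#'
#' eGFR = 133 * min(Scys/0.8, 1)^-0.499 * max(Scys/0.8, 1)^-1.328 *
#' 0.996^age * 0.932 (if female), in mL/min/1.73 m^2.
#'
#' @param cystatin_c Serum cystatin C in mg/L (> 0). Vectorized.
#' @param age Age in years (>= 0).
#' @param sex `"female"` or `"male"` (recycled).
#' @return Numeric vector of eGFR values.
#' @examples
#' egfr_cystatin_c(0.8, 60, "male")   # 133 * 0.996^60
#' @export
egfr_cystatin_c <- function(cystatin_c, age, sex) {
  if (any(!is.na(cystatin_c) & cystatin_c <= 0)) {
    stop("cystatin_c must be positive")
  }
  stopifnot(all(is.na(age) | age >= 0))
  sex <- rep_len(as.character(sex), length(cystatin_c))
  r <- cystatin_c / 0.8
  133 * pmin(r, 1)^-0.499 * pmax(r, 1)^-1.328 * 0.996^age *
    ifelse(sex == "female", 0.932, 1)
}

#' Flag laboratory values against normal limits
#'
#' Strict comparisons: hypocalcemia means calcium strictly below the LLN,
#' hyperphosphatemia means phosphate strictly above the ULN. Missing labs give
#' missing flags.
#'
#' @param calcium,phosphate Numeric vectors in mM (either may be `NULL`).
#' @param lln Calcium lower limit of normal (default 2.2 mM).
#' @param uln Phosphate upper limit of normal (default 1.45 mM).
#' @return List with logical vectors `hypocalcemia` and `hyperphosphatemia`.
#' @export
flag_labs <- function(calcium = NULL, phosphate = NULL,
                      lln = adh1_lab_limits[["calcium_lln"]],
                      uln = adh1_lab_limits[["phosphate_uln"]]) {
  list(
    hypocalcemia = if (is.null(calcium)) NULL else calcium < lln,
    hyperphosphatemia = if (is.null(phosphate)) NULL else phosphate > uln
  )
}

#' Collapse repeated laboratory measurements to one value
#'
#' @param values Numeric vector of repeated measurements, in time order.
#' @param policy `"mean"` (average across measurements) or `"first"`
#'   (earliest measurement).
#' @return A single value; `NA` if `values` is empty.
#' @export
collapse_measurements <- function(values, policy = c("mean", "first")) {
  policy <- match.arg(policy)
  values <- values[!is.na(values)]
  if (length(values) == 0) return(NA_real_)
  switch(policy, mean = mean(values), first = values[[1L]])
}

.split_field <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) v[v != ""])
}

#' Build the analysis-ready phenotype table
#'
#' Turns a raw individual table (demographics, covariates, labs, ICD-10 codes,
#' medication strings) into one row per individual with phecode category
#' flags, the ADH1 medication count, lab flags, and eGFR. Repeated lab
#' measurements may be supplied in long format and are collapsed per `policy`.
#'
#' @param individuals `data.frame` with columns `individual_id`, `stratum`,
#'   `age`, `sex`, `pc1`..`pc10`, `calcium`, `phosphate`, `cystatin_c`,
#'   `icd10_codes` (`;`-separated), `medications` (`;`-separated), and
#'   optionally `record_coverage` (0/1).
#' @param phecode_map ICD-10-to-phecode map (default: bundled subset).
#' @param labs Optional long-format lab table with columns `individual_id`,
#'   `lab` (`"calcium"`/`"phosphate"`), `value`, in time order; when present it
#'   overrides the single-value lab columns.
#' @param policy Measurement collapsing policy, see [collapse_measurements()].
#' @param lln,uln Lab limits, see [flag_labs()].
#' @param keywords Medication keywords, see [count_adh1_medications()].
#' @param collapse_epilepsy Collapse the epilepsy phecodes into one category.
#' @return `data.frame` with the input identifiers/covariates plus `phecodes`,
#'   one logical `dx_<category>` column per ADH1 category, `any_adh1_dx`,
#'   `any_direct_dx`, `adh1_med_count`, `med_user`, `hypocalcemia`,
#'   `hyperphosphatemia` and `egfr`.
#' @export
build_phenotypes <- function(individuals,
                             phecode_map = adh1_phecode_map(),
                             labs = NULL,
                             policy = "mean",
                             lln = adh1_lab_limits[["calcium_lln"]],
                             uln = adh1_lab_limits[["phosphate_uln"]],
                             keywords = adh1_medication_keywords(),
                             collapse_epilepsy = TRUE) {
  stopifnot(is.data.frame(individuals))
  req <- c("individual_id", "stratum", "age", "sex")
  miss <- setdiff(req, names(individuals))
  if (length(miss)) stop("individuals table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- individuals

  if (!is.null(labs)) {
    for (lb in c("calcium", "phosphate")) {
      sub <- labs[labs$lab == lb, , drop = FALSE]
      if (nrow(sub)) {
        collapsed <- vapply(split(sub$value, sub$individual_id),
                            collapse_measurements, numeric(1), policy = policy)
        out[[lb]] <- unname(collapsed[match(out$individual_id,
                                            names(collapsed))])
      }
    }
  }

  categories <- adh1_phecode_categories(collapse_epilepsy)
  code_sets <- .split_field(out$icd10_codes)
  phecode_sets <- withCallingHandlers(
    lapply(code_sets, map_icd_to_phecodes, phecode_map = phecode_map),
    warning = function(w) invokeRestart("muffleWarning")  # unmapped noise
  )
  out$phecodes <- vapply(phecode_sets, paste, character(1), collapse = ";")
  for (cat in names(categories)) {
    out[[paste0("dx_", cat)]] <- vapply(
      phecode_sets, function(p) any(p %in% categories[[cat]]), logical(1))
  }
  dx_cols <- paste0("dx_", names(categories))
  out$any_adh1_dx <- Reduce(`|`, out[dx_cols])
  out$any_direct_dx <- Reduce(`|`, out[paste0("dx_", ADH1_DIRECT_DX_CATEGORIES)])

  med_sets <- .split_field(out$medications)
  out$adh1_med_count <- vapply(med_sets, count_adh1_medications, integer(1),
                               keywords = keywords)
  out$med_user <- out$adh1_med_count >= 1L

  fl <- flag_labs(out$calcium, out$phosphate, lln = lln, uln = uln)
  out$hypocalcemia <- fl$hypocalcemia
  out$hyperphosphatemia <- fl$hyperphosphatemia
  out$egfr <- if ("cystatin_c" %in% names(out)) {
    egfr_cystatin_c(out$cystatin_c, out$age, out$sex)
  } else NA_real_
  if (!"record_coverage" %in% names(out)) out$record_coverage <- 1L
  out
}
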