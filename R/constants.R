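#' Laboratory reference limits used throughout the package
#'
#' Serum calcium lower limit of normal (LLN) and serum phosphate upper limit of
#' normal (ULN), in mM. These are the defaults for lab flagging and penetrance
#' estimation; every function taking limits accepts overrides.
#'
#' @format Named numeric vector with elements `calcium_lln` (2.2 mM) and
#'   `phosphate_uln` (1.45 mM).
#' @export
adh1_lab_limits <- c(calcium_lln = 2.2, phosphate_uln = 1.45)

# CaSR protein length (residues), used by the synthetic generator when placing
# variants along the protein.
CASR_PROTEIN_LENGTH <- 1078L

#' ADH1-associated medication keywords
#'
#' The keyword list used to count ADH1-relevant medications in free-text
#' prescription strings: calcium supplements, active vitamin D analogues and
#' parathyroid-hormone replacement. Matching (see
#' [count_adh1_medications()]) is case-insensitive substring matching, except
#' for `"PTH"`, which is matched as a whole word only to avoid hits inside
#' longer tokens.
#'
#' @return Character vector of keywords.
#' @export
adh1_medication_keywords <- function() {
  c("calcichew", "calcichew d3 tablet", "colecalciferol", "cholecalciferol",
    "calcitriol", "calcium citrate", "calcium carbonate", "alfacalcidol",
    "PTH", "natpar", "teriparatide", "forteo")
}

#' ADH1-associated phecode categories
#'
#' The five diagnosis categories treated as ADH1-associated, as sets of
#' phecodes: hypoparathyroidism (252.2), disorders of calcium/phosphorus
#' metabolism (275.5), tetany (350.1), paresthesia (687.4), and epilepsy
#' (345, 345.1, 345.11, 345.12 -- collapsed into one category by default).
#'
#' @param collapse_epilepsy If `FALSE`, the epilepsy phecodes are returned as
#'   separate categories instead of one collapsed `"epilepsy"` entry.
#' @return Named list mapping category label to a character vector of phecodes.
#' @export
adh1_phecode_categories <- function(collapse_epilepsy = TRUE) {
  base <- list(
    hypoparathyroidism = "252.2",
    calcium_phosphorus = "275.5",
    tetany             = "350.1",
    paresthesia        = "687.4"
  )
  epi <- c("345", "345.1", "345.11", "345.12")
  if (collapse_epilepsy) {
    c(base, list(epilepsy = epi))
  } else {
    c(base, as.list(stats::setNames(epi, paste0("epilepsy_", epi))))
  }
}

# Categories counted as "directly suggestive" of an ADH1 diagnosis when
# estimating diagnosis-code penetrance (hypocalcemia / calcium-phosphorus
# disorder and hypoparathyroidism).
ADH1_DIRECT_DX_CATEGORIES <- c("calcium_phosphorus", "hypoparathyroidism")

#' Bundled phecode map subset (synthetic fixture)
#'
#' Reads the small ICD-10-to-phecode map shipped with the package. The file is
#' a hand-built subset in the Phecode Map 1.2 column layout (`icd10`,
#' `phecode`, `label`) covering the ADH1-associated categories plus a handful
#' of unrelated background codes; it is a synthetic stand-in for the full
#' 1,518-phenotype map, sufficient for the bundled simulator and the examples.
#' Supply your own full map for real data.
#'
#' @return `data.frame` with columns `icd10`, `phecode`, `label`.
#' @export
adh1_phecode_map <- function() {
  path <- system.file("extdata", "phecode_map_synthetic.tsv",
                      package = "adh1score", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}
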