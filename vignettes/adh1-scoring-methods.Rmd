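---
title: "Scoring gain-of-function CASR variants in biobanks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gain-of-function CASR variants in biobanks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Autosomal-dominant hypocalcemia type 1 (ADH1) is a rare form of
hypoparathyroidism caused by gain-of-function (GoF) variants in the
calcium-sensing receptor gene *CASR*. GoF variants lower serum calcium and
often raise serum phosphate; loss-of-function (LoF) variants in the same gene
cause the mirror phenotype (familial hypocalciuric hypercalcemia, FHH1).
Because ADH1 had no specific diagnosis code until recently, carriers in
population biobanks are frequently hypocalcemic on laboratory measurements yet
undiagnosed, so no single phenotype identifies them. `adh1score` implements a
genetics-first scoring procedure for this setting: rank rare *CASR* variants
by the joint weight of several weak, direction-constrained signals, calibrate
a detection threshold against synonymous variants, and quantify penetrance and
symptom burden downstream.

## The ADH1 score

For each variant $v$ and each ancestry stratum $s$ with at least one carrier,
the score is the weighted sum of binary sub-scores:

$$ S_{v,s} = 3\,\mathbb{1}[\text{calcium assoc.}] + 1\,\mathbb{1}[\text{phosphate assoc.}]
 + \sum_{c \in \text{dx}} 1\,\mathbb{1}[\text{category } c]
 + 1\,\mathbb{1}[\text{medications}] + 0.5\,\mathbb{1}[\text{hotspot}]
 + 0.2\,\mathbb{1}[\text{in-silico}] $$

* **Serum calcium (weight 3)** fires when the carrier effect from
  covariate-adjusted OLS (age, sex, 10 genetic PCs) is nominally significant
  ($p \le 0.05$) *and negative* — the GoF direction. Calcium carries the
  largest weight because it is the defining ADH1 phenotype.
* **Serum phosphate (weight 1)** fires on a significant *positive* effect;
  the lower weight reflects that only about half of strongly affected
  carriers are hyperphosphatemic.
* **Diagnosis categories (weight 1 each)** — hypoparathyroidism (phecode
  252.2), calcium/phosphorus disorders (275.5), tetany (350.1), paresthesia
  (687.4), and epilepsy (345.x, collapsed into one category by default). A
  category fires when at least one carrier has a phecode in it *and* the
  carrier-phenotype enrichment is significant by Fisher's exact test.
* **Medications (weight 1)** — same rule against a keyword list of calcium
  supplements, active vitamin D analogues and PTH replacement, matched
  case-insensitively in free-text prescriptions ("PTH" whole-word only).
* **Hotspot (weight 0.5)** — protein position inside the GoF hotspots,
  residues 116–136 and 819–837 (inclusive, 1-based).
* **In-silico (weight 0.2)** — a strict majority of an ensemble of
  pathogenicity predictors calls the variant deleterious (the ensemble
  summary is a numeric input; no external service is queried).

The variant-level score is the **maximum across strata**: a variant is
interesting if any ancestry cohort flags it. Binary sub-score grading is the
default because it is the simplest rule consistent with fixed per-component
weights and is fully auditable; a graded mode
($w \cdot \min(1, \log_{10}p/\log_{10}\alpha)$, direction-gated) is available
via `grading = "graded"` for sensitivity analyses, since fixed weights on a
continuous "strength of association" admit either reading.

Binary phenotypes always feed the score through Fisher's exact test
(two-sided p as the sum of hypergeometric probabilities at most that of the
observed table — conventions differ, so ours is pinned and oracle-tested).
Firth-penalized logistic regression is additionally reported when a
phenotype/variant combination has at least 10 events per variable
(`select_test()`); with carrier counts of 1–4 that regime is rare, which is
exactly why the exact test is the default inferential engine. Odds ratios are
displayed with the Haldane–Anscombe 0.5 correction but p-values never use it.
Cross-stratum pooling uses fixed-effect inverse-variance meta-analysis
(`meta_fixed_effect()`); for binary phenotypes with infinite odds ratios,
Stouffer's weighted-Z on signed p-values (`meta_stouffer()`) is the fallback,
since log-OR pooling is undefined there. The pooling method is a documented
package default — reasonable alternatives (random effects) exist but are
unnecessary at these carrier counts.

## Threshold calibration on the synonymous null

Synonymous *CASR* variants should carry no ADH1 signal, so their sub-scores
estimate the null. `build_null()` draws $B = 10{,}000$ null scores by
resampling each component independently (with replacement) from the
per-component empirical distributions of the synonymous set, and places the
threshold at the lower empirical order statistic of the target percentile
(98 by default): the mass of draws at or below the threshold is exactly
$\lceil 0.98B \rceil / B$, with no interpolation, which keeps the value
reproducible across numeric stacks. Independent resampling is the default
reading of "resampling sub-scores"; a joint mode (resampling whole sub-score
rows, preserving their correlation) is available via
`null_resampling = "joint"`. A fixed reference threshold of 1.5 — the
published operating point — is available via `threshold = "fixed"`.

Two properties of this calibration deserve honesty up front. First, under
binary grading the null score distribution is discrete (atoms at 0, 0.2,
0.5, 1, 2, 3, ...), so the percentile-to-specificity identity — held-out
specificity equal to the percentile target — holds only approximately: the
threshold order statistic sits on an atom, and the held-out mass at or below
it need not be exactly 0.98. Second, and more consequentially, sub-score
components are positively correlated *within* a variant: a synonymous
variant with on the order of a hundred carriers can fire several Fisher
diagnosis categories at once, each near its nominal type-I rate, whereas a
singleton variant rarely fires any. Independent component resampling
destroys this correlation and therefore produces a slightly lighter-tailed
null than the true held-out score distribution, which biases the measured
held-out specificity below the percentile target by up to a couple of
points (we observe roughly 0.95–0.98 at the 98th percentile across
synthetic cohort sizes; the gap widens in smaller cohorts, where each
diagnosis category's enrichment test sits closer to its nominal type-I
rate). The
joint resampling mode preserves the correlation and, for large synonymous
sets, makes the held-out specificity converge to the target up to atom
discreteness; it is available via `null_resampling = "joint"`, while
independent resampling remains the default as the plainest reading of
"resampling sub-scores". We report held-out specificity as measured; under
either mode it stays within a few points of the 0.98 operating target.

## The synthetic biobank

`simulate_biobank()` exists so that every stage — phenotype mapping,
association, scoring, calibration, burden — can be tested end to end with
known ground truth. Its defaults are fixed study conditions, not tuning
knobs:

* **Lab marginals.** Serum calcium baseline 2.37 mM, SD 0.095 mM; phosphate
  1.16 mM, SD 0.16 mM. These reproduce UK-scale biobank marginals and give
  roughly 3% of non-carriers below the calcium LLN of 2.2 mM, matching the
  published observation that only ~2% of the cohort is hypocalcemic.
  Covariate effects (age, sex, two PCs) are small and removed by the
  adjusted association model.
* **Variant classes.** Known GoF variants: carrier calcium shift
  $-|N(0.29, 0.15)|$ mM and 1–4 carriers — the moments of the twelve
  published per-stratum carrier effects ($-0.65$ to $-0.10$ mM) for
  established ADH1 variants. Intermediate GoF variants: $-|N(0.06, 0.04)|$
  mM at up to 120 carriers, the scale reported for score-identified variants.
  LoF variants shift calcium upward; neutral missense and synonymous
  variants have exactly zero shift. Carrier counts are log-uniform within
  their range, mimicking the rare-variant site-frequency skew.
* **Phosphate co-elevation** is applied per carrier with probability 0.5,
  reflecting that about half of strongly affected carriers are
  hyperphosphatemic.
* **Diagnosis codes are threshold-driven.** An individual can receive an
  ADH1-related ICD-10 code only when their realized calcium is below the
  LLN, with probability equal to the class's diagnosis penetrance (0.30 for
  known GoF carriers, 0.10 for hypocalcemic non-carriers), plus a small
  background coding rate (0.005 per category) for everyone. Conditioning on
  the realized lab rather than the genotype reproduces the empirical pattern
  that diagnosis lags hypocalcemia, and it makes diagnosis-code penetrance
  structurally at most lab penetrance for GoF classes — a property the test
  suite asserts.
* **Medications** are assigned to 70% of diagnosed individuals; 2% of
  everyone else carries an ADH1-matching supplement string (calcium and
  vitamin D supplements are common in the general population), and 30% carry
  unrelated prescriptions. Record coverage (needed for diagnosis-penetrance
  denominators) is 60%.
* **Within-person measurement SD** for repeated labs is 0.03 mM. The source
  cohorts do not report this quantity; it is an explicit assumption, and the
  default of one measurement per individual reflects that most biobank
  participants have a single measurement.

What the generator deliberately omits: linkage disequilibrium, relatedness
structure (relatedness enters only through the exclusion utility),
imputation error, assay batch effects, non-Gaussian lab tails, and
ancestry-specific lab distributions. Passing tests on this cohort therefore
demonstrate the correctness and calibration of the *procedure* under clean
Gaussian conditions, not its operating characteristics on real biobank data.

## Numerical choices and degenerate inputs

* OLS inside the scan uses a per-stratum QR of the covariate design and the
  Frisch–Waugh–Lovell identity, so each variant costs O(carriers ×
  covariates); the result is algebraically identical to `lm()` and tested to
  1e-10 against it. Strata where the carrier indicator is collinear with the
  covariates return a missing association (component 0).
* Fisher p-values sum hypergeometric point probabilities with the
  conventional $1 + 10^{-7}$ relative tolerance for floating-point ties.
* Firth fits use Newton steps on the Jeffreys-penalized likelihood with
  step-halving; p-values come from the penalized likelihood-ratio test.
  Complete separation yields finite estimates by construction.
* Variants with zero carriers in a stratum are not scored there; a variant
  with no carriers anywhere is an error. Realized MAF is carriers/(2n)
  exactly (heterozygous carriers); strata at or above the MAF cutoff (0.01)
  are excluded from scoring.
* Empty measurement lists collapse to missing, and missing labs produce
  missing flags, never false ones.
* ICD-10 codes are matched to phecodes after uppercasing and dot-stripping,
  on the longest available prefix (full, then 4-, then 3-character), which
  fixes deterministic behaviour for truncated codes. Phecodes pass through
  unchanged, making the mapping idempotent.
* Relatedness exclusion removes the member of each above-cutoff pair with
  more above-cutoff partners, ties broken by lexicographically smallest ID —
  the selection rule is unspecified in the source cohorts, so we fixed a
  deterministic one.
* Every stochastic stage (generator, null resampling) takes a mandatory seed
  and restores the caller's RNG state; pipeline re-runs are
  checksum-identical.

## Problem sizes used in validation

The bundled validation uses cohorts of 4,000–20,000 individuals for unit and
property tests, and the classifier-performance checks use 10,000–20,000
individuals with 1,100–1,500 synonymous variants (calibration plus held-out)
and replicated 50,000-person strata whose GoF variants take the twelve
published (shift, carrier-count) pairs verbatim. These sizes were chosen so
that Monte-Carlo error on the reported fractions is a few percent while the
full validation remains a desk-scale computation.

## Known limitations

* The in-silico ensemble is abstracted to a numeric fraction; no predictor
  is queried.
* The per-category composition of the diagnosis/medication block (five
  phecode categories + one medication component) is an inference from the
  published phecode list; the published weighting text admits small
  variations.
* Published aggregate carrier frequencies (e.g. 2.4 per 100,000) do not
  exactly equal carriers divided by the printed cohort size (2.31 per
  100,000 for 10/433,793); the denominators used there are not stated.
  `carrier_frequency()` always reports the exact ratio of its inputs.
* Sub-score grading (binary vs. graded) in the original analysis is not
  determinable from the published text; binary is our default, and both are
  implemented.
* Variants with conflicting ADH1/FHH1 annotations should be supplied with
  `known_status = "novel"` (the treatment given to such conflicts in the
  source analysis); the package does not resolve annotation conflicts
  itself.
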