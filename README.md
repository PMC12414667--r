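# adh1score

Genetics-first detection of gain-of-function *CASR* variants in population
biobanks.

## The problem

Autosomal-dominant hypocalcemia type 1 (ADH1) is a rare hypoparathyroidism
caused by gain-of-function (GoF) variants in the calcium-sensing receptor
gene *CASR*. GoF variants lower serum calcium (often raising serum
phosphate), but carriers in biobanks are widely undiagnosed — hypocalcemia on
laboratory values far outnumbers ADH1-consistent diagnosis codes — so no
single phenotype identifies them. This package is for statistical geneticists
who want to prioritize candidate GoF variants from biobank-scale genotype +
phenotype data and quantify their penetrance and symptom burden.

## The method

For each rare (MAF < 0.01) missense/nonsense/frameshift variant $v$ and each
ancestry stratum $s$, the **ADH1 score** is a weighted sum of binary,
direction-constrained sub-scores:

$$S_{v,s} = 3\,\mathbb{1}[\beta_{\mathrm{Ca}} < 0,\ p \le \alpha]
 + 1\,\mathbb{1}[\beta_{\mathrm{P}} > 0,\ p \le \alpha]
 + \textstyle\sum_{c=1}^{5} \mathbb{1}[\text{dx category } c]
 + \mathbb{1}[\text{medications}]
 + 0.5\,\mathbb{1}[\text{hotspot}] + 0.2\,\mathbb{1}[\text{in-silico}]$$

with $\alpha = 0.05$; carrier lab effects come from covariate-adjusted OLS
(age, sex, 10 genetic PCs), diagnosis/medication enrichment from Fisher's
exact test (Firth-penalized logistic regression reported when there are at
least 10 events per variable), the hotspot term from the GoF residue ranges
116–136 and 819–837, and the in-silico term from a majority-deleterious
ensemble consensus. The variant-level score is the maximum over strata. The
detection threshold is calibrated so that 98% of an empirical null —
built by resampling sub-scores of synonymous variants — falls below it
(the published fixed operating point 1.5 is also available). Downstream
utilities estimate carrier frequency per 100,000, laboratory and
diagnosis-code penetrance, excess symptom burden over the cohort baseline,
the allelic series of effect size versus frequency, and cross-cohort
concordance. A synthetic biobank generator with known ground truth makes the
whole pipeline testable end to end.

## Worked example

```r
library(adh1score)

co <- simulate_biobank(sim_config(n_individuals = 4000, seed = 7))
scan <- adh1_scan(co$variants, co$individuals, seed = 3)
summary(scan)
#> ADH1 variant scan summary
#>   variants by consequence:
#>
#>   missense synonymous
#>         69         90
#>   threshold 1 (empirical)
#>   mean score synonymous: 0.139; known ADH1: 3.8
#>   sensitivity 1 (n=5), specificity 0.978 (n=90)
#>   7 candidate call(s) above threshold; top:
#>  variant_id consequence score
#>     var0011    missense   6.0
#>     var0010    missense   5.2
#>     ...
```

Reading the output: 159 of the 174 simulated variants could be scored (at
least one carrier, below the MAF filter). The empirical null over the 90
scored synonymous variants put the 98th-percentile threshold at 1.0 in this
small cohort; all 5 simulated known-GoF variants exceed it
(sensitivity 1.0), 2% of synonymous variants do (specificity 0.978), and 7
novel missense candidates are called, led by scores combining a significant
calcium drop (weight 3) with phosphate, diagnosis, medication, hotspot or
in-silico support. `coef(scan)` returns the per-variant scores,
`predict(scan)` the above-threshold calls, `plot(scan)` the score histogram
against the threshold, and `scan$scores` the full per-(variant, stratum)
sub-score table.

Penetrance utilities work directly on published carrier values: the ten
reported carrier calcium measurements give
`lab_penetrance(c(2.13, 2.07, 2.07, 2.19, 2.19, 2.20, 1.96, 2.39, 2.22,
2.36), 2.2, "below")` = **0.6** (60% hypocalcemia penetrance), and the
matching phosphate values give 0.4 above the 1.45 mM limit.

For file-based runs, `write_cohort()` / `read_cohort()` handle the fixture
formats (TSV + VCF) and `run_pipeline(run_config(...))` executes phenotype
mapping → association → scoring → calibration → burden, writing per-stage
TSV/JSON outputs and a manifest with checksums; re-runs are byte-identical.

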