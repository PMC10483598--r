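---
title: "Methods: tissue-ctDNA concordance scoring and its survival implications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-ctDNA concordance scoring and its survival implications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctconcord)
```

## The problem

Advanced-cancer patients are frequently profiled twice: a tissue biopsy
sequenced on one targeted panel and a blood draw whose circulating tumor
DNA (ctDNA) is sequenced on another. The two reports rarely agree exactly.
`ctconcord` quantifies their agreement per patient and asks whether the
*amount* of agreement — how many genes carry a characterized alteration in
both assays — is itself prognostic for overall survival.

## Concordance definitions

All scoring is restricted to the *comparable universe*: genes sequenced by
both assays, resolved by the blood-draw date because the liquid panel
changed over time (a pre-2015-02 era with 53 comparable genes, 3 of them
amplification-eligible, and a later era with 55 and 16). Synonymous
variants and variants of unknown significance are excluded before any
comparison; gene symbols are upper-cased and passed through an optional
synonym map; protein-change descriptors are compared after stripping a
`p.` prefix and upper-casing.

Two nested definitions are used, both counting **distinct genes**:

* **Gene-level concordance** — the same gene carries a characterized
  alteration in both assays, not necessarily at the same position.
* **Mutation (locus)-level concordance** — the same locus aberration is
  present in both: equal normalized protein-change descriptors for point
  mutations and indels, or an amplification in both assays. Fusions are
  matched at gene level only, and an amplification on one side never
  locus-matches a point mutation on the other.

A patient's profile is the pair of counts plus a status: `N_N` (no mutual
gene), `Y_N` (mutual gene but no mutual mutation), `Y_Y` (both). The
locus-level set is a subset of the gene-level set by construction, which
gives the invariant chain
`mutual_mutation ≤ mutual_gene ≤ min(tissue genes, ctDNA genes)` that the
test suite checks on every generated cohort, alongside equivalence with an
independent brute-force all-pairs matcher.

With counts of gene-level concordant tumors per gene across a cohort, the
*conditional* locus-identity frequency `mutual_mutation_n / mutual_gene_n`
is reported for genes with at least five concordant tumors (the retention
threshold is a parameter; five, inclusive, is the default — the source
material uses "five or more" and "more than five" interchangeably, and on
the packaged per-gene table both rules retain the same 11 genes).

## Survival models

Overall survival is measured from diagnosis; death is the event and
patients alive at last follow-up are censored. All fits are Cox
proportional-hazards partial-likelihood fits with Efron tie handling (the
`survival` package's default, and the convention of the original
analysis). The fixed multivariable adjustment set is: age at diagnosis,
sex, cancer-type group (reference level = most frequent group), signed
months between tissue biopsy and blood draw, maximum percent ctDNA of any
deleterious variant, tissue and ctDNA distinct altered-gene counts, and
tumor mutational burden — continuous covariates entered untransformed.
On top of the continuous-count model the package provides:

* **Threshold analysis** — replace the count by the indicator
  `[count ≥ k]` and refit (`k` = 1, 2, 3 by default).
* **Time-gap sensitivity** — refit on patients with `|gap| ≤` 48, 24, 12,
  6 months (absolute value, since gaps may be negative).
* **Covariate-omission scan** — drop one adjustment covariate at a time
  and track the concordance term's hazard ratio and p.
* **Kaplan–Meier curves** with a single-covariate Cox comparison. Whether
  such univariate p-values should be score, Wald or likelihood-ratio
  statistics is a matter of convention; the package computes all three and
  reports the likelihood-ratio p as the headline.

Left truncation is deliberately ignored (survival runs from diagnosis
although the blood draw happens later), reproducing the original design;
this is an immortal-time limitation inherent to that design, not an
artifact of the implementation.

## The synthetic cohort generator

No per-patient study data are redistributable, so the package ships a
generator whose *defaults are the stated world* of the reference cohort
(433 patients):

1. **Tumor types** from a seven-group categorical distribution
   (gastrointestinal 28%, breast/gynecologic 20%, lung 14%,
   hepatopancreatobiliary 8%, head & neck 7%, brain 5%, other 18%).
2. **Tissue alterations**: per-gene Bernoulli presence with prevalence
   taken from the packaged per-gene cohort table (e.g. TP53 196/433),
   scaled by a mild per-type multiplier; an altered gene carries
   `1 + Poisson(λ)` alterations, λ calibrated so the expectation is 1.97
   alterations/patient. In amplification-eligible genes (era-resolved per
   patient) an alteration is an amplification with probability 0.34,
   matching the cohort's 114/853 tissue share. Loci are drawn from
   per-gene hotspot lists (a synthetic fixture).
3. **Shedding and detection**: a latent per-patient shedding factor
   `s ~ Gamma(shape = 0.45, mean = type multiplier)` (brain tumors shed
   least); each tissue alteration is detected in blood with probability
   `plogis(0.20 + log s)`. An optional clonal-drift term decays the
   detection logit with the absolute biopsy-to-draw gap (off by default).
4. **Locus identity**: a detected point mutation is locus-identical with
   per-gene probability `q_g` (the packaged table's observed ratios where
   it has ≥5 concordant tumors, median fallback 0.63), otherwise re-drawn
   at a different hotspot of the same gene.
5. **Blood-private alterations**: `Poisson(0.85)` extra ctDNA alterations
   per patient in genes *not* tissue-altered for that patient
   (resistance/CHIP-like). Drawing them from non-tissue genes keeps the
   detection calibration clean; the cost is that coincidental gene-level
   concordance not caused by shedding is absent from the generator.
6. **VAF**: `pct = 100 · min(1, s · Beta(0.3, 15))`, giving sub-percent
   medians; the clinical `pct_ctdna` is the per-patient maximum.
7. **Survival**: Weibull baseline (shape 1.1, scale 28 months) under a
   proportional-hazards model whose log hazard is linear in the TRUE
   mutual gene count (default coefficient `log 1.25`), age (0.02/year,
   centered at 58.6), percent ctDNA (0.015/%), and a tumor-type offset
   (brain +0.4, hepatopancreatobiliary +0.5); independent uniform
   censoring on [6, 120] months.

The calibration constants (`detect_a = 0.20`, `shed_shape = 0.45`,
`blood_private_rate = 0.85`) were frozen once from long-run Monte Carlo
(n = 50k–100k) against the cohort targets — tissue 1.97 and ctDNA 1.57
alterations/patient, mean mutual gene count 0.67, 42.5% of patients with
at least one mutual gene — and verified at n = 100k as
1.974 / 1.577 / 0.668 / 0.435. The generator's ground truth (shedding
factor, true mutual count, linear predictor) is emitted alongside the
tables but never consumed by the pipeline under test.

```{r example}
cohort <- generate_cohort(preset_paperlike(n_patients = 433, seed = 1))
frame <- build_cohort_frame(harmonize_cohort(cohort$alterations),
                            cohort$clinical)
fit <- cox_fit(frame, c(default_covariates(), "mutual_gene_count"))
cox_term(fit, "mutual_gene_count")
```

### What a green test does and does not establish

The generator reproduces the cohort's first-order structure: alteration
burdens, the concordance distribution, shedding-driven positive
association between %ctDNA and mutual counts, tumor-type heterogeneity,
and a proportional-hazards survival dependence. It does **not** emulate
subclonal architecture, treatment-induced ctDNA suppression, CHIP
mutational spectra, assay-specific limits of detection, panel-version
drift within an era, or correlation between TMB and anything else (TMB is
independent noise, as in the cohort, where it was uncorrelated with
concordance). Green property tests therefore establish correctness of the
scoring and inference machinery under a plausible mechanism — not that
the mechanism is biologically complete.

## Numerical and design choices

* **Counting unit**: mutual counts are distinct genes; a gene with two
  locus matches counts once. Required for consistency with the printed
  0–5 ranges and the subset invariant.
* **Chi-square binning**: mutual counts are binned `0 / 1 / 2 / ≥3` by
  default before tumor-type contingency tests (the original binning is
  unstated; the rule is a parameter). Pearson standardized residuals
  `(O−E)/√E` are returned, so `Σ residual² = statistic`.
* **Missingness**: pairwise deletion for correlations (dropped ids
  reported), listwise within each model fit.
* **p-value floor**: values below 2.2e-16 are printed as `< 2.2e-16` but
  stored as raw doubles.
* **Era boundary** 2015-02-01, configurable in the panel JSON; the era is
  a property of the liquid assay, so the earliest ctDNA draw date
  resolves it.
* **Monotonicity property**: the stated "increasing the shedding slope
  increases concordance and %ctDNA" is tested as monotonicity in the
  shedding *level* (scale), because with median `s < 1` a steeper
  logistic slope lowers detection for most patients and %ctDNA does not
  depend on the slope at all — the level is the well-posed version of the
  property.
* **Known small-sample behavior**: the per-term Wald p is mildly
  anti-conservative in cohorts of a few hundred with the full
  ~15-parameter adjustment set (measured type-I ≈ 0.061 at n = 433
  vs ≈ 0.043 at n = 1000 over fresh replicates); the type-I acceptance
  criterion is therefore evaluated at n = 1000, the same size its
  companion parameter-recovery criterion states.

## Limitations

Reproduction of the published per-patient numbers requires the study's
supplementary per-sample tables, which cannot be redistributed here; the
`reproduce` entry point accepts them as delimited exports and the
acceptance tests encode every printed target against that path. Two
internal inconsistencies of the published summary are documented in the
package rather than resolved: the printed conditional-frequency maximum
(0.875, APC) is exceeded by the printed PTEN row (9/10 = 0.9), and the
printed mean mutual-mutation count (0.6) is not reproducible from the
printed per-gene table (169/433 ≈ 0.39 distinct genes per patient); the
package reports the table-derived quantities. The cohort-status tallies
(patients with ≥1 mutual gene vs the Y_N/Y_Y split) are reported as
separate outputs and never forced to agree.
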