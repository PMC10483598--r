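# ctconcord

Concordance between tumor-tissue and circulating-tumor-DNA (ctDNA) panel
reports, and what that concordance means for survival.

Patients with advanced cancer are often profiled twice: a tissue biopsy on
one targeted NGS panel and a liquid biopsy (ctDNA from blood) on another.
`ctconcord` is for clinical-genomics analysts who need to (a) harmonize
two such per-patient alteration reports to the genes both panels actually
sequenced, (b) score per-patient agreement at two resolutions, and (c)
test whether the amount of agreement independently predicts overall
survival.

## The statistics at the core

For patient *i* with characterized (non-VUS) alteration sets restricted
to the date-resolved comparable gene universe:

* **mutual gene count** `G_i` = #{genes altered in both assays}
  (gene-level concordance);
* **mutual mutation count** `M_i` = #{genes with an identical locus
  aberration in both — same protein change for SNVs/indels, or
  amplification in both}; `M_i ≤ G_i` always;
* **status** `N_N` / `Y_N` / `Y_Y` from (`G_i`, `M_i`).

Prognosis is modeled with Cox proportional hazards (Efron ties):

```
h_i(t) = h0(t) · exp(β·G_i + γ' z_i)
```

with `z_i` the fixed adjustment set (age at diagnosis, sex, cancer-type
group, biopsy-to-draw gap in months, maximum %ctDNA, per-assay altered
gene counts, TMB). Threshold variants replace `G_i` by `[G_i ≥ k]`;
sensitivity analyses refit after gap filtering or one-covariate omission.
A calibrated synthetic-cohort generator (gene prevalences seeded from the
published 433-patient per-gene table, a latent gamma shedding factor
driving logistic detection of tissue alterations in blood, blood-private
alterations, Weibull proportional-hazards survival) makes the whole chain
runnable and testable with no external data.

## Worked example

```r
library(ctconcord)

cohort <- generate_cohort(preset_paperlike(n_patients = 433, seed = 7))
harm   <- harmonize_cohort(cohort$alterations)
s      <- cohort_summary(harm, cohort$clinical$patient_id)
gt     <- cohort_gene_table(harm)
frame  <- build_cohort_frame(harm, cohort$clinical)
fit    <- cox_fit(frame, c(default_covariates(), "mutual_gene_count"))
```

which prints (seed 7):

```
tissue: 837 alterations (1.93/patient), ctDNA: 697 (1.61/patient)
patients with >=1 mutual gene: 181 (41.8%), mean mutual count 0.62

   gene tissue_n ctdna_n mutual_gene_n mutual_mutation_n
   TP53      197     151            79                58
   KRAS       69      79            31                18
 PIK3CA       49      51            24                13

                term      coef hazard_ratio   ci_low  ci_high          p
   mutual_gene_count 0.2865828     1.331868 1.098926 1.614188 0.00348147
```

Reading it: this simulated 433-patient cohort has ~1.9 tissue and ~1.6
ctDNA alterations per patient; 42% of patients have at least one gene
altered in both assays; TP53 is concordant in 79 tumors, 58 of them at
the identical locus. Each additional mutual gene multiplies the death
hazard by 1.33 (95% CI 1.10–1.61) after full adjustment — consistent
with the generating coefficient of 1.25.

Real data enter through `read_alteration_table()` (TSV/CSV in the
canonical schema, or any layout via a `schema_adapter`) and
`reproduce_cohort_analysis()`, or the CLI:

```sh
Rscript -e 'ctconcord::ctconcord_cli()' simulate --out sim --seed 7
Rscript -e 'ctconcord::ctconcord_cli()' reproduce \
    --alterations sim/alterations.tsv --clinical sim/clinical.tsv --out results
```

## Layout

* `R/` — harmonization (`panels.R`), concordance engine
  (`concordance.R`), cohort statistics (`stats.R`), survival models
  (`survival.R`), synthetic cohorts (`simulate.R`), pipeline + CLI.
* `inst/extdata/` — packaged two-era panel lists (cardinalities 53/3 and
  55/16; membership beyond the published 34-gene table is a synthetic
  stand-in, as the filename says), the published per-gene concordance
  table, synthetic hotspot loci.
* `vignettes/ctconcord-methods.Rmd` — model assumptions, generator
  calibration, numerical choices, limitations.
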