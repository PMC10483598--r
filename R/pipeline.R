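#' Cohort-level descriptive summary
#'
#' The headline counts of the concordance analysis: alterations by assay
#' and kind, per-patient means, and the mutual-gene / mutual-mutation
#' distribution.
#'
#' @param alterations Harmonized, characterized `alteration_table`.
#' @param patient_ids Optional full patient universe (patients with no
#'   alterations included in denominators); defaults to patients in the
#'   table.
#' @return Named list of scalars: `n_patients`, `tissue_alterations`,
#'   `tissue_point_mutations`, `tissue_amplifications`,
#'   `ctdna_alterations`, `ctdna_point_mutations`,
#'   `ctdna_amplifications`, `mean_tissue_per_patient`,
#'   `mean_ctdna_per_patient`, `n_with_mutual_gene`,
#'   `frac_with_mutual_gene`, `mean_mutual_gene_count`,
#'   `max_mutual_gene_count`, `mean_mutual_mutation_count`, `n_Y_N`,
#'   `n_Y_Y`.
#' @export
cohort_summary <- function(alterations, patient_ids = NULL) {
  if (is.null(patient_ids)) patient_ids <- unique(alterations$patient_id)
  n <- length(patient_ids)
  prof <- profile_cohort(alterations, patient_ids)
  cnt <- function(assay, kind = NULL) {
    sub <- alterations[alterations$assay == assay, , drop = FALSE]
    if (!is.null(kind)) sub <- sub[sub$kind %in% kind, , drop = FALSE]
    nrow(sub)
  }
  snv <- c("point_mutation", "indel")
  list(n_patients = n,
       tissue_alterations = cnt("tissue"),
       tissue_point_mutations = cnt("tissue", snv),
       tissue_amplifications = cnt("tissue", "amplification"),
       ctdna_alterations = cnt("ctdna"),
       ctdna_point_mutations = cnt("ctdna", snv),
       ctdna_amplifications = cnt("ctdna", "amplification"),
       mean_tissue_per_patient = cnt("tissue") / n,
       mean_ctdna_per_patient = cnt("ctdna") / n,
       n_with_mutual_gene = sum(prof$mutual_gene_count > 0),
       frac_with_mutual_gene = mean(prof$mutual_gene_count > 0),
       mean_mutual_gene_count = mean(prof$mutual_gene_count),
       max_mutual_gene_count = max(prof$mutual_gene_count),
       mean_mutual_mutation_count = mean(prof$mutual_mutation_count),
       n_Y_N = sum(prof$status == "Y_N"),
       n_Y_Y = sum(prof$status == "Y_Y"))
}

#' Run the full concordance-and-survival pipeline
#'
#' Harmonize -> per-patient concordance -> cohort gene table and
#' descriptive statistics -> survival models, writing every artifact as
#' tab-separated text plus a JSON run manifest. Deterministic: the same
#' inputs and config produce byte-identical outputs.
#'
#' @param alterations Raw `alteration_table` (both assays, characterized
#'   flag set).
#' @param clinical Clinical table (see [build_cohort_frame()]).
#' @param out_dir Output directory (created if needed).
#' @param panel_set Panel eras (default packaged).
#' @param covariates Multivariable covariate set.
#' @param thresholds Cutoffs for the threshold analyses.
#' @param gap_filters Time-gap sensitivity thresholds in months.
#' @param min_mutual Gene-retention threshold for conditional
#'   mutation-frequency.
#' @param seed Recorded in the manifest (the pipeline itself draws no
#'   random numbers).
#' @return Invisibly, a list with all computed objects (`harmonized`,
#'   `profiles`, `gene_table`, `cond_freq`, `frame`, `summary`,
#'   `correlations`, `chisq`, `km`, `cox_full`, `thresholds`,
#'   `gap_sensitivity`, `omission`).
#' @export
run_pipeline <- function(alterations, clinical, out_dir,
                         panel_set = load_packaged_panels(),
                         covariates = default_covariates(),
                         thresholds = c(1L, 2L, 3L),
                         gap_filters = c(48, 24, 12, 6),
                         min_mutual = 5L, seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  harmonized <- harmonize_cohort(alterations, panel_set)
  profiles <- profile_cohort(harmonized, patient_ids = clinical$patient_id)
  gene_table <- cohort_gene_table(harmonized)
  cond <- conditional_mutation_frequency(gene_table, min_mutual)
  frame <- build_cohort_frame(harmonized, clinical)
  summ <- cohort_summary(harmonized, clinical$patient_id)

  correlations <- list(
    mutual_vs_tissue = correlate(frame, "mutual_gene_count", "tissue_gene_count"),
    mutual_vs_tmb = correlate(frame, "mutual_gene_count", "tmb"),
    mutual_vs_gap = correlate(frame, "mutual_gene_count", "gap_months"),
    pct_vs_mutual = correlate(frame, "pct_ctdna", "mutual_gene_count"))
  chisq <- list(
    mutual_gene_by_type = chisq_residual_table(frame, "tumor_type",
                                               "mutual_gene_count"),
    mutual_mutation_by_type = chisq_residual_table(frame, "tumor_type",
                                                   "mutual_mutation_count"))
  kw <- group_compare(frame, "ctdna_gene_count", "status")

  km <- km_logrank(frame, "mutual_gene_count")
  cox_full <- cox_fit(frame, c(covariates, "mutual_gene_count"))
  thr <- lapply(thresholds, function(k)
    threshold_analysis(frame, "mutual_gene_count", k, covariates))
  names(thr) <- paste0("ge", thresholds)
  gaps <- gap_sensitivity(frame, gap_filters, covariates = covariates)
  omis <- covariate_omission_scan(frame, "mutual_gene_count", covariates)

  wtab <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtab(gene_table, "gene_concordance_table.tsv")
  wtab(profiles, "patient_profiles.tsv")
  wtab(cond$per_gene, "conditional_mutation_frequency.tsv")
  wtab(forest_table(cox_full), "cox_multivariable.tsv")
  wtab(gaps, "gap_sensitivity.tsv")
  wtab(omis, "covariate_omission.tsv")
  jsonlite::write_json(
    list(summary = summ,
         conditional_median = cond$median,
         correlations = lapply(correlations, function(x) x[c("r", "p", "n")]),
         chisq = lapply(chisq, function(x) x[c("statistic", "df", "p")]),
         kruskal_ctdna_by_status = kw[c("statistic", "df", "p")],
         km_univariate_p = km$p,
         cox_full = forest_table(cox_full),
         thresholds = lapply(thr, forest_table)),
    file.path(out_dir, "results.json"), auto_unbox = TRUE, digits = 10)
  manifest <- list(package = "ctconcord",
                   version = as.character(utils::packageVersion("ctconcord")),
                   r_version = R.version.string,
                   seed = seed,
                   n_patients = nrow(clinical),
                   n_alterations_in = nrow(alterations),
                   n_alterations_harmonized = nrow(harmonized),
                   covariates = covariates, thresholds = thresholds,
                   gap_filters = gap_filters, min_mutual = min_mutual)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(harmonized = harmonized, profiles = profiles,
                 gene_table = gene_table, cond_freq = cond, frame = frame,
                 summary = summ, correlations = correlations, chisq = chisq,
                 kruskal = kw, km = km, cox_full = cox_full, thresholds = thr,
                 gap_sensitivity = gaps, omission = omis))
}

#' Reproduce the published analysis from supplementary-style inputs
#'
#' Convenience wrapper: reads the alteration and clinical tables from
#' delimited text files laid out in the canonical schema (a
#' `schema_adapter` can map other layouts) and runs [run_pipeline()].
#' The published study's own per-sample tables are distributed as
#' journal supplementary spreadsheets and are not packaged here; export
#' them to TSV/CSV with the canonical headers to reproduce the cohort
#' numbers.
#'
#' @param alterations_path,clinical_path Input files.
#' @param out_dir Output directory.
#' @param schema_adapter Optional adapter for [read_alteration_table()].
#' @param ... Passed to [run_pipeline()].
#' @return The [run_pipeline()] result list, invisibly.
#' @export
reproduce_cohort_analysis <- function(alterations_path, clinical_path,
                                      out_dir, schema_adapter = NULL, ...) {
  alts <- read_alteration_table(alterations_path,
                                schema_adapter = schema_adapter)
  clin <- utils::read.table(clinical_path, header = TRUE,
                            sep = if (grepl("\\.csv$", clinical_path)) "," else "\t",
                            stringsAsFactors = FALSE)
  clin$death <- as.logical(clin$death)
  run_pipeline(alts, clin, out_dir, ...)
}

#' Write a synthetic cohort to disk in the pipeline's input schema
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_alteration_table(cohort$alterations,
                         file.path(out_dir, "alterations.tsv"))
  clin <- cohort$clinical
  clin$tissue_date <- as.character(clin$tissue_date)
  clin$blood_date <- as.character(clin$blood_date)
  utils::write.table(clin, file.path(out_dir, "clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       dataframe = "columns", digits = 10)
  invisible(out_dir)
}
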