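#' Build the per-patient cohort analysis frame
#'
#' Joins the clinical table with per-assay distinct altered gene counts
#' and the concordance profile. This frame is the single input consumed by
#' the descriptive statistics and survival layers.
#'
#' @param alterations Harmonized, characterized `alteration_table`.
#' @param clinical data.frame with one row per patient: `patient_id`,
#'   `age_dx` (years at diagnosis), `sex` ("F"/"M"), `tumor_type` (group
#'   label), `gap_months` (signed months, blood draw minus tissue biopsy;
#'   may be derived from `tissue_date`/`blood_date` when absent),
#'   `os_months` (months from diagnosis to death or last follow-up),
#'   `death` (logical), `tmb` (mutations/Mb), `pct_ctdna` (max VAF of any
#'   deleterious ctDNA variant, percent).
#' @return data.frame, one row per patient, clinical fields plus
#'   `tissue_gene_count`, `ctdna_gene_count`, `mutual_gene_count`,
#'   `mutual_mutation_count`, `status`.
#' @export
build_cohort_frame <- function(alterations, clinical) {
  stopifnot(is.data.frame(clinical), "patient_id" %in% names(clinical))
  if (anyDuplicated(clinical$patient_id)) {
    stop("clinical table has duplicated patient_id(s)", call. = FALSE)
  }
  if (!"gap_months" %in% names(clinical)) {
    if (!all(c("tissue_date", "blood_date") %in% names(clinical))) {
      stop("clinical table needs gap_months or tissue_date+blood_date",
           call. = FALSE)
    }
    clinical$gap_months <- as.numeric(as.Date(clinical$blood_date) -
                                        as.Date(clinical$tissue_date)) / 30.44
  }
  prof <- profile_cohort(alterations, patient_ids = clinical$patient_id)
  count_genes <- function(assay) {
    sub <- alterations[alterations$assay == assay, c("patient_id", "gene")]
    sub <- unique(sub)
    tab <- table(sub$patient_id)
    as.integer(tab[match(clinical$patient_id, names(tab))])
  }
  frame <- clinical
  tg <- count_genes("tissue"); tg[is.na(tg)] <- 0L
  cg <- count_genes("ctdna"); cg[is.na(cg)] <- 0L
  frame$tissue_gene_count <- tg
  frame$ctdna_gene_count <- cg
  m <- match(frame$patient_id, prof$patient_id)
  frame$mutual_gene_count <- prof$mutual_gene_count[m]
  frame$mutual_mutation_count <- prof$mutual_mutation_count[m]
  frame$status <- prof$status[m]
  if (!"pct_ctdna" %in% names(frame)) {
    ct <- alterations[alterations$assay == "ctdna", , drop = FALSE]
    mx <- tapply(ct$vaf_percent, ct$patient_id, function(v) {
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    })
    frame$pct_ctdna <- as.numeric(mx[match(frame$patient_id, names(mx))])
    frame$pct_ctdna[is.na(frame$pct_ctdna)] <- 0
  }
  frame
}
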