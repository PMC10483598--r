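#' Locus-level match between two alterations
#'
#' Two characterized alterations from opposite assays match at the locus
#' (mutation) level iff they hit the same gene and either both are
#' amplifications, or both are point mutations / indels with equal
#' normalized protein-change descriptors. Fusions and "other" kinds never
#' locus-match: they contribute to gene-level concordance only.
#'
#' @param a,b Single-row data.frames (or lists) with `gene`, `kind`,
#'   `locus` fields, already normalized.
#' @return Logical scalar.
#' @export
match_locus <- function(a, b) {
  if (a$gene != b$gene) return(FALSE)
  if (a$kind == "amplification" && b$kind == "amplification") return(TRUE)
  snv <- c("point_mutation", "indel")
  if (a$kind %in% snv && b$kind %in% snv) {
    return(nzchar(a$locus) && identical(a$locus, b$locus))
  }
  FALSE
}

new_concordance_profile <- function(patient_id, mutual_genes,
                                    mutual_mutation_genes) {
  mg <- length(mutual_genes)
  mm <- length(mutual_mutation_genes)
  status <- if (mg == 0L) "N_N" else if (mm == 0L) "Y_N" else "Y_Y"
  structure(list(patient_id = patient_id,
                 mutual_genes = sort(mutual_genes),
                 mutual_mutation_genes = sort(mutual_mutation_genes),
                 mutual_gene_count = mg,
                 mutual_mutation_count = mm,
                 status = status),
            class = "concordance_profile")
}

#' @export
print.concordance_profile <- function(x, ...) {
  cat(sprintf("<concordance_profile %s> status=%s mutual genes=%d [%s] mutual mutations=%d [%s]\n",
              x$patient_id, x$status,
              x$mutual_gene_count, paste(x$mutual_genes, collapse = ","),
              x$mutual_mutation_count,
              paste(x$mutual_mutation_genes, collapse = ",")))
  invisible(x)
}

#' Per-patient concordance profile
#'
#' Computes, for one patient's harmonized and characterized alteration
#' lists, the set of mutual genes (altered in both assays), the subset
#' with at least one locus-identical alteration pair, the two counts, and
#' the N_N / Y_N / Y_Y status. Counts are numbers of distinct genes: a
#' gene with two locus matches still counts once.
#'
#' @param tissue_alts,ctdna_alts `alteration_table` rows for one patient,
#'   restricted to the same comparable gene set and characterized-only.
#' @return A `concordance_profile`.
#' @export
profile_patient <- function(tissue_alts, ctdna_alts) {
  pids <- unique(c(tissue_alts$patient_id, ctdna_alts$patient_id))
  if (length(pids) > 1L) {
    stop("alteration lists span multiple patients: ",
         paste(pids, collapse = ", "), call. = FALSE)
  }
  pid <- if (length(pids)) pids else NA_character_
  mutual <- intersect(unique(tissue_alts$gene), unique(ctdna_alts$gene))
  snv <- c("point_mutation", "indel")
  mm_genes <- character()
  for (g in mutual) {
    ta <- tissue_alts[tissue_alts$gene == g, , drop = FALSE]
    ca <- ctdna_alts[ctdna_alts$gene == g, , drop = FALSE]
    amp_both <- any(ta$kind == "amplification") && any(ca$kind == "amplification")
    loci_t <- ta$locus[ta$kind %in% snv & nzchar(ta$locus)]
    loci_c <- ca$locus[ca$kind %in% snv & nzchar(ca$locus)]
    if (amp_both || length(intersect(loci_t, loci_c))) {
      mm_genes <- c(mm_genes, g)
    }
  }
  new_concordance_profile(pid, mutual, mm_genes)
}

#' Concordance profiles for a whole cohort
#'
#' @param alterations Harmonized, characterized `alteration_table` for the
#'   cohort (both assays).
#' @param patient_ids Optional character vector fixing the patient
#'   universe (patients with no alteration in either assay are N_N with
#'   zero counts); defaults to patients present in the table.
#' @return data.frame with one row per patient: `patient_id`,
#'   `mutual_gene_count`, `mutual_mutation_count`, `status`.
#' @export
profile_cohort <- function(alterations, patient_ids = NULL) {
  if (is.null(patient_ids)) {
    patient_ids <- sort(unique(alterations$patient_id))
  }
  # vectorized over (patient, gene) keys; profile_patient gives the same
  # answer patient-by-patient (property-tested)
  snv <- c("point_mutation", "indel")
  tis <- alterations[alterations$assay == "tissue", , drop = FALSE]
  ct <- alterations[alterations$assay == "ctdna", , drop = FALSE]
  gkey <- function(d) unique(paste(d$patient_id, d$gene, sep = "\r"))
  mutual <- intersect(gkey(tis), gkey(ct))
  amp_mm <- intersect(gkey(tis[tis$kind == "amplification", ]),
                      gkey(ct[ct$kind == "amplification", ]))
  lkey <- function(d) {
    d <- d[d$kind %in% snv & nzchar(d$locus), , drop = FALSE]
    unique(paste(d$patient_id, d$gene, d$locus, sep = "\r"))
  }
  loc_hit <- intersect(lkey(tis), lkey(ct))
  loc_mm <- unique(sub("\r[^\r]*$", "", loc_hit))
  mm <- union(amp_mm, loc_mm)
  count_by_pid <- function(keys) {
    pidv <- sub("\r.*$", "", keys)
    tab <- table(pidv)
    out <- as.integer(tab[match(patient_ids, names(tab))])
    out[is.na(out)] <- 0L
    out
  }
  mg_n <- count_by_pid(mutual)
  mm_n <- count_by_pid(mm)
  data.frame(patient_id = patient_ids,
             mutual_gene_count = mg_n,
             mutual_mutation_count = mm_n,
             status = ifelse(mg_n == 0L, "N_N",
                             ifelse(mm_n == 0L, "Y_N", "Y_Y")),
             stringsAsFactors = FALSE)
}

#' Cohort-level per-gene concordance table
#'
#' One row per gene with at least one alteration anywhere in the cohort:
#' the number of tumors with a tissue alteration in the gene, with a ctDNA
#' alteration, with the gene altered in both assays, and with a
#' locus-identical alteration in both assays. Each tumor contributes at
#' most one to each count per gene.
#'
#' @param alterations Harmonized, characterized `alteration_table`.
#' @return data.frame with columns `gene`, `tissue_n`, `ctdna_n`,
#'   `mutual_gene_n`, `mutual_mutation_n`, sorted by decreasing
#'   `tissue_n`.
#' @export
cohort_gene_table <- function(alterations) {
  genes <- sort(unique(alterations$gene))
  pids <- unique(alterations$patient_id)
  snv <- c("point_mutation", "indel")
  out <- data.frame(gene = genes, tissue_n = 0L, ctdna_n = 0L,
                    mutual_gene_n = 0L, mutual_mutation_n = 0L,
                    stringsAsFactors = FALSE)
  tis <- alterations[alterations$assay == "tissue", , drop = FALSE]
  ct <- alterations[alterations$assay == "ctdna", , drop = FALSE]
  for (i in seq_along(genes)) {
    g <- genes[i]
    tg <- tis[tis$gene == g, , drop = FALSE]
    cg <- ct[ct$gene == g, , drop = FALSE]
    pt <- unique(tg$patient_id)
    pc <- unique(cg$patient_id)
    both <- intersect(pt, pc)
    mm <- vapply(both, function(pid) {
      ta <- tg[tg$patient_id == pid, , drop = FALSE]
      ca <- cg[cg$patient_id == pid, , drop = FALSE]
      (any(ta$kind == "amplification") && any(ca$kind == "amplification")) ||
        length(intersect(ta$locus[ta$kind %in% snv & nzchar(ta$locus)],
                         ca$locus[ca$kind %in% snv & nzchar(ca$locus)])) > 0L
    }, logical(1))
    out$tissue_n[i] <- length(pt)
    out$ctdna_n[i] <- length(pc)
    out$mutual_gene_n[i] <- length(both)
    out$mutual_mutation_n[i] <- sum(mm)
  }
  out[order(-out$tissue_n, out$gene), , drop = FALSE]
}

#' Conditional mutation-level concordance frequency per gene
#'
#' For genes with at least `min_mutual` tumors showing gene-level
#' concordance, the chance that the concordance is locus-identical:
#' `mutual_mutation_n / mutual_gene_n`. Also returns the median across
#' retained genes.
#'
#' @param gene_table Output of [cohort_gene_table()] (or an equivalent
#'   data.frame).
#' @param min_mutual Minimum `mutual_gene_n` for a gene to be retained
#'   (inclusive; default 5).
#' @return List with `per_gene` (data.frame gene, mutual_gene_n,
#'   mutual_mutation_n, frequency) and `median` (NA-free scalar, or a
#'   zero-row frame and `NA` when no gene qualifies).
#' @export
conditional_mutation_frequency <- function(gene_table, min_mutual = 5L) {
  stopifnot(min_mutual >= 1L)
  keep <- gene_table$mutual_gene_n >= min_mutual
  per_gene <- gene_table[keep, c("gene", "mutual_gene_n", "mutual_mutation_n"),
                         drop = FALSE]
  if (!nrow(per_gene)) {
    per_gene$frequency <- numeric(0)
    return(list(per_gene = per_gene, median = NA_real_))
  }
  per_gene$frequency <- per_gene$mutual_mutation_n / per_gene$mutual_gene_n
  per_gene <- per_gene[order(-per_gene$frequency, per_gene$gene), , drop = FALSE]
  rownames(per_gene) <- NULL
  list(per_gene = per_gene, median = stats::median(per_gene$frequency))
}
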