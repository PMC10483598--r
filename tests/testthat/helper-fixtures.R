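# shared fixture builders and independent oracles

alt_row <- function(patient_id, assay, gene, kind = "point_mutation",
                    locus = "", vaf = NA_real_, characterized = TRUE,
                    date = as.Date("2016-06-01")) {
  data.frame(patient_id = patient_id, assay = assay, gene = gene,
             kind = kind, locus = locus, vaf_percent = vaf,
             characterized = characterized, sample_date = date,
             stringsAsFactors = FALSE)
}

make_alts <- function(...) {
  alteration_table(do.call(rbind, list(...)))
}

# independent O(n^2) all-pairs concordance oracle: enumerates every
# (tissue, ctdna) alteration pair and classifies matches from first
# principles, without reusing profile_patient internals
brute_profile <- function(tissue, ctdna) {
  mutual <- character(0)
  mm <- character(0)
  for (i in seq_len(nrow(tissue))) {
    for (j in seq_len(nrow(ctdna))) {
      a <- tissue[i, ]; b <- ctdna[j, ]
      if (a$gene == b$gene) {
        mutual <- union(mutual, a$gene)
        snv <- c("point_mutation", "indel")
        same_locus <-
          (a$kind == "amplification" && b$kind == "amplification") ||
          (a$kind %in% snv && b$kind %in% snv &&
             nzchar(a$locus) && a$locus == b$locus)
        if (same_locus) mm <- union(mm, a$gene)
      }
    }
  }
  list(mutual_genes = sort(mutual), mutual_mutation_genes = sort(mm))
}

# random small paired-assay case for property tests
random_case <- function(genes = c("TP53", "KRAS", "EGFR", "PIK3CA", "MYC"),
                        loci = c("A1B", "C2D", "E3F", ""),
                        max_alts = 5L) {
  draw <- function(assay) {
    k <- sample(0:max_alts, 1)
    if (k == 0) return(alt_row("P1", assay, "TP53")[0, ])
    kind <- sample(c("point_mutation", "indel", "amplification", "fusion"),
                   k, replace = TRUE)
    locus <- ifelse(kind %in% c("point_mutation", "indel"),
                    sample(setdiff(loci, ""), k, replace = TRUE), "")
    alt_row("P1", assay, sample(genes, k, replace = TRUE), kind, locus)
  }
  list(tissue = alteration_table(draw("tissue")),
       ctdna = alteration_table(draw("ctdna")))
}

small_sim <- function(n = 300, seed = 1, ...) {
  p <- preset_paperlike(n_patients = n, seed = seed)
  over <- list(...)
  p[names(over)] <- over
  generate_cohort(p)
}
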