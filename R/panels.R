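#' Panel definitions and the comparable gene universe
#'
#' A ctDNA panel definition names the genes a liquid-biopsy panel version
#' sequenced, the subset reported for copy-number amplification, and the
#' half-open calendar interval \[effective_from, effective_to) in which that
#' version was in use. The tissue panel is a superset of the comparable
#' sets, so the comparable universe is the intersection of the tissue gene
#' list with the era-resolved ctDNA panel.
#'
#' @param name Panel version label.
#' @param genes Character vector of gene symbols.
#' @param amp_genes Subset of `genes` reportable as amplifications.
#' @param effective_from,effective_to Dates (coercible); inclusive start,
#'   exclusive end.
#' @return A `panel_definition` list.
#' @export
panel_definition <- function(name, genes, amp_genes,
                             effective_from, effective_to) {
  genes <- unique(normalize_gene_symbol(genes))
  amp_genes <- unique(normalize_gene_symbol(amp_genes))
  effective_from <- as.Date(effective_from)
  effective_to <- as.Date(effective_to)
  if (!all(amp_genes %in% genes)) {
    stop("amp_genes not a subset of genes: ",
         paste(setdiff(amp_genes, genes), collapse = ", "), call. = FALSE)
  }
  if (!isTRUE(effective_from < effective_to)) {
    stop("panel '", name, "': effective_from must precede effective_to",
         call. = FALSE)
  }
  structure(list(name = name, genes = genes, amp_genes = amp_genes,
                 effective_from = effective_from, effective_to = effective_to),
            class = "panel_definition")
}

#' Read panel definitions from a JSON config
#'
#' The file is an array of objects with fields `name`, `genes`,
#' `amp_genes`, `effective_from`, `effective_to`.
#'
#' @param path JSON file path.
#' @return List of `panel_definition` objects.
#' @export
read_panel_definitions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(raw)), function(i) {
    panel_definition(raw$name[i],
                     unlist(raw$genes[i]),
                     unlist(raw$amp_genes[i]),
                     raw$effective_from[i], raw$effective_to[i])
  })
}

#' Load the packaged two-era comparable gene lists
#'
#' Returns the two panel eras shipped with the package: a pre-2015-02 era
#' whose intersection with the tissue panel has 53 genes (3
#' amplification-eligible) and a later era with 55 genes (16
#' amplification-eligible). Gene membership beyond the 34 genes whose
#' cohort counts are packaged alongside is a synthetic stand-in
#' (cardinalities and amplification-eligible subsets follow the study
#' design; see the fixture file name).
#'
#' @return List of two `panel_definition` objects, earliest era first.
#' @export
load_packaged_panels <- function() {
  read_panel_definitions(system.file("extdata", "panels_synthetic.json",
                                     package = "ctconcord", mustWork = TRUE))
}

#' Resolve the comparable gene set for a sample date
#'
#' Picks the ctDNA panel era containing `sample_date` (the blood-draw
#' date; the panel version is a property of the liquid-biopsy test) and
#' intersects it with the tissue gene universe. Amplification-eligible
#' genes are the intersection of both assays' amplification lists; when
#' `tissue_amp_genes` is `NULL` the tissue assay is assumed to report
#' amplifications for every comparable gene, so the ctDNA amp list rules.
#'
#' @param sample_date Date (coercible).
#' @param panel_set List of `panel_definition`s with disjoint eras.
#' @param tissue_genes Character vector: the tissue assay's gene universe.
#' @param tissue_amp_genes Optional character vector of tissue
#'   amplification-eligible genes.
#' @return A `comparable_gene_set` list with `genes`, `amp_genes`, `era`.
#' @export
resolve_comparable_set <- function(sample_date, panel_set, tissue_genes,
                                   tissue_amp_genes = NULL) {
  sample_date <- as.Date(sample_date)
  stopifnot(length(sample_date) == 1L, !is.na(sample_date))
  hits <- vapply(panel_set, function(p) {
    sample_date >= p$effective_from && sample_date < p$effective_to
  }, logical(1))
  if (sum(hits) != 1L) {
    stop("sample date ", format(sample_date), " falls in ", sum(hits),
         " panel eras (need exactly 1); check panel configuration",
         call. = FALSE)
  }
  era <- panel_set[[which(hits)]]
  tissue_genes <- normalize_gene_symbol(tissue_genes)
  genes <- intersect(tissue_genes, era$genes)
  amp <- intersect(genes, era$amp_genes)
  if (!is.null(tissue_amp_genes)) {
    amp <- intersect(amp, normalize_gene_symbol(tissue_amp_genes))
  }
  structure(list(genes = sort(genes), amp_genes = sort(amp), era = era$name),
            class = "comparable_gene_set")
}

#' Restrict alterations to a comparable gene set
#'
#' Keeps an alteration iff its gene is in the comparable universe and, for
#' amplifications, the gene is amplification-eligible. Order is preserved;
#' the operation is idempotent and never grows the table.
#'
#' @param alterations An `alteration_table`.
#' @param cgs A `comparable_gene_set`.
#' @return The filtered `alteration_table`.
#' @export
restrict_alterations <- function(alterations, cgs) {
  stopifnot(inherits(cgs, "comparable_gene_set"))
  keep <- alterations$gene %in% cgs$genes &
    (alterations$kind != "amplification" |
       alterations$gene %in% cgs$amp_genes)
  alterations[keep, , drop = FALSE]
}

#' Keep characterized (pathogenic) alterations only
#'
#' Drops synonymous alterations and variants of unknown significance,
#' which are flagged `characterized = FALSE` upstream; concordance is
#' always computed on characterized alterations.
#'
#' @param alterations An `alteration_table`.
#' @return The filtered `alteration_table`.
#' @export
filter_characterized <- function(alterations) {
  alterations[alterations$characterized %in% TRUE, , drop = FALSE]
}

#' Harmonize a cohort's alteration tables
#'
#' Per patient, resolves the comparable gene set from the ctDNA sample
#' date and restricts both assays' alterations to it, then drops
#' uncharacterized variants. Patients without a resolvable ctDNA date use
#' `default_date`.
#'
#' @param alterations An `alteration_table` for the whole cohort (both
#'   assays).
#' @param panel_set List of `panel_definition`s (default: packaged eras).
#' @param default_date Fallback date when a patient has no ctDNA
#'   sample_date.
#' @return An `alteration_table` restricted and characterized-only.
#' @export
harmonize_cohort <- function(alterations, panel_set = load_packaged_panels(),
                             default_date = as.Date("2016-01-01")) {
  tissue_universe <- sort(unique(unlist(lapply(panel_set, `[[`, "genes"))))
  # one era date per patient (earliest ctDNA draw), then a vectorized
  # membership check against that era's comparable set
  pids <- unique(alterations$patient_id)
  isct <- alterations$assay == "ctdna" & !is.na(alterations$sample_date)
  era_date <- rep(default_date, length(pids))
  if (any(isct)) {
    mind <- tapply(alterations$sample_date[isct],
                   alterations$patient_id[isct], min)
    hit <- match(pids, names(mind))
    era_date[!is.na(hit)] <- as.Date(mind[hit[!is.na(hit)]],
                                     origin = "1970-01-01")
  }
  cgs_by_pid <- lapply(era_date, resolve_comparable_set, panel_set,
                       tissue_universe)
  # patients share one of a handful of eras; dedupe by era label
  era_lab <- vapply(cgs_by_pid, `[[`, character(1), "era")
  keep <- logical(nrow(alterations))
  for (lab in unique(era_lab)) {
    cgs <- cgs_by_pid[[match(lab, era_lab)]]
    rows <- alterations$patient_id %in% pids[era_lab == lab]
    keep[rows] <- alterations$gene[rows] %in% cgs$genes &
      (alterations$kind[rows] != "amplification" |
         alterations$gene[rows] %in% cgs$amp_genes) &
      alterations$characterized[rows] %in% TRUE
  }
  alterations[keep, , drop = FALSE]
}
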