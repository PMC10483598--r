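#' @keywords internal
"_PACKAGE"

ALTERATION_KINDS <- c("point_mutation", "indel", "amplification", "fusion", "other")
ALTERATION_COLS <- c("patient_id", "assay", "gene", "kind", "locus",
                     "vaf_percent", "characterized", "sample_date")

#' Normalize a raw gene symbol
#'
#' Trims whitespace, upper-cases, and passes the result through an optional
#' synonym map so that the two assays' reports use one symbol per gene.
#' Idempotent: applying it twice is the same as applying it once (synonym
#' maps are expected to map onto canonical symbols, not chains).
#'
#' @param raw Character vector of raw gene symbols.
#' @param synonym_map Named character vector mapping non-canonical symbols
#'   (after upper-casing) to canonical ones, e.g. `c(MLL2 = "KMT2D")`.
#'   Default empty.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_gene_symbol("tp53 ")                       # "TP53"
#' normalize_gene_symbol("MLL2", c(MLL2 = "KMT2D"))     # "KMT2D"
#' @export
normalize_gene_symbol <- function(raw, synonym_map = character()) {
  if (length(raw) == 0L) return(character())
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    bad <- which(is.na(raw) | !nzchar(trimws(raw)))
    stop("empty or missing gene symbol at record(s): ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  }
  sym <- toupper(trimws(raw))
  if (length(synonym_map)) {
    hit <- match(sym, toupper(names(synonym_map)))
    sym[!is.na(hit)] <- toupper(trimws(synonym_map[hit[!is.na(hit)]]))
  }
  sym
}

#' Normalize a locus (protein-change) descriptor
#'
#' Strips an optional leading "p." prefix, trims, and upper-cases so that
#' descriptors from the two assays compare by exact string equality.
#' Amplifications carry an empty locus.
#'
#' @param locus Character vector of locus descriptors (may contain `NA` /
#'   empty strings).
#' @return Normalized character vector; `NA` becomes `""`.
#' @export
normalize_locus <- function(locus) {
  locus[is.na(locus)] <- ""
  locus <- trimws(locus)
  locus <- sub("^[pP]\\.", "", locus)
  toupper(locus)
}

#' Construct / validate an alteration table
#'
#' The alteration table is the pipeline's central currency: one row per
#' called genomic aberration in one assay for one patient. Validation
#' enforces the schema invariants (known kind, empty locus for
#' amplifications, VAF in \[0, 100\]) and normalizes gene symbols and loci.
#'
#' @param df A data.frame with columns `patient_id`, `assay`
#'   ("tissue"/"ctdna"), `gene`, `kind` (one of point_mutation, indel,
#'   amplification, fusion, other), `locus`, `vaf_percent`,
#'   `characterized` (logical; FALSE marks VUS/synonymous), `sample_date`.
#'   Missing `vaf_percent` / `sample_date` columns are filled with `NA`.
#' @param synonym_map Passed to [normalize_gene_symbol()].
#' @return The validated, normalized data.frame (class `alteration_table`).
#' @export
alteration_table <- function(df, synonym_map = character()) {
  stopifnot(is.data.frame(df))
  if (!"vaf_percent" %in% names(df)) df$vaf_percent <- NA_real_
  if (!"sample_date" %in% names(df)) df$sample_date <- as.Date(NA)
  if (!"locus" %in% names(df)) df$locus <- ""
  miss <- setdiff(ALTERATION_COLS, names(df))
  if (length(miss)) {
    stop("alteration table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- df[, ALTERATION_COLS]
  errs <- character()
  bad_assay <- which(!df$assay %in% c("tissue", "ctdna"))
  if (length(bad_assay)) {
    errs <- c(errs, paste0("row ", bad_assay, ": unknown assay '",
                           df$assay[bad_assay], "'"))
  }
  bad_kind <- which(!df$kind %in% ALTERATION_KINDS)
  if (length(bad_kind)) {
    errs <- c(errs, paste0("row ", bad_kind, ": unknown kind '",
                           df$kind[bad_kind], "'"))
  }
  vaf <- suppressWarnings(as.numeric(df$vaf_percent))
  bad_vaf <- which(!is.na(vaf) & (vaf < 0 | vaf > 100))
  if (length(bad_vaf)) {
    errs <- c(errs, paste0("row ", bad_vaf, ": vaf_percent out of [0,100]: ",
                           vaf[bad_vaf]))
  }
  gene_missing <- which(is.na(df$gene) | !nzchar(trimws(as.character(df$gene))))
  if (length(gene_missing)) {
    errs <- c(errs, paste0("row ", gene_missing, ": missing gene symbol"))
  }
  if (length(errs)) {
    stop("invalid alteration table (", length(errs), " error(s)):\n  ",
         paste(utils::head(errs, 20L), collapse = "\n  "), call. = FALSE)
  }
  df$gene <- normalize_gene_symbol(as.character(df$gene), synonym_map)
  df$locus <- normalize_locus(as.character(df$locus))
  df$locus[df$kind == "amplification"] <- ""
  df$vaf_percent <- vaf
  df$characterized <- as.logical(df$characterized)
  df$sample_date <- as.Date(df$sample_date)
  class(df) <- c("alteration_table", "data.frame")
  df
}

#' Read an alteration table from delimited text
#'
#' Expects a header with the canonical columns (see [alteration_table()]).
#' A `schema_adapter` may rename/derive columns from other layouts before
#' validation; it receives and returns a data.frame.
#'
#' @param path Path to a tab- or comma-separated file.
#' @param schema_adapter Optional function applied to the raw data.frame.
#' @param sep Field separator; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @param synonym_map Passed to [alteration_table()].
#' @return An `alteration_table` data.frame.
#' @export
read_alteration_table <- function(path, schema_adapter = NULL, sep = NULL,
                                  synonym_map = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", colClasses = "character")
  if (!is.null(schema_adapter)) raw <- schema_adapter(raw)
  if (nrow(raw)) {
    raw$characterized <- tolower(raw$characterized) %in% c("true", "t", "1", "yes")
  } else {
    raw$characterized <- logical(0)
  }
  alteration_table(raw, synonym_map = synonym_map)
}

#' Write an alteration table as tab-separated text
#'
#' Inverse of [read_alteration_table()] on valid tables (round-trip safe).
#'
#' @param alts An `alteration_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alteration_table <- function(alts, path) {
  out <- as.data.frame(alts)
  out$vaf_percent <- format_num(out$vaf_percent)
  out$sample_date <- as.character(out$sample_date)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# 6-significant-digit formatting for diff-stable text outputs
format_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 6, format = "g"))
}
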