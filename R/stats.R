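#' Pearson correlation between two cohort-frame fields
#'
#' Pairwise deletion: records missing either field are dropped (and
#' reported via the `dropped` element).
#'
#' @param frame Cohort data.frame.
#' @param x,y Column names.
#' @return List with `r`, `p`, `n`, `dropped` (patient_ids removed).
#' @export
correlate <- function(frame, x, y) {
  xs <- frame[[x]]; ys <- frame[[y]]
  stopifnot(!is.null(xs), !is.null(ys))
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ", x, " vs ", y,
                         call. = FALSE)
  if (stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0) {
    stop("zero variance in '", if (stats::sd(xs[ok]) == 0) x else y,
         "': correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(xs[ok], ys[ok], method = "pearson")
  dropped <- if ("patient_id" %in% names(frame)) {
    frame$patient_id[!ok]
  } else which(!ok)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok), dropped = dropped)
}

#' Bin a non-negative count into categories
#'
#' Default bins are 0, 1, 2, and 3+ — the categorization used when a
#' mutual-alteration count enters a chi-square contingency table.
#'
#' @param x Integer vector of counts.
#' @param breaks Increasing non-negative integers; the last bin is
#'   open-ended.
#' @return Factor with levels like "0", "1", "2", ">=3".
#' @export
bin_counts <- function(x, breaks = c(0L, 1L, 2L, 3L)) {
  stopifnot(all(diff(breaks) > 0), all(breaks >= 0))
  labs <- c(as.character(breaks[-length(breaks)]),
            paste0(">=", breaks[length(breaks)]))
  cut(x, breaks = c(breaks, Inf), right = FALSE, labels = labs)
}

#' Chi-square test with standardized residuals
#'
#' Cross-tabulates two categorical fields (numeric count fields are first
#' binned with [bin_counts()]), runs a chi-square test of independence
#' without continuity correction, and returns the Pearson standardized
#' residuals (observed - expected)/sqrt(expected) per cell — the
#' quantities drawn in balloon plots.
#'
#' @param frame Cohort data.frame.
#' @param row_factor,col_factor Column names.
#' @param bin_breaks Passed to [bin_counts()] for numeric fields.
#' @return List with `table`, `statistic`, `df`, `p`, `residuals`.
#' @export
chisq_residual_table <- function(frame, row_factor, col_factor,
                                 bin_breaks = c(0L, 1L, 2L, 3L)) {
  get_factor <- function(col) {
    v <- frame[[col]]
    stopifnot(!is.null(v))
    if (is.numeric(v)) bin_counts(v, bin_breaks) else factor(v)
  }
  rf <- get_factor(row_factor); cf <- get_factor(col_factor)
  ok <- !is.na(rf) & !is.na(cf)
  tab <- table(droplevels(rf[ok]), droplevels(cf[ok]))
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp == 0)) {
    bad <- which(exp == 0, arr.ind = TRUE)[1, ]
    stop("expected count 0 in cell (", rownames(tab)[bad[1]], ", ",
         colnames(tab)[bad[2]], ")", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, statistic = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value,
       residuals = ht$residuals)
}

#' Kruskal-Wallis comparison of a value across groups
#'
#' @param frame Cohort data.frame.
#' @param value Numeric column name.
#' @param group Grouping column name (e.g. the N_N/Y_N/Y_Y status).
#' @return List with `statistic`, `df`, `p`, `group_n`.
#' @export
group_compare <- function(frame, value, group) {
  v <- frame[[value]]; g <- factor(frame[[group]])
  stopifnot(!is.null(v), !is.null(g))
  ok <- !is.na(v) & !is.na(g)
  g <- droplevels(g[ok]); v <- v[ok]
  cnt <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  if (any(cnt == 0)) {
    stop("group with zero observations: ",
         paste(names(cnt)[cnt == 0], collapse = ", "), call. = FALSE)
  }
  ht <- stats::kruskal.test(v, g)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, group_n = as.integer(cnt))
}

#' Human-readable p-value, floored at the double-precision limit
#' @param p Numeric p-value.
#' @return Character: "< 2.2e-16" for values below the floor, otherwise a
#'   compact scientific representation.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 2.2e-16, "< 2.2e-16", formatC(p, digits = 3, format = "g"))
}
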