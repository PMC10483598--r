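#' The fixed multivariable covariate set
#'
#' The prognostic models adjust the concordance term for age at
#' diagnosis, sex, cancer-type group, the signed months between tissue
#' biopsy and blood draw, maximum percent ctDNA, the per-assay distinct
#' altered gene counts, and tumor mutational burden. Continuous covariates
#' enter untransformed; `tumor_type` and `sex` are categorical with the
#' most frequent level as reference.
#'
#' @return Character vector of covariate column names (the concordance
#'   term under test is appended by the caller).
#' @export
default_covariates <- function() {
  c("age_dx", "sex", "tumor_type", "gap_months", "pct_ctdna",
    "tissue_gene_count", "ctdna_gene_count", "tmb")
}

prepare_survival_data <- function(records, covariates) {
  need <- unique(c("os_months", "death", covariates))
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- records[stats::complete.cases(records[, need, drop = FALSE]), ,
               drop = FALSE]
  if (!nrow(d)) stop("no complete records for the requested model",
                     call. = FALSE)
  if (any(d$os_months <= 0)) stop("non-positive survival time in data",
                                  call. = FALSE)
  for (cv in covariates) {
    v <- d[[cv]]
    if (is.character(v) || is.factor(v)) {
      # reference level = most frequent category
      tab <- sort(table(v), decreasing = TRUE)
      d[[cv]] <- stats::relevel(factor(v), ref = names(tab)[1])
    } else if (length(unique(v)) < 2L) {
      stop("covariate '", cv, "' has zero variance", call. = FALSE)
    }
  }
  d
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron ties) of overall survival from diagnosis
#' on the given covariates, via [survival::coxph()]. Death is the event;
#' patients alive at last follow-up are censored.
#'
#' @param records Cohort data.frame with `os_months` (> 0), `death`
#'   (logical) and the covariate columns.
#' @param covariates Ordered character vector of covariate names.
#' @return A `cox_result`: data.frame `terms` (term, hazard_ratio,
#'   ci_low, ci_high, p), plus `loglik`, `n`, `n_events`, `covariates`,
#'   `reference_levels`, p-values of the global likelihood-ratio, Wald and
#'   score tests, and the underlying `fit`.
#' @export
cox_fit <- function(records, covariates) {
  d <- prepare_survival_data(records, covariates)
  if (!any(d$death)) stop("no events (deaths) in data", call. = FALSE)
  fml <- stats::as.formula(paste("survival::Surv(os_months, death) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron")
  if (!is.null(fit$info) && grepl("did not converge", paste(fit$info))) {
    stop("Cox fit did not converge", call. = FALSE)
  }
  s <- summary(fit)
  terms <- data.frame(term = rownames(s$coefficients),
                      coef = s$coefficients[, "coef"],
                      hazard_ratio = s$coefficients[, "exp(coef)"],
                      ci_low = s$conf.int[, "lower .95"],
                      ci_high = s$conf.int[, "upper .95"],
                      p = s$coefficients[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  refs <- lapply(d[covariates], function(v) if (is.factor(v)) levels(v)[1])
  structure(list(terms = terms,
                 loglik = fit$loglik[2],
                 n = s$n, n_events = s$nevent,
                 covariates = covariates,
                 reference_levels = Filter(Negate(is.null), refs),
                 lr_p = unname(s$logtest["pvalue"]),
                 wald_p = unname(s$waldtest["pvalue"]),
                 score_p = unname(s$sctest["pvalue"]),
                 fit = fit),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("<cox_result> n=%d events=%d loglik=%.2f LR p=%s\n",
              x$n, x$n_events, x$loglik, format_pvalue(x$lr_p)))
  t <- x$terms
  t$hazard_ratio <- round(t$hazard_ratio, 3)
  t$ci_low <- round(t$ci_low, 3); t$ci_high <- round(t$ci_high, 3)
  t$p <- format_pvalue(t$p)
  print(t[, c("term", "hazard_ratio", "ci_low", "ci_high", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Extract one covariate's row from a cox_result
#'
#' Matches by prefix so categorical terms ("statusY_Y") are found from the
#' covariate name.
#' @param result A `cox_result`.
#' @param term Covariate name (or full term label).
#' @return One-row data.frame from `result$terms`.
#' @export
cox_term <- function(result, term) {
  t <- result$terms
  hit <- t[t$term == term, , drop = FALSE]
  if (!nrow(hit)) hit <- t[startsWith(t$term, term), , drop = FALSE]
  if (!nrow(hit)) stop("term '", term, "' not in model", call. = FALSE)
  hit
}

#' Kaplan-Meier curves with a univariate Cox comparison
#'
#' Product-limit survival estimates per group plus a single-covariate
#' proportional-hazards comparison across groups. The likelihood-ratio p
#' is the headline; score (equivalent to the log-rank test for untied
#' data) and Wald p-values are also reported.
#'
#' @param records Cohort data.frame with `os_months`, `death`, and the
#'   grouping field.
#' @param group_field Column name; numeric fields are treated as
#'   continuous in the Cox comparison and as discrete levels for the
#'   curves.
#' @return List with `curves` (a [survival::survfit] object), `p`
#'   (likelihood ratio), `score_p`, `wald_p`, `n`, `n_events`. With zero
#'   events the comparison p-values are `NA` and `all_censored = TRUE`.
#' @export
km_logrank <- function(records, group_field) {
  need <- c("os_months", "death", group_field)
  d <- records[stats::complete.cases(records[, need, drop = FALSE]), ,
               drop = FALSE]
  grp <- d[[group_field]]
  sf <- survival::survfit(survival::Surv(os_months, death) ~ g,
                          data = data.frame(os_months = d$os_months,
                                            death = d$death, g = factor(grp)))
  if (!any(d$death)) {
    return(list(curves = sf, p = NA_real_, score_p = NA_real_,
                wald_p = NA_real_, n = nrow(d), n_events = 0L,
                all_censored = TRUE))
  }
  cv <- if (is.numeric(grp)) grp else factor(grp)
  if (length(unique(cv)) < 2L) {
    return(list(curves = sf, p = NA_real_, score_p = NA_real_,
                wald_p = NA_real_, n = nrow(d), n_events = sum(d$death),
                all_censored = FALSE, single_group = TRUE))
  }
  fit <- survival::coxph(survival::Surv(d$os_months, d$death) ~ cv,
                         ties = "efron")
  s <- summary(fit)
  list(curves = sf, p = unname(s$logtest["pvalue"]),
       score_p = unname(s$sctest["pvalue"]),
       wald_p = unname(s$waldtest["pvalue"]),
       n = nrow(d), n_events = sum(d$death), all_censored = FALSE)
}

#' Threshold (cutoff) analysis of a concordance count
#'
#' Replaces the count by the indicator \[count >= k\] and refits the full
#' multivariable model, testing e.g. ">=2 mutual genes vs 0-1".
#'
#' @param records Cohort data.frame.
#' @param count_field Column holding the count.
#' @param k Cutoff (>= 1).
#' @param covariates Adjustment covariates (default [default_covariates()]).
#' @return A `cox_result`; the indicator term is named
#'   `<count_field>_ge<k>`.
#' @export
threshold_analysis <- function(records, count_field, k,
                               covariates = default_covariates()) {
  stopifnot(k >= 1L)
  ind <- as.integer(records[[count_field]] >= k)
  if (length(unique(ind[!is.na(ind)])) < 2L) {
    stop("indicator [", count_field, " >= ", k, "] is constant", call. = FALSE)
  }
  term <- paste0(count_field, "_ge", k)
  records[[term]] <- ind
  cox_fit(records, c(setdiff(covariates, count_field), term))
}

#' Time-gap sensitivity analysis
#'
#' Refits the full multivariable model on the subset of patients whose
#' absolute tissue-to-blood gap is at most each threshold, and reports the
#' concordance term's hazard ratio and p at each threshold. `Inf`
#' reproduces the unfiltered model.
#'
#' @param records Cohort data.frame with `gap_months`.
#' @param max_gap_months Numeric vector of thresholds in months.
#' @param target Concordance covariate under test (default
#'   `"mutual_gene_count"`).
#' @param covariates Adjustment covariates; `target` is appended.
#' @return data.frame: `max_gap_months`, `n`, `n_events`, `hazard_ratio`,
#'   `p`, `low_events` (flag: fewer than 5 events per covariate).
#' @export
gap_sensitivity <- function(records, max_gap_months,
                            target = "mutual_gene_count",
                            covariates = default_covariates()) {
  stopifnot(all(max_gap_months > 0))
  covs <- c(setdiff(covariates, target), target)
  rows <- lapply(max_gap_months, function(th) {
    keep <- !is.na(records$gap_months) & abs(records$gap_months) <= th
    sub <- records[keep, , drop = FALSE]
    res <- cox_fit(sub, covs)
    tr <- cox_term(res, target)
    data.frame(max_gap_months = th, n = res$n, n_events = res$n_events,
               hazard_ratio = tr$hazard_ratio[1], p = tr$p[1],
               low_events = res$n_events < 5 * length(covs))
  })
  do.call(rbind, rows)
}

#' Leave-one-covariate-out sensitivity scan
#'
#' For each adjustment covariate, refits the multivariable model without
#' it and reports the target term's hazard ratio and p, flagging
#' omissions that move the target across the 0.05 significance line.
#'
#' @param records Cohort data.frame.
#' @param target Covariate whose effect is under scrutiny.
#' @param covariates Adjustment covariates; `target` is appended.
#' @return data.frame: `omitted` ("(none)" row first = full model),
#'   `hazard_ratio`, `p`, `significant`, `changes_significance`, `error`.
#' @export
covariate_omission_scan <- function(records, target,
                                    covariates = default_covariates()) {
  covs <- setdiff(covariates, target)
  full <- cox_fit(records, c(covs, target))
  full_term <- cox_term(full, target)
  full_sig <- full_term$p[1] < 0.05
  rows <- list(data.frame(omitted = "(none)",
                          hazard_ratio = full_term$hazard_ratio[1],
                          p = full_term$p[1], significant = full_sig,
                          changes_significance = FALSE, error = NA_character_))
  for (cv in covs) {
    row <- tryCatch({
      res <- cox_fit(records, c(setdiff(covs, cv), target))
      tr <- cox_term(res, target)
      sig <- tr$p[1] < 0.05
      data.frame(omitted = cv, hazard_ratio = tr$hazard_ratio[1], p = tr$p[1],
                 significant = sig, changes_significance = sig != full_sig,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(omitted = cv, hazard_ratio = NA_real_, p = NA_real_,
                 significant = NA, changes_significance = NA,
                 error = conditionMessage(e))
    })
    rows <- c(rows, list(row))
  }
  do.call(rbind, rows)
}

#' Forest-plot-ready table from a cox_result
#' @param result A `cox_result`.
#' @return data.frame with term, hazard_ratio, ci_low, ci_high, p, n,
#'   n_events.
#' @export
forest_table <- function(result) {
  cbind(result$terms[, c("term", "hazard_ratio", "ci_low", "ci_high", "p")],
        n = result$n, n_events = result$n_events)
}
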