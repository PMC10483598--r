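surv_frame <- function(n, seed = 1) {
  # two-group exponential survival with known rate ratio 2
  set.seed(seed)
  grp <- rep(0:1, each = n / 2)
  data.frame(patient_id = paste0("P", seq_len(n)),
             os_months = stats::rexp(n, rate = 0.05 * 2^grp),
             death = TRUE, grp = grp,
             age = stats::rnorm(n, 60, 10))
}

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  d <- data.frame(os_months = 1:6,
                  death = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
                  g = "all")
  km <- km_logrank(d, "g")
  s <- summary(km$curves)
  # product limits: 5/6 at t=1; 5/6 * 3/4 at t=3; * 2/3 at t=4
  expect_equal(s$time, c(1, 3, 4))
  expect_equal(s$surv, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3),
               tolerance = 1e-12)
  # curves are non-increasing and start at 1
  expect_true(all(diff(km$curves$surv) <= 0))
  expect_lte(max(km$curves$surv), 1)
})

test_that("all-censored input yields unit curves and a flagged comparison", {
  d <- data.frame(os_months = c(3, 6, 9, 12), death = FALSE,
                  g = c("a", "a", "b", "b"))
  km <- km_logrank(d, "g")
  expect_true(km$all_censored)
  expect_true(is.na(km$p))
  expect_true(all(km$curves$surv == 1))
})

test_that("cox_fit recovers a known exponential rate ratio and reports three global tests", {
  d <- surv_frame(2000, seed = 99)
  res <- cox_fit(d, "grp")
  hr <- cox_term(res, "grp")$hazard_ratio
  expect_gt(hr, 1.75); expect_lt(hr, 2.25)
  expect_true(cox_term(res, "grp")$ci_low <= hr && hr <= cox_term(res, "grp")$ci_high)
  expect_true(all(c(res$lr_p, res$wald_p, res$score_p) < 1e-10))
  # time-scale invariance of the partial likelihood
  d2 <- d; d2$os_months <- d2$os_months * 2
  res2 <- cox_fit(d2, "grp")
  expect_equal(cox_term(res2, "grp")$hazard_ratio, hr, tolerance = 1e-8)
  expect_equal(cox_term(res2, "grp")$p, cox_term(res, "grp")$p,
               tolerance = 1e-8)
  # degenerate covariate is a precondition error
  d$zero <- 0
  expect_error(cox_fit(d, "zero"), "zero variance")
})

test_that("threshold at k=1 equals the raw-count fit when counts are binary", {
  d <- surv_frame(400, seed = 5)
  d$mutual <- d$grp                    # counts in {0, 1}
  raw <- cox_fit(d, c("age", "mutual"))
  thr <- threshold_analysis(d, "mutual", 1L, covariates = c("age", "mutual"))
  expect_equal(cox_term(thr, "mutual_ge1")$hazard_ratio,
               cox_term(raw, "mutual")$hazard_ratio, tolerance = 1e-10)
  expect_equal(cox_term(thr, "mutual_ge1")$p, cox_term(raw, "mutual")$p,
               tolerance = 1e-10)
  expect_error(threshold_analysis(d, "mutual", 5L,
                                  covariates = c("age", "mutual")),
               "constant")
})

test_that("gap filtering reproduces the unfiltered model at an infinite threshold", {
  co <- small_sim(n = 400, seed = 13)
  frame <- build_cohort_frame(harmonize_cohort(co$alterations), co$clinical)
  full <- cox_fit(frame, c(default_covariates(), "mutual_gene_count"))
  gs <- gap_sensitivity(frame, c(Inf, 6))
  expect_equal(gs$p[1], cox_term(full, "mutual_gene_count")$p,
               tolerance = 1e-10)
  expect_lt(gs$n[2], gs$n[1])
})

test_that("omitting an independent covariate leaves the target essentially unchanged", {
  co <- small_sim(n = 500, seed = 17)
  frame <- build_cohort_frame(harmonize_cohort(co$alterations), co$clinical)
  set.seed(1); frame$noise <- stats::rnorm(nrow(frame))
  scan <- covariate_omission_scan(frame, "mutual_gene_count",
                                  covariates = c(default_covariates(), "noise"))
  full_p <- scan$p[scan$omitted == "(none)"]
  noise_p <- scan$p[scan$omitted == "noise"]
  expect_lt(abs(noise_p - full_p), 0.05)
  expect_equal(scan$omitted[1], "(none)")
  expect_true(all(is.na(scan$error)))
})
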