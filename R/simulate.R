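#' Load the packaged cohort gene-frequency table
#'
#' Per-gene counts of tumors with tissue alterations, ctDNA alterations,
#' gene-level concordance and locus-level concordance in the 433-patient
#' reference cohort. Used both as a published summary to compare against
#' and as the prevalence seed of the synthetic-cohort generator.
#'
#' @return data.frame with `gene`, `tissue_n`, `ctdna_n`,
#'   `mutual_gene_n`, `mutual_mutation_n`.
#' @export
load_gene_concordance_table <- function() {
  utils::read.table(system.file("extdata", "table1_gene_concordance.tsv",
                                package = "ctconcord", mustWork = TRUE),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Load the packaged per-gene hotspot locus lists (synthetic stand-in)
#' @return Named list: gene -> character vector of protein-change loci.
#' @export
load_hotspots <- function() {
  h <- utils::read.table(system.file("extdata", "hotspots_synthetic.tsv",
                                     package = "ctconcord", mustWork = TRUE),
                         header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(strsplit(h$loci, ",", fixed = TRUE), h$gene)
}

REFERENCE_COHORT_N <- 433L

#' Simulation parameters for the paired-assay cohort generator
#'
#' See `vignette("ctconcord-methods")` for the generative model. All
#' probabilities must be in \[0, 1\] and all rates non-negative; the seed
#' fully determines the output.
#'
#' @param n_patients Cohort size.
#' @param tumor_type_probs Named probability vector over type groups.
#' @param gene_prev Named base per-gene alteration prevalence
#'   (tumor-level, tissue assay).
#' @param type_prev_mult Named per-type multiplier on `gene_prev`.
#' @param extra_alteration_rate Poisson mean of additional alterations in
#'   an altered gene (so alterations per altered gene = 1 + Pois).
#' @param amp_prob Probability an alteration in an amplification-eligible
#'   gene is an amplification (tissue assay).
#' @param shed_shape Gamma shape of the latent per-patient shedding
#'   factor s (scale set so the reference type has E\[s\] = 1).
#' @param type_shed_mult Named per-type multiplier on the shedding scale.
#' @param detect_a,detect_b Detection probability of each tissue
#'   alteration in blood = plogis(detect_a + detect_b * log s).
#' @param gap_decay Clonal-drift term: the detection logit loses
#'   `gap_decay * |gap_months|` (default 0 = off).
#' @param blood_private_rate Poisson mean of ctDNA-only (blood-private)
#'   alterations per patient.
#' @param private_amp_prob Probability a blood-private alteration in an
#'   amp-eligible gene is an amplification.
#' @param locus_identity Named per-gene probability q_g that a detected
#'   point mutation is locus-identical; `locus_identity_default` fills
#'   genes not named.
#' @param locus_identity_default Scalar fallback q.
#' @param vaf_shape1,vaf_shape2 Beta parameters of the VAF draw;
#'   pct_ctdna = 100 * min(1, s * Beta).
#' @param beta_mutual,beta_age,beta_pct Log-hazard coefficients of the
#'   true mutual gene count, age at diagnosis (years, centered at 58.6)
#'   and percent ctDNA.
#' @param type_effects Named log-hazard offsets per tumor type.
#' @param weibull_shape,weibull_scale Baseline Weibull survival (months).
#' @param censor_min,censor_max Independent uniform censoring window
#'   (months).
#' @param amp_genes Amplification-eligible genes; `NULL` (default)
#'   resolves eligibility per patient from the packaged panel eras by
#'   blood-draw date.
#' @param seed Integer RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_patients = 433L,
                       tumor_type_probs = c(gastrointestinal = 0.28,
                                            breast_gyn = 0.20, lung = 0.14,
                                            head_neck = 0.07, brain = 0.05,
                                            hepatopancreatobiliary = 0.08,
                                            other = 0.18),
                       gene_prev = NULL,
                       type_prev_mult = c(gastrointestinal = 1.15,
                                          breast_gyn = 1.05, lung = 1.00,
                                          head_neck = 0.95, brain = 0.85,
                                          hepatopancreatobiliary = 1.10,
                                          other = 0.95),
                       extra_alteration_rate = NULL,
                       amp_prob = 0.34,
                       shed_shape = 0.8,
                       type_shed_mult = c(gastrointestinal = 1.2,
                                          breast_gyn = 1.1, lung = 1.0,
                                          head_neck = 0.9, brain = 0.3,
                                          hepatopancreatobiliary = 1.2,
                                          other = 0.9),
                       detect_a = 0, detect_b = 1, gap_decay = 0,
                       blood_private_rate = 0.9,
                       private_amp_prob = 0.45,
                       locus_identity = NULL,
                       locus_identity_default = 0.63,
                       vaf_shape1 = 0.3, vaf_shape2 = 15,
                       beta_mutual = log(1.25), beta_age = 0.02,
                       beta_pct = 0.015,
                       type_effects = c(gastrointestinal = 0,
                                        breast_gyn = -0.1, lung = 0.2,
                                        head_neck = 0, brain = 0.4,
                                        hepatopancreatobiliary = 0.5,
                                        other = 0.1),
                       weibull_shape = 1.1, weibull_scale = 28,
                       censor_min = 6, censor_max = 120,
                       amp_genes = NULL,
                       seed = 20230325L) {
  tbl <- load_gene_concordance_table()
  if (is.null(gene_prev)) {
    gene_prev <- stats::setNames(tbl$tissue_n / REFERENCE_COHORT_N, tbl$gene)
  }
  if (is.null(locus_identity)) {
    # observed locus-identity fraction, where the cohort table has enough
    # concordant tumors to estimate it
    est <- tbl[tbl$mutual_gene_n >= 5L, ]
    locus_identity <- stats::setNames(est$mutual_mutation_n / est$mutual_gene_n,
                                      est$gene)
  }
  # NULL amp_genes = resolve amplification eligibility per patient from
  # the packaged panel eras (by blood-draw date)
  if (is.null(extra_alteration_rate)) {
    # calibrate alteration multiplicity so the expected number of tissue
    # alterations per patient matches the 1.97 cohort target
    e_distinct <- sum(outer(unname(type_prev_mult[names(tumor_type_probs)]),
                            gene_prev, function(m, p) pmin(0.95, m * p)) %*%
                        rep(1, length(gene_prev)) * tumor_type_probs)
    extra_alteration_rate <- max(0, 1.97 / e_distinct - 1)
  }
  p <- list(n_patients = as.integer(n_patients),
            tumor_type_probs = tumor_type_probs, gene_prev = gene_prev,
            type_prev_mult = type_prev_mult,
            extra_alteration_rate = extra_alteration_rate,
            amp_prob = amp_prob, shed_shape = shed_shape,
            type_shed_mult = type_shed_mult, detect_a = detect_a,
            detect_b = detect_b, gap_decay = gap_decay,
            blood_private_rate = blood_private_rate,
            private_amp_prob = private_amp_prob,
            locus_identity = locus_identity,
            locus_identity_default = locus_identity_default,
            vaf_shape1 = vaf_shape1, vaf_shape2 = vaf_shape2,
            beta_mutual = beta_mutual, beta_age = beta_age,
            beta_pct = beta_pct, type_effects = type_effects,
            weibull_shape = weibull_shape, weibull_scale = weibull_scale,
            censor_min = censor_min, censor_max = censor_max,
            amp_genes = amp_genes, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  probs <- c(p$tumor_type_probs, p$gene_prev, p$amp_prob,
             p$private_amp_prob, p$locus_identity, p$locus_identity_default)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]",
                                       call. = FALSE)
  if (abs(sum(p$tumor_type_probs) - 1) > 1e-8) {
    stop("tumor_type_probs must sum to 1", call. = FALSE)
  }
  rates <- c(p$extra_alteration_rate, p$blood_private_rate, p$shed_shape,
             p$weibull_shape, p$weibull_scale)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  if (all(p$gene_prev == 0)) {
    stop("gene prevalence is identically zero: no alterations can be drawn",
         call. = FALSE)
  }
  need <- names(p$tumor_type_probs)
  for (fld in c("type_prev_mult", "type_shed_mult", "type_effects")) {
    if (!all(need %in% names(p[[fld]]))) {
      stop(fld, " must name every tumor type", call. = FALSE)
    }
  }
  invisible(p)
}

#' Calibrated "reference-cohort-like" simulation preset
#'
#' A parameter set calibrated (once, by long-run simulation; see the
#' methods vignette) so that in expectation: tissue alterations/patient
#' is about 1.97, ctDNA alterations/patient about 1.57, the mean mutual
#' gene count about 0.67, the fraction of patients with at least one
#' mutual gene about 0.425, and the median per-gene locus-identity
#' probability about 0.63.
#'
#' @param n_patients Cohort size (default: the reference cohort's 433).
#' @param seed RNG seed.
#' @param ... Overrides passed to [sim_params()].
#' @return A `sim_params` list.
#' @export
preset_paperlike <- function(n_patients = 433L, seed = 20230325L, ...) {
  sim_params(n_patients = n_patients, seed = seed,
             detect_a = CALIB_DETECT_A, detect_b = 1,
             shed_shape = CALIB_SHED_SHAPE,
             blood_private_rate = CALIB_PRIVATE_RATE, ...)
}

# Frozen calibration constants: chosen once by long-run Monte Carlo
# (n = 80k) against the cohort summary targets, before any test was run.
CALIB_DETECT_A <- 0.20
CALIB_SHED_SHAPE <- 0.45
CALIB_PRIVATE_RATE <- 0.85

#' Generate a synthetic paired-assay cohort
#'
#' Draws tumor types, per-gene tissue alterations, a latent per-patient
#' ctDNA shedding factor, probabilistic detection of each tissue
#' alteration in blood (locus-identical with per-gene probability q_g,
#' otherwise at a different hotspot of the same gene), blood-private
#' ctDNA alterations, VAFs, clinical covariates, and overall survival
#' from a Weibull proportional-hazards model whose log hazard is linear
#' in the TRUE mutual gene count, age, percent ctDNA and tumor type.
#' Deterministic given `params$seed`.
#'
#' @param params A `sim_params` list.
#' @return A list of class `synthetic_cohort`: `alterations`
#'   (`alteration_table`, both assays), `clinical` (per-patient frame with
#'   survival fields), and `truth` (latent shedding factor, true mutual
#'   counts, linear predictor — never consumed by the pipeline under
#'   test).
#' @export
generate_cohort <- function(params) {
  validate_sim_params(params)
  set.seed(params$seed)
  n <- params$n_patients
  genes <- names(params$gene_prev)
  hot <- load_hotspots()
  pid <- sprintf("P%05d", seq_len(n))

  types <- sample(names(params$tumor_type_probs), n, replace = TRUE,
                  prob = params$tumor_type_probs)
  age <- pmin(90.5, pmax(2.2, stats::rnorm(n, 58.6, 14)))
  sex <- ifelse(stats::runif(n) < 0.55, "F", "M")
  tmb <- stats::rlnorm(n, log(4), 0.8)
  gap <- stats::rlnorm(n, log(4.7), 1.0) - 1          # months, median ~3.7
  blood_date <- as.Date("2014-06-01") + floor(stats::runif(n, 0, 1218))
  tissue_date <- blood_date - round(gap * 30.44)
  s <- stats::rgamma(n, shape = params$shed_shape,
                     scale = params$type_shed_mult[types] / params$shed_shape)
  d_det <- stats::plogis(params$detect_a + params$detect_b * log(pmax(s, 1e-12)) -
                           params$gap_decay * abs(gap))

  # tissue gene presence: (patient, gene) pairs
  prev <- outer(unname(params$type_prev_mult[types]), params$gene_prev,
                function(m, p) pmin(0.95, m * p))
  pres <- which(matrix(stats::runif(n * length(genes)), n) < prev,
                arr.ind = TRUE)
  pi <- pres[, 1]; gi <- pres[, 2]
  npair <- length(pi)
  q_g <- params$locus_identity[genes]
  q_g[is.na(q_g)] <- params$locus_identity_default
  names(q_g) <- genes

  # tissue alterations per altered gene: 1 + Poisson extras; at most one
  # amplification per (patient, gene)
  n_alt <- 1L + stats::rpois(npair, params$extra_alteration_rate)
  # amplification eligibility: fixed list, or era-resolved per patient
  # (by blood-draw date) so simulated reports respect panel versions
  if (is.null(params$amp_genes)) {
    panels <- load_packaged_panels()
    era2 <- blood_date >= panels[[2]]$effective_from
    amp_ok <- function(p_idx, g_sym) {
      ifelse(era2[p_idx], g_sym %in% panels[[2]]$amp_genes,
             g_sym %in% panels[[1]]$amp_genes)
    }
  } else {
    amp_ok <- function(p_idx, g_sym) g_sym %in% params$amp_genes
  }
  eligible <- amp_ok(pi, genes[gi])
  has_amp <- eligible & stats::runif(npair) < params$amp_prob
  n_pm <- pmax(0L, n_alt - as.integer(has_amp))

  t_pid <- character(0); t_gene <- character(0); t_kind <- character(0)
  t_locus <- character(0)
  pm_loci <- vector("list", npair)
  for (j in seq_len(npair)) {
    g <- genes[gi[j]]
    if (n_pm[j] > 0L) {
      pool <- hot[[g]]
      if (is.null(pool)) pool <- paste0("X", 100 + seq_len(8), "Y")
      k <- min(n_pm[j], length(pool))
      pm_loci[[j]] <- sample(pool, k)
    } else pm_loci[[j]] <- character(0)
  }
  n_pm_eff <- lengths(pm_loci)
  rep_amp <- which(has_amp)
  t_pid <- c(pid[pi[rep_amp]], rep(pid[pi], n_pm_eff))
  t_gene <- c(genes[gi[rep_amp]], rep(genes[gi], n_pm_eff))
  t_kind <- c(rep("amplification", length(rep_amp)),
              rep("point_mutation", sum(n_pm_eff)))
  t_locus <- c(rep("", length(rep_amp)), unlist(pm_loci))
  t_pair <- c(rep_amp, rep(seq_len(npair), n_pm_eff))

  # detection of each tissue alteration in blood
  det <- stats::runif(length(t_pid)) < d_det[match(t_pid, pid)]
  c_pid <- t_pid[det]; c_gene <- t_gene[det]; c_kind <- t_kind[det]
  c_locus <- t_locus[det]
  is_pm <- c_kind == "point_mutation"
  ident <- stats::runif(length(c_pid)) < q_g[c_gene]
  redraw <- which(is_pm & !ident)
  for (j in redraw) {
    pool <- setdiff(if (is.null(hot[[c_gene[j]]]))
      paste0("X", 100 + seq_len(8), "Y") else hot[[c_gene[j]]], c_locus[j])
    if (length(pool)) c_locus[j] <- sample(pool, 1L)
  }

  # blood-private alterations, in genes not tissue-altered for the patient
  n_priv <- stats::rpois(n, params$blood_private_rate)
  pres_by_patient <- split(gi, factor(pi, levels = seq_len(n)))
  priv_pid <- vector("list", n); priv_gene <- vector("list", n)
  for (i in which(n_priv > 0L)) {
    gidx <- pres_by_patient[[i]]
    absent <- if (!length(gidx)) genes else genes[-gidx]
    if (!length(absent)) next
    w <- params$gene_prev[absent]
    if (sum(w) == 0) next
    gsel <- sample(absent, min(n_priv[i], length(absent)), prob = w)
    priv_pid[[i]] <- rep(pid[i], length(gsel))
    priv_gene[[i]] <- gsel
  }
  p_pid <- unlist(priv_pid); p_gene <- unlist(priv_gene)
  if (length(p_pid)) {
    p_amp <- amp_ok(match(p_pid, pid), p_gene) &
      stats::runif(length(p_pid)) < params$private_amp_prob
    p_locus <- vapply(seq_along(p_pid), function(j) {
      if (p_amp[j]) return("")
      pool <- hot[[p_gene[j]]]
      if (is.null(pool)) pool <- paste0("X", 100 + seq_len(8), "Y")
      sample(pool, 1L)
    }, character(1))
    c_pid <- c(c_pid, p_pid); c_gene <- c(c_gene, p_gene)
    c_kind <- c(c_kind, ifelse(p_amp, "amplification", "point_mutation"))
    c_locus <- c(c_locus, p_locus)
  }

  vaf <- 100 * pmin(1, s[match(c_pid, pid)] *
                      stats::rbeta(length(c_pid), params$vaf_shape1,
                                   params$vaf_shape2))
  pct <- rep(0, n)
  if (length(c_pid)) {
    mx <- tapply(vaf, c_pid, max)
    pct[match(names(mx), pid)] <- as.numeric(mx)
  }

  # true mutual gene count (tissue gene with >=1 detected alteration)
  mutual_true <- integer(n)
  if (any(det)) {
    dm <- unique(data.frame(p = t_pid[det], g = t_gene[det]))
    tb <- table(dm$p)
    mutual_true[match(names(tb), pid)] <- as.integer(tb)
  }

  lp <- params$beta_mutual * mutual_true +
    params$beta_age * (age - 58.6) +
    params$beta_pct * pct +
    unname(params$type_effects[types])
  u <- stats::runif(n)
  tdeath <- params$weibull_scale *
    (-log(u) / exp(lp))^(1 / params$weibull_shape)
  cens <- stats::runif(n, params$censor_min, params$censor_max)
  os <- pmax(0.03, pmin(tdeath, cens))
  death <- tdeath <= cens

  alt <- data.frame(
    patient_id = c(t_pid, c_pid),
    assay = c(rep("tissue", length(t_pid)), rep("ctdna", length(c_pid))),
    gene = c(t_gene, c_gene),
    kind = c(t_kind, c_kind),
    locus = c(t_locus, c_locus),
    vaf_percent = c(rep(NA_real_, length(t_pid)), round(vaf, 4)),
    characterized = TRUE,
    sample_date = as.Date(c(tissue_date[match(t_pid, pid)],
                            blood_date[match(c_pid, pid)]),
                          origin = "1970-01-01"),
    stringsAsFactors = FALSE)
  alt <- alt[order(alt$patient_id, alt$assay, alt$gene, alt$locus), ]
  rownames(alt) <- NULL

  clinical <- data.frame(
    patient_id = pid, age_dx = round(age, 1), sex = sex, tumor_type = types,
    tissue_date = tissue_date, blood_date = blood_date,
    gap_months = round(gap, 2), os_months = round(os, 2), death = death,
    tmb = round(tmb, 2), pct_ctdna = round(pct, 4), stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = pid, shed_factor = s,
                      detect_prob = d_det, true_mutual_gene_count = mutual_true,
                      linear_predictor = lp, stringsAsFactors = FALSE)

  structure(list(alterations = alteration_table(alt), clinical = clinical,
                 truth = truth, params = params),
            class = "synthetic_cohort")
}
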