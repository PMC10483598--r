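test_that("locus matching follows the gene+kind+descriptor rule", {
  t1 <- alt_row("P1", "tissue", "TP53", "point_mutation", "R175H")
  c1 <- alt_row("P1", "ctdna", "TP53", "point_mutation", "R175H")
  c2 <- alt_row("P1", "ctdna", "TP53", "point_mutation", "R273H")
  expect_true(match_locus(t1, c1))
  expect_false(match_locus(t1, c2))
  # amplification in both counts as the same locus aberration
  expect_true(match_locus(alt_row("P1", "tissue", "MYC", "amplification"),
                          alt_row("P1", "ctdna", "MYC", "amplification")))
  # indels behave like point mutations; fusions never locus-match
  expect_true(match_locus(alt_row("P1", "tissue", "EGFR", "indel", "E746_A750DEL"),
                          alt_row("P1", "ctdna", "EGFR", "point_mutation", "E746_A750DEL")))
  expect_false(match_locus(alt_row("P1", "tissue", "ALK", "fusion"),
                           alt_row("P1", "ctdna", "ALK", "fusion")))
  # amp on one side vs point mutation on the other: gene-level only
  expect_false(match_locus(alt_row("P1", "tissue", "EGFR", "amplification"),
                           alt_row("P1", "ctdna", "EGFR", "point_mutation", "L858R")))
  # "p." prefixes are stripped upstream
  expect_true(match_locus(
    make_alts(alt_row("P1", "tissue", "TP53", "point_mutation", "p.R175H"))[1, ],
    c1))
})

test_that("per-patient profiles enumerate mutual genes and statuses", {
  empty <- make_alts(alt_row("P1", "tissue", "TP53"))[0, ]
  ct <- make_alts(alt_row("P1", "ctdna", "TP53", "point_mutation", "R175H"))
  p <- profile_patient(empty, ct)
  expect_equal(p$status, "N_N")
  expect_equal(c(p$mutual_gene_count, p$mutual_mutation_count), c(0L, 0L))

  tis <- make_alts(alt_row("P1", "tissue", "TP53", "point_mutation", "R175H"),
                   alt_row("P1", "tissue", "KRAS", "point_mutation", "G12D"))
  ct2 <- make_alts(alt_row("P1", "ctdna", "TP53", "point_mutation", "R273H"),
                   alt_row("P1", "ctdna", "EGFR", "point_mutation", "L858R"))
  p2 <- profile_patient(tis, ct2)
  expect_equal(p2$mutual_genes, "TP53")
  expect_equal(p2$mutual_mutation_genes, character(0))
  expect_equal(p2$status, "Y_N")

  # de-duplication at gene level: two matching loci still one gene
  tis3 <- make_alts(alt_row("P1", "tissue", "TP53", "point_mutation", "R175H"))
  ct3 <- make_alts(alt_row("P1", "ctdna", "TP53", "point_mutation", "R175H"),
                   alt_row("P1", "ctdna", "TP53", "point_mutation", "R273H"))
  p3 <- profile_patient(tis3, ct3)
  expect_equal(c(p3$mutual_gene_count, p3$mutual_mutation_count), c(1L, 1L))
  expect_equal(p3$status, "Y_Y")

  expect_error(profile_patient(tis, make_alts(alt_row("P2", "ctdna", "TP53"))),
               "multiple patients")
})

test_that("profiles agree with the brute-force all-pairs oracle", {
  set.seed(101)
  for (i in 1:300) {
    cs <- random_case()
    got <- profile_patient(cs$tissue, cs$ctdna)
    want <- brute_profile(cs$tissue, cs$ctdna)
    expect_identical(got$mutual_genes, want$mutual_genes)
    expect_identical(got$mutual_mutation_genes, want$mutual_mutation_genes)
    # symmetry: swapping assays leaves both sets unchanged
    sw_t <- cs$ctdna; sw_t$assay <- rep("tissue", nrow(sw_t))
    sw_c <- cs$tissue; sw_c$assay <- rep("ctdna", nrow(sw_c))
    sw <- profile_patient(sw_t, sw_c)
    expect_identical(sw$mutual_genes, got$mutual_genes)
    expect_identical(sw$mutual_mutation_genes, got$mutual_mutation_genes)
  }
})

test_that("vectorized cohort profiling equals patient-by-patient profiling", {
  co <- small_sim(n = 120, seed = 19)
  harm <- harmonize_cohort(co$alterations)
  prof <- profile_cohort(harm, co$clinical$patient_id)
  for (pid in co$clinical$patient_id) {
    sub <- harm[harm$patient_id == pid, , drop = FALSE]
    p <- profile_patient(sub[sub$assay == "tissue", , drop = FALSE],
                         sub[sub$assay == "ctdna", , drop = FALSE])
    row <- prof[prof$patient_id == pid, ]
    expect_equal(row$mutual_gene_count, p$mutual_gene_count)
    expect_equal(row$mutual_mutation_count, p$mutual_mutation_count)
    expect_equal(row$status, p$status)
  }
})

test_that("per-patient invariants hold on random synthetic cohorts", {
  co <- small_sim(n = 250, seed = 7)
  harm <- harmonize_cohort(co$alterations)
  prof <- profile_cohort(harm, co$clinical$patient_id)
  tg <- table(unique(harm[harm$assay == "tissue", c("patient_id", "gene")])$patient_id)
  cg <- table(unique(harm[harm$assay == "ctdna", c("patient_id", "gene")])$patient_id)
  for (i in seq_len(nrow(prof))) {
    pid <- prof$patient_id[i]
    nt <- if (pid %in% names(tg)) tg[[pid]] else 0L
    nc <- if (pid %in% names(cg)) cg[[pid]] else 0L
    expect_lte(prof$mutual_mutation_count[i], prof$mutual_gene_count[i])
    expect_lte(prof$mutual_gene_count[i], min(nt, nc))
  }
  expect_true(all((prof$status == "N_N") == (prof$mutual_gene_count == 0)))
  expect_true(all((prof$status == "Y_N") ==
                    (prof$mutual_gene_count > 0 & prof$mutual_mutation_count == 0)))
})

test_that("cohort gene table matches hand counts and per-patient sums", {
  alts <- make_alts(
    alt_row("P1", "tissue", "TP53", "point_mutation", "R175H"),
    alt_row("P1", "ctdna", "TP53", "point_mutation", "R175H"),
    alt_row("P2", "tissue", "TP53", "point_mutation", "R273H"),
    alt_row("P2", "ctdna", "TP53", "point_mutation", "R175H"),
    alt_row("P2", "tissue", "KRAS", "point_mutation", "G12D"),
    alt_row("P3", "tissue", "TP53", "point_mutation", "R175H"))
  tab <- cohort_gene_table(alts)
  tp53 <- tab[tab$gene == "TP53", ]
  # hand count: 3 tissue tumors, 2 ctdna tumors, 2 mutual, 1 locus-identical
  expect_equal(unlist(tp53[, -1], use.names = FALSE), c(3L, 2L, 2L, 1L))
  expect_equal(unlist(tab[tab$gene == "KRAS", -1], use.names = FALSE),
               c(1L, 0L, 0L, 0L))
  # single patient, tissue-only alteration
  solo <- cohort_gene_table(make_alts(alt_row("P9", "tissue", "TP53",
                                              "point_mutation", "R175H")))
  expect_equal(unlist(solo[, -1], use.names = FALSE), c(1L, 0L, 0L, 0L))

  # cross-check against per-patient profiles on a synthetic cohort:
  # sum over genes of mutual_gene_n equals sum over patients of counts
  co <- small_sim(n = 200, seed = 11)
  harm <- harmonize_cohort(co$alterations)
  gt <- cohort_gene_table(harm)
  prof <- profile_cohort(harm)
  expect_equal(sum(gt$mutual_gene_n), sum(prof$mutual_gene_count))
  expect_equal(sum(gt$mutual_mutation_n), sum(prof$mutual_mutation_count))
  expect_true(all(gt$mutual_mutation_n <= gt$mutual_gene_n))
  expect_true(all(gt$mutual_gene_n <= pmin(gt$tissue_n, gt$ctdna_n)))
})

test_that("conditional mutation frequency reproduces published per-gene ratios", {
  tbl <- load_gene_concordance_table()
  cf <- conditional_mutation_frequency(tbl, min_mutual = 5L)
  expect_equal(cf$per_gene$frequency[cf$per_gene$gene == "APC"], 14 / 16)
  expect_equal(cf$per_gene$frequency[cf$per_gene$gene == "KRAS"], 11 / 36)
  # a gene with all-identical matches has frequency 1
  toy <- data.frame(gene = "X", tissue_n = 9, ctdna_n = 9,
                    mutual_gene_n = 6, mutual_mutation_n = 6)
  expect_equal(conditional_mutation_frequency(toy)$per_gene$frequency, 1)
  # empty retained set is explicit, not NaN
  none <- conditional_mutation_frequency(toy, min_mutual = 7L)
  expect_equal(nrow(none$per_gene), 0L)
  expect_true(is.na(none$median))
  expect_error(conditional_mutation_frequency(toy, min_mutual = 0L))
})
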