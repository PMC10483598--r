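test_that("gene symbol normalization trims, uppercases, maps synonyms, and is idempotent", {
  expect_equal(normalize_gene_symbol("tp53 "), "TP53")
  expect_equal(normalize_gene_symbol("TP53"), "TP53")
  expect_equal(normalize_gene_symbol("MLL2", c(MLL2 = "KMT2D")), "KMT2D")
  # idempotence incl. through the synonym map
  m <- c(MLL2 = "KMT2D")
  once <- normalize_gene_symbol(c("mll2", " braf", "KMT2D"), m)
  expect_equal(normalize_gene_symbol(once, m), once)
  expect_error(normalize_gene_symbol("  "), "empty")
  expect_error(normalize_gene_symbol(c("TP53", NA)), "record")
})

test_that("packaged panel eras load with the 53/3 and 55/16 cardinalities", {
  panels <- load_packaged_panels()
  expect_length(panels, 2L)
  expect_length(panels[[1]]$genes, 53L)
  expect_length(panels[[1]]$amp_genes, 3L)
  expect_length(panels[[2]]$genes, 55L)
  expect_length(panels[[2]]$amp_genes, 16L)
  # every cohort-table gene is comparable in both eras
  tbl <- load_gene_concordance_table()
  expect_true(all(tbl$gene %in% panels[[1]]$genes))
  expect_true(all(tbl$gene %in% panels[[2]]$genes))
})

test_that("comparable set resolution is era-driven by sample date", {
  panels <- load_packaged_panels()
  universe <- sort(unique(unlist(lapply(panels, `[[`, "genes"))))
  pre <- resolve_comparable_set(as.Date("2014-10-01"), panels, universe)
  expect_length(pre$genes, 53L)
  expect_length(pre$amp_genes, 3L)
  post <- resolve_comparable_set(as.Date("2016-01-01"), panels, universe)
  expect_length(post$genes, 55L)
  expect_length(post$amp_genes, 16L)
  # identity intersection
  one <- panel_definition("x", "ABC1", character(0), "2000-01-01", "2100-01-01")
  got <- resolve_comparable_set(as.Date("2016-01-01"), list(one), "ABC1")
  expect_equal(got$genes, "ABC1")
  # date in zero eras
  late <- panel_definition("y", "A", "A", "2000-01-01", "2001-01-01")
  expect_error(resolve_comparable_set(as.Date("2016-01-01"), list(late), "A"),
               "0 panel eras")
})

test_that("restriction keeps comparable genes and era-eligible amplifications only", {
  panels <- load_packaged_panels()
  universe <- panels[[2]]$genes
  pre <- resolve_comparable_set(as.Date("2014-10-01"), panels, universe)
  alts <- make_alts(
    alt_row("P1", "tissue", "TP53", "point_mutation", "R175H"),
    alt_row("P1", "tissue", "KRAS", "amplification"),   # not amp-eligible pre-2015
    alt_row("P1", "tissue", "MET", "amplification"),    # amp-eligible pre-2015
    alt_row("P1", "tissue", "NOTAGENE", "point_mutation", "A1B"))
  got <- restrict_alterations(alts, pre)
  expect_equal(got$gene, c("TP53", "MET"))
  expect_equal(nrow(restrict_alterations(alts[0, ], pre)), 0L)
  # idempotent, never grows
  expect_identical(restrict_alterations(got, pre), got)
  expect_lte(nrow(got), nrow(alts))
})

test_that("characterized filtering and restriction commute", {
  alts <- make_alts(
    alt_row("P1", "tissue", "TP53", "point_mutation", "R175H"),
    alt_row("P1", "tissue", "TP53", "point_mutation", "P72R", characterized = FALSE),
    alt_row("P1", "ctdna", "EGFR", "amplification"),
    alt_row("P1", "ctdna", "IDH1", "point_mutation", "R132H", characterized = FALSE))
  expect_equal(nrow(filter_characterized(alts)), 2L)
  expect_equal(nrow(filter_characterized(alts[0, ])), 0L)
  panels <- load_packaged_panels()
  cgs <- resolve_comparable_set(as.Date("2016-05-01"), panels,
                                panels[[2]]$genes)
  set.seed(42)
  for (i in 1:25) {
    cs <- random_case()
    both <- rbind(cs$tissue, cs$ctdna)
    both$characterized <- runif(nrow(both)) < 0.6
    a <- filter_characterized(restrict_alterations(both, cgs))
    b <- restrict_alterations(filter_characterized(both), cgs)
    expect_identical(a, b)
  }
})

test_that("panel definition invariants are enforced", {
  expect_error(panel_definition("x", "A", "B", "2000-01-01", "2001-01-01"),
               "subset")
  expect_error(panel_definition("x", "A", "A", "2001-01-01", "2000-01-01"),
               "precede")
})
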