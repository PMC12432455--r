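# Variant-to-gene assignment, eQTL rescue, cross-trait flags.

test_that("proximity assignment applies the 5 kb window on gene bodies", {
  g <- toy_genes(list(gene_id = "G1", chrom = "1", start = 10000, end = 20000))
  cfg <- ssc_config()
  # 3 kb upstream: assigned with the gap as distance
  near <- quiet(assign_proximal(toy_variants("rs1", "1", 7001), g, NULL, cfg))
  expect_identical(near$assignments$gene_id, "G1")
  expect_identical(near$assignments$distance, 3000)
  expect_identical(near$assignments$mechanism, "proximal")
  expect_identical(nrow(near$intergenic), 0L)
  # 6 kb away: intergenic
  far <- quiet(assign_proximal(toy_variants("rs2", "1", 26001), g, NULL, cfg))
  expect_identical(nrow(far$assignments), 0L)
  expect_identical(far$intergenic$rsid, "rs2")
  # inside the body: distance 0
  inside <- quiet(assign_proximal(toy_variants("rs3", "1", 15000), g, NULL, cfg))
  expect_identical(inside$assignments$distance, 0)
  # exactly at the window edge is still proximal
  edge <- quiet(assign_proximal(toy_variants("rs4", "1", 25000), g, NULL, cfg))
  expect_identical(edge$assignments$distance, 5000)
})

test_that("consequence severity decides among competing genes", {
  g <- toy_genes(list(gene_id = "A", chrom = "1", start = 10000, end = 20000),
                 list(gene_id = "B", chrom = "1", start = 22000, end = 30000))
  v <- toy_variants("rs1", "1", 19500)  # inside A, ~2.5 kb from B
  cons <- data.frame(rsid = "rs1", gene_id = c("A", "B"),
                     term = c("intron_variant", "missense_variant"))
  res <- quiet(assign_proximal(v, g, cons, ssc_config()))
  expect_identical(res$assignments$gene_id, "B")
  expect_identical(res$assignments$consequence, "missense_variant")
  # without consequences the smaller distance wins
  res2 <- quiet(assign_proximal(v, g, NULL, ssc_config()))
  expect_identical(res2$assignments$gene_id, "A")
  # severity resolution ignores the order of the gene table
  res3 <- quiet(assign_proximal(v, g[2:1, ], cons, ssc_config()))
  expect_identical(res3$assignments$gene_id, "B")
})

test_that("only protein-coding genes attract assignments", {
  g <- toy_genes(list(gene_id = "NC", chrom = "1", start = 10000, end = 20000,
                      biotype = "lincRNA"))
  res <- quiet(assign_proximal(toy_variants("rs1", "1", 15000), g, NULL,
                               ssc_config()))
  expect_identical(nrow(res$assignments), 0L)
  expect_identical(res$intergenic$rsid, "rs1")
  # chromosome missing from the gene set is intergenic, not an error
  res2 <- quiet(assign_proximal(toy_variants("rs2", "9", 100), g, NULL,
                                ssc_config()))
  expect_identical(res2$intergenic$rsid, "rs2")
})

test_that("assignment and intergenic lists partition the input", {
  fx <- make_ssc_fixture(1)
  res <- quiet(assign_proximal(fx$summary_stats, fx$genes, fx$consequences,
                               ssc_config()))
  got <- sort(c(res$assignments$rsid, res$intergenic$rsid))
  expect_identical(got, sort(fx$summary_stats$rsid))
  expect_identical(length(intersect(res$assignments$rsid,
                                    res$intergenic$rsid)), 0L)
})

test_that("eQTL rescue honors tissue, p-value and best-record rules", {
  cfg <- ssc_config()
  inter <- toy_variants(c("rsA", "rsB", "rsC", "rsD"), "1",
                        c(1e6, 2e6, 3e6, 4e6))
  eqtl <- data.frame(
    rsid = c("rsA", "rsA", "rsB", "rsC"),
    gene_id = c("G2", "G1", "G3", "G4"),
    tissue = c("whole_blood", "whole_blood", "liver", "whole_blood"),
    pvalue = c(1e-6, 1e-12, 1e-12, 1e-3),
    stringsAsFactors = FALSE)
  res <- quiet(eqtl_rescue(inter, eqtl, cfg))
  # rsA rescued to its lowest-p whole-blood gene
  expect_identical(res$assignments$rsid, "rsA")
  expect_identical(res$assignments$gene_id, "G1")
  expect_identical(res$assignments$mechanism, "eqtl")
  # rsB only in liver, rsC above eqtl_p_max, rsD unrecorded: all dropped
  expect_setequal(res$dropped$rsid, c("rsB", "rsC", "rsD"))
  expect_identical(sort(c(res$assignments$rsid, res$dropped$rsid)),
                   sort(inter$rsid))
})

test_that("cross-trait flags require presence and genome-wide significance", {
  cfg <- ssc_config()
  v <- toy_variants(c("rs1", "rs2", "rs3"), "1", c(1, 2, 3))
  sec <- data.frame(rsid = c("rs1", "rs2"), pvalue = c(1e-12, 0.2))
  fl <- quiet(flag_cross_trait(v, sec, cfg))
  expect_identical(fl$cross_trait, c(TRUE, FALSE, FALSE))
})
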