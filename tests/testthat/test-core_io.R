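# Readers, writers, validators and the coordinate conventions.

test_that("summary statistics round-trip through write/read unchanged", {
  x <- random_summary_stats(50)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(x, path)
  y <- read_summary_stats(path)
  expect_equal(y, x, tolerance = 1e-12)

  small <- x[1:3, ]
  write_summary_stats(small, path)
  got <- read_summary_stats(path)
  expect_equal(nrow(got), 3L)
  expect_identical(got$rsid, small$rsid)  # row order preserved
})

test_that("variant invariants are enforced with the offending rsid named", {
  x <- random_summary_stats(5)
  x$maf[3] <- 0.7
  path <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(x, path, sep = "\t")
  expect_error(read_summary_stats(path), x$rsid[3],
               class = "sscgwas_validation_error")

  y <- random_summary_stats(4)
  y$rsid[2] <- y$rsid[1]
  expect_error(validate_variants(y), "duplicate",
               class = "sscgwas_validation_error")

  z <- random_summary_stats(4)[, -6]  # drop maf
  path2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(z, path2, sep = "\t")
  expect_error(read_summary_stats(path2), "maf",
               class = "sscgwas_format_error")
})

test_that("GFF3 coordinates convert to the 0-based half-open convention", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tx\tgene\t101\t200\t.\t+\t.\tID=gene:G1;Name=G1;biotype=protein_coding"),
             path)
  g <- read_gene_models(path)
  expect_identical(g$start, 100L)
  expect_identical(g$end, 200L)
  # position 101 (1-based) maps inside, 100 outside, 200 inside, 201 outside
  cfg <- ssc_config(proximity_bp = 1)  # thresholds must be positive
  inside <- quiet(assign_proximal(toy_variants("rsA", "1", 101), g, NULL, cfg))
  expect_identical(inside$assignments$distance, 0)
  edge <- quiet(assign_proximal(toy_variants("rsB", "1", 100), g, NULL, cfg))
  expect_identical(edge$assignments$distance, 1)
  last <- quiet(assign_proximal(toy_variants("rsC", "1", 200), g, NULL, cfg))
  expect_identical(last$assignments$distance, 0)
  past <- quiet(assign_proximal(toy_variants("rsD", "1", 201), g, NULL, cfg))
  expect_identical(past$assignments$distance, 1)
})

test_that("gene models round-trip and malformed GFF3 reports the line number", {
  genes <- toy_genes(list(gene_id = "A", chrom = "1", start = 100, end = 500),
                     list(gene_id = "B", chrom = "chr2", start = 900,
                          end = 1400, biotype = "lincRNA"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(genes, path)
  got <- read_gene_models(path)
  expect_identical(got$gene_id, genes$gene_id)
  expect_identical(got$start, as.integer(genes$start))
  expect_identical(got$end, as.integer(genes$end))
  expect_identical(got$chrom, c("1", "2"))  # chr prefix stripped

  writeLines(c("##gff-version 3", "1\tx\tgene\t101\t200\t.\t+",  # 7 fields
               "1\tx\tgene\t301\t400\t.\t+\t.\tID=g2"), path)
  expect_error(read_gene_models(path), "line 2",
               class = "sscgwas_format_error")
})

test_that("BED peaks parse as 0-based half-open with mark|cell_type names", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr7\t92600000\t92601000\tH3K4me1|neutrophil", path)
  p <- read_peaks(path)
  expect_identical(p$mark, "H3K4me1")
  expect_identical(p$cell_type, "neutrophil")
  expect_identical(p$chrom, "7")
  expect_identical(p$start, 92600000L)
  expect_identical(p$end, 92601000L)

  writeLines("7\t100\t200\tH3K9me3|neutrophil", path)
  expect_error(read_peaks(path), "H3K9me3",
               class = "sscgwas_validation_error")
  writeLines("7\t100\t200\tH3K4me1_neutrophil", path)
  expect_error(read_peaks(path), class = "sscgwas_format_error")
})

test_that("peaks round-trip through BED", {
  peaks <- data.frame(mark = c("H3K4me1", "H3K27ac"),
                      cell_type = c("neutrophil", "myelocyte"),
                      chrom = c("1", "2"), start = c(100L, 5000L),
                      end = c(700L, 5600L), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".bed")
  write_peaks(peaks, path)
  expect_equal(read_peaks(path), peaks)
})

test_that("expression reader rejects duplicates and negative values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tneutrophil\tmyelocyte", "MPO\t5\t2", "CDK6\t1\t0"), path)
  m <- read_expression(path)
  expect_identical(rownames(m), c("MPO", "CDK6"))
  expect_equal(m["MPO", "neutrophil"], 5)

  writeLines(c("gene\tneutrophil", "MPO\t5", "MPO\t2"), path)
  expect_error(read_expression(path), "duplicate",
               class = "sscgwas_validation_error")
  writeLines(c("gene\tneutrophil", "MPO\t-1"), path)
  expect_error(read_expression(path), "negative",
               class = "sscgwas_validation_error")
})

test_that("consequence and eQTL readers enforce their vocabularies", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tgene_id\tterm", "rs1\tG1\tmissense_variant"), path)
  expect_identical(read_consequences(path)$term, "missense_variant")
  writeLines(c("rsid\tgene_id\tterm", "rs1\tG1\tnot_a_term"), path)
  expect_error(read_consequences(path), "not_a_term",
               class = "sscgwas_validation_error")

  writeLines(c("rsid\tgene_id\ttissue\tpvalue", "rs1\tG1\twhole_blood\t0"),
             path)
  expect_error(read_eqtl(path), class = "sscgwas_validation_error")
})

test_that("genotype panels round-trip through the TSV pair", {
  p <- simulate_genotypes(list(ld_block("3", 500, 4, rho = 0.5)), 60, seed = 5)
  dp <- withr::local_tempfile(fileext = ".tsv")
  vp <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_panel(p, dp, vp)
  q <- read_genotype_panel(dp, vp)
  expect_equal(unname(q$dosages), unname(p$dosages))
  expect_identical(q$variants$rsid, p$variants$rsid)
  expect_identical(q$ids, p$ids)
})

test_that("configuration validates, serializes, and digests stably", {
  cfg <- ssc_config()
  expect_identical(cfg$p_threshold, 8.31e-9)
  expect_identical(cfg$block_gap_bp, 1e7)
  expect_identical(cfg$proximity_bp, 5000)
  expect_match(config_digest(cfg), "^[0-9a-f]{8}$")
  expect_identical(config_digest(cfg), config_digest(ssc_config()))
  expect_false(config_digest(cfg) == config_digest(ssc_config(n_pcs = 3)))

  path <- withr::local_tempfile(fileext = ".cfg")
  write_config(ssc_config(proximity_bp = 2500, eqtl_tissue = "liver"), path)
  back <- read_config(path)
  expect_identical(back$proximity_bp, 2500)
  expect_identical(back$eqtl_tissue, "liver")

  writeLines("not_a_key = 5", path)
  expect_error(read_config(path), "not_a_key",
               class = "sscgwas_format_error")
  expect_error(ssc_config(proximity_bp = -1), class = "sscgwas_config_error")
  expect_error(ssc_config(severity_table = c("a", "a")),
               class = "sscgwas_config_error")
})
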