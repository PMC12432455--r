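# Association engine: OLS scan, variance explained, blocks, conditional
# selection, LD and clumping.

test_that("variance explained matches hand arithmetic and its properties", {
  expect_equal(variance_explained(0.1, -0.12), 0.002592, tolerance = 1e-12)
  expect_equal(variance_explained(0.24, 0.28), 0.02860032, tolerance = 1e-12)
  expect_identical(variance_explained(0.3, 0), 0)
  # sign symmetry and vectorization
  expect_equal(variance_explained(c(0.1, 0.24), c(0.12, -0.28)),
               variance_explained(c(0.1, 0.24), c(-0.12, 0.28)))
  # maximal over maf at 0.5 for fixed |beta|
  grid <- seq(0.01, 0.5, by = 0.01)
  expect_identical(which.max(variance_explained(grid, 0.3)), length(grid))
  expect_error(variance_explained(0, 0.1), class = "sscgwas_parameter_error")
  expect_error(variance_explained(0.6, 0.1), class = "sscgwas_parameter_error")
})

test_that("noise-free effects are recovered to numerical precision", {
  p <- simulate_genotypes(list(ld_block("1", 1, 3, rho = 0)), 2000, seed = 51)
  x <- p$dosages[, 2]
  y <- 0.5 * as.numeric(scale(x))  # beta = 0.5 on the standardized dosage
  a <- quiet(run_association(p, y, n_pcs = 0))
  expect_equal(a$beta[2] * sd(x), 0.5, tolerance = 1e-6)
  expect_equal(a$maf[2], min(mean(x) / 2, 1 - mean(x) / 2), tolerance = 1e-12)
})

test_that("association agrees with summary.lm as an independent oracle", {
  p <- simulate_genotypes(list(ld_block("1", 1, 5, rho = 0.3)), 400, seed = 52)
  y <- simulate_phenotype(p, causal_plan(1, 0.3, 1), seed = 53)
  a <- quiet(run_association(p, y, n_pcs = 2))
  pcs <- prcomp(scale(p$dosages), center = FALSE, rank. = 2)$x
  for (j in c(1, 4)) {
    fit <- summary(lm(y ~ p$dosages[, j] + pcs))$coefficients
    expect_equal(a$beta[j], fit[2, "Estimate"], tolerance = 1e-10)
    expect_equal(a$se[j], fit[2, "Std. Error"], tolerance = 1e-10)
    expect_equal(a$pvalue[j], fit[2, "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("monomorphic variants are flagged and excluded", {
  d <- cbind(v1 = rbinom(100, 2, 0.4), v2 = rep(0L, 100),
             v3 = rbinom(100, 2, 0.3))
  p <- panel_from_matrix(d)
  a <- quiet(run_association(p, rnorm(100), n_pcs = 0))
  expect_identical(a$rsid, c("v1", "v3"))
  expect_identical(attr(a, "skipped"), "v2")
  expect_error(quiet(run_association(p, rnorm(5), n_pcs = 0)),
               class = "sscgwas_parameter_error")
  expect_error(quiet(run_association(p, rnorm(100), n_pcs = 100)),
               class = "sscgwas_parameter_error")
})

test_that("blocks chain by the 10 Mb gap rule and never bridge chromosomes", {
  v <- toy_variants(c("a", "b", "c"), "1", c(1e6, 5e6, 2e7))
  bl <- partition_blocks(v, gap_bp = 1e7)
  expect_length(bl, 2L)
  expect_identical(bl[[1]]$rsid, c("a", "b"))
  expect_identical(bl[[2]]$rsid, "c")

  expect_length(partition_blocks(v[1, ], 1e7), 1L)

  v2 <- rbind(v, toy_variants(c("d", "e", "f"), "2", c(1e6, 5e6, 2e7)))
  bl2 <- partition_blocks(v2, gap_bp = 1e7)
  expect_length(bl2, 4L)
  expect_identical(unname(vapply(bl2, nrow, 1L)), c(2L, 1L, 2L, 1L))
  # exact-gap boundary splits (distance >= gap starts a new block)
  v3 <- toy_variants(c("g", "h"), "3", c(1e6, 1e6 + 1e7))
  expect_length(partition_blocks(v3, 1e7), 2L)
})

test_that("stepwise selection finds independent signals and collapses shadows", {
  cfg <- ssc_config(n_pcs = 0)
  # two independent strong signals in one block
  p <- simulate_genotypes(list(ld_block("1", 1e6, 10, rho = 0)), 4000,
                          seed = 61)
  y <- simulate_phenotype(p, causal_plan(c(2, 7), c(0.5, 0.4), 0.8),
                          seed = 62)
  sel <- quiet(stepwise_conditional(p, y, p$variants$rsid, cfg))
  expect_setequal(sel$rsid, p$variants$rsid[c(2, 7)])
  expect_identical(sel$rsid[1], p$variants$rsid[2])  # stronger signal first

  # a near-perfect shadow of a single causal variant yields one selection
  p2 <- simulate_genotypes(list(ld_block("1", 1e6, 2, rho = 0.995)), 4000,
                           seed = 63)
  y2 <- simulate_phenotype(p2, causal_plan(1, 0.5, 0.8), seed = 64)
  sel2 <- quiet(stepwise_conditional(p2, y2, p2$variants$rsid, cfg))
  expect_identical(nrow(sel2), 1L)

  # nothing significant -> empty selection
  y3 <- simulate_phenotype(p, causal_plan(noise_sd = 1), seed = 65)
  sel3 <- quiet(stepwise_conditional(p, y3, p$variants$rsid, cfg))
  expect_identical(nrow(sel3), 0L)

  expect_error(quiet(stepwise_conditional(p, y, c("nope"), cfg)),
               class = "sscgwas_parameter_error")
})

test_that("selected sets agree with the exhaustive forward-selection oracle", {
  cfg <- ssc_config(n_pcs = 0)
  for (s in 1:4) {
    p <- simulate_genotypes(list(ld_block("1", 1e6, 8, rho = 0.6)), 3000,
                            seed = 70 + s)
    y <- simulate_phenotype(p, causal_plan(c(1, 5), c(0.4, 0.3), 1),
                            seed = 80 + s)
    sel <- quiet(stepwise_conditional(p, y, p$variants$rsid, cfg))
    oracle <- naive_forward_selection(p, y, p$variants$rsid, cfg$p_threshold)
    expect_identical(sel$rsid, oracle)
  }
})

test_that("selected variants never exceed r-squared 0.95 pairwise", {
  cfg <- ssc_config(n_pcs = 0)
  for (s in 1:3) {
    p <- simulate_genotypes(list(ld_block("1", 1e6, 10, rho = 0.9)), 3000,
                            seed = 90 + s)
    y <- simulate_phenotype(p, causal_plan(c(2, 8), c(0.5, 0.5), 0.8),
                            seed = 95 + s)
    sel <- quiet(stepwise_conditional(p, y, p$variants$rsid, cfg))
    if (nrow(sel) > 1) {
      r2 <- compute_ld(p, sel$rsid)
      expect_lt(max(r2[upper.tri(r2)]), 0.95)
    }
  }
})

test_that("merging blocks removes long-range redundant signals idempotently", {
  cfg <- ssc_config(n_pcs = 0)
  # correlated pair placed 30 Mb apart so block partition separates them
  blk <- simulate_genotypes(list(ld_block("1", 1, 2, rho = 0.995)), 5000,
                            seed = 101)
  r2 <- cor(blk$dosages[, 1], blk$dosages[, 2])^2
  expect_gt(r2, 0.8)
  expect_lt(r2, 0.95)
  vars <- blk$variants
  vars$pos <- c(1e6, 3.1e7)
  p <- genotype_panel(blk$dosages, vars)
  y <- simulate_phenotype(p, causal_plan(1, 0.5, 0.5), seed = 102)
  a <- quiet(run_association(p, y, 0))
  expect_true(all(a$pvalue < cfg$p_threshold))  # both marginally significant
  blocks <- partition_blocks(a, cfg$block_gap_bp)
  expect_length(blocks, 2L)
  per_block <- lapply(blocks, function(b)
    quiet(stepwise_conditional(p, y, b$rsid, cfg)))
  expect_identical(sum(vapply(per_block, nrow, 1L)), 2L)
  merged <- quiet(merge_and_rerun(p, y, per_block, cfg))
  expect_identical(nrow(merged), 1L)
  again <- quiet(merge_and_rerun(p, y, merged, cfg))
  expect_identical(again$rsid, merged$rsid)

  # mutually independent selections survive the merge unchanged
  p2 <- simulate_genotypes(list(ld_block("1", 1e6, 3, rho = 0),
                                ld_block("1", 4.1e7, 3, rho = 0)), 4000,
                           seed = 103)
  y2 <- simulate_phenotype(p2, causal_plan(c(1, 4), c(0.5, 0.5), 0.8),
                           seed = 104)
  sel2 <- quiet(merge_and_rerun(
    p2, y2,
    list(quiet(stepwise_conditional(p2, y2, p2$variants$rsid[1:3], cfg)),
         quiet(stepwise_conditional(p2, y2, p2$variants$rsid[4:6], cfg))),
    cfg))
  expect_setequal(sel2$rsid, p2$variants$rsid[c(1, 4)])
})

test_that("LD computation reflects dosage correlation structure", {
  d <- cbind(v1 = rbinom(200, 2, 0.4), v3 = rbinom(200, 2, 0.3))
  d <- cbind(d, v2 = d[, "v1"], v4 = 2L - d[, "v1"])[, c("v1", "v2", "v3", "v4")]
  p <- panel_from_matrix(d)
  r2 <- compute_ld(p, c("v1", "v2", "v4"))
  expect_equal(unname(r2["v1", "v2"]), 1)           # duplicated column
  expect_equal(unname(r2["v1", "v4"]), 1)           # reflected column
  expect_identical(unname(diag(r2)), c(1, 1, 1))
  d0 <- cbind(d, v5 = rep(1L, 200))
  expect_error(compute_ld(panel_from_matrix(d0), c("v1", "v5")), "v5",
               class = "sscgwas_parameter_error")
  expect_error(compute_ld(p, "ghost"), class = "sscgwas_parameter_error")
})

test_that("greedy clumping follows the documented rule", {
  # independent variants -> singleton clumps
  ld0 <- diag(3)
  dimnames(ld0) <- list(c("a", "b", "c"), c("a", "b", "c"))
  v <- data.frame(rsid = c("a", "b", "c"), pvalue = c(1e-10, 1e-9, 1e-8))
  cl0 <- greedy_clump(v, ld0, 0.8)
  expect_identical(length(unique(cl0$clump)), 3L)

  # tight pair -> one clump indexed by the smaller p-value
  ld1 <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cl1 <- greedy_clump(data.frame(rsid = c("a", "b"), pvalue = c(1e-8, 1e-12)),
                      ld1, 0.8)
  expect_identical(unique(cl1$index_rsid), "b")

  # chain a-b .9, b-c .9, a-c .5 with p(a) < p(b) < p(c): {a,b} and {c}
  ld2 <- matrix(c(1, .9, .5, .9, 1, .9, .5, .9, 1), 3,
                dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  cl2 <- greedy_clump(data.frame(rsid = c("a", "b", "c"),
                                 pvalue = c(1e-12, 1e-10, 1e-8)), ld2, 0.8)
  expect_identical(cl2$index_rsid[cl2$rsid == "a"], "a")
  expect_identical(cl2$index_rsid[cl2$rsid == "b"], "a")
  expect_identical(cl2$index_rsid[cl2$rsid == "c"], "c")
  # boundary: r-squared exactly at the threshold does not join
  ld3 <- matrix(c(1, .8, .8, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  cl3 <- greedy_clump(data.frame(rsid = c("a", "b"), pvalue = c(1e-9, 1e-8)),
                      ld3, 0.8)
  expect_identical(length(unique(cl3$clump)), 2L)
})
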