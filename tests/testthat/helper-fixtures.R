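# Builders and independent oracles shared across the test files.

# A small gene table on the internal 0-based half-open convention.
toy_genes <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r$gene_id, symbol = r$gene_id, chrom = r$chrom,
               start = r$start, end = r$end,
               biotype = if (is.null(r$biotype)) "protein_coding" else r$biotype,
               strand = "+", stringsAsFactors = FALSE)))
}

# A minimal variant table; pos is 1-based.
toy_variants <- function(rsid, chrom, pos, maf = 0.2, beta = 0.1,
                         se = 0.02, pvalue = 1e-10, cond_pvalue = 1e-10) {
  data.frame(rsid = rsid, chrom = chrom, pos = pos, ref = "A", alt = "G",
             maf = maf, beta = beta, se = se, pvalue = pvalue,
             cond_pvalue = cond_pvalue, stringsAsFactors = FALSE)
}

# Random well-formed summary-statistics table for round-trip tests.
random_summary_stats <- function(n, seed = 99) {
  withr::with_seed(seed, {
    data.frame(
      rsid = sprintf("rs%06d", seq_len(n)),
      chrom = as.character(sample(1:22, n, replace = TRUE)),
      pos = sample.int(1e8, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      maf = round(runif(n, 0.01, 0.5), 4),
      beta = round(rnorm(n, 0, 0.1), 4),
      se = round(runif(n, 0.005, 0.05), 4),
      pvalue = signif(10^runif(n, -20, -1), 4),
      cond_pvalue = signif(10^runif(n, -20, -1), 4),
      stringsAsFactors = FALSE)
  })
}

# Build a genotype_panel directly from a dosage matrix.
panel_from_matrix <- function(d, chrom = "1", pos = NULL) {
  if (is.null(colnames(d))) colnames(d) <- sprintf("v%d", seq_len(ncol(d)))
  if (is.null(pos)) pos <- 1e6 + (seq_len(ncol(d)) - 1) * 1000
  sscgwas::genotype_panel(d, data.frame(
    rsid = colnames(d), chrom = chrom, pos = pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE))
}

# Independent forward-selection oracle: repeatedly fit plain lm() with the
# already selected dosages as covariates, select the smallest focal p-value
# while it stays under the threshold. Deliberately written with R's formula
# interface, independent of the package's qr-based scan.
naive_forward_selection <- function(panel, trait, rsids, threshold,
                                    max_steps = 50) {
  d <- panel$dosages
  selected <- character(0)
  for (step in seq_len(max_steps)) {
    remaining <- setdiff(rsids, selected)
    if (!length(remaining)) break
    ps <- vapply(remaining, function(r) {
      df <- data.frame(y = trait, x = d[, r])
      if (length(selected))
        df <- cbind(df, as.data.frame(d[, selected, drop = FALSE]))
      fit <- summary(lm(y ~ ., data = df))$coefficients
      if (!"x" %in% rownames(fit)) return(1)
      fit["x", "Pr(>|t|)"]
    }, numeric(1))
    if (min(ps) >= threshold) break
    selected <- c(selected, remaining[which.min(ps)])
  }
  selected
}

# Brute-force count of variants lying strictly inside a protein-coding gene
# body (0-based half-open containment of pos - 1).
brute_force_inside_count <- function(variants, genes) {
  pc <- genes[genes$biotype == "protein_coding", ]
  sum(vapply(seq_len(nrow(variants)), function(i) {
    g <- pc[pc$chrom == variants$chrom[i], ]
    any(g$start <= variants$pos[i] - 1 & variants$pos[i] - 1 < g$end)
  }, logical(1)))
}

quiet <- function(expr) suppressMessages(expr)
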