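# Deterministic synthetic annotation bundle. The composition mirrors the
# published filter flow for neutrophil side scatter: 72 conditionally
# significant variants, 60 proximal / 12 intergenic at 5 kb, 2 eQTL rescues,
# 37 mapped genes, 6 unexpressed, 9 known granule components (one of them
# also unexpressed), 23 candidates, 8 with histone-mark support, CDK6 on top
# with two variants. Coordinates are a self-consistent pseudo-genome, not
# reference-genome positions; rsIDs are labels only. Unexpressed genes and
# filler candidates carry placeholder symbols (NOEXn, CANDnn) because their
# identities are not public.

fixture_shortlist_genes <- function() {
  c("CDK6", "CDKN2D", "E2F2", "PTBP1", "BCL6", "SMAP1", "TMCC2", "SLC23A2")
}

fixture_known_genes <- function() {
  c("MPO", "DEFA4", "PRTN3", "ELANE", "CTSG", "AZU1", "LTF", "LCN2", "CAMP")
}

fixture_table1_rsids <- function() {
  c(CDK6 = "rs445", CDK6 = "rs3731387", CDKN2D = "rs58573889",
    E2F2 = "rs2742972", PTBP1 = "rs8103323", BCL6 = "rs3774298",
    SMAP1 = "rs781984", TMCC2 = "rs1172132", SLC23A2 = "rs6139587")
}

#' Build the synthetic reference-composition fixture
#'
#' Generates, deterministically for a given seed, a complete annotation
#' bundle (primary and secondary summary statistics, gene models,
#' consequence annotations, eQTL records, expression matrix, histone-mark
#' peaks, known-granule list and expected flow counts) whose structure
#' drives every stage of the prioritization pipeline. The bundle contains
#' summary-level data only; no individual-level genotypes are required
#' downstream of it.
#'
#' @param seed integer seed controlling the incidental numeric draws
#'   (allele frequencies, effect sizes, p-values of non-anchored variants);
#'   the combinatorial composition is identical for every seed.
#' @return list of class `ssc_fixture` with elements `summary_stats`,
#'   `secondary_stats`, `genes`, `consequences`, `eqtl`, `expression`,
#'   `peaks`, `known_genes`, `expected_flow`, `seed`.
#' @examples
#' fx <- make_ssc_fixture(seed = 1)
#' nrow(fx$summary_stats)
#' @export
make_ssc_fixture <- function(seed = 1L) {
  shortlist <- fixture_shortlist_genes()
  known <- fixture_known_genes()  # CAMP is the known gene without expression
  noex <- sprintf("NOEX%d", 1:5)
  cand <- sprintf("CAND%02d", 1:15)  # CAND14/CAND15 are reached via eQTL only
  symbols <- c(shortlist, known, noex, cand)  # 37 mapped genes

  # pseudo-genome: genes cycle over 8 chromosomes, 20 kb bodies, 200 kb apart
  chrom <- rep(as.character(1:8), length.out = length(symbols))
  slot <- stats::ave(seq_along(symbols), chrom, FUN = seq_along) - 1L
  start <- 1e6 + slot * 2e5
  genes <- data.frame(
    gene_id = symbols, symbol = symbols, chrom = chrom,
    start = start, end = start + 2e4, biotype = "protein_coding",
    strand = rep(c("+", "-"), length.out = length(symbols)),
    stringsAsFactors = FALSE)
  # non-coding decoy: nearby variants must still count as intergenic
  genes <- rbind(genes, data.frame(
    gene_id = "LINCX1", symbol = "LINCX1", chrom = "1",
    start = 8e6, end = 8.02e6, biotype = "lincRNA", strand = "+",
    stringsAsFactors = FALSE))

  # proximal variant multiplicities per gene (total 60)
  counts <- c(setNames(c(2, rep(1, 7)), shortlist),
              setNames(c(3, 3, 3, 2, 2, 2, 2, 2, 1), known),
              setNames(rep(1, 5), noex),
              setNames(c(rep(2, 13), 0, 0), cand))
  stopifnot(sum(counts) == 60)

  withr::with_seed(seed, {
    g_at <- function(sym) genes[genes$gene_id == sym, ]
    alleles <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"),
                    c("A", "C"), c("G", "T"))
    t1 <- fixture_table1_rsids()
    auto <- 0L
    vrows <- list()
    crows <- list()
    cons_terms <- c("intron_variant", "missense_variant", "3_prime_UTR_variant",
                    "5_prime_UTR_variant", "splice_region_variant")
    for (sym in names(counts)) {
      k <- counts[[sym]]
      if (k == 0) next
      g <- g_at(sym)
      for (j in seq_len(k)) {
        if (sym == "CDK6") {
          rsid <- c("rs445", "rs3731387")[j]
          pos0 <- g$start + c(3000, 9000)[j]
          term <- "intron_variant"
        } else if (sym %in% names(t1)) {
          rsid <- unname(t1[names(t1) == sym])
          pos0 <- if (sym == "CDKN2D") g$start - 3000 else g$start + 2000
          term <- if (sym == "CDKN2D") "upstream_gene_variant" else "intron_variant"
        } else {
          auto <- auto + 1L
          rsid <- sprintf("rs9%06d", auto)
          pos0 <- g$start + 2000 + (j - 1) * 3000
          term <- cons_terms[(auto %% length(cons_terms)) + 1L]
        }
        al <- alleles[[(length(vrows) %% length(alleles)) + 1L]]
        if (rsid == "rs445") { maf <- 0.1; beta <- -0.12 }
        else if (rsid == "rs3731387") { maf <- 0.24; beta <- 0.28 }
        else {
          maf <- round(runif(1, 0.05, 0.5), 4)
          beta <- round(runif(1, -0.25, 0.25), 4)
          if (beta == 0) beta <- 0.01
        }
        cp <- signif(10^runif(1, -28, -8.6), 3)
        vrows[[length(vrows) + 1L]] <- data.frame(
          rsid = rsid, chrom = g$chrom, pos = pos0 + 1, ref = al[1],
          alt = al[2], maf = maf, beta = beta,
          se = round(runif(1, 0.01, 0.03), 4),
          pvalue = signif(cp * runif(1, 0.1, 0.9), 3), cond_pvalue = cp,
          stringsAsFactors = FALSE)
        crows[[length(crows) + 1L]] <- data.frame(
          rsid = rsid, gene_id = sym, term = term, stringsAsFactors = FALSE)
      }
    }

    # 12 intergenic variants in gene deserts; #3 sits 2 kb from the
    # non-coding decoy and must still be classified intergenic
    for (k in 1:12) {
      ichrom <- as.character(((k - 1) %% 8) + 1)
      pos0 <- 9e6 + k * 5e4
      if (k == 3) { ichrom <- "1"; pos0 <- 7998000 }
      al <- alleles[[(k %% length(alleles)) + 1L]]
      cp <- signif(10^runif(1, -28, -8.6), 3)
      vrows[[length(vrows) + 1L]] <- data.frame(
        rsid = sprintf("rs8%06d", k), chrom = ichrom, pos = pos0 + 1,
        ref = al[1], alt = al[2], maf = round(runif(1, 0.05, 0.5), 4),
        beta = round(runif(1, -0.25, 0.25), 4),
        se = round(runif(1, 0.01, 0.03), 4),
        pvalue = signif(cp * runif(1, 0.1, 0.9), 3), cond_pvalue = cp,
        stringsAsFactors = FALSE)
    }
    summary_stats <- do.call(rbind, vrows)
    summary_stats <-
      summary_stats[order_variants(summary_stats$chrom, summary_stats$pos,
                                   summary_stats$rsid), , drop = FALSE]
    rownames(summary_stats) <- NULL
    consequences <- do.call(rbind, crows)

    # eQTL records: two intergenic rescues (whole blood), decoys that fail
    # the tissue or p-value filter, and one record for a proximal variant
    eqtl <- data.frame(
      rsid = c("rs8000001", "rs8000001", "rs8000002", "rs8000004",
               "rs8000005", "rs8000006", "rs445"),
      gene_id = c("CAND14", "CAND09", "CAND15", "CAND05", "CAND06", "CAND07",
                  "CDK6"),
      tissue = c("whole_blood", "whole_blood", "whole_blood", "liver",
                 "whole_blood", "liver", "whole_blood"),
      pvalue = c(1e-12, 1e-6, 2.5e-8, 1e-12, 1e-3, 1e-9, 1e-8),
      stringsAsFactors = FALSE)

    # expression: neutrophil-lineage columns plus an irrelevant monocyte
    # column; CAMP and NOEX1-5 stay below threshold in every relevant type
    cell_types <- c("promyelocyte", "myelocyte", "metamyelocyte",
                    "neutrophil", "monocyte")
    unexpressed <- c("CAMP", noex)
    expr <- matrix(0, nrow = length(symbols), ncol = length(cell_types),
                   dimnames = list(symbols, cell_types))
    for (sym in symbols) {
      expr[sym, ] <- if (sym %in% unexpressed)
        c(round(runif(4, 0, 0.5), 2), round(runif(1, 0, 50), 2))
      else c(round(runif(4, 2, 50), 2), round(runif(1, 0, 50), 2))
    }
    expr["NOEX1", "monocyte"] <- 30  # expression outside the lineage must not rescue

    # histone-mark peaks: CDK6's two variants sit inside broad H3K4me1 peaks
    # in neutrophils and metamyelocytes; each remaining shortlist variant
    # sits in one qualifying peak; decoys fail the cell-type filter, overlap
    # a non-candidate gene's variant, or overlap nothing
    cdk6 <- g_at("CDK6")
    prows <- list(
      data.frame(mark = "H3K4me1", cell_type = "neutrophil",
                 chrom = cdk6$chrom, start = cdk6$start + 2500,
                 end = cdk6$start + 9500),
      data.frame(mark = "H3K4me1", cell_type = "metamyelocyte",
                 chrom = cdk6$chrom, start = cdk6$start + 2500,
                 end = cdk6$start + 9500))
    other_marks <- c("H3K27ac", "H3K4me3", "H3K4me1")
    rel_ct <- c("neutrophil", "metamyelocyte", "myelocyte", "promyelocyte")
    others <- setdiff(shortlist, "CDK6")
    for (i in seq_along(others)) {
      v <- summary_stats[summary_stats$rsid ==
                           unname(t1[names(t1) == others[i]]), ]
      prows[[length(prows) + 1L]] <- data.frame(
        mark = other_marks[((i - 1) %% 3) + 1L],
        cell_type = rel_ct[((i - 1) %% 4) + 1L],
        chrom = v$chrom, start = v$pos - 1 - 500, end = v$pos - 1 + 500)
    }
    decoy_at <- function(gene, mark, cell_type) {
      rs <- consequences$rsid[consequences$gene_id == gene][1]
      v <- summary_stats[summary_stats$rsid == rs, ]
      data.frame(mark = mark, cell_type = cell_type, chrom = v$chrom,
                 start = v$pos - 1 - 400, end = v$pos - 1 + 400)
    }
    prows[[length(prows) + 1L]] <- decoy_at("CAND01", "H3K4me1", "monocyte")
    prows[[length(prows) + 1L]] <- decoy_at("NOEX1", "H3K27ac", "neutrophil")
    prows[[length(prows) + 1L]] <- decoy_at("MPO", "H3K4me3", "neutrophil")
    prows[[length(prows) + 1L]] <- data.frame(
      mark = "H3K4me1", cell_type = "neutrophil", chrom = "2",
      start = 5e6, end = 5.001e6)
    peaks <- do.call(rbind, prows)
    peaks$start <- as.integer(peaks$start)
    peaks$end <- as.integer(peaks$end)

    # secondary trait (neutrophil count): rs445 genome-wide significant,
    # twenty other variants present but null, the rest absent
    nonsig <- head(setdiff(summary_stats$rsid, "rs445"), 20)
    sec_rows <- summary_stats[match(c("rs445", nonsig), summary_stats$rsid),
                              c("rsid", "chrom", "pos", "ref", "alt", "maf")]
    sec_rows$beta <- round(runif(nrow(sec_rows), -0.05, 0.05), 4)
    sec_rows$se <- round(runif(nrow(sec_rows), 0.01, 0.03), 4)
    sec_rows$pvalue <- c(3e-15, round(runif(length(nonsig), 0.05, 0.9), 4))
    sec_rows$beta[1] <- 0.21
    rownames(sec_rows) <- NULL

    bundle <- structure(list(
      summary_stats = summary_stats,
      secondary_stats = sec_rows,
      genes = genes,
      consequences = consequences,
      eqtl = eqtl,
      expression = expr,
      peaks = peaks,
      known_genes = c(known, "LYZ"),  # LYZ: known granule gene not mapped here
      expected_flow = flow_counts(
        n_input = 72, n_proximal = 60, n_intergenic = 12, n_rescued = 2,
        n_dropped = 10, n_retained_variants = 62, n_unique_genes = 37,
        n_unexpressed = 6, n_known_granule = 9, n_candidates = 23,
        n_epigenetic_supported = 8, n_no_count_assoc = 71),
      seed = as.integer(seed)
    ), class = "ssc_fixture")
    bundle
  })
}

#' @export
print.ssc_fixture <- function(x, ...) {
  cat(sprintf("<ssc_fixture> seed %d: %d variants, %d gene models, %d peaks, %d eQTL records\n",
              x$seed, nrow(x$summary_stats), nrow(x$genes), nrow(x$peaks),
              nrow(x$eqtl)))
  invisible(x)
}

#' Write / read a fixture bundle as its file set
#'
#' Serializes a fixture to the pipeline's external formats (summary-stat
#' TSVs, GFF3 gene models, BED peaks, TSV annotations, plain-text known-gene
#' list) plus a `manifest.tsv` listing member files and the generating seed.
#' `read_fixture()` reconstructs the bundle from such a directory.
#'
#' @param bundle an `ssc_fixture` from [make_ssc_fixture()].
#' @param dir output directory (created if missing).
#' @return `write_fixture()` returns `dir` invisibly; `read_fixture()`
#'   returns an `ssc_fixture`.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ssc_fixture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_summary_stats(bundle$summary_stats, fp("summary_stats.tsv"))
  data.table::fwrite(bundle$secondary_stats, fp("neutrophil_count_stats.tsv"),
                     sep = "\t", na = "NA", quote = FALSE)
  write_gene_models(bundle$genes, fp("genes.gff3"))
  data.table::fwrite(bundle$consequences, fp("consequences.tsv"), sep = "\t",
                     na = "NA", quote = FALSE)
  data.table::fwrite(bundle$eqtl, fp("eqtl.tsv"), sep = "\t", na = "NA",
                     quote = FALSE)
  write_expression(bundle$expression, fp("expression.tsv"))
  write_peaks(bundle$peaks, fp("peaks.bed"))
  writeLines(bundle$known_genes, fp("known_granule_genes.txt"))
  data.table::fwrite(as.data.frame(unclass(bundle$expected_flow)),
                     fp("expected_flow_counts.tsv"), sep = "\t", quote = FALSE)
  manifest <- data.frame(
    key = c("seed", "summary_stats", "secondary_stats", "genes",
            "consequences", "eqtl", "expression", "peaks", "known_genes",
            "expected_flow"),
    value = c(bundle$seed, "summary_stats.tsv", "neutrophil_count_stats.tsv",
              "genes.gff3", "consequences.tsv", "eqtl.tsv", "expression.tsv",
              "peaks.bed", "known_granule_genes.txt",
              "expected_flow_counts.tsv"),
    stringsAsFactors = FALSE)
  data.table::fwrite(manifest, fp("manifest.tsv"), sep = "\t", quote = FALSE)
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  man <- data.table::fread(file.path(dir, "manifest.tsv"), sep = "\t",
                           data.table = FALSE)
  val <- setNames(man$value, man$key)
  fp <- function(k) file.path(dir, val[[k]])
  ef <- data.table::fread(fp("expected_flow"), sep = "\t", data.table = FALSE)
  structure(list(
    summary_stats = read_summary_stats(fp("summary_stats")),
    secondary_stats = read_summary_stats(fp("secondary_stats")),
    genes = read_gene_models(fp("genes")),
    consequences = read_consequences(fp("consequences")),
    eqtl = read_eqtl(fp("eqtl")),
    expression = read_expression(fp("expression")),
    peaks = read_peaks(fp("peaks")),
    known_genes = read_known_genes(fp("known_genes")),
    expected_flow = do.call(flow_counts, as.list(ef)),
    seed = as.integer(val[["seed"]])
  ), class = "ssc_fixture")
}
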