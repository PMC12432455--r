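# Readers and writers for the pipeline's file formats. All tabular formats
# are TSV with a header and "NA" for missing optional values; gene models are
# GFF3 and peaks BED4, both parsed through rtracklayer. Internally all
# genomic intervals are 0-based half-open (GFF3 converted on read, BED taken
# as-is); variant positions stay 1-based as in summary-statistics tables and
# are converted to 0-based point coordinates where intervals are compared.

summary_stat_cols <- function() {
  c("rsid", "chrom", "pos", "ref", "alt", "maf", "beta", "se", "pvalue")
}

#' Validate a table of GWAS variants
#'
#' Enforces the invariants of a summary-statistics table: unique rsids,
#' positions >= 1, minor allele frequency in (0, 0.5], positive standard
#' errors and p-values in (0, 1] where present.
#'
#' @param x data.frame with columns `rsid, chrom, pos, ref, alt, maf, beta,
#'   se, pvalue` and optionally `cond_pvalue`.
#' @param context character used in error messages.
#' @return `x`, invisibly, with `chrom` normalized.
#' @export
validate_variants <- function(x, context = "variant table") {
  need <- summary_stat_cols()
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing column(s) %s", context,
                         paste(missing_cols, collapse = ", ")))
  x$chrom <- norm_chrom(x$chrom)
  if (nrow(x) == 0L) return(invisible(x))
  dup <- x$rsid[duplicated(x$rsid)]
  if (length(dup))
    abort_validation(sprintf("%s: duplicate rsid '%s'", context, dup[1]))
  bad <- which(!is.finite(x$pos) | x$pos < 1)
  if (length(bad))
    abort_validation(sprintf("%s: pos < 1 for rsid '%s'", context, x$rsid[bad[1]]))
  bad <- which(!is.finite(x$maf) | x$maf <= 0 | x$maf > 0.5)
  if (length(bad))
    abort_validation(sprintf("%s: maf outside (0, 0.5] for rsid '%s'",
                             context, x$rsid[bad[1]]))
  bad <- which(!is.na(x$se) & x$se <= 0)
  if (length(bad))
    abort_validation(sprintf("%s: se <= 0 for rsid '%s'", context, x$rsid[bad[1]]))
  bad <- which(!is.na(x$pvalue) & (x$pvalue <= 0 | x$pvalue > 1))
  if (length(bad))
    abort_validation(sprintf("%s: pvalue outside (0, 1] for rsid '%s'",
                             context, x$rsid[bad[1]]))
  if ("cond_pvalue" %in% names(x)) {
    bad <- which(!is.na(x$cond_pvalue) &
                   (x$cond_pvalue <= 0 | x$cond_pvalue > 1))
    if (length(bad))
      abort_validation(sprintf("%s: cond_pvalue outside (0, 1] for rsid '%s'",
                               context, x$rsid[bad[1]]))
  }
  invisible(x)
}

#' Read / write GWAS summary statistics
#'
#' TSV with header columns `rsid, chrom, pos, ref, alt, maf, beta, se,
#' pvalue` and optionally `cond_pvalue` (the p-value at the variant's
#' selection step of the conditional analysis). Row order is preserved and
#' all variant invariants are enforced on read.
#'
#' @param path file path.
#' @return `read_summary_stats()` returns a data.frame; `write_summary_stats()`
#'   returns `path` invisibly.
#' @export
read_summary_stats <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         na.strings = "NA", colClasses = list(character = "chrom"))
  x <- validate_variants(x, context = basename(path))
  x$chrom <- norm_chrom(x$chrom)
  x
}

#' @rdname read_summary_stats
#' @param x a variant data.frame as returned by [read_summary_stats()].
#' @export
write_summary_stats <- function(x, path) {
  validate_variants(x)
  keep <- intersect(c(summary_stat_cols(), "cond_pvalue"), names(x))
  data.table::fwrite(x[, keep, drop = FALSE], path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses `gene` features from a GFF3 file into a data.frame with the
#' internal 0-based half-open interval convention (GFF3 is 1-based
#' inclusive, so `start` is decremented on read). Requires `ID` and expects
#' `Name` and `biotype` (or `gene_biotype`) attributes.
#'
#' @param path GFF3 file path.
#' @return data.frame with columns `gene_id, symbol, chrom, start, end,
#'   biotype, strand`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE), length, 1L)
  if (any(nfield != 9L))
    abort_format(sprintf("%s: malformed GFF3 line %d (%d fields, expected 9)",
                         basename(path), body[nfield != 9L][1],
                         nfield[nfield != 9L][1]))
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  meta <- as.data.frame(GenomicRanges::mcols(gr))
  biotype <- if ("biotype" %in% names(meta)) meta$biotype
             else if ("gene_biotype" %in% names(meta)) meta$gene_biotype
             else rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = sub("^gene:", "", as.character(meta$ID)),
    symbol = if ("Name" %in% names(meta)) as.character(meta$Name)
             else sub("^gene:", "", as.character(meta$ID)),
    chrom = norm_chrom(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    biotype = as.character(biotype),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  validate_gene_models(genes, context = basename(path))
}

#' Validate a gene-model table
#'
#' @param genes data.frame as produced by [read_gene_models()] (0-based
#'   half-open coordinates).
#' @param context character used in error messages.
#' @return the validated data.frame.
#' @export
validate_gene_models <- function(genes, context = "gene models") {
  need <- c("gene_id", "symbol", "chrom", "start", "end", "biotype", "strand")
  missing_cols <- setdiff(need, names(genes))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing column(s) %s", context,
                         paste(missing_cols, collapse = ", ")))
  genes$chrom <- norm_chrom(genes$chrom)
  bad <- which(!(genes$start < genes$end))
  if (length(bad))
    abort_validation(sprintf("%s: start >= end for gene '%s'",
                             context, genes$gene_id[bad[1]]))
  bad <- which(!genes$biotype %in% allowed_biotypes())
  if (length(bad))
    abort_validation(sprintf("%s: unknown biotype '%s' for gene '%s'",
                             context, genes$biotype[bad[1]], genes$gene_id[bad[1]]))
  if (anyDuplicated(genes$gene_id))
    abort_validation(sprintf("%s: duplicate gene_id '%s'", context,
                             genes$gene_id[duplicated(genes$gene_id)][1]))
  genes
}

#' @rdname read_gene_models
#' @param genes gene-model data.frame (internal 0-based coordinates).
#' @export
write_gene_models <- function(genes, path) {
  validate_gene_models(genes)
  lines <- c("##gff-version 3",
             sprintf("%s\tsscgwas\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s;biotype=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id, genes$symbol, genes$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Read histone-mark peaks from BED
#'
#' BED4+ where the name field encodes `mark|cell_type` (e.g.
#' `H3K4me1|neutrophil`). BED coordinates are 0-based half-open, matching the
#' internal convention, so they pass through unchanged. Marks outside
#' H3K4me1/H3K27ac/H3K4me3 are rejected.
#'
#' @param path BED file path.
#' @return data.frame with columns `mark, cell_type, chrom, start, end`.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  name <- as.character(gr$name)
  parts <- strsplit(name, "|", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad))
    abort_format(sprintf("%s: peak name '%s' is not 'mark|cell_type'",
                         basename(path), name[bad[1]]))
  peaks <- data.frame(
    mark = vapply(parts, `[[`, "", 1),
    cell_type = vapply(parts, `[[`, "", 2),
    chrom = norm_chrom(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # undo rtracklayer's 1-based shift
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  validate_peaks(peaks, context = basename(path))
}

#' Validate a peak table
#'
#' @param peaks data.frame as produced by [read_peaks()].
#' @param context character used in error messages.
#' @return the validated data.frame.
#' @export
validate_peaks <- function(peaks, context = "peaks") {
  need <- c("mark", "cell_type", "chrom", "start", "end")
  missing_cols <- setdiff(need, names(peaks))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing column(s) %s", context,
                         paste(missing_cols, collapse = ", ")))
  peaks$chrom <- norm_chrom(peaks$chrom)
  bad <- which(!peaks$mark %in% allowed_marks())
  if (length(bad))
    abort_validation(sprintf("%s: mark '%s' not in {%s}", context,
                             peaks$mark[bad[1]],
                             paste(allowed_marks(), collapse = ", ")))
  bad <- which(!(peaks$start < peaks$end))
  if (length(bad))
    abort_validation(sprintf("%s: start >= end in peak %d", context, bad[1]))
  peaks
}

#' @rdname read_peaks
#' @param peaks peak data.frame.
#' @export
write_peaks <- function(peaks, path) {
  validate_peaks(peaks)
  writeLines(sprintf("%s\t%d\t%d\t%s|%s", peaks$chrom, peaks$start, peaks$end,
                     peaks$mark, peaks$cell_type), path)
  invisible(path)
}

#' Read consequence annotations
#'
#' TSV with columns `rsid, gene_id, term`; every term must appear in the
#' configured severity table.
#'
#' @param path file path.
#' @param severity_table ordered consequence vocabulary; see
#'   [default_severity_table()].
#' @return data.frame `rsid, gene_id, term`.
#' @export
read_consequences <- function(path, severity_table = default_severity_table()) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         na.strings = "NA")
  need <- c("rsid", "gene_id", "term")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing column(s) %s", basename(path),
                         paste(missing_cols, collapse = ", ")))
  bad <- which(!x$term %in% severity_table)
  if (length(bad))
    abort_validation(sprintf("%s: consequence term '%s' not in severity table",
                             basename(path), x$term[bad[1]]))
  x[, need]
}

#' Read eQTL records
#'
#' TSV with columns `rsid, gene_id, tissue, pvalue`; p-values must lie in
#' (0, 1].
#'
#' @param path file path.
#' @return data.frame `rsid, gene_id, tissue, pvalue`.
#' @export
read_eqtl <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         na.strings = "NA")
  need <- c("rsid", "gene_id", "tissue", "pvalue")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    abort_format(sprintf("%s: missing column(s) %s", basename(path),
                         paste(missing_cols, collapse = ", ")))
  bad <- which(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1)
  if (length(bad))
    abort_validation(sprintf("%s: eQTL pvalue outside (0, 1] for rsid '%s'",
                             basename(path), x$rsid[bad[1]]))
  x[, need]
}

#' Read a gene-by-cell-type expression matrix
#'
#' TSV whose first column (`gene`) holds gene symbols and whose remaining
#' columns are non-negative expression values per cell type. Duplicate gene
#' rows and negative values are rejected.
#'
#' @param path file path.
#' @return numeric matrix with gene symbols as row names and cell types as
#'   column names.
#' @export
read_expression <- function(path) {
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                         na.strings = "NA")
  if (names(x)[1] != "gene")
    abort_format(sprintf("%s: first column must be 'gene'", basename(path)))
  if (anyDuplicated(x$gene))
    abort_validation(sprintf("%s: duplicate gene row '%s'", basename(path),
                             x$gene[duplicated(x$gene)][1]))
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort_format(sprintf("%s: non-numeric expression values",
                                           basename(path)))
  if (any(m < 0, na.rm = TRUE))
    abort_validation(sprintf("%s: negative expression value", basename(path)))
  rownames(m) <- x$gene
  m
}

#' @rdname read_expression
#' @param expr expression matrix (genes in rows, cell types in columns).
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a known-granule-gene list
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path file path.
#' @return character vector of symbols.
#' @export
read_known_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read / write a genotype panel
#'
#' A dosage TSV (first column `individual_id`, one column of {0,1,2} dosages
#' per variant, named by rsid) plus a variant sidecar TSV (`rsid, chrom, pos,
#' ref, alt`).
#'
#' @param dosage_path,variants_path file paths.
#' @return a `genotype_panel` object; see [genotype_panel()].
#' @export
read_genotype_panel <- function(dosage_path, variants_path) {
  d <- data.table::fread(dosage_path, sep = "\t", header = TRUE,
                         data.table = FALSE)
  if (names(d)[1] != "individual_id")
    abort_format(sprintf("%s: first column must be 'individual_id'",
                         basename(dosage_path)))
  ids <- as.character(d$individual_id)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- ids
  v <- data.table::fread(variants_path, sep = "\t", header = TRUE,
                         data.table = FALSE,
                         colClasses = list(character = "chrom"))
  genotype_panel(m, v, ids)
}

#' @rdname read_genotype_panel
#' @param panel a `genotype_panel`.
#' @export
write_genotype_panel <- function(panel, dosage_path, variants_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  df <- data.frame(individual_id = panel$ids, panel$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  data.table::fwrite(df, dosage_path, sep = "\t", quote = FALSE)
  data.table::fwrite(panel$variants, variants_path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(dosage_path)
}

#' Construct a genotype panel
#'
#' @param dosages integer matrix (individuals x variants) with entries in
#'   {0, 1, 2}; column names are rsids.
#' @param variants data.frame with at least `rsid, chrom, pos` matching the
#'   dosage columns.
#' @param ids individual identifiers (defaults to dosage row names).
#' @return list of class `genotype_panel` with elements `dosages`,
#'   `variants`, `ids`.
#' @export
genotype_panel <- function(dosages, variants, ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) ids <- sprintf("ind%05d", seq_len(nrow(dosages)))
  if (ncol(dosages) != nrow(variants))
    abort_validation("dosage column count does not match variant metadata rows")
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$rsid
  if (!identical(colnames(dosages), as.character(variants$rsid)))
    abort_validation("dosage column names do not match variant rsids")
  if (!all(dosages %in% c(0, 1, 2)))
    abort_validation("dosages must be in {0, 1, 2}")
  variants$chrom <- norm_chrom(variants$chrom)
  structure(list(dosages = dosages, variants = variants,
                 ids = as.character(ids)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d variants on chromosome(s) %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$variants$chrom), collapse = ", ")))
  invisible(x)
}

#' Read the annotation resources used downstream of the GWAS
#'
#' Convenience loader bundling the gene models, consequence annotations,
#' eQTL records, expression matrix, histone-mark peaks and known-granule
#' gene list into one list, with all invariants enforced.
#'
#' @param genes_path GFF3 gene models.
#' @param consequences_path consequence TSV.
#' @param eqtl_path eQTL TSV.
#' @param expression_path expression TSV.
#' @param peaks_path peak BED.
#' @param known_genes_path known-gene text file.
#' @param severity_table consequence vocabulary.
#' @return list with elements `genes, consequences, eqtl, expression, peaks,
#'   known_genes`.
#' @export
read_annotation_bundle <- function(genes_path, consequences_path, eqtl_path,
                                   expression_path, peaks_path,
                                   known_genes_path,
                                   severity_table = default_severity_table()) {
  list(
    genes = read_gene_models(genes_path),
    consequences = read_consequences(consequences_path, severity_table),
    eqtl = read_eqtl(eqtl_path),
    expression = read_expression(expression_path),
    peaks = read_peaks(peaks_path),
    known_genes = read_known_genes(known_genes_path)
  )
}
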