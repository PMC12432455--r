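# Multi-omic triangulation of mapped genes: neutrophil-lineage expression
# filter, known-granule annotation, and histone-mark peak overlap.

#' Filter mapped genes by neutrophil-lineage expression
#'
#' A gene counts as expressed if its value reaches `config$expression_min`
#' in at least one of the configured relevant cell types (neutrophil
#' progenitors and mature neutrophils by default). Genes absent from the
#' matrix are treated as unexpressed and logged.
#'
#' @param gene_ids character vector of mapped gene symbols.
#' @param expr expression matrix ([read_expression()]).
#' @param config an [ssc_config()]; all `relevant_cell_types` must be matrix
#'   columns.
#' @return list with character vectors `expressed` and `unexpressed`
#'   (a partition of `gene_ids`).
#' @export
expression_filter <- function(gene_ids, expr, config = ssc_config()) {
  missing_ct <- setdiff(config$relevant_cell_types, colnames(expr))
  if (length(missing_ct))
    abort_config(sprintf("cell type(s) missing from expression matrix: %s",
                         paste(missing_ct, collapse = ", ")))
  gene_ids <- unique(as.character(gene_ids))
  absent <- setdiff(gene_ids, rownames(expr))
  if (length(absent))
    message(sprintf("[sscgwas] expression_filter: %d gene(s) absent from matrix treated as unexpressed: %s",
                    length(absent), paste(head(absent, 5), collapse = ", ")))
  present <- intersect(gene_ids, rownames(expr))
  if (length(present)) {
    vals <- expr[present, config$relevant_cell_types, drop = FALSE]
    is_expr <- apply(vals, 1, function(v)
      any(v >= config$expression_min, na.rm = TRUE))
    expressed <- present[is_expr]
  } else expressed <- character(0)
  unexpressed <- c(setdiff(present, expressed), absent)
  log_stage("expression_filter", length(gene_ids), length(expressed), config)
  list(expressed = gene_ids[gene_ids %in% expressed],
       unexpressed = gene_ids[gene_ids %in% unexpressed])
}

#' Annotate known granule components
#'
#' Case-insensitive symbol match of all mapped genes against the
#' known-granule list (applied to the full mapped set, not only expressed
#' genes). The candidate-eligible set for novelty-oriented prioritization is
#' expressed AND not known.
#'
#' @param gene_ids character vector of mapped gene symbols.
#' @param known_genes character vector of known granule-component symbols.
#' @param expressed character vector of expressed genes (from
#'   [expression_filter()]); defaults to all of `gene_ids`.
#' @return list with character vectors `known` (subset of `gene_ids`) and
#'   `candidates` (expressed and not known).
#' @export
annotate_known <- function(gene_ids, known_genes, expressed = gene_ids) {
  gene_ids <- unique(as.character(gene_ids))
  known <- gene_ids[tolower(gene_ids) %in% tolower(known_genes)]
  candidates <- setdiff(intersect(gene_ids, expressed), known)
  log_stage("annotate_known", length(gene_ids), length(candidates))
  list(known = known, candidates = candidates)
}

#' Histone-mark support for candidate genes
#'
#' A gene is epigenetically supported if at least one of its assigned
#' variants lies inside at least one qualifying peak: mark in
#' H3K4me1/H3K27ac/H3K4me3 and cell type among the configured relevant cell
#' types. Containment is half-open on the internal 0-based convention
#' (`start <= pos - 1 < end`), so a variant at the peak start is inside and
#' one at the peak end is outside. The result records every (mark,
#' cell_type) combination hit per gene and is invariant to peak order and
#' duplication.
#'
#' @param profiles data.frame with one row per assigned variant: `gene_id,
#'   rsid, chrom, pos` (1-based variant position).
#' @param peaks peak data.frame ([read_peaks()]).
#' @param config an [ssc_config()].
#' @return list with `supported` (character vector of gene ids) and
#'   `evidence` (data.frame `gene_id, rsid, mark, cell_type`, deduplicated).
#' @export
epigenetic_support <- function(profiles, peaks, config = ssc_config()) {
  peaks <- validate_peaks(peaks)
  peaks <- peaks[peaks$mark %in% allowed_marks() &
                   peaks$cell_type %in% config$relevant_cell_types, ,
                 drop = FALSE]
  peaks <- unique(peaks)
  profiles$chrom <- norm_chrom(profiles$chrom)
  rows <- list()
  for (i in seq_len(nrow(profiles))) {
    pos0 <- profiles$pos[i] - 1
    hit <- peaks[peaks$chrom == profiles$chrom[i] & peaks$start <= pos0 &
                   pos0 < peaks$end, , drop = FALSE]
    if (nrow(hit) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = profiles$gene_id[i], rsid = profiles$rsid[i],
      mark = hit$mark, cell_type = hit$cell_type, stringsAsFactors = FALSE)
  }
  evidence <- if (length(rows)) unique(do.call(rbind, rows))
    else data.frame(gene_id = character(0), rsid = character(0),
                    mark = character(0), cell_type = character(0))
  rownames(evidence) <- NULL
  supported <- unique(evidence$gene_id)
  log_stage("epigenetic_support", length(unique(profiles$gene_id)),
            length(supported), config)
  list(supported = supported, evidence = evidence)
}
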