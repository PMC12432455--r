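# Variant-to-gene assignment: proximity mapping with consequence-severity
# tie-breaking, eQTL rescue of intergenic variants, and cross-trait flags.

# bp distance from a 1-based variant position to a 0-based half-open gene
# interval; 0 if the variant falls inside the gene body.
gene_distance <- function(pos, start, end) {
  pos0 <- pos - 1
  ifelse(pos0 >= start & pos0 < end, 0,
         ifelse(pos0 < start, start - pos0, pos0 - end + 1))
}

#' Assign variants to proximal protein-coding genes
#'
#' Each variant within `config$proximity_bp` of a protein-coding gene body
#' receives exactly one gene assignment. When several genes fall inside the
#' window, the gene whose recorded consequence term ranks most severe in the
#' configured severity table wins; genes without a recorded consequence rank
#' below any recorded one, and remaining ties resolve by smallest distance,
#' then gene id. Variants with no gene in the window (including variants on
#' chromosomes absent from the gene set, which are logged) are returned as
#' intergenic.
#'
#' @param variants data.frame of conditionally significant variants
#'   (`rsid, chrom, pos`, ...).
#' @param genes gene-model data.frame ([read_gene_models()] convention);
#'   only `protein_coding` entries are considered.
#' @param consequences data.frame `rsid, gene_id, term`, or `NULL`.
#' @param config an [ssc_config()].
#' @return list with `assignments` (data.frame `rsid, gene_id, mechanism,
#'   consequence, distance`) and `intergenic` (the unassigned variant rows).
#' @export
assign_proximal <- function(variants, genes, consequences = NULL,
                            config = ssc_config()) {
  genes <- validate_gene_models(genes)
  pc <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  variants$chrom <- norm_chrom(variants$chrom)
  no_chrom <- setdiff(unique(variants$chrom), unique(pc$chrom))
  if (length(no_chrom) && nrow(variants))
    message(sprintf("[sscgwas] assign_proximal: no protein-coding genes on chromosome(s) %s; variants there treated as intergenic",
                    paste(no_chrom, collapse = ", ")))
  sev_rank <- function(term) {
    r <- match(term, config$severity_table)
    ifelse(is.na(r), Inf, r)
  }
  assign_rows <- list()
  intergenic_idx <- integer(0)
  for (i in seq_len(nrow(variants))) {
    g <- pc[pc$chrom == variants$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { intergenic_idx <- c(intergenic_idx, i); next }
    dist <- gene_distance(variants$pos[i], g$start, g$end)
    cand <- which(dist <= config$proximity_bp)
    if (length(cand) == 0L) { intergenic_idx <- c(intergenic_idx, i); next }
    g <- g[cand, , drop = FALSE]
    dist <- dist[cand]
    term <- rep(NA_character_, nrow(g))
    if (!is.null(consequences) && nrow(consequences)) {
      hit <- consequences[consequences$rsid == variants$rsid[i], , drop = FALSE]
      term <- hit$term[match(g$gene_id, hit$gene_id)]
    }
    pick <- order(sev_rank(term), dist, g$gene_id)[1]
    assign_rows[[length(assign_rows) + 1L]] <- data.frame(
      rsid = variants$rsid[i], gene_id = g$gene_id[pick],
      mechanism = "proximal", consequence = term[pick],
      distance = dist[pick], stringsAsFactors = FALSE)
  }
  assignments <- if (length(assign_rows)) do.call(rbind, assign_rows)
    else data.frame(rsid = character(0), gene_id = character(0),
                    mechanism = character(0), consequence = character(0),
                    distance = numeric(0))
  intergenic <- variants[intergenic_idx, , drop = FALSE]
  rownames(assignments) <- rownames(intergenic) <- NULL
  log_stage("assign_proximal", nrow(variants), nrow(assignments), config)
  list(assignments = assignments, intergenic = intergenic)
}

#' Rescue intergenic variants through whole-blood eQTLs
#'
#' An intergenic variant is retained if at least one eQTL record matches its
#' rsid with tissue `config$eqtl_tissue` and p-value <= `config$eqtl_p_max`;
#' it is assigned to the gene of the best (lowest-p) matching record, with
#' ties broken by gene id. Variants with no qualifying record are dropped
#' from further analysis.
#'
#' @param intergenic data.frame of intergenic variants (`rsid`, ...).
#' @param eqtl data.frame `rsid, gene_id, tissue, pvalue` ([read_eqtl()]).
#' @param config an [ssc_config()].
#' @return list with `assignments` (data.frame `rsid, gene_id, mechanism,
#'   consequence, distance`, mechanism `"eqtl"`) and `dropped` (variant
#'   rows without eQTL support).
#' @export
eqtl_rescue <- function(intergenic, eqtl, config = ssc_config()) {
  hits <- eqtl[eqtl$tissue == config$eqtl_tissue &
                 eqtl$pvalue <= config$eqtl_p_max, , drop = FALSE]
  rows <- list()
  dropped_idx <- integer(0)
  for (i in seq_len(nrow(intergenic))) {
    h <- hits[hits$rsid == intergenic$rsid[i], , drop = FALSE]
    if (nrow(h) == 0L) { dropped_idx <- c(dropped_idx, i); next }
    h <- h[order(h$pvalue, h$gene_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      rsid = intergenic$rsid[i], gene_id = h$gene_id[1], mechanism = "eqtl",
      consequence = NA_character_, distance = NA_real_,
      stringsAsFactors = FALSE)
  }
  assignments <- if (length(rows)) do.call(rbind, rows)
    else data.frame(rsid = character(0), gene_id = character(0),
                    mechanism = character(0), consequence = character(0),
                    distance = numeric(0))
  dropped <- intergenic[dropped_idx, , drop = FALSE]
  rownames(assignments) <- rownames(dropped) <- NULL
  log_stage("eqtl_rescue", nrow(intergenic), nrow(assignments), config)
  list(assignments = assignments, dropped = dropped)
}

#' Flag variants associated with a secondary trait
#'
#' Marks each variant that reaches genome-wide significance in a secondary
#' summary-statistics table (here: neutrophil count), distinguishing signals
#' specific to granularity from signals shared with cell abundance. Variants
#' absent from the secondary table are unflagged.
#'
#' @param variants data.frame with `rsid`.
#' @param secondary secondary-trait summary statistics (`rsid, pvalue`, ...).
#' @param config an [ssc_config()]; `p_threshold` is the flagging cutoff.
#' @return data.frame `rsid, cross_trait` (logical), in input order.
#' @export
flag_cross_trait <- function(variants, secondary, config = ssc_config()) {
  p <- secondary$pvalue[match(variants$rsid, secondary$rsid)]
  flag <- !is.na(p) & p < config$p_threshold
  log_stage("flag_cross_trait", nrow(variants), sum(flag), config)
  data.frame(rsid = variants$rsid, cross_trait = flag,
             stringsAsFactors = FALSE)
}
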