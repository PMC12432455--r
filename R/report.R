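# Shortlist ranking, filter-flow accounting with conservation identities,
# and the end-to-end pipeline orchestrator.

flow_count_fields <- function() {
  c("n_input", "n_proximal", "n_intergenic", "n_rescued", "n_dropped",
    "n_retained_variants", "n_unique_genes", "n_unexpressed",
    "n_known_granule", "n_candidates", "n_epigenetic_supported",
    "n_no_count_assoc")
}

#' Filter-flow counts
#'
#' Machine-readable record of how many variants and genes survive each
#' pipeline stage. [validate_flow_counts()] enforces the conservation
#' identities (proximal + intergenic = input; rescued + dropped =
#' intergenic; retained = proximal + rescued) and fails with an integrity
#' error naming the violated stage.
#'
#' @param n_input conditionally significant input variants.
#' @param n_proximal variants assigned by proximity.
#' @param n_intergenic variants beyond the proximity window.
#' @param n_rescued intergenic variants rescued by eQTL.
#' @param n_dropped intergenic variants without eQTL support.
#' @param n_retained_variants proximal + rescued variants.
#' @param n_unique_genes distinct genes the retained variants map to.
#' @param n_unexpressed mapped genes failing the expression filter.
#' @param n_known_granule mapped genes on the known-granule list.
#' @param n_candidates expressed, not-known genes.
#' @param n_epigenetic_supported candidates with histone-mark support.
#' @param n_no_count_assoc input variants with no secondary-trait
#'   association.
#' @return list of class `ssc_flow_counts`.
#' @export
flow_counts <- function(n_input = 0, n_proximal = 0, n_intergenic = 0,
                        n_rescued = 0, n_dropped = 0, n_retained_variants = 0,
                        n_unique_genes = 0, n_unexpressed = 0,
                        n_known_granule = 0, n_candidates = 0,
                        n_epigenetic_supported = 0, n_no_count_assoc = 0) {
  fc <- mget(flow_count_fields())
  fc <- lapply(fc, as.integer)
  structure(fc, class = "ssc_flow_counts")
}

#' @rdname flow_counts
#' @param fc an `ssc_flow_counts` object.
#' @export
validate_flow_counts <- function(fc) {
  stopifnot(inherits(fc, "ssc_flow_counts"))
  if (fc$n_proximal + fc$n_intergenic != fc$n_input)
    abort_integrity(sprintf(
      "flow integrity violated at gene assignment: proximal (%d) + intergenic (%d) != input (%d)",
      fc$n_proximal, fc$n_intergenic, fc$n_input))
  if (fc$n_rescued + fc$n_dropped != fc$n_intergenic)
    abort_integrity(sprintf(
      "flow integrity violated at eQTL rescue: rescued (%d) + dropped (%d) != intergenic (%d)",
      fc$n_rescued, fc$n_dropped, fc$n_intergenic))
  if (fc$n_retained_variants != fc$n_proximal + fc$n_rescued)
    abort_integrity(sprintf(
      "flow integrity violated at retention: retained (%d) != proximal (%d) + rescued (%d)",
      fc$n_retained_variants, fc$n_proximal, fc$n_rescued))
  invisible(TRUE)
}

#' @export
print.ssc_flow_counts <- function(x, ...) {
  cat("<ssc_flow_counts>\n")
  for (f in flow_count_fields()) cat(sprintf("  %-24s %d\n", f, x[[f]]))
  invisible(x)
}

#' Rank epigenetically supported candidate genes
#'
#' Orders candidates by number of distinct associated variants (descending),
#' then by maximum absolute effect size (descending), then alphabetically by
#' symbol, and assigns ranks 1..k.
#'
#' @param profiles data.frame with one row per supported gene: `symbol`,
#'   `n_snvs`, `max_abs_beta`, and optionally `evidence` (summary string).
#' @return data.frame `rank, symbol, n_snvs, max_abs_beta, evidence`,
#'   ordered by rank (zero rows for empty input).
#' @export
rank_candidates <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L)
    return(data.frame(rank = integer(0), symbol = character(0),
                      n_snvs = integer(0), max_abs_beta = numeric(0),
                      evidence = character(0)))
  if (!"evidence" %in% names(profiles)) profiles$evidence <- NA_character_
  ord <- order(-profiles$n_snvs, -profiles$max_abs_beta, profiles$symbol)
  out <- profiles[ord, c("symbol", "n_snvs", "max_abs_beta", "evidence"),
                  drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Assemble per-gene evidence profiles from the pipeline state.
build_evidence <- function(assignments, variants, genes, expressed, known,
                           support_evidence) {
  if (nrow(assignments) == 0L)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      expressed = logical(0), known_granule = logical(0),
                      n_snvs = integer(0), max_abs_beta = numeric(0),
                      marks = character(0)))
  beta <- variants$beta[match(assignments$rsid, variants$rsid)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(assignments)),
                                     assignments$gene_id), function(ix) {
    gid <- assignments$gene_id[ix[1]]
    ev <- support_evidence[support_evidence$gene_id == gid, , drop = FALSE]
    marks <- if (nrow(ev))
      paste(sort(unique(paste0(ev$mark, "|", ev$cell_type))), collapse = ";")
    else ""
    data.frame(gene_id = gid,
               symbol = genes$symbol[match(gid, genes$gene_id)],
               expressed = gid %in% expressed,
               known_granule = gid %in% known,
               n_snvs = length(unique(assignments$rsid[ix])),
               max_abs_beta = max(abs(beta[ix])),
               marks = marks, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the filter-flow report
#'
#' Recomputes every flow count from the raw stage outputs held in `state`,
#' asserts the conservation identities (aborting with an integrity error if
#' any stage double-counted or lost a variant), and renders a plain-text
#' per-stage report including the configuration digest and the variance
#' explained by each shortlist variant.
#'
#' @param state list with elements `variants` (input), `proximal`
#'   (assignments), `intergenic`, `rescued` (assignments), `dropped`,
#'   `expressed`, `unexpressed`, `known`, `candidates`, `supported`,
#'   `cross_trait` (data.frame from [flag_cross_trait()]), `shortlist`, and
#'   `config`.
#' @return list with `flow_counts` (validated [flow_counts()]) and `report`
#'   (character vector of report lines).
#' @export
build_flow_report <- function(state) {
  retained <- rbind(state$proximal, state$rescued)
  fc <- flow_counts(
    n_input = nrow(state$variants),
    n_proximal = nrow(state$proximal),
    n_intergenic = nrow(state$intergenic),
    n_rescued = nrow(state$rescued),
    n_dropped = nrow(state$dropped),
    n_retained_variants = nrow(retained),
    n_unique_genes = length(unique(retained$gene_id)),
    n_unexpressed = length(state$unexpressed),
    n_known_granule = length(state$known),
    n_candidates = length(state$candidates),
    n_epigenetic_supported = length(state$supported),
    n_no_count_assoc = sum(!state$cross_trait$cross_trait))
  validate_flow_counts(fc)
  digest <- if (!is.null(state$config)) config_digest(state$config) else "-"
  lines <- c(
    sprintf("sscgwas filter-flow report (config %s)", digest),
    sprintf("  input conditionally significant variants : %d", fc$n_input),
    sprintf("  proximal (<= %s bp)                      : %d",
            format(state$config$proximity_bp, trim = TRUE), fc$n_proximal),
    sprintf("  intergenic                               : %d", fc$n_intergenic),
    sprintf("  eQTL-rescued                             : %d", fc$n_rescued),
    sprintf("  dropped (no eQTL support)                : %d", fc$n_dropped),
    sprintf("  retained variants                        : %d",
            fc$n_retained_variants),
    sprintf("  unique mapped genes                      : %d",
            fc$n_unique_genes),
    sprintf("  unexpressed in relevant cell types       : %d",
            fc$n_unexpressed),
    sprintf("  known granule components                 : %d",
            fc$n_known_granule),
    sprintf("  candidate genes (expressed, not known)   : %d",
            fc$n_candidates),
    sprintf("  with histone-mark support                : %d",
            fc$n_epigenetic_supported),
    sprintf("  without secondary-trait association      : %d",
            fc$n_no_count_assoc))
  if (!is.null(state$shortlist) && nrow(state$shortlist)) {
    lines <- c(lines, "", "shortlist (rank, gene, n_snvs, max|beta|):")
    lines <- c(lines, sprintf("  %2d  %-10s %d  %.4f", state$shortlist$rank,
                              state$shortlist$symbol, state$shortlist$n_snvs,
                              state$shortlist$max_abs_beta))
    sl_var <- rbind(state$proximal, state$rescued)
    sl_var <- sl_var[sl_var$gene_id %in% state$shortlist$symbol, , drop = FALSE]
    v <- state$variants[match(sl_var$rsid, state$variants$rsid), , drop = FALSE]
    lines <- c(lines, "", "variance explained per shortlist variant:")
    lines <- c(lines, sprintf("  %-12s %-10s maf=%.4f beta=% .4f R2=%.6g",
                              v$rsid, sl_var$gene_id, v$maf, v$beta,
                              variance_explained(v$maf, v$beta)))
  }
  list(flow_counts = fc, report = lines)
}

#' Run the full prioritization pipeline
#'
#' Orchestrates gene assignment, eQTL rescue, cross-trait flagging,
#' expression filtering, known-granule annotation, histone-mark support and
#' shortlist ranking over a fixture bundle (or a directory written by
#' [write_fixture()]), returning all stage outputs plus the validated flow
#' counts. The run is deterministic given its inputs and configuration and
#' consumes summary-level data only.
#'
#' Input variants are those whose conditional p-value (falling back to the
#' marginal p-value when `cond_pvalue` is absent) passes
#' `config$p_threshold`.
#'
#' @param bundle an `ssc_fixture`, a list with the same elements, or a
#'   directory path containing a fixture file set.
#' @param config an [ssc_config()].
#' @param out_dir optional directory; when given, writes `assignments.tsv`,
#'   `evidence.tsv`, `shortlist.tsv`, `flow_counts.tsv` and `report.txt`.
#' @return list of class `ssc_pipeline_result` with elements `assignments`,
#'   `evidence`, `shortlist`, `flow_counts`, `report`, `cross_trait`,
#'   `state`.
#' @examples
#' \donttest{
#' res <- run_pipeline(make_ssc_fixture(1), ssc_config())
#' res$flow_counts
#' head(res$shortlist)
#' }
#' @export
run_pipeline <- function(bundle, config = ssc_config(), out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_fixture(bundle)
  variants <- validate_variants(bundle$summary_stats)
  cp <- if ("cond_pvalue" %in% names(variants) &&
            !all(is.na(variants$cond_pvalue)))
    variants$cond_pvalue else variants$pvalue
  variants <- variants[!is.na(cp) & cp < config$p_threshold, , drop = FALSE]
  log_stage("input_filter", nrow(bundle$summary_stats), nrow(variants), config)

  prox <- assign_proximal(variants, bundle$genes, bundle$consequences, config)
  resc <- eqtl_rescue(prox$intergenic, bundle$eqtl, config)
  retained <- rbind(prox$assignments, resc$assignments)
  cross <- flag_cross_trait(variants, bundle$secondary_stats, config)

  mapped_genes <- unique(retained$gene_id)
  ef <- expression_filter(mapped_genes, bundle$expression, config)
  kn <- annotate_known(mapped_genes, bundle$known_genes, ef$expressed)

  cand_assign <- retained[retained$gene_id %in% kn$candidates, , drop = FALSE]
  vpos <- match(cand_assign$rsid, variants$rsid)
  profiles <- data.frame(gene_id = cand_assign$gene_id,
                         rsid = cand_assign$rsid,
                         chrom = variants$chrom[vpos],
                         pos = variants$pos[vpos], stringsAsFactors = FALSE)
  supp <- epigenetic_support(profiles, bundle$peaks, config)

  evidence <- build_evidence(retained, variants, bundle$genes, ef$expressed,
                             kn$known, supp$evidence)
  sl_profiles <- evidence[evidence$gene_id %in% supp$supported,
                          c("symbol", "n_snvs", "max_abs_beta", "marks"),
                          drop = FALSE]
  names(sl_profiles)[names(sl_profiles) == "marks"] <- "evidence"
  shortlist <- rank_candidates(sl_profiles)

  state <- list(variants = variants, proximal = prox$assignments,
                intergenic = prox$intergenic, rescued = resc$assignments,
                dropped = resc$dropped, expressed = ef$expressed,
                unexpressed = ef$unexpressed, known = kn$known,
                candidates = kn$candidates, supported = supp$supported,
                cross_trait = cross, shortlist = shortlist, config = config)
  rep <- build_flow_report(state)

  res <- structure(list(assignments = retained, evidence = evidence,
                        shortlist = shortlist, flow_counts = rep$flow_counts,
                        report = rep$report, cross_trait = cross,
                        state = state),
                   class = "ssc_pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(retained, file.path(out_dir, "assignments.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    data.table::fwrite(evidence, file.path(out_dir, "evidence.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    data.table::fwrite(shortlist, file.path(out_dir, "shortlist.tsv"),
                       sep = "\t", na = "NA", quote = FALSE)
    data.table::fwrite(as.data.frame(unclass(rep$flow_counts)),
                       file.path(out_dir, "flow_counts.tsv"), sep = "\t",
                       quote = FALSE)
    writeLines(rep$report, file.path(out_dir, "report.txt"))
  }
  res
}

#' @export
print.ssc_pipeline_result <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
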