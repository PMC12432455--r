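#' Default consequence-severity table
#'
#' Ordered subset of variant consequence terms, most severe first, consistent
#' with the Variant Effect Predictor's published ranking. Used to pick a
#' single gene when several protein-coding genes fall inside the proximity
#' window of one variant.
#'
#' @return character vector of consequence terms, most severe first.
#' @export
default_severity_table <- function() {
  c("stop_gained", "frameshift_variant", "missense_variant",
    "splice_region_variant", "5_prime_UTR_variant", "3_prime_UTR_variant",
    "intron_variant", "upstream_gene_variant", "downstream_gene_variant",
    "intergenic_variant")
}

# Histone marks accepted as evidence of an open chromatin state.
allowed_marks <- function() c("H3K4me1", "H3K27ac", "H3K4me3")

# Gene biotypes the readers accept.
allowed_biotypes <- function() {
  c("protein_coding", "lincRNA", "lncRNA", "pseudogene", "processed_pseudogene",
    "miRNA", "snoRNA", "snRNA", "antisense", "misc_RNA", "rRNA", "TEC")
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the prioritization pipeline with the
#' defaults used throughout: genome-wide significance at p < 8.31e-9 (a
#' threshold stricter than the conventional 5e-8, accommodating low-frequency
#' variants), 10 Mb gaps to partition significant variants into blocks for
#' conditional analysis, r-squared > 0.8 for greedy clumping, a 5 kb
#' proximity window for variant-to-gene assignment, the top 10 genotype
#' principal components as association covariates, and a whole-blood eQTL
#' lookup for intergenic variants.
#'
#' @param p_threshold genome-wide significance threshold on the association
#'   (and conditional) p-value.
#' @param block_gap_bp gap, in bp, at or above which two consecutive
#'   significant variants on the same chromosome start separate conditional
#'   blocks.
#' @param clump_r2 r-squared above which a variant joins its index variant's
#'   clump.
#' @param proximity_bp maximum distance, in bp, from a protein-coding gene
#'   body for proximal assignment.
#' @param n_pcs number of genotype principal components included as
#'   covariates in association models.
#' @param expression_min minimum expression value (on the input matrix's own
#'   scale) in at least one relevant cell type for a gene to count as
#'   expressed.
#' @param relevant_cell_types cell types of the neutrophil lineage consulted
#'   by the expression filter and the histone-peak overlap.
#' @param severity_table ordered consequence terms, most severe first; see
#'   [default_severity_table()].
#' @param eqtl_tissue tissue label an eQTL record must carry to rescue an
#'   intergenic variant.
#' @param eqtl_p_max maximum eQTL p-value for a rescue.
#' @param rng_seed integer seed recorded with the configuration.
#' @return a list of class `ssc_config`.
#' @examples
#' cfg <- ssc_config()
#' cfg$p_threshold
#' @export
ssc_config <- function(p_threshold = 8.31e-9,
                       block_gap_bp = 1e7,
                       clump_r2 = 0.8,
                       proximity_bp = 5000,
                       n_pcs = 10,
                       expression_min = 1.0,
                       relevant_cell_types = c("neutrophil", "metamyelocyte",
                                               "myelocyte", "promyelocyte"),
                       severity_table = default_severity_table(),
                       eqtl_tissue = "whole_blood",
                       eqtl_p_max = 1e-5,
                       rng_seed = 1L) {
  cfg <- list(
    p_threshold = as.numeric(p_threshold),
    block_gap_bp = as.numeric(block_gap_bp),
    clump_r2 = as.numeric(clump_r2),
    proximity_bp = as.numeric(proximity_bp),
    n_pcs = as.integer(n_pcs),
    expression_min = as.numeric(expression_min),
    relevant_cell_types = as.character(relevant_cell_types),
    severity_table = as.character(severity_table),
    eqtl_tissue = as.character(eqtl_tissue),
    eqtl_p_max = as.numeric(eqtl_p_max),
    rng_seed = as.integer(rng_seed)
  )
  for (f in c("p_threshold", "block_gap_bp", "clump_r2", "proximity_bp",
              "expression_min", "eqtl_p_max")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0)
      abort_config(sprintf("config field '%s' must be a single positive number", f))
  }
  if (cfg$n_pcs < 0) abort_config("n_pcs must be non-negative")
  if (length(cfg$severity_table) == 0L)
    abort_config("severity_table must be non-empty")
  if (anyDuplicated(cfg$severity_table))
    abort_config("severity_table must not contain duplicate terms")
  if (length(cfg$relevant_cell_types) == 0L)
    abort_config("relevant_cell_types must be non-empty")
  structure(cfg, class = "ssc_config")
}

#' @export
print.ssc_config <- function(x, ...) {
  cat("<ssc_config> digest", config_digest(x), "\n")
  for (f in names(x)) {
    v <- x[[f]]
    cat(sprintf("  %-20s %s\n", f,
                paste(format(v, trim = TRUE), collapse = ", ")))
  }
  invisible(x)
}

#' Short digest of a configuration
#'
#' Eight-hex-digit hash of the configuration's canonical serialization,
#' emitted in every stage log line and in the flow report so runs can be
#' matched to their parameters.
#'
#' @param config an [ssc_config()] object.
#' @return a character scalar of 8 hex digits.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "ssc_config"))
  canon <- paste(
    vapply(names(config), function(f) {
      paste0(f, "=", paste(format(config[[f]], digits = 15, trim = TRUE),
                           collapse = ","))
    }, character(1)),
    collapse = ";")
  fnv1a_hex(canon)
}

#' Read / write a pipeline configuration
#'
#' Plain `key = value` text file mirroring the [ssc_config()] fields;
#' list-valued fields are comma-separated. Unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_config()` returns an `ssc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) < 2L
  if (any(bad))
    abort_format(sprintf("config line %d is not 'key = value'", which(bad)[1]))
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  defaults <- ssc_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    abort_format(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  args <- list()
  for (i in seq_along(keys)) {
    f <- keys[i]
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    if (is.numeric(defaults[[f]]) || is.integer(defaults[[f]])) v <- as.numeric(v)
    args[[f]] <- v
  }
  do.call(ssc_config, args)
}

#' @rdname read_config
#' @param config an [ssc_config()] object to serialize.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ssc_config"))
  lines <- vapply(names(config), function(f) {
    sprintf("%s = %s", f,
            paste(format(config[[f]], digits = 15, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
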