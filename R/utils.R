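# Shared internal helpers: structured errors, chromosome normalization,
# config digests, stage logging.

ssc_abort <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "sscgwas_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

abort_format <- function(msg) ssc_abort(msg, "sscgwas_format_error")
abort_validation <- function(msg) ssc_abort(msg, "sscgwas_validation_error")
abort_parameter <- function(msg) ssc_abort(msg, "sscgwas_parameter_error")
abort_config <- function(msg) ssc_abort(msg, "sscgwas_config_error")
abort_integrity <- function(msg) ssc_abort(msg, "sscgwas_integrity_error")

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` prefix so that mixed-source tables (e.g. a BED
#' file using `chr7` and summary statistics using `7`) compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector without the `chr` prefix.
#' @examples
#' norm_chrom(c("chr7", "7", "chrX"))
#' @export
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used only for
# short config digests in log lines and reports; not cryptographic.
fnv1a_hex <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low 16 bits (b < 256), keeping h a double < 2^32
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    # 32-bit modular multiply by the FNV prime, split to stay within
    # double precision
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# One structured log line per pipeline stage (FlowCounts auditability).
log_stage <- function(stage, n_in, n_out, config = NULL) {
  digest <- if (is.null(config)) "-" else config_digest(config)
  message(sprintf("[sscgwas] stage=%s in=%d out=%d config=%s",
                  stage, as.integer(n_in), as.integer(n_out), digest))
  invisible(NULL)
}

# Deterministic ordering used for chromosome-aware sorts: numeric chromosomes
# first in numeric order, then others lexicographically.
chrom_rank <- function(chrom) {
  chrom <- norm_chrom(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  order(order(key, chrom))  # rank within the vector
}

# order() helper for (chrom, pos [, rsid]) with natural chromosome order.
order_variants <- function(chrom, pos, rsid = NULL) {
  chrom <- norm_chrom(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  key <- ifelse(is.na(num), Inf, num)
  if (is.null(rsid)) order(key, chrom, pos) else order(key, chrom, pos, rsid)
}
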