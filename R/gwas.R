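# Association engine: OLS scan with principal-component covariates,
# variance explained, 10 Mb block partition, forward-selection conditional
# analysis, block merge-and-rerun, panel LD, and greedy clumping.

# OLS of y on (intercept, focal, covars); beta/se/two-sided p for the focal
# term. Returns NAs when the focal column is aliased; aliased covariates are
# dropped and the model refit.
ols_focal <- function(y, focal, covars = NULL) {
  n <- length(y)
  X <- cbind(1, focal)
  if (!is.null(covars) && NCOL(covars) > 0) X <- cbind(X, covars)
  qrX <- qr(X)
  co <- qr.coef(qrX, y)
  if (is.na(co[2L]))
    return(c(beta = NA_real_, se = NA_real_, pvalue = NA_real_))
  if (anyNA(co)) {
    keep <- which(!is.na(co))
    X <- X[, keep, drop = FALSE]
    qrX <- qr(X)
    co <- qr.coef(qrX, y)
  }
  p <- ncol(X)
  df <- n - p
  if (df <= 0) abort_parameter("more model terms than observations")
  res <- y - as.numeric(X %*% co)
  sigma2 <- sum(res^2) / df
  Rinv <- backsolve(qr.R(qrX), diag(p))
  vc <- matrix(NA_real_, p, p)
  pv <- qrX$pivot
  vc[pv, pv] <- sigma2 * tcrossprod(Rinv)
  se <- sqrt(vc[2L, 2L])
  tval <- unname(co[2L]) / se
  c(beta = unname(co[2L]), se = se,
    pvalue = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

# Top-k principal components of the column-standardized dosage matrix,
# computed over the analyzable (non-constant) columns.
pc_covariates <- function(panel, n_pcs) {
  d <- panel$dosages
  n <- nrow(d)
  if (n_pcs >= n)
    abort_parameter("n_pcs must be smaller than the number of individuals")
  if (n_pcs == 0L) return(NULL)
  v <- apply(d, 2, var)
  d <- d[, v > 0, drop = FALSE]
  k <- min(n_pcs, ncol(d), n - 1L)
  if (k == 0L) return(NULL)
  z <- scale(d)
  pcs <- prcomp(z, center = FALSE, scale. = FALSE, rank. = k)$x
  colnames(pcs) <- sprintf("PC%d", seq_len(ncol(pcs)))
  pcs
}

#' Genome-wide association scan
#'
#' Per-variant ordinary least squares of the trait on allelic dosage, an
#' intercept, and the top `n_pcs` principal components of the standardized
#' dosage matrix. Effect sizes are per alternate-allele copy; p-values are
#' two-sided t tests on the dosage coefficient. Minor allele frequencies are
#' computed from the dosages. Zero-variance (monomorphic) variants are
#' flagged and excluded from the results (their rsids are returned in the
#' `"skipped"` attribute).
#'
#' @param panel a [genotype_panel()].
#' @param trait numeric trait vector, one value per individual.
#' @param n_pcs number of principal-component covariates; must be smaller
#'   than the number of individuals.
#' @return data.frame with columns `rsid, chrom, pos, ref, alt, maf, beta,
#'   se, pvalue`, one row per analyzable variant in panel order.
#' @export
run_association <- function(panel, trait, n_pcs = 10) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (length(trait) != nrow(d))
    abort_parameter("trait length does not match the number of individuals")
  pcs <- pc_covariates(panel, n_pcs)
  v <- apply(d, 2, var)
  skipped <- colnames(d)[v == 0]
  if (length(skipped))
    message(sprintf("[sscgwas] run_association: skipping %d monomorphic variant(s): %s",
                    length(skipped), paste(head(skipped, 5), collapse = ", ")))
  keep <- which(v > 0)
  stats <- t(vapply(keep, function(j) ols_focal(trait, d[, j], pcs),
                    c(beta = 0, se = 0, pvalue = 0)))
  af <- colMeans(d[, keep, drop = FALSE]) / 2
  vmeta <- panel$variants[keep, , drop = FALSE]
  out <- data.frame(
    rsid = vmeta$rsid, chrom = vmeta$chrom, pos = vmeta$pos,
    ref = if ("ref" %in% names(vmeta)) vmeta$ref else NA_character_,
    alt = if ("alt" %in% names(vmeta)) vmeta$alt else NA_character_,
    maf = pmin(af, 1 - af), beta = stats[, "beta"], se = stats[, "se"],
    pvalue = stats[, "pvalue"], stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}

#' Phenotypic variance explained by a variant
#'
#' `R^2 = 2 * maf * (1 - maf) * beta^2`, the variance in a standardized
#' trait attributable to a biallelic variant in Hardy-Weinberg equilibrium
#' with minor allele frequency `maf` and per-allele effect `beta`.
#'
#' @param maf minor allele frequency in (0, 0.5]; vectorized.
#' @param beta per-allele effect size in trait-SD units; vectorized.
#' @return numeric vector of variance fractions.
#' @examples
#' variance_explained(0.1, -0.12)
#' @export
variance_explained <- function(maf, beta) {
  if (any(!is.finite(maf) | maf <= 0 | maf > 0.5))
    abort_parameter("maf must lie in (0, 0.5]")
  2 * maf * (1 - maf) * beta^2
}

#' Partition significant variants into conditional-analysis blocks
#'
#' Variants are sorted by (chromosome, position) and chained: consecutive
#' same-chromosome variants closer than `gap_bp` share a block; a gap of
#' `gap_bp` or more, or a chromosome change, starts a new block.
#'
#' @param variants data.frame with at least `chrom` and `pos`.
#' @param gap_bp block-splitting gap in bp (default 10 Mb).
#' @return list of data.frames, one per block, in genomic order.
#' @export
partition_blocks <- function(variants, gap_bp = 1e7) {
  if (nrow(variants) == 0L) return(list())
  ord <- order_variants(variants$chrom, variants$pos, variants$rsid)
  v <- variants[ord, , drop = FALSE]
  new_block <- c(TRUE, norm_chrom(v$chrom[-1]) != norm_chrom(v$chrom[-nrow(v)]) |
                   (v$pos[-1] - v$pos[-nrow(v)]) >= gap_bp)
  split(v, cumsum(new_block))
}

# r-squared between one dosage column and a set of columns.
r2_with <- function(d, rsid, others) {
  if (length(others) == 0L) return(numeric(0))
  as.numeric(cor(d[, rsid], d[, others, drop = FALSE]))^2
}

#' Stepwise conditional association within a block
#'
#' Forward selection: the variant with the lowest p-value enters the model,
#' its dosage becomes a covariate, the remaining block variants are re-tested
#' conditional on all selected variants (and the principal-component
#' covariates), and the procedure repeats while any conditional p-value is
#' below `config$p_threshold`. Each selected variant's `cond_pvalue` is its
#' p-value at the step it was selected. Candidates with r-squared > 0.95 to
#' an already selected variant are skipped (and logged) to guard against
#' collinear fits; ties in the minimum p-value break deterministically by
#' (chromosome, position, rsid).
#'
#' @param panel a [genotype_panel()].
#' @param trait numeric trait vector.
#' @param block character vector of rsids (or data.frame with an `rsid`
#'   column) forming one block; all must be panel columns.
#' @param config an [ssc_config()].
#' @return data.frame `rsid, chrom, pos, cond_pvalue` in selection order
#'   (zero rows if no variant reaches significance).
#' @export
stepwise_conditional <- function(panel, trait, block, config = ssc_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.data.frame(block)) block <- block$rsid
  block <- as.character(block)
  d <- panel$dosages
  missing_rs <- setdiff(block, colnames(d))
  if (length(missing_rs))
    abort_parameter(sprintf("block variant(s) absent from panel: %s",
                            paste(head(missing_rs, 5), collapse = ", ")))
  pcs <- pc_covariates(panel, config$n_pcs)
  vmeta <- panel$variants[match(block, panel$variants$rsid), , drop = FALSE]
  selected <- character(0)
  sel_p <- numeric(0)
  dropped_collinear <- character(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 50L)
      abort_parameter("stepwise_conditional exceeded 50 iterations; collinearity suspected")
    remaining <- setdiff(block, c(selected, dropped_collinear))
    if (length(remaining) == 0L) break
    # collinearity guard against the selected set
    if (length(selected)) {
      r2max <- vapply(remaining, function(r) max(r2_with(d, r, selected)), 0)
      newly <- remaining[r2max > 0.95]
      if (length(newly)) {
        message(sprintf("[sscgwas] stepwise_conditional: skipping collinear variant(s): %s",
                        paste(newly, collapse = ", ")))
        dropped_collinear <- c(dropped_collinear, newly)
        remaining <- setdiff(remaining, newly)
        if (length(remaining) == 0L) break
      }
    }
    covars <- if (length(selected)) cbind(d[, selected, drop = FALSE], pcs) else pcs
    ps <- vapply(remaining, function(r) ols_focal(trait, d[, r], covars)["pvalue"], 0)
    ps[is.na(ps)] <- 1  # aliased focal terms cannot be selected
    pmin_val <- min(ps)
    if (pmin_val >= config$p_threshold) break
    cand <- remaining[ps == pmin_val]
    if (length(cand) > 1L) {
      cm <- vmeta[match(cand, vmeta$rsid), , drop = FALSE]
      cand <- cand[order_variants(cm$chrom, cm$pos, cm$rsid)][1]
    } else cand <- cand[1]
    selected <- c(selected, cand)
    sel_p <- c(sel_p, pmin_val)
  }
  sm <- vmeta[match(selected, vmeta$rsid), , drop = FALSE]
  data.frame(rsid = selected, chrom = sm$chrom, pos = sm$pos,
             cond_pvalue = sel_p, stringsAsFactors = FALSE, row.names = NULL)
}

#' Merge per-block selections and rerun the conditional analysis
#'
#' Pools the variants selected in each block by chromosome and reruns
#' [stepwise_conditional()] on every pooled set, removing signals that are
#' redundant through long-range LD between blocks. The operation is
#' idempotent: applying it to its own output changes nothing.
#'
#' @param panel a [genotype_panel()].
#' @param trait numeric trait vector.
#' @param selections data.frame of selected variants (rbind of
#'   [stepwise_conditional()] outputs) or a list of such data.frames.
#' @param config an [ssc_config()].
#' @return data.frame `rsid, chrom, pos, cond_pvalue`.
#' @export
merge_and_rerun <- function(panel, trait, selections, config = ssc_config()) {
  if (is.list(selections) && !is.data.frame(selections))
    selections <- do.call(rbind, selections)
  if (is.null(selections) || nrow(selections) == 0L)
    return(data.frame(rsid = character(0), chrom = character(0),
                      pos = numeric(0), cond_pvalue = numeric(0)))
  out <- lapply(split(selections, norm_chrom(selections$chrom)), function(s)
    stepwise_conditional(panel, trait, s$rsid, config))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order_variants(out$chrom, out$pos, out$rsid), , drop = FALSE]
}

#' Pairwise LD (r-squared) from panel dosages
#'
#' @param panel a [genotype_panel()].
#' @param rsids variants to include; all must be panel columns with non-zero
#'   variance.
#' @return symmetric matrix of squared Pearson correlations with unit
#'   diagonal, dimnames = rsids.
#' @export
compute_ld <- function(panel, rsids) {
  stopifnot(inherits(panel, "genotype_panel"))
  rsids <- as.character(rsids)
  missing_rs <- setdiff(rsids, colnames(panel$dosages))
  if (length(missing_rs))
    abort_parameter(sprintf("rsid(s) absent from panel: %s",
                            paste(head(missing_rs, 5), collapse = ", ")))
  d <- panel$dosages[, rsids, drop = FALSE]
  v <- apply(d, 2, var)
  if (any(v == 0))
    abort_parameter(sprintf("zero-variance dosage column: %s",
                            rsids[v == 0][1]))
  r2 <- cor(d)^2
  diag(r2) <- 1
  r2
}

#' Greedy LD clumping
#'
#' Repeatedly takes the unassigned variant with the minimum p-value as an
#' index and assigns to its clump every unassigned variant with
#' r-squared > `r2_threshold` to that index, until all variants are
#' assigned. By construction the clumps partition the input and pairwise
#' r-squared between any two index variants is <= `r2_threshold`.
#'
#' @param variants data.frame with `rsid` and `pvalue` (and optionally
#'   `chrom`, `pos` used for deterministic tie-breaking).
#' @param ld r-squared matrix covering all input rsids (see [compute_ld()]).
#' @param r2_threshold clumping threshold (default 0.8).
#' @return data.frame `clump, index_rsid, rsid, pvalue, is_index`, one row
#'   per input variant.
#' @export
greedy_clump <- function(variants, ld, r2_threshold = 0.8) {
  rsids <- as.character(variants$rsid)
  missing_rs <- setdiff(rsids, rownames(ld))
  if (length(missing_rs))
    abort_parameter(sprintf("rsid(s) absent from LD matrix: %s",
                            paste(head(missing_rs, 5), collapse = ", ")))
  has_pos <- all(c("chrom", "pos") %in% names(variants))
  unassigned <- rsids
  rows <- list()
  k <- 0L
  while (length(unassigned)) {
    cand <- variants[match(unassigned, rsids), , drop = FALSE]
    ord <- if (has_pos)
      order(cand$pvalue, chrom_rank(cand$chrom), cand$pos, cand$rsid)
    else order(cand$pvalue, cand$rsid)
    idx <- as.character(cand$rsid[ord[1]])
    members <- unassigned[ld[idx, unassigned] > r2_threshold]
    members <- union(idx, members)
    k <- k + 1L
    mrows <- variants[match(members, rsids), , drop = FALSE]
    rows[[k]] <- data.frame(clump = k, index_rsid = idx, rsid = members,
                            pvalue = mrows$pvalue, is_index = members == idx,
                            stringsAsFactors = FALSE)
    unassigned <- setdiff(unassigned, members)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full association-to-index-variant scan
#'
#' Convenience wrapper running the complete engine: association scan,
#' genome-wide significance filter, 10 Mb block partition, per-block
#' stepwise conditional analysis, merge-and-rerun across blocks, and greedy
#' clumping of the surviving conditionally significant variants.
#'
#' @param panel a [genotype_panel()].
#' @param trait numeric trait vector.
#' @param config an [ssc_config()].
#' @return list with elements `assoc` (full scan), `significant` (marginal
#'   hits), `selected` (final conditionally significant set with
#'   `cond_pvalue`), `clumps` (clump table; zero rows if nothing selected),
#'   and `summary` (selected variants with summary statistics,
#'   `cond_pvalue`, and `clump_index`).
#' @export
gwas_scan <- function(panel, trait, config = ssc_config()) {
  assoc <- run_association(panel, trait, config$n_pcs)
  sig <- assoc[assoc$pvalue < config$p_threshold, , drop = FALSE]
  log_stage("association", nrow(assoc), nrow(sig), config)
  empty_sel <- data.frame(rsid = character(0), chrom = character(0),
                          pos = numeric(0), cond_pvalue = numeric(0))
  if (nrow(sig) == 0L)
    return(list(assoc = assoc, significant = sig, selected = empty_sel,
                clumps = data.frame(), summary = data.frame()))
  blocks <- partition_blocks(sig, config$block_gap_bp)
  sel <- lapply(blocks, function(b)
    stepwise_conditional(panel, trait, b$rsid, config))
  final <- merge_and_rerun(panel, trait, sel, config)
  log_stage("conditional", nrow(sig), nrow(final), config)
  if (nrow(final) == 0L)
    return(list(assoc = assoc, significant = sig, selected = final,
                clumps = data.frame(), summary = data.frame()))
  ld <- compute_ld(panel, final$rsid)
  cl <- greedy_clump(
    data.frame(rsid = final$rsid, chrom = final$chrom, pos = final$pos,
               pvalue = final$cond_pvalue, stringsAsFactors = FALSE),
    ld, config$clump_r2)
  summary <- assoc[match(final$rsid, assoc$rsid), , drop = FALSE]
  summary$cond_pvalue <- final$cond_pvalue
  summary$clump_index <- cl$index_rsid[match(final$rsid, cl$rsid)]
  rownames(summary) <- NULL
  log_stage("clump", nrow(final), length(unique(cl$clump)), config)
  list(assoc = assoc, significant = sig, selected = final, clumps = cl,
       summary = summary)
}
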