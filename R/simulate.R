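# Genotype and phenotype simulator. Haplotypes are drawn from a Gaussian
# copula with exchangeable within-block correlation, thresholded at each
# variant's allele frequency, and summed to diploid dosages; this gives
# direct control over target r-squared between neighboring variants without
# a coalescent machinery.

#' Specify an LD block
#'
#' A run of `n_variants` equally spaced biallelic variants whose haplotypes
#' share an exchangeable latent correlation `rho`. Distinct blocks are
#' simulated independently, so between-block LD is zero in expectation.
#'
#' @param chrom chromosome name.
#' @param start 1-based position of the first variant.
#' @param n_variants number of variants in the block.
#' @param rho latent (copula) correlation in `[0, 1)`; dosage correlation
#'   approaches `rho` as allele frequencies grow balanced.
#' @param af_range range the block's shared allele frequency is drawn from;
#'   variants within a block carry one common frequency, as tightly linked
#'   variants on a shared haplotype background do.
#' @param spacing_bp distance between consecutive variants.
#' @return list of class `ld_block_spec`.
#' @export
ld_block <- function(chrom, start, n_variants, rho,
                     af_range = c(0.1, 0.5), spacing_bp = 1000) {
  if (rho < 0 || rho >= 1)
    abort_parameter("rho must lie in [0, 1)")
  if (n_variants < 1) abort_parameter("n_variants must be >= 1")
  if (length(af_range) != 2L || af_range[1] <= 0 || af_range[2] > 0.5 ||
      af_range[1] > af_range[2])
    abort_parameter("af_range must be increasing within (0, 0.5]")
  structure(list(chrom = norm_chrom(chrom), start = as.numeric(start),
                 n_variants = as.integer(n_variants), rho = as.numeric(rho),
                 af_range = as.numeric(af_range),
                 spacing_bp = as.numeric(spacing_bp)),
            class = "ld_block_spec")
}

#' Simulate an LD-blocked genotype panel
#'
#' For each individual and block, two latent haplotype vectors are drawn from
#' a Gaussian copula with exchangeable correlation `rho`
#' (`z = sqrt(rho) * w + sqrt(1 - rho) * e` with a shared factor `w` per
#' haplotype), each thresholded at the variant's allele frequency
#' (`z < qnorm(af)` carries the alternate allele), and summed to a dosage in
#' {0, 1, 2}.
#'
#' @param blocks list of [ld_block()] specifications.
#' @param n_individuals number of diploid individuals (>= 50).
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @return a [genotype_panel()].
#' @examples
#' p <- simulate_genotypes(list(ld_block("1", 1e6, 5, rho = 0.9)), 100, seed = 1)
#' dim(p$dosages)
#' @export
simulate_genotypes <- function(blocks, n_individuals, seed) {
  if (inherits(blocks, "ld_block_spec")) blocks <- list(blocks)
  stopifnot(all(vapply(blocks, inherits, TRUE, "ld_block_spec")))
  if (n_individuals < 50) abort_parameter("n_individuals must be >= 50")
  n <- as.integer(n_individuals)
  withr::with_seed(seed, {
    dose_list <- vector("list", length(blocks))
    var_list <- vector("list", length(blocks))
    for (b in seq_along(blocks)) {
      blk <- blocks[[b]]
      m <- blk$n_variants
      # one frequency per block: variants in strong LD ride the same
      # haplotype background, and equal thresholds are what lets the dosage
      # correlation approach the latent rho (unequal thresholds cap the
      # attainable phi coefficient well below it)
      af <- rep(runif(1, blk$af_range[1], blk$af_range[2]), m)
      thresh <- qnorm(af)
      dosage <- matrix(0L, n, m)
      for (h in 1:2) {
        w <- rnorm(n)
        z <- sqrt(blk$rho) * w +
          sqrt(1 - blk$rho) * matrix(rnorm(n * m), n, m)
        dosage <- dosage + (z < matrix(thresh, n, m, byrow = TRUE))
      }
      rsid <- sprintf("sim%s_b%d_v%d", blk$chrom, b, seq_len(m))
      var_list[[b]] <- data.frame(
        rsid = rsid, chrom = blk$chrom,
        pos = blk$start + (seq_len(m) - 1) * blk$spacing_bp,
        ref = "A", alt = "G", af = af, stringsAsFactors = FALSE)
      colnames(dosage) <- rsid
      dose_list[[b]] <- dosage
    }
    dosages <- do.call(cbind, dose_list)
    variants <- do.call(rbind, var_list)
    rownames(dosages) <- sprintf("ind%05d", seq_len(n))
    genotype_panel(dosages, variants)
  })
}

#' Plan planted causal effects
#'
#' @param indices column indices of causal variants in the panel.
#' @param betas effect sizes, in trait-SD units per standardized dosage.
#' @param noise_sd standard deviation of the Gaussian environmental noise.
#' @return list of class `causal_plan`.
#' @export
causal_plan <- function(indices = integer(0), betas = numeric(0), noise_sd = 1) {
  if (length(indices) != length(betas))
    abort_parameter("indices and betas must have equal length")
  if (noise_sd < 0) abort_parameter("noise_sd must be >= 0")
  structure(list(indices = as.integer(indices), betas = as.numeric(betas),
                 noise_sd = as.numeric(noise_sd)),
            class = "causal_plan")
}

#' Simulate a quantitative trait with planted effects
#'
#' `trait = sum(beta_k * standardized dosage_k) + N(0, noise_sd^2)`.
#'
#' @param panel a [genotype_panel()].
#' @param plan a [causal_plan()]; indices must reference panel columns with
#'   non-zero variance.
#' @param seed integer seed.
#' @return numeric vector of length `n_individuals`.
#' @export
simulate_phenotype <- function(panel, plan, seed) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(plan, "causal_plan"))
  m <- ncol(panel$dosages)
  if (length(plan$indices) && (min(plan$indices) < 1 || max(plan$indices) > m))
    abort_parameter("causal plan references variant indices outside the panel")
  n <- nrow(panel$dosages)
  withr::with_seed(seed, {
    g <- numeric(n)
    for (k in seq_along(plan$indices)) {
      x <- panel$dosages[, plan$indices[k]]
      if (var(x) == 0)
        abort_parameter(sprintf("causal variant column %d has zero variance",
                                plan$indices[k]))
      g <- g + plan$betas[k] * as.numeric(scale(x))
    }
    g + rnorm(n, 0, plan$noise_sd)
  })
}
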