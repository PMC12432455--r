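# sscgwas

Variant-to-gene prioritization for neutrophil side-scatter (SSC) GWAS
signals.

Neutrophil SSC, reported by automated hematology analyzers during a routine
blood count, is a flow-cytometric proxy for cytoplasmic granularity.
Genome-wide association scans of SSC yield dozens of conditionally
independent variants; `sscgwas` turns such a list into a ranked shortlist of
candidate granule-regulator genes, for genetic epidemiologists and
immunologists triaging loci for functional follow-up. The package covers
both halves of the problem:

* **Association engine** — OLS association with principal-component
  covariates, per-variant variance explained
  (R² = 2·MAF·(1−MAF)·β²), partition of significant variants into blocks
  separated by ≥ 10 Mb, forward-selection conditional analysis within
  blocks (iterating while any conditional p < 8.31×10⁻⁹), merge-and-rerun
  across blocks, and greedy LD clumping at r² > 0.8.
* **Prioritization** — assignment of each variant to one protein-coding
  gene within 5 kb (consequence severity breaking ties), rescue of
  intergenic variants through whole-blood eQTLs, filtering by
  neutrophil-lineage expression, annotation of known granule components,
  overlap of variant positions with H3K4me1/H3K27ac/H3K4me3 peaks, and a
  shortlist ranked by distinct SNV count then maximum |β|.
* **Simulator & fixture** — an LD-blocked Gaussian-copula genotype
  simulator with planted causal effects, and a deterministic synthetic
  annotation bundle that exercises every filter on a pseudo-genome.

Every run emits filter-flow counts whose conservation identities are
checked mechanically, plus a plain-text report.

## Worked example

```r
library(sscgwas)

res <- run_pipeline(make_ssc_fixture(seed = 1), ssc_config())
res$flow_counts
#> <ssc_flow_counts>
#>   n_input                  72
#>   n_proximal               60
#>   n_intergenic             12
#>   n_rescued                2
#>   n_dropped                10
#>   n_retained_variants      62
#>   n_unique_genes           37
#>   n_unexpressed            6
#>   n_known_granule          9
#>   n_candidates             23
#>   n_epigenetic_supported   8
#>   n_no_count_assoc         71

head(res$shortlist, 3)
#>   rank  symbol n_snvs max_abs_beta                                 evidence
#> 1    1    CDK6      2       0.2800 H3K4me1|metamyelocyte;H3K4me1|neutrophil
#> 2    2   PTBP1      1       0.2460                        H3K4me1|myelocyte
#> 3    3 SLC23A2      1       0.1960                        H3K27ac|myelocyte
```

Reading the counts top to bottom: of 72 conditionally significant input
variants, 60 sit within 5 kb of a protein-coding gene and 12 are
intergenic; 2 of the 12 are rescued by a whole-blood eQTL and 10 are
dropped, leaving 62 retained variants that map to 37 unique genes. Six
genes show no expression in the neutrophil lineage, nine are already known
granule components, and the remaining 23 candidates are tested for
histone-mark overlap, which 8 pass. 71 of the 72 variants have no
association with neutrophil count, so the signals are granularity-specific
rather than abundance-driven. The shortlist ranks CDK6 first: two distinct
associated variants (the most of any candidate) with a maximum |β| of 0.28
SD per allele, both inside H3K4me1 peaks in neutrophils and metamyelocytes.

The association engine is exercised the same way on simulated panels:

```r
panel <- simulate_genotypes(list(ld_block("1", 1e6, 10, rho = 0.9),
                                 ld_block("1", 2.1e7, 10, rho = 0.9)),
                            n_individuals = 5000, seed = 42)
trait <- simulate_phenotype(panel, causal_plan(c(3, 14), c(0.4, 0.4), 1),
                            seed = 43)
scan <- gwas_scan(panel, trait, ssc_config(n_pcs = 0))
scan$summary[, c("rsid", "beta", "pvalue", "cond_pvalue", "clump_index")]
#>         rsid      beta        pvalue   cond_pvalue clump_index
#> 1 sim1_b1_v3 0.6358699 2.299466e-131 6.547805e-155  sim1_b1_v3
#> 2 sim1_b2_v4 0.6430820 2.982919e-137 2.982919e-137  sim1_b2_v4
```

The engine recovers exactly the two planted causal variants as index
variants, collapsing their LD shadows through the conditional analysis.

A thin command-line wrapper with `fixture`, `simulate`, `gwas` and
`prioritize` subcommands is installed at `inst/scripts/sscgwas-cli.R`.

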