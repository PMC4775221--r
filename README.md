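# mtcn — relative mitochondrial DNA copy number from sequencing depth

`mtcn` estimates the relative mitochondrial DNA (mtDNA) copy number of a
sample from aligned whole-exome (WXS) or whole-genome (WGS) sequencing
reads, and provides the cohort statistics typically built on those
estimates in tumor studies. It is aimed at computational biologists working
with tumor/normal sequencing cohorts who want a tested, reproducible
implementation of the depth-ratio estimator and its downstream analyses,
plus a synthetic-cohort generator that makes every stage testable without
access to controlled patient data.

## The model

For a sample with $r_m$ filtered reads on the mitochondrial contig and
$r_n$ filtered reads on the primary nuclear contigs,

$$ m = \frac{r_m}{r_n} \times R, \qquad
   R_\text{tumor} = \frac{\text{purity}\times\text{ploidy} +
   (1-\text{purity})\times 2}{2}, \quad R_\text{normal} = 1 $$

where the read filters (QC pass, non-duplicate, properly paired, MAPQ > 30)
suppress reads attracted by nuclear-embedded mitochondrial segments
(NUMTs), and $R$ corrects the nuclear denominator for tumor purity and
ploidy ("effective ploidy"). Plate batch effects are removed by fitting,
per cancer type,

$$ \log_{10} m_{ijk} = \mu + \alpha_i + \beta_j + \epsilon_{ijk} $$

over plates $i$ and tissue classes $j$ (tissue vs blood), and subtracting
$\hat\alpha_i$ from WXS samples. On top of the corrected estimates the
package provides:

- paired tumor vs adjacent-normal depletion tests
  ($r = \log_2 m_T/m_N$, Wilcoxon signed-rank, BH-corrected);
- WXS/WGS concordance and generic covariate correlation (Spearman);
- univariate Cox survival association with Wald tests;
- per-gene Spearman correlation with expression and a mean-rank gene-set
  enrichment test with signed $-\log_{10}(q)$ scores;
- Mann-Whitney association scans for somatic mutations and copy-number
  alterations, with optional stratification against subtype confounding;
- a fully seeded synthetic-cohort generator (`simulate_cohort()`) and a
  miniature BAM fixture writer (`generate_bam_fixture()`) with recorded
  ground truth.

See `vignettes/mtdna-copy-number-methods.Rmd` for the full methods
account.

## Worked example

A synthetic cohort of 120 patients with planted signals: tumors depleted by
0.5 log2 units relative to matched normals, one gene set whose expression
rises with copy number, and survival hazard increasing with copy number
(log-hazard coefficient 1).

```r
library(mtcn)

cohort <- simulate_cohort(n_patients = 120, seed = 42,
                          tumor_log2_shift = -0.5,
                          planted_set_effect = 1, survival_gamma = 1)

est <- estimate_copy_number(cohort$counts, cohort$meta, cohort$purity)
fit <- fit_batch_model(est, cohort$meta)
glance(fit)
#> # A tibble: 1 × 6
#>   cancer_type     n n_plates    mu sigma tissue_dropped
#>   <chr>       <int>    <int> <dbl> <dbl> <lgl>
#> 1 SYNTH         287        6 -4.00 0.247 FALSE

est <- correct_copy_number(fit, est, cohort$meta)
depletion_test(build_pairs(est, cohort$meta))
#> # A tibble: 1 × 8
#>   cancer_type n_pairs frac_depleted median_r statistic       p       q direction
#>   <chr>         <int>         <dbl>    <dbl>     <dbl>   <dbl>   <dbl> <chr>
#> 1 SYNTH            85           0.8   -0.492       443 1.32e-9 1.32e-9 depleted

cox_survival(est, cohort$survival, cohort$meta)
#> # A tibble: 1 × 10
#>   cancer_type     n n_events coefficient hazard_ratio  wald_p median_cut n_high
#>   <chr>       <int>    <int>       <dbl>        <dbl>   <dbl>      <dbl>  <int>
#> 1 SYNTH         120      101        1.12         3.08 0.00833      -4.00     60

corr <- gene_correlations(filter_genes(cohort$expression), est)
head(gene_set_scan(corr, cohort$gene_sets, tissue_label = "tumor"), 3)
#> # A tibble: 3 × 7
#>   gene_set     tissue direction n_genes_in_universe        p        q
#>   <chr>        <chr>  <chr>                   <int>    <dbl>    <dbl>
#> 1 PLANTED_SET  tumor  up                         18 1.60e-50 1.63e-48
#> 2 DECOY_SET_03 tumor  up                         18 3.90e- 4 1.99e- 2
#> 3 DECOY_SET_50 tumor  up                         16 3.40e- 3 1.16e- 1
```

Reading the output: the grand mean $\mu \approx -4.0$ is the cohort-level
$\log_{10}$ read ratio (WXS captures mtDNA at a few percent efficiency, so
the ratio is far below the per-cell copy number); 80% of the 85 matched
pairs have less tumor than normal mtDNA, with a median log2 ratio of
−0.49 — the planted −0.5 — and the cancer type is called `depleted` at
$q \approx 10^{-9}$. The Cox coefficient 1.12 recovers the planted
log-hazard of 1 (hazard ratio ≈ 3 per tenfold copy-number increase). The
planted gene set ranks first with an enrichment score of
$-\log_{10}(q) \approx 47.8$; one of the fifty decoy sets happens to clear
$q < 0.05$ in this particular cohort, a useful reminder that a 5% FDR is
not zero. Plots: `plot_paired_ratios()`, `plot_enrichment()`,
`plot_survival_split()`, and `autoplot()` on the batch fit.

Counting reads directly from a BAM:

```r
counts <- count_filtered_reads("sample.bam", sample_id = "S1")  # per contig
estimate_copy_number(summarise_mt_counts(counts))
```

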