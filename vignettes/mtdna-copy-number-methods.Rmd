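---
title: "Estimating relative mtDNA copy number from sequencing depth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative mtDNA copy number from sequencing depth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcn)
```

Human cells carry hundreds to thousands of copies of the 16.6 kb
mitochondrial genome, and this copy number shifts in disease, notably in
tumors. `mtcn` estimates *relative* mtDNA copy number from aligned
short-read sequencing and runs the cohort statistics commonly built on such
estimates. This vignette is the package's own account of the models it
implements, the assumptions behind them, and the design decisions taken
where the methodology was genuinely open.

## The depth-ratio estimator

If equal-ploidy regions of a genome are sequenced to comparable depth, the
ratio of mitochondrial to nuclear read counts is proportional to the number
of mtDNA copies per diploid nuclear genome. For a sample with filtered
mitochondrial read count $r_m$ and nuclear read count $r_n$,

$$ m = \frac{r_m}{r_n} \times R $$

where $R$ corrects the nuclear denominator for tumor purity and ploidy (see
below). $m$ is relative: exome capture recovers mtDNA only off-target, at a
platform- and kit-dependent efficiency, so $m$ is never converted to copies
per cell and raw values are never compared across platforms. Within a
platform and plate, a higher $m$ means more mtDNA.

### Read filters

`count_filtered_reads()` keeps primary alignments that pass platform QC,
are not duplicates, are properly paired, and have Phred-scaled mapping
quality strictly greater than 30 (probability of correct placement
$1 - 10^{-30/10} = 99.9\%$). The pairing and MAPQ requirements exist to
suppress NUMTs — nuclear insertions of mitochondrial sequence that
otherwise attract mitochondrial reads and inflate the nuclear count (and
vice versa). The threshold is exposed (`mapq_min`, default 30); published
work suggests 20 is already adequate, so the default is conservative.
Single-end data are refused outright: the properly-paired filter would
silently delete every read, which is a configuration problem, not an
empty result.

The nuclear denominator $r_n$ sums primary autosome/sex-chromosome contigs
only. Decoys, unplaced scaffolds and alternate haplotypes (matched by
`nonprimary_contig_regex()`) contribute to neither count. Whether such
contigs belong in $r_n$ is an interpretation — they are excluded here
because the estimator contrasts the mitochondrial genome against the
well-defined diploid nuclear complement.

### The effective-ploidy correction

A bulk tumor sample mixes tumor cells at average ploidy $P$ and fraction
$\rho$ (purity) with diploid stromal/immune cells. Its average nuclear
genome content per cell is $\rho P + (1-\rho) \cdot 2$, so the correction

$$ R = \frac{\rho P + (1-\rho)\,2}{2} $$

rescales the denominator to a diploid standard. At $\rho = 0$ the sample is
pure normal tissue and $R = 1$ for any ploidy; normal tissue and blood are
always $R = 1$. Purity and ploidy are consumed as inputs (e.g. from
allele-specific copy-number callers); tumors lacking them follow a
configurable policy (`error`, the default, or fall back to $R = 1$ with a
warning), because silently mixing corrected and uncorrected tumors is the
worse failure mode. Samples with $r_m = 0$ are flagged and excluded from
all log-scale stages rather than pseudocounted — a zero at realistic depth
indicates capture failure, not an empty cell.

## The plate batch-effect model

Sequencing plates differ systematically in mtDNA yield, most strongly in
exome data where mtDNA coverage is an accident of capture chemistry. Per
cancer type, the observed $\log_{10} m$ values indexed by plate $i$, tissue
class $j$ (tissue-derived vs blood — exactly two classes) and sample $k$
are modelled as

$$ M_{ijk} = \mu + \alpha_i + \beta_j + \epsilon_{ijk} $$

fitted by ordinary least squares. The model is over-parameterized; the
package reports effects under a *sample-size-weighted sum-to-zero*
constraint on both $\alpha$ and $\beta$, chosen so that subtracting
$\hat\alpha$ preserves the cohort mean. Any full-rank coding yields
identical corrected *differences* between samples, which is what every
downstream rank-based statistic consumes; the test suite asserts this
invariance, so the constraint choice is cosmetic by construction.
All logs are base 10 here; only the paired tumor/normal ratio uses base 2.

`correct_copy_number()` subtracts $\hat\alpha_{\text{plate}}$ from WXS
samples only. WGS passes through uncorrected: the batch signal there is
small and inconsistent, and correcting it would mostly inject estimation
noise. The tissue effect $\beta$ is biology, never subtracted. Both raw and
corrected values are always kept. Degenerate designs are handled
explicitly: a single plate forces $\hat\alpha = 0$; a single-sample plate
is estimated but flagged low-confidence; perfect plate–tissue confounding
drops $\beta$ with a warning.

`batch_diagnostics()` reproduces the two screens that justify the
correction: Kruskal–Wallis tests of copy number across plates (blood and
tissue separately), and the Pearson correlation of per-plate mean blood vs
mean tissue copy number — blood and tissue from a patient are often on
different plates, so a positive correlation across plates indicates a
shared plate-level contribution rather than biology. The correlation needs
at least 3 plates with 3 blood and 3 tissue samples each; below that it is
reported as not applicable.

## Paired depletion analysis

For each patient with a tumor and an adjacent-normal sample from the same
center, platform and plate (so the plate effect cancels in the ratio),

$$ r = \log_2 (m_T / m_N). $$

Blood normals are never used — blood mtDNA content differs from solid
tissue for reasons unrelated to the tumor. Patients with several admissible
combinations contribute the lexicographically smallest (tumor, normal) pair,
a deterministic tie-break that is logged. Per cancer type with at least 10
pairs, a two-sided Wilcoxon signed-rank test compares the $r$ values
against zero, with Benjamini–Hochberg correction across the cancer types of
one run (never pooled across pipeline stages). A direction (depleted /
accumulated) is called from the median sign only at $q < 0.05$. The signed
rank test uses the zero-discard convention and the exact distribution for
$n \le 25$ untied values, switching to the normal approximation with
continuity correction above; the exact branch is validated against full
enumeration of sign assignments in the test suite.

## Concordance, covariates, survival

*Platform concordance.* Specimens profiled by both WXS and WGS are matched
on (patient, sample type) and their corrected values compared by Spearman
rank correlation per cancer type (minimum 3 matched samples). Because the
estimate is only relative, rank agreement is the appropriate validation
currency.

*Covariate correlation* (`correlate_covariate()`) is a Spearman screen of
copy number — or the paired log ratio — against any per-sample score, e.g.
immune/stromal infiltration estimates. Its p-values are reported
uncorrected and labelled as such.

*Survival.* Per cancer type, a univariate Cox proportional-hazards model
regresses overall survival on the continuous $\log_{10}$ corrected tumor
copy number; significance comes from the Wald test. The median-split
two-group summary (and `plot_survival_split()`) exists for visualization
only — dichotomizing a continuous predictor discards information, so
inference never uses it. Groups with fewer than 2 events or constant copy
number are marked unestimable rather than fitted.

## Expression association and gene-set enrichment

Genes with mean read count below 16 are removed (a gene at exactly 16 is
kept). With at least 20 overlapping samples — fewer is refused as
underpowered — each gene's expression is Spearman-correlated with copy
number. Correlations with uncorrected $p > 0.05$ are then set to zero.
Zeroing at an uncorrected 0.05 is an unusual guard (it is a hard threshold,
not shrinkage) but is implemented exactly as specified because the
downstream ranking is defined on the thresholded statistic; the threshold
is a parameter (`zero_p`) for users who prefer otherwise.

Gene sets are scored by a mean-rank test: midranks of the thresholded
correlations, set vs complement, via the Wilcoxon rank-sum normal
approximation with the tie correction — the mass of exact zeros created by
thresholding makes proper tie handling essential, and is why the normal
approximation (not an exact rank-sum) is the right tool. Each set is tested
in both directions (two one-sided tests), since positive and negative
enrichment are reported separately; BH correction spans all
(set, direction) pairs within one (study, tissue) run. The reported
enrichment score is $-\log_{10}(q)$ signed by direction. For the "down"
direction the *signed* statistics are ranked with a lower-tail alternative;
ranking absolute values instead would conflate the two tails. The analytic
p-value is validated in the tests against a 10,000-draw permutation
estimate of the mean-rank null and against an independent rank-based
implementation. `single_gene_report()` returns the unthresholded
correlation for a named gene (e.g. TFAM), since the zeroing rule exists
only to stabilize the set-level ranking.

## Somatic alteration association

Mutation carriers are derived from MAF-style calls restricted to
nonsynonymous coding classes (missense, nonsense, frameshift, in-frame
indels, splice site). Samples with more than 600 such mutations are removed
*before* any counting — the order is ambiguous in common practice, so the
choice is recorded in the output attributes — and genes mutated in strictly
more than 4% of the remaining patients are retained, with the denominator
being patients that have any mutation data. CNA carrier sets arrive as a
binary matrix (upstream significance filtering is the caller's
responsibility). Each alteration is tested two-sided by Mann–Whitney U
against non-carriers on corrected tumor copy number, with direction
assigned post hoc from medians; mutations and CNAs form separate BH
families by default (`bh_family = "all"` pools them). A stratification
label can be supplied to compare within strata (values are median-centered
per stratum first), the guard against subtype confounding — e.g. when a
high-CNA subtype itself carries a copy-number phenotype, naïve carrier
tests rediscover the subtype rather than the alteration. `group_compare()`
covers one-off two-group questions (subtype vs rest, mtDNA-variant class vs
unmutated) with the same machinery.

## The synthetic cohort generator

`simulate_cohort()` generates every pipeline input from an explicit
generative model and records all latent parameters, so each stage can be
scored against ground truth. Defaults are chosen to resemble a plausible
solid-tumor cohort:

| parameter | default | rationale |
|---|---|---|
| `mean_copies` | 1000 | typical solid tissues carry ~500–2000 mtDNA copies per cell |
| `sd_patient`, `sd_sample` | 0.20, 0.11 (log10) | between-patient spread dominates; paired log2 ratios get SD ≈ 0.5 |
| `blood_shift` | −0.3 log10 | blood leukocytes carry less mtDNA than solid tissue |
| `plate_sd` | 0.15 log10 | batch shifts of the size that motivate plate correction |
| `capture_wxs`, `capture_wgs` | 0.05, 1 | exome capture recovers mtDNA off-target at a few percent efficiency; WGS is unbiased |
| `nuclear_depth` | 10^6 | enough reads that Poisson noise is secondary to biology, small enough to simulate cheaply |
| purity, ploidy | Beta(6,3); {2,3,4} w.p. (.6,.25,.15) | bulk tumors are mostly 50–85% pure and often aneuploid |

Counts are Poisson (a gamma `overdispersion` knob is available); tumor
reads are generated under the *true* purity/ploidy mixture so the
effective-ploidy correction is genuinely exercised rather than trivially
inverted. One master seed spawns per-stream sub-seeds drawn up front, so
adding a new output stream cannot perturb existing ones and a fixed
(config, seed) pair is exactly reproducible. Planted signals — a depleted
tumor shift in log2, a gene set with expression monotone in copy number, an
alteration that shifts carriers, a survival log-hazard linear in
$\log_{10} m$ — are all optional and default to zero (a global null).

What the generator does **not** emulate: real genome sequence (BAM fixtures
from `generate_bam_fixture()` are minimal valid files, not realistic
reads), GC or capture-probe coverage structure, contamination or sample
swaps, negative-binomial expression dispersion (expression noise is
Poisson–lognormal), or correlated gene–gene structure beyond the planted
sets. Passing tests therefore demonstrate that the estimators and tests
recover the *statistical* structure they target at realistic effect sizes
and depths — not that any particular real cohort is free of artifacts the
generator does not model.

## Numerical choices and degenerate inputs

- Exact null distributions are used for the Wilcoxon signed-rank
  ($n \le 25$, no ties/zeros) and Mann–Whitney (total $n \le 50$, no ties)
  tests, otherwise normal approximations with continuity correction.
- Spearman p-values use the $t$ approximation throughout (the estimator is
  validated against `cor.test` in the tests); $|\rho| = 1$ reports $p = 0$.
- Ties everywhere are handled by midranks; the mean-rank test includes the
  tie term in its variance.
- Degenerate inputs fail loudly and specifically: $r_n = 0$, constant
  covariates, one-level groups, sets covering the whole universe, unknown
  plates at correction time. Quantities that cannot be estimated are
  *flagged* (untestable/unestimable) rather than dropped silently.

## Simulation sizes in the test suite

The packaged tests use 200 replicates for plate-effect recovery, 20
replicates each for the survival-coefficient, planted-gene-set and planted-
alteration power checks (with >90% detection thresholds), and 1000
replicates for the global-null type-I calibration of the four inferential
stages (acceptance band: the binomial 95% interval around 5%). These sizes
are the package's own trade-off between Monte-Carlo resolution and a test
suite that runs in minutes; all loops are seeded and deterministic.

## Known limitations

- $m$ is relative; absolute copies-per-cell would require calibration
  against the platform's mtDNA capture efficiency, which is out of scope.
- The plate model is plain least squares with no shrinkage; very small
  plates get noisy effect estimates (flagged, not shrunk).
- Survival models are strictly univariate; stage/grade confounding is the
  user's to address.
- The purity/ploidy correction assumes a two-population mixture (tumor at
  ploidy $P$, diploid everything else); focal amplifications near NUMTs or
  non-diploid infiltrate violate it.
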