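---
title: "Mapping metabolite QTL in a two-parent RIL panel: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping metabolite QTL in a two-parent RIL panel: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metaboqtl` implements the quantitative-genetic analysis of targeted
metabolomics (fatty-acid and amino-acid panels) measured across a
recombinant inbred line (RIL) population derived from two inbred
parents, here labelled N2 and CB (the *C. elegans* N2 x CB4856 cross is
the motivating design). This vignette explains the statistical models,
the meaning and defaults of every tunable parameter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions made where the methodology left genuine freedom.

## The data and its normalization

The raw input is a long table of per-sample concentrations
(nmol/mg protein) with strain, batch and replicate labels, and a
metabolite class (`FA` or `AA`). The normalization chain runs in a
fixed order:

1. **Detection limits.** Concentrations strictly below the limit of
   quantification are unreliable and become missing: 0.03 nmol/mg for
   FAs, 0.4 nmol/mg for AAs. Boundary values are kept; "below" is read
   as a strict inequality.
2. **Detection filter.** Only metabolites detected in strictly more
   than `min_samples` samples (default 100) are carried into
   heritability estimation and mapping.
3. **Composition ratios.** Because both panels are measured on the
   same homogenate, each concentration is expressed as the fraction
   \(R_{x,i} = M_{x,i} / \sum_i M_{x}\) of its own class within the
   sample. Removed (below-LOQ) values are treated as *absent* from the
   class total, not as zeros; the alternative reading would shrink all
   fractions in samples with many censored values.
4. **Batch correction.** Per metabolite,
   \(R^{cor}_{x,i} = R_{x,i} - (\bar R_{batch} - \bar R_{total})\),
   which equalizes every batch mean to the grand mean and removes any
   additive batch offset exactly. The same formula is applied to the
   untransformed concentrations when absolute fold-differences between
   extreme strains are evaluated.
5. **z-scores.** \(Z_{x,i} = (R^{cor}_{x,i} - \mu_i)/\sigma_i\). The
   sample standard deviation (n − 1) is used; the methodology does not
   specify the denominator and the unbiased choice is conventional. A
   `sd_type = "population"` switch is provided. Metabolites with zero
   variance are dropped: a constant trait carries no mappable
   variation.
6. **Outlier removal.** Within each (strain, metabolite), replicate
   values strictly outside \(\mu \pm 2\sigma\) of that strain's
   replicates become missing. Both moments include the candidate
   point; a consequence worth knowing is that with fewer than six
   replicates no point can ever exceed 2 sample SDs
   (\(\max_i |x_i - \bar x| / s \le (n-1)/\sqrt n\)), so the rule only
   bites on well-replicated strains — parents in the reference design.
   Strains with fewer than three replicates are skipped outright since
   \(\sigma\) is degenerate there.
7. **Strain means.** The per-strain mean z-score is the mapping
   phenotype; replicate counts are kept alongside.

Missing values are excluded from every mean and SD and never imputed.
The chain is deterministic: identical input produces an identical
trait table.

## Transgression, heritability, correlation

**Transgressive segregation.** Parental means \(\mu_{N2}, \mu_{CB}\)
and the pooled SD \(\sigma = \sqrt{(\sigma_{N2}^2 + \sigma_{CB}^2)/2}\)
(unweighted mean of the two variances; a df-weighted pool is a
reasonable alternative and the choice is exposed) define the envelope
\([\mu_{low} - 2\sigma, \mu_{high} + 2\sigma]\). The statistic is the
number of RIL strain means strictly beyond the envelope. Significance
comes from permuting trait values over the strain designations
(parents and RILs jointly) 1000 times; the FDR = 0.05 cutoff is the
50th highest null count, scaling as \(\lceil 0.05\,n_{perm}\rceil\) for
other permutation numbers. The null is heavy-tailed: pseudo-parents
drawn from the genetically dispersed pool occasionally have a tiny
estimated \(\sigma\) and hence huge counts, which makes the test
conservative for moderate architectures.

**Broad-sense heritability.** For the replicated subset (51 strains
with \(n \ge 3\) in the reference design), a one-way ANOVA over
strains gives \(V_{res} = MS_{within}\) and
\(V_{strain} = \max(0, (MS_{between} - MS_{within})/\bar n)\) with the
unbalanced-design effective replicate number
\(\bar n = (N - \sum n_i^2/N)/(k-1)\). Then
\(H^2 = V_{strain}/(V_{strain} + V_{res})\), clipped to \([0,1]\).
Expected-mean-squares components are the default because the simpler
between/total sum-of-squares ratio overestimates \(H^2\) under
replication; both are available (`method = "ems"` / `"ss"`).
Permutation FDR as above.

**Parental heritability.** From the two parental strains
(\(n = 11\) each in the reference design),
\(h^2_P = 0.5\,V_{parent}/(0.5\,V_{parent} + V_{res})\); the factor
0.5 corrects the overestimation of additive variance between inbred
lines. \(V_{parent}\) is defined as the *population* variance of the
two parental genotype effects — \(d^2/4\) for a parental mean
difference \(d\) — i.e. the genotypic variance a balanced segregant
population of those alleles would show. The expected-mean-squares
component with its \(k-1\) divisor would instead converge to
\(d^2/2\) and break the closed form
\(h^2_P = 0.5(d^2/4)/(0.5(d^2/4)+1)\) that the estimator is checked
against.

**Correlation.** Pairwise-complete Pearson correlation between strain
means, FAs and AAs independently; cells with fewer than three complete
pairs are reported missing.

## Genome scans

**Single-marker model.** Per metabolite and marker,
\(Z_{i,j} = x_j + e_j\) with the biallelic genotype as the single
predictor — numerically identical to the pooled-variance two-sample
t-test between allele groups (the F-test of the one-predictor ANOVA is
the square of the same t). Effects are reported as CB-group mean minus
N2-group mean, so a positive effect means the CB allele raises the
trait. Strains missing the trait or the genotype are dropped pairwise
per marker; monomorphic markers yield missing results; −log10(p) is
capped at 300 to avoid underflow artifacts.

**Genome-wide threshold.** Each metabolite's trait values are permuted
over strains (genotypes are never shuffled) and the scan repeated over
100 permuted panels. For candidate thresholds \(t\) on a 0.1-step
grid, \(RDS(t)\) counts metabolites with at least one real marker
above \(t\) and \(FDS(t)\) is the mean of the same count over
permutations. The threshold is the smallest \(t\) with
\[
FDS(t)/RDS(t) \le (m_0/m)\, q \log(m), \qquad m_0 = m - RDS(t),
\]
the multiple-testing-under-dependency bound with \(q = 0.05\) and
\(m\) the number of metabolites. \(\log\) is taken as the natural
logarithm — the dependency correction constant
\(\sum_{i=1}^m 1/i \approx \ln m + \gamma\) is the origin of the term
and the base is not otherwise pinned down. Counting discoveries per
metabolite (not per marker) follows from \(m_0\) being defined as
\(m - RDS\) in units of metabolites. On the reference panel this
procedure yields 3.7, which is also the default when permutations are
skipped (`n_perm = 0`).

**Peaks and intervals.** Per metabolite and chromosome, the marker
with the highest −log10(p) (leftmost on ties) is a peak if above the
threshold; its confidence interval is the maximal contiguous marker
run around the peak staying strictly above peak − 1.5, truncated at
chromosome ends, reported as the bp positions of the run's flanking
markers.

**Multi-marker model.** Up to three peak markers enter jointly,
\(Z = x_1 + \dots + x_n + e\), to check that multiple peaks are not a
linkage artifact; duplicated genotype columns are dropped with a
warning.

**Two-locus interaction scan.** For every pair more than 50 markers
apart or on different chromosomes,
\(Z = x_1 + x_2 + x_1 x_2 + e\). In the saturated two-way binary
layout the interaction t-test is the contrast
\(m_{11} - m_{10} - m_{01} + m_{00}\) against the pooled within-cell
variance, which is how the scan is vectorized (a handful of
marker-by-marker cross-products per trait instead of millions of
`lm()` calls). Pairs with fewer than 5 strains in any genotype class
are skipped. P-values are Benjamini–Hochberg adjusted across all
eligible (pair, metabolite) tests — `p.adjust` with the BH method,
the standard FDR family — and pairs with \(q < 0.1\) are reported.
For traits with a significant pair, sequential ANOVA of the full model
decomposes variance into additive and interaction fractions. Under
linkage disequilibrium false rejections arrive in correlated clusters,
so the FDR guarantee is on the family-level rate, not on the expected
count of pairs.

## Power analysis

One additive QTL at a time is planted on the genetic map with
allele-effect difference \(a = 2\sigma\sqrt{R^2/(1-R^2)}\) (so 50%
explained variance corresponds to a group-mean difference of two
residual SDs) and standard-normal residuals; the trait is scanned and
classified at the genome-wide threshold. The reference design plants
10 replicates per marker across \(R^2 = 0.05, \dots, 0.80\) in steps
of 0.05. "Correctly detected" is operationalized as the true marker
lying inside the 1.5-drop confidence interval of a peak exceeding the
threshold; the counting of categories does not itself define a
containment rule, so this natural rule is the default and
`detect_rule` offers exact-marker and same-chromosome alternatives.
Significant peaks whose interval does not contain the true marker are
counted as false positives, both per scan and per chromosome (the two
counters answer slightly different questions and both are emitted).
Effect-size recovery is recorded at the peak marker, location error in
both bp and marker indices. Marker-level power agrees with the
normal-approximation closed form
\(\Phi(\sqrt{nR^2/(1-R^2)} - z_{\alpha/2})\) to within Monte-Carlo
error; CI-containment power at \(R^2 = 0.10\), \(n = 199\) and
threshold 3.7 is ≈ 0.80.

## Introgression-line confirmation

Each IL is compared to its genetic-background parent with a one-sided
equal-variance Student's t-test in the direction implied by the RIL
mQTL effect sign and the introgression's allele; BH correction runs
across the ILs tested together for one locus (the correction family is
configurable — the natural alternatives are per-experiment or
per-metabolite families). An IL confirms when \(q < 0.05\) *and* the
observed shift matches the tested direction. The narrowed region is
the intersection of confirming introgressions minus the union of
non-confirming ones on the QTL chromosome; a non-confirming IL only
excludes its own introgressed segment, since a non-significant result
localizes the absence of the allele effect nowhere else. Candidate
genes supplied as a user table (no database access) are filtered to
the region and ranked: high-impact coding before regulatory before
low-impact coding, lipid-metabolism or transcription-factor tags
before others, then position for a stable order.

## The synthetic-data generator

The generator exists so every stage has a no-download test surface and
defines the study conditions the tests run under:

* **Map:** six chromosomes with *C. elegans* physical lengths, 729
  markers allocated proportionally and evenly spaced.
* **Genotypes:** per strain and chromosome a two-state Markov chain —
  first marker Bernoulli(0.5), then a parental-origin flip with
  probability `switch_prob` per interval (default 0.03, chosen to give
  realistic RIL block structure and LD decay; exposed in the config).
  This is a Haldane-like no-interference model; no genetic-map
  distances are modelled because the downstream statistics only need
  realistic LD.
* **Replication:** the reference design — parents n = 7 (n = 11 for
  the parental-heritability experiments), 7 RILs x5, 44 x4, 27 x2,
  121 x1, with the 51 strains at n ≥ 3 forming the heritability
  subset — scaled proportionally for smaller panels.
* **Batches:** six by default (five primary growth batches plus one
  replication batch) with additive per-batch offsets; a round-robin
  assignment is available for balanced designs.
* **Effects:** additive QTL contribute \(\pm a/2\) per allele with
  \(a\) from the variance-fraction algebra above (balanced allele
  frequencies assumed); epistatic effects use centred product coding
  \(u_1 u_2/2\), \(u = 2x - 1\), calibrated by the same algebra. A
  positive baseline (default 10) keeps emitted "concentrations"
  non-negative and above the LOQ cutoffs unless a test deliberately
  lowers it.

What it does **not** emulate: mass-spectrometry measurement error
structure, internal-standard calibration, protein-content
normalization, censoring correlated with abundance, non-Gaussian
residuals, or genotyping error. Passing tests therefore demonstrate
the statistical machinery under the stated model, not robustness to
instrument pathology.

## Problem sizes and numerical notes

The test suite runs its simulation checks at deliberately chosen desk
scales: 500 power replicates at \(R^2 = 0.10\) (the boundary claim
gets a two-standard-error binomial margin), 200 replicates for
effect-size and heritability recovery, 100 replicates for epistasis
recovery, 20 null panels of 56 traits for threshold calibration, and
500 replicates for the IL null. Quantities with exact algebraic
expectations (ratio sums, batch-mean equalization, z-score moments,
round-trips) are checked to 1e-10 or tighter.

Tie-breaks are deterministic (leftmost maximum); −log10(p) is capped
at 300; negative variance components truncate at zero; monomorphic
markers, constant metabolites, zero class totals and degenerate
parental replication all degrade to missing values with messages
rather than errors. File coordinates are 1-based inclusive bp,
converted to half-open intervals internally and back on write; allele
codes on disk are `N2`/`CB`/`NA`, internally 0/1/`NA`.

## Interfaces

The package's surface is its exported functions; `run_pipeline()`
chains the stages under a single flat-key configuration
(`pipeline_config()`, optionally read from YAML) with every default
equal to the reference values, writes all result TSVs with provenance
headers, and emits a machine-readable run manifest. An R script over
these functions (see `scripts/acceptance.R` for the pattern) is the
intended batch entry point; no separate shell tool is shipped.

## Known limitations

* No kinship or mixed-model correction: RIL panels with balanced
  mosaic genomes rarely need it, but related designs would.
* No interval mapping between markers; the scan tests observed
  markers only.
* The permutation threshold is calibrated per panel; transferring the
  default 3.7 to a different map, population size or trait count is
  an approximation.
* The interaction scan's pooled-variance t assumes homoscedastic
  cells; a strong additive QTL partially correlated with both tested
  markers makes rejections arrive in LD clusters.
* With fewer than six replicates the per-strain outlier rule cannot
  remove anything; this mirrors its defining formula rather than a
  defect, but users expecting aggressive trimming should know.
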