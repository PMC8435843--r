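---
title: "Methods: quantifying a domestication bottleneck from transcriptome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying a domestication bottleneck from transcriptome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

wildcrop implements a comparative analysis of a domesticated crop and its
wild progenitor from transcriptome data of the two pools: per-gene
nucleotide-diversity statistics from coding-sequence genotype alignments,
negative-binomial differential expression and expression-diversity (CV)
analysis from read counts, a diversity-matched resampling test linking the
two views, and signed weighted co-expression modules. This vignette explains
the statistical model behind each stage, the defaults and why they were
chosen, what the synthetic-data generator does and does not emulate, and the
numerical decisions a user auditing results should know about.

## The scientific setting

A domestication bottleneck removes genetic diversity genome-wide: the crop
carries a subsample of the wild gene pool. Against that genome-wide
baseline, individual genes can depart in ways that indicate selection: a
gene monomorphic in the crop but polymorphic in the wild is a selective
sweep candidate; a gene whose crop/wild diversity ratio exceeds 1 suggests
balancing or diversifying selection or relaxed constraint. Expression adds
a second axis: domestication can shift mean expression (differential
expression between pools) and shrink expression variability (the
coefficient of variation across accessions), and the two need not co-occur
with nucleotide divergence — a gene can diverge in regulation while its
coding sequence stays undifferentiated.

The design assumes two pools of inbred-ish diploid accessions (defaults: 9
wild, 11 domesticated), one pooled RNA profile per accession, and per-gene
coding-sequence genotypes callable for most accessions.

## Population-genetic statistics (`popgen_stats`, `pairwise_stats`)

**Site filter.** Positions called in fewer than `min_called = 5` individuals
in either pool are removed; because downstream synonymous/nonsynonymous
analysis needs an intact reading frame, the whole codon containing a removed
position is dropped and the callable length recomputed.

**Nucleotide diversity.** Per-site pi uses the unbiased pairwise estimator
`(1 - sum p_a^2) * n/(n-1)` with `n` the called haplotypes at the site,
averaged over the callable length; it equals the mean pairwise Hamming
distance per site (the test suite checks this identity exactly against a
brute-force pair count).

**piS and piN.** Nei–Gojobori site counting with the universal code: per
codon position, the synonymous site fraction is the proportion of the three
possible changes that preserve the amino acid; changes creating stop codons
count as nonsynonymous so that synonymous + nonsynonymous sites sum to
exactly 3 per codon. Pairwise differences at multi-hit codons average over
the orderings of the changes, excluding orderings that pass through a stop
codon (if all do, all orderings are used). Codons with missing data are
skipped for the affected haplotypes. `piN/piS` is undefined when `piS = 0`.

**Tajima's D.** The standard normalization
`D = (kbar - S/a1) / sqrt(e1 S + e2 S (S-1))`. Under missing data the
sample size `n` entering the constants is the median per-site called
haplotype count at segregating sites, and `kbar` is the per-site pi summed
over the filtered callable length. This choice is checked against
complete-data evaluation in the tests; D is undefined at `S = 0`.

**Inbreeding coefficient.** `F = 1 - H_obs/H_exp` aggregated as a ratio of
sums over polymorphic sites (per pool, across genes), with the unbiased
`n/(n-1)` expected heterozygosity. Under the selfing model below,
`E[F_hat]` is slightly below the selfing-model f (by a factor of roughly
`(2I - 2)/(2I - 1 - f)` at `I` individuals), visible at small sample sizes.

**F_ST.** The Hudson-style ratio of sums over sites:
`1 - sum(Hw)/sum(Hb)` with `Hw` the mean unbiased within-pool
heterozygosity and `Hb = p1(1-p2) + p2(1-p1)`. We chose the Hudson form for
its robustness at small and unequal sample sizes; negative estimates are
kept (not truncated) so that "F_ST at or below 0" is a meaningful category
for the regulatory-only candidate scan.

**Diversity-ratio classes.** `r = pi_crop/pi_wild` with `0/0` undefined and
`x/0` infinite; classes: `sweep_candidate` (`r = 0`, wild polymorphic),
`reduced` (`0 < r <` baseline), `baseline` (baseline `<= r <= 1`),
`elevated` (`r > 1`). The default baseline of 0.65 is the genome-wide
bottleneck ratio the generator plants and the analysis recovers; on real
data users should set it to their own genome-wide mean. Total pi feeds the
default ratio; piS- and piN-based ratios are also computed so users can
compare all three.

## Expression statistics (`filter_expressed`, `exact_test_de`, `expression_cv`)

Genes are kept when they reach `min_cpm = 1` counts per million (raw
library sizes) in at least `min_accessions = 5` accessions. We use the
permissive at-least-five-accessions reading (rather than "every
accession"): requiring every accession would discard most of a 20-accession
transcriptome; both readings are available via the arguments.

Normalization and testing follow the classic TMM + exact-test pipeline, via
edgeR: trimmed mean of M-values factors (double trim 30%/5%,
precision weights, upper-quartile reference), counts quantile-adjusted to a
common effective library size, a *common* NB dispersion estimated by
conditional maximum likelihood, and the exact conditional test on per-gene
pool totals, two-sided by summing outcome probabilities at or below the
observed one, with Benjamini–Hochberg correction (default FDR 0.01). A
single common dispersion (no tagwise shrinkage) keeps the model minimal;
accuracy is assessed by simulation properties (type-I error, FDR control,
recall), not by reproducing any particular gene list. Note that an exact
conditional test is slightly conservative: under a simulated null its
p-values sit a little above uniform (type-I error ~0.045 at the 0.05
level).

The logFC sign convention is log2(wild/crop): genes downregulated in the
crop have positive logFC.

Expression diversity is the per-pool coefficient of variation (sample
sd/mean) of TMM-normalized CPM; zero-mean genes are flagged undefined. Note
that the sample CV at 9–11 accessions is biased a few percent below the
population CV for skewed count distributions; the bias largely cancels in
the crop/wild ratio.

## The matched-resampling CV test (`matched_resampling_test`)

The question: do highly differentiated genes (F_ST outliers) lose more
expression diversity than expected given that they also tend to have lower
nucleotide diversity? Outliers are genes at or above an F_ST percentile (90,
95, 99). The observed statistic is the mean `CV_wild - CV_crop` over
outliers. Each null resample draws, for every outlier, one non-outlier gene
uniformly among those with equal or lower diversity (`pi` at most the
outlier's, matched per outlier — the stricter, paired reading of
diversity matching); the empirical p-value is `(1 + #{null >= obs})/(B + 1)`
with `B = 1000` draws by default, which can never return 0. Matching uses
the wild-pool total pi by default (configurable). An outlier with no
eligible donor falls back to the nearest-pi donor with a warning. Draws are
reproducible bit-exactly under a seed.

## Joint comparisons

`de_vs_nonde_distributions` summarises piS, piN, piN/piS, Tajima's D, the
diversity ratio and F_ST by DE class (up/down in crop vs non-DE) and runs
two-sample Kolmogorov–Smirnov tests (suppressed below 5 genes per group).
`polymorphism_expression_regression` fits per-pool OLS of log10(pi) on
log10(mean normalized expression) plus a pooled model with a
pool-by-expression interaction F-test; genes with zero polymorphism or
expression are excluded by the log transform, which is worth remembering
when comparing slopes across pools with different zero fractions.
`enrichment_2x2` is Fisher's exact test (two-sided by the point-probability
rule), reporting the Haldane-corrected sample odds ratio alongside the
conditional-MLE estimate. `direction_bias_test` compares the
down-in-crop fraction among DE genes with the whole-set fraction by a 2x2
chi-square (exact binomial below 10 DE genes). `zero_fst_candidates`
returns DE genes with F_ST at or below zero: regulatory-only divergence
candidates.

## Co-expression modules (`coexpression_modules`)

The network is signed: similarity `s = (1 + cor)/2` on log2(CPM + 1)
(Pearson, pairwise-complete), adjacency `a = s^beta` with `beta = 20` by
default; `pick_soft_power` offers scale-free-fit-based selection (smallest
power with signed R^2 of the log-log connectivity fit at or above 0.8) for
users who prefer it. The topological overlap matrix is
`TOM_ij = (sum_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 - a_ij)`, checked in
the tests against an O(n^3) triple-sum oracle at 1e-12.

Module detection clusters `1 - TOM` by average linkage. The cut strategy is
a simplified alternative to the full dynamic tree cut, whose many
heuristics are beyond this package's scope: an initial static cut placed
just below the *background* dissimilarity (the median off-diagonal dissTOM
— with a sparse network almost all pairs are unrelated, so this estimates
the chance level; margin 2%, floor 0.3), followed by recursive re-cutting
of each candidate cluster at its own local background until every cluster's
internal median dissimilarity is clearly below the background (cohesion
fraction 0.9). Sub-minimum fragments become unassigned (label 0); pieces of
one true module that get separated are re-joined by the eigengene-merging
stage. We evaluated and rejected two simpler rules — a cut at a high
quantile of merge heights (average linkage chains the unrelated background
together just below any high quantile, swallowing modules) and a
largest-gap rule on merge heights (fragile when within-module merge heights
spread). The adopted rule recovers planted modules across four regimes
(modules plus background, no background, one all-encompassing module, pure
noise) in the test suite.

Eigengenes are unit-norm first principal components of the
gene-standardized module expression, sign-oriented to correlate positively
with the module mean. Modules whose eigengene dissimilarity `1 - cor` falls
below `merge_height = 0.25` are merged iteratively; final modules are
relabeled by decreasing size (module 1 largest, label 0 unassigned) and
given conventional color names for reporting. Detection is deterministic:
no randomness enters the clustering path. `module_enrichment` applies the
Fisher test per module (BH across modules) and reports each module's mean
expression direction in the crop; `outlier_accession_report` gives each
accession's eigengene z-score within its pool (flag at |z| > 2.5 — note
the within-pool z of one accession is bounded by `(n-1)/sqrt(n)`, so flags
are only attainable in pools of about 8 or more).

## The synthetic-data generator (`sim_params`, `simulate_dataset`)

The generator is first-class, tested code: it produces data with exactly
the marginal structure the analysis assumes, plus a truth ledger, so every
stage is testable end-to-end without external data.

**Genotypes.** Per gene, an ancestral coding sequence without internal
stops; segregating sites drawn with wild-pool counts from the neutral
folded SFS (`P(i)` proportional to `1/i` among `2 x 9` haplotypes), placed
on random haplotype slots — this makes `E[kbar] = S/a1` exact, so neutral
Tajima's D centres at zero by construction. Site positions and derived
bases are weighted so nonsynonymous changes occur at a relative rate that
plants a genome-wide piN/piS of 0.16 under NG86 counting (stop-creating
changes are never introduced; the acceptance weight is rescaled by the
fraction of nonsynonymous opportunity that is stop-free). The crop
bottleneck is per-site lineage thinning: crop frequencies resample `m` of
the realized wild lineages, with `m` solved in closed form from the target
ratio (`(m-1)/m = b * d_wild/d_crop`, `d` the selfing-duplication factor
`(2I-1-f)/(2I-1)`) and randomized between the neighbouring integers so the
expectation is exact; `m` is about 3 at the default ratio 0.65. Because the
crop draw conditions on the realized wild alignment, the per-gene ratio
`pi_crop/pi_wild` is unbiased for the target — mean-of-ratios, not just
ratio-of-means. Swept genes (5% by default) get monomorphic crop
alignments. Selfing is probability-f whole-gene haplotype duplication
within an individual, giving `E[F_hat]` close to f (0.40 recovered at
f = 0.42; the neutral-D property is tested at f = 0 because duplication
shifts mean D upward by about +0.1 at f = 0.42). Genotypes are masked at
random (`missing_rate = 0.05`) to emulate coverage-based call filtering;
`theta_wild` is defined as the *observed* expected pi, with the internal
mutation intensity scaled to compensate the duplication loss.

**Counts.** `NB(mean = lib x q_g x 2^(pool effect), dispersion phi)` with
lognormal baseline abundances, library sizes uniform on 0.5–2 million
(deliberately scaled down from sequencing-scale libraries; every CPM-based
threshold is size-independent). DE genes (4%) get a symmetric pool effect
of 2 log2 units, with exactly 82% down in the crop; 20% of DE genes are
placed on genes from the least-differentiated decile, planting
regulatory-only divergence for the zero-F_ST candidate scan. The crop's
biological CV is shrunk by 0.84 genome-wide, and by a further 19% for the
top 10% most-differentiated genes — together these reproduce an outlier CV
loss near 30% against a genome-wide loss near 16%, and they are what makes
the matched-resampling test's alternative true under defaults. Module genes
(3 modules of 50) share an accession-level lognormal factor carrying a
fraction `module_cor = 0.85` of their biological log-variance, with the
private part shrunk so total variance — hence CV — is unchanged by module
membership.

**Defaults as study conditions.** 9 + 11 accessions; `theta_wild = 0.0016`
(mean pi 1.6 per kb); genes of 500 codons (~1.5 kb coding); bottleneck
0.65; F 0.42/0.99; piN/piS 0.16; 949-in-24,646-scale DE fraction (4%); 82%
down; CV shrink 0.84 (sample CVs ~0.73 wild / ~0.63 crop at
`nb_dispersion = 0.55`). These are the conditions under which the
acceptance battery measures parameter recovery.

**What the generator does not emulate.** No recombination or linkage
(either within or between genes), no indels, no gene flow or post-bottleneck
recovery, a single pooled expression profile per accession (no tissue
structure), no coupling between a gene's expression level and its
polymorphism (the polymorphism~expression regressions therefore recover
slopes near zero on simulated data; the regression machinery itself is
tested on planted-line fixtures), and no shared demographic history beyond
the thinning step.
Consequences worth knowing: mean Hudson F_ST implied by thinning to 65%
diversity is ~0.15–0.2, higher than the weak differentiation reported for
real crop/wild panels whose diversity loss accrued gradually with gene
flow; the fraction of ratio-zero genes (~9% at default gene length) is
smaller than in short-contig real data; expression PC1 explains a few
percent of variance rather than tens. Passing tests therefore demonstrate
correct statistics and faithful parameter recovery under the stated model,
not that real data will show these effect sizes.

## Numerical choices and degenerate inputs

- Empirical p-values use the `(r+1)/(B+1)` estimator and cannot be zero.
- Diversity-ratio class boundaries carry a 1e-9 tolerance so that ratios
  computed in floating point classify as intended at the boundaries.
- A gene losing all sites to the codon-wise filter is flagged, not an
  error; `piN/piS` and Tajima's D propagate `NA` rather than failing.
- PCA mean-imputes missing genotypes, drops constant columns, and fixes
  signs deterministically (largest-|loading| element positive), so repeated
  runs and duplicated samples are reproducible.
- All generator randomness flows from `sim_params(seed)`; the count
  simulator uses `seed + 1` so the two streams are independent;
  `run_pipeline` re-seeds every stochastic stage from the run seed and its
  outputs are byte-identical across reruns with the same configuration.
- Problem sizes used by the tests and the acceptance script — 2,000 genes
  of 500 codons for diversity recovery, 5,000–8,000 genes for error-control
  and DE summaries, 1,000 resamples, networks of up to 2,000 genes — were
  chosen as the smallest sizes at which the recovered quantities are stable
  to within the tolerances asserted.

## Known limitations

- The common-dispersion exact test is mildly conservative and, like the
  original, assumes a single dispersion shared across genes.
- `F_ST` from 9 + 11 accessions is noisy per gene; percentile-based outlier
  sets, not per-gene significance, are the intended use.
- The simplified module cut does not reproduce dynamic-tree-cut label
  boundaries; acceptance is planted-module recovery, and on real data users
  should treat module membership near boundaries as soft.
- The per-gene Tajima's D under heavy missingness uses one median `n`; with
  extremely uneven per-site coverage a site-resolved treatment would
  differ.
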