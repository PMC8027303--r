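---
title: "Methods: simulating admixture and scanning for post-admixture selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating admixture and scanning for post-admixture selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `admixscan`, the parameters a user
can turn, the numerical conventions the implementation commits to, and what
the synthetic cohorts can and cannot tell you about real data.

# The simulation model

## Ancestral panels

`generateAncestralPanels()` draws, for every variant, an ancestral allele
frequency $p$ uniformly from a configurable range (default $(0.05, 0.95)$,
chosen so that simulated panels are polymorphic the way an exome callset
restricted to segregating sites is). Each population's frequency is then a
Balding–Nichols draw, $\mathrm{Beta}$ with mean $p$ and variance
$p(1-p)F$, where $F$ is the population's divergence from the shared
ancestral pool; haplotype alleles are independent Bernoulli draws. $F = 1$
is rejected (the Beta degenerates) and $F < 10^{-12}$ short-circuits to
$p$ exactly. The default $F = 0.15$ per population puts pairwise Fst between
panels in the range typical of continental comparisons; under this model two
populations each at divergence $F$ show pairwise Hudson Fst close to $F$,
which is how the simulator is validated against the estimator.

Sites are drawn independently, so ancestral panels carry **no background
LD**. All long-range haplotype structure in a simulated cohort comes from
the tract mosaic and from finite panel size (two admixed haplotypes that
copy the same panel haplotype over overlapping tracts are locally
identical). This is deliberate: it makes EHH decay interpretable (decay to
the duplicate-copy floor within a handful of informative sites) and keeps
the neutral scan calibratable; it also means simulated EHH curves are not
quantitatively comparable to real exome curves, only qualitatively.

## Variant positions

`simulateExomePositions()` emulates exome sparsity by clustering variants
into "gene" windows (default 25 variants per 20-kb window, windows uniform
on a 200-Mb chromosome) under a uniform genetic map (default 1 cM/Mb, so the
default chromosome is 2 morgans). Haplotype statistics are sensitive to site
density because EHH is truncated by data edges and gaps; a clustered grid
exercises that behaviour in tests. A user-supplied genetic-map table
(`geneticMapInterpolate()`) replaces the uniform map at I/O time.

## The admixed cohort

Each admixed haplotype is a Markov mosaic: recombination breakpoints form a
Poisson process with rate $g$ per morgan ($g$ = generations since the
single-pulse admixture event, default 16 as estimated for the Brazilian
admixture), each tract's ancestry is an independent draw from the mixture
proportions (default EUR/AFR/NAT = 0.746/0.160/0.094, the genome-wide
composition reported for southeastern Brazilian exome cohorts), and alleles
within a tract are copied from one random panel haplotype of that ancestry.
This conditional-independence approximation to the pedigree process is
standard for admixture dating: it reproduces the exponential tract-length
distribution (mean $1/g$ morgans before same-ancestry merging; after
merging, observed runs have mean $1/(g \cdot (1 - \sum_k q_k^2)$-ish, which
the tests account for) while ignoring the correlation between homologous
chromosomes of one individual. Single-pulse is an approximation — the real
admixture was extended in time — and matters mainly for the tract-length
variance, not for the mean proportions the package recovers.

## Sweep injection

`injectAncestrySweep()` raises one ancestry's proportion inside a region to
a target by resampling whole non-target tract segments from the target
panel. Runs are visited in random order and converted until a quota —
`round(target × cells) − current` labelled cells — is met, splitting the
last run at a variant boundary. The quota design makes the *realised*
regional proportion equal the target up to rounding (a per-run Bernoulli
scheme reaches it only in expectation, with substantial variance when a
3.7-Mb region holds a single tract per haplotype). Because replacement
copies whole segments from a finite panel, the swept region also gains long
shared haplotypes, which is what gives the EHH family of statistics
something to detect. Variants outside the region are untouched (a tested
locality contract), and lowering a proportion is refused as unsupported.

## QC defects

`corruptForQc()` embeds exactly the requested defects — duplicated
individuals, an individual heterozygous at every site, per-variant
missingness masks, strand-ambiguous allele rewrites, all-heterozygous
(Hardy–Weinberg-violating) variants — and ledgers each one, so the QC
filters are validated against known truth rather than against themselves.

# QC conventions

Boundary rules follow the stated inequalities: missingness removal is
strictly `> 0.10`, MAF removal strictly `< 0.01`. Heterozygosity outliers
use a single pass (mean and SD computed once on everybody; no
re-iteration). The Hardy–Weinberg exact test is the conditional test: the
p-value sums the probabilities of heterozygote counts no more probable than
the observed one given the allele counts; monomorphic input returns 1; the
removal threshold defaults to $10^{-6}$, conventional for exome QC (no
published cutoff exists for this pipeline, so it is exposed as a
parameter). The GRM is the average standardised-dosage cross-product
$\frac{1}{m}\sum_j (x_{ij}-2p_j)(x_{kj}-2p_j)/(2p_j(1-p_j))$ with
monomorphic sites excluded and missing entries excluded pairwise.
Relatedness pruning removes, at each step, the individual with the most
relationships above 0.125 (ties: the earliest id), which maximises the kept
sample on the sparse graphs relatedness data produce; tests verify it
attains the exhaustive maximum-independent-set size on small graphs. LD
pruning repeatedly removes, within each 50-variant window (step 5), the
lower-MAF member of the currently worst pair with $r^2 > 0.5$ (ties: the
later position), giving a deterministic kept set.

The pipeline applies filters in the order: ambiguous → biallelic/autosomal
→ HWE → missingness → heterozygosity → relatedness → MAF → LD pruning, and
the `QCReport` ledger records that order with per-step removals; a validity
method enforces `before − removed = after` at every step.

# Population structure

PCA standardises dosages by $\sqrt{2p(1-p)}$, imputes missing entries to
the mean (zero after centring) and eigendecomposes the individual
covariance; coordinates are eigenvectors scaled by the root eigenvalues.

AMOVA is the two-level decomposition on squared Euclidean dosage distances
(the common default; the distance is configurable in the sense that the
function takes any dosage matrix you give it). Sums of squares among and
within groups convert to variance components via the moment estimators
($\sigma^2_w = MS_w$, $\sigma^2_a = (MS_a - MS_w)/n_0$), and
$\phi = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. Two choices are worth
stating. First, a negative among-group component is floored at zero, so
$\phi = 0$ exactly for indistinguishable groups and $\phi \ge 0$ always;
the permutation test is unaffected because the same flooring applies to
every permuted replicate. Second, the permutation p-value uses the add-one
estimator $(1 + \#\{\phi^* \ge \phi\})/(1 + B)$, which cannot return 0 —
with $B = 10^4$ its floor is $10^{-4}$. Within-individual variance is not
modelled as a stratum; the decomposition is two-level and labelled as such.
A random subset of 10,000 variants (seeded) is used by default, matching
how genome-wide AMOVA is usually run.

Inversion-karyotype calling reduces the region's genotypes to the first
metric-MDS axis and fits a three-component 1-D Gaussian mixture
(`mclust`, whose model-based hierarchical initialisation makes the EM
deterministic, so no random restarts are needed). Components ordered by
mean give karyotypes 0/1/2 by maximum posterior. Degeneracy is decided by
BIC: if one component explains the axis at least as well as three, the
region carries no karyotype structure, the fit is flagged and all calls
collapse to the majority. Which extreme cluster is "inverted" is arbitrary
without an external anchor — calls are comparable only through
`callsetAgreement()`, which is also why agreement between two call sets of
the same individuals is the unit this module reports.

# Local ancestry

Per-variant proportions are haplotype counts per label over non-unknown
haplotypes; group summaries average individual haplotype fractions.
Regional deviation is a z-score of the regional mean against the
genome-wide per-variant distribution, flagged at $|z| > 3$ by default — a
conventional outlier threshold, exposed as a parameter, since the deviation
itself is reported qualitatively in the literature. Note that the
genome-wide SD includes the region itself; a sweep occupying a large
fraction of the simulated genome inflates the SD and shrinks its own
z-score, which is why tests and the acceptance analysis use a 3.7-Mb region
on a 200-Mb chromosome, matching the geometry of a real candidate locus.
Segment ancestry in `flankingPatterns()` is the majority vote over the
segment's variant labels; exact ties are labelled "mixed" and excluded from
named patterns, and haplotypes with an empty flank are counted as
unscorable rather than silently dropped. Forward–backward posteriors from a
local-ancestry caller are expected to be collapsed to argmax labels before
import; all summaries here are label-based.

# The selection scan

EHH at distance $x$ from a core is
$\sum_k \binom{n_k}{2} / \binom{n_c}{2}$ over extended-haplotype classes
among the core-allele carriers, computed independently in each direction;
missing alleles break haplotype identity (treated as a third allele state).
iHH integrates the piecewise-linear EHH curve by the trapezoid rule from
the core to the point where the interpolated curve crosses the cutoff
(default 0.05); a curve still above the cutoff at a chromosome edge or at
the extension cap (default 50 cM) is integrated to the edge and flagged
truncated rather than dropped — exome data truncate often, and silently
dropping truncated variants would bias block composition. The bulk scanner
is compiled (Rcpp) and cross-checked against the plain-R curve
implementation and against pair-enumeration oracles in the tests.

Per-variant statistics: iHS is $\ln(iHH_A/iHH_D)$ standardised to mean 0,
SD 1 within derived-allele-frequency bins (default 50 equal-width bins;
bins with fewer than 2 values yield NA); intra-population ΔiHH is
$iHH_D - iHH_A$ standardised the same way; XP-EHH is
$\ln(iHH_{pop A}/iHH_{pop B})$ over all haplotypes per population,
standardised genome-wide; cross-population ΔiHH is the corresponding
difference (the notational ambiguity between a cross-population and a
derived-allele-restricted reading is resolved by implementing both —
`deltaIhhCross(mode = "all" | "derived")` — with the cross-population
reading as default, recorded in the scan manifest); PBS uses per-variant
Hudson ratios with the focal admixed cohort against two reference panels,
clamping Fst at $1 - 10^{-9}$. Without an ancestral-allele table the
reference allele is the ancestral proxy, and the scan manifest records
that decision.

Combination: each statistic maps to a one-sided empirical p-value by ranks,
$p_i = \mathrm{rank\ from\ the\ extreme\ tail}/(n+1)$ with average ranks for
ties — strictly inside $(0,1)$, so $\ln p$ is always finite — where
"extreme" means large $|iHS|$, large $|\Delta iHH|$ (both), large XP-EHH
and large PBS, the directions indicating selection in the focal cohort.
$FCS = -2\sum \ln p_i$ over the statistics available at the variant, with
the per-variant count $k$ reported rather than restricting to
fully-observed variants (the alternative is logged as a design choice; the
default keeps exome variants that lose one statistic to truncation).
Outliers are variants with FCS strictly above the empirical 99th
percentile; chromosomes are split into consecutive 100-variant blocks
(final partial block kept and flagged), and blocks with outlier fraction
strictly above the 99.5th percentile of block fractions are selected —
strict inequalities at both thresholds, matching the "higher than"
definitions, which makes the neutral outlier rate 1% and the selected-block
rate at most 0.5% by construction on distinct values.

# Problem sizes and calibration checks

The test-suite and acceptance analyses run at sizes chosen to make the
statistical checks sharp while staying lightweight: ancestry-recovery on
100 individuals × 20,000 variants (recovery within ±0.015 of the mixture;
the genome-wide mean's standard error at these sizes is ≈ 0.006, so the
band is ≈ 2.5 SE); neutral scan calibration on the same cohort (200 blocks);
sweep power as 20 replicate cohorts of 50 individuals × 6,000 variants with
NAT raised to 0.24 in a 3.7-Mb window, where the deviation z-scores land
between 3.5 and 5.5 and the |z| > 3 flag is expected in at least 18 of 20
replicates; Fst recovery on 5,000 variants × 200 haplotypes at
$F \in \{0.05, 0.1, 0.2\}$ within ±0.02; and oracle equivalence on panels of
at most 8 haplotypes × 12 variants, where exhaustive pair enumeration is
feasible.

# Limitations

* No coalescent genealogy: panel haplotypes are exchangeable Bernoulli
  draws, so site-frequency-spectrum and background-LD features of real data
  are absent, and absolute magnitudes of haplotype statistics do not
  transfer to real cohorts.
* Single-pulse admixture and independence between the two haplotypes of an
  individual.
* No sequencing error, reference bias, phasing error or local-ancestry
  miscall model: the "truth" labels stand in for a caller's output, so
  pipeline behaviour under caller error is untested here.
* The inversion module infers karyotype structure from genotype geometry
  only; exome site density may not support it, and polarity is undefined
  without an external anchor.
* Downsampling an ancestry (a negative sweep) is not implemented.
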