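---
title: "Methods: multi-population mixed-model trait dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-population mixed-model trait dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosspop)
```

crosspop dissects a quantitative trait measured in several related but
distinct populations: per-population mixed-model association, a
sample-size-weighted z-score meta-analysis across populations, and a
haplotype-level follow-up that asks whether the populations share the same
causal chromosomal segment or carry private ones.  This vignette explains
the models, the numerical choices, and what the simulation-based validation
does and does not establish.

## The association model

Within one population the trait is modelled per SNP as

$$ y = x\beta + Zu + e, \qquad
   u \sim \mathrm{MVN}(0, \sigma_a^2 G), \quad
   e \sim \mathrm{MVN}(0, \sigma_e^2 I), $$

where `y` holds phenotypes already corrected for sex and slaughter batch
(`residualize()` removes them by ordinary least squares; the fit tolerates
confounded designs through its pivoting solver), `x` counts copies of the
minor allele (0/1/2), `Z` is the identity, and `G` is the genomic
relationship matrix in its centered-and-scaled form

$$ G = \frac{1}{m}\sum_k \frac{(x_k - 2p_k)(x_k - 2p_k)^\top}{2p_k(1-p_k)}, $$

with missing dosages mean-imputed per marker.  Quality control before any
of this follows the usual chip rules — individual call rate, SNP call rate,
and minor-allele frequency, all strict `>` comparisons (thresholds of 0
disable a rule entirely).

### REML through one spectral decomposition

`reml_fit()` estimates the variance components by restricted maximum
likelihood, profiling out $\sigma_a^2$ and searching over the ratio
$\delta = \sigma_e^2/\sigma_a^2$.  After one eigendecomposition
$G = U\Lambda U^\top$, every likelihood evaluation is $O(n)$ in the rotated
basis, so a dense search is cheap: a 64-point logarithmic grid on
$[10^{-5}, 10^5]$ brackets the optimum, and bounded scalar optimisation
refines it (tolerance $10^{-10}$; a `boundary` flag marks optima at the grid
ends).  The grid-then-refine strategy is deliberate — profiled REML surfaces
on small, strongly structured GRMs can be mildly multimodal, and a pure
local optimiser can stall on the wrong shoulder.  Genomic heritability is
reported as $h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2) = 1/(1+\delta)$.

### The per-SNP test

`lmm_scan()` computes, for every variant, the generalised least squares
estimate $\hat\beta = (x^\top V^{-1}x)^{-1}x^\top V^{-1}y$ with
$V = \hat\sigma_a^2 G + \hat\sigma_e^2 I$, its standard error from the GLS
information matrix, and a two-sided Wald $\chi^2_1$ p-value.  Two variance
component modes are offered: `null_reuse` (default) estimates the
components once under the null and reuses them for every SNP — the fast
approximation popularised by EMMAX — while `per_snp` re-optimises $\delta$
for every marker, which matches what a full per-marker REML fit (GEMMA
style) does at roughly the cost of one extra grid search per SNP.  On null
data the two agree closely; at strongly associated markers `per_snp` is
slightly more conservative.  Wald tests were chosen because the effect and
its standard error are the quantities the downstream meta-analysis and the
reporting tables consume.

Per-variant variance explained is offered both as
$(V_{reduce}-V_{full})/V_{reduce}$ — the residual-variance contrast of
ordinary linear models without and with the genotype — and as the closed
form $2p(1-p)a^2/\sigma_p^2$; on simulated loci the two agree to well
within 0.03 absolute, and the acceptance suite re-verifies that agreement.

### Leads, sentinels, classification

A *lead* variant is the strongest sub-threshold variant
($p < 5\times10^{-8}$, the conventional empirical genome-wide line) per
chromosome and trait, ties broken by position.  One lead per chromosome per
trait is an interpretation choice: the alternative (multiple independent
signals per chromosome) requires conditional analysis that is out of scope
here.  Because correlated traits stack leads in narrow regions, leads
within 1 Mb on a chromosome are merged by single linkage and represented by
their strongest member (*sentinel*).  Single linkage is deliberate — a
chain of sub-1 Mb gaps is one region even when its ends are farther apart.
Against a reference scan (for instance a chip-density analysis), a lead is
*novel* when no same-chromosome reference lead lies within 1 Mb, *enhanced*
when one does but the association strength gained at least 2 units of
$-\log_{10}p$, and *known* otherwise.

## Meta-analysis

`meta_z()` implements the sample-size z-score scheme: per-population
signed scores $z_i = \mathrm{sign}(\beta_i)\,\Phi^{-1}(1-p_i/2)$ combine as

$$ Z = \frac{\sum_i \sqrt{N_i}\, z_i}{\sqrt{\sum_i N_i}}, \qquad
   p = 2\,(1 - \Phi(|Z|)). $$

Before combining, `align_alleles()` harmonises every record to a common
effect allele: swapped effect/other alleles negate the direction,
incompatible allele pairs are excluded (flagged, never silently dropped),
and strand-ambiguous pairs (A/T, C/G) are kept but flagged.  P-values
below `1e-300` are clamped and flagged rather than converted to infinite
scores.  Variants absent from some populations are combined over the
populations that carry them, with a `?` in the direction string; crossing
populations are given their nominal sample size without an effective-size
correction.  The scheme is invariant to population order and to rescaling
all sample sizes, identities the acceptance suite checks to $10^{-10}$.
An inverse-variance scheme was considered and rejected as the default
because the per-population traits are standardised differently; the
z-scheme needs only directions, p-values and sample sizes.

## Haplotype analysis

At a focal lead, `extract_window()` collects the phased haplotypes of the
41 SNPs centered on it (20 each side; windows truncate with a warning at
chromosome ends rather than erroring).  Haplotypes with frequency above
0.05 get their own column of the incidence matrix `H` (copies carried,
0/1/2); everything rarer is pooled into a single `rare` column so that each
row still sums to 2 and no individual is discarded.

The effect model $y = H\beta + Zu + e$ is estimated by whitening: with
$V = \sigma_a^2 G + \sigma_e^2 I$ and $W = V^{1/2}$ obtained from the
eigendecomposition of $V$, the transformed model
$W^{-1}y = (W^{-1}H)\beta + W^{-1}(Zu+e)$ has white residuals and is fit by
ordinary least squares.  As printed, that model has no intercept and rows
of `H` summing to 2, which is perfectly collinear with an intercept; the
package therefore drops the most frequent haplotype as the reference and
fits an intercept, reporting per-copy effects as deviations from the
reference (whose effect is identically 0).  Standard errors use the
whitened residual variance and p-values a t-distribution with
$n - \mathrm{ncol}(design)$ degrees of freedom — the transformed model is
an ordinary regression, so t rather than z is the natural reference
distribution.  Collinear columns (possible when a pooled column duplicates
a retained one) are dropped with a warning.

`shared_segment()` formalises the cross-population comparison: given the
selected haplotypes of several populations over a common position list, it
returns the longest run of consecutive positions at which all of them carry
identical alleles, as a 1-based inclusive interval (leftmost run on ties,
empty when nothing agrees).  In the pipeline the selected haplotypes are
those significant at $\alpha = 0.01$ with the dominant effect sign — the
paper-style selection is narrative, so a reproducible rule had to be fixed;
both the level and the sign constraint are configurable.
`classify_sharing()` labels a haplotype *specific* when it reaches the
presence frequency (default 0.05) in exactly one population and stays below
the absence frequency (default 0.01) everywhere else, *shared* when it
reaches presence in two or more, and *absent* otherwise.

Haplotype trees use plain Hamming distances between allele strings and a
from-scratch Saitou–Nei neighbor joining: Q-matrix agglomeration, standard
branch-length equations, negative branch lengths clamped to zero with a
flag, and ties in Q broken by the smallest pair of original label indices
so that runs are reproducible.  NJ is exact on additive distances, and the
acceptance suite verifies topology and branch lengths are recovered
perfectly on random additive trees; the distance metric is Hamming because
the tree input is binary allele strings, not nucleotide sequences.

## Peak enrichment and candidate genes

BED intervals are converted from 0-based half-open to 1-based inclusive on
read, merged per mark when overlapping or abutting, and queried through an
interval index.  A variant on an interval boundary counts as inside.  Fold
enrichment is the ratio of the lead-set overlap proportion to the
background overlap proportion (all tested SNPs), reported overall — a
variant inside peaks of two marks counts once — and per mark; a zero
background proportion yields a flagged undefined fold rather than an
infinity.  No p-value accompanies the fold by default.  Candidate genes are
those whose annotated span lies within 500 kb of a lead (distance zero
inside the span, boundary inclusive), sorted by distance.

## The synthetic study design

The generator emulates the essential features of a multi-population pig
study without attempting coalescent realism.  An ancestral panel of binary
haplotypes is built from a limited set of deep founders (default 30;
derived-allele frequencies Beta(0.4, 0.4) for a U-shaped frequency
spectrum) expanded by a few generations of random-mating recombination at
`recomb_rate` per adjacent site pair (default 0.003).  Each study
population draws a bottleneck of `drift` founder haplotypes (default 40)
and recombines them into `2n` chromosomes — one parameter thus controls
both differentiation between populations and relatedness within them.
Positions are spaced ~2 kb apart on average, so the default 1500-site panel
spans roughly 3 Mb and the 1 Mb sentinel and novelty distances remain
meaningful.  The limited founder count is what makes 41-SNP window
haplotypes recur at frequencies above the 0.05 reporting floor, as they do
in real livestock data.

Causal haplotypes are planted by overwriting the window alleles of randomly
chosen chromosomes until the target carrier frequency is met (a rejection
cap of 10 times the chromosome count guards infeasible targets); the truth
record keeps the exact carrier list.  Phenotypes are
$y = \mu + \mathrm{sex} + \mathrm{batch} + c\,a + u + e$ with carrier copy
count $c$, per-copy effect $a$, $u \sim \mathrm{MVN}(0, \sigma_a^2 G)$
drawn from the realised GRM with $\sigma_a^2$ set from the heritability
target (default 0.46, a typical genomic heritability for fatty-acid
composition traits), and iid residuals.  Sex and batch act as fixed offsets
of $+1\sigma_e$ for every non-reference level — large enough that skipping
residualization would visibly distort the scan, small enough not to
dominate.

Two desk-scale artefacts deserve explicit mention because they shaped the
defaults:

* **Proximal contamination.**  On a simulated genome of a few thousand
  markers, a planted window is a non-trivial fraction of the GRM; carriers
  then form their own direction in `G` and the mixed model partially
  absorbs the causal effect.  The association fixtures therefore use panels
  of 1200–2000 sites with 7-SNP causal cores (contamination is then mild,
  and the scan keeps the conventional whole-genome GRM), while the
  dedicated haplotype-effect fixtures — whose planted window spans all 41
  SNPs — exclude the focal window from the GRM used both to draw the
  polygenic background and to whiten.  That leave-locus-out choice emulates
  genome-scale data, where one window contributes negligibly to `G`.
* **Relatedness costs power.**  With strong bottlenecks the GLS information
  at a random marker is well below the independent-sample value; the
  default effect sizes (variance explained roughly 10–25%) sit inside the
  range reported for major fatty-acid loci and were chosen so the planted
  loci are detectable at genome-wide stringency under those conditions.

What passing the simulation suite shows: the estimators are unbiased under
the generator's assumptions, type-I error is controlled under a polygenic
null, the meta-analysis gains power at loci shared across populations, and
the haplotype machinery localises planted segments exactly.  What it cannot
show: robustness to phasing error, imputation artefacts, genotyping batch
effects, selection, or trait distributions far from Gaussian — none of
which the generator emulates.

## Pipeline and problem sizes

`run_full_pipeline()` chains simulate → per-population GWAS → meta →
haplotype follow-up (at the strongest meta lead) → enrichment, writing
plain TSV/VCF/YAML artifacts plus a manifest carrying the package version,
seed, configuration and its hash.  Seeds are mandatory for simulation;
rerunning a configuration reproduces the association tables bit for bit.
The default design uses six populations of 591, 296, 608, 305, 331 and 315
individuals — unequal sizes in the 300–600 range — with one haplotype
shared by three populations and one private to a fifth.  The test suite
runs a four-population scaled-down design (220–320 individuals, 800 sites)
so the whole suite stays interactive; the acceptance checks use the sizes
stated above for each quantity (for example, heritability recovery at
n = 500 over 50 replicates).  The thin command-line wrapper in
`inst/cli/crosspop` exposes the same stages as subcommands; the R
functions are the primary interface.
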