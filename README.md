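# crosspop

Dissecting quantitative traits across several related populations: mixed-model
GWAS within each population, sample-size-weighted z-score meta-analysis across
them, and haplotype-level follow-up that distinguishes causal segments shared
between populations from segments private to one.

The package is aimed at quantitative and livestock geneticists who have phased
genotypes and phenotypes for two or more populations (different breeds,
crosses, or cohorts) and want to run the complete loop — variance components,
association, meta-analysis, lead/sentinel calling, haplotype effects, shared
segment detection, haplotype trees, and regulatory-peak enrichment — as
reproducible, seedable R functions.  A built-in multi-population simulator
with planted causal haplotypes provides ground-truthed data for validating
every stage.

## The models

Per-population association uses the standard single-SNP mixed model

    y = xβ + Zu + e,   u ~ MVN(0, σ²ₐG),   e ~ MVN(0, σ²ₑI)

with minor-allele dosage coding (0/1/2), a centered-and-scaled genomic
relationship matrix G, and REML variance components obtained through a single
spectral decomposition of G (each likelihood evaluation is O(n) in the rotated
basis).  Per-SNP tests are GLS Wald tests; variance components are reused from
the null model by default or refit per SNP.

Populations are combined METAL-style: zᵢ = sign(βᵢ)·Φ⁻¹(1−pᵢ/2) weighted as
Z = Σ√Nᵢzᵢ/√ΣNᵢ after harmonising all records to a common effect allele.

Haplotype effects over 41-SNP windows centered on a lead come from the
whitened model W⁻¹y = (W⁻¹H)β + W⁻¹(Zu+e), where H counts haplotype copies,
V = σ²ₐG + σ²ₑI and W = V^1/2 via eigendecomposition; after whitening the fit
is ordinary least squares with the most frequent haplotype as reference.
Cross-population shared segments are the longest run of window positions at
which the selected haplotypes agree exactly; haplotype trees are Saitou–Nei
neighbor joining on Hamming distances.

## A worked example

Simulate three populations that share one trait-decreasing causal haplotype,
scan each, and combine:

```r
library(crosspop)

panel <- simulate_panel(l_sites = 800, n_pool = 120, seed = 1)
pops <- list(
  PopA = sample_population(panel, "PopA", 260, drift = 30, seed = 11),
  PopB = sample_population(panel, "PopB", 220, drift = 30, seed = 12),
  PopC = sample_population(panel, "PopC", 240, drift = 30, seed = 13))

w <- panel$positions[c(237, 243)]            # 7-SNP causal core
planted <- plant_causal_haplotype(
  pops, w[1], w[2], distinct_window_string(panel, w[1], w[2]),
  frequency = c(PopA = 0.3, PopB = 0.3, PopC = 0.3),
  effect = -1.0, h2 = 0.46, seed = 2)        # planted at 441,677-453,874 bp

scans <- lapply(planted$pops, function(pop) {
  pheno <- simulate_phenotypes(pop, planted$truth, seed = 3) |> residualize()
  geno  <- qc_filter(as_geno_matrix(pop))    # call rate > 90%, MAF > 5%
  grm   <- compute_grm(geno)
  vc    <- reml_fit(pheno$resid, grm)        # h2-hat: 0.491 / 0.502 / 0.508
  lmm_scan(pheno$resid, geno, G = grm, vc = vc,
           trait = "trait", population = pop$name)
})

res <- meta_scan(scans, threshold = 5e-8)
res$leads
#> # A tibble: 1 x 7
#>      pos     Z        p n_total direction best_single_log10p meta_log10p
#>    <int> <dbl>    <dbl>   <int> <chr>                  <dbl>       <dbl>
#> 1 445036 -7.76 8.21e-15     720 ---                     5.55        14.1
```

The meta-analysis lead sits inside the planted window (441,677–453,874 bp),
its direction string shows a consistent trait-decreasing effect in all three
populations (`---`), and combining raises the association strength from a
best single-population −log₁₀p of 5.5 (sub-threshold) to 14.1 — the typical
signature of a shared causal variant.  From here, `extract_window()`,
`build_incidence()` and `estimate_haplotype_effects()` quantify per-haplotype
effects, `shared_segment()` reports the exact interval the significant
haplotypes share, and `neighbor_joining()` draws their tree.

The whole loop is also available as one call:

```r
cfg <- run_config(out_dir = "run1", seed = 7)   # six-population default design
run_full_pipeline(cfg)
summarize_run("run1")
```

or from a shell via the thin wrapper `inst/cli/crosspop`
(`simulate | gwas | meta | haplo | enrich | all | summarize`).

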