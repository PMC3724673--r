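# codonbias

Genome-wide amino acid and codon usage bias, relative entropy against the
zeroth-order null, and hierarchical mixed-model regression for microbial
genomes.

## The problem

Prokaryotic base composition spans roughly 25–86% A+T, and because most
of a microbial genome codes for protein, that gradient propagates into
codon and amino-acid usage. For a cohort of genomes — each supplied as a
multi-FASTA of coding sequences or a GenBank flat file, plus a
phylum/genus/species/strain taxonomy — this package computes per-genome
composition profiles and three statistics:

- **AAUB** (amino acid usage bias): the sample standard deviation of the
  20 amino-acid frequencies, `sqrt(sum((x_i - 1/n)^2) / (n - 1))` with
  `n = 20`. High values mean a few residues dominate.
- **CUB** (codon usage bias): the same statistic over the 64 codon
  frequencies (`n = 64`). This is a dispersion measure, not a codon
  adaptation index.
- **KL** (relative entropy, bits): the Kullback–Leibler divergence of
  observed codon frequencies `F(XYZ)` from the factorized expectation
  `F(X)F(Y)F(Z)` built from genomic base frequencies,
  `KL = Σ F(XYZ) · log2(F(XYZ) / (F(X)F(Y)F(Z)))`.
  KL = 0 when codons look like independent draws of single bases.

Downstream it provides correlation-matrix PCA and complete-linkage
(Euclidean) clustering of frequency matrices, OLS of %AT on the 64 codon
frequencies, a phylum ANOVA of AAUB, penalized-spline GAMs, and GAMMs with
nested phylum/genus/species random intercepts and %AT random slopes,
compared by ML-based AIC. A synthetic-cohort generator with a tunable
exponential codon tilt (closed-form KL) makes every stage testable without
downloading genomes. It is aimed at comparative genomicists studying
base-composition evolution, and at anyone needing a reproducible
composition-profiling pipeline.

## Worked example

Simulate a cohort of 180 genomes (15 phyla × 4 genera × 3 species, %AT
gradient 0.25–0.86, codon tilt decreasing with %AT), profile it, and run
the core analyses:

```r
library(codonbias)

cfg <- cohort_config(n_phyla = 15, genera_per_phylum = 4, species_per_genus = 3,
                     n_codons_per_genome = 5000, seed = 42)
sim <- simulate_cohort(cfg)
profiles <- profile_cohort(sim$sequences)
profiles[1:3, c("genome_id", "at_fraction", "aaub", "cub", "kl")]
#> # A tibble: 3 × 5
#>   genome_id            at_fraction   aaub    cub      kl
#>   <chr>                      <dbl>  <dbl>  <dbl>   <dbl>
#> 1 Phylum01_G01_S01_T01       0.833 0.0487 0.0223 0.0135
#> 2 Phylum01_G01_S02_T01       0.859 0.0536 0.0248 0.0103
#> 3 Phylum01_G01_S03_T01       0.835 0.0489 0.0226 0.00812
```

These AT-rich genomes have low KL: their codon usage is close to what base
composition alone predicts. PCA of the amino-acid frequencies shows the
%AT gradient dominating the proteome:

```r
aa <- as.matrix(profiles[, grep("^aa_", names(profiles))])
rownames(aa) <- profiles$genome_id
pca <- pca_correlation(aa, at = profiles$at_fraction)
pca
#> Correlation-matrix PCA: 180 genomes, 20 categories
#> Variance explained (%): 58.5, 27.7, 2.7, 2.2, 1.9 ...
regress_component_on_covariate(pca$scores$PC1, profiles$at_fraction)
#> # A tibble: 1 × 4
#>   r_squared   p_value    df     n
#>       <dbl>     <dbl> <dbl> <int>
#> 1     0.985 3.08e-165     1   180
```

The first component explains 58% of the variance and tracks genomic %AT
almost perfectly (R² = 0.985). The KL mixed model — KL as response, a
spline of %AT, AAUB as a linear term, and nested random intercepts and
%AT slopes for phylum/genus/species — shows relative entropy rising with
amino-acid bias, and the random effects earn their AIC cost:

```r
fit <- fit_kl_gamm(profiles, sim$taxonomy)
tidy(fit)[, c("term", "estimate", "std_error", "p_value", "type")]
#> # A tibble: 3 × 5
#>   term           estimate std_error  p_value type
#>   <chr>             <dbl>     <dbl>    <dbl> <chr>
#> 1 (Intercept)      -0.214    0.0118 1.58e-41 parametric
#> 2 aaub              6.04     0.254  5.53e-56 parametric
#> 3 s(at_fraction)   NA       NA      0        smooth

compare_aic(fit_kl_gamm(profiles, sim$taxonomy, method = "ML"),
            fit_gam(profiles, "kl", smooth_terms = "at_fraction",
                    linear_terms = "aaub", method = "ML"),
            c("random_effects", "fixed_only"))
#> # A tibble: 1 × 4
#>   preferred      delta_aic  aic_a  aic_b
#>   <chr>              <dbl>  <dbl>  <dbl>
#> 1 random_effects     -31.1 -1279. -1248.
```

The AAUB coefficient is positive (6.04 ± 0.25, p < 1e-55): genomes whose
codon usage departs further from the factorized null also use amino acids
more unevenly, after adjusting for %AT and taxonomy. `autoplot(fit)`
draws the fitted %AT smooth with its 2-standard-error band;
`cluster_genomes()` + `export_heatmap_inputs()` produce plot-ready
heatmap tables, and `dendrogram_newick()` exports the clustering.

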