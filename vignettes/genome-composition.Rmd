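---
title: "Composition bias, relative entropy and hierarchical regression in microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition bias, relative entropy and hierarchical regression in microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The model

Prokaryotic genomes span an enormous base-composition gradient — roughly
25% to 86% A+T — and that gradient reshapes the proteome, because codons
and therefore amino acids are drawn from the same mutating DNA. This
package quantifies three per-genome statistics on coding sequences and
then asks how they relate across a taxonomically structured cohort:

* **AAUB**, amino acid usage bias: the sample standard deviation of the 20
  amino-acid frequencies, $\sqrt{\sum_i (x_i - \mu)^2 / (n-1)}$ with
  $n = 20$ and $\mu = 1/n$ (for proportions the mean is identically
  $1/n$). High AAUB means a few residues dominate the proteome.
* **CUB**, codon usage bias: the same statistic over the 64 codon
  frequencies ($n = 64$, stop codons included). This is a dispersion
  measure, deliberately distinct from codon adaptation indices such as
  CAI, which are out of scope.
* **KL**, relative entropy: the Kullback–Leibler divergence of observed
  codon frequencies $F(XYZ)$ from the zeroth-order (factorized)
  expectation built from the genome's base frequencies,
  $$\mathrm{KL} = \sum_{XYZ} F(XYZ)\,\log_2 \frac{F(XYZ)}{F(X)F(Y)F(Z)}.$$
  KL is zero exactly when codons look like independent draws of single
  bases; it grows as codon usage carries structure beyond base
  composition. We report bits (`log2`); nats are available.

Because the product distribution $F(X)F(Y)F(Z)$ is itself a valid
probability distribution over the 64 codons, Gibbs' inequality guarantees
$\mathrm{KL} \ge 0$, with equality iff the codon distribution factorizes.
When the base marginals are computed from the counted codons themselves
(the default), every codon with positive frequency has positive marginals,
so KL is always finite. A whole-replicon marginals mode exists
(`marginals = "whole"`) because base composition can also be measured on
the full replicon; the CDS-based default guarantees internal consistency
and differs negligibly for real coding-dense genomes.

Downstream, the package runs the analyses such a cohort invites:
correlation-matrix PCA of amino-acid and codon frequency matrices (each
category standardized to unit variance), complete-linkage/Euclidean
clustering for heatmap ordering, OLS of principal components on %AT and on
phylum, OLS of %AT on all 64 codon frequencies, a phylum ANOVA of AAUB,
and generalized additive mixed models.

## The hierarchical random-slope GAMM

Genomes are not independent: model organisms are sequenced in bulk, and
close relatives share base composition. The mixed models therefore carry
nested random effects at phylum, genus and species/strain level — each
level contributing a random intercept and an independent random slope on
genomic %AT (a "hierarchical random slope model"). The two headline
models are

1. `aaub ~ s(cub)` — a penalized-spline GAM, and
2. the same fixed structure plus the nested random effects, and the KL
   model `kl ~ s(at_fraction) + aaub` with the same random structure.

Fitting goes through `mgcv::gamm()`: smooths are cubic regression splines
(`bs = "cr"`, basis dimension `k = 10` by default) whose smoothness is
estimated as a variance component by REML (default) or ML, and the nested
random effects are `nlme::lme` terms with a diagonal covariance per level
(`pdDiag(~at_fraction)`). We chose plain cubic regression splines over
shrinkage bases after observing that shrinkage splines retain ~5 spurious
effective degrees of freedom under REML on an exactly linear truth.

Two practical points deserve emphasis:

* **Singleton leaves.** When every species/strain group holds one genome,
  its random intercept is confounded with the residual; `lme` needs
  `allow.n.lt.q = TRUE` to fit at all, and the species-level variance
  split is then arbitrary. Fixed-effect estimates are unaffected, but
  leaf-level variance components from such designs should not be
  interpreted. Calibration experiments in the tests therefore use designs
  with replication at every level they interpret.
* **AIC.** REML likelihoods are not comparable across fixed-effect
  structures, and mixed-model AICs are not comparable with `mgcv::gam`
  marginal-likelihood AICs. `compare_aic()` refits both models by ML
  through the same `lme` representation (the fixed-effects model as a
  `gamm` without random terms) before differencing.

## What the synthetic cohort emulates

`simulate_cohort()` generates the structure the analyses assume, with
known truth:

* **Nested %AT.** Phylum mean %AT is uniform on `at_range`
  (default 0.25–0.86, the observed prokaryotic span); genus and species
  add zero-mean Gaussian deviations (defaults 0.03 and 0.015), so %AT is
  most similar within species, then genera, then phyla — exactly the
  random-slope correlation structure the GAMM posits.
* **Codon bias with closed-form KL.** Each genome's codon distribution is
  the factorized distribution for its %AT (A=T at/2, C=G (1−at)/2),
  exponentially tilted: $p_c \propto p^{(0)}_c e^{\beta w_c}$ with the
  fixed weight vector `codon_tilt_weights()`. Exponential tilting keeps
  all 64 codons supported (KL stays finite), grows KL smoothly in
  $\beta$, and gives the exact ("analytic") KL of every genome by direct
  evaluation. The weights score leucine and serine codons +1 and are
  centred within A+T-count groups; under the A=T, C=G null all codons of
  equal A+T count are equiprobable, so the centring makes the tilt
  orthogonal to %AT to first order. Leucine and serine were chosen
  because their six-codon families span the base-composition range and
  both residues are abundant at every %AT, which makes AAUB increase
  monotonically with $\beta$ at any fixed %AT — the AAUB/CUB/KL coupling
  the analyses probe. (An earlier candidate that pitted AT-favored
  against GC-favored amino acids failed exactly this requirement: at the
  GC-rich end it evened out the baseline skew and *reduced* AAUB.)
* **Bias heterogeneity.** The default link makes $\beta$ decrease
  linearly from `bias_beta` (1.5) at the AT-poor end to 0 at the AT-rich
  end, reproducing by construction the pattern that codon frequencies
  become more "random" (lower KL) as genomes become AT-richer. On top of
  the link, phylum-level (`bias_sd_phylum = 0.10`) and genome-level
  (`bias_sd_genome = 0.05`) Gaussian jitter make taxa share bias beyond
  what %AT explains and genomes at equal %AT differ. Both are essential
  for identifiability: with a deterministic link, KL and AAUB would be
  functions of %AT alone and the KL model's AAUB coefficient would be
  undefined conditional on the %AT smooth, and there would be no residual
  clustering for the random-effects AIC comparison to find.
* **Genome sizes.** Per-genome codon counts are the configured
  `n_codons_per_genome` (default 20000) times a uniform multiplier on
  `size_range` (0.7–1.3), giving size variation that is independent of
  bias — the null the KL-vs-size model should not reject.

What the generator does **not** emulate: phylogenetic sequence evolution
along a tree (relatedness enters only through the hierarchical random
effects), gene-level heterogeneity within a genome (codons are i.i.d.),
horizontal transfer, and annotation noise. Passing tests therefore show
that the statistics and models recover the structure they assume — not
that real genomes satisfy those assumptions.

## Numerical choices and degenerate inputs

* Codons are counted as non-overlapping in-frame triplets; triplets
  containing `N` are skipped, never redistributed. CDS whose length is not
  a positive multiple of 3 are dropped (truncation would shift frames)
  with a logged count. A sliding-window mode is deliberately absent from
  the defaults.
* Translation uses NCBI table 11; terminal stops are dropped, internal
  stops and ambiguous codons yield no residue and are counted.
* KL terms with $F(XYZ) = 0$ contribute zero; results within $10^{-12}$
  below zero are clamped to zero; an observed codon with a zero-probability
  factorized expectation raises an infinite-divergence error (impossible
  under CDS-based marginals).
* PCA signs are fixed (PC1 positively correlated with %AT when supplied;
  other components by largest-loading-positive), zero-variance columns are
  dropped with a warning, and clustering sorts rows by genome id first so
  dendrograms are deterministic under ties.
* The %AT-on-codons OLS is exactly collinear by construction (frequencies
  sum to 1 and %AT is a linear functional of them); aliased coefficients
  are reported as such rather than erroring.
* A constant response in `fit_gam()` collapses to an intercept-only fit,
  since REML is undefined at zero deviance.
* Non-converged GAMM fits are returned flagged (`converged = FALSE`) so
  cohort-scale loops complete; they are refused by `compare_aic()`.

## Problem sizes used by the tests

The test-suite simulations were sized so that each check's Monte-Carlo
error is small against the quantity it asserts: the structure-recovery
cohort uses the full 30 phyla × 5 genera × 4 species design at 20000
codons per genome (KL sampling inflation ≈ 63/(2N ln 2) ≈ 0.002 bits,
far below the ~0.2-bit KL range); replicate-cohort AIC comparisons reuse
that shape through the multinomial fast path
(`simulate_cohort_profiles()`, exactly equivalent to sequence profiling
and proven so in the tests); the null variance-component calibration uses
a balanced 10 × 2 × 2 × 600 design, where REML sampling fluctuation in any
component's response-variance contribution is ~2 × 10⁻⁴ of the residual —
slope components are compared through their contribution (variance ×
mean(w²)) because raw slope variances carry different units. Type-I error
of the size model uses 100 cohorts of 48 genomes at 30000 codons, large
enough that the size-dependent part of KL sampling inflation is
negligible against between-genome bias jitter.

## Known limitations

* The species/strain variance component is not interpretable when strains
  are unreplicated (see above) — true of any fitter, but worth repeating.
* p-values for smooth terms in mixed models are approximate; the package
  reports the parametric (linear-term) p-values where calibration matters
  (the KL-vs-size test), and its type-I behaviour is verified by
  simulation rather than assumed.
* The exponential-tilt generator produces one bias axis; real codon usage
  bias is multi-causal (translational selection, strand asymmetry, HGT).
* %AT computed from coding sequence differs slightly from whole-replicon
  %AT; both modes are provided and the default is documented rather than
  hidden.
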