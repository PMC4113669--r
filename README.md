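# vigorclass

Genome-enabled classification of binary traits in line-structured plant
populations, built around root vigor in sugar beet (*Beta vulgaris*) as the
motivating case. Root vigor — recorded as high/low from seedling root
elongation — is an agronomically important binary trait; the package is for
breeders and quantitative geneticists who want to predict such a trait for
unphenotyped plants from a modest SNP panel, and for methodologists who want
a transparent, fully testable reference implementation of the
liability-threshold G-BLUP classifier.

## The model

Binary phenotypes y ∈ {0, 1} (low/high vigor) are modeled through a latent
liability

&nbsp;&nbsp;&nbsp;&nbsp; l = 1μ + X g + e,&nbsp;&nbsp; g ~ N(0, G σ²ₐ),&nbsp;&nbsp; e ~ Logistic(0, s = 1),

where X maps phenotype records to the genetic values g of phenotyped plants
and G is the VanRaden genomic relationship matrix

&nbsp;&nbsp;&nbsp;&nbsp; G = Z Z′ / (2 Σᵢ pᵢ(1 − pᵢ)),

with Z the matrix of allele-frequency-centered SNP dosages. Because the
residual is logistic with scale 1 (variance π²/3 ≈ 3.29), heritability on the
liability scale is

&nbsp;&nbsp;&nbsp;&nbsp; h² = σ²ₐ / (σ²ₐ + π²/3).

The model is fitted by Laplace-approximate maximum marginal likelihood (inner
Newton for (μ, g), outer Brent search for σ²ₐ on the log scale). A plant —
phenotyped or not — is classified high-vigor iff
p = exp(μ + g)/(1 + exp(μ + g)) > 0.5; unphenotyped plants receive g through
the joint prior, i.e. through their genomic relationships with the training
plants. Classification error is estimated by repeated k-fold cross-validation
(ER per test fold, averaged over folds × repeats), and model fit is judged by
a likelihood-ratio test against the intercept-only model with the
boundary-corrected ½χ²₀ + ½χ²₁ null.

Around the classifier the package provides the full pipeline: genotype QC
(duplicate samples, call-rate ≤ 85%, MAF ≤ 2.5% editing), scaffold-restricted
LD-based genotype imputation with a masking (accuracy-curve) experiment,
single-SNP logistic association scans with quasi-separation flags, LD (r²)
summaries, a fixed-heritability sensitivity mode, and a synthetic-population
generator that emulates the study design (18 related inbred lines, 192 SNPs on
99 scaffolds, an oligogenic high-h² liability trait) so every stage is
testable without external data.

## Worked example

```r
library(vigorclass)

# a population emulating the study design: 124 plants (one duplicated) from
# 18 lines, 192 SNPs, h2 = 0.783, 3% missing genotypes
sim   <- simulate_dataset(sim_config(seed = 20140722))
qc    <- qc_filter(sim$masked_panel, max_snp_missing = 0.15, min_maf = 0.025)
panel <- impute_missing(qc$panel)
grm   <- compute_grm(panel, missing_policy = "require_complete")

fit <- fit_threshold_model(panel$samples$vigor_class, grm)
print(fit)
#> liability-threshold G-BLUP fit
#>   n phenotyped: 123 | mu = 3.8476
#>   sigma_a2 = 48.4511  h2 = 0.936 (SE 0.073)
#>   deviance 36.553 (null 126.882) | converged: TRUE

likelihood_ratio_test(fit)$p_value
#> [1] 1.008169e-21

cv <- run_repeated_cv(panel, grm, k = 5, repeats = 100, rng_seed = 97)
print(cv)
#> repeated 5-fold CV, 100 repeats (500 replicates, 0 skipped)
#>   CV error (mean of replicate ERs): 0.019777 (1.978%)
#>   pooled: 243 misclassified of 12300 test observations (0.019756)
```

The heritability estimate (0.936, SE 0.073) overshoots the simulated truth
(0.783) by about two standard errors on this single dataset — across replicate
populations the median estimate sits within a few points of truth (the test
suite measures this over 20 seeds); the deviance drop of 90.3 gives p ≈ 10⁻²¹, i.e. the genomic
relationships explain the trait far beyond the intercept; and the repeated
5-fold CV error of ~2% reflects near-perfect classification — the residual
errors are plants whose binary phenotype was flipped by the logistic liability
noise, which no genomic classifier can recover.

The numbered scripts under `analysis/` run this same flow as a narrative
workflow (simulate → QC/impute → GRM → heritability → CV and the fixed-h²
sweep → association/LD → imputation masking experiment), each writing its
tables under `results/`.

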