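---
title: "Liability-threshold G-BLUP for binary traits: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liability-threshold G-BLUP for binary traits: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the tunable parameters and why their defaults are what they are,
what the synthetic populations do and do not emulate, the numerical choices,
and the known limits of what the tests demonstrate.

## The model

A binary phenotype $y_i \in \{0,1\}$ (low/high root vigor) is linked to a
continuous latent liability

$$ l = \mathbf{1}\mu + X g + e, \qquad g \sim N(0,\, G\sigma_a^2), \qquad
   e_i \sim \mathrm{Logistic}(0, s{=}1), $$

with $y_i = 1$ exactly when $l_i > 0$. $X$ allocates phenotype records to the
genetic values of phenotyped individuals; individuals without records still
appear in $g$ and are predicted through the joint prior — algebraically the
conditional mean $g_{\text{test}} = G_{21} G_{11}^{-1} g_{\text{train}}$, but
implemented in the joint form so that one fit yields probabilities for
phenotyped and unphenotyped plants alike. The classification rule is
$p_i = \mathrm{logistic}(\mu + g_i) > 0.5$ for the high class, with ties
($p_i = 0.5$ exactly) assigned low.

$G$ is the VanRaden realized-relationship matrix
$G = ZZ'/(2\sum_i p_i(1-p_i))$. The source material describes $Z$ as centered
$-1/0/1$ genotypes without stating the centering constant; we center each
column by its allele frequency (subtract $2p_i$ from the dosage, equivalently
$2p_i - 1$ from the $-1/0/1$ code), the convention the denominator
presupposes. By default $p_i$ is estimated from the panel itself; a
base-population frequency vector can be supplied instead. One consequence
worth knowing: with sample-estimated frequencies the columns of $Z$ sum to
zero, so all entries of $G$ sum to zero and the *mean* off-diagonal
relationship is slightly negative by construction. Population structure then
shows in the spread and the block extremes, not the mean — a different
convention (e.g. uncentered $-1/0/1$ coding) yields large positive means for
the same population, which is why the summary reports both off-diagonal-only
and all-entries variants.

Because the residual is logistic with scale 1 (variance $\pi^2/3 \approx
3.29$), heritability on the liability scale is
$h^2 = \sigma_a^2/(\sigma_a^2 + \pi^2/3)$, and a target $h^2$ converts back to
a variance as $\sigma_a^2 = h^2/(1-h^2)\cdot\pi^2/3$ (the fixed-heritability
sensitivity mode).

## Fitting: Laplace, not MCMC, not PQL

`fit_threshold_model()` maximizes the Laplace-approximate marginal likelihood:
an inner Newton optimization of the penalized Bernoulli-logit log-likelihood
for $(\mu, g)$ given $\sigma_a^2$, and an outer Brent search for $\sigma_a^2$
on the log scale over $[10^{-6}, 10^4]$. Convergence tolerances: $10^{-8}$ on
the inner gradient norm, $10^{-6}$ on $\log\sigma_a^2$. Hitting the upper
bracket flags quasi-separation (`converged = FALSE`); since $\sigma_a^2 = 0$
is a boundary point Brent cannot return, the fit collapses exactly to the
intercept-only model whenever the interior optimum does not beat it — which
also makes the null model the exact $\sigma_a^2 \to 0$ limit of the full one.

Instead of inverting $K = G\sigma_a^2$ (which would need a ridge on the
rank-deficient $G$ produced by near-clonal lines and duplicates), the fit
reparameterizes $g = L v$ with $L$ from the eigendecomposition of $G$
(negative eigenvalues clamped to zero, their columns dropped) and a standard
normal prior on $v$. $K$ is never inverted, no ridge is ever added to the
likelihood, positive semidefiniteness is handled exactly, and the
G-BLUP/RR-BLUP equivalence — $g = Za$ with ridge-penalized marker effects
$a \sim N(0, I\sigma_a^2/(2\sum p_i(1-p_i)))$ — holds to solver precision
(the test suite verifies $10^{-6}$ agreement against an independently coded
ridge-logistic Newton).

Two caveats the tests make explicit:

* **Laplace is an approximation.** Against exact 3-dimensional Gauss–Hermite
  quadrature at $n = 3$, the marginal log-likelihood agrees to $10^{-3}$ only
  for small variances ($\sigma_a^2 \lesssim 0.25$); at $\sigma_a^2 = 2$ the
  intrinsic approximation gap is $\approx 0.06$. The suite therefore checks
  quadrature agreement where the mathematics permits, exact agreement with an
  independently coded Laplace everywhere, and monotone shrinkage of the gap
  as $\sigma_a^2 \to 0$. For binary data with large variance components,
  Laplace-type estimates of $h^2$ carry finite-sample bias; the
  parameter-recovery test bounds the median error at $\pm 0.10$ over 20
  simulated populations ($n = 400$, true $h^2 = 0.8$) rather than claiming
  unbiasedness.
* **The $h^2$ standard error** is a delta-method transform of the numerical
  curvature of the profile log-likelihood,
  $SE(h^2) = c/(\sigma_a^2+c)^2 \cdot SE(\sigma_a^2)$ with $c = \pi^2/3$. A
  mixed-model package's internal SE for the same data need not match it
  numerically.

The likelihood-ratio test against the intercept-only model uses the
boundary-corrected null $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ (so
$p = \tfrac12 P(\chi^2_1 > \text{stat})$, and $p = 0.5$ at a zero statistic),
because $\sigma_a^2 = 0$ lies on the boundary of its parameter space. Its
empirical size is checked against the nominal 5% over 200 null simulations.

## Cross-validation

`run_repeated_cv()` repeats a random $k$-fold split (default $k = 5$, 100
repeats): each fold's phenotypes are set to missing, the model is refitted on
the rest — re-estimating $\sigma_a^2$ per training fold unless a fixed $h^2$
is imposed or `reestimate = FALSE` — and the held-out plants are classified.
The per-fold error $ER = \frac1n \sum I(y_i \ne \hat y_i)$ is averaged over
all folds × repeats; because folds differ in size by one, this average can
differ from the pooled ratio (misclassified/total) in the fourth decimal, so
both are reported and neither is "corrected". The GRM is computed once on all
samples and reused across folds: relationships are phenotype-free, so no
label information leaks into training. Folds are not stratified by class or
line by default (a plain random split); stratification is available as an
option. Training folds containing a single class are skipped with a warning
and counted — an intercept-only classifier has no defined decision change and
imputing its predictions would distort the error average.

## The synthetic populations

`simulate_dataset()` runs the analysis model forward, with structure chosen to
emulate the motivating study's population:

* **Markers.** 192 SNPs on 99 scaffolds assigned to chromosomes 1–9 or
  unassigned; within a scaffold, haplotype alleles follow a Gaussian copula
  with AR(1) latent correlation (`within_scaffold_rho = 0.9`), independent
  across scaffolds; allele frequencies uniform on `maf_range = (0.05, 0.5)`
  (mean MAF ≈ 0.27, near the study's 0.26).
* **Lines.** 18 lines from a closed breeding program: founder haplotypes are
  per-scaffold mosaics of a small ancestral pool (`n_founder_pool = 4`) with
  per-line divergence flips (`line_divergence = 0.02`), so lines are related
  to one another with a wide spread, as the study's relationship heatmap
  shows. Lines are inbred: the second founder haplotype is a lightly mutated
  copy of the first (`founder_het = 0.03`), and plants within a line add only
  small Mendelian/genotyping noise (`noise_rate = 0.02`) — plants of a line
  are near-clones, which is what makes line-consistent phenotypes and
  near-zero cross-validation error attainable at all.
* **Trait.** 10 QTL clustered on a few large scaffolds. Divergent selection
  is modeled through two class archetype haplotypes per QTL scaffold
  (favorable vs unfavorable alleles); each low-vigor line is derived from a
  "sister" high-vigor line, sharing its genome except on the QTL scaffolds —
  the study describes exactly this: its closest line pair straddled the
  classes, sharing most of their genetic basis while differing at the vigor
  loci. Genetic values are effect-weighted centered dosages rescaled so the
  realized $\mathrm{Var}(g)/(\mathrm{Var}(g)+\pi^2/3)$ equals `target_h2`
  (default 0.783) exactly. Liability adds a standard logistic residual to
  $\mu = 2.2$, chosen so prevalence sits near the study's 100:24 high:low
  balance; the threshold at 0 replaces the study's subjective phenotyping —
  a documented simplification. Line labels (HIGH*/LOW*) follow realized
  line-mean liability so the configured 15/3 split always holds.
* **Bookkeeping defects.** One exact duplicate sample (drawn from a high
  line, as in the study) and 3% missing-completely-at-random genotypes in the
  `masked_panel` copy. `make_qc_fixture()` additionally engineers one marker
  at call rate 0.80 and sixteen markers at MAF ≈ 0.012 — and pushes every
  other marker safely above the MAF threshold — so the editing pipeline's
  123 × 175 outcome is a deterministic consequence of construction, not luck.

What the generator does **not** emulate: genotyping-error structure beyond
MCAR missingness, recombination maps or scaffold order (unknown in the real
assembly), selection/drift dynamics, and the exact shape of the study's
relationship distribution. Passing tests therefore show the estimators are
correct and behave sensibly under a faithful statistical caricature of the
study — not that the package would reproduce the study's numbers on the real
(undeposited) data.

One behavioral difference is worth stating plainly. On these populations the
fixed-$h^2$ sensitivity sweep (0.783 → 0.5 → 0.33 → 0.2) yields a median CV
error that is non-decreasing but nearly flat, while the study reported a steep
rise (to ~18% at $h^2 = 0.2$). The mechanism — shrinkage of held-out genetic
values toward the intercept as the prior variance falls, which misclassifies
low-vigor plants once $|g| < \mu$ — is present and verified directly: held-out
low-line class probabilities rise strictly monotonically as the fixed $h^2$ is
lowered. But its crossover point depends on the balance between within-line
likelihood strength and cross-class relatedness; in our populations it binds
only below $h^2 \approx 0.1$. The crossover location is a property of the
(unavailable) real relationship structure, not of the estimator.

## Imputation

The study imputed missing genotypes with a haplotype-clustering tool before
analysis; reimplementing that tool is out of scope here, and the package
substitutes a transparent scaffold-restricted k-nearest-LD regression imputer:
for each target marker, the $k = 5$ most LD-correlated same-scaffold markers
with $r^2 \ge 0.1$ (pairwise-complete) serve as linear predictors; predictions
are rounded to the nearest valid genotype with ties toward the heterozygote,
and cells with no informative neighbors fall back to the marker's modal
genotype. The masking experiment — the study's own computation — is kept
intact: mask 1/2/3/5/10/20% of a complete panel (5 replicates each), impute,
score exact-genotype matches over masked cells only, and read the empirical
accuracy curve at the dataset's observed missing rate by linear interpolation
(the interpolation method is unstated in the source; linear is assumed and
documented). On sparse panels (~2 SNPs per scaffold) the LD imputer has little
signal to exploit and converges to the modal baseline; its advantage is
demonstrated on block-LD panels (10 SNPs per scaffold, rho 0.95), where it
beats the baseline in ≥ 9/10 seeds.

## Association scan and LD

The single-SNP scan fits $\mathrm{logit}(p_i) = \mu + \beta\,\mathrm{dosage}$
per marker by Newton iteration (≤ 50 iterations), flagging quasi-separation
when $|\beta| > 10$ log-odds per dosage unit and reporting the effect at the
cap without a standard error. No multiple-testing correction is applied: the
scan is descriptive (effect magnitudes and their clustering on scaffolds), not
an inference procedure. "Large-effect" markers are the top decile of
$|\beta|$ by default — the source shows them graphically without a numeric
threshold. LD is the squared Pearson correlation of dosage vectors (the
standard unphased composite estimator; haplotype phase is unavailable), and
because scaffold order along chromosomes is unknown, summaries cover all
within-scaffold pairs rather than adjacency chains.

## Numerical and degenerate-input choices

* Genotypes are stored as 0/1/2 dosages; the $-1/0/1$ coding is dosage − 1.
* QC thresholds are inclusive ("≤ removes"), order fixed as duplicates →
  call-rate → MAF with frequencies recomputed after sample removal; duplicate
  comparison uses jointly called genotypes only and keeps the first of a
  group.
* Monomorphic markers contribute zero to both numerator and denominator of
  $G$; an all-monomorphic panel is a denominator-zero error.
* The QC report prints missingness as both numerator and denominator, since
  the percentage's denominator convention (all cells of the edited panel) is
  a choice others may want to audit.
* Seeds: every stochastic operation takes an explicit seed and restores the
  caller's RNG state; a single pipeline seed expands into per-stage seeds via
  a documented multiplicative rule (`stage_seed`), so stages can be rerun in
  isolation.
* Problem sizes in the test suite (20 recovery replicates at $n = 400$, 200
  null simulations at $n = 60$, 20-repeat CV sweeps) were chosen as the
  smallest designs whose binomial/Monte-Carlo noise is clearly below the
  assertion margins.

## Known limitations

* Laplace-based $h^2$ estimates for binary traits at small $n$ are variable
  (SE ≈ 0.07–0.09 at $n = 123$) and can carry finite-sample bias; intervals,
  not point estimates, should be interpreted.
* No fixed covariates beyond the intercept, no multi-class extension, no
  Bayesian sampler, no pedigree matrices, no phased/haplotype LD, and no
  PLINK-format I/O — the supported formats are the TSV dialect and biallelic
  SNP VCF.
* The imputer is not a substitute for haplotype-model imputation on dense
  panels; it is honest about sparse-panel limits (modal fallback) and its
  accuracy claims are tied to the block-LD regime stated above.
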