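---
title: "Methods: mixed-model estimation, genomic prediction and the trait simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model estimation, genomic prediction and the trait simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the numerical choices
and the simulation design behind gblupr, at the level of detail a user
needs to judge what the package's results do and do not show.

## The mixed linear model

The phenotype of individual $i$ is modelled as
$$y_i = \mu + \sum_{j=1}^{M} z_{ij} a_j + e_i,$$
where $z_{ij} = (s_{ij} - \bar s_j)/\sigma_j$ is the standardized
genotype ($s_{ij}$ counts copies of the reference allele, PLINK A1
throughout), $a \sim N(0, I\sigma^2_a)$ are random SNP effects and
$e \sim N(0, I\sigma^2_e)$. Collecting $g = Za$, the phenotypic
covariance is
$$V = ZZ'\sigma^2_a + I\sigma^2_e = G\,\sigma^2_g + I\sigma^2_e,
\qquad G = ZZ'/M,\ \ \sigma^2_g = M\sigma^2_a.$$
The model assumes additivity (no dominance or epistasis), a homogeneous
cohort (one residual variance, no structure beyond what $G$ captures),
and equal expected variance per standardized marker.

**Standardization s.d.** The package defaults to the Hardy–Weinberg
value $\sigma_j = \sqrt{2p_j(1-p_j)}$ (the GCTA convention), with the
empirical dosage s.d. available via `sd_method = "empirical"`. Both are
defensible; the HWE choice makes $\sigma_j$ a function of the allele
frequency alone, so training statistics transfer cleanly to new
cohorts. Missing genotypes are mean-imputed ($z = 0$ after
standardization), which keeps $G = ZZ'/M$ well-defined with a single
fixed denominator $M$ rather than per-pair counts — and that fixed
denominator is what makes the identity $\hat g = Z\hat a$ (below)
exact, which the test suite exploits.

## REML estimation: two routes, one optimum

The restricted log-likelihood (constant $-\tfrac{N-c}{2}\log 2\pi$
omitted everywhere, so values are comparable across routes) is
$$\ell(\sigma^2_g, \sigma^2_e) = -\tfrac12\left[\log|V| +
\log|X'V^{-1}X| + y'Py\right],\qquad
P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}.$$

**AI-REML** (`airml_fit`). Scores
$s_k = -\tfrac12[\mathrm{tr}(PA_k) - y'PA_kPy]$ with $A_1 = G$,
$A_2 = I$, and the average-information matrix
$\mathrm{AI}_{kl} = \tfrac12\, y'PA_kPA_lPy$ drive Newton-type updates
$\theta \leftarrow \theta + \mathrm{AI}^{-1}s$, with up to 10 step
halvings whenever a step would decrease the likelihood and a scaled
gradient step if the AI matrix is singular. Starting values are
$\sigma^2_g = \sigma^2_e = \mathrm{var}(y)/2$. Components falling below
$\varepsilon = 10^{-6}\,\mathrm{var}(y)$ are clamped there and the fit
is flagged `boundary` (not an error): a variance estimate of zero is a
legitimate outcome, e.g. for a trait with no genetic signal.
Convergence requires both $|\Delta\ell| < 10^{-6}$ and a maximum
relative parameter change below $10^{-6}$, within `max_iter = 100`
iterations; non-convergence is flagged, not thrown. Standard errors
come from the inverse AI matrix at the optimum; the s.e. of
$h^2 = \sigma^2_g/(\sigma^2_g + \sigma^2_e)$ by the delta method.
AI-REML was chosen over EM or Fisher scoring for its fast convergence
and because the AI matrix doubles as the curvature estimate for
standard errors.

AI-REML has two *computational backends* that produce identical
iterates: a dense one that builds $V$ explicitly, and one that first
rotates the model by the orthogonal eigenvector matrix of $G$, after
which every per-iteration quantity costs $O(Nc^2)$ instead of $O(N^3)$.
The rotation is exact linear algebra, not an approximation, and the
suite asserts that both backends agree to $10^{-8}$ including iteration
counts. When the GRM comes from $M < N$ markers its spectrum is
obtained from the $M \times M$ cross-product ($G$ has rank $\le M$;
`grm_eigen_from_genotypes`), and the rotated algebra handles the
rank-deficient basis exactly via Gram-matrix corrections for the null
space.

**Eigen-rotation profile REML** (`reml_fit_eigen`). In the eigenbasis
the covariance is $\sigma^2_e\,\mathrm{diag}(\delta d_k + 1)$ with
$\delta = \sigma^2_g/\sigma^2_e$; $\sigma^2_e$ and the fixed effects
have closed-form profile solutions, leaving a one-dimensional
maximization over $\log_{10}\delta \in [-5, 5]$ done by Brent's method
(tolerance $10^{-8}$). The bracket covers $h^2$ from roughly $10^{-5}$
to $1 - 10^{-5}$ for typical eigenvalue scales; an optimum at either
end is reported with the `boundary` flag. The two routes maximize the
same function by entirely different iterations, which the tests use as
a cross-validation of both: estimates agree to $10^{-4}$ relative
across random instances, and on tiny problems AI-REML agrees with a
brute-force 2-D grid search of the likelihood surface.

Degenerate inputs: a singular $V$ or $X'V^{-1}X$ raises a named error;
$\sigma^2_g = 0$ reduces the likelihood to its OLS form, which is
tested in closed form. Ties among GRM eigenvalues make eigenvectors
non-unique; nothing downstream depends on eigenvector sign or on
ordering within ties (PCA output fixes signs only for display, by
making each component's largest-magnitude loading positive).

## BLUP, polygenic scores and accuracy

At the fitted components, with $r = y - X\hat\beta$:
$$\hat g = \hat\sigma^2_g\, G\, \hat V^{-1} r, \qquad
\hat a = (\hat\sigma^2_g/M)\, Z'\hat V^{-1} r, \qquad
\hat g = Z\hat a \ \text{(exactly)}.$$
A new individual is scored as
$\hat P_i = \sum_j \hat a_j\,(s_{ij} - \bar s_j)/\sigma_j$ using the
*training* mean and s.d. stored in the effect table — never statistics
of the cohort being scored. Alleles are reconciled per SNP at scoring
time: dosages are used as-is when the cohort's A1 matches the table's
reference allele, flipped to $2 - s$ when A1/A2 are swapped, and
anything else is an error, because a silent mismatch corrupts scores
with the wrong sign. Missing validation genotypes contribute zero
(training-mean imputation, consistent with the training side). Scores
are centred and no intercept is added; accuracy is measured by Pearson
correlation, which is translation-invariant, so this is harmless.
Accuracy is also reported relative to its ceiling $\sqrt{h^2}$.

## The trait and genotype simulator

The simulator generates the study conditions for the package's
experiments: cohorts of unrelated individuals, biallelic SNPs with
allele frequencies uniform on [0.05, 0.5] by default, traits controlled
by `n_qtn` causal variants and a target heritability
$h^2 \in \{0.2, 0.5, 0.7\}$ in the canonical settings, 90/10
train/validation splits, and three genotyping-array scenarios
(`partial_qtn` with 20% of QTNs on the array, `all_qtn`, `qtn_only`).

* **Genotypes.** With `ld_rho = 0`, dosages are Binomial(2, $p_j$) —
  Hardy–Weinberg, linkage equilibrium. With `ld_rho > 0`, two
  haplotypes per individual follow a first-order Markov chain across
  sites with stationary frequency $p_j$ and adjacent-site correlation
  `ld_rho`; transition probabilities are clamped to [0, 1], so between
  sites of very different frequency the realized correlation is
  attenuated toward its Fréchet bound (it is exact at equal adjacent
  frequencies, where the tests check it). This one-parameter AR(1)
  model is deliberately simple: it emulates *the presence of* local LD,
  not any real population's LD structure.
* **Effects.** QTN positions are drawn uniformly without replacement;
  effects are standard normal *on the standardized scale*, matching the
  model's $a \sim N(0, I\sigma^2_a)$, so dosage-scale effects scale as
  $u_j/\sigma_j$ and rarer alleles have larger per-allele effects. The
  effect-size–frequency relationship is an assumption of this design,
  not an estimate.
* **Exact variance partition.** Genetic values are rescaled to
  empirical variance $h^2$; residuals are drawn normal, orthogonalized
  against $[1, g]$, and rescaled to empirical variance $1 - h^2$. The
  orthogonalization is what makes
  $\mathrm{var}(g)/\mathrm{var}(y) = h^2$ hold *exactly* (to $10^{-12}$)
  for every seed, giving the suite a sharp invariant instead of a
  Monte-Carlo tolerance. Every generator is a pure function of its
  arguments including a mandatory seed, and restores the caller's RNG
  state.

What passing these tests shows — and does not. The simulator draws
unrelated, unstructured individuals with exchangeable markers, so the
estimator-calibration results (REML recovering the generating $h^2$;
the linear behaviour of $1/r^2_{\text{gen}}$ in $1/N$ with intercept
one, checked in the `qtn_only` design where its independence
assumptions hold) validate the *implementation*, not robustness to
population structure, relatedness, realistic LD, ascertained arrays or
non-additive architecture, none of which the generator produces.

## The prediction experiments

`run_prediction_experiment` wires the full pipeline — simulate, split,
standardize with training statistics, factorize, REML, SNP-effect BLUP,
score, correlate — over a grid of training sizes and replicates. One
master seed generates a table of per-run child seeds up-front, so any
cell can be re-run independently and the whole grid is reproducible.
REML failures in a cell flag the row and the run continues. The
reported quantities are $r_{\text{pheno}}$ (score vs phenotype, the
figure-style curve quantity), $r_{\text{gen}}$ (score vs true genetic
value, the quantity whose inverse square is regressed on $1/N$), and
$r_{\text{pheno}}/\sqrt{h^2}$.

Problem sizes in the shipped tests were chosen as the largest grids
that keep the whole suite comfortably interactive on one CPU: 50
replicates at $N = 2{,}000$, $M = 1{,}000$ for heritability recovery;
training sizes 1,000–8,000 with $M = 500$ causal markers for the
inverse-accuracy regression; six replicates per cell (the same
replicate count as the canonical experiment design this emulates).
Absolute accuracies from biobank-scale cohorts with real-LD arrays are
*not* reproduction targets at these sizes; the qualitative structure —
accuracy increasing with $N$ and $h^2$, bounded by $\sqrt{h^2}$, and
ordered `qtn_only` ≥ `all_qtn` ≥ `partial_qtn` across array scenarios —
is.

## Known limitations

Univariate traits only (no bivariate or multi-component REML); GWAS is
plain OLS with user covariates, not mixed-model association — fitting
each marker against a polygenic background is a different estimator and
deliberately out of scope; dense linear algebra throughout, so memory
is $O(N^2)$ when a full GRM is materialized (the genotype-factor path
avoids that when $M < N$); PLINK 1 binary and GCTA GRM formats only, no
dosage/VCF input; no LD-aware effect re-weighting or p-value
thresholding in the scoring step.
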