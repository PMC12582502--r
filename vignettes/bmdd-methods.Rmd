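---
title: "The bimodal Dirichlet-multinomial model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bimodal Dirichlet-multinomial model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Microbiome count tables are zero-heavy: most entries of a samples-by-taxa
matrix `W` are zero, yet many downstream analyses (log-ratio transforms,
diversity indices, log-linear differential abundance models) require strictly
positive relative abundances. The usual fixes — pseudocounts, or replacing
zeros by a constant — distort the composition in ways that depend on
sequencing depth. `bmdd` instead treats the unobserved composition as a
latent variable, models the zero-generating mechanism explicitly, and imputes
by posterior inference.

## The model

For sample $i$ with sequencing depth $N_i$ and taxa $j = 1, \dots, m$:

* mode indicators $\delta_{ij} \sim \mathrm{Bernoulli}(\pi_j)$, independent
  across taxa and samples;
* per-taxon concentrations $\theta_{ij} = \alpha_{j,1}$ if $\delta_{ij} = 1$
  and $\alpha_{j,0}$ otherwise, with $\alpha_{j,0} \le \alpha_{j,1}$ by
  convention;
* composition $X_i \sim \mathrm{Dirichlet}(\theta_{i1}, \dots, \theta_{im})$;
* counts $W_i \sim \mathrm{Multinomial}(N_i, X_i)$.

Each taxon's marginal concentration is thus a two-point mixture: a near-zero
"absent" spike $\alpha_{j,0}$ and an abundant mode $\alpha_{j,1}$, mixed with
probability $\pi_j$. Observed zeros can arise either from the spike (truly
near-absent) or from undersampling an abundant taxon; the posterior separates
the two using the depth and the taxon's behaviour across samples.

## Variational EM

The marginal likelihood sums over $2^m$ mode configurations per sample, so we
use a mean-field approximation
$q(X_i, \delta_i) = \mathrm{Dirichlet}(X_i \mid \beta_i)
\prod_j \mathrm{Bernoulli}(\delta_{ij} \mid \gamma_{ij})$
optimized by coordinate ascent, interleaved with empirical-Bayes updates of
$(\pi, \alpha)$:

* **β update** (closed form):
  $\beta_{ij} = W_{ij} + \gamma_{ij}\alpha_{j,1} + (1-\gamma_{ij})\alpha_{j,0}$.
* **γ update**: $\gamma_{ij} = \mathrm{logistic}\{h_{ij}(1) - h_{ij}(0) +
  \mathrm{logit}(\pi_j)\}$, where $h_{ij}(d)$ collects the terms of the bound
  that involve $\delta_{ij} = d$, with the intractable
  $E[\log\Gamma(\sum_k \theta_{ik})]$ replaced by a Jensen lower bound through
  the mean concentration $\bar\alpha_{ik} = \gamma_{ik}\alpha_{k,1} +
  (1-\gamma_{ik})\alpha_{k,0}$ of the *other* taxa. Sweeps over taxa repeat
  (at most 20 per outer iteration) until $\max|\Delta\gamma| < 10^{-4}$.
* **π update** (closed form): $\pi_j = \tfrac1n \sum_i \gamma_{ij}$, clipped
  to $[0, 1-10^{-8}]$ so $\mathrm{logit}(\pi_j)$ stays finite.
* **α update**: `stats::nlminb` on $(\log\alpha_0, \log\alpha_1)$ with
  analytic gradients, box constraints $[10^{-6}, 10^{4}]$, a warm start at
  the previous value, and a fallback that rejects any step that worsens the
  objective.

### The monitored objective

The exact ELBO contains $E_\delta[\log\Gamma(\sum_k \theta_{ik})]$, which has
no closed form. The package monitors a *surrogate* ELBO in which this term is
replaced by the same Jensen bound used in the updates,
$\log\Gamma(\sum_k \bar\alpha_{ik})$. With $\beta = W + \bar\alpha$ the
digamma terms cancel and the surrogate has a closed form. The β, π and α
updates are exact ascent steps for this surrogate. The γ sweep maximizes the
per-coordinate chord of the bound and is not *provably* monotone for the
surrogate; the test suite asserts monotonicity (slack $10^{-6}$) on seeded
datasets, and no violation has been observed. Convergence is declared when
the relative change of the surrogate falls below `rel_tol` ($10^{-6}$ by
default, `max_iter = 200`).

### Initialization and identifiability

Moment initialization: $\gamma_{ij} = \mathbf 1\{W_{ij} > 0\}$, $\pi_j$ = the
taxon's prevalence, $\alpha_{j,1} = \hat\mu_j \hat A$ with $\hat\mu_j$ the
mean observed proportion and $\hat A$ a shared method-of-moments precision,
and $\alpha_{j,0} = 0.01$. A seeded random restart
(`bmdd_config(init_strategy = "random")`) guards against poor local optima.
The two modes are exchangeable, so after every M-step the labels are
canonicalized to $\alpha_{j,0} \le \alpha_{j,1}$ (swapping relabels
$\gamma \to 1 - \gamma$, $\pi \to 1 - \pi$; $\bar\alpha$ and $\beta$ are
invariant).

Degenerate cases: `m = 1` is rejected (the composition is identically 1);
an all-zero taxon is retained with a warning — its posterior is driven by
the prior, since the data carry no mode information.

## Exact oracle

For $m \le 15$, `exact_posterior()` enumerates all $2^m$ mode configurations
with log-sum-exp accumulation and returns the exact posterior mode
probabilities, the exact posterior mean composition (a mixture of
Dirichlet-multinomial posterior means), and the exact log marginal
likelihood. It exists to test the variational approximation: the mean-field
E-step must track the exact posterior mean, and the surrogate ELBO must never
exceed the exact log marginal.

## Imputation and posterior sampling

* `posterior_mean(fit)` returns $\beta_i / \sum_j \beta_{ij}$ — strictly
  positive, so zeros never survive imputation.
* `posterior_sample(fit, L)` draws $L$ composition matrices from the fitted
  Dirichlet factors for multiple imputation. Cells imputed as near-absent
  have concentrations around $10^{-2}$, whose Dirichlet draws underflow to
  exact zeros in double precision; draws are therefore floored at `1e-10`
  and renormalized, perturbing each row by at most $m \times 10^{-10}$ while
  keeping every draw log-transformable.
* `posterior_predict(fit, W, L)` re-draws counts at the observed depths and
  summarizes per-taxon zero proportions and count standard deviations — a
  posterior predictive check aimed at the zero structure.

## Differential abundance with multiple imputation

`daa_single()` regresses each taxon's log relative abundance on a binary
group label. Because log-composition effects are only identified up to a
common shift, the taxon-wise coefficients are bias-corrected by subtracting
the mode of their kernel density estimate (valid when most taxa are null).
`daa_multiple()` repeats this across $L$ posterior draws and combines by
Rubin's rules with Barnard-Rubin degrees of freedom (default), or by a
stacked linear mixed model with a random sample intercept
(`combine = "stacked_lmm"`, using `lme4`; t-tests use $n - 2$ degrees of
freedom because the $n$ samples, not the $nL$ stacked rows, carry the
information). `shuffled_fdr()` permutes the group labels to estimate the
empirical false discovery rate of any such method under the global null.

## Synthetic data generators

Exact parameter settings of the reference simulations are not available, so
the generators expose every distribution parameter and fix documented
defaults chosen once as study conditions:

* `random_hyperparams()`: $\pi_j \sim \mathrm{Beta}(2,2)$, $\alpha_{j,0}$
  log-uniform on $[0.01, 0.5]$, $\alpha_{j,1}$ log-uniform on $[0.5, 20]$ —
  a genus-level-like mix of rare spikes and abundant modes.
* `default_depths()`: log-uniform on $[5\times10^3, 5\times10^4]$ reads.
* Misspecified families (`simulate_parametric`): gamma (default shape 0.5 —
  heavily right-skewed) or log-normal latent abundances normalized to the
  simplex, or Poisson / negative-binomial (size 0.5) counts drawn directly;
  cross-taxon dependence via a Gaussian copula with exchangeable or AR(1)
  structure. These deliberately violate the model's assumptions.
* `simulate_daa()`: two equal groups, 10% of taxa differential by default
  with a 10-fold mean shift in group 1.

These defaults emulate the *shape* of published benchmark designs (bimodal
abundance, log-uniform depths, copula-correlated misspecification,
two-group folds); they do not reproduce any published dataset, and the
negative-binomial/Poisson variants only set count scale through relative
depths.

## Study sizes used by the package's own checks

The acceptance suite (one test block per property) uses: oracle agreement at
$n=20, m=3$; 50 random equal-mode instances for the Dirichlet-multinomial
limit; ascent on 10 datasets at $n=50, m=20$; recovery at $n=300, m=30$
(5 seeds); imputation-vs-pseudocount at $n=80, m=100$ (10 replicates);
posterior predictive coverage at $n=60, m=40, L=200$; and the two DAA
harnesses at $n=50, m=50$ with $L=20$ imputations and 100 repetitions.
`scripts/acceptance.R` recomputes the same quantities from a single
command-line seed.

## Limitations

* The ascent property of the γ sweep is empirical, not proven, for the
  monitored surrogate; the exact ELBO is never computed during fitting.
* The surrogate bound degrades when both modes are large and similar
  (`exact_posterior` is the arbiter at small $m$).
* The mode-based bias correction in the DAA assumes most taxa are null;
  designs with a majority of differential taxa will mis-center estimates.
* No covariate or phylogenetic regression on $\pi$/$\alpha$; no
  Monte-Carlo evaluation of the $\delta$ expectation; single-threaded.
* `exact_posterior` is exponential in $m$ and refuses $m > 15$.
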