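---
title: "Models and methods behind hicmrf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hicmrf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicmrf)
```

## The problem

A Hi-C (or micro-C) experiment yields a matrix of contact counts between
pairs of fixed-size genomic bins. Most entries are noise — random ligation
events whose intensity is shaped by technical biases — and the analyst's
task is to decide which bin pairs interact more than the background
predicts. Two features of these matrices drive the design of `hicmrf`:

* counts are over-dispersed and zero-heavy, so a plain Poisson background
  fits poorly;
* neighbouring entries are correlated, because a genuine 3D contact between
  two loci drags their neighbouring bins into proximity as well.

## The mixture model

Each upper-triangle entry $y_s$ (a pair $s = \{i,j\}$) is modelled by a
$K$-component mixture

$$f(y_s) = \alpha_1\, \mathrm{ZIP}(\tau, \lambda_s^{(1)}) +
  \sum_{k=2}^{K} \alpha_k\, \mathrm{Pois}(\lambda_s^{(k)}),$$

where the first component (noise) is a zero-inflated Poisson with
extra-zero probability $\tau$ — mean $(1-\tau)\lambda$ and variance
$\lambda(1-\tau)(1+\tau\lambda)$ — and the remaining components are
Poisson. With $K = 2$ the components are noise and true signal; with
$K = 3$ a third, high-mean *false signal* component absorbs pairs whose
counts look like signal but whose bias profile looks like noise.

Every component mean is corrected for four bias covariates through a
log-linear regression,

$$\log \lambda_s^{(k)} = \beta_0^{(k)} + \beta_1^{(k)} \log D_s +
  \beta_2^{(k)} \log GC_s + \beta_3^{(k)} \log TE_s +
  \beta_4^{(k)} \log ACC_s,$$

with $D_s$ the genomic distance between the two bins' midpoints, and
$GC_s$, $TE_s$, $ACC_s$ the arithmetic means over the two bins of GC
fraction, transposable-element count and DNA accessibility. This replaces
matrix balancing: biases are modelled, not divided out, and the fitted
$\beta$s themselves say which biases matter in a given library.

Units matter for interpretation: the real-data path measures $D_s$ in bp,
so $\beta_1$ is per log-bp; the synthetic generator uses bin-unit
distances (multiples of the bin size), so $\beta_1$ there is per
log-bin. GC is a fraction in (0, 1), not a percentage.

## The spatial prior

The latent labels $z_s \in \{1..K\}$ live on the two-dimensional lattice of
bin pairs, with the four neighbours $N_s = \{(i\pm1,j), (i,j\pm1)\}$, and
follow a Potts model

$$p(z \mid \gamma) = \frac{1}{C(\gamma)}
  \exp\Big(\gamma \sum_{(s\sim t)} \delta_{z_s z_t}\Big),$$

where each unordered neighbour pair is counted once (double counting would
only rescale $\gamma$; fixing the convention fixes the $\gamma$ scale).
$\gamma = 0$ gives independent uniform labels; values near 1 give strong
spatial coherence. The partition function $C(\gamma)$ sums over $K^n$
configurations and is intractable beyond toy lattices;
`potts_partition_bruteforce()` evaluates it exactly for up to 16 sites and
serves as the test oracle for everything built on top.

The mixture weights $\alpha_k$ and the Potts prior both speak about label
frequencies. `hicmrf` treats the Potts field as the sole prior on labels
and reports $\alpha_k$ as the empirical label frequencies of each retained
draw; this keeps a single coherent generative story while leaving
$\alpha$ available for reporting and for non-spatial simulation.

## Inference

`run_mcmc()` is a Metropolis-within-Gibbs sampler:

* **Labels.** One systematic-scan Gibbs sweep per iteration; the full
  conditional at a site multiplies the Potts neighbour term by the
  component emission (ZIP for the noise component).
* **Coefficients.** Per-component, per-coefficient random-walk Metropolis
  against the conditional posterior given the current labels, with
  independent normal priors. Proposal scales (default 0.05) adapt toward
  44% acceptance during burn-in only and are frozen afterwards, so
  detailed balance holds over retained draws.
* **Extra zeros.** Data augmentation: each zero count labelled noise draws
  an extra-zero indicator from its conditional Bernoulli, then $\tau$
  is drawn from its conjugate Beta posterior.
* **Potts interaction.** The update of $\gamma$ would need $C(\gamma)$, so
  it uses Approximate Bayesian Computation instead: draw
  $\gamma^{*}$ from the prior, simulate a pseudo-field at $\gamma^{*}$ by
  Gibbs sweeps from a random start, and accept when the discrepancy
  between the pseudo-field's and the current field's concordant-pair count
  falls under a tolerance set to the 1% quantile of pilot discrepancies
  (20 pilot simulations from the prior, refreshed each call). The
  concordant-pair count is the Potts sufficient statistic, so the ABC
  acceptance is exact in the small-tolerance limit for this update; a
  count-level discrepancy would mix information about all parameters into
  a move that only updates $\gamma$.

Priors default to normals of sd 1 on every coefficient, Beta(10, 5) on
$\gamma$ (scaled to a configurable support $[0, \gamma_{max}]$, default
$\gamma_{max} = 1$ since couplings near 1 already saturate spatial
coherence) and Beta(1, 1) on $\tau$. `empirical_bayes_hyperpriors()`
offers a data-driven alternative: count-quantile strata, an OLS fit of
$\log(y+1)$ on the log covariates per stratum for the prior means,
ten-fold inflated standard errors as prior sds, and a zero-fraction-based
Beta prior on $\tau$. The inflation acknowledges that an OLS fit on
$\log(y+1)$ is only a rough guide to Poisson-regression coefficients.

Initialization is deterministic: the lowest-count fraction $\pi_0 = 0.6$
of sites starts in the noise component (the prior expectation that noise
dominates), the rest split evenly among the other components;
coefficients, $\tau$ and $\gamma$ start at their prior means.

Mixture components are only identified up to permutation. The ordering
rule: compute each component's average fitted mean over all sites from
the posterior-mean coefficients; the smallest is noise, the intermediate
(at $K=3$) true signal, the largest false signal. Two means tying within
1e-9 are reported as an identifiability error rather than silently
ordered.

## Model selection and calling

`compute_dic()` implements a complete-likelihood deviance information
criterion for latent-variable models,

$$\mathrm{DIC} = -4\, E_{\theta,z}\big[\log f(y, z \mid \theta)\big] +
  2 \log f(y, \hat z \mid \hat\theta),
  \qquad f(y, z \mid \theta) = \prod_s \alpha_{z_s}\, f_{z_s}(y_s \mid \theta),$$

with the expectation averaged over retained draws (labels included) and
the plug-in term taken at the posterior-mean parameters and per-site
modal labels. The multinomial label term matters: it is what charges a
sparsely occupied extra component for the entropy of its weight, and
without it (the emissions-only conditional variant, available as
`include_label_prior = FALSE`) an overfitted component that stably
captures a few tail sites goes essentially unpenalized, making the
criterion a coin flip between adjacent $K$. The Potts normalizing
constant is omitted from the complete likelihood — it is intractable and,
at a common fitted $\gamma$, common to the candidate models being
compared. Smaller is better; `select_K()` fits each candidate $K$ and
takes the argmin. The criterion's absolute magnitude depends on the
dataset, so the package validates it by its ordering behaviour: on data
simulated with a known $K$, the DIC prefers the generating $K$ in the
large majority of replicates, in both directions.

`call_interactions()` turns per-site label frequencies into calls: the
label is the maximum-probability role, ties break toward the lower-mean
role (conservative: a site is only promoted to signal when the evidence
is strict), and a call is *significant* when it is labelled signal with
probability at least 0.5. The cutoff is a flag, not a constant;
probability heatmaps (`plot_calls()`) are often more informative than any
single threshold.

## The synthetic-data generator

`simulate_hic()` draws data with exactly the statistical structure the
model assumes, so every inference path is testable without any external
download. Labels come either from the Potts field (Gibbs sweeps, default
200, on the configured lattice) or i.i.d. from declared proportions;
covariates come from declared distributions; counts from the labelled
emissions.

Defaults define the package's standard study conditions: n = 2500 pairs
on a 50 x 50 lattice, $K=2$, proportions 0.7 noise / 0.3 signal,
$\tau = 0.3$, $\gamma = 0.4$, noise coefficients
$(7, -0.7, 0.3, -0.2, -0.3)$ and signal coefficients
$(9.5, -0.9, 0.36, -0.1, 0.15)$. Two of these choices deserve their
rationale spelled out:

* **Distance units.** The default distance distribution is uniform over a
  grid of bin-unit distances 1..50 rather than bp. With bp-scale
  distances $\log D$ sits around 10–13 with little relative spread, which
  makes the intercept nearly collinear with the distance slope; its
  variance-inflation factor (~170) would make tight intercept recovery at
  n = 2500 impossible under any realistic counts. Bin-unit distances keep
  $\log D$ in (0, 3.9) and every coefficient identifiable.
* **Coefficient magnitudes.** The generating coefficients were chosen, by
  a Fisher-information calculation done before any fitting, so that the
  worst posterior sd among the ten coefficients is about 0.01 at
  n = 2500 — the regime in which posterior means recover the truth to
  within ±0.02. That recovery bound is the package's headline validation
  target, and the default design is the experiment that tests it.

Covariate defaults — GC uniform on (0.3, 0.7), TE a shifted Poisson
(strictly positive), accessibility log-normal — are realistic in range
and strictly positive, so the log-linear regression is evaluable
everywhere. All draws are additionally lower-truncated at a configurable
floor.

What the generator does *not* emulate: read-level artefacts, distance
decay correlated across covariates, chromosome-wide banding,
trans-chromosomal contacts, and replicate structure. Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the model's own assumptions, not robustness to real-data model
misspecification.

## Numerical choices and degenerate inputs

* $|\log\lambda|$ is capped at 50: a current state beyond the cap is an
  error (it names the offending observation), while Metropolis proposals
  beyond it are simply rejected.
* Zero covariates are floored at a pseudocount (default 0.5, in the units
  of the track; pseudocount x bin size for diagonal distances) before the
  log transform. The diagonal is included in the dense enumeration of a
  region: an m-bin region yields m(m+1)/2 pairs.
* Symmetric duplicate entries in a triplet file are merged; disagreeing
  counts are an error, not a silent average. Mixed dialects and malformed
  lines fail with line numbers.
* BED and bedGraph coordinates are 0-based half-open, GFF 1-based
  inclusive; internally everything is 0-based half-open. Strand is
  ignored throughout (Hi-C bins are unstranded).
* All-identical counts make empirical-Bayes strata undefined and are
  refused, as are zero-variance covariates.
* Bin categories for call characterization use precedence P > G > O; the
  TAD partition requires both bins *within* one common TAD interval.

## Validation problem sizes

The test suite validates exactness on enumerable instances (lattices of
up to 9 sites against brute-force partition functions; a 3 x 3 label
posterior against enumeration of all 512 configurations) and recovery on
the standard n = 2500 design. Monte-Carlo comparisons against exact
distributions use $10^5$ Gibbs sweeps, and the comparison cases were
chosen by a power calculation so that the sampling noise of the
total-variation estimate stays below the 0.02 bound being asserted;
larger configuration spaces would need proportionally more draws. The
recovery suite runs at 5,000 iterations / 2,500 burn-in; the acceptance
script (`scripts/acceptance.R`) runs the full 20,000 / 10,000 design.
Model-selection and calling experiments run 10 replicate seeds each at
n = 2500 with shortened chains (250-800 iterations), which pilot runs
showed to be past the burn-in needed on these well-separated designs.

## Known limitations

* The sampler is exact but not fast: chromosome-scale matrices imply
  millions of sites and the per-iteration cost is linear in sites, so
  full-genome runs are long; the compiled label and field sweeps are the
  hot path.
* The ABC step's tolerance refreshes its pilot set at every call, which
  is statistically clean but costs `abc_pilot_draws` field simulations
  per iteration.
* The DIC's absolute value is not comparable across datasets and the
  package makes no attempt to reproduce any particular published
  magnitude; only the ordering across K is validated.
* Posterior credible intervals are equal-tailed sample quantiles;
  with strongly autocorrelated chains their Monte-Carlo error can be
  non-trivial — inspect `autoplot(chain)` traces before trusting
  borderline significance flags.
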