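---
title: "Predicting trait segregation in progeny populations from genome-wide markers"
author: "segpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting trait segregation in progeny populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segpred)
```

## The problem

In cross breeding — especially of perennial fruit trees, where a progeny
population takes years and large field areas to evaluate — the choice of a
parental combination largely determines what a programme can achieve. Two
parents with similar mean performance can produce very different progeny
distributions, so the *average* potential of a cross is not enough: a
breeder wants the full predicted segregation pattern, the probability that
a progeny will beat a named reference cultivar in several traits at once,
and the population size needed to find such a progeny with reasonable odds.

`segpred` addresses this by combining three components:

1. a Bayesian shrinkage regression (BayesA) of phenotypes on genome-wide
   multi-allelic marker genotypes, with a latent-variable threshold
   extension for ordinally scored traits, fitted by Gibbs sampling;
2. a meiosis simulator that generates virtual F1 progeny from *phased*
   parental haplotypes and a linkage map, using Haldane's map function
   with no crossover interference;
3. a posterior-predictive computation of the proportion of simulated
   progeny that fulfil multi-trait selection criteria, evaluated at every
   retained MCMC cycle so that its spread reflects the uncertainty of the
   marker-effect estimates.

## The model

For individual $i$, the latent (or observed) phenotype is modelled as

$$y_i = \beta_0 + \sum_{j=1}^{J}\sum_{l=1}^{L_j} (x_{ijl} + x'_{ijl})\,\beta_{jl} + e_i,$$

where marker $j$ carries $L_j$ alleles, $x_{ijl}$ and $x'_{ijl}$ indicate
the individual's two alleles, and $\beta_{jl}$ is the additive effect of
allele $l$ of marker $j$. Effects of marker $j$ share a variance
$\sigma_j^2$ with a scaled inverse chi-square prior
$\mathrm{Inv}\text{-}\chi^2(\nu_g, S_g^2)$ — the BayesA construction that
lets individual markers carry large effects while shrinking most toward
zero. The residual is $e_i \sim N(0, \sigma_e^2)$ with
$\sigma_e^2 \sim \mathrm{Inv}\text{-}\chi^2(\nu_e, S_e^2)$.

For a trait recorded in $M$ ordered categories, the score is
$s_i = m \iff K_{m-1} < y_i \le K_m$ with $K_0 = -\infty$, $K_1 = 0$,
$K_M = +\infty$; the free cut-points $K_2, \dots, K_{M-1}$ are estimated.
The Gibbs sampler cycles truncated-normal draws of the latent $y_i$,
conjugate normal draws of $\beta_0$ and each $\beta_{jl}$, uniform
conditional draws of the free cut-points (the Albert–Chib scheme: $K_m$
uniform between the largest latent value of category $m$ and the smallest
of category $m+1$), and scaled-inverse-chi-square draws of all variances.

A genotype-effect variant replaces the allele dosages with one indicator
per *observed unordered genotype class* per marker, so each class effect
absorbs additive plus dominance variation. Only observed classes get a
column, to avoid over-parameterization with multi-allelic markers.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| $\nu_g$, $S_g^2$ | 4, 0.004 | prior df and scale of per-marker effect variances (allelic model) |
| $S_g^2$ (genotype model) | 0.012 | genotype-class effects (additive + dominance) have larger variance than single-allele effects |
| $\nu_e$, $S_e^2$ | −2, 0 | flat prior on $\sigma_e^2$; the update becomes $\mathrm{Inv}\text{-}\chi^2(n-2,\ \mathrm{SSE}/(n-2))$ |
| cycles / burn-in / thin | 50000 / 10000 / 10 | retains 4000 samples |
| progeny per cross $S$ | 1000 | granularity of proportion samples is $1/S$ |

The prior notation treats the scale parameter as a squared quantity
($S_g^2 = 0.004$) throughout.

## Breeding values, cross-validation, scores

The estimated breeding value of any genotyped individual is the posterior
mean of the genetic part of the linear predictor,
$\hat y_i = \mathrm{E}[\beta_0 + \sum_{jl}(x_{ijl}+x'_{ijl})\beta_{jl}]$;
the residual is excluded because its expectation is zero. Predictive
accuracy is assessed by leave-one-out cross-validation (`loocv()`):
each individual is predicted from a model refitted without it, and the
accuracy is the Pearson correlation between cross-validated and whole-data
breeding values. Ordinal scores are predicted by drawing, at each retained
cycle, a phenotype from $N(\text{predictor}, \sigma_e^2)$, binning it with
that cycle's cut-points, and reporting the modal category (ties go to the
lower category); the coincidence — the fraction of exact matches,
displayed as an observed-by-predicted confusion table — summarises ordinal
accuracy.

## Progeny simulation and the posterior proportion

Gametes are simulated per linkage group: the transmitted haplotype starts
from either parental haplotype with probability 1/2 and switches across
each adjacent-marker interval independently with probability
$r = \tfrac12(1 - e^{-2d/100})$ ($d$ in cM) — Haldane's function, which is
exactly the no-interference assumption. Co-located markers never
recombine; markers absent from the map segregate independently
($r = 0.5$, with a warning). Each progeny is the union of one gamete from
each parent, so every progeny allele is one of the four parental alleles.

For a candidate cross, the breeding value of progeny $i$ at retained cycle
$n$ is $\tilde g_i[n] = \beta_0[n] + \sum_{jl}(x_{ijl}+x'_{ijl})\beta_{jl}[n]$.
A selection criterion compares $\tilde g_i[n]$ (strictly) with either a
fixed threshold or the cycle-$n$ breeding value of a named reference
cultivar — recomputing the reference per cycle propagates its uncertainty
into the result. The cycle-$n$ proportion of acceptable progeny is

$$p[n] = \frac{1}{S} \sum_{i=1}^{S} \prod_{c \in \text{criteria}} I_c(\tilde g_i[n]),$$

and the collection $\{p[n]\}$ over retained cycles is the posterior
distribution of the proportion. Multi-trait criteria pair the traits'
chains by cycle index, which requires equal retained lengths.
`rank_crosses()` applies this to every unordered parent pair and sorts by
posterior mean (ties broken lexicographically by cross label), with
per-cross simulation seeds derived deterministically from one master seed.

## The synthetic-data generator

The real dataset this methodology was developed for — a germplasm
collection of 84 pear cultivars genotyped at 333 mapped SSR markers — is
not publicly deposited, so the package ships a generator that emulates its
structure: 84 diploid phased individuals, 333 multi-allelic markers
(2–8 alleles, SSR-like labels) on 17 linkage groups, adjacent-marker
spacings drawn from a log-normal with mean 4.0 and median 2.7 cM
(right-skewed, like real maps), allele frequencies from a uniform
Dirichlet, and relatedness/LD created by propagating the founders through
3 generations of random crossing with the package's own meiosis simulator.
Seventeen linkage groups is the pear chromosome number; random crossing
(rather than a coalescent) mirrors how breeding germplasm actually
acquired its kinship. Traits are generated from QTL planted at markers
with a geometric series of variance contributions and Gaussian noise at a
target heritability; ordinal traits are cut at phenotype quantiles (or
user-supplied cut-points). Every generated dataset carries its full truth
(phase, QTL effects, genetic values), so recovery tests can score the
fitted models.

What the generator does *not* emulate: SSR mutation, genotyping error,
population stratification between cultivar groups, selection history, or
any particular real LD profile. Passing tests on generated data therefore
demonstrate the correctness and internal consistency of the machinery and
its behaviour under the assumed genetic architecture — not field
performance on any particular crop.

## The validation simulation study

`run_simulation_study()` reproduces the method's self-check: per
replicate, 30 QTL are planted at randomly chosen markers with geometric
variance shares solved so the effective QTL number
$(\sum_k v_k)^2 / \sum_k v_k^2$ equals 10; environmental noise targets
$h^2 = 0.75$ and the QTL set is resampled until the realised heritability
(variance of genetic values over variance of phenotypes on the panel,
which varies because of LD between sampled QTL) lands in $[0.70, 0.80]$.
A continuous-response BayesA model is fitted to the panel, the panel is
randomly paired into 42 crosses, 1000 progeny are simulated per cross
*once*, and on the same progeny the true proportion (true genetic value
above the true panel mean) and the predicted proportion (posterior-mean
breeding value above the estimated panel mean) are compared; computing
both on the same progeny set isolates model error from Monte Carlo
progeny error. Accuracy is the cross-wise Pearson correlation, averaged
over replicates. The predicted proportion uses posterior-mean effects (a
point prediction) because a single predicted value per cross is compared
against a single truth.

### Problem sizes and numerical choices

The packaged validation runs 10 replicates with chains of 10000 cycles
(2000 burn-in, thin 10, i.e. the reference schedule scaled by one fifth):
at $n = 84$ the accuracy of the proportion predictions is limited by the
information in the panel rather than by Monte Carlo error in the
posterior means, so longer chains are spent where they do not help.
Replicate stages use isolated sub-seeds (trait, fit, pairing, per-cross
progeny), so the simulated data of a replicate are invariant to the MCMC
schedule — users can verify the schedule-insensitivity directly by
running paired studies that differ only in `mcmc`.

Other numerical choices:

* **Initialisation**: effects 0, $\sigma_j^2 = S_g^2$, $\sigma_e^2 = 1$,
  latent values at category midpoints on an equally spaced grid, free
  cut-points equally spaced in $(0, M-1)$ — deterministic and absorbed by
  burn-in.
* **Truncated normals** are drawn by inverse-CDF; when the bin's
  probability mass underflows (predictor far outside the bin) the draw
  falls back to the nearest admissible point rather than producing NaN.
* **Empty score categories** borrow the neighbouring cut-points as the
  bounds of the uniform cut-point draw, keeping the chain defined.
* **Missing genotypes** are mean-imputed in the design matrix with twice
  the panel allele frequency, preserving column means; missing phenotypes
  drop the individual from that trait's likelihood while its breeding
  value remains predictable from markers.
* **Root finding** for the geometric ratio brackets $(0, 1)$ with
  tolerance $10^{-10}$; the equal-variance case returns $\lambda = 1$
  exactly.
* **Ties** in ordinal score prediction go to the lower category; ties in
  cross ranking are broken lexicographically.

## Design choices that were genuinely open

* **Sampling $\sigma_e^2$.** Threshold models often fix
  $\sigma_e^2 = 1$; here the residual variance is sampled under the flat
  prior, with identification provided by $K_1 = 0$ together with the
  proper prior on marker-effect variances (whose scale $S_g^2$ anchors
  the latent metric). This identification is weak: it is reliable in the
  intended regime (panels of roughly 80+ phenotyped individuals) but in
  very small toy problems (a few dozen observations with many hundreds of
  effect columns) the latent scale can drift and the chain diverges. The
  option `fix_residual_variance = TRUE` is available for such cases and
  for users preferring the conventional cumulative-probit constraint.
* **Cut-point updates** use the uniform conditional (Albert–Chib) Gibbs
  step — the simplest correct scheme. Its mixing degrades for large $n$,
  which is acceptable at the panel sizes this package targets.
* **LOOCV refits** default to a reduced schedule (4000/1000/5): with ~84
  refits per trait the full schedule costs minutes for no measurable
  change in the accuracy estimate.
* **Genetic correlation** between traits is the Pearson correlation of
  posterior-mean breeding values (not per-cycle samples).
* **Criteria reference values** are recomputed per MCMC cycle from the
  reference parent's genotypes rather than fixed at the posterior mean,
  so the reference's uncertainty widens the posterior of the proportion.

## Limitations

* Phasing is out of scope: the package consumes phased input (`a|b`
  cells) or generates phased data synthetically; real panels must be
  phased upstream (e.g. with BEAGLE-class software).
* No crossover interference (Kosambi etc.) and no multi-generation
  pedigrees beyond F1 within a single simulation call.
* Single-trait chains only; traits interact solely through shared progeny
  genotypes when criteria are combined.
* Ordinal scoring discards information relative to continuous recording;
  small-effect QTL may be undetectable from coarse scores.
* Accuracy on any real panel depends on its relatedness and LD structure;
  the synthetic panel is one plausible such structure, not a calibration
  target.
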