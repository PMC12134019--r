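---
title: "Methods: Bayesian pathway analysis of early tamoxifen discontinuation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian pathway analysis of early tamoxifen discontinuation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Adjuvant tamoxifen roughly halves recurrence risk in premenopausal ER-positive
breast cancer, yet a substantial minority of patients stop taking it well
before the recommended five years. Tamoxifen is a prodrug: phase I CYP
oxidation (chiefly CYP2D6) produces the active metabolites 4-hydroxy
tamoxifen, N-desmethyl tamoxifen and endoxifen; phase II sulfotransferases and
UDP-glucuronosyltransferases conjugate them for excretion; ABC/SLCO
transporters move them across membranes. Functional polymorphisms in these
enzymes shift active-metabolite exposure, and with it both efficacy and the
side-effect burden that drives discontinuation. Because many enzymes act
jointly on the same metabolites, single-variant regression underuses the known
biology. `tampath` implements a Bayesian pathway approach: a Metropolis-
Hastings search over *interaction trees* — small sets of variant "leaves"
combined multiplicatively — constrained by a prior metabolic-pathway graph and
scored by the Cox partial likelihood of time to discontinuation.

## The discontinuation endpoint

Supply diaries are built from dispensing records (one 182-day supply per
refill). A refill made before the previous supply is exhausted carries the
unused remainder forward, capped at 182 days of carried stock; the new supply
always counts in full. Diaries are truncated at the earliest of death,
recurrence, first aromatase-inhibitor (AI) registration, emigration, or five
years after diagnosis. Early discontinuation is at least 182 *consecutive*
uncovered days, dated at the 182nd uncovered day; time runs from tamoxifen
initiation. Conventions chosen where the endpoint definition is silent:

* days are integers, day 0 = diagnosis; a supply dispensed on day `d` covers
  the half-open interval `[d, d + days_supplied)`;
* censoring ties resolve death > recurrence > AI switch > emigration >
  administrative cutoff;
* the carry-over cap applies to the carried remainder only (a reading of
  "up to 6 months of carry-over"; configurable);
* a gap cut short by the window end never counts — the event requires 182
  *observed* uncovered days.

The interval engine is tested for exact agreement with a day-by-day stock
simulation on 1,000 randomized subjects.

## The interaction-tree model

A tree `T` is a set of leaf variants with per-leaf interaction weights
`theta` and an overall pathway effect `beta`. A subject with minor-allele
dosages `g` contributes the log hazard

```
h(g) = beta * ( prod_leaves (1 + theta_l * g_l) - 1 )
```

so the all-reference genotype contributes 0, and a two-leaf tree expands
exactly into main effects plus a product interaction
(`beta*theta1*g1 + beta*theta2*g2 + beta*theta1*theta2*g1*g2`). A single-leaf
tree fixes `theta = 1`, reducing to an ordinary per-allele log hazard
`beta * g`.

This form was adopted because it reproduces the published
genotype-combination hazard-ratio grid for the CYP2D6*2 x ABCC2 pair to
rounding error (`fit_grid_params()` recovers `beta = 0.0180`,
`theta = (4.82, 3.17)` from five printed cells and predicts the three held-out
cells as 2.182 / 2.118 / 4.004 against printed 2.18 / 2.12 / 4.00); a pure
`theta^g` product form does not.

Free parameters are fitted on unconstrained coordinates `(beta, log(1 +
theta))` with independent standard-normal priors on each coordinate — a
weakly-informative scale for log-hazard effects that keeps leaf factors
positive. The origin of these coordinates is a saddle point of the
multiplicative model (at `beta = 0`, `theta = 0` every derivative vanishes),
so optimization starts from small non-zero values and, for cold starts, from
a mirrored pair of starting points.

## Marginal likelihood and the chain

Each tree is scored by the Laplace approximation to its marginal likelihood:
the Efron-tied Cox partial likelihood of the tree's subject scores (entered
as offsets, no free regression parameters) plus the parameter log prior,
maximized by compiled damped Newton iterations with analytic gradient and
Hessian; and

```
log ML ~ logpost(MAP) + (k/2) log(2*pi) - 0.5 * log det(curvature)
```

with `k = 1` for single-leaf trees and `k = 1 + L` otherwise. A non-positive-
definite curvature is ridged by 1e-6 and flagged. Marginal likelihoods are
memoized per canonical tree id within a run, and each new tree's optimization
warm-starts from the current tree's MAP.

Two numerical hazards of the multiplicative model shape the optimizer. The
origin of the `(beta, log(1 + theta))` coordinates is a saddle point — every
derivative vanishes at `beta = 0, theta = 0` — so starts are kept away from
it, Newton steps use eigenvalue-floored curvature (steps are always descent
directions), and a stationary point with non-positive curvature is escaped
along the most negative-curvature eigenvector. The posterior can also be
multimodal: a warm start inherited from a neighbouring tree can converge to
a worse mode, and because fitted values are memoized, a silently bad fit
would permanently undervalue that tree in the chain. Every fit therefore
runs from two starting points (the warm start and a standard cold start, or
a mirrored pair for cold fits) and keeps the better optimum. The fit kernel
(partial-likelihood value, score gradient and parameter-space Hessian) is
compiled; a pure-R twin of the likelihood/gradient path is retained and
tested for exact agreement.

The tree prior is `kappa^(L-1) * omega^(#same-gene leaf pairs)` with defaults
`kappa = 0.5` (each extra leaf halves prior mass — an explicit Occam penalty)
and `omega = 2` (leaves within one gene are a priori twice as plausible
together). The proposal kernel picks add / drop / swap uniformly among the
legal move types and corrects the acceptance ratio for forward/reverse move
counts; `max_leaves = 4` bounds the state space (the published trees have two
leaves). Prior probabilities come from a data-free chain (the
marginal-likelihood term is identically zero), posterior probabilities from a
chain with data; both tally visit frequencies after a 10% burn-in for every
variant (leaf membership), concept (at least one leaf mapped to the concept)
and tree. Probabilities are Jeffreys-smoothed, `(visits + 1/2)/(n + 1)`, so
Bayes Factors — posterior odds over prior odds — are always finite; the raw
posterior frequency is used for the `pp >= 0.01` top-tree threshold. The
posterior chain does not adjust for clinical covariates; covariate adjustment
lives in the conventional Cox screen.

At full scale the analysis scripts run 300,000 prior and 100,000 posterior
iterations (`analysis/05_alps.R`); the test suite uses 50,000-iteration prior
chains and 1,000–2,000-iteration posterior chains at n = 2,000–4,000, which
already identify a two-locus effect of the published magnitude reliably.

## Genotype QC and imputation

Variants are coded as minor-allele dosages 0/1/2 throughout (a frequency
above 0.5 is flipped and flagged); functional-allele orientation is carried
as pathway metadata only. QC drops variants with MAF < 0.05, one-degree-of-
freedom Hardy-Weinberg chi-square p < 1e-3 (the threshold is configurable —
the source analysis names its exclusions rather than a cutoff), or membership
of the pathway file's exclusion list. Missing genotypes are imputed by
chained equations: each locus in turn is modelled by a proportional-odds
regression on clinical covariates and the other loci's current dosages
(multinomial logit fallback where the proportional-odds fit fails, marginal
draws for degenerate loci), 5 sweeps per dataset, m = 50 independently
initialized datasets by default. Aggregation to a single analysis dataset
takes the per-cell modal genotype, ties broken toward fewer minor alleles and
flagged. Both the imputation family and the aggregation rule are
implementation choices; the source describes only "imputation from patient
characteristics and co-loci" and "aggregation into one dataset". A stacked
analysis of all m datasets is deliberately not the default.

## Conventional screen and shrinkage

`per_variant_screen()` fits one `survival::coxph` model per variant (genotype
numeric, Efron ties — discontinuation times are day-resolution and tie
heavily) adjusted for age, stage (ref I), surgery (ref mastectomy),
radiotherapy, chemotherapy, grade (ref I), HER2 (ref negative), cohabitation
and employment. Empirical-Bayes (semi-Bayes) shrinkage tempers multiple
comparisons without an externally set prior: the grand mean is the
precision-weighted mean of the log hazard ratios, the between-variant
variance is the method-of-moments estimate `max(0, var(coef) - mean(se^2))`,
and each coefficient is pulled toward the mean by `tau2/(tau2 + se^2)`.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the statistical structure the analysis assumes, at
the scale of the source cohort (defaults, all configurable):

* n = 3,729; 26 biallelic loci in 15 genes, independent, in Hardy-Weinberg
  equilibrium, with plausible European MAFs (0.05–0.45; the source reports no
  numeric MAFs) and 5% MCAR genotype missingness;
* covariate margins matching the published descriptive table (stage II 55%,
  chemotherapy 91%, ...); cohabitation (75%) and employment (70%) are not
  tabulated in the source and default to plausible population values;
* a latent stop time that is exponential with rate `baseline_hazard *
  exp(tree log-hazard)` — the Cox estimands are baseline-shape-free, so the
  simplest constant baseline is used; refills every 182 days until the latent
  stop or censoring;
* independent exponential censoring clocks per cause. The AI-switch rate
  (4.45e-4/day) and baseline stop rate (1.50e-4/day) were calibrated once by
  forward simulation so the default configuration yields ~47% AI switching
  and a ~14% observed discontinuation proportion over five years, the two
  dominant features of the source cohort's follow-up; recurrence (4.0e-5/day)
  and death (3.5e-5/day) approximate the published ten-year proportions, and
  emigration is rare (2e-6/day). These defaults are frozen;
* the default genetic effect is the published two-locus interaction
  (`beta = 0.0180`, `theta = (4.82, 3.17)` on rs16947 and rs3740065).

Deliberately not emulated: linkage disequilibrium between loci,
genotype-covariate confounding (an optional hook exists in the design but
covariates are independent of genotype by default, isolating what each test
exercises), informative censoring, dose changes or partial adherence below
the stop-time model, and calendar-time structure (everything is in days from
diagnosis). Passing tests therefore demonstrate correct recovery under the
model's own assumptions, not robustness to their violation in real registry
data.

## Numerical choices

* Efron tie correction everywhere by default (day-resolution times);
  Breslow available and used where a closed-form check requires it.
* The offset partial likelihood and its score-gradient are computed by
  cumulative sums over the sorted risk sets; correctness is pinned to
  `survival::coxph` offset log-likelihoods at 1e-10 and to numerical
  gradients at 1e-5.
* `fit_grid_params` is deterministic least squares in log-HR space from the
  fixed initialization `beta = 0.01, theta = 1`, polished to residuals below
  1e-8 on round trips.
* Monomorphic loci return HWE chi-square 0 with a warning rather than an
  error; all-missing columns are errors.
* Visit-probability smoothing constants and chain settings are recorded in
  the run metadata so every Bayes Factor can be recomputed exactly from the
  logged counts.

## Known limitations

* **Laplace accuracy at very small n.** On 20-subject two-leaf fixtures the
  pure Laplace approximation deviates from mode-centred Gauss-Hermite
  quadrature (and from brute-force Monte Carlo integration, which agree with
  each other to ~0.005 nats) by ~0.4–0.6 nats in the typical case: with three
  free parameters and a handful of events the posterior is visibly
  non-Gaussian. The error falls below ~0.25 nats by n = 200 and is negligible
  at cohort sizes, where the approximation is actually used. Single-parameter
  trees are accurate to ~0.01–0.05 nats already at n = 20.
* Under a null cohort the per-variant Bayes Factors centre slightly below 1
  (median ~0.7–0.8): the Occam penalty shifts posterior mass toward smaller
  trees relative to the prior chain, which lowers every variant's posterior
  visit frequency. This is a property of visit-frequency BFs, not a bug.
* The default pathway ships the 12 variants the source names plus 14
  placeholder loci (real pharmacogenetic rsids in the same gene families,
  flagged `placeholder: true`) so the graph has the source's dimensionality;
  users with real panels should supply their own pathway file.
* Whether the metabolite-edge placement of CYP2C9/CYP2C19 and the individual
  UGTs matches the source figure cannot be determined from its text; the
  default graph places them on N-desmethyl-tamoxifen and the glucuronide
  respectively and treats these edges as configuration, not ground truth.
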