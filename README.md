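# tampath

Bayesian pathway analysis of early tamoxifen discontinuation in breast
cancer pharmacogenetics.

Premenopausal ER-positive breast cancer patients should take adjuvant
tamoxifen for at least five years, but many stop early. Tamoxifen is a
prodrug: phase I CYP enzymes (chiefly CYP2D6) produce its active metabolites
(4-OH tamoxifen, N-desmethyl tamoxifen, endoxifen), phase II SULTs/UGTs
conjugate them for excretion, and ABC/SLCO transporters move them across
membranes. Functional variants in these genes shift active-metabolite
exposure — and with it the side-effect burden that drives discontinuation.
`tampath` is for biostatisticians and pharmacoepidemiologists who want to
analyse that question the way a pathway-aware Bayesian would, or to study the
operating characteristics of such an analysis on fully synthetic cohorts.

The package implements the whole workflow as reusable, tested functions:

1. **Synthetic cohorts** (`simulate_cohort`): genotypes under Hardy-Weinberg
   equilibrium, realistic clinical covariate margins, 6-monthly dispensing
   records, and competing censoring (aromatase-inhibitor switch ~47%,
   recurrence, death, emigration, 5-year cutoff).
2. **Supply diaries** (`build_diary`, `derive_cohort_outcomes`): coverage
   intervals with carry-over of unused supply (capped at 182 days), and the
   early-discontinuation endpoint — ≥182 consecutive uncovered days, dated at
   the 182nd, measured from initiation.
3. **Genotype QC and imputation** (`qc_filter`, `impute_genotypes`): MAF ≥ 5%
   filter, Hardy-Weinberg chi-square, a-priori exclusion lists, and chained
   multiple imputation (m = 50) aggregated by per-cell mode.
4. **Conventional screen** (`per_variant_screen`, `eb_shrink`): adjusted Cox
   models per variant (HR per minor allele) with empirical-Bayes shrinkage
   across variants.
5. **Pathway tree search** (`run_chain`, `summarize_features`): Metropolis-
   Hastings over interaction trees constrained by a metabolic pathway graph.

## The model

An interaction tree `T` is a set of leaf variants with per-leaf weights θ and
an overall pathway effect β. A subject with minor-allele dosages *g*
contributes the log hazard

    h(g) = β · ( ∏_{l ∈ T} (1 + θ_l g_l) − 1 ),

so the reference genotype contributes 0 and a two-leaf tree is exactly main
effects plus a product interaction. Trees are scored by the Laplace-
approximated marginal likelihood of the Efron-tied Cox partial likelihood
(subject scores as offsets; standard-normal priors on β and log(1+θ)), and
explored under the tree prior κ^(|T|−1) · ω^(#same-gene pairs) (κ = 0.5,
ω = 2). For any feature — a variant, a pathway concept such as "CYP2D6
activity", or a whole tree — the Bayes Factor is the posterior odds of
visiting that feature divided by its prior odds from a data-free chain:

    BF = [p₁/(1−p₁)] / [p₀/(1−p₀)],   p = (visits + ½)/(n + 1).

## Worked example

Recover the two-locus (CYP2D6*2 rs16947 × ABCC2 rs3740065) interaction
parameters from a printed genotype hazard-ratio grid, then verify them by
forward simulation:

```r
library(tampath)

# five observed cells of the 3x3 HR grid (margins + first interaction cell)
cells <- data.frame(g1 = c(1, 2, 0, 0, 1),
                    g2 = c(0, 0, 1, 2, 1),
                    hr = c(1.09, 1.19, 1.06, 1.12, 1.52))
fp <- fit_grid_params(cells)
round(c(beta = fp$beta, theta1 = fp$theta[1], theta2 = fp$theta[2]), 3)
#>   beta theta1 theta2
#>  0.018  4.824  3.167

hr_grid(list(leaves = c("rs3740065", "rs16947")),
        list(beta = fp$beta, theta = fp$theta))
#>    g2
#> g1         0        1        2
#>   0 1.000000 1.058640 1.120719
#>   1 1.090697 1.520000 2.118279
#>   2 1.189620 2.182422 4.003773
```

The three cells not used in the fit come out as 2.18, 2.12 and 4.00: a
patient homozygous for the minor allele at both loci has four times the
discontinuation hazard of a double-reference patient. Simulating a default
cohort under exactly this effect and running it through the diary stage:

```r
cc <- cohort_config(seed = 1)            # n = 3729, shipped defaults
ch <- simulate_cohort(cc)
oc <- derive_cohort_outcomes(ch$supplies, ch$events, ch$covariates)
round(mean(oc$event), 3)
#> [1] 0.138
table(oc$censor_reason)
#>
#>  ai_switch      death emigration five_years       none recurrence
#>       1750        141         10       1152        513        163
```

13.8% of subjects discontinue within five years and 47% are censored at an
aromatase-inhibitor switch, matching the follow-up profile the generator is
calibrated to. The full pipeline (QC → imputation → Cox screen → pathway
search → report) runs from the numbered scripts:

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_supply_diary.R
Rscript analysis/03_genotype_qc.R
Rscript analysis/04_cox_screen.R
Rscript analysis/05_alps.R
Rscript analysis/06_report.R
```

writing tables under `results/analysis/` (variant QC, screened HRs with
shrinkage, Bayes Factors for variants / concepts / trees, top-tree HR
grids, combined report). `run_pipeline()` performs the same stages in one
call with a single fanned-out seed. On the default cohort the stage-5 log
reads, in part:

```
concept Bayes Factors:
  four_hydroxy_tamoxifen   14.21
  CYP2D6_activity          14.21
  endoxifen                11.47
  transporters             8.64
  phase_I_metabolism       5.87
  ...
  phase_II_metabolism      0.28
top tree: rs16947+rs3740065 (BF 171.0, pp 0.060)
```

— the search recovers the generating two-locus interaction as the top tree
and ranks the pathway concepts accordingly (activation and CYP2D6 supported,
phase II conjugation null).

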