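---
title: "Multilevel phylogenetic meta-analysis of telomere-length heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel phylogenetic meta-analysis of telomere-length heritability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telometa)
```

## The problem

Heritability estimates of vertebrate telomere length vary enormously across
the literature — from below zero to above one — and they arrive with very
different precisions, from very different laboratory assays (terminal
restriction fragment methods, qPCR), statistical estimators (parent–offspring
regression, pedigree animal models, twin designs, SNP-based methods, family
mixed models), and species. `telometa` implements the full analysis chain for
synthesizing such estimates: curation of raw effect sizes, a multilevel
random-effects meta-analytic model with a phylogenetic correlation structure,
heterogeneity decomposition, moderator meta-regression, publication-bias
diagnostics, and bootstrap uncertainty for the variance components.

## The model

Each record is a heritability estimate $y_i$ with known sampling variance
$v_i = \mathrm{SE}_i^2$. The intercept-only model is

$$y_i = \beta_0 + u_{j(i)} + a_{k(i)} + s_{k(i)} + e_i + m_i,$$

with four independent random terms and a known-variance error:

* $u_j \sim N(0, \sigma_u^2)$ — study effects (a study contributes several
  estimates that share design and population);
* $a \sim N(0, \sigma_a^2 A)$ — phylogenetic species effects, correlated
  across species through the matrix $A$ built from the tree;
* $s_k \sim N(0, \sigma_s^2)$ — species effects independent of phylogeny
  (species ecology);
* $e_i \sim N(0, \sigma_e^2)$ — estimate-level effects (within-study,
  between-estimate variation);
* $m_i \sim N(0, v_i)$ — sampling error, variance known and fixed.

Marginally $\mathrm{Var}(y) = \sigma_u^2 Z_uZ_u' + \sigma_a^2 Z_sAZ_s' +
\sigma_s^2 Z_sZ_s' + \sigma_e^2 I + \mathrm{diag}(v)$. The components are
estimated by restricted maximum likelihood (REML); fixed effects are the GLS
solution at the optimum with model-based standard errors. Note that the
phylogeny and species terms share one grouping factor and differ only in the
correlation structure: their separation is weakly identified by construction
(with 18 species it is common for one of the two to be estimated at zero),
and the fitter is designed to report such boundary estimates rather than
fail.

The phylogenetic correlation matrix uses Grafen node heights: the height of
an internal node is $((\text{descendant tips} - 1)/(\text{total tips} -
1))^\rho$, tips at 0, root at 1, so the correlation between two species is
the depth of their most recent common ancestor. $\rho = 1$ by default
(Grafen's original choice); it is exposed as a parameter because published
analyses rarely state it. Polytomies need no special treatment under this
rule. Species present in the data but missing from the tree are a hard
error, never pruned silently — the phylogenetic term needs a complete $A$.

## Heterogeneity

The typical sampling-error variance summarizes the known $v_i$ in one
number, $\sigma_m^2 = (k-1)\sum w_i / \left[(\sum w_i)^2 - \sum
w_i^2\right]$ with $w_i = 1/v_i$; it returns the common value exactly when
all $v_i$ are equal. Total heterogeneity is

$$I^2 = \frac{\sigma_u^2+\sigma_a^2+\sigma_s^2+\sigma_e^2}
{\sigma_u^2+\sigma_a^2+\sigma_s^2+\sigma_e^2+\sigma_m^2},$$

and each component divided by the same denominator gives its share of total
variance; the shares sum to one with the sampling-error share equal to
$1-I^2$. The formula for $\sigma_m^2$ lives in one function
(`typical_sampling_variance()`) so an alternative summary (e.g. the plain
mean of $v_i$) can be swapped without touching the $I^2$ pipeline.

## Effect-size curation

Conversion rules applied when assembling the table:

* mid-parent regression slope → $h^2$ as-is; single-parent slope →
  $2\times$ slope, sign preserved (negative estimates are retained — they
  are informative about estimation bias);
* standard error from a 95% CI as $(\text{upper limit} -
  \text{estimate})/1.96$, using only the upper limit, and only when no SE is
  reported; records with neither SE nor CI are rejected with a recorded
  reason;
* every rejection is reported, never silent.

The Fisher-z sensitivity path transforms $z = \mathrm{arctanh}(h^2)$ with
variance $1/(n-3)$. The variance rule is pluggable: the standard Fisher
variance is the default because the transform's stated purpose is a
variance-stabilized reanalysis keyed to sample size, but the exact rule used
by earlier reanalyses of heritabilities (as opposed to correlations) is not
always printed, and a user can pass any function of $n$. Records with
$|h^2| \ge 1$ (undefined after the transform), missing $n$, or $n \le 3$
are excluded with reasons; the same exclusion set defines the "trimmed"
sensitivity model on the raw scale, so transformation effects and trimming
effects can be told apart.

## Moderator meta-regression

The five standard moderators enter as treatment-coded factors against fixed
reference levels: environmental setting (artificial), age at measurement
(adult), laboratory method (TRF Southern blot), statistical method
(correlation-based), repeated measurement (yes). This yields 12 fixed-effect
columns. Parental sex specificity can be added interacting with statistical
method; with 104 records over a $5\times3$ cell grid some interaction cells
are routinely empty, so the pipeline's interaction stage drops aliased
(inestimable) interaction columns with a message, while the default
`build_model()` contract keeps rank deficiency a hard error naming the
aliased columns. Wald tests use normal theory ($z = \hat\beta/\mathrm{SE}$,
CI $\pm 1.96\,\mathrm{SE}$); likelihood-ratio tests for random terms refer
$2\Delta\ell_R$ to $\chi^2_1$, matching the convention of standard
meta-analytic software — the 50:50 boundary mixture, which halves the
p-value, is available behind a flag.

## Numerical choices

The restricted log-likelihood is maximized directly on the variance scale
under box constraints $\sigma^2 \ge 0$ (PORT routine), with the analytic
gradient $\partial\ell_R/\partial\sigma_r^2 = -\tfrac12[\mathrm{tr}(PK_r) -
y'PK_rPy]$. Optimizing on the variance scale (rather than log-variance)
lets boundary solutions come out as exact zeros, matching the reporting
convention of published tables whose bootstrap intervals start at 0.000.
Three deterministic starts are used by default (method-of-moments excess
split, equal split of the marginal variance, near-zero); across simulated
datasets at the design scale used here the three starts agree to $10^{-7}$,
so bulk simulations (bootstrap, type-I-error and recovery experiments) use
a single start. Components below $10^{-8}\,\mathrm{var}(y)$ at the optimum
are snapped to zero. The restricted likelihood includes the
$+\tfrac12\log|X'X|$ constant so values are directly comparable with the
most widely used meta-analytic implementation; the constant cancels in
every likelihood-ratio test. Trial covariance matrices that lose positive
definiteness to rounding receive a relative jitter of $10^{-10}$ on the
diagonal before factorization.

The fitter was validated three ways: against the two-study closed form
($\hat\mu$ = mean, $\hat\tau^2 = (\Delta y)^2/2 - v$), against brute-force
grid-plus-refinement maximization of an independently coded restricted
likelihood on small datasets (agreement to $10^{-4}$ in components), and
against `metafor::rma.mv` on full-scale synthetic datasets (agreement to
$\sim 10^{-7}$ in components, fixed effects, SEs and log-likelihood).

## Publication-bias diagnostics

The Egger variant regresses $y_i$ on its sampling variance $v_i$ in a mixed
model with study and species random intercepts and an estimate-level
residual, weighted by the known $v_i$. The sampling variance is used both
as the predictor and as the known error variance — the double use follows
the published procedure as stated; a standard-error predictor is available
behind a flag. The funnel export uses marginal residuals $y - X\hat\beta$
of the full meta-regression: the moderators' heterogeneity is removed, but
the random-effect spread the funnel is meant to display is retained
(conditional residuals, with predicted random effects subtracted too, are
an option). The time-lag model replaces the predictor with publication year,
centered at its mean so the intercept stays interpretable; centering leaves
the slope untouched.

## Bootstrap

Nonparametric percentile intervals: resample with replacement, refit by
REML, take the order statistics at positions $\lceil(R+1)\cdot
0.025\rceil$ and $\lfloor(R+1)\cdot 0.975\rfloor$ — stated explicitly so
tie and rounding behaviour is deterministic. Two resampling units are
offered and labelled in the output rather than silently chosen: record-level
(rows with their $v_i$) and study-level (whole clusters, with resampled
copies of a study relabelled so they enter as independent clusters). Records
within studies are dependent, so the two units answer slightly different
questions; published analyses rarely state which was used, and reporting
both side by side is the honest default. One master seed derives
per-replicate substream seeds by a counter, so results are independent of
execution order. Replicates that fail to fit are dropped and counted; more
than 20% failures aborts with an error.

## The synthetic-data generator

`sim_config()` defaults encode the design of the published vertebrate
telomere-length heritability dataset: 104 estimates from 43 studies and 18
species; variance components study 0.066, phylogeny 0.017, species 0.012,
estimate 0.005; mean heritability 0.449; sampling variances log-uniform on
$[5\times10^{-4}, 0.05]$, bracketing the published typical sampling-error
variance of 0.001. The species-assignment weights concentrate 60% of
studies on one species, mirroring the human dominance of the real
literature, with every species appearing at least once (as in the real
dataset); moderator level frequencies are imbalanced in the same spirit
(qPCR the most common assay, artificial settings and non-specific parental
estimates in the majority). Moderator effects default to zero so the
intercept-only model is correctly specified; any subset of true moderator
effects can be switched on by name. Sample sizes are derived from the
sampling variances ($n_i \approx 1/v_i$), keeping precision and $n$
consistent, which matters for the Fisher-z path. A censoring hook
(`censor_fn`) lets bias experiments suppress records after generation.

What the generator does *not* emulate: telomere biology (attrition, assay
error structure), non-normal effect-size distributions, correlated
moderators, or dependence between sampling variance and true effect.
Passing tests therefore demonstrate the statistical machinery under its own
assumptions, not robustness to their violation on real data.

## Design choices where the design was open

* **Egger type-I experiment**: the unbiased generative model sets
  $\sigma_a^2 = 0$ (other components at their published magnitudes) so the
  generating structure matches the bias model's own random terms (study +
  species + estimate). With phylogenetic effects switched on, the
  experiment would measure model misspecification as well as size
  distortion.
* **Problem sizes**: the recovery experiment uses 200 replicates at the
  104/43/18 design; the type-I experiment 1000 replicates; bootstrap
  defaults to $R = 1000$ in the drivers. These sizes give Monte-Carlo
  standard errors small relative to the quantities examined.
* **Fisher-z variance** $1/(n-3)$, pluggable (see above).
* **Reference levels** fixed to the published table's parenthetical levels
  rather than alphabetical order, so coefficients are directly comparable.

## Known limitations

* Wald intervals for the mean use plug-in variance components with no
  small-sample degrees-of-freedom correction (the Knapp–Hartung adjustment
  is out of scope). At the design scale emulated here — few species, one
  dominant, components weakly identified — the simulation experiments show
  the consequences plainly: component estimates carry small systematic
  finite-sample biases (of order $\pm 0.004$ on the study and species
  components, from boundary truncation and study/species leakage), and
  coverage of the nominal 95% interval for the mean runs at roughly
  84–90%. Intervals built at the *true* components cover at ~94.5%, so the
  shortfall is attributable to variance-component estimation noise, not to
  the generator or the GLS step. This is a property of plug-in REML
  inference at this design, shared by the standard implementations it was
  validated against.
* The species/phylogeny decomposition is weakly identified with 18 species;
  single components should be interpreted through their bootstrap intervals,
  which routinely touch zero.
* LRT p-values use $\chi^2_1$ without the boundary correction by default
  (convention-compatible, conservative direction known); the mixture option
  exists but changes halving only.
* The pipeline reproduces a published analysis only given its deposited
  dataset; nothing in this package re-creates the literature search or
  screening that produced the dataset.
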