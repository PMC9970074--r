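---
title: "Modelling shared decision making competence as a skills network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling shared decision making competence as a skills network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Shared decision making (SDM) competence is usually measured either by
trained observers coding recorded consultations (expensive, slow) or by
averaging questionnaire ratings (cheap, but physician self-ratings
notoriously disagree with observer ratings). The skills-network approach
takes a third route: rather than treating the nine SDM skills of the
physician questionnaire (each rated 0--5 per consultation) as exchangeable
indicators of a single latent trait, it models competence as a structured
network of interacting skills. What carries the signal is not the level of any one
skill but how the skills co-vary within a physician's consultations: a
competent physician deploys skills in a coordinated pattern.

`sdmnet` implements that pipeline: per-consultation ratings go in, one
directed 9-node network per physician comes out, and network parameters
(activation, instrength, outstrength) feed Bayesian regressions that predict
per-physician observer-rated competence scores.

## The model

### Node-wise multilevel regression

For each skill $j \in \{1, \dots, 9\}$ we fit a Bayesian multilevel linear
regression of that skill on the other eight, pooled over all consultations
$i$ of all physicians $p$:

$$y_{ij} = b_{p(i)j0} + \sum_{k \neq j} b_{p(i)jk}\, y_{ik} + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma_j^2),$$

with physician-varying intercept and slopes
$\mathbf b_{pj} \sim \mathcal N(\boldsymbol\beta_j, \Sigma_j)$ (unstructured
$\Sigma_j$ by default, via a Wishart prior on its inverse; a flag drops the
correlations for very small data sets). The physician-specific coefficient is
by construction the population coefficient plus the physician's deviation at
every retained MCMC iteration. Sampling is done in JAGS through `rjags`.

The coefficient of predictor $k$ in the model for outcome $j$ becomes the
weight of the directed edge $k \to j$. This direction convention makes
*outstrength* (the row sums, see below) read literally as "how strongly a
skill influences the other skills".

Why this is principled rather than ad hoc: if the nine ratings were jointly
Gaussian with precision matrix $\Omega$, the node-wise regression
coefficients would equal $-\omega_{jk}/\omega_{jj}$ — the conditional
(partial) association structure. The synthetic-data generator exploits
exactly this identity to provide an analytic ground truth.

### Networks and node parameters

Per physician, edge weights are the posterior means of that physician's
coefficients. An edge is retained only when its 95% equal-tailed credible
interval (empirical posterior quantiles) excludes zero; everything else is
pruned as presumably spurious. Then, per skill:

* **activation** — the physician's mean rating of the skill across their
  consultations (0--5);
* **instrength** — the sum of retained incoming edge weights;
* **outstrength** — the sum of retained outgoing edge weights.

A population network uses the population-level (fixed-effect) coefficient
posteriors, with activation averaged over physicians with equal weight.
Node placement uses the Fruchterman--Reingold force-directed layout with
absolute edge weights as attraction strengths, so strongly associated skills
sit close together.

Two choices here were genuinely open and are configurable:

* *Which draws prune a physician's edges?* We use the physician-specific
  draws (physician-level inference for physician-level graphs);
  `prune_by = "population"` switches to population draws.
* *What is the population network?* We use the fixed-effect posteriors (the
  model's own population summary); `method = "average"` instead averages the
  physician-specific draws per iteration. On balanced data the two agree up
  to shrinkage, which a test verifies.

Strengths are always recomputed as plain sums over the retained weight
matrix, so the stored values are exactly reproducible by brute force, and
raw (unpruned) strengths are kept alongside for sensitivity analysis.

### Predicting observer-rated competence

Observer instruments (OPTION-12, OPTION-5, the Invest-in-the-End subscale of
the 4HCS) are rescaled to 0--100 and averaged per physician. Two analyses
regress these scores on network parameters with Gaussian-likelihood Bayesian
linear regression:

* **Confirmatory**: activation, instrength and outstrength of skills 1
  (focusing the decision), 6 (eliciting preferences) and 7 (deliberating the
  decision) — nine predictors — with per-coefficient informative Gaussian
  priors supplied as a file (typically posterior summaries from earlier
  work). Without a file the model falls back to weakly informative defaults
  with a warning. A clearly labelled *synthetic* example file ships under
  `inst/extdata/` to document the format; it is illustrative, not estimated
  from any dataset.
* **Exploratory**: stage 1 fits one model per parameter type (all nine
  skills' activations, then instrengths, then outstrengths) per instrument;
  a skill is selected when *any* of its parameters is significant in *any*
  stage-1 model — the most permissive selection rule; the stage-1 reports
  are exported in full so stricter rules can be audited against them. The
  final model uses all three parameter types of the
  selected skills, per instrument, with weakly informative priors. An empty
  selection produces an honest intercept-only model.

Reported per fit: coefficient posterior medians with 95% credible intervals
and a significance flag (interval excludes zero); the multiple correlation
$R$, defined as the posterior distribution of $\mathrm{cor}(\hat y^{(s)}, y)$
over draws $s$ and floored at zero so that $0 \le R \le 1$ (negative
correlations only arise in near-null fits); $R^2 = R \cdot R$ draw by draw;
and per-physician calibration pairs (posterior-mean prediction vs observed).
No multiplicity correction is applied anywhere; instead the test suite
quantifies the realized per-coefficient false-positive rate of the
machinery under a pure-noise null (it is 5%, as it should be).

## Priors and MCMC settings

Exact prior hyperparameters used in published applications of this approach
are not restated in main texts, so the package's defaults are standard
weakly informative choices, all overridable via `prior_spec()`:

* slopes: $\mathcal N(0, 2.5^2)$ on the 0--5 rating scale — wide relative to
  any plausible conditional association between two 0--5 items;
* intercepts: $\mathcal N(0, 10^2)$;
* residual SD: half-$t_3$ with scale 2.5;
* random-effect precision: Wishart with identity scale and dimension-plus-one
  degrees of freedom (a minimally informative proper choice);
* prediction models (response on 0--100): `autoscale = TRUE` rescales the
  slope prior SD by $\mathrm{sd}(y)/\mathrm{sd}(x_k)$ and centres the
  intercept prior at $\bar y$, so the same defaults are weakly informative
  regardless of predictor units.

A sensitivity test verifies that at $n = 500$ two different weakly
informative priors move posterior means by less than one posterior SD.

MCMC bookkeeping is explicit: `mcmc_config(n_chains, iterations, burn_in,
thinning)` retains `n_chains * (iterations - burn_in) / thinning` draws.
Shorthand recipes for such analyses often mix per-chain and total iteration
counts ambiguously, so every quantity here is per chain and the arithmetic
is enforced; the default — four chains, 10,000 iterations with 5,000
burn-in each, thinning 10 — retains exactly 2,000 draws, a customary
posterior sample size for this kind of model. Convergence is monitored by
split-half R-hat (each
chain halved, Gelman--Rubin over the half-sequences) for every sampled
parameter; the pipeline refuses to continue (configurable) when any R-hat
exceeds its threshold.

Seeds propagate deterministically: a master seed derives per-node,
per-chain and per-stage seeds, and two runs with the same configuration
produce byte-identical outputs and manifests.

## The synthetic-data generator

Because consultation-level SDM rating data are not publicly deposited, the
package validates itself on synthetic data with known truth. The generator
is first-class, tested code, not a fixture.

Each physician's nine ratings are multivariate Gaussian with precision
matrix $\Omega_p$. Node-wise regressions are exactly the conditionals of
this joint, so the true directed edge $k \to j$ is
$-\omega_{jk}/\omega_{jj}$ (true $k \to j$ and $j \to k$ weights differ when
the diagonal does). The default population structure encodes a realistic
skills topology: skills 1--2 form a strongly tied dyad conditionally
independent of everything else; skills 3, 4, 6 and 8 cluster around skill 7;
skill 5 hangs off 4 and skill 9 off 8. Partial correlations (0.18--0.45)
give marginal SDs near 1.1 rating points and pairwise correlations up to
0.45 — plausible for Likert-type skill items. Default item means sit in the
upper half of the 0--5 scale (physicians self-rate generously), with
planning actions highest.

Between-physician heterogeneity adds a symmetric Gaussian perturbation
(SD = `heterogeneity`, default 0.08) to the *structurally nonzero*
off-diagonal precision entries, with an eigenvalue floor and a
shrink-and-retry repair (and a hard error if the scale cannot be repaired).
Restricting the perturbation to the structural support keeps the
conditional-independence topology — including the disconnected 1--2 dyad —
true for every individual physician, not merely on average, which is what
the structural-recovery tests exercise. Physicians also receive their own
item means (population means plus Gaussian noise, SD = `mean_heterogeneity`,
default 0.3 rating points, clipped to [0, 5]); without this, true
activations would be identical across physicians and activation could not
predict anything.

Observer scores are linear in true network parameters plus Gaussian noise
(default SD 5 on the 0--100 scale), clipped to [0, 100]. The default
coefficient set makes activation and outstrength of skill 6 and outstrength
of skill 7 the drivers, echoing the kind of sparse dependence the
confirmatory analysis posits.

Discretization is clip-then-round onto the $\{0, \dots, 5\}$ grid. The
information loss this induces is accepted and *quantified* by tests
(recovery tests use continuous mode for exactness; discretized mode is used
where scale contracts matter). What the generator does **not** emulate:
response styles, item wording effects, ordinal measurement (graded-response
models), informative missingness, or observer-rater disagreement. Passing
recovery tests therefore demonstrate that the estimation machinery is
correct and calibrated under the stated generative model — not that real
consultation data satisfy that model.

Study-scale defaults follow the realistic scale of an outpatient SDM study:
28 physicians, 11 consultations each (308 rows), observer scores for a
24-physician subset with per-instrument coverage 22/24/22.

## Preprocessing choices

* Consultations with more than two of the nine skills missing are excluded
  (with a per-consultation report); one or two missing items are imputed.
* Imputation is expectation-maximization under a single multivariate
  Gaussian pooled over all consultations. Pooling is the default because
  per-physician row counts (often ~11) cannot support a stable 9-dimensional
  covariance; a per-physician option exists behind a flag. Imputed values
  are left continuous — the downstream regressions consume continuous
  values, and rounding would discard information. The observed-data
  log-likelihood is non-decreasing across iterations (tested), convergence
  is declared below a log-likelihood tolerance, and non-convergence is a
  hard error carrying the iteration trace. On monotone missingness patterns
  the EM fixed point has a closed form (complete-case least squares), which
  the tests use as an independent oracle at 1e-4.
* Observer instruments are rescaled affinely to 0--100 from configured raw
  ranges (ranges are configuration, not hard-coded), then averaged per
  physician; physicians without rated consultations are absent, not
  zero-filled.

## Numerical and degenerate-input behaviour

* A single physician (or `varying = "none"`) drops the grouping level and
  fits an ordinary Bayesian regression; physician draws equal population
  draws. This is also what makes the OLS oracle test exact.
* A constant outcome yields slope posteriors concentrated at zero; a
  rank-deficient prediction design is refused with the offending columns
  named; too few physicians for a prediction design is a hard "small-n"
  error at $n < p + 2$.
* Pruning uses empirical quantiles (type-7); degenerate draw sets (all equal)
  give a zero-width interval and behave correctly at the definition.
* Zero-variance parameters get split R-hat 1 by convention.

## Problem sizes used in validation

The test and acceptance runs use deliberately modest but adequate problem
sizes, chosen once as what a methodological validation in this field would
use: single-physician oracles at $n = 500$ consultations; pipeline recovery
at 30 physicians × 50 consultations (five replicates); prediction recovery
at 100 physicians with noise SD 5; null calibration at 200 physicians with
40--100 pure-noise replicates; and the study-scale structural run at 28
physicians × 11 consultations. Test fits run 2 chains × 1,000 retained
draws, above the 500-draw floor the pruning operation requires; production
defaults retain 2,000 draws from 4 chains.

## Known limitations

* The Gaussian likelihood treats 0--5 integer ratings as continuous; with
  strong ceiling effects (means near 5) edge weights attenuate. No ordinal
  variant is provided.
* Informative confirmatory priors must be supplied by the user; the shipped
  file is a synthetic format example.
* The exploratory procedure's selection step is not cross-validated; its
  realized false-selection behaviour is characterized under the null by
  simulation instead.
* R (multiple correlation) is floored at zero, so intercept-only and
  near-null fits report $R = 0$ rather than small negative correlations.
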