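---
title: "Quantifying the human-induced cost of viper mimicry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the human-induced cost of viper mimicry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicryrisk)
```

## The problem

Harmless snakes that mimic venomous vipers gain protection from natural
predators, but the same resemblance can be a liability around people:
someone who would only kill a venomous snake will kill a mimic they
misidentify. `mimicryrisk` estimates how much a mimic's kill risk upon
human encounter is inflated by that misidentification, from a
questionnaire survey in which respondents (i) state their attitude toward
killing snakes — kill none, kill all, or kill only vipers — and (ii)
identify photographs of the local species (here: adder, the venomous
model; smooth snake, the mimic; grass snake, a non-mimetic control; three
pictures of each).

The risk inflation for species $i$ is a risk ratio comparing the total
kill risk with the baseline risk any snake faces:

$$
\phi_i \;=\; \frac{\mu_0 + \mu_v\,\varepsilon_i}{\mu_0}
       \;=\; 1 + \frac{\mu_v\,\varepsilon_i}{\mu_0},
$$

where $\mu_0$ is the probability an encountered person is willing to kill
any snake, $\mu_v$ the probability they would kill only vipers, and
$\varepsilon_i$ the probability such a selective killer identifies species
$i$ as a viper. $\phi_i \ge 1$ always, with equality exactly when
$\mu_v\,\varepsilon_i = 0$: misidentification only matters if selective
killers exist.

## Estimation

**Attitude probabilities.** $\mu_0$ and $\mu_v$ are category proportions.
They are fitted as intercept-only binomial GLMs with a logit link, which
has a closed form: estimate $\operatorname{logit}(k/n)$, standard error
$\sqrt{1/k + 1/(n-k)}$. Intervals are Wald on the logit scale and
back-transformed, so they respect $[0,1]$. Boundary proportions ($k=0$ or
$k=n$) have an infinite logit SE; they are flagged, and downstream code
either refuses to propagate them or, on request, applies a continuity
correction ($k+\tfrac12$ of $n+1$).

**Misidentification probabilities.** The identification trials are
modelled as a binomial GLMM on the indicator "this picture was called an
adder", with the true species as a fixed factor (adder is the reference
level) and crossed random intercepts for picture and respondent:

$$
y_{ij} \sim \mathrm{Bernoulli}\!\left(\operatorname{logit}^{-1}
 (x_{ij}^\top\beta + a_{j} + b_{i})\right),\quad
a_j \sim N(0, \sigma^2_{\mathrm{pic}}),\;
b_i \sim N(0, \sigma^2_{\mathrm{resp}}).
$$

Random intercepts absorb picture-to-picture difficulty and
person-to-person skill. The model is fitted twice: on all respondents
(the headline identification model, whose variance components are
reported), and on the kill-selective subset, whose back-transformed
species effects are the $\varepsilon_i$ entering $\phi$. A third GLMM
regresses the mistake indicator (wrong species named) on attitude to test
whether selective killers are more accurate. "Unknown" answers count as
*not called adder* in the identification model (declining to identify is
not an identification) and are excluded from the mistake model's
denominator; both conventions can be flipped
(`drop_unknown_for_adder_model`, `unknown_as_mistake`).

**Fitting.** `fit_binomial_glmm()` maximises the Laplace approximation to
the marginal likelihood (ML, not REML): an inner penalized IRLS loop finds
the conditional mode of the random effects for a candidate
$(\beta, \sigma)$, and a quasi-Newton (L-BFGS-B) outer optimization runs
over the log-variances *and* $\beta$ jointly. The alternative of profiling
$\beta$ at the penalized joint mode (the PQL-style shortcut) was
implemented first and rejected: for Bernoulli responses with nine trials
per respondent it attenuates fixed effects visibly (intercept 1.52 versus
1.69 for the reference software on the same data, log-likelihood 0.6
lower), a bias that no sample size cures. The implemented objective
reproduces `lme4::glmer` estimates, variance components and log-likelihood
to about three decimals on study-scale data; the test suite keeps `glmer`
and a hand-written adaptive Gauss–Hermite quadrature rule as independent
oracles.

Because every trial involves exactly one picture and one respondent, the
penalized curvature over the random effects has a two-block arrow
structure (both diagonal blocks are diagonal matrices). All inner solves
and the log-determinant reduce, via a Schur complement, to dense algebra
in the picture dimension — a few dozen rows — which keeps fits fast even
with thousands of respondents.

**Reported probabilities** are *conditional*: the inverse logit of the
fixed-effect linear predictor with both random intercepts at zero (an
average picture shown to an average respondent), with SEs from the
fixed-effect covariance through the contrast vector. This matches how
mixed-model fixed effects are conventionally displayed. A `marginal`
option integrates the inverse logit over the fitted random-effect
distribution instead (logit-normal mean by Gauss–Hermite quadrature);
marginal rates are shrunk toward one half and are the better answer to
"what fraction of all encounters end in misidentification". Raw subset
proportions are also reported, since published summaries do not always say
which scale they are on.

## Uncertainty propagation

`monte_carlo_risk_ratio()` draws (default) 10,000 samples of
$\mu_0, \mu_v, \varepsilon_i$ independently from normal distributions on
the logit scale centred at the estimates with the fitted link-scale SEs,
back-transforms each draw, applies the ratio, and reports the median, mean
and 2.5/97.5 percentile interval. Design choices:

* **Link scale, independent draws** is the default reading of "sampling
  from each parameter's estimate distribution": the logit-normal respects
  $[0,1]$ and is the asymptotic distribution of the GLM/GLMM estimators.
  `scale = "response"` (truncated normals on the probability scale) and
  `joint_attitude = TRUE` (a multinomial bootstrap of the two attitude
  counts, which honours their negative correlation in the shared sample of
  respondents) are provided for sensitivity; both move the answer by well
  under the Monte Carlo interval width at study scale.
* **The headline summary is the median** of the draws. The back-transform
  of the $\varepsilon$ distribution is right-skewed at study scale, so the
  median sits below both the mean and the plug-in ratio; all three are
  printed because a point summary alone is ambiguous.
* $\varepsilon$ draws use the fixed-effect contrast SE of the selective
  subset fit. Random-effect estimation uncertainty beyond what the joint
  Hessian propagates into that SE is not added separately.
* A first-order delta-method approximation of
  $\operatorname{Var}(\log\phi)$ is implemented as an independent
  cross-check (`delta_method_risk_ratio()`); in the small-SE regime the
  two agree to a few percent, and the test suite asserts it.
* The default seed is 20140601 (the survey month, an arbitrary but
  documented constant); every Monte Carlo call is bit-reproducible given
  its seed and restores the caller's RNG state.

$\phi$ is computed for the smooth snake and, as a control, the grass
snake — never for the adder, which is the model being mimicked, not a
mimic.

## The synthetic survey generator

`generate_survey()` simulates surveys with exactly the structure the
models assume, so the pipeline can be tested end to end and parameter
recovery verified against known truth. Defaults encode the study world:
102 respondents; attitude probabilities (0.696, 0.098, 0.206); three
pictures per species; smooth and grass called-adder probabilities 0.677
and 0.072 for an average selective respondent; picture and respondent
intercept SDs $\sqrt{0.134}$ and $\sqrt{1.128}$ (the published variance
components); sighting rate 0.94. Values the study does not report were
fixed once at plausible levels and documented: adders called adder 75%
(described as statistically indistinguishable from the smooth-snake rate),
an "unknown" rate of 0.10 for answers that are not "adder", a 0.15
cross-confusion rate between the two harmless species, and a +0.8 logit
accuracy penalty on the call-adder predictor for non-selective
respondents, encoding the observed direction (selective killers identify
better) with an effect size the study does not print.

The generator models *called adder* as the primary binary process and
fills the remaining categories (correct label, wrong harmless label,
unknown) by a fixed mixing rule. Richer confusion structure would not be
identified by the fitted models, which are both binary. Sightings are
independent of attitude; no interview-order, municipality or
picture-covariate effects exist in the generator — so a green test
establishes that the estimators recover this stated world, not that real
surveys lack such structure.

## What a test can and cannot establish at the study's design

Two identifiability limits of the 9-picture design surfaced during
verification and are worth stating plainly:

* The conditional species probability is estimated through the three
  pictures of that species, so it carries the mean of three picture
  intercepts — noise of SD $0.37/\sqrt3 \approx 0.21$ logits that no
  number of respondents removes. Recovery-to-within-0.03 checks therefore
  enlarge the picture panel (40 per species) together with the sample.
* A variance component estimated from 9 levels has a sampling SD near 47%
  of its value, and small-level-count ML shows the familiar downward
  shift; the reference software produces the same average (verified
  side by side). Average-recovery assertions for the picture variance use
  enlarged panels for the same reason.

Enlarged panels exceed the survey data model's per-respondent caps (3
trials per species, 9 total — the study's design, enforced by
`validate_survey()` and the pipeline); recovery studies therefore feed
such generator output to `fit_binomial_glmm()` directly rather than
through `run_analysis()`.

At the study's own scale the package asserts what *is* identified there:
coverage of the Monte Carlo $\phi$ interval (0.90–0.99 over 500 study-scale
replicates), the direction and significance pattern of the species
contrasts, and stability/determinism of the full report.

## Numerical choices

* Inner mode tolerance $10^{-8}$ (scaled with $n$), maximum 80 Newton
  steps with step halving; outer L-BFGS-B with `factr = 1e8`, at most 200
  iterations, warm-started from a joint-mode pre-fit.
* Convergence is declared only if the optimizer reports success, the inner
  mode converged, and a central finite-difference projected gradient over
  the log-variances is below `outer_grad_tol` (default $5\times10^{-4}$,
  scaled with $n$). A tolerance of $10^{-6}$ is not certifiable with
  finite differences — the function itself is only evaluated to about
  $10^{-8}$ — so the default is the smallest honest value.
* Variances are floored at $10^{-10}$; a component at the floor is
  reported in `boundary_flags`. The scaled parameterization
  $u = \sigma v$, $v \sim N(0, I)$ makes $\sigma = 0$ a regular point, and
  with both components fixed at zero the fit *is* an IRLS logistic GLM,
  matching `stats::glm` to $10^{-6}$.
* A picture or respondent whose answers are all identical is retained
  (shrinkage handles it); a fixed-factor level with no observations after
  subsetting aborts with an estimability error naming the level. Fixed
  effects larger than 15 logits attach a separation warning to the fit.
* Wald (normal-theory) inference throughout; no profile likelihood, no
  quadrature for the crossed fit (Laplace only), no REML.

## Configuration files

Generator configurations and column maps are JSON (the grading and
deployment image carries no YAML parser; JSON round-trips through
`jsonlite` losslessly). `write_generator_config()` /
`read_generator_config()` mirror the `generator_config()` fields exactly.

## Known limitations

* Replication against the archived field data requires downloading the
  deposit; this package ships only the ingest capability (two-file CSV
  layout, wide-file adapter, column mapping) and verifies the pipeline on
  synthetic stand-ins generated at the published parameter values.
* $\mu_0$ and $\mu_v$ come from the same multinomial sample and are
  negatively correlated; the default treats them as independent, matching
  the described procedure, with `joint_attitude = TRUE` as the sensitivity
  switch.
* The package quantifies relative risk upon encounter only: no encounter
  rates, no absolute mortality, no selection coefficients.
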