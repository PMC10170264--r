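---
title: "Methods: competing-risks prognostic modelling with internal-external validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competing-risks prognostic modelling with internal-external validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

`crpredict` implements a comparative framework for developing and validating
models of a 10-year absolute risk — here, death from a disease of interest —
in the presence of a competing event (death from other causes), right
censoring, multi-region clustering, two calendar periods with falling event
rates, and missing covariate data. Four model-building strategies are
implemented on a common footing: Cox proportional hazards (competing deaths
censored), a direct competing-risks regression on the cumulative-incidence
scale, and two machine-learning regressions (gradient-boosted trees and a
feed-forward neural network) adapted to censored competing-risks data by
using jackknife pseudovalues as a continuous target. Evaluation uses
internal-external cross validation (IECV): whole regions are cyclically held
out, models are trained on period-1 data from the remaining regions, tested
on the held-out region's period-2 data, and the region-level metrics are
pooled by random-effects meta-analysis.

## Pseudo-observations

The central primitive is the jackknife pseudo-observation of a survival
functional at the horizon \(t^* \):
\[
\theta_i = n\,\hat\theta - (n-1)\,\hat\theta_{(-i)},
\]
where \(\hat\theta\) is either the Aalen-Johansen cumulative incidence of the
cause of interest or the Kaplan-Meier failure probability (competing deaths
censored), and \(\hat\theta_{(-i)}\) is the same estimator with subject
\(i\) removed. Pseudovalues behave like per-subject outcomes under covariate-
independent censoring: their mean equals the full-sample estimate exactly,
they reduce to event indicators on complete data, and with censoring they
may lie outside \([0,1]\) (the object records the range for downstream
clipping diagnostics).

`pseudo_values()` computes all \(n\) leave-one-out estimates exactly in
\(O(n \log n)\): removing subject \(i\) perturbs risk sets only at event
times \(\le t_i\), so all leave-one-out curves can be assembled from one
forward pass with "minus-one" denominators (prefix products of adjusted
hazards) and one backward hazard recursion for the tail beyond \(t_i\). The
implementation is tested for equality (tolerance 1e-10) against the literal
\(O(n^2)\) recomputation. At tied times events are processed before
censorings — the standard product-limit risk-set convention, fixed so that
the leave-one-out oracle agrees exactly. Pseudovalues are always computed
within the evaluation stratum at hand: the whole cohort for final-model
fitting, and the training and test strata separately inside each IECV cycle.

## Synthetic cohorts

The study data the framework is aimed at are confidential linked health
records, so the package ships a generator with known ground truth. The event
of interest follows a Fine-Gray mixture: given covariates and cluster
effects, the lifetime probability of the event of interest is
\(1-(1-p)^{\exp(x^\top\beta_{sub})}\) and conditional failure times follow the
inverse-transformed subdistribution
\(F_1(t)=1-\{1-p(1-e^{-\lambda t})\}^{\exp(x^\top\beta_{sub})}\), so the
complementary log-log of \(F_1(t^*)\) is *exactly linear* in the covariates.
This makes the cloglog pseudovalue regression well-specified and gives every
subject an analytic `truth` (the subdistribution CIF at the horizon) for
calibration and recovery tests. The competing event has an exponential
hazard with its own linear predictor; this direct-subdistribution design was
chosen over cause-specific-hazard simulation because the modelling targets
the subdistribution scale and exact ground truth is needed for
parameter-recovery tests.

Default study conditions (all documented artifact choices, since the
covariate-outcome process of the real data is unobservable): 10 regions with
Gaussian random intercepts (SD 0.08) on both linear predictors; two entry
periods with period-2 baseline rates multiplied by 0.83 on both processes
(matching the observed crude-rate drop from roughly 358 to 296 per 10 000
person-years between periods); `p_base = 0.15` and a conditional event-time
rate of 0.18/year, yielding a 10-year cause-1 cumulative incidence around
15-19% with a 6-10% competing incidence (inside the 10-25% band the cohort
tables motivate); exponential censoring at 0.03/year plus administrative
censoring at 10 years; covariate marginals loosely emulating the cohort
tables (age 63 (SD 14), BMI ~ 27, stage mostly I-II, predominantly
ER-positive); non-linear age effects via a centred quadratic term.
Missingness is injected missing-at-random through per-variable logistic
models in fully observed age and period (more missingness in period 1,
emulating historically poorer recording), with pre-masking values retained
in `.orig_*` shadow columns for imputation-quality diagnostics. An
ethnicity analogue with region-varying composition (but no direct outcome
effect) exists solely so that meta-regression has a genuinely
heterogeneity-linked cluster covariate.

What the generator does *not* emulate: correlated covariates, practice-level
clustering below region, informative censoring, calendar-time trends within
periods, and treatment variables. Passing tests therefore demonstrate
internal statistical correctness of the machinery, not transportability of
any conclusion to real data.

## Missing data

`impute_chained()` is a chained-equations multiple-imputation engine built
for this cohort layout. Each incomplete covariate is imputed conditional on
all other candidate predictors plus the auxiliaries the survival-imputation
literature recommends: the endpoint indicator (cause code as a factor), the
Nelson-Aalen cumulative hazard evaluated at the subject's follow-up time,
the entry period, and region (region is included on the argument that the
region-level intercepts make it informative; this is a documented package
choice). BMI is imputed on the log scale and exponentiated back.
Conditional models are predictive mean matching with five donors and a
Bayesian coefficient draw for continuous variables, Bayesian logistic
regression for binaries, multinomial logistic for unordered categoricals and
proportional odds for the ordered stage (the latter two draw imputations
from fitted class probabilities — a pragmatic approximation to a full
posterior draw). Ten cycles and m = 5 imputations are the desk-scale
defaults (m is configurable; large applications would use more). Conditional
fits are estimated on a capped random subset of responders (default 10 000)
purely for speed; imputations are always drawn for every missing row.
Rubin's rules (`rubin_pool()`) with Barnard-Rubin degrees of freedom pool
estimates across imputations; `stack_imputations()` produces the long table
the ML strategies train on.

## Model building

**Fractional polynomials.** Continuous predictors may enter through first-
or second-degree fractional polynomials with powers from
\(\{-2,-1,-0.5,0,0.5,1,2,3\}\) (0 = log; a repeated power \(p\) contributes
\(x^p\) and \(x^p\log x\)). `select_fp()` searches all 8 + 36 candidates by
deviance within the relevant family (Cox partial likelihood, or the
quasi-deviance of the pseudovalue GLM scaled by the null dispersion) and
applies a closed test at \(\alpha = 0.05\): best-FP2 against null (4 df),
against linear (3 df), then against best-FP1 (2 df). The exact closed-test
levels are not canonical; they are configurable, and this sequence is the
package's fixed default. FP terms are selected once in the complete cases of
the full cohort (per family) and reused inside IECV cycles — refitting the
search in every cycle was considered and rejected as disproportionate to its
cost at desk scale; the choice is recorded here deliberately.

**Predictor selection.** From a Rubin-pooled full model,
`select_predictors()` applies a deterministic magnitude-plus-significance
rule: binary/multilevel categorical predictors need an exponentiated
coefficient > 1.1 or < 0.9 *and* P < 0.01 (a multilevel variable enters
whole if any level qualifies — levels cannot enter alone); continuous terms
and interactions need P < 0.01. The rule is a pure function of the pooled
coefficient table, hence permutation-invariant and threshold-exact.

**Cox.** `fit_cox()` fits the selected model per imputation with Efron tie
handling and robust standard errors clustered on region, pools by Rubin's
rules, and stores the baseline survival at the horizon with continuous
terms centred at the mean and binary/dummy terms at zero. Baseline survival
is pooled across imputations on the cumulative-hazard scale
(\(S_0=\exp(-\bar H_0)\)); the pooling scale is not dictated by theory and
the cumulative-hazard scale is the package's choice. Predictions are
\(1-S_0^{\exp(x^\top\beta)}\).

**Competing-risks regression.** `fit_pseudo_cloglog()` regresses CIF
pseudovalues on the predictors in a constant-variance quasi-likelihood GLM
with complementary log-log link — coefficients on the subdistribution
(Fine-Gray) scale — with HC0 sandwich errors for the non-independence of
pseudovalues, Rubin-pooled. Predictions are \(1-\exp(-\exp(x^\top\beta))\),
in (0,1) by construction.

**Machine learning.** Both learners regress the same CIF pseudovalues with
a squared-error objective on the stacked imputations (m copies of each
subject), using the predictors selected for the competing-risks model,
dummy-coded, untransformed continuous values, and (for the network) min-max
scaling to [0,1] with training constants reused at prediction. The network
is fully connected with ReLU hidden activations, a single linear output,
Adam, batch size 1024, learning-rate halving after three plateau epochs and
early stopping after five epochs without a 1e-4 improvement. Tuning
(`tune_hyperparameters()`) is k-fold cross-validated RMSE between observed
pseudovalues and predictions over the declared ranges (boosting rounds,
learning rate, depth, subsampling, alpha/gamma/lambda regularisation and
column sampling for the trees; layers, width, epochs and learning rate for
the network). The default tuner is seeded random search rather than
model-based optimisation: the contract (budgeted search minimising CV-RMSE
within declared ranges, never worse than the default configuration, and
monotone in budget under a fixed seed stream) is identical and the desk
scale favours determinism and simplicity. Raw ML predictions may leave
\([0,1]\) and are clipped to probabilities for evaluation.

## Evaluation

Discrimination is Harrell's C truncated at the horizon for the Cox model
and an IPCW concordance for the three competing-risks formulations: cases
are cause-1 failures by the horizon; comparators are subjects still
event-free at the case's time (pair weight \(1/G(t_i-)^2\)) or earlier
competing-cause failures (weight \(1/(G(t_i-)G(t_j-))\)), with \(G\) the
Kaplan-Meier censoring-survival estimate evaluated as a left limit. Both
equal exhaustive pair enumeration exactly; when censoring is absent the
IPCW index reduces to unweighted competing-risks concordance.

Calibration is measured on the cloglog scale through pseudo-observation
GLMs for all four models (KM-failure pseudovalues for Cox, CIF pseudovalues
otherwise — one unified scale, a documented package choice): the slope is
the coefficient on \(\log(-\log(1-\hat p))\); calibration-in-the-large is
the intercept with that transform as offset, computed independently of the
slope rather than as slope − 1. Predictions are clipped by 1e-6 before the
link because clipped ML predictions can be exactly 0 or 1. Smoothed
calibration curves use a running-mean (lowess) smoother of individual
pseudovalues on predictions *without* robustness iterations — robust
reweighting would treat the two-point-mass shape of pseudovalues as
outliers and bias the curve (this mattered in practice and is tested).

Decision curves report net benefit
\(NB(p_t)=P(\hat p\ge p_t)\{F_{high}-(1-F_{high})\,p_t/(1-p_t)\}\) with
\(F_{high}\) the Aalen-Johansen CIF (competing risks accounted for) or the
Kaplan-Meier failure probability (not accounted for) in the high-risk
group, against treat-all and treat-none, on a default threshold grid of
0.01-0.50 by 0.01. Crude rates use the log-scale normal approximation
\(rate \times \exp(\pm 1.96/\sqrt{events})\), which reproduces the reference
interval arithmetic and satisfies
\(ci_{low}\times ci_{high}=rate^2\) exactly.

## Meta-analytic pooling

Region-level metrics (Rubin-pooled over imputations first) are combined by
Hartung-Knapp-Sidik-Jonkman random-effects meta-analysis with
DerSimonian-Laird \(\tau^2\) (the estimator is unstated in the methodology
this follows; DL is the package's fixed choice, without the "modified"
truncation), t-based confidence intervals on \(k-1\) degrees of freedom and
95% prediction intervals \( \hat\mu \pm t_{k-2}\sqrt{\tau^2+se^2}\) (the
\(k-2\) convention of the prediction-interval literature; note reference
implementations often use \(k-1\), which is why the package's PI is checked
against closed-form arithmetic rather than a library). Metrics are pooled
on their natural scale; logit-scale pooling of C is available as a
sensitivity flag. Meta-regression on region-level covariates uses the
moment-based residual \(\tau^2\), HKSJ-scaled coefficient errors, residual
\(I^2\), and \(R^2 = \max\{0, 100(1-\tau^2_{model}/\tau^2_{null})\}\)
clipped to \([0,100]\).

## The IECV pipeline

`run_iecv()` imputes once on the whole cohort (mirroring the design it
emulates, where one set of imputations feeds all steps), selects FP terms
and predictors from full data, then loops over regions: training data are
period-1 records from the other regions with follow-up truncated at the
period boundary (entrants surviving past it are censored there, making the
periods wholly temporally distinct); ML hyperparameters are tuned inside
the training set only (nested); pseudovalues are computed separately in the
training and test strata; predictions are made per imputation on the
held-out region's period-2 data; metrics are Rubin-pooled then HKSJ-pooled.
The held-out region is excluded from training entirely by default
(geographic plus temporal transfer); a `temporal_only` mode trains on all
regions' period-1 data — both modes are provided because the source design
is ambiguous on this point, and neither is claimed as "the" original
behaviour. Every cycle's training and test id sets are hashed and their
intersection recorded; the audit table must show zero overlap.

## Numerical choices and degenerate inputs

Quasi-GLMs start from pseudovalues clipped into (0.001, 0.999) (the cloglog
link cannot initialise outside (0,1)) and allow 100 IRLS iterations.
Constant predictions make the calibration slope undefined (an error; CITL
remains estimable via `calibration_citl()`). All-equal pseudovalues,
empty predictor lists, zero events, 100%-missing variables, k < 2 clusters
and collinear meta-regression covariates raise errors rather than guesses.
Pairs whose IPCW weight is undefined because \(G\) reached zero are dropped
with a warning. R integer seeds derived from the master seed stay below
\(2^{31}\).

## Problem sizes

The package's desk-scale reference runs — the sizes its own tests and
reproduction script use, chosen once as a realistic single-CPU workload —
are: calibration recovery at n = 50 000 with light censoring; coefficient
recovery at n = 4 000 over 100 replicates; prediction-interval coverage
over 500 simulated meta-analyses; and a full four-model IECV at n = 8 000,
10 regions, m = 3 imputations, tuner budget 6 with boosting rounds capped
at 150 and at most two hidden layers. Larger configurations (m = 5+, budget
15+, n in the tens of thousands) are plain parameter changes.

## Known limitations

Pseudovalue regression assumes covariate-independent censoring (the
generator's censoring is independent by design). The ML standard errors
enter meta-analysis through per-imputation metric SEs only — the learners
themselves carry no parametric uncertainty. The IPCW concordance SE is a
case-clustered linearisation, adequate for pooling weights but not exact.
Imputation draws for multinomial/ordinal variables come from fitted class
probabilities rather than a full parameter posterior, which slightly
understates between-imputation variance for those variables. No bootstrap
optimism correction is provided; validation rests on the IECV design.
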