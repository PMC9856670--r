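---
title: "Screening and prognostic modeling for competing risks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and prognostic modeling for competing risks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pshscreen)
```

## The problem

In many prognostic studies — bladder-cancer progression is the motivating
setting for this package — the endpoint of interest (progression or death
from the disease) competes with other events (death from unrelated causes).
A subject who dies of another cause can never progress, so naive
survival-analysis tools that censor competing deaths overestimate the
incidence of the event of interest. The quantity to model is the cumulative
incidence function (CIF)

$$F_1(t; X, Z) = \Pr(T \le t,\ \epsilon = 1 \mid X, Z),$$

the probability of failing *from cause 1* by time $t$ in the presence of
the other causes. At the same time, modern feature panels (gene expression,
metabolomics) supply $p \gg n$ candidate predictors next to a handful of
clinical covariates that must stay in the model. `pshscreen` implements the
full pipeline for this situation: conditional feature screening for the
Fine–Gray model, boosting-based selection with mandatory clinical
covariates, IPCW evaluation, and risk stratification.

## The proportional subdistribution hazards model

The subdistribution hazard of cause 1,
$\lambda_1(t) = -\,d\log\{1 - F_1(t)\}/dt$, is the instantaneous cause-1
failure rate among subjects who have not yet failed from cause 1 — a risk
set that deliberately retains subjects who already failed from a competing
cause. The Fine–Gray model assumes proportionality on this scale:

$$\lambda_1(t; X, Z) = \lambda_{1,0}(t)\, e^{\beta^\top X + \gamma^\top Z}.$$

With right censoring the subdistribution risk set is not fully observed
(a subject censored at $Y_i$ might or might not have failed from cause 2
later), so estimation maximizes a *censoring-weighted* log partial
likelihood: at each cause-1 event time $t$, a subject with an earlier
observed competing event stays in the risk set with weight
$w_j(t) = \hat G(t)/\hat G(Y_j)$, where $\hat G$ is the Kaplan–Meier
estimate of the censoring survival $\Pr(C \ge t)$. `psh_fit()` maximizes
this likelihood by Newton–Raphson with analytic score and information,
step-halving, and a relative log-likelihood tolerance of `1e-9` (at most
100 iterations, zero start — the Breslow-tie likelihood is concave, so a
zero start is robust). Two conventions are fixed once and used everywhere:

* $\hat G$ is **left-continuous** (its drop takes effect strictly after
  each censoring time), matching the "$\ge$" in $\Pr(C \ge t)$;
* at tied times, **failures precede censorings**: a subject failing at $t$
  is not in the censoring risk set at $t$. The conventions coincide with
  those of the standard competing-risks fitters on tie-free data, which is
  how the test suite cross-checks them.

Ties among cause-1 event times use the Breslow approximation. The baseline
cumulative subdistribution hazard $\hat H_{1,0}$ is the Breslow step
function, and predicted incidence is
$\hat F_1(t \mid x, z) = 1 - \exp\{-\hat H_{1,0}(t)\,
e^{\hat\beta^\top x + \hat\gamma^\top z}\}$.

Monotone likelihood (a feature perfectly ordering the events) is detected
by coefficient divergence and reported as a non-converged fit rather than a
spurious estimate. The reported coefficient covariance is the inverse
negative Hessian and is labeled *naive*: it ignores the sampling
variability of $\hat G$; the full influence-function sandwich is out of
scope by design.

## Conditional sure-independence screening (PSH-CSIS)

When $p + p_0 > n$ the partial likelihood cannot be maximized jointly.
Screening reduces the dimension first: for each feature $X_j$ fit the PSH
model with covariates $(X_j, Z)$ only and record its maximized log partial
likelihood $\hat u_j$. Since the controls-only maximum is a common
constant, ranking by $\hat u_j$ ranks features by their marginal
contribution *after adjusting for the mandatory controls* — this
conditioning is what makes the screening "controlled". The top $d$
features are recruited. Implementation choices:

* every per-feature Newton solve is warm-started at the controls-only
  $\hat\gamma$, which roughly halves the iteration count without changing
  the maximizer;
* a feature whose one-dimensional fit fails (constant column, separation,
  singular information) is demoted to $\hat u_j = \max_\gamma l_n(0,\gamma)$
  and flagged, never propagated as an error — with thousands of columns a
  few degenerate ones are certain, and screening must survive them;
* ties in $\hat u_j$ break by ascending feature index, making the ranking
  deterministic.

The default model size is $d = n - p_0 - 1$, the largest size that leaves
the downstream fit identifiable; $[n/\log n]$ and its small multiples are
available through `default_model_size()`. Sure screening — all truly
active features retained with high probability — is checked empirically in
the acceptance suite: with $n = 200$, $p = 500$ and four active features
at $|\beta| = 0.8$, the top-$[n/\log n]$ set contains all four in well
over 90% of replicates.

## Component-wise boosting with mandatory controls

After screening, `cv_boost()` performs the precise selection. Each step
computes, for every candidate feature, the first derivative $U_j$ and
curvature $I_j$ of the weighted partial likelihood at the current linear
predictor, updates the single coefficient maximizing the penalized score
statistic $U_j^2/(I_j + \lambda)$ by $\delta_j = U_j/(I_j + \lambda)$, and
then refreshes the *unpenalized* control coefficients by one Newton step
with the feature contribution as an offset — the clinical covariates are
never shrunk. The penalty defaults to $\lambda = 9 \times$ (number of
cause-1 events), making each update roughly one tenth of the unpenalized
Newton step, the customary calibration in the likelihood-boosting
literature. The number of steps $M$ is the effective tuning parameter,
chosen by $K$-fold cross-validation (10 folds by default, stratified by
cause code so every fold keeps cause-1 events): $M^*$ maximizes the mean
held-out weighted partial log-likelihood, each held-out fold evaluated
under its own censoring KM. Held-out likelihood is used directly rather
than the Verweij–van Houwelingen difference — simpler, and
monotone-equivalent in the regimes exercised here. Only $M$ is tuned;
$\lambda$ stays at its rule value.

## Evaluation

Prediction accuracy for the CIF is measured by the IPCW Brier curve

$$Err(t) = \frac1n \sum_i \{N_i(t) - \hat F_1(t \mid X_i, Z_i)\}^2 W_i(t),
\qquad
W_i(t) = \frac{I(Y_i \le t,\ \epsilon_i \ne 0)}{\hat G(Y_i-)} +
         \frac{I(Y_i > t)}{\hat G(t)},$$

with the *marginal* censoring KM throughout: subjects censored before $t$
get weight zero and the remaining observations are up-weighted to
compensate. The curve is only defined where $\hat G(t) > 0$; later grid
points are truncated with a warning. Training-set (apparent) error
underestimates true error, so `dot632plus()` blends apparent and
out-of-bag bootstrap error with the data-driven `.632+` weight, where the
no-information error pairs every subject with every prediction. Bootstrap
draws resample subjects with replacement, out-of-bag subjects form the
test set, and $\hat G$ is re-estimated on each out-of-bag set. The default
of $B = 100$ draws is the package's own choice.

Discrimination at a horizon $t$ uses the IPCW time-dependent ROC:
cases are cause-1 failures by $t$; controls are subjects event-free at $t$
*plus* subjects with a competing event by $t$ — the latter are known to be
free of the event of interest, which is exactly what the CIF predicts. The
AUC is the weighted concordance with ties counted one half, equal to the
trapezoidal area of the traced curve.

Risk stratification scores each subject by the selected-feature linear
combination $\hat\beta^\top x$ (the gene-signature value; controls
excluded so the score isolates the genomic contribution), splits at the
training median (strictly-greater = high risk; the frozen cutoff is reused
verbatim on the test cohort), and compares groups by Aalen–Johansen curves
and Gray's $K$-sample test. Gray's test and the Aalen–Johansen estimator
are delegated to `cmprsk::cuminc` and `survival::survfit` respectively —
the standard implementations — while everything upstream of them is this
package's own machinery; only the unweighted ($\rho = 0$) Gray test is
exposed, the default of the standard software.

## The simulator

`simulate_crdata()` draws from the classical unit-exponential mixture
design, chosen because the proportional-subdistribution assumption holds
*exactly* under it, giving a clean parameter-recovery oracle:

* cause assignment $\Pr(\epsilon = 1 \mid v) = 1 - (1-\pi)^{\exp(\eta_1)}$,
  with $\pi$ the baseline cause-1 mass and $\eta_1$ the true linear
  predictor;
* given $\epsilon = 1$, the event time is drawn by inverse-CDF from
  $F_1(t; v) = 1 - \{1 - \pi(1 - e^{-t})\}^{\exp(\eta_1)}$ (time unit =
  one baseline-exponential scale);
* given $\epsilon = 2$, an exponential time with log-rate $\eta_2$;
* independent $\mathrm{Uniform}(0, c_{\max})$ censoring.

Features are standard normal with optional AR(1) correlation; the default
controls are one standard normal plus one balanced binary column, echoing
the mix of continuous and dichotomous clinical covariates in a typical
cohort table. What the simulator does **not** emulate: microarray
intensity distributions (heavy tails, batch effects), covariate-dependent
censoring, and non-proportional subdistribution effects. Passing tests
therefore certify the estimators under the model's own assumptions, not
robustness to their violation.

Canonical study designs are frozen in `make_fixture()`:
`tiny` ($n = 8$), `screening` ($n = 200$, $p = 500$, four active features
at $|\beta| = 0.8$, $\pi = 0.5$, ~20% censoring), `boosting` ($n = 400$,
one dominant feature at $\beta = 1.5$ among 50), and `evaluation`
($n = 300$ with censoring calibrated into the 25–35% band via
$c_{\max} = 2.8$). For the parameter-recovery studies, $\pi = 0.3$ with
$c_{\max} = 3.1$ yields the stated 30% censoring.

## Numerical and design choices

* **Split.** The train/test split stratifies on the cross of cause code
  with quartile bins of the first control column and apportions each
  stratum by largest remainder, so each stratum lands within one subject
  of the target ratio and the overall train size is exact. This replaces a
  support-points ("optimal representative subset") scheme with a simpler
  stratified design that achieves the same stated goal — cohorts with
  similar clinical composition — in a directly testable way.
* **Degenerate weights.** If a reference $\hat G$ reaches zero before a
  competing event's follow-up time, that subject's late weights are
  undefined; they are set to 0 and flagged with a warning rather than
  propagating `NaN`.
* **Overflow.** Every risk-set log-sum-exp shifts by the maximum linear
  predictor first.
* **Determinism.** All randomness (splits, folds, bootstrap, simulator)
  flows through explicit integer seeds via a private RNG stream that never
  perturbs the caller's `.Random.seed`; rerunning any pipeline config
  reproduces every artifact byte-for-byte apart from timestamps.
* **Problem sizes in the validation suite.** The simulation studies run at
  their stated reference designs: coefficient recovery at $n = 1000$ over
  200 replicates; sure screening at $n = 200$, $p = 500$ over 100
  replicates; Gray-test calibration at $n = 200$ over 2000 replicates; and
  the benchmark-ordering study at $n = 300$, $p = 100$ over 50 replicates
  with 5-fold CV and 30 boosting steps — sizes chosen to make the Monte
  Carlo error small relative to the properties being checked while keeping
  the full suite runnable in a few minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(pshscreen)

d <- simulate_crdata(sim_config(
  n = 300, p = 100, p0 = 2,
  beta1 = c(0.8, -0.8, 0.8, -0.8, numeric(96)),
  gamma1 = c(0.3, 0.3), pi_mix = 0.5, censor_max = 6, seed = 42))

s <- split_train_test(d, ratio = c(4, 1), seed = 1)
train <- d[s$train_index]; test <- d[s$test_index]

sr <- psh_csis(train, d = default_model_size(n_subjects(train), 2,
                                             "n_over_logn"))
bf <- cv_boost(train, features = sr$selected, max_steps = 50, seed = 1)
fit <- boost_as_psh_fit(bf, train)

grid <- seq(0.5, 3, by = 0.5)
err <- brier_cif(test, predict_cif_matrix(fit, test$X, test$Z, grid), grid)
roc <- roc_cif(test, risk_score(fit, test), horizon = 1)
strat <- stratify(risk_score(fit, train), risk_score(fit, test))
gray_test(test, strat$test_group)
```

## Known limitations

* The coefficient covariance is naive (no $\hat G$ propagation); Wald
  intervals from `summary()` are labeled accordingly.
* No time-varying coefficients, stratified baselines, or left truncation.
* Censoring is assumed independent of covariates in all IPCW weights.
* The Lasso-penalized selector is not implemented; the boosting interface
  (`features` index in, coefficients out) is the seam where an alternative
  selector would plug in.
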