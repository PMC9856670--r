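# pshscreen

Feature screening and prognostic modeling for survival endpoints with
**competing risks**. The package is aimed at biostatisticians building
prognostic models from high-dimensional molecular data (gene expression,
metabolomics) where the clinical endpoint — say, cancer progression — can
be pre-empted by other events such as death from unrelated causes, and
where a handful of clinical covariates (age, grade, stage, treatment) must
remain in every model.

## What it computes

The modeling target is the cumulative incidence function (CIF)
`F1(t; X, Z) = Pr(T <= t, cause = 1 | X, Z)` under the Fine–Gray
proportional subdistribution hazards (PSH) model

```
lambda1(t; X, Z) = lambda10(t) * exp(beta'X + gamma'Z),
```

whose risk set keeps subjects who already failed from a competing cause,
weighted by the censoring Kaplan–Meier `G(t) = Pr(C >= t)`. On top of the
weighted-partial-likelihood fitter (`psh_fit`), the package provides the
full screening-then-selection pipeline:

* **PSH-CSIS** (`psh_csis`): conditional sure-independence screening —
  each feature `Xj` is scored by `u_j = max l_n(beta_j, gamma)`, the
  maximized PSH log partial likelihood of the model containing `Xj` plus
  the mandatory controls `Z`; the top `d` features are recruited
  (`d = n - p0 - 1` by default, or `[n/log n]` variants via
  `default_model_size`).
* **Component-wise likelihood boosting** (`boost_fit`, `cv_boost`): sparse
  selection among the screened features with *unpenalized* clinical
  covariates, step count tuned by cause-stratified K-fold CV.
* **IPCW evaluation** (`brier_cif`, `dot632plus`, `roc_cif`): prediction
  error `Err(t) = mean[(Ni(t) - F1_hat(t|Xi,Zi))^2 Wi(t)]` with inverse
  probability of censoring weights, the bootstrap .632+ correction, and
  time-dependent ROC/AUC where competing-event subjects count as controls.
* **Risk stratification** (`risk_score`, `stratify`, `aalen_johansen`,
  `gray_test`): median-cutoff high/low risk groups compared by
  Aalen–Johansen cumulative incidence and Gray's K-sample test.
* **A Fine–Gray simulator** (`simulate_crdata`) whose mixture design makes
  the PSH assumption hold exactly, so every estimator can be validated
  against known truth; `run_pipeline` orchestrates the whole analysis from
  a YAML config and writes TSV artifacts plus a reproducibility manifest
  (a CLI wrapper lives in `inst/cli/pshscreen.R`).

## Worked example

Simulate a 300-subject cohort with 100 features of which four carry signal
(`beta = +/-0.8`), two clinical controls, ~13% censoring and a competing
cause; then screen, boost, and evaluate on a held-out fifth:

```r
library(pshscreen)

d <- simulate_crdata(sim_config(
  n = 300, p = 100, p0 = 2,
  beta1 = c(0.8, -0.8, 0.8, -0.8, numeric(96)),
  gamma1 = c(0.3, 0.3), pi_mix = 0.5, censor_max = 6, seed = 42))

s <- split_train_test(d, ratio = c(4, 1), seed = 1)
train <- d[s$train_index]; test <- d[s$test_index]

sr <- psh_csis(train, d = default_model_size(n_subjects(train), 2,
                                             "n_over_logn"))
bf  <- cv_boost(train, features = sr$selected, max_steps = 50, seed = 1)
fit <- boost_as_psh_fit(bf, train)

grid <- seq(0.5, 3, by = 0.5)
brier_cif(test, predict_cif_matrix(fit, test$X, test$Z, grid), grid)
roc_cif(test, risk_score(fit, test), horizon = 1)
strat <- stratify(risk_score(fit, train), risk_score(fit, test))
gray_test(test, strat$test_group)
```

Output:

```
<screening_result: 43 of 100 features selected (null loglik -581.768)>
  top features: g2 (u=-559.041), g1 (u=-566.273), g4 (u=-566.577),
                g3 (u=-567.726), g57 (u=-578.257)
<boost_fit: 50 steps, lambda=1.04e+03, 4/43 features nonzero>
  CV-selected steps M* = 50 (of 0..50 candidates)
<pe_curve 'model' (apparent): 6 grid points, mean Err 0.1529>
<roc_result at t=1: AUC 0.8310 (26 cases, 30 controls)>
Gray's test (cause 1): chi-square = 17.9619, df = 1, p = 2.254e-05
```

Reading it: screening ranks the four truly active features (`g1`–`g4`)
first among 100 by their adjusted likelihood contribution `u`; boosting
keeps exactly those four nonzero; on the held-out cohort the signature
discriminates 1-unit-horizon progressors with AUC 0.83, and the
median-split risk groups have clearly different cumulative incidence
(Gray's p ≈ 2e-5 on 60 test subjects alone).

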