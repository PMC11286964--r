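# coxformer

Joint modelling of longitudinal biomarkers and right-censored survival
outcomes in randomized oncology trials, with a causal temporal
self-attention encoder and Cox proportional-hazards prediction heads.

`coxformer` is written for biostatisticians and ML researchers working on
clinical trial data — multiple myeloma is the motivating disease — who need
one model that simultaneously:

1. **forecasts biomarker trajectories** (M-protein, free light chains,
   hemoglobin, ...) over arbitrary horizons,
2. **predicts time-to-event risks** — progression-free survival (PFS),
   overall survival (OS) and twelve adverse-event categories — from any
   length of observed history, and
3. **estimates individual treatment effects** (CATE) between the two
   randomized arms, feeding subgroup discovery.

Because the real trial data such models are built on are proprietary, the
package ships a synthetic randomized-trial simulator with latent
disease-burden dynamics, proportional-hazards event generation, right
censoring and structured missingness, so every stage is trainable and
testable offline.

## The model

A patient's history — baseline covariates `B`, biomarkers `X(t)` with
observation mask `M(t)`, treatments `A(t)`, over 28-day treatment periods —
is embedded per period as one affine map of `[B, X(t), M(t), A(t), E(t)]`
(with `E(t)` a sinusoidal time embedding) and passed through `L = 2` layers
of **causal** self-attention:

    z_t^(l+1) = f_l( softmax( q_t K_{<=t}^T / sqrt(d_k) ) V_{<=t} ),

so states at period `t` use no information after `t`. Three head families
share the states: a forecasting MLP (`X̂_{t+1} = f_pred(z_t)`, iterated
autoregressively for longer horizons), and Cox event heads
`ŷ_t = f_event([z_t, ..., z_{t+K}])` trained on the negative Breslow partial
log-likelihood with a frozen backbone. Training is therefore two-stage:
forecasting pre-training, then event-head fine-tuning; bootstrap aggregation
(5 models, 1.5x resamples) provides uncertainty. Evaluation uses the
truncated IPCW (Uno) concordance averaged over event-time quantiles, masked
forecasting MSE against a last-observation-carried-forward baseline, and
paired-t / two-way-ANOVA comparison machinery. Counterfactual predictions
at baseline give `CATE = ŷ¹ − ŷ⁰`; a median-threshold policy plus a shallow
surrogate decision tree turn CATEs into an interpretable subgroup, assessed
on a held-out half by Kaplan–Meier curves, log-rank test and stratified Cox
regression.

See the vignette (`vignettes/joint-longitudinal-survival.Rmd`) for the full
methods account: normalization by clinical normal ranges with an invertible
squashing non-linearity, imputation and filtering rules, the simulator's
design, and every recorded convention.

## Worked example

```r
library(coxformer)

# 1. Simulate a two-arm randomized trial (400 patients, 12 periods)
cfg <- sim_config(n_patients = 400, n_periods = 12, seed = 7)
cohort <- generate_cohort(cfg)

# 2. Preprocess: split, filter, impute, normalize, standardize
plan <- split_cohort(400, seed = 7)
prep <- preprocess_cohort(cohort, train_idx = plan$trainval)

# 3. Pre-train the encoder on forecasting, then fine-tune the PFS Cox head
model <- init_model(prep, encoder_config(d_z = 16, tau = 8), seed = 1)
model <- pretrain(model, prep, idx = plan$trainval, epochs = 100,
                  lr = 3e-3, seed = 2)
model <- finetune_heads(model, prep, "pfs", idx = plan$trainval,
                        t_cond = 1, epochs = 150, lr = 2e-2, seed = 3)

# 4. Held-out evaluation: risk discrimination and forecasting vs LOCF
test <- subset_cohort(prep, plan$test)
out <- subset(prep$outcomes, event == "pfs" &
              patient_id %in% test$baseline$patient_id)
scores <- event_score(model, test, t_cond = 1, type = "pfs")
averaged_cindex(scores, out$time, out$status)
truth <- list(X = test$X[, 2:7, ], M = test$M[, 2:7, ])
forecast_mse(rollout(model, test, 1, 6)$X_pred, truth$X, truth$M)
forecast_mse(locf_forecast(test, 1, 6), truth$X, truth$M)

# 5. Individual treatment effects from baseline
po <- predict_potential_outcomes(model, test, horizon = 6)
mean(po$cate)
```

Output from this exact script:

```
averaged IPCW C-index (PFS): 0.685
forecast MSE  model: 0.081   LOCF: 0.191
mean CATE on test fold: -0.366 (negative = IRd lowers predicted progression risk)
```

Read: on held-out patients the fine-tuned PFS head ranks event times well
above chance (C-index 0.685 vs 0.5 for random guessing); the rolled-out
6-period forecasts more than halve the LOCF baseline's error on the
normalized scale; and the model recovers the sign of the simulated
treatment benefit (the experimental arm was configured with a protective
log hazard ratio).

A command-line surface wraps the same pipeline (`simulate`, `preprocess`,
`pretrain`, `finetune`, `evaluate`, `forecast`, `predict-events`, `cate`,
`subgroup`, `introspect`):

```sh
Rscript inst/cli/coxformer.R simulate --config cohort.yaml --out sim/ --seed 7
```

Every run writes a manifest (config hash, seed, package version) next to its
outputs.

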