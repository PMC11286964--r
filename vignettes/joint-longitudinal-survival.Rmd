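---
title: "Joint longitudinal forecasting and survival prediction with a causal transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint longitudinal forecasting and survival prediction with a causal transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Managing multiple myeloma requires balancing three linked questions about one
patient: how long until progression or death, which adverse events threaten,
and where the disease-burden biomarkers (monoclonal protein, free light
chains, hemoglobin, creatinine, ...) are heading. `coxformer` models all
three jointly. A single temporal encoder turns a patient's clinical history —
baseline covariates $B$, longitudinal biomarkers $X(t)$ with an observation
mask $M(t)$, and treatments $A(t)$, indexed by 28-day treatment periods — into
a sequence of hidden states $z_t$, and separate prediction heads read risk
scores and one-step biomarker forecasts off those shared states.

The package targets two-arm randomized trials (an experimental triplet "IRd"
versus a control doublet "Rd" in the shipped simulator), which is what makes
the counterfactual layer honest: randomization at baseline licenses
predicting each patient's outcome under both arms and differencing the two.

## Architecture

**Input embedding.** At each period the concatenation
$[B, X(t), M(t), A(t), E(t)]$ is passed through one learned affine map to
dimension $D_z$. $E(t)$ is a sinusoidal time embedding,
$E_{2k}(t) = \sin(t / T_{\max}^{2k/\tau})$,
$E_{2k+1}(t) = \cos(t / T_{\max}^{(2k+1)/\tau})$. The mask is itself an input
channel; masked biomarker values are imputed, so the model always sees a
complete matrix plus the information of *what* was actually measured.

**Causal self-attention.** Each of $L = 2$ layers computes queries, keys and
values as linear maps of the (layer-normalized) states and attends with
softmax$(q_t K_{\le t}^\top / \sqrt{d_k}) V_{\le t}$, restricted to periods
$\le t$. The causal (lower-triangular) mask is not optional decoration: every
prediction contract in the package ("a score at $t$ uses no information after
$t$") rests on it, and a dedicated test suite perturbs future inputs and
asserts bit-level invariance of earlier outputs. With $H$ heads, $d_k$ is the
per-head key dimension $D_z/H$ (the natural reading when the state is split
across heads; one head is the default). Attention is followed by a pre-norm
residual block with a ReLU feed-forward map of width $4 D_z$ — residual
placement and width are unspecified in the underlying design space, so they
are configurable, with these defaults.

**Heads.** A forecasting MLP maps $z_t^{(L)}$ to $\hat X_{t+1}$. Event heads
for progression-free survival (PFS), overall survival (OS) and twelve
adverse-event categories consume the concatenation
$[z_t^{(L)}, \ldots, z_{t+K}^{(L)}]$, where the $K$ future states are
produced by autoregressive rollout (default $K = 1$). Heads are
one-hidden-layer ReLU perceptrons when the non-linearity flag is on, affine
otherwise.

**Rollout.** Multi-step forecasts feed each prediction back as the next
period's input, with the mask channel set to "observed" (a prediction
substitutes for a measurement). Treatments and time embeddings advance with
the rollout by default; a `literal_rollout` flag reproduces the strict
one-step-update reading in which $A(t), E(t)$ are reused, for comparability.

## Preprocessing

Longitudinal variables are normalized by their *clinical normal range*
$(\alpha_j, \beta_j)$: $x^* = 4(x - \alpha_j)/(\beta_j - \alpha_j) - 2$ maps
the normal range onto $[-2, 2]$, after which an invertible squashing
non-linearity $x^\dagger = 7/(1 + e^{-0.25 x^*}) - 3.5$ bounds every value in
$(-3.5, 3.5)$ while keeping near-unit slope around the normal range — so the
clinically informative low range keeps its variance while the huge
above-range excursions typical of immunoglobulins are compressed rather than
allowed to dominate the loss. Variables whose values run far above their
normal range (free light chains in the shipped table) carry an extra $1/5$
scale factor; it is applied to the range-normalized value $x^*$ *before*
squashing (whether the scaling acts before or after the range map is
ambiguous in the design space; the choice is recorded as the `scale_raw`
flag, and the default keeps $\alpha_j \mapsto$ a fixed point independent of
the factor). Normal ranges ship as an editable CSV: they are configuration,
not constants.

Baseline covariates are standardized with means and standard deviations
fitted on the training fold only; categoricals are one-hot encoded;
zero-variance columns scale by 1 with a warning. Missing baseline
categoricals take the mode, continuous the mean; longitudinal values missing
at the first period take the training-fold mean there, later gaps are
forward-filled. Variables missing in more than 15% of patients (baseline) or
70% of panel entries (longitudinal) are dropped — the thresholds are read as
maxima: a variable is *retained* when its missingness is below the
threshold. Splitting is 80/20 with five 75/25 resplits of the 80% for
validation; the smaller partition is floored.

## Training

Training is two-stage. **Pre-training** minimizes the masked forecasting
loss — per patient, squared one-step error summed over observed entries and
divided by that patient's observed count, then averaged over patients —
with Adam under teacher forcing. All gradients are exact analytic backprop
through the attention stack (verified against central finite differences at
$10^{-4}$ relative tolerance in the tests). **Fine-tuning** freezes every
backbone parameter and trains only the selected event head on the negative
Breslow partial log-likelihood
$-\sum_{i:\Delta_i = 1}\big(\hat y_i - \log \sum_{j \in R(y_i)} e^{\hat y_j}\big)$,
with scores taken at the conditioning time. A landmark-weighted variant
(each event term weighted by $\sum_{t \ge y_i} 1/d(t)$, reducing the
landmark-aggregated sum to reweighted partial likelihoods) is available
behind a flag. Ties use Breslow's convention — the simplest one consistent
with a plain risk-set sum. The freeze is a contract, not an intention: tests
serialize the backbone before and after fine-tuning and require
byte-identical bytes and identical rollouts. The twelve adverse-event
outputs are fine-tuned jointly with a summed loss by default (per-column
optimization sits behind `ae_joint = FALSE`).

Bootstrap aggregation trains five models on with-replacement resamples of
the training set at 1.5 times its size; predictions are aggregated by the
mean and the between-model standard deviation is the uncertainty estimate.
The tuning grid is hidden dimension {16, 32}, dropout {0.1, 0.2}, rollout
window {0, 1}, 2 layers, linear/non-linear event head; selection is by mean
validation forecasting loss across the five folds, and $K = 1$ is the
default when tuning is skipped. Optimizer defaults (Adam at $10^{-3}$ for
pre-training, $10^{-2}$ for head fine-tuning, full-cohort batches at these
problem sizes, optional early stopping on validation loss) are package
decisions.

## Evaluation protocol

Event prediction is scored by the truncated IPCW (Uno-type) concordance:
pairs $(i, j)$ with an observed event $y_i < y_j$, $y_i \le \tau$, weighted
by $1/G(y_i^-)^2$ where $G$ is the Kaplan–Meier estimate of the censoring
survival. Where events and censorings tie, events are taken to occur first
(the censoring risk set at $t$ excludes subjects with an event at $t$); this
convention is recorded here once and used everywhere. The headline metric
averages the concordance over the 25th/50th/75th quantiles (linear
interpolation) of the *evaluation fold's* observed event times — whether the
full cohort's or the test fold's quantiles are meant is unspecified, and the
test fold is chosen as the self-contained option. With no censoring and
$\tau$ past the last event the estimator provably equals Harrell's pairwise
concordance, and the tests hold it to an all-pairs enumeration oracle.

Forecasting is scored by masked MSE on the normalized scale over the window
$(t_{\text{cond}}, t_{\text{cond}} + t_{\text{horizon}}]$, against a
last-observation-carried-forward (LOCF) baseline. Grid evaluation reports
mean ± between-model sd over the bagged models per (task, window, horizon,
subgroup) cell; Ig-subtype cells with fewer than five evaluable patients are
reported missing rather than zero. Method comparison uses a paired t-test
across the five per-fold models (4 degrees of freedom — five replicates only
yield df = 4 when paired; the unpaired Welch test is available behind an
argument) and an overall two-way ANOVA without interaction (method +
condition cell), Bonferroni-corrected across method pairs.

## Counterfactuals and subgroup discovery

Potential outcomes are predicted **at baseline only** — the only time point
at which randomization holds — by running the model twice with the treatment
arm indicator in $B$ and the dosages in $A$ rewritten to each arm, sharing
the identical $X(0)$. The conditional average treatment effect is
CATE $= \hat y^1 - \hat y^0$ on the risk-score scale (negative = the
experimental arm lowers predicted progression risk). Raw Cox scores are used
by default: the median-threshold policy is invariant to monotone rescaling,
so the normalized score (below) changes nothing and sits behind a flag.

Subgroup discovery uses a dedicated 50/50 split: preprocessing statistics,
model weights, the CATE threshold $\delta$ (the training-half median CATE)
and a depth-3 surrogate classification tree on baseline covariates are all
derived from one half; Kaplan–Meier curves, the log-rank test and a
(optionally stratified) Cox arm effect are estimated on the other. The
stratification variables are configurable rather than fixed. A sentinel test
rewrites the held-out half's biomarkers and asserts the learned policy is
bit-identical.

## Introspection

For interpretation, the package reports (i) Pearson correlation maps between
each hidden dimension and the predicted risk / next-step biomarker
predictions at inspection times {1, 3, 6, 9, 12} periods, with a 0.4 display
threshold that filters the display set but never the stored values, and with
undefined correlations (constant dimensions) excluded rather than zeroed —
zeroing would fabricate evidence of no association; (ii) patient-level
narrative summaries using the normalized risk
$(\hat y - \hat y_{\min})/(\hat y_{\max} - \hat y_{\min})$ over the
training-set score range, read as a cohort quantile ("70% of patients have a
lower risk score"), with forecasts de-normalized to clinical units and
labelled up/down/flat by slope; and (iii) a thin 2-D embedding hook for the
baseline hidden states, defaulting to classical multidimensional scaling
with any user routine accepted.

## The synthetic trial simulator

The simulator is first-class, tested code, and defines the study conditions
under which every claim in the test suite is evaluated. Each patient carries
a scalar latent disease burden: initial value log-normal around an
ISS-stage-driven mean, then a discrete-time linear update
$b_{t+1} = \rho_{\text{arm}} b_t + \varepsilon_t$ with arm-specific decay
($\rho = 0.95$ control, $0.88$ experimental — treatment clears disease
faster under the triplet). Biomarkers are affine emissions of the burden
(positive loadings for M-protein, light chains, creatinine; negative for
hemoglobin and albumin, i.e. anemia tracks burden) with Gaussian noise
proportional to each loading. Events follow discrete-time proportional
hazards $h_t = 1 - \exp(-\exp(\beta_0 + \beta_b b_t + \beta_a \cdot
\text{arm}))$ sampled period by period, with uniform random censoring plus
administrative censoring at follow-up end; adverse events use positive
$\beta_a$ (toxicity) and only qualifying events are emitted — grades are not
modelled. Arm assignment is Bernoulli(1/2) independent of all covariates.
Ig-subtype marginals default to the published newly-diagnosed-cohort mix
(IgG 57.3%, IgA 20.2%, ...). Missingness is MCAR by default with a monotone
dropout option, since the real trials' missingness process is not
characterized — an emulation, not a calibration.

Two generator choices deserve explanation. First, the initial-burden log-sd
defaults to 0.6: this was calibrated so that the *true burden itself*, used
as a risk score, attains an averaged concordance near 0.67 on a large
cohort — the discrimination level real myeloma risk models reach — making
"recover the signal" a meaningful bar. Second, ground-truth fields (burden
paths and a per-patient true CATE computed on the noise-free burden path)
exist purely so recovery tests can be written; nothing in the modelling
pipeline reads them.

What the simulator deliberately does not emulate: pharmacokinetics, dose
modification, cytogenetics, informative missingness, competing risks, or
any real-data marginal beyond the subtype table. Tests that pass on this
simulator therefore certify the machinery (information contracts, losses,
estimators, recovery under correct specification), not clinical validity on
trial data.

## Problem sizes and numerical choices

The shipped tests train at deliberately modest sizes chosen as the smallest
that make the scientific point: signal recovery uses 600 patients over 18
periods with 150 pre-training epochs; subgroup recovery uses ten replicate
trials of 800 patients over 12 periods with an injected IgA-only log-HR of
−1. Layer normalization uses $\varepsilon = 10^{-5}$; dropout is inverted
(scaled at train time); softmax rows are max-shifted before exponentiation;
the Cox loss shifts scores by their maximum (it is shift-invariant);
degenerate cases error loudly rather than silently (no events, no comparable
pairs, degenerate score ranges, empty grids). All randomness flows through
explicit integer seeds, with child seeds derived by hashing a stream label,
so every artifact is reconstructible from its manifest.

## Known limitations

The encoder is small by design and trained full-batch on CPU; this is a
research replica, not a production training stack. The IPCW estimator
assumes censoring independent of covariates (plain Kaplan–Meier weights).
CATE estimates inherit the model's misspecification and carry no
post-selection inference correction — the subgroup analysis is
hypothesis-generating. The 2-D embedding hook defaults to MDS, which
preserves global rather than local structure; any manifold learner can be
plugged in.
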