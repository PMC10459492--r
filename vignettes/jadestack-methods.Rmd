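---
title: "Methods: stacked ensemble identification of stimulus-evoked time series"
author: "jadestack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble identification of stimulus-evoked time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The identification problem

The package targets single-input/single-output stimulus-response records
of the kind produced by evoked-response experiments: a designed periodic
perturbation $u(t)$ (for example a multisine wrist-angle perturbation)
drives a strongly nonlinear dynamic system whose noisy output $y(t)$ (for
example the amplitude of one independent EEG component) is observed at a
fixed sampling rate. Linear models explain only a small share of the
output variance in such systems, so the package fits a nonlinear
autoregressive model with exogenous input (NARX),

$$y(t) = f\{y(t-1),\dots,y(t-n_y),\ u(t-1),\dots,u(t-n_u),\
u^F(t-1)\} + \varepsilon(t),$$

where $f$ is learned by a stacked ensemble and $u^F(t-1)$ is a set of six
engineered features of the once-lagged input: the rolling mean, standard
deviation and skewness over a causal window of three samples, the first
difference $u(t-1)-u(t-2)$, the cube $u(t-1)^3$, and a signed logarithm
$\operatorname{sign}(x)\log(1+|x|)$. The default lag depths are $n_y=5$
and $n_u=3$; the first $\max(n_y,n_u,w)=5$ samples of every signal are
discarded as burn-in so that every regressor is fully observed, and lags
never cross signal boundaries. The design matrix satisfies a strict
no-lookahead contract: the row predicting $y(t)$ references only samples
at times $\le t-1$ (this is asserted by a mutation test in the suite).

A plain logarithm is undefined on a zero-crossing perturbation signal, so
the package uses the odd, total, monotone transform
$\operatorname{sign}(x)\log(1+|x|)$ as its logarithmic feature. Rolling
standard deviation uses divisor $w-1$; skewness is the moment coefficient
$g_1 = m_3/m_2^{3/2}$ with the convention $g_1 = 0$ at zero variance.

## Experimental protocol

Each participant contributes seven periodic perturbation signals. The
first six form the training set; the seventh is held out as the test
record. Cross-validation is leave-one-signal-out over the six training
signals (six folds), which keeps entire records together and respects the
dependence structure within a signal. One independent model is fitted per
participant.

## The stacked ensemble

**Layer 0** consists of five deliberately diverse base regressors:

| learner | family | tuned hyperparameters (defaults) |
|---|---|---|
| LASSO | regularised linear model | penalty $\lambda \in \{0.001, 0.01, 0.1, 0.9\}$ |
| MLP | single-hidden-layer network, sigmoid hidden / identity output | hidden units $\{1,3,5\}$ |
| GP | Gaussian process, RBF kernel | kernel width $\sigma \in \{0.01, 0.03, 0.08, 0.2\}$ |
| SVR | support-vector regression, RBF kernel | $\sigma$ as GP; cost $\{0.25, 0.5, 1\}$ |
| XGBoost | gradient boosting, linear booster | rounds $\{50,150\}$, rate $\{0.3,0.4\}$, L1/L2 $\{0,10^{-4},0.1\}$ |

Every learner is grid-searched by six-fold cross-validated RMSE (first
grid point wins ties), its out-of-fold (OOF) predictions at the chosen
point are retained, and the learner is refitted on all training rows.
Grid contents are configurable through `stack_learners()`; the defaults
bracket the magnitudes such models select on evoked-response records.
The boosting learner uses the linear booster with the deterministic
coordinate-descent updater, which makes its fits exactly reproducible on
a single thread.

**Layer 1** is a rule-based meta-learner that receives the $n \times 5$
OOF prediction matrix $Z$ as its inputs. Using OOF predictions during
training (rather than refit-on-all predictions) is the standard guard
against information leakage in stacked generalization: the meta-learner
never sees a base prediction produced by a model that was trained on that
row. At prediction time the base learners refitted on all training rows
produce the meta inputs.

## The rule-based meta-learner

`cubist_rules()` implements a Cubist-style rule-based regression with the
two hyperparameters the tuner searches — committees and neighbors — as a
documented approximation rather than a re-implementation of any specific
Cubist release:

1. a variance-reduction model tree is grown (minimum leaf size 8, a
   split must reduce the node's squared error by at least 1%, depth cap
   12), with a linear model at every node;
2. the tree is post-pruned bottom-up: a split is collapsed whenever the
   node's own model has no worse adjusted error
   $\overline{|r|}\,(n+p)/(n-p)$ than the cover-weighted error of its
   subtree;
3. each surviving leaf's model is smoothed with its ancestors' models
   (weights $n : k$ with $k = 15$), the classic M5 guard against
   small-leaf overfitting — because all node models are linear, every
   smoothed leaf model is again linear with closed-form coefficients;
4. the smoothed leaves are flattened into mutually exclusive rules; a
   global linear fallback guarantees a prediction for every input.

Node models are fitted by ridge-stabilised least squares on standardised
predictors with $\lambda = 0.01\,n$, followed by a coefficient-pruning
pass that drops predictors contributing less than 1% of the response
spread. The ridge floor matters: stacked base predictions are strongly
collinear, and unregularised leaf fits on a handful of rows produce
enormous opposite-signed coefficients that explode on held-out data. The
fixed shrinkage fraction of 1% is negligible on well-determined
directions but dominates the near-null directions responsible for the
instability. Predictions are additionally truncated to the training
target range extended by half its span — a deliberately wide guard that
stops runaway extrapolation without touching ordinary out-of-range
predictions (held-out records legitimately exceed the training extremes).

*Committees* ($c \in [0, 60]$): member $j>1$ is trained on the corrected
pseudo-target $y + (y - \bar{\hat y}_{j-1})$, where $\bar{\hat y}_{j-1}$
is the running average prediction of members $1..j{-}1$; the final
output averages all members. $c = 0$ and $c = 1$ both mean a single
member. *Neighbors* ($k \in [0, 20]$): the committee prediction $m(x)$
is blended 50/50 with a weighted average over the $k$ nearest training
rows (Euclidean distance on training-standardised features) of the
adjusted values $y_n + m(x) - m(x_n)$, weighted $1/(d_n + 0.5)$; $k = 0$
disables the correction. An external rule-model implementation can be
substituted through the `backend` argument; the tuner and the stack
operate unchanged against the seam.

## Hyperparameter tuning by adaptive differential evolution

The committees/neighbors pair is chosen by maximising the mean six-fold
cross-validated VAF of the meta-learner on $(Z, y)$ over the integer box
$[0,60]\times[0,20]$, with a budget of population 10 and 10 generations.
`jade()` implements the self-adaptive "current-to-pbest/1" strategy:

* initialisation uniform in the box, $x = LB + r\,(UB - LB)$;
* mutation $v_i = x_i + F_i(x^p_{best} - x_i) + F_i(x_{r1} -
  \tilde x_{r2})$, with $x^p_{best}$ drawn from the top
  $\lceil p\,NP \rceil$ candidates ($p = 0.05$), $r_1$ from the
  population and $\tilde r_2$ from the population plus an archive of
  replaced parents (capped at $NP$ by random removal);
* per-individual $F_i \sim$ Cauchy($\mu_F$, 0.1), resampled while
  non-positive and truncated to 1; $CR_i \sim$ Normal($\mu_{CR}$, 0.1)
  clipped to $[0,1]$;
* binomial crossover with a forced coordinate $j_{rand}$;
* strictly-better selection (ties keep the parent, and only successes
  record $F_i$, $CR_i$ and archive the parent);
* after each generation $\mu_F \leftarrow (1-c)\mu_F + c\,
  \mathrm{mean}_L(S_F)$ with the Lehmer mean $\sum s^2/\sum s$, and
  $\mu_{CR} \leftarrow (1-c)\mu_{CR} + c\,\overline{S_{CR}}$, with
  $c = 0.1$ and both initialised at 0.5.

Mutants violating a bound are repaired by midpoint reflection toward the
parent, $v_j \leftarrow (b_j + x_{i,j})/2$, which preserves diversity
relative to clipping. Integer dimensions are rounded half-away-from-zero
and clamped at evaluation time only, so the search stays continuous.
Non-finite objective values are treated as worst-possible fitness rather
than raised, so a stochastic learner failure cannot abort a tuning run.
$p = 0.05$ and $c = 0.1$ are the canonical settings for this algorithm
family and are exposed in the configuration. A classic fixed-parameter
DE (`de_classic()`, rand/1/bin, defaults $NP = 100$, $CR = 0.5$,
$F = 0.2$) is available as a baseline tuner, and `tuner = "grid"`
enumerates the whole integer box exactly.

The tuning objective is served by a per-fold incremental cache: committee
members are fitted at most once per fold up to the largest committee
count ever requested, and the neighbor correction reuses precomputed
nearest-neighbor tables, so the cost of the evolutionary search is
bounded by the grid size rather than the number of objective
evaluations. After tuning, the meta-learner is refitted on all training
rows at the tuned pair.

## Prediction and evaluation

One-step prediction feeds the observed lags through the refit base
learners and the tuned meta-learner. Multi-step prediction at horizon
$h$ is recursive: the one-step predictor is iterated, substituting its
own predictions into the output-lag slots beyond the forecast origin
while all input-derived regressors keep using the known perturbation
signal (the input is a designed, exogenous quantity). Recursion carries
prediction errors forward, which is why accuracy degrades with horizon;
$h = 1$ is bitwise identical to the one-step path.

Accuracy is measured by variance accounted for,
$\mathrm{VAF} = 100\,(1 - \mathrm{var}(y - \hat y)/\mathrm{var}(y))$
(sample variance, divisor $n-1$, in both terms — the ratio is
insensitive to the estimator as long as it is consistent), and RMSE.
VAF ignores a constant prediction offset and can be negative.

Models are compared across participants by the Friedman rank test in its
mean-rank form (average ranks on ties by default) followed by the
Nemenyi critical difference
$CD = q_{\infty,k,\alpha}/\sqrt2 \cdot \sqrt{k(k+1)/(6n)}$, with the
studentized-range quantile taken from `qtukey` at infinite degrees of
freedom. A one-sample Kolmogorov–Smirnov test of the standardised
one-step residuals against the standard normal serves as the whiteness
check.

The packaged reference result tables (ten participants, one- and
three-step horizons) ship as plain-text fixtures. Their Average and Std
rows use the arithmetic mean and the *population* (divisor $n$) standard
deviation; `summarize_metrics()` follows that convention. The tables
print VAF to two decimals, which creates one artificial within-
participant tie; `published_comparison()` therefore ranks with
sequential tie-breaking, which restores the untied ordering of the
underlying values, and compares the nine models
{five base learners, the JADE- and DE-tuned stacks, NARMAX-HNN,
NARMAX-P} at three steps, plus the two Volterra columns at one step.

## The synthetic benchmark

Because the motivating EEG dataset is confidential, the package ships a
generator whose corpora have the same *structure* as the benchmark
protocol: per participant, seven periodic multisine signals
($u(t) = \sum_h A_h \sin(2\pi h t/T + \varphi_h)$, random phases, no DC,
default harmonics 1–8 with amplitudes $\sqrt{2/H}$ normalising the
variance, 256 samples per 1-s period), a 6-train/1-test split, and a
nonlinear dynamic SISO response. The response is a Wiener-type
surrogate: a stable second-order linear block
$z(t) = a_1 z(t-1) + a_2 z(t-2) + b_1 u(t-1)$ followed by the static
nonlinearity $y = c_1 z + c_3 z^3$ plus Gaussian output noise. The cubic
term gives the corpus a large nonlinear variance share — the defining
difficulty of the target application — while keeping the ground truth
and the achievable accuracy known: no predictor can exceed
$100\,(1 - \sigma^2/\mathrm{var}(y))$ on average, and the generator
records this bound per participant from a $10^4$-sample noise-free
simulation of the test signal's periodic input (the record-level
variance is the right denominator, because short multisine realisations
differ substantially in trajectory variance).

The surrogate's role is testability, not biological fidelity. Passing
the synthetic suites shows that the pipeline recovers known nonlinear
dynamics to their noise floor, honours the no-leakage and no-lookahead
contracts, and degrades with horizon as recursive forecasting must; it
does not show that the learned models capture any particular
neurophysiology, nor how the method behaves under non-stationarity,
artifacts, or model misspecification beyond the Wiener class.

## Problem sizes and numerical choices

The generator's reference settings are 256 samples/s and 5-s signals.
The test-suite and acceptance computations run the same pipeline at a
reduced scale chosen to keep a full multi-seed study inside a desk-run:
64 samples/s with 1–2-s signals (i.e. 350–750 training rows per
participant) and, for multi-seed loops, thinned hyperparameter grids via
`stack_learners()`. These sizes are the package's own trade-off between
statistical resolution and turnaround; all of them are ordinary function
arguments.

Other numerical conventions, collected in one place: grid-search ties
break to the first grid point; meta-learner selection strictly improves
or keeps the parent (optimizer selection is strict, matching "better
than"); the archive trims uniformly at random; integer decoding rounds
half-away-from-zero; burn-in rows are dropped, never padded; degenerate
inputs (constant targets, zero-variance windows, constant meta-input
columns) follow explicit conventions (zero skewness, single-rule models,
a logged message) rather than erroring mid-pipeline.

## Known limitations

* Free-run simulation (closed-loop generation without any observed
  output) is out of scope; prediction is one-step or recursive
  multi-step.
* The meta-learner is a Cubist-style approximation; it reproduces the
  committees/neighbors semantics but is not bit-compatible with any
  external Cubist implementation (the backend seam exists for exactly
  that comparison).
* Base-learner and feature sets are fixed by design; no automatic
  feature or learner selection is performed.
* Only the two meta-learner hyperparameters are tuned by the optimizer;
  base learners rely on their cross-validated grids.
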