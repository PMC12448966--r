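---
title: "Modeling forgetting and predicting it from the connectome"
author: "sofcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling forgetting and predicting it from the connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sofcpm)
```

`sofcpm` implements a two-stage analysis: estimate an individual *speed of
forgetting* (SoF) from adaptive fact-learning behavior with a trace-decay
memory model, then predict that phenotype from resting-state functional
connectivity with a penalized regression and a full validation battery.
This vignette explains the models, the tunable parameters, the synthetic
study the package can generate, and the numerical and design choices that
were genuinely open.

## The trace-decay memory model

Each encoding or successful retrieval of a memory item leaves an episodic
trace. A trace created at time $t_i$ decays as a power law with its own
rate $d_i$, and the item's activation at time $t$ is the log of the summed
trace strengths:

$$A(m, t) = \log \sum_i (t - t_i)^{-d_i}.$$

The exponent is $-d_i$: strengths decay. Decay rates are coupled across
traces — a trace formed while the memory is highly active decays faster:

$$d_i = c\,e^{A(m, t_i)} + \varphi, \qquad c = 0.25,$$

where the activation is evaluated just *before* the new trace is added.
For the very first trace the empty log-sum gives $A = -\infty$, hence
$d_1 = \varphi$ exactly: the decay intercept $\varphi$ — the *speed of
forgetting* — is the model's only free parameter. Activation maps onto
behavior through the retrieval probability $P(m) = 1/(1 + e^{-A})$ and the
retrieval latency $T = t_0 + F e^{-A}$ with $t_0 = 0.3$ s (perceptual and
motor overhead) and $F = 1$.

Two consequences matter for everything downstream. First, forgetting under
a power law is front-loaded: with $\varphi = 0.3$, a single unrehearsed
memory falls below $P = 0.25$ within ten minutes (the value at 600 s is
0.128), so a short session carries most of the identifiable signal.
Second, at a lag of exactly 1 s activation is 0 and $P = 0.5$ regardless
of $\varphi$ — latencies at very short lags carry almost no information
about the decay intercept, which shapes how the estimator behaves (below).

All times are in seconds on a session clock starting at 0. $\varphi$ is
estimated on a bounded grid $[0.10, 0.60]$ in steps of 0.001, comfortably
containing the empirically plausible range while keeping the activation
sums well-behaved.

## The adaptive session and the $\varphi$ estimator

`run_session()` drives a scheduler against a responder (a human replay or
a simulated learner). The scheduler introduces the 25 cue–target pairs one
at a time and re-tests the item whose predicted activation a 15-second
lookahead into the future is lowest *and* below a threshold; if none is at
risk it introduces a new item, and once all items are introduced it tests
the lowest-activation one. The clock advances by the response time plus a
600 ms inter-stimulus interval after correct responses or a 4 s corrective
feedback period after errors (fixed, so the simulated clock is
deterministic; the live task is participant-paced). Study trials and
correct test trials re-encode the item at trial onset; incorrect test
trials re-encode at feedback onset (`encode_on_incorrect`, on by default —
the learner re-studies the pair while the correction is on screen).

The activation threshold default is $-1.2$. It was calibrated so that a
learner with $\varphi \approx 0.3$ completes roughly 140 trials in a
12-minute session, the intended pacing of the design; both threshold and
lookahead are configurable.

After every test response, `update_phi()` re-estimates the item's
$\varphi$ by grid search: for each candidate, the item's trace decay rates
are replayed from its encoding times and the latency equation is evaluated
at each past test trial. The refit minimizes squared residuals on the
*log*-latency scale, because the response-time noise of the generative
model (and of response times generally) is multiplicative — on the linear
scale a few slow trials dominate the fit. Incorrect responses need care.
Retrieval latency is undefined when retrieval fails, and under the
logistic retrieval probability a spacing scheduler necessarily operates in
a regime where failures are common; treating every failure as a
maximally-slow response (the 8 s cap) makes the summed residuals a
monotone function of $\varphi$ and pins every estimate at the grid bound.
The estimator therefore fits correct-trial latencies once an item has any,
and uses the capped-failure surrogate only before the first success —
preserving the qualitative rule that errors push $\varphi$ up while fast
correct responses pull it down. On noise-free sessions the estimator
recovers the generating $\varphi$ to within the grid step (the test suite
verifies per-item recovery correlations above 0.99).

A participant's SoF is the unweighted mean of the final per-item
$\varphi$ values over items presented at least three times
(`compute_sof()`).

## Model-fit diagnostics

`predicted_rts()` replays every item's encodings with all decay rates
recomputed under the single participant-level SoF and predicts each test
latency; observed latencies above 8 s are excluded as outliers. Both
distributions are binned into ten 800 ms bins. `kl_divergence()` reports
KL(observed ‖ predicted) in bits — the bits lost when observations are
replaced by model predictions — with 0.5 pseudo-counts per bin on both
sides so an empty model bin cannot produce an infinite divergence.
`chi_square_fit()` scales the predicted proportions to the observed total
and merges adjacent bins until every expected count is at least 1 before
computing $\sum (O-E)^2/E$ with dof = bins − 1. The predicted histogram is
deterministic (no predictive noise is added), which makes the diagnostics
reproducible. `accuracy_diagnostics()` crosses the model's predicted
correctness ($P > 0.5$, i.e. $A > 0$; the boundary counts as incorrect)
with observed correctness.

## Connectomes and the feature space

`partial_connectome()` computes, for each network pair, the correlation
remaining after the other 15 network time series are partialled out of
both — obtained in one pass from the inverse covariance,
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$, which is
algebraically identical to the 136 residual-regression correlations but
$O(p^3)$ once (the equivalence is a test oracle). A near-singular
covariance falls back to a ridge-regularized inverse (1e-6 times the mean
diagonal) with a warning. Group averages use Fisher's r-to-z: transform,
average, back-transform (`fisher_group_average()`).

The shipped parcellation (`yeo17_parcellation()`) lists the 17 Yeo
networks with their group assignment: the three Default Mode subnetworks;
a six-network Retrieval group (Control A/B, Dorsal Attention A, Salience
B, Limbic B, Temporal Parietal) of frontoparietal control regions; and an
eight-network Storage group (Visual A/B, Somatomotor A/B, Dorsal Attention
B, Salience A, Limbic A, Control C) of sensory and consolidation-related
regions. The regression features are the 45 DMN-anchored edges — the 3
within-DMN pairs followed by each Default subnetwork's 14 connections, in
parcellation order — restricting 136 possible edges to the theoretically
motivated ones while keeping the feature count below twice the sample
size. The canonical order is serialized in every output header because
weights are meaningless without it.

## The prediction pipeline

The lasso objective is
$\tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert_2^2 +
\lambda\lVert\beta\rVert_1$ — stating the scaling matters because the
numeric value of $\lambda$ is not transferable across conventions.
Features are standardized to unit variance internally, the intercept is
unpenalized, and coefficients are reported on the original scale. The
solver is cyclic coordinate descent on the Gram matrix, compiled; the
cross-validation path uses a relaxed tolerance with an early exit once the
training fit saturates ($R^2 > 0.999$, only reachable past the
interpolation point when $p > n$), while the reported model is always
re-solved at tolerance 1e-7 and checked against the KKT stationarity
conditions.

$\lambda$ is chosen by leave-one-out cross-validation over 100 log-spaced
values spanning four decades below the all-zero threshold
$\lambda_{max}$. The default selection rule is the one-standard-error
rule: the largest penalty whose held-out error is within one standard
error of the minimum. With $n = 33$ and LOO's high variance, the strict
minimum rule admits spurious features on a pure-noise response roughly
half the time; the 1-SE rule is the standard sparsity-favoring correction
and is what makes the permutation null behave (most shuffles produce an
intercept-only model). `rule = "min"` is available.

The validation battery mirrors how such models should be audited:

- `loo_validate()` refits *unpenalized* least squares on the fixed
  selected support for each left-out participant — support fixed, weights
  refit — giving an honest generalization estimate (always below the
  in-sample fit).
- `feature_removal_test()` drops features and re-runs the whole selection;
  if the removed set carried the signal, cross-validation settles on the
  intercept-only model.
- `vif()` reports $1/(1-R^2_j)$ collinearity diagnostics for the selected
  features (values above 10 conventionally indicate trouble).
- `permutation_test()` re-runs selection and refit on shuffled phenotypes;
  a shuffle whose selected model is intercept-only counts as failed to
  converge, and a converged shuffle is *comparable* when its in-sample
  correlation reaches the observed model's. The empirical p-value uses the
  add-one correction $(1 + \#comparable)/(1 + \#shuffles)$. Defining
  "comparable fit" by the in-sample correlation is one reading of that
  informal phrase; it is conservative in the direction that matters, since
  overfit dense null models can only inflate, never deflate, the p-value.

Network-level interpretation: `node_importance()` scores each network by
the L1 norm of selected weights on its incident edges (each edge counts at
both endpoints, so total importance is twice the weight norm);
`storage_retrieval_test()` runs a two-sided one-sample t test of the eight
storage-network importances against zero, with zeros kept for unselected
networks; `selection_enrichment()` gives the exact hypergeometric
probability that a storage-only edge set arises by chance, with the pool
convention (42 DMN-to-other edges by default, within-DMN edges excluded
from the draw) exposed as a parameter because more than one convention is
defensible; and `sign_adjusted_weights()` multiplies each weight by the
sign of its edge's group-mean connectivity so that a positive adjusted
weight always reads "stronger connectivity predicts faster forgetting".

## The synthetic cohort

`cohort_spec()` defines the simulated study the test suite runs:

- 33 participants whose true SoF values are drawn from a normal with mean
  0.305 and SD 0.029, truncated to $[0.20, 0.45]$ — a smooth density
  respecting the plausible range of the phenotype.
- Simulated learners answer test probes with Bernoulli correctness at the
  logistic retrieval probability of their *true* activation (the session
  keeps a ground-truth replay of every history under the true $\varphi$,
  independent of the scheduler's estimates) and latencies equal to the
  model prediction times lognormal noise with sdlog 0.3, capped at 8 s;
  study trials take lognormal time around 1.5 s.
- Per participant, 210 volumes of 17-network ROI time series (TR 2 s) are
  drawn as independent multivariate-normal samples from a precision
  matrix parameterized directly by its partial correlations: a fixed base
  pattern (0.10 between consecutive networks and on every planted edge)
  plus, on each planted edge, $\gamma_e (SoF - 0.305)/0.029$. The default
  plants $\gamma = +0.12, +0.12, -0.12$ on Default A–Default C,
  Default B–Visual A and Default C–Dorsal Attention B: about 1.7 Fisher-z
  standard errors per SD of SoF at 210 volumes, a strong but not trivial
  signal for $n = 33$. Planting on the partial-correlation scale is
  deliberate — that is the scale the analysis consumes, and
  covariance-scale planting would distort the targets. The mixed slope
  signs exercise the sign-adjustment step; the positive base on planted
  edges gives each one a stable group-mean sign for it.
- A single master seed governs everything; reruns are byte-identical.

What the generator does *not* emulate: temporal autocorrelation of the
BOLD signal (partial correlations are insensitive to it to first order),
motion or physiological artifacts, spatial structure within networks, and
real learners' departures from the trace-decay model (lapses, fatigue,
strategy shifts). Passing tests on this cohort therefore demonstrate that
the pipeline recovers what it assumes, not that the model is true of
brains.

## Numerical choices and degenerate inputs

- Activation of an empty history is $-\infty$ (probability 0); queries at
  or before a trace time are errors, and the scheduler probes activation a
  microsecond after a just-created trace when the two would coincide.
- Grid ties in the $\varphi$ refit break toward the smaller value; CV ties
  at the error minimum break toward the larger (sparser) penalty.
- Coefficients below 1e-12 after soft-thresholding are clipped to exactly
  zero so that "number of selected features" is well-defined.
- Histogram comparisons require identical bin edges; the $\chi^2$ merge
  threshold (expected count ≥ 1) and the KL pseudo-count (0.5) are
  parameters, not magic.
- Degenerate situations flag rather than fail where a flag is meaningful:
  zero-variance importances (undefined t), empty support (undefined
  held-out r), perfectly collinear features (infinite VIF), correlations
  of exactly ±1 before Fisher averaging (clipped, with a warning).

## Problem sizes and known limitations

The test suite exercises the full pipeline at the study's native scale
(33 participants, 25 items, 12-minute sessions, 210 volumes, 45 features)
with 200 permutation shuffles, and the oracle-equivalence checks at the
same scale; the pure-noise selection calibration uses 50 replicate
responses against one feature draw.

Two honest limitations surface in the acceptance tests. At the default
response-time noise (sdlog 0.3) the cohort-level SoF recovery correlation
sits around 0.85: with roughly 31% test accuracy under the logistic
retrieval probability there are only one or two informative latencies per
item, and the noise-free recovery correlation of 0.997 shows this is an
information ceiling of the design, not estimator error. Relatedly, the
pure-noise calibration leaves the intercept-only rate near 85% rather
than above 90%: LOO cross-validation at $n = 33$ retains that much
variance even under the 1-SE rule. Both bounds are stated by the tests
themselves; lowering the simulated noise or lengthening the session moves
them, as the low-noise pipeline-closure test demonstrates.
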