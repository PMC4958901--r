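---
title: "Modelling the response inhibition network: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the response inhibition network: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopdcm)
```

## The scientific problem

Stopping an action engages a small cortico-subcortical circuit: the
pre-supplementary motor area (preSMA) and the right inferior frontal gyrus
(IFG) project to the subthalamic nucleus (STN), which brakes the motor
output of primary motor cortex (M1). `stopdcm` models this four-node
network as a dynamic causal model (DCM): a deterministic neural state
equation whose directed couplings are the quantities of interest, observed
through a haemodynamic model, and fitted to region-averaged BOLD
time-series by approximate Bayesian inference. On top of the single-session
fit the package implements the group-level machinery this kind of study
needs — random-effects Bayesian model selection over a 20-model space,
Bayesian model and parameter averaging, stop-signal behaviour with SSRT
estimation, and individual-differences regressions — together with a
synthetic crossover-cohort generator so that every stage can be validated
end-to-end against known ground truth.

## The neural and observation model

Neural activity $z \in \mathbb{R}^n$ follows the bilinear/non-linear state
equation

$$\dot z = \Big(A + \sum_j u_j B^{(j)} + \sum_k z_k D^{(k)}\Big) z + C u,$$

where $A$ holds average coupling rates (Hz), $B^{(j)}$ the change in
coupling induced by modulatory input $j$, $C$ the driving-input gains, and
$D^{(k)}$ the gating of each connection by the activity of region $k$ — the
non-linear term that lets preSMA activity gate the IFG→STN projection.
Self-connections are parameterized as $a_{ii} = -0.5\,e^{\theta_{ii}}$ so
that every admissible parameter vector has intrinsically decaying dynamics.

Each region's BOLD signal is generated by the balloon–Windkessel model: a
vasodilatory signal $s$ (decay rate per region), inflow $f$, venous volume
$v$ (mean transit time per region, Grubb exponent $\alpha$) and
deoxyhaemoglobin $q$, read out through the static non-linear BOLD equation
with the intra/extravascular ratio $\epsilon$ per region. The shared
constants default to the standard literature values (autoregulation
0.32 s⁻¹, prior-mean decay 0.64 s⁻¹, transit 2 s, $\alpha = 0.32$, resting
extraction 0.4, $V_0 = 4\%$, echo-dependent signal coefficients at
TE = 30 ms); all are configurable via `balloon_constants()`.

### Numerical scheme

Both subsystems are integrated by fixed-step 4th-order Runge–Kutta on a
microtime grid of `TR / microtime_bins` (default TR/16). Inputs are held
constant within a bin (they are boxcar indicators, so this is exact); the
neural drive entering the balloon model is interpolated linearly across
each bin, which keeps the neural→haemodynamic composition second-order
accurate — halving the step changes predicted BOLD by well under 0.1%
relative. The integrators are compiled (Rcpp) because group-level model
recovery requires thousands of model inversions; tests cross-check them
against closed forms, `Matrix::expm` on piecewise-constant segments, and an
independent `deSolve` integration of the balloon equations. A state
excursion beyond a configurable bound (default |z| > 16) raises an explicit
instability error naming the offending parameters.

## The 20-model space

`enumerate_models()` constructs the candidate space programmatically. All
models share a backbone of average connections (preSMA→STN, IFG→STN,
STN→M1, plus self-connections) and task driving inputs into both frontal
regions. The four families code the frontal-frontal average coupling:
absent (A), IFG→preSMA (B), preSMA→IFG (C), bidirectional (D). Twelve
linear models let successful stopping modulate the cortico-subcortical
connections directly (three placements per family: IFG→STN, preSMA→STN, or
both); eight non-linear models let stopping drive one frontal region
(preSMA or IFG) whose activity gates the other region's projection to the
STN. In the non-linear models the stopping contrast therefore also enters
as a driving input to the gating region — without it a non-linear model
would carry no stopping-specific signal at all. The exact backbone and the
three linear placements are configurable, since model spaces of this kind
are conventionally inherited from prior work rather than fully reprinted.

## Inversion: variational Laplace

`dcm()` fits one model to one session by expectation–maximization with
damped Gauss–Newton updates on a local linearization of the forward model
(finite-difference Jacobian computed in compiled code). The posterior is
Gaussian; per-region noise precisions are re-estimated each iteration in
closed form under a weak Gamma hyperprior. Steps are accepted only when
they increase the free energy

$$F = \underbrace{\mathbb{E}_q[\log p(y \mid \theta)]}_{\text{accuracy}}
  - \underbrace{\mathrm{KL}\!\left[q(\theta)\,\|\,p(\theta)\right]}_{\text{complexity}},$$

and rejected steps raise a Levenberg–Marquardt damping factor that bends
the update towards the gradient — plain step-halving proved prone to
stalling in a wrong basin on strongly-driven sessions. Convergence is
declared when $|\Delta F| < 10^{-2}$ for three consecutive iterations
(cap 128; reduced caps are used for the test fixtures). The optimization is
deterministic given its settings. $F$ approximates the log model evidence
and differences of 5 correspond to Bayes factors near 150.

### Priors

Off-diagonal couplings are zero-mean Gaussians with variance 1/4 (SD
0.5 Hz), self-connection log-scalings N(0, 1/2), driving gains N(0, 1),
bilinear and gating gains N(0, 1/16), and haemodynamic log-scalings
N(0, 0.0625) around the standard constants. The coupling and
self-connection variances are deliberately liberal: tighter coupling priors
(e.g. variance 1/16) shrink session differences of coupling estimates by
roughly a factor of three at realistic session lengths, which visibly
biases drug-minus-placebo deltas; with the liberal prior a planted 0.3 Hz
drug effect on IFG→STN is recovered with mean error under 0.1 Hz across 19
simulated patients. `prior_draw()` samples the prior restricted (by
rejection) to the stable domain of $A$; the unconstrained Gaussian is used
for inference, where step rejection handles unstable excursions.

## Group-level model selection

`ffx_bms()` is the fixed-effects softmax of summed free energies.
`rfx_bms()` implements the variational Dirichlet scheme over population
model frequencies (uniform prior, $\alpha_0 = 1$); exceedance probabilities
are estimated from $10^6$ seeded Dirichlet samples by default (Monte-Carlo
error ≈ 0.001). `protected_xp()` computes the Bayesian omnibus risk as the
posterior probability of the all-frequencies-equal null from the free
energies of the null and the fitted random-effects model — both are
returned for audit — and shrinks the exceedance probabilities towards
chance: $pXP = XP(1-BOR) + BOR/K$. `family_bms()` assigns each family
equal prior mass (divided within family, i.e. $\alpha_{0k} = 1/|f_k|$),
which makes family-level inference invariant to duplicating a model inside
a family; this prior-mass correction is the package default and can be
bypassed by passing per-model $\alpha_0$ directly.

`hierarchical_selection()` runs the three-step procedure: linear vs
non-linear (family level), preSMA vs IFG gating among the non-linear
models, then the four non-linear preSMA models individually with pXP and
BOR. An exceedance probability above 0.9 is treated as decisive (configurable).
With a single subject the random-effects machinery is degenerate; the
function warns and falls back to fixed-effects posteriors.
`outlier_sensitivity()` flags subjects with monitored parameters beyond a
z-threshold (default 2 SD), repeats the selection without them, and reports
the change in the top-two evidence gap and the exceedance probabilities.

## Averaging and conditional probabilities

`bma()` averages across models within a subject by sampling the mixture of
Gaussian posteriors ($10^4$ samples by default, SD stable to ~1%);
parameters excluded by a model's masks contribute exactly zero when that
model is drawn. Models enter the average when their probability exceeds
0.05 under the convention used for heterogeneous groups; the probability
used defaults to the random-effects expected frequency. `bpa()` combines
subjects by precision weighting (summed precisions, precision-weighted
mean). The conditional probability that a parameter is non-zero,
`conditional_probability()`, is the sign-aware one-sided Gaussian mass
$\max\{P(\theta > 0), P(\theta < 0)\}$ — a two-sided variant around a
threshold is available by flag. Session deltas (`delta_parameters()`) are
elementwise drug-minus-placebo differences of the averaged posterior means
for the monitored parameters (IFG→STN coupling; preSMA gating gain).

## Stop-signal behaviour

`build_session()` fixes the session composition at 360 Go, 80 Stop and 40
NoGo trials (stimulus onset asynchrony 2.5 s) in seeded random order.
`simulate_session()` runs the independent race model: ex-Gaussian go and
stop finishing times, optional go-omission and trigger-failure
probabilities; a response occurs on a stop trial iff the go process beats
SSD + stop latency. The stop-signal delay starts at 250 ms and moves in
±50 ms steps (floor 0 ms, no ceiling) towards 50% successful inhibition.
`estimate_ssrt()` implements the integration method: omitted go trials are
assigned the maximum observed go RT (quantile re-normalization available by
flag), the response rate on stop trials picks the $n$-th ranked go RT with
$n = \lceil pN \rceil$, and the mean SSD is subtracted. NoGo trials are
races at SSD = 0 and are excluded from SSRT estimation. Default race
parameters are declared (go ex-Gaussian 450/60/80 ms; stop 180/30/20 ms,
i.e. a true mean stop latency of 200 ms); the estimator recovers that mean
within 15 ms over 200 sessions of 80 stop trials.

`build_dcm_inputs()` turns an event table into the two input channels: an
all-trials indicator of 1 s boxcars, and the stopping contrast on the same
boxcars with +1 for correct stops and −1 for go trials by default (a 1/0
coding is available via the contrast table). No serial orthogonalization is
applied; inputs are left uncentred by default with a mean-centring flag.

## The synthetic cohort

`generate_cohort()` emulates a crossover pharmacological study: 19 patients
× 2 sessions (placebo/drug) plus 20 single-session controls, TR 2 s, with
each session's network driven by the events of its own simulated behaviour.
Controls and half of the patients (configurable fraction) are generated
from the non-linear preSMA family-C model; the remaining patients lack the
preSMA→IFG coupling on placebo and have it restored on drug. Drug sessions
add planted, covariate-linked changes: IFG→STN coupling shifts with
standardized UPDRS-III (default 0.15 Hz/SD) and the preSMA gating gain with
standardized plasma level (default 0.1 Hz/SD, levels uniform on the
147–516 ng/ml range); session order is counterbalanced at random and
recorded. Observation noise is Gaussian per region at a configured SNR
(sd(signal)/sd(noise), default 1). Stop latencies give group mean SSRTs
near 171 ms (controls), 224 ms (patients on placebo) and 228 ms (drug),
with a baseline-dependent improvement rule so that worse baseline
performers improve more.

The ground-truth coupling values (0.2–0.45 Hz; gating 0.4) were calibrated
once, by forward simulation, to satisfy two constraints simultaneously:
neural excursions stay physiological (peak clean BOLD ≈ 5–7%; the
generator refuses configurations beyond 20%), and the family structure and
gating remain identifiable at SNR 1 — with a weak stopping drive the
frontal-frontal coupling is nearly collinear with the task drive and no
method could recover it. The generator emulates the *structure* of such a
study, not its full physiology: it omits scanner drift and physiological
noise (noise is white), motion, regional timing differences, and
between-region noise correlations. Passing recovery tests therefore show
the pipeline is correct and well-calibrated under its own assumptions, not
that real data of this size would yield the same certainty.

## Problem sizes used by the tests

Unit and acceptance tests run at reduced, documented sizes chosen for
desk-scale reproducibility: sessions of 100–300 volumes at TR/4 microtime
(the full 600-volume session is used where shrinkage bias matters), 10
seeded replicates of the 20-subject × 20-model recovery study, 200
simulated behavioural sessions for the SSRT estimator, and $10^5$
Dirichlet samples where exceedance probabilities are compared at 0.01
tolerance. The three-step recovery study inverts all 20 models for each of
20 subjects and selects the generating model (non-linear, preSMA-gated,
family C) decisively in at least 8 of 10 replicates.

## Known limitations

- The Gaussian-posterior (Laplace) approximation and the local
  linearization can understate posterior uncertainty near the stability
  boundary; free energies of badly mis-specified models are approximate.
- Noise is modelled as independent Gaussian per region (no AR(1) term);
  serially correlated noise would bias the noise precisions optimistic.
- The forward model couples neural to haemodynamic states one-way; neural
  feedback from the vasculature is not modelled.
- Model inversion is per-session; no hierarchical (empirical-Bayes) group
  inversion or Bayesian model reduction is provided.
- With strongly shrinking priors, session-difference estimates of coupling
  parameters are biased towards zero; the liberal defaults mitigate but do
  not remove this.
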