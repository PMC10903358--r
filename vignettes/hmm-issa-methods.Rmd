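---
title: "State-switching step selection: models, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-switching step selection: models, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
state-switching step-selection model, how the estimator works, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions a user or maintainer should know about.

## The model

We observe a track of locations $x_1,\dots,x_T$ at regular time intervals.
Each step (the segment between consecutive locations) has a length $l$ and,
from the second step on, a turning angle $\alpha \in (-\pi,\pi]$ — the
change in heading, counterclockwise positive. Behavioural state matters:
a resting vole moves differently from a foraging one and reacts to habitat
differently. We model the state of step $t$ as a hidden $N$-state Markov
chain $S_t$ with transition matrix $\Gamma$ and initial distribution
$\delta$, and, conditional on $S_t = i$, the next location as a draw from

$$f_i(x_{t+1}\mid x_t, x_{t-1}) \;\propto\;
  \underbrace{\phi(l,\alpha;\theta_i)}_{\text{movement kernel}}\;
  \underbrace{\exp\!\big(Z(x_{t+1})^\top\beta_i\big)}_{\text{selection function}},$$

with a gamma (shape $k_i$, rate $r_i$) step-length distribution and a von
Mises (concentration $\kappa_i$; mean $0$, or $\pi$ when $\kappa_i < 0$)
turning-angle distribution in the kernel, and a log-linear selection
weight over the habitat covariates $Z$. Positive $\beta$ means preference,
negative avoidance. Setting $N = 1$ gives the ordinary integrated
step-selection model (iSSA); setting all $\beta_i = 0$ gives a movement
HMM. These nestings are what makes AIC/BIC comparison across the three
candidates meaningful.

Because gamma $\times$ von Mises is an exponential family, the kernel and
selection weight combine into one log-linear function of the movement
covariates $C = (\log l,\, -l,\, \cos\alpha)$ with coefficients
$(k_i - 1,\, r_i,\, \kappa_i)$ (plus a $-\log l$ Jacobian term in
Cartesian coordinates). Under the uniform-angle variant the $\cos\alpha$
term is dropped.

## Case-control estimation

The normalising integral of $f_i$ is intractable, so estimation uses a
case-control design. For every step with a defined turning angle we form a
choice set: the used step plus $M$ control steps drawn in polar
coordinates from a tentative proposal — gamma$(k_0, r_0)$ lengths fitted
to the observed steps by maximum likelihood, uniform angles. Because
controls are sampled in $(l, \alpha)$, the $-\log l$ term cancels, and the
state-dependent probability of the used step is a softmax over the choice
set. Two consequences matter:

* the fitted coefficient on $\log l$ estimates $k_i - k_0$ (and on $-l$,
  $r_i - r_0$): movement coefficients are *corrections to the proposal*,
  and `recover_movement_parameters()` maps them back. The package
  parameterises fits directly in natural space ($k = e^\eta$), so
  positivity is structural and the recovery is built in;
* estimates are invariant (up to Monte-Carlo error that shrinks with $M$)
  to the proposal actually used — a property the test suite checks by
  refitting under a deliberately wrong proposal.

The full likelihood is the HMM matrix product
$\delta^\top P(\tilde x_3)\Gamma P(\tilde x_4)\Gamma\cdots\Gamma
P(\tilde x_T)\mathbf{1}$ with $P$ the diagonal matrix of state-dependent
choice probabilities, evaluated by the scaled forward algorithm in $C{++}$.
Bursts (independent track segments) restart the recursion at $\delta$.
$\delta$ is fixed to the stationary distribution of $\Gamma$ rather than
estimated: the chain contributes $T-2$ transitions but only one initial
state, so freeing $\delta$ buys little and destabilises short bursts.
The parameter count is therefore $N\,\dim\theta + N\,\dim\beta + N(N-1)$.

Maximisation is quasi-Newton (BFGS) with an analytic gradient: the
coefficient gradient combines forward–backward state posteriors with the
softmax score of each choice set; the $N(N-1)$ transition logits are
differenced centrally on the cached choice-probability matrix, which costs
only a rerun of the $O(TN^2)$ recursion and automatically accounts for the
dependence of $\delta$ on $\Gamma$. Convergence uses a relative
log-likelihood tolerance of $10^{-9}$ with an iteration cap of 2000.

**Multi-start policy.** The likelihood is multimodal, most severely when
the states share the same movement kernel and differ only in selection:
there the moment-based initialisation (which splits steps by length
quantiles) carries no information, and a noticeable fraction of single
starts ends in a local maximum whose decoding is near chance. The first
start is a deterministic moment-based one; further starts draw
shape/rate/concentration log-uniformly within $[1/4, 4]\times$ the moment
estimates, $\beta \sim U(-2,2)$ and transition-matrix diagonals
$U(0.7, 0.95)$. The fitting default is 50 starts; the packaged study
replications use 2 starts for scenarios with separated kernels and 5 for
the shared-kernel scenario, which removed every local-optimum run we
observed. Starts within $10^{-4}$ log-likelihood of each other are treated
as the same optimum, and the per-start spread is kept in the fit object as
a multimodality diagnostic.

Inference: standard errors come from the inverse observed information
(numerical Hessian at the optimum, working scale). Selection coefficients
are identical on working and natural scales, so their Wald $z$-tests are
reported directly; movement-parameter intervals would require the delta
method and are not reported by default. Viterbi decoding breaks ties
toward the lower state index (a measure-zero event in practice).

## The two competitors

* **iSSA** is the same machinery with $N = 1$, fitted through a dedicated
  conditional-logistic path with analytic gradient. It is cross-checked
  against `survival::clogit` to $10^{-4}$ in the test suite.
* **TS-iSSA** first fits a movement-only HMM to $(l, \alpha)$ (gamma ×
  mean-zero von Mises), Viterbi-decodes, splits the steps by decoded
  state, and fits one iSSA per state. Controls for state $s$ are drawn
  from that state's *fitted* gamma and von Mises distributions, so the
  cosine coefficient is interpreted against the proposal concentration
  ($\kappa = \kappa_{0,s} + \hat\theta_{\cos}$). States decoded to fewer
  than 30 steps are skipped with a warning. No uncertainty from the
  classification stage reaches the second-stage standard errors — that is
  the point the comparison study quantifies, not an omission to fix.

## The synthetic-data generator

The simulation study needs a habitat covariate and tracks with known
states.

**Landscape.** A stationary zero-mean Gaussian random field with
exponential covariance $\sigma^2 e^{-d/\phi}$, $\sigma^2 = 1$,
$\phi = 10$, on a $100\times100$ grid at unit resolution. Grid size and
resolution are not dictated by the model; we fixed them once so that the
correlation range is a tenth of the domain and the short-state mean step
(≈1 unit) resolves individual cells. Distances are measured on the torus,
matching the toroidal boundary policy used for covariate lookup, and the
field is sampled exactly via the 2-D FFT of the block-circulant
covariance (a dense eigendecomposition sampler serves as an independent
small-grid alternative). The torus covariance of a coarse grid is not
exactly positive semi-definite; negative eigenvalue mass up to 5% is
clamped and the spectrum rescaled so the marginal variance is exact.
Covariate lookup is nearest-cell (raster semantics), not interpolation.

**Tracks.** The state chain is simulated from $(\delta, \Gamma)$; given
the state, the next location is drawn from $f_i$ by importance resampling:
$K = 1000$ candidate steps from the movement kernel, one selected with
probability $\propto \exp(Z^\top\beta_i)$. This is exact for constant $Z$
and converges to exact sampling as $K$ grows; study results were
insensitive to $K$ between 500 and 4000. A warning is logged if the
resampling weights' effective sample size drops below 10. The first two
locations start at the domain centre with a uniform initial heading.

What the generator does **not** emulate: irregular sampling intervals,
location error, boundary avoidance (animals wrap toroidally rather than
react to edges), multi-layer or categorical covariates, and
covariate-dependent transition probabilities. Passing tests therefore
demonstrate correct estimation under the model's own assumptions, not
robustness to the ways real telemetry violates them.

## The simulation study

Four scenarios (2-state unless noted) with $\gamma_{11}=\gamma_{22}=0.9$:
(1) *active–inactive* — short/undirected/no-selection state vs
long/directed state with $\beta = 2$; (2) *switching preferences* —
identical kernels, $\beta = \mp 2$; (3) *HMM* — different kernels, no
selection; (4) single-state iSSA (robustness check, not an evaluation
surface). Each run simulates a fresh landscape and a $T = 1000$ track,
fits a tentative gamma, builds case-control data at the requested $M$, and
fits the requested estimators; per-run records hold label-aligned
estimates, Wald $p$-values, AIC/BIC and Viterbi misclassification.
Label alignment uses the permutation minimising misclassification against
the simulated truth and is applied to all of a run's parameters.
Aggregation is a pure function of the records: significance rates,
mean (sd) misclassification, AIC/BIC winner percentages, mean bias.

The shipped default profile is scaled down (20 runs, $M = 20$); the full
comparison used 100 runs and $M \in \{20, 100, 500\}$ and is selectable
through the study config. The packaged acceptance checks use 100 runs
where the fits are cheap (movement HMM, TS-iSSA, iSSA), 50 runs for the
$M = 500$ bias summaries and 20 runs for the joint-model significance and
model-selection summaries — sizes chosen so the whole replication runs on
a desktop core in minutes while keeping binomial noise a few percentage
points.

## Numerical details and degenerate inputs

* Log-space throughout: softmax via logsumexp, forward algorithm with
  per-step scaling; an overflowing line-search step returns a large
  penalty instead of aborting.
* Zero-length steps (possible in discretised real data) are floored at
  $10^{-6}\times$ the median length so $\log l$ stays finite, with a
  message; a strict error policy is available.
* (Near-)constant step lengths make the gamma MLE diverge; the tentative
  fit then falls back to a sharply concentrated proposal with a warning.
* Degenerate transition matrices (reducible/periodic) fall back to a
  uniform stationary distribution with a warning.
* Control draws use one substream per choice set, derived from the master
  seed by a counter, so growing $M$ extends choice sets without
  reshuffling earlier draws, and per-run records do not depend on which
  other estimators were requested.
* The von Mises sampler is the Best–Fisher wrapped-Cauchy rejection
  algorithm; the density uses the exponentially scaled Bessel function to
  avoid overflow at large concentration.

## Known limitations

Only scalar (single-layer) habitat covariates are supported in the
simulator and CLI (the likelihood itself accepts any covariate matrix);
transition probabilities are homogeneous; angular covariates for biased
walks are out of scope; there is no GeoTIFF reader — gridded fields
travel in a plain-text grid format. AIC tends to over-select state-rich
models in HMMs generally; the study's model-selection results concern the
three-candidate comparison, not general order selection.
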