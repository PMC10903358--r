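# msissa: Markov-switching integrated step-selection analysis

Animals switch between behavioural modes — resting, foraging, travelling —
and both their movement patterns and their habitat preferences change with
the mode. Standard step-selection analyses (SSA/iSSA) ignore this and fit a
single set of movement and selection parameters to a whole track; two-step
workflows first classify steps with a movement-only hidden Markov model
(HMM) and then fit separate iSSAs per decoded state, discarding the
classification uncertainty. `msissa` implements the joint alternative: a
**Markov-switching conditional logistic regression** (HMM-iSSA) that
estimates the hidden behavioural states, the state-dependent movement
kernels and the state-dependent habitat-selection coefficients in a single
likelihood, together with both competitors and a simulation framework for
comparing them.

The package is aimed at movement ecologists and biostatisticians working
with regularly sampled telemetry data and gridded habitat covariates.

## Model

A track `x_1, ..., x_T` (regular intervals) is described by steps with
length `l` and turning angle `α`. Given the behavioural state `S_t = i` of
a step, the next location follows the state-dependent step-selection
density

    f_i(x_{t+1} | x_t, x_{t-1}) ∝ φ(l, α; θ_i) · exp(Z(x_{t+1})ᵀ β_i),

a gamma(shape `k_i`, rate `r_i`) × von Mises(`κ_i`) movement kernel φ
weighted by a log-linear selection function of the habitat covariates `Z`.
The states follow a hidden `N`-state Markov chain with transition matrix
`Γ`. With an exponential-family kernel the density has a log-linear form in
the movement covariates `C = (log l, −l, cos α)`, so the model can be
estimated on a case-control design: each observed step is compared with `M`
control steps drawn from a tentative gamma/uniform proposal, giving the
state-dependent choice probability

    p_{0,t,i} = exp(C_0ᵀθ_i + Z_0ᵀβ_i) / Σ_{m=0..M} exp(C_mᵀθ_i + Z_mᵀβ_i),

and the full likelihood is the HMM form `δᵀ P(x̃_3) Γ P(x̃_4) Γ ··· Γ
P(x̃_T) 1`, evaluated with the scaled forward algorithm and maximised
numerically with multi-start quasi-Newton optimisation under structural
positivity constraints. Fitted movement coefficients are corrections to the
proposal parameters (`k = k₀ + θ̂_logl`, etc.). With `N = 1` the model is
the plain iSSA; with `β = 0` it is a movement HMM. States are decoded with
the Viterbi algorithm; selection coefficients get Wald tests; AIC/BIC
support model selection among the three candidates.

## Worked example

```r
library(msissa)

# scenario 1 ("active-inactive"): state 1 short undirected steps, no
# selection; state 2 long directed steps, strong selection (beta = 2)
sc    <- scenario_parameters(1)
field <- simulate_grf(sc$grf, seed = 11)            # habitat covariate
sim   <- simulate_track(sc$model, field, T = 1000, seed = 12)
cc    <- build_case_control(sim$track[c("x", "y")], field, M = 100, seed = 13)
fit   <- hmm_issa(cc, n_states = 2, n_starts = 10, seed = 14)
fit
```

```
2-state HMM-iSSA
  998 choice sets (1 used + 100 controls), von_mises angles
  logLik -4016.438  (np = 10)  AIC 8052.88  BIC 8101.93
  natural-scale estimates:
       state1 state2
shape  1.1609 2.3072
rate   1.1793 0.2452
kappa  0.3599 1.0087
beta_z 0.1348 1.8623
  transition probability matrix:
      [,1]  [,2]
[1,] 0.902 0.098
[2,] 0.089 0.911
```

The two columns recover the generating parameters (truth: 1.20/1.25/0.30
with `beta = 0`, and 2.50/0.29/1.00 with `beta = 2`) and the transition
probabilities (0.9). Decoding and comparing against the simulated truth:

```r
dec <- viterbi(fit)
misclassification_rate(dec, sim$states[2:999])
#> [1] 2.60521      # percent of steps decoded into the wrong state
summary(fit)        # Wald tests for the selection coefficients
```

The competitors use the same data: `hmm_issa(cc, n_states = 1)` is the
plain iSSA, `hmm_issa(cc, use_selection = FALSE)` the no-selection HMM
candidate, and `ts_issa(track, field, n_states = 2, M = 100)` the two-step
analysis. `run_simulation_study()` replicates the full comparison and
`summarize_significance()` / `summarize_misclassification()` /
`summarize_model_selection()` / `summarize_bias()` aggregate it. A thin
command-line front end is installed at `inst/cli/msissa`
(`simulate`, `fit`, `simstudy`, `show-defaults`).

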