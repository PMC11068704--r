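# wavenetid

Data-driven identification of single-neuron dynamics with wavelet
networks ("wavenets"), in R.

## The problem

Most electrophysiological recordings never get a mathematical model
attached to them: characterizing every ionic channel of a cell is slow
and expensive. An alternative is to treat the neuron as a black box and
learn its dynamics directly from a stimulation experiment — inject a
designed current `I_app(t)`, record the response, and fit a model that
predicts the next state from the current one. `wavenetid` implements
this program in silico for four classic neuron models (Morris–Lecar,
FitzHugh–Nagumo, a three-variable FitzHugh–Nagumo with slow adaptation,
and a Wang-type conductance model of a pyramidal neuron), which serve as
ground truth for training and for judging generalization.

## The model

The predictor is a *wavenet*: a single-hidden-layer network whose
activation functions are fixed members of a multiresolution spline
wavelet frame, so the network is **linear in its trainable weights**.
For a (normalized) input `x` the approximation is

    f̂(x) = a·x + Σ_k b_k φ_k(x) + Σ_k Σ_r Σ_n c_{r,n}^{(k)} ψ_{r,n}^{(k)}(x)

with `N_S` displaced B-spline scaling functions `φ_k`, wavelets
`ψ_{r,n}^{(k)}(x) = 2^{r/2} ψ_k(2^r x − n)` at resolution levels
`r = 0..N_R−1`, and an identity ("linear bypass") term. Multi-input
frames are tensor products, and training reduces to one ridge-regularized
least-squares solve of the normal equations
`(GᵀG + γI)σ = Gᵀy` with `γ = μ·λ_max(GᵀG)`, accumulated over row
chunks so the design matrix `G` is never held in memory.

Two training paradigms: *full state* (all state variables + current as
inputs — the in-silico benchmark) and *voltage history* (only lagged
voltage samples + current — the configuration that transfers to real
recordings). Generalization is scored on fresh stepwise and stochastic
oscillatory test currents with the `(1−r²)` regression score, un-centered
cross-correlation `R(k)`, cosine similarity `S_C = R(0)`, and
interspike-interval statistics.

## Worked example

Identify the FitzHugh–Nagumo neuron from 50 s of stepwise stimulation
(2% of the reference duration; a 1002-wavelon bicubic frame), then test
one-step-ahead prediction on a noisy stepwise current and on a
stochastic oscillatory current:

```r
library(wavenetid)
run <- run_identification("fhn", scale = 0.02, seed = 1)
print(run)
```

```
Identification of fhn ( full_state ), 50 s training, 1002 wavelons
-- stepwise test (xi_bar = 0.01 ) --
Score report (transient 100 ms discarded)
  one_minus_r2_pct cosine_similarity
v        2.346e-05                 1
w        2.680e-04                 1
spikes (true/pred): 69 / 69  ISI overlap: 0.9853
-- oscillatory test --
Score report (transient 100 ms discarded)
  one_minus_r2_pct cosine_similarity
v        1.291e-05                 1
w        1.651e-04                 1
spikes (true/pred): 74 / 74  ISI overlap: 1
```

Reading the numbers: `one_minus_r2_pct` is the normalized residual of
the one-step prediction in percent (0 = perfect; here ~10⁻⁵ % of the
signal variance), `cosine_similarity` is the un-centered correlation at
zero lag (1 = perfect), and the ISI lines compare the spike trains of
the simulated neuron and the network's prediction over the 5 s test.
The stepwise test perturbs the leak/recovery parameters by 1% during
the test integration, so its score includes an irreducible noise floor;
the smooth oscillatory test isolates the approximation error — which is
why it scores better, a pattern the test suite checks for both 2D
models.

Lower-level entry points: `neuron_model()` / `integrate_neuron()`
(simulation), `stepwise_current()` / `oscillatory_current()` (stimuli),
`wavelet_frame()` / `design_matrix()` (the frame), `build_dataset()` /
`fit_wavenet()` (training), `predict_teacher_forced()` / `free_run()`
(prediction), `score_prediction()` (indicators),
`run_hyperparameter_sweep()` (the 12-combination frame study). A thin
command-line driver is installed as `exec/wavenetid`
(`simulate`, `identify`, `sweep`). See the vignette
(`vignettes/wavenet-identification.Rmd`) for the model, the stimulus
design, and every numerical choice.

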