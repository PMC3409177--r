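# puncta

Individual synapses exchange their molecular components continuously with
extrasynaptic pools, yet must hold on to their individual "identity" —
their size and molecular content relative to their neighbors — for hours
to days if synaptic configurations are to be stable. `puncta` is an R
package for quantifying this **synaptic tenacity** from long-term
time-lapse fluorescence imaging of tagged synaptic proteins (scaffold
proteins such as PSD-95, vesicle proteins, surface receptors), for
experimenters comparing genotypes or pharmacological conditions.

It implements, as tested and reusable building blocks:

- **FRAP analysis** — normalization and correction for ongoing
  acquisition photobleaching,
  `F_norm(t) = (F_t/F_0) · (F_nb0/F_nbt)`, using non-bleached reference
  puncta, followed by bounded nonlinear least-squares fitting of the
  two-pool recovery model

  ```
  F(t) = F_bl + (1 − F_bl)·[P_f·(1 − e^(−t/τ_f)) + (1 − P_f)·(1 − e^(−t/τ_s))]
  ```

  returning a classed `frap_fit` object with the usual `coef`, `predict`,
  `summary`, `plot`, `simulate`, `residuals` methods; plus fractional
  recovery (mean of the last three normalized values) and point-wise
  curve averaging with SEM.
- **Content-constancy statistics** — per-punctum *range over mean*
  `(F_max − F_min)/F̄` on 5-point-smoothed traces; the *Similarity Index*
  `SI(t) = g_0·g_t/(‖g_0‖‖g_t‖)` between a neuron's punctum-intensity
  vectors, normalized to the neuron's attainable floor estimated by
  cyclic permutation of the final vector; punctum loss rates; and
  two-sample Kolmogorov–Smirnov group comparisons.
- **Punctum tracking** — maximal-intensity projection, local-maximum
  detection, per-frame recentering with 7×7-pixel box-mean intensity
  measurement, and loss/split/merge flagging.
- **A synthetic-data generator** — mean-reverting multiplicative
  intensity dynamics around slowly drifting setpoints, photobleaching,
  loss events, FRAP forward simulation and rendered image stacks with
  ground truth, so that every estimator is validated end to end without
  any external data.

## Worked example

Simulate a wild-type / knockout contrast at 10 neurons per group and run
the full constancy pipeline:

```r
library(puncta)
rep <- run_constancy_pipeline(run_config(groups = list(wt = "wt", ko = "ko"),
                                         n_neurons = 10, seed = 42))
print(rep)
#> Content-constancy report
#>   wt           10 neurons,   696 puncta | range over mean 33.0+/-12.4% | loss rate 7.2+/-2.9% | SI endpoint 0.88
#>   ko           10 neurons,   692 puncta | range over mean 36.7+/-14.8% | loss rate 7.7+/-2.7% | SI endpoint 0.84
#>   wt vs ko:
#>     range_over_mean  D = 0.099, p = 0.0023
#>     si_endpoint      D = 0.600, p = 0.0524
#>     loss_rate        D = 0.200, p = 0.922
```

Per group the report gives mean ± SD of per-punctum range over mean
(higher = less stable content), the per-neuron fraction of puncta lost,
and the endpoint of the normalized SI decay curve (1 = configuration
unchanged, 0 = reshuffled to the attainable floor); below are the KS
comparisons — here the knockout's larger fluctuations are detected in the
range-over-mean distribution (p ≈ 0.002), while 10 neurons per group are
not yet enough to resolve its loss-rate excess.

A single FRAP experiment, simulated from known kinetics and refit:

```r
fit <- frap_fit(bleach_correct(simulate_frap_experiment(
  frap_presets("ko"), frap_schedule(), noise_sd = 0.02,
  bleach_rate = 1e-3, seed = 42)))
summary(fit)
#> Two-pool FRAP recovery fit
#>   post-bleach level F_bl : 0.1144
#>   fast-pool fraction P_f : 0.3785
#>   tau_fast  : 23.62 min
#>   tau_slow  : 877.97 min (14.63 h)
#>   residual SD: 0.0274 on 22 points; converged: TRUE
```

A 3-hour recording constrains a 7-hour slow pool only weakly, so
single-curve estimates of `τ_s` scatter widely at this noise level;
`run_frap_pipeline()` therefore also fits the averaged population curve,
which recovers the generating parameters closely (see below). Lower-level
entry points (`smooth_trace()`, `range_over_mean()`,
`similarity_index()`, `shuffled_si_floor()`, `normalized_si_curve()`,
`loss_rate()`, `detect_puncta()`, `track_puncta()`, `stack_to_traces()`)
expose each analysis stage separately; the methods vignette
(`vignettes/tenacity-analysis.Rmd`) documents the models and design
choices.

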