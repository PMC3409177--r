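---
title: "Quantifying synaptic tenacity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic tenacity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puncta)
```

Individual synapses hold their molecular content — scaffold proteins,
vesicle pools, receptors — only loosely: molecules exchange continuously
with extrasynaptic pools, yet synapses must remain individually stable for
hours to days if their configuration is to store anything. `puncta`
quantifies this *tenacity* from long-term live imaging of fluorescently
tagged synaptic proteins, at two time scales: molecular exchange measured
by FRAP over minutes to hours, and content constancy of tracked puncta
over many hours. This vignette explains the models behind each estimator,
the parameters that matter, and the design decisions taken where the
underlying conventions are ambiguous.

## The FRAP exchange model

After a punctum is photobleached, recovery of its normalized fluorescence
is modelled as exchange from two kinetically distinct pools:

$$F(t) = F_{bl} + (1 - F_{bl})\left[P_f\left(1 - e^{-t/\tau_f}\right) +
  (1 - P_f)\left(1 - e^{-t/\tau_s}\right)\right]$$

with $F(0) = F_{bl}$, the residual fluorescence immediately after
bleaching, an asymptote at the pre-bleach level 1, a fast pool of
fractional size $P_f$ with time constant $\tau_f$, and a slow pool
$(1-P_f, \tau_s)$. This functional form is our rendering of the
convention established for synaptic scaffold FRAP; it is the unique
two-exponential form satisfying the stated semantics (start at $F_{bl}$,
full recovery at infinity, $P_f$ a fraction of the *recoverable*
amplitude).

**Photobleaching correction.** Time-lapse acquisition itself bleaches.
Before fitting, the bleached punctum's series is normalized as

$$F_{norm}(t) = \frac{F_t}{F_0}\cdot\frac{F_{nb0}}{F_{nbt}}$$

with $F_0$ its pre-bleach level and $F_{nbt}$ the average over (at least
ten) non-bleached reference puncta. The contract is exact algebraic
cancellation: any per-time-point factor shared by all series drops out,
which the test suite asserts to machine precision.

**Fitting.** `frap_fit()` minimizes squared error with `L-BFGS-B` over
$(F_{bl}, P_f, \log\tau_f, \log(\tau_s/\tau_f))$, bounding
$F_{bl}, P_f \in [0,1]$ and $\tau_s/\tau_f \ge 1$. The log-ratio
parameterization enforces pool ordering and removes label switching; the
log scales condition the search when $\tau_s$ is far beyond the sampling
horizon. The default start places $\tau_f$ at the half-recovery time with
$\tau_s = 10\tau_f$, $P_f = 0.5$; two perturbed starts guard against
local minima (`factr = 1e2`, i.e. relative tolerance near `1e-13`, up to
2000 iterations). Two degeneracies are flagged rather than hidden: a
constant curve returns `P_f = NA` with a `degenerate` flag (nothing was
bleached), and fits with $\tau_s < 2\tau_f$ carry `poor_separation`,
because two exponentials that close are barely identifiable and the pool
split is then unreliable. Note that a 3-hour recording samples a 7-hour
slow pool only on its initial slope; noiseless recovery is still exact,
but on noisy single-synapse curves $\tau_s$ is the least certain
parameter — fitting the averaged population curve (also provided) is the
more stable entry point.

## Content-constancy statistics

**Range over mean.** Per punctum, the trace is smoothed and
$(F_{max}-F_{min})/\bar F$ computed on the smoothed series. The "5-point
low-pass filter" is interpreted as an unweighted centered moving average —
the most common reading when only a width is named — with symmetric window
truncation at the boundaries (the end points pass through unchanged, the
second point uses a width-3 window, and so on). Width is a parameter;
statistics from smoothed data are scale- and time-reversal-invariant,
which is asserted exactly.

**Similarity Index.** For the vector $g_t$ of punctum intensities of a
neuron at time $t$,

$$SI(t) = \frac{g_0\cdot g_t}{\lVert g_0\rVert\,\lVert g_t\rVert},$$

the cosine of the angle between the configuration at $t$ and at the
start. Global multiplicative factors — photobleaching — change the
vector's length, not its angle, so SI is exactly invariant to them.

**Shuffle floor and normalization.** SI between unrelated positive
vectors is well above 0, and its floor depends on each neuron's intensity
spread. The attainable minimum is estimated by cyclically rotating the
final vector against $g_0$: the mean of $SI(g_0, \mathrm{rot}_k(g_T))$
over ten nonzero offsets $k$ (all offsets when fewer than ten exist,
otherwise a seeded uniform sample without replacement — the offset
selection rule is unspecified in the antecedent convention, so it is made
explicit and reproducible here). The normalized curve is the affine map
sending the floor to 0 and 1 to 1:

$$SI_{norm}(t) = \frac{SI(t) - SI_{shuffled}}{1 - SI_{shuffled}},$$

the only affine normalization consistent with "normalize to the minimum
attainable value". Values are clipped below at 0 — when the final
configuration happens to align with one of the floor's own rotations the
raw SI can fall below the floor average — and the raw SI is always
emitted alongside so the normalization remains auditable. If the floor is
numerically 1 (all puncta identical), $SI_{norm}$ is defined as 1 where
the raw SI is 1 and `NA` elsewhere.

**Which puncta enter SI.** Only puncta tracked across the entire window
contribute to the SI vectors; lost puncta are excluded (their
near-background values would otherwise dominate the angle) but counted in
the loss rate, `n_lost / (n_tracked + n_lost)`. Split/merge rejections are
excluded from both. The pipeline counts every exclusion per category, so
nothing is dropped silently.

**Group comparison.** SI decay curves are compared by averaging each
neuron's final three normalized values and applying a two-sample
two-sided Kolmogorov–Smirnov test to the pooled per-neuron endpoints; the
same KS machinery (`stats::ks.test`, which switches to exact p-values at
small sample sizes) compares range-over-mean and loss-rate distributions,
with mean ± SD reported per group. Fractions are kept in $[0,1]$
internally; percentages appear only in printed reports. No
multiple-testing correction is applied beyond these single pairwise tests,
mirroring standard practice for this design.

## The synthetic-data generator

No imaging data are deposited with studies of this kind, so every
estimator here is validated against a generator with known ground truth.
Per punctum $i$, a *setpoint* $s_i(t)$ performs a slow random walk in log
space (step SD `reconfiguration_sd`), and the observed intensity follows
discrete mean-reverting dynamics toward it:

$$\log F_i(t+1) = \log F_i(t) + \kappa\,[\log s_i(t+1) - \log F_i(t)] +
  \varepsilon_t,\quad \varepsilon_t\sim N(0, \sigma_{fl}^2),$$

with per-step pull $\kappa = \min(1, \texttt{reversion\_rate}\cdot dt)$.
This separates the two phenomena the statistics measure: fast
fluctuations (`fluctuation_sd`, driving range over mean) and slow
relative reordering (`reconfiguration_sd`, driving SI decay). All puncta
share an $e^{-\lambda t}$ photobleaching factor (which SI must ignore);
loss events draw an exponential waiting time scaled so the probability of
loss within the experiment equals `loss_prob`; additive measurement noise
is truncated at zero. Traces are background-subtracted signal; background
exists only in the image-rendering layer. Initial setpoints are lognormal
with spread `size_sd` (default 0.5 log-units), the between-punctum size
heterogeneity without which the shuffle floor would degenerate to 1.

Default timing is the reference recording condition: 73 frames at 10-min
intervals (12 h). Image mode renders each punctum as an isotropic
Gaussian spot (SD `psf_sd`, default 1.2 px) whose integrated intensity
equals the trace value, on constant background with Gaussian noise, with
optional linear stage drift; ground-truth centers are stored per frame.

**Presets and their calibration.** `genotype_presets()` encodes the four
study conditions (`wt`, `ko`, `wt_blocked`, `ko_blocked`), differing only
in `fluctuation_sd`, `reconfiguration_sd` and `loss_prob`: knockout
exceeds wild type on all three, and the activity-blockade pair reverses
the fluctuation ordering. The published record constrains orderings and
the range-over-mean percentages, but no per-time-point variances, so
absolute magnitudes are calibration choices, fixed once by simulation:
the presets reproduce realistic range-over-mean distributions (about 33%
wild type, 38% knockout, SD 12–15%) and loss rates (6% / 9%). One
structural limitation follows from the model: with independent
per-punctum log random walks, the same walk that reorders puncta also
inflates each punctum's own range, so range-over-mean near 33% implies a
shallower SI decay (normalized endpoints near 0.88/0.84 at 12 h) than
real recordings show (≈0.6). Reproducing both simultaneously would need
correlated or compensating remodelling (e.g. exchange of material between
neighbors), which the generator deliberately does not model. All
ordering-based validation is unaffected; magnitude-based SI claims should
not be read off the synthetic presets.

What passing tests show, and what they do not: the estimators are exact
on their algebraic contracts, statistically calibrated (type-I rates,
binomial consistency) and accurate against ground truth *under this
generative model* — multiplicative lognormal dynamics, isotropic Gaussian
spots, uniform background. Real recordings add focus drift, uneven
illumination, overlapping neighbors and non-Gaussian noise; the tracker
and detector make no claim of robustness to those beyond what the
round-trip tests exercise.

## Tracking

The paper-convention measurement path is: maximal-intensity projection
across Z, detection of puncta as pruned local maxima, and per-frame
recentering of each track on the brightest pixel within a search radius,
measuring mean intensity in a fixed odd box (default 7×7 px) at the
integer-rounded center. The original tracking software's algorithm is
unpublished; this tracker is a documented stand-in whose contract is the
round trip — simulated traces, rendered to images, tracked and re-measured,
must correlate with ground truth at r > 0.98 with sub-pixel position
error — not fidelity to any particular implementation. Three flags mirror
the stated exclusions, with explicit numeric criteria where the
convention says only "clearly":

- **lost**: background-subtracted box mean below $k\sigma_{bg}$ for $m$
  consecutive frames (defaults $k=2$, $m=3$; both configurable);
- **merged**: two track centers within `merge_distance` (default 3 px);
- **split**: a second maximum in the search window at ≥ 60% of the
  primary's background-subtracted height, both at least $5\sigma_{bg}$
  above background (the significance guard keeps noise maxima around a
  lost punctum from masquerading as splits).

Background and its SD are estimated from the first frame (median and
MAD) unless supplied. Centers stay at integer pixels for box extraction,
matching the fixed-box measurement convention. The tracker contains no
randomness: identical stacks give identical tracks.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state; identical parameters and seed give bit-identical
output, including CSV files written by the pipelines, whose provenance
file records the full configuration, seed and package version. Validation
uses problem sizes chosen to make each check statistically decisive while
keeping the whole suite fast: 1000 puncta for binomial loss-rate
consistency, 10⁴ increments for the fluctuation-SD check, 200 replicates
for type-I calibration of the KS comparisons, 25 noisy curves for FRAP
parameter recovery, 8–45 neurons per group for ordering checks.

## Limitations

- The two-pool model is phenomenological: no diffusion–reaction FRAP
  modelling, and no claim that pools map onto molecular states.
- Presets encode orderings and plausible magnitudes, not mechanistic
  biology; see the calibration note above.
- The tracker is validated by round trip on rendered data only.
- KS comparisons are the only inferential machinery, as in the antecedent
  analysis convention; no hierarchical modelling of neuron/punctum
  nesting is attempted.
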