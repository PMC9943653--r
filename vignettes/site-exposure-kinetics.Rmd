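---
title: "Site-exposure kinetics of transcription factor binding in nucleosomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-exposure kinetics of transcription factor binding in nucleosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siteexposure)
```

## The model

Nucleosomal DNA transiently unwraps from the histone octamer, exposing
transcription factor (TF) binding sites that the fully wrapped nucleosome
occludes.  `siteexposure` analyses this *site-exposure* mechanism with a
three-state continuous-time Markov chain:

* **State 1** — wrapped nucleosome, site occluded (high FRET between a
  DNA-attached donor and a histone-attached acceptor);
* **State 2** — transiently unwrapped nucleosome, site exposed but unbound
  (low FRET, but far too short-lived to observe at camera frame rates);
* **State 3** — unwrapped nucleosome with the TF bound (low FRET,
  observable).

Transitions are `1 -> 2` (unwrapping, `k12`), `2 -> 1` (rewrapping, `k21`),
`2 -> 3` (bimolecular binding, `k23 * [TF]`) and `3 -> 2` (dissociation,
`k32`).  Units are s^-1 for the unimolecular rates, nM^-1 s^-1 for `k23`,
and nM for concentrations, everywhere in the package.

Because rewrapping happens on the 10 ms scale while unwrapping is on the
hertz scale (`k12 << k21`), the exposed-unbound state is essentially never
populated (its stationary occupancy is below `k12/k21`, under 1% at the
defaults).  Eliminating it gives closed forms for the two transition rates
a camera actually sees, as functions of TF concentration `c`:

* high to low FRET: `k_HL(c) = k12 / (1 + k12 / (kon_eff * c))`, where
  `kon_eff = (k12/k21) * k23` is the site-exposure-limited effective
  binding rate constant;
* low to high FRET: `k_LH(c) = k32 / (1 + kon_eff * c / k12)`.

At low concentration `k_HL` rises linearly as `kon_eff * c` and `k_LH`
equals `k32`; once binding to the exposed site outpaces rewrapping
(`c` above `c_cross = k12/kon_eff = k21/k23`), `k_HL` saturates at the
unwrapping rate while `k_LH` decays hyperbolically because the TF
dissociates and rebinds several times before the nucleosome manages to
rewrap.  The ratio `KD_eff = k32/kon_eff` is the effective dissociation
constant of occupancy; `regime_metrics()` reports both characteristic
concentrations, which are deliberately kept distinct because they answer
different questions (half-occupancy versus kinetic regime change).

Only the triple (`k12`, `k32`, `kon_eff`) is identifiable from
concentration series of the two apparent rates; `k21` and `k23` enter
through their ratio alone.  The simulator therefore carries `k21`
explicitly with a default of 100 s^-1 (rewrapping on the 10 ms scale) and
derives `k23` from `kon_eff` when constructing ground truths.

`spectral_solution()` and `propagate_master_equation()` provide the exact
eigen-solution of the master equation; the closed forms agree with the
slowest relaxation eigenvalue of the corresponding absorbing-variant rate
matrices to within 2% once `k12` is fifty-fold below both `k21` and
`k23*c`, which the test suite asserts over random parameter draws.  A
scaling-and-squaring matrix exponential backs up the eigendecomposition
for near-defective generators (tolerance 1e-10).  The absorbing variants
keep all three rows and columns so state indices always mean the same
thing.

## What the simulator emulates — and what it does not

`simulate_experiment()` produces cohorts of single-molecule FRET traces:
exact Gillespie paths of the chain, rendered into camera frames as the
occupancy-time-weighted average of two emission levels plus Gaussian
noise.  Defaults, chosen once as a realistic prism-TIRF configuration and
used as the study conditions throughout the tests:

| parameter | default | why |
|---|---|---|
| frame time | 0.1 s | 10 ms rewrapping is sub-frame; published rates (0.3-2.5 s^-1) give tens of events per trace |
| trace duration | 120 s | hundreds of frames; dwell statistics per trace without modelling bleaching |
| E_high / E_low | 0.75 / 0.15 | arbitrary two-level separation; only the gap matters |
| noise sd | 0.08 | typical per-frame efficiency noise at these rates |
| k21 | 100 s^-1 | rewrapping on the 10 ms time scale |
| initial state | wrapped (1) | unwrapping is rare, so traces start wrapped |

State 2 emits at `E_low` like state 3: the unwrapped geometry dominates
the dye separation whether or not the TF is bound.  An isolated
`1 -> 2 -> 1` excursion (mean 10 ms) perturbs one 0.1 s frame by
0.6 x 0.01/0.1 = 0.06 efficiency units in expectation, below the noise sd
of 0.08, so unbound site exposure is invisible — the simulator reproduces
the central observability constraint of camera-rate smFRET.  The
analytically expected fraction of such excursions exceeding three noise
sds is `exp(-4)` (about 1.8%), which the tests verify by Monte Carlo.

Not modelled: photophysics (blinking, crosstalk, gamma), photon-level
emission, drift, and photobleaching by default (an injected bleach step is
available to exercise `truncate_trace()`).  Passing tests on these
synthetic cohorts therefore demonstrate correctness of the estimators
under the three-state model with Gaussian two-level emission — not
robustness to every artefact of real recordings.

`generate_titration()` supplies the ensemble side: one- or two-event
binding isotherms `E(c) = E0 - sum_i dE_i c/(S_i + c)` on a 12-point
logarithmic grid from 0.1 to 3000 nM plus a zero point, three replicates,
noise sd 0.02.  The grids are documented choices, not claims about any
particular experiment's sampling.

## Idealization

`idealize_hmm()` fits a two-state Gaussian-emission hidden Markov model by
maximum-likelihood EM and decodes the most probable path (Viterbi).  A
maximum-likelihood fit suffices because the idealization is used only to
harvest dwell times; no posterior over paths is needed.  The state count
is fixed at two — possible low-FRET substructure is deliberately collapsed
into a single low state.  Initialization uses the 10th/90th percentile
means, the trace sd for both states, and 0.05 transition probability;
degenerate EM runs are retried from jittered starts (3 attempts) and fall
back to the threshold idealizer with a warning flag.  Convergence is 1e-6
in log-likelihood, at most 500 iterations; sds are floored to avoid
variance collapse.  States are canonically ordered by mean, so swapping
the initial labels cannot change the result.  On cohorts at the default
signal-to-noise (level gap 0.6, sd 0.08) the frame-label accuracy against
the generating path exceeds 98%, and the threshold idealizer agrees with
the HMM on at least 95% of frames.

## Dwell-time analysis

Dwells are contiguous same-label runs times the frame time.  Two
numerical guards matter:

* **Dead time.** Single-frame dwells are ambiguous with noise blips, so
  the minimum trustworthy dwell is `t_min = 2` frames and the exponential
  likelihood is left-truncated and renormalised on `[t_min, Inf)`.  The
  one-component truncated MLE is the closed form
  `rate = 1/(mean(d) - t_min)`.
* **Edge dwells.** The first and last runs of a trace are censored.  The
  package's default likelihood keeps them with their correct semantics:
  the first run's *start* is unobserved, but by the memorylessness of the
  exponential its observed portion is a complete draw (its terminating
  transition is seen); the last run is right-censored and contributes its
  survivor function.  For one component this reduces to the classic
  events / total-observed-time estimator.  The simpler policy of fitting
  only complete interior dwells (`use_censored = FALSE`) is also
  available, but it is *biased* whenever dwells are comparable to the
  trace length: a complete dwell of length `L` fits in a window of length
  `T` with probability proportional to `T - L`, under-sampling long
  dwells.  At the inner-region study conditions (mean high dwell ~26 s in
  120 s traces) that bias reaches tens of percent on the slowest rate
  points and propagates into the global fit, which is why the
  censoring-aware likelihood is the default.

Two-component fits maximise the truncated mixture likelihood from four
starts (Nelder-Mead in log-rate / logit-amplitude space).  Rates are
capped at `1/t_min`: faster components are unobservable by construction,
and an unbounded mixture exploits the frame-quantised pile-up of
durations at the truncation boundary with a runaway fast component.
Model choice between one and two components is a likelihood-ratio test
against chi-squared with 2 df at alpha = 0.05 (BIC reported alongside);
ties go to one component, as does any two-component fit whose fast rate
sits at the cap — such a component reflects quantisation, not kinetics.
When two genuine populations are present the reported "primary" rate is
the larger-amplitude component, tie-broken toward the faster rate, which
reproduces the generating rate when a minor (~10% amplitude) contaminant
is injected.

Per-concentration rates pool dwells across traces; standard errors come
from a nonparametric bootstrap over traces (default 200 replicates,
seeded), refitting the selected model from its fitted parameters.

## Global kinetic fit

`global_fit_site_exposure()` minimises the joint weighted least squares
of the measured `kHL` and `kLH` series against the two closed forms,
sharing (`k12`, `k32`, `kon_eff`).  Weights default to inverse bootstrap
variances so neither curve dominates; fitting is in log-parameter space
to enforce positivity, with nine log-spaced multi-starts.  Confidence
intervals use a parametric bootstrap — each rate point redrawn from its
standard error — because with only three or four concentrations
resampling points with replacement is nearly degenerate.  On noiseless
closed-form input the fit recovers the generating triple to 1e-6
relative; on full synthetic cohorts at the published parameter values it
recovers `k32` and `kon_eff` to a few percent.  `k12` is the weakly
identified parameter whenever the concentration range stays well below
`c_cross` (it enters only through the curvature of `kHL`), which the
bootstrap interval makes visible; the outer-region design (1-10 nM
against `c_cross` = 23 nM) leaves it with an upper bound beyond twice the
point estimate, and even the inner-region design reaching 0.44 `c_cross`
determines it only to roughly 15-20%.

`linear_two_state_fit()` provides the naive comparison model — a
zero-intercept line for `kHL` (binding vanishes without TF) and an
inverse-variance-weighted constant for `kLH` — which is adequate for
outer-region data and visibly wrong for inner-region data.

## Equilibrium titrations

`fit_isotherm()` fits one- or two-event binding isotherms by
Levenberg-Marquardt NLS with log-spaced half-saturation starts,
replicates fitted jointly (Hill coefficient fixed at 1; amplitudes and
`E0` unconstrained and shared across events, a documented choice).  The
zero-concentration points pin `E0`.  Event count is decided by an
extra-sum-of-squares F-test, a quantitative stand-in for judging
inflection points by eye; ties go to one event.  Under the default
design the first event's half-saturation is recovered with a median
error under 15%, while a second event near 380 nM on a grid ending at
3000 nM carries an asymptotic relative standard error around 30% — the
fits report exactly that uncertainty, and the tests assert the errors
are calibrated to it rather than pretending to more precision than the
design contains.  `ratioA_to_efficiency()` is a minimal affine
conversion from a corrected acceptor-ratio readout; spectral unmixing is
out of scope.

## Free-energy profile and landscape comparison

Half-saturations (ensemble) or `KD_eff = k32/kon_eff` (kinetic) convert
to relative occupancy free energies `ddG = ln(v / v_ref)` in kBT, with
first-order error propagation and the reference construct at exactly
zero.  Binding-site positions map onto the unwrapping coordinate as
inner-edge + 3 bp (the DNA unwraps a few base pairs beyond the site).
`compare_to_landscape()` shifts the profile by a constant so that it
matches the landscape at a calibration position (29 bp by default) —
relative free energies carry an arbitrary offset, so every result is
translation-invariant, which the tests assert — and then compares the
calibrated profile against the landscape interpolated (linearly) at the
same positions with a two-sample Kolmogorov-Smirnov test.  Whether the
original comparison was paired or two-sample is not derivable from the
method's description, so a paired sign-flip permutation test is offered
as an alternative; both are exposed and documented.  The package ships a
*synthetic* landscape (`synthetic_unwrap_landscape()`) with the
qualitative shape — a shallow outer region and a sharp ~5 kBT rise
between 30 and 35 bp — because the published landscape table is not
redistributed; real comparisons should load a measured table with
`read_landscape_table()`.  kBT is the energy unit throughout, with
`kbt_to_kcal()` (0.593 kcal/mol per kBT at 298 K) at the output boundary
only.

## Reproducibility and problem sizes

Every stochastic step takes a seed; `run_pipeline()` derives per-stage
and per-trace seeds from one master seed by a fixed counter scheme, so
any subset (a single trace, one bootstrap) can be regenerated in
isolation, and two runs of the same config are identical.  Reports carry
a config hash, the seed, and the package version.

The package's own validation uses cohorts of 400 traces per
concentration at four concentrations per construct (1, 2, 5, 10 nM for
the outer region; 50, 100, 250, 500 nM for the inner region), 120 s
traces at 0.1 s frames — the scale at which the published parameter
triples were estimated — plus smaller cohorts (tens of traces) for unit
properties.  Titration checks use 100 simulated repeats for the model
selection operating characteristics and 50 for recovery medians.

## Known limitations

* Frame-rate effects leave a residual 2-5% bias on the fastest apparent
  rates (sub-frame bound events are missed and merged); the dead-time
  truncation removes the worst of it but no inverse correction is
  applied.
* `k12` is honestly uncertain whenever the sampled concentrations stay
  below `c_cross`; treat its point estimate together with its bootstrap
  interval.
* The two-state idealizer cannot represent genuine low-FRET
  substructure; it mirrors the deliberate analysis choice of collapsing
  it.
* The synthetic landscape is for mechanics and illustration, not
  inference about any real nucleosome positioning sequence.
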