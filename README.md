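# siteexposure

Kinetic and equilibrium analysis of transcription factor (TF) binding at
target sites *inside* nucleosomes, through the Polach–Widom site-exposure
mechanism.  Nucleosomal DNA transiently unwraps from the histone octamer;
a TF can only bind during those brief excursions, so its apparent binding
kinetics and occupancy are set jointly by its intrinsic rates and by the
nucleosome unwrapping/rewrapping equilibrium.  The package is written for
single-molecule FRET (smFRET) and ensemble FRET data of the kind produced
by titrating a TF against donor/acceptor-labelled nucleosomes.

## The model

A three-state continuous-time Markov chain,

```
  1 (wrapped, high FRET)  <-- k21 --  2 (exposed, unbound)  -- k23·[TF] -->  3 (bound, low FRET)
                           -- k12 -->                        <--   k32   --
```

with rewrapping much faster than unwrapping (`k12 << k21`), so the
exposed-unbound state is effectively invisible and the two observable
FRET transition rates depend on TF concentration `c` as

```
k_HL(c) = k12 / (1 + k12/(kon_eff·c))        kon_eff = (k12/k21)·k23
k_LH(c) = k32 / (1 + kon_eff·c/k12)
```

Only the triple (`k12`, `k32`, `kon_eff`) is identifiable.  Derived
quantities: the effective dissociation constant of occupancy
`KD_eff = k32/kon_eff`, and the crossover concentration
`c_cross = k12/kon_eff = k21/k23` above which the TF rebinds faster than
the nucleosome rewraps.  Sites whose `KD_eff << c_cross` saturate in the
"outer" regime (binding rate linear in `c`, dissociation constant in
`c`); sites with `KD_eff ~ c_cross` live in the "inner" regime (binding
limited by the unwrapping rate, apparent dissociation slowing with `c`).

What the package does end to end:

* simulate smFRET trace cohorts from the chain (exact Gillespie paths,
  camera-frame rendering, Gaussian noise) and noisy ensemble titrations;
* idealize traces with a two-state maximum-likelihood hidden Markov
  model (EM + Viterbi), with a threshold fallback;
* extract censored dwell times and fit truncated exponential (mixture)
  models by maximum likelihood, with likelihood-ratio model selection;
* globally fit `k_HL` and `k_LH` versus concentration to recover
  (`k12`, `k32`, `kon_eff`) with bootstrap intervals, plus the naive
  linear two-state fit and fold changes between constructs;
* fit one- and two-event binding isotherms to titrations with F-test
  model selection and extract half-saturation (`S1/2`) values;
* build relative occupancy free-energy profiles
  `ddG = kBT · ln(S1/2 / S1/2_ref)`, map them onto the nucleosome
  unwrapping coordinate (inner site edge + 3 bp), calibrate at a
  reference position and compare against an unwrapping free-energy
  landscape (Kolmogorov–Smirnov or paired sign-flip test).

Everything is a tibble in, tibble out; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Recover the outer-region parameter triple from a simulated cohort at the
published P26 ground truth (`k12 = 2.5 s^-1`, `k32 = 0.66 s^-1`,
`kon_eff = 0.11 nM^-1 s^-1`, so `k23 = kon_eff·k21/k12 = 4.4`):

```r
library(siteexposure)

rates  <- rate_set(k12 = 2.5, k21 = 100, k23 = 4.4, k32 = 0.66)
cohort <- simulate_experiment(rates, conc_list = c(1, 2, 5, 10),
                              n_traces = 100, duration = 120, seed = 42)
ideal  <- idealize_cohort(cohort)
dwells <- extract_dwells_cohort(ideal)
series <- rate_series(dwells, bootstrap_reps = 100, seed = 43)
series
#> # A tibble: 4 × 9
#>   conc_nM    kHL  kHL_se   kLH  kLH_se n_high n_low ncomp_high ncomp_low
#>     <dbl>  <dbl>   <dbl> <dbl>   <dbl>  <int> <int>      <int>     <int>
#> 1       1 0.0989 0.00287 0.649 0.0211    1089   921          1         1
#> 2       2 0.205  0.00484 0.618 0.0153    1836  1689          1         1
#> 3       5 0.442  0.00795 0.525 0.00985   2706  2625          1         1
#> 4      10 0.766  0.0130  0.439 0.00940   3045  3055          1         1

fit <- global_fit_site_exposure(series, bootstrap_reps = 300, seed = 44,
                                label = "P26")
fit
#> Global site-exposure fit: P26
#> # A tibble: 3 × 5
#>   term    estimate      se ci_lo ci_hi
#>   <chr>      <dbl>   <dbl> <dbl> <dbl>
#> 1 k12        2.39  0.139   2.17  2.70
#> 2 k32        0.654 0.0111  0.632 0.675
#> 3 kon_eff    0.110 0.00172 0.106 0.113
#> KD_eff = 5.961 nM, c_cross = 21.75 nM
```

Reading the output: the apparent binding rate `kHL` climbs nearly
linearly over 1–10 nM (the outer regime) while the apparent dissociation
rate `kLH` stays near `k32`; the global fit recovers the dissociation
rate (0.654 vs 0.66 s^-1) and effective binding rate constant (0.110 vs
0.11 nM^-1 s^-1) to about a percent, and `KD_eff` of ~6 nM matches the
ensemble half-saturation scale for this site position.  `autoplot(fit)`
overlays the fitted closed forms on the rate points.

The same machinery runs as one deterministic pipeline from a config
(`exposure_config()` → `run_pipeline()`), including optional titration
fitting and the free-energy profile/landscape comparison stages.

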