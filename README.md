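# nfkbsync

NF-κB is a transcription factor whose nuclear concentration oscillates when
cells are stimulated with the inflammatory cytokine TNF-α. Whether those
oscillations are self-sustained (a limit cycle) or damped ringing around a
stable steady state changes how the system responds to *periodic*
stimulation: a damped oscillator simply follows the drive over a broad band
of forcing periods, while a genuine clock entrains only near resonance.
`nfkbsync` implements the computational toolkit for studying this question:
a deterministic ODE model of the NF-κB network with its two negative
feedbacks (IκBα and A20), eigenvalue-based classification of damped versus
sustained regimes, single-cell trace statistics for oscillation synchrony,
model fitting to dynamics and transcription, soft clustering of
gene-expression time courses, and seed-reproducible synthetic-data
generators for all of the above.

The package is aimed at systems biologists who want to simulate, fit, or
benchmark analyses of NF-κB (or similar damped-oscillator) dynamics without
access to raw imaging or microarray data: every pipeline stage can be
exercised end-to-end on generated data with known ground truth.

## The model

All variables are normalized to order one. `K` is active IKK, `N` the free
(nuclear) NF-κB fraction, `I` free IκBα, `A` the A20 protein, and each gene
carries an activation fraction `G` and a mature-mRNA level `R`:

    dK/dt   = −d_K·K + S(t)/(1 + Aⁿ)
    dN/dt   = d·(1−N) + γ·d_I·(1−N) + p·K·(1−N) − a·I·N
    dG_I/dt = (k_on,I·N + k_on0,I)(1−G_I) − (k_off,I·I + k_off0,I)·G_I
    dR_I/dt = d_R,I·(G_I − R_I)
    dI/dt   = d·(1−N) − κ·p·K·I − a·I·N + k_I·R_I − d_I·I
    dG_A/dt, dR_A/dt  analogous with A-subscripted rates
    dA/dt   = k_A·R_A − d_A·A

plus, for any NF-κB-controlled gene, a telegraph module
`dG/dt = (k_on,G·N + k_on0,G)(1−G) − (k_off,G·I + k_off0,G)·G`,
`dR/dt = d_R,G·(G − R)`. The stimulus `S(t)` (h⁻¹) encodes the TNF-α
protocol — constant flow, square wave of period `T_f = T1 + T2`, or a
sawtooth pulse-and-decay — with 10 ng/ml TNF-α corresponding to
`S = 2 h⁻¹`. The observable compared with live-cell imaging is the
nuclear-to-cytoplasmic intensity `NCI = (1/3)·N/(1−N)`.

The regime of a parameter set is read off the Jacobian at the fixed point
under constant stimulation: all eigenvalue real parts negative means damped
oscillations; any positive real part means an unstable fixed point circled
by a stable limit cycle (sustained oscillations). Synchrony of a cohort of
single-cell traces to the forcing is quantified by the entropy of the
phase-difference distribution over 8 bins, `η = 1 − S/S_max`: 0 for a flat
distribution, 1 for perfect locking.

## Worked example

```r
library(nfkbsync)

p <- kinetic_params()          # calibrated baseline (damped, T0 = 90 min)

## 1. regime classification at constant 10 ng/ml TNF-alpha
classify_stability(p, S_const = 2)
#> <stability_report> damped (max Re lambda = -0.1914, 2 complex pairs)

## 2. a synthetic forced cohort and its synchrony
fc <- forcing_signal("square", S_high = 2, S_low = 0, T1 = 45, T2 = 45,
                     t_start = 60)               # T_f = 90 min
co <- generate_cohort(cohort_spec(n_cells = 60, forcing = fc, seed = 1))
an <- analyze_traces(co$traces, fc)
round(an$synchrony$eta, 3)
#> [1] 0.532
median(an$periods)          # pooled inter-peak periods, min
#> [1] 90

## 3. does the damped oscillator follow the forcing period?
forcing_period_scan(p, T_f_grid = c(60, 90, 180, 240))
#>   T_f amplitude n_peaks T_numerical ratio small_peak_regime
#> 1  60         2       9          60   1.0             FALSE
#> 2  90         2       6          90   1.0             FALSE
#> 3 180         2       3         180   1.0             FALSE
#> 4 240         2       5         120   0.5              TRUE
```

The stability report says the baseline sits in the damped regime, with its
dominant eigenvalue pair ringing at the 90-min natural period. The cohort
locked to a 90-min square-wave drive shows a clearly peaked phase-difference
distribution (η = 0.53; an unforced cohort decays to η ≈ 0 beyond the first
response peak) and a modal inter-peak period equal to the forcing period.
The period scan shows the ratio `T_numerical/T_f` pinned at 1 across a
two-octave band of forcing periods — the signature of a driven damped
oscillator — until, at very long periods, smaller native-period peaks
appear between stimulations and the ratio drops toward 0.5 (flagged).

Downstream stages follow the same pattern: `fit_model()` /
`fit_gene_panel()` fit NCI and fold-change series by Metropolis exploration
plus Levenberg–Marquardt refinement of the mean relative error per
timepoint; `standardize_profiles()`, `fuzzy_cmeans()`, `extract_cores()`
and `enrichment_test()` reproduce the expression-pattern pipeline
(deregulation calls, soft clustering with membership ≥ 0.5 cores, Fisher
target enrichment); `run_pipeline()` chains everything and writes a JSON
report plus a reproducibility manifest.

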