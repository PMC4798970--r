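---
title: "Methods: a damped NF-κB oscillator under periodic forcing"
author: "nfkbsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a damped NF-kB oscillator under periodic forcing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfkbsync)
```

This vignette explains the models and procedures implemented in `nfkbsync`,
the assumptions behind them, the numerical and design choices that were
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## 1. The network model

The model tracks the canonical TNF-α → IKK → NF-κB axis with its two
negative feedbacks. Free NF-κB is treated as nuclear and the
NF-κB:IκBα complex as cytoplasmic; total NF-κB is conserved, so the free
fraction `N ∈ [0, 1]` and the complex is `1 − N`. IκBα is re-expressed
under NF-κB control (first feedback, variables `G_I`, `R_I`, `I`), and A20
inhibits IKK activation through the Hill term `S(t)/(1 + Aⁿ)` (second
feedback, `G_A`, `R_A`, `A`). Mass-action kinetics and normalization give
the eight equations listed in the README; every rate is in h⁻¹ and all
state variables are of order one. The equations and the interpretation of
each term:

* `dK/dt = −d_K·K + S(t)/(1+Aⁿ)` — IKK activation by the stimulus,
  spontaneously reverting, throttled by accumulated A20.
* `dN/dt` — NF-κB is released from the complex by spontaneous dissociation
  (`d`), degradation of complexed IκBα (`γ·d_I`), and IKK-driven
  degradation (`p·K`), and is re-sequestered by free IκBα (`a·I·N`).
* Gene modules — two-state (telegraph) promoters: the on-rate is
  proportional to nuclear NF-κB, the off-rate (optionally) to free IκBα,
  which here also acts as a transcriptional repressor. Setting
  `repressor_active = FALSE` removes the `k_off·I` terms while keeping
  basal inactivation; simulations in that variant remain bounded and
  qualitatively similar, so nothing downstream hinges on the repressor
  assumption.
* mRNA and protein — first-order relaxation of mRNA toward the promoter
  state (`d_R·(G − R)`) and translation/degradation for proteins.

Per-gene transcription modules (`gene_params()`) hang off the core state
but do not feed back on it. This is why the resting level of any gene
follows in closed form from the core rest point, and why per-gene fits can
hold the shared dynamics fixed.

**Assumptions worth keeping in mind.** The model is deterministic — it has
no transcriptional bursting or molecular noise; heterogeneity between
simulated cells comes entirely from parameter variation. IKK activation is
summarized in a single A20-modulated rate rather than a mechanistic kinase
cascade. Delay comes only from the mRNA/protein relaxation chain, not from
explicit transport terms.

## 2. Forcing protocols and units

`forcing_signal()` supports constant flow, square waves (high dose `D1`
for `T1` minutes, low dose `D2` for `T2`, period `T_f = T1 + T2`), and a
sawtooth mimicking pulse-then-stop microfluidics: a `pulse_len` plateau
followed by exponential clearance. The clearance half-life is not a
measured quantity; the default (30 min) is configurable and chosen so that
the ligand is essentially gone before the next 90-min pulse. The
dose-to-rate map is linear through the single calibrated anchor
(10 ng/ml ↔ `S = 2 h⁻¹`); linearity below the anchor is a modeling choice,
not a measurement. All user-facing times are minutes; rates are h⁻¹ and
conversion happens once, inside the integrator wrapper.

Integration uses `deSolve::lsoda` with the analytic Jacobian
(`rtol = 1e-8`, `atol = 1e-10`), compiled in C for throughput, and is
performed *piecewise between forcing switch times* so square-wave edges are
never smeared by the adaptive step size. The pure-R vector field is kept
as a reference implementation and the two are compared in the tests, as is
a fixed-step RK4 oracle.

## 3. The baseline parameter set

The 21 baseline rates in `default_parameters()` are effective, normalized
parameters chosen by calibration, not a literature table. The calibration
targets, fixed before anything downstream was built, are the experimentally
established features of the system at constant 10 ng/ml TNF-α: a
responding trajectory (N exceeds 0.4 within 3 h and relaxes below 0.4), a
first nuclear peak ~27 min after stimulus onset, a ~90-min inter-peak
interval (the natural period `T0`), at least two NCI peaks above the
significance threshold when a pre-stimulus baseline is present, and a
stable (damped) fixed point with enough margin that randomization under
the default uncertainty degrees leaves sustained-oscillation parameter
sets clearly in the minority. `scripts/calibrate_baseline.R` reproduces
the two-stage search (broad log-uniform screen, then greedy coordinate
refinement). The dominant Jacobian eigenvalue pair of the result,
`−0.19 ± 4.2i h⁻¹`, rings at 2π/4.2 ≈ 90 min.

Each parameter carries an *uncertainty degree* `D ∈ [0, 1]`
(`default_degrees()`): randomization multiplies the rate by `10^u`,
`u ~ U(−D, D)`. Manually calibrated and feedback-summary parameters (the
Hill exponent, the whole A20 module, promoter on/off rates) get `D = 1`;
degradation/binding rates anchored in prior literature get `D = 0.3`. The
Hill exponent is randomized like any other parameter and floored at 1
rather than rounded to integers.

## 4. Stability classification and scans

`find_fixed_point()` polishes a long-transient state with damped Newton
iterations to a residual below 1e−10 h⁻¹; `classify_stability()` labels a
parameter set *sustained* when any Jacobian eigenvalue has positive real
part (tolerance 1e−9; marginal sets are labelled damped and flagged rather
than given a third class). `stability_scan()` draws parameter sets from
the degree prior, keeps those passing the responding filter (max `N` over
the first 3 h above 0.4 **and** mean `N` over the last 2 h of a 20 h run
at or below 0.4 — the window lengths are configurable defaults, since only
"the first 3 hr" is pinned by the filter's definition), and reports the
sustained fraction plus per-parameter summaries. Under the defaults,
roughly 55% of draws respond and 8–10% of responding draws are sustained.
The scan is bit-for-bit reproducible given its seed.

`forcing_period_scan()` drives the model with symmetric square waves and
measures `T_numerical/T_f` from significant NCI peaks. Two choices matter
here. First, peaks earlier than `skip_first` (default 360 min) are
discarded: at forcing periods well below the natural period the model
entrains only after a few cycles (a transient period-2 regime), and
including the transient would bias the asymptotic period estimate. Second,
ratios below 0.75 are flagged as the small-peak regime: at long forcing
periods the system inserts native-period peaks between stimulations, and
the mean inter-peak interval legitimately drops toward `T_f/2`.

## 5. Trace analysis

Peak detection follows the min–max–min reading: maxima are strict local
maxima of the series (plateaus collapsed to their midpoint sample; trace
endpoints are never extrema), and each maximum's flanking minima are the
lowest samples between it and the neighbouring maxima or the trace
boundary, taking the tied sample nearest the maximum. The peak height θ is
the maximum minus the *higher* flanking minimum; peaks spanning only three
consecutive samples are noise peaks; significance requires θ > 0.15 (the
imaging-calibrated threshold) and a wider-than-3-sample span. Cohort
statistics use tracks of at least 7 h.

Phase is anchored at 2π on significant maxima and π on the minima between
them, linearly interpolated in time, undefined outside the anchored range.
Phase differences to the forcing take, for each forcing-cycle start, the
closest significant peak in either direction (ties toward the earlier
peak) and reduce `2πΔT/T_f` to `[0, 2π)`; a forward-only search is
available. Synchrony is `η = 1 − S/log(8)` from the 8-bin entropy of the
phase differences; the limits 0 (flat) and 1 (delta) are exact and the
statistic is invariant to the entropy's log base and to shifting all
phases by multiples of 2π.

One caveat the tests make explicit: the *pooled* η of a deterministic
damped cohort under constant stimulation is dominated by the first
response peak, which is synchronized in every condition (cells are all
stimulated at the same moment). The discriminating statistic for the
synchronization effect of periodic forcing is the per-cycle η beyond the
first cycle (`synchrony_per_cycle()`): a driven cohort keeps emitting
locked peaks cycle after cycle (flat η_n ≈ 0.7 — no cumulative "training"
effect), while an unforced cohort loses significant peaks and its residual
phase spread grows. Real unforced cells keep oscillating incoherently for
many hours because of molecular noise the deterministic model does not
contain; this is the main fidelity gap of the generator.

## 6. Fitting

The objective is the mean relative error per timepoint,
`d = (1/N)·Σ |X−x| / max(X, x)`, summed over datasets; `0/0` terms count
as zero so that pre-stimulus fold-change points normalized to baseline are
well-defined. Fitting runs in log10-parameter space inside the box given
by each parameter's uncertainty degree: a single-chain Metropolis walk
(Gaussian proposals scaled by the degree, acceptance `exp(−Δd/T)`,
defaults `n_steps` 1500, `T` 0.02 — the method is prescribed, its settings
are ours) followed by Levenberg–Marquardt refinement. LM needs
least-squares residuals, so the refinement minimizes squared relative
residuals and its result is kept only when it improves the original
distance; the reported optimum therefore never exceeds the best explored
state. Fits require explicit seeds and record their acceptance trace.

Per-gene fits (`fit_gene_panel()`) hold the shared dynamics fixed and vary
only that gene's telegraph parameters, with a wider search box
(`gene_degree = 1.5`) because fitted mRNA turnover legitimately spans two
orders of magnitude between oscillating and accumulating genes. A known
identifiability limit: above the sampling rate, turnover trades off
against activation rate (a gene whose mRNA decays fully between samples
looks the same a bit faster or slower), so individual fast-gene estimates
scatter upward while group medians and the fast/slow ordering are robust —
which is what the degradation-rate contrast analysis actually uses.

## 7. Expression patterns

The pipeline mirrors standard array practice: optional detection-p filter
(keep genes with p < 0.05 in at least one condition), deregulation calls
(|log2 fold change| vs the t = 0 reference strictly greater than 1 at any
timepoint; the most extreme timepoint gives the direction), per-gene
standardization of log2 profiles to mean 0 and *population* sd 1, and
fuzzy c-means on Euclidean distance with fuzzifier `m = 1.5`. The c-means
implementation is the package's own: farthest-point plus random seeded
restarts (`n_start = 10`, lowest objective kept — single initializations
occasionally land in poor local optima), membership update
`u ∝ (1/d²)^(1/(m−1))`, objective checked non-increasing. The independent
`e1071::cmeans` implementation serves as a cross-check in the tests, never
as the implementation. Cluster cores are genes with membership ≥ 0.5
(disjoint for any threshold strictly above 0.5); cluster count is chosen
from the minimum inter-centroid distance curve, with the largest relative
drop flagged as the elbow. Set overlap uses the Szymkiewicz–Simpson
coefficient and target enrichment a one-sided Fisher exact test, checked
against direct hypergeometric enumeration.

## 8. Synthetic data: what it emulates, and what it does not

`generate_cohort()` emulates a live-imaging experiment: per-cell parameter
jitter (every rate scaled by `10^U(−D_cell, D_cell)`, default
`D_cell = 0.15`), 6-min sampling over 12 h, multiplicative log-normal
measurement noise on NCI (sd 0.05, natural scale), and geometric per-frame
tracking loss (0.002/frame), with tracks never cut below three frames so
the short-track filter is exercised. The noiseless significant-peak times
are returned as detector ground truth.

`generate_expression_panel()` produces fold-change time courses for six
dynamical archetypes: three NF-κB-driven up-patterns (pulse-resetting
fast-turnover, persistently-activated plateau, slowly accumulating with
turnover two orders of magnitude below the oscillating archetype) and
three NF-κB-independent decays (immediate, delayed-onset, gradual).
Because standardization removes scale, archetypes must differ in
*normalized shape* — pure exponential decays of different rates are
exactly collinear after z-scoring and would be unrecoverable by any
shape-based clustering. Panel noise is multiplicative log-normal with its
sd quoted on the log2 scale (the array-replicate convention; default
0.1). Sampling follows the pulsed-stimulation schedule: t = 0 and 20, 40,
60 min after each of three 180-min-period pulses.

Passing the planted-recovery tests shows the pipeline is correct and
well-conditioned under these conditions; it does not show that real
NF-κB data are this clean. In particular the generator has no intrinsic
stochasticity (unforced cells stop emitting detectable peaks once the
deterministic ringing decays), no trends or segmentation artifacts in NCI,
and archetypes are exact model trajectories rather than mixtures.

## 9. Numerical choices and degenerate inputs

* Resting state: integrate the unstimulated core until the residual falls
  below 1e−8 h⁻¹, with a Newton polish for very stiff draws whose
  integrator accuracy floor sits above the tolerance; gene states follow
  in closed form.
* Bound repair: solver excursions beyond state bounds smaller than 1e−6
  are clipped; larger ones raise.
* Fixed points: damped Newton with step halving; the scan seeds Newton
  from the end of the responding-filter trajectory (for sustained sets
  this starts on the limit cycle, and the fallback reseeds from a long
  transient).
* Fuzzy memberships at zero distance: membership 1 at the coincident
  centroid (limit convention). Zero-variance genes are excluded from
  standardization with a warning.
* Distance `0/0` terms: zero, as discussed; negative observations are
  errors, not clamped.
* Problem sizes in the tests (cohorts of 40–120 cells, panels of 6–120
  genes, 2000-draw scans, 50-set classifier cross-checks) were chosen so
  the whole suite exercises every stage at cohort scale in about a
  minute of compute.

## 10. Known limitations

* Determinism: no transcriptional bursting or extrinsic noise; cohort
  asynchrony under constant input is under-represented (Section 5).
* The baseline is a calibrated effective parameter set; individual rates
  (e.g. the fast A20 mRNA turnover) should be read as lumped, normalized
  quantities, not molecular measurements.
* Fast mRNA turnover is only identifiable up to the sampling rate
  (Section 6).
* The classifier's simulation cross-check excludes marginal sets
  (|Re λ| < 1e−6); near the Hopf boundary decay times diverge and any
  finite-horizon oracle is unreliable.
* No bifurcation-branch tracing, no stochastic simulation, and no
  mechanistic IKK module — each is outside the model's intended scope.
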