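---
title: "Models and methods of the multi-frequency DEP spring toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the multi-frequency DEP spring toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depspring)
```

## The measurement this package models

The dielectrophoresis (DEP) spring is a label-free single-cell assay: cells
flow over a pair of slanted coplanar electrodes, experience a negative-DEP
force opposing fluid drag, and settle at a *balance position* $\delta$
(measured from the electrode-pair center) that encodes the real part of the
cell's Clausius–Mossotti (CM) factor at the drive frequency. Switching the
drive frequency in a repeating schedule yields several Re[CM] values per
cell — several independent looks at its electrical phenotype — at a
throughput far above electrorotation, and with more frequencies per cell
than typical impedance cytometry.

`depspring` implements the computational side of this experiment on
synthetic data: the dielectric cell model, a Monte Carlo study that selects
the most discriminating measurement frequencies, the force-balance model
and its inverse, trajectory processing and balance validation, particle
detection/tracking, and 0-1-loss discrimination.

## Single-shell dielectrics

A cell is idealized as a conducting cytoplasm sphere (radius $R - d$)
wrapped in a thin insulating membrane shell (thickness $d$ = 10 nm, the
phospholipid bilayer). Each compartment is a lossy dielectric with complex
permittivity $\varepsilon^* = \varepsilon_0\varepsilon_r - j\sigma/\omega$
(time convention $e^{+j\omega t}$; Re[CM] is convention-independent). The
shelled particle reduces to an equivalent homogeneous sphere through the
standard radius-ratio formula with $g = R/(R-d)$:

$$\varepsilon^*_{eq} = \varepsilon^*_{mem}
  \frac{g^3 + 2K}{g^3 - K}, \qquad
  K = \frac{\varepsilon^*_{cyt} - \varepsilon^*_{mem}}
           {\varepsilon^*_{cyt} + 2\varepsilon^*_{mem}},$$

and the CM factor is
$\mathrm{CM}(f) = (\varepsilon^*_{eq} - \varepsilon^*_{m}) /
(\varepsilon^*_{eq} + 2\varepsilon^*_{m})$ with the medium permittivity
$\varepsilon^*_m$. The test suite checks this reduction against an
independent concentric-sphere boundary-value solution (a 4×4 complex linear
system for the potential coefficients) to $10^{-9}$ relative accuracy, and
checks the closed-form conductivity-only (low-frequency) and
permittivity-only (high-frequency) limits.

Across 10 kHz–1 GHz a typical cell shows two dispersions: membrane charging
(interfacial polarization of the shell) around 0.1–10 MHz, and the
cytoplasm/medium dispersion in the tens-to-hundreds of MHz. Only the first
is visible in the experimentally accessible 500 kHz–25 MHz window — one
reason the wide frequency range carries more independent information.

```{r spectrum, fig.width = 6, fig.height = 4}
sp <- cm_spectrum(midpoint_cell(), medium(), log_frequency_grid(1e4, 1e9))
plot(sp)
count_dispersions(sp)
```

## Monte Carlo populations

`sample_population()` draws each of the five free parameters independently
and uniformly on literature-derived ranges: cytoplasm conductivity
0.2–1.2 S/m, cytoplasm permittivity 20–80 $\varepsilon_0$, membrane
conductivity 10 nS/m–1 µS/m, membrane permittivity 2–20 $\varepsilon_0$,
outer radius 2–8 µm; membrane thickness is fixed at 10 nm and the medium at
1.5 S/m, 78.5 $\varepsilon_0$. All draws are linear-uniform, including
membrane conductivity: the study design states plain uniform sampling, and
we follow it; because that range spans two decades, a log-uniform option
(`log_membrane_conductivity = TRUE`) is provided for sensitivity analyses
without any claim that it reproduces the reference conditions. One RNG
stream per population, seed recorded in the output, makes every study
reproducible.

## The spring model and its single calibrated constant

Equating Stokes drag in the near-wall shear flow with the nDEP force gives
a dimensionless spring argument

$$u = \frac{3\eta\,\sin\theta\,\bigl[\tfrac{6Q}{wh^3}(h-R)\bigr]\,g^3}
           {R\,\varepsilon_m\,\lvert\mathrm{Re[CM]}\rvert\,
            V_{RMS}^2\,p(f,\sigma_m)}$$

($\eta$ viscosity, $\theta$ electrode angle, $Q$ flow rate, $w\times h$
channel cross-section, $g$ the electrode gap length scale normalizing the
field gradient $\nabla E^2 \sim V^2/g^3$, and $p$ a dimensionless
frequency-dependent field normalization calibrated with polystyrene beads).
The position dependence of the DEP force, $q_R$, is modelled as exponential
decay — the dominant behavior above coplanar electrodes — so

$$\delta = q_R^{-1}(u) = -\lambda \ln u,$$

with $u > 1$ clamped to $\delta = 0$ (the DEP force is too weak to push the
cell off the electrode center; the model warns and records a zero
position). $q_R^{-1}$ is a plug-in argument of `balance_position()`, so a
different decay law can be substituted without touching the rest of the
pipeline. The closed-form inverse makes `invert_cm()` exact (round trips at
$10^{-9}$), and cell-size correction is simply invert-at-measured-radius /
re-forward-at-reference-radius.

Two consequences of the exponential $q_R$ organize everything downstream:

* a position uncertainty $\Delta\delta$ maps to a *relative* CM tolerance
  $\Delta\mathrm{CM} = |\mathrm{CM}|\,\Delta\delta/\lambda$ (the balance
  position is $\lambda\ln|\mathrm{CM}|$ + device terms), so sensitivity is
  greatest where Re[CM] approaches zero;
* the device has a *measurability window*: below
  $|\mathrm{Re[CM]}| = u^{-1}$-threshold the cell never balances. With the
  default device (4 V RMS, 20 µm channel, 25 µm gap, 0.6 µL/min, mid-size
  5 µm cell) $u = 1$ falls at $|\mathrm{Re[CM]}| \approx 0.05$, which is the
  default `min_measurable_cm` of the tolerance model.

**Calibration.** The single free constant of the tolerance mapping is the
ratio $\Delta\delta/\lambda$. $\Delta\delta$ = 0.5 µm is the stated
balance-position uncertainty (about twice the measured position noise). The
ratio was calibrated once so that the wide-range Monte Carlo study's mean
fraction of cells remaining after one optimally chosen frequency matches
the reference level of ~11%; this gives $\Delta\delta/\lambda = 0.12$,
i.e. $\lambda \approx 4.17$ µm, which is the package-wide default
(`DEFAULT_DECAY_LENGTH`). It was fixed before examining any other summary
of the study and is not tuned per quantity.

## Greedy frequency selection

For each of 100 runs, a population of 1000 cells is drawn, one reference
cell is picked at random, and frequencies are added greedily from a
100-point log-spaced candidate grid: at each step the frequency minimizing
the number of *remaining* cells is appended (ties broken toward the lowest,
experimentally cheapest frequency). A cell remains if no chosen frequency
discriminates it, and a frequency discriminates a pair of cells only if

1. both cells attain measurable balance positions there
   ($\mathrm{Re[CM]} \le -0.05$), and
2. their Re[CM] differ by more than the tolerance
   $|\mathrm{CM}_{ref}|\,\Delta\delta/\lambda$.

Condition 1 is the package's design choice where the design was genuinely
open. A tolerance rule without it concentrates all discriminating power at
the top of the grid — the tolerance shrinks with $|\mathrm{CM}|$, and
$|\mathrm{CM}|$ is smallest at GHz frequencies — even though no balance
positions can actually be observed there; with it, the optimal first
frequency in the wide range lands in the second dispersion
(tens-to-hundreds of MHz), where spectra are maximally spread while still
measurable, and in the narrow range at the top of the accessible window
(25 MHz). We also considered treating "reference balances, neighbor does
not" as a discrimination; that convention re-creates the grid-top artifact
(the unbalanced minority is small at 1 GHz) and credits discrimination to
the *absence* of a measurement, so it was rejected. Fractions are reported
over the $n-1$ non-reference cells; each run records the full chosen
sequence, and the study summarizes per-step means/medians, per-candidate
sweep curves, and the modal frequency combination.

At the defaults, one wide-range frequency leaves ~12% of cells, two ~2%,
four ~0.7%; the narrow range saturates near 4–5% after three frequencies
with 25 MHz as the modal first choice. The modal *wide-range* first
frequency is unstable by construction: the mean-fraction-vs-frequency curve
is nearly flat across the second dispersion, so the mode across 100 runs
can land anywhere in roughly 50–600 MHz depending on the seed.

## Trajectories and balance validation

The reference frequency schedule is 25 MHz for 1.3 s, 1.2 MHz for 1.8 s,
2 MHz for 0.7 s, repeated. Measured (or synthetic) trajectories are
smoothed with a trailing four-point moving average (shrinking window at the
start, preserving length and timestamps — validation operates on the
smoothed series, matching the stated processing order), segmented at the
cumulative schedule boundaries (a sample exactly on a boundary is the
closing dwell's final measurement), and validated: with $D$ the cell's mean
absolute difference between consecutive segment balance positions, a
segment is valid when every sample of its final 250 ms stays within
$0.1\,D$ of the segment's final position. $D$ is computed per cell by
default ("average difference" is read per trajectory, which is how
individual trajectories can be validated in isolation); a population-wide
scale can be supplied via `reference_scale`. The truncation analysis
rescales every dwell by a common factor and re-runs validation, reproducing
the full analysis exactly at factor 1.

Synthetic trajectories are first-order relaxations toward the
forward-model balance position of the active frequency, with additive
Gaussian observation noise (default 0.25 µm, matching the position-noise
standard deviation implied by the 0.5 µm uncertainty) sampled at 20 frames/s
— a typical rate for the camera class used in such experiments, and enough
for 5 samples per 250 ms validation window. They emulate settling dynamics
and measurement noise only: no hydrodynamic cell–cell or wall interactions,
no x-dependence of channel height, no intensity-dependent localization
error, so passing tests demonstrate the correctness of the processing
chain, not the fidelity of any real device.

## Imaging

The detection chain is deliberately minimal, mirroring common practice:
temporal-median background (≥3 frames), absolute-difference thresholding,
8-connected component labelling with a minimum blob area (default 4 px²,
suppressing single-pixel noise), intensity-unweighted centroids, and greedy
nearest-neighbor frame-to-frame linking within a maximum displacement
(cells are dilute, so global assignment is unnecessary). Threshold, minimum
area and displacement limit are configuration, as no reference values
exist. The synthetic renderer (Gaussian blobs, constant background,
Gaussian noise) closes the loop: at SNR 10 the end-to-end
render→detect→link round trip recovers trajectories with ≥95% frame
coverage and ≤0.5 px RMSE. Centroids of thresholded masks carry a small
pixel-grid bias (≲0.2 px) for blobs at fractional positions; sub-pixel PSF
fitting is out of scope.

## Discrimination

Features are the (size-corrected) Re[CM] values at the schedule
frequencies. The 0-1 loss is minimized *directly* by deterministic
exhaustive search — unit directions on a 1° grid (hemisphere; orientation
handled by the threshold sign) × all inter-point thresholds — which is
exact and reproducible at the relevant sizes ($n \approx$ hundreds,
$k \le 3$). Ties break toward the larger margin, then the earlier grid
direction. Multiclass decisions are majority votes over pairwise rules,
with vote ties resolved toward the nearest class centroid. Reported
accuracies are training accuracies ((tested − errors)/tested); no held-out
evaluation is implied. Significance is assessed by a label-permutation test
(p = (1 + #{permuted ≥ observed})/(1 + N)); because the accuracy statistic
is discrete, ties make the test conservative, never anti-conservative.

## Numerical and design notes

* Frequency grids default to 100 log-spaced points per range — enough to
  resolve both dispersions smoothly at negligible cost.
* The field normalization $p(f)$ is interpolated log-linearly in frequency
  between bead-calibrated points (electrode polarization varies smoothly on
  a log-frequency scale) and is normalized to 1 at the lowest calibrated
  frequency.
* `greedy_select` always reports a first frequency; the
  stop-on-no-improvement rule applies from the second step. The Monte Carlo
  driver always records `max_steps` selections so per-step summaries are
  complete (remaining counts are non-increasing regardless).
* Degenerate inputs are defined, not special-cased: a population of
  identical cells keeps the remaining fraction at 1; a constant trajectory
  has $D = 0$ and validates; index-matched particles have identically zero
  spectra.
* Problem sizes in the tests are chosen for seconds-scale suites: the
  quantitative Monte Carlo checks run 20–25 runs × 200–300 cells (the
  remaining *fraction* is density-driven and scale-stable); the full
  100 × 1000 study behind the headline numbers runs in a few seconds and is
  what `scripts/acceptance.R` executes.

## Known limitations

* The exponential $q_R$ is a model; the true position decay of a particular
  electrode layout differs in detail. All position-derived quantities
  (tolerance slope, measurability floor) inherit this choice, which is why
  the constant $\Delta\delta/\lambda$ is calibrated rather than derived.
* Uniform, independent parameter draws ignore biological covariation
  (e.g. radius–permittivity correlations) and multi-shell (nucleated)
  structure.
* The wide-range modal first frequency is a mode over a nearly flat
  objective and should be read as "somewhere in the second dispersion".
* Discrimination accuracies are training accuracies of an exhaustively
  optimized rule and overstate generalization for small samples — the
  permutation test, not the accuracy, carries the evidence.
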