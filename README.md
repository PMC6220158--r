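# depspring

Computational toolkit for the **multi-frequency DEP spring** — a label-free
microfluidic assay that reads a single cell's electrical phenotype from the
positions at which a negative dielectrophoretic (nDEP) force balances fluid
drag, at several drive frequencies per cell.

It is written for experimenters designing or analyzing DEP-spring
measurements and for anyone studying frequency selection for single-cell
electrical phenotyping. Everything runs on synthetic data; no instrument is
required.

## The model in brief

A cell is a single-shell dielectric sphere: cytoplasm (conductivity
σ_cyt, permittivity ε_cyt) wrapped in a 10 nm membrane (σ_mem, ε_mem),
outer radius R. Its Clausius–Mossotti factor in a medium ε*_m is

    CM(f) = (ε*_eq − ε*_m) / (ε*_eq + 2 ε*_m),
    ε*_eq = ε*_mem (g³ + 2K)/(g³ − K),  K = (ε*_cyt − ε*_mem)/(ε*_cyt + 2 ε*_mem),

with g = R/(R−10 nm) and ε* = ε − jσ/ω. Over slanted coplanar electrodes the
cell settles at a balance position

    δ = q_R⁻¹( 3η sinθ [6Q/(wh³)](h−R) g³ / (R ε_m |Re CM| V_RMS² p(f,σ_m)) ),

modelled with exponential force decay q_R(δ) = exp(−δ/λ), which gives a
closed-form inverse (position → Re[CM]), a bead-based calibration of the
field normalization p(f), and a cell-size correction. A Monte Carlo study
(100 runs × 1000 cells drawn uniformly from literature ranges) greedily
selects the measurement frequencies that minimize how many cells remain
indistinguishable from a random reference cell under the
position-uncertainty-derived CM tolerance. Downstream, trajectory
segmentation/validation, particle tracking, and an exhaustive-search
0-1-loss linear classifier complete the pipeline. See
`vignettes/multifrequency-dep-spring.Rmd` for the full account.

## Worked example

```r
library(depspring)

# Re[CM] of the mid-range cell at the three schedule frequencies
cm <- Re(cm_factor(midpoint_cell(), medium(), c(1.2e6, 2e6, 25e6)))
round(cm, 4)
#> [1] -0.4163 -0.3481 -0.2201

# forward spring model: balance positions (um) for a 5.2 um cell ...
dev <- device_state()
d <- balance_position(5.2e-6, cm, dev, c(1.2e6, 2e6, 25e6))
round(d$position_m * 1e6, 2)
#> [1] 9.13 8.38 6.47

# ... and the exact inverse back to Re[CM]
round(invert_cm(d$position_m, 5.2e-6, dev, c(1.2e6, 2e6, 25e6)), 4)
#> [1] -0.4163 -0.3481 -0.2201

# the two-range frequency-selection study (a few seconds)
study <- run_frequency_study(run_config(seed = 1))
print(study$wide)
#> Monte Carlo frequency-selection study: 100 runs x 1000 cells
#> grid: 100 points, 1e+04 Hz - 1e+09 Hz
#> mean fraction remaining by step: 11.778%, 2.201%, 0.949%, 0.684%
print(study$narrow)
#> Monte Carlo frequency-selection study: 100 runs x 1000 cells
#> grid: 100 points, 5e+05 Hz - 2.5e+07 Hz
#> mean fraction remaining by step: 13.920%, 4.525%, 4.114%
```

Reading the numbers: the three negative Re[CM] values are the cell's
electrical signature at the schedule frequencies (more negative = stronger
nDEP = farther balance position). In the wide-range study, one optimally
chosen frequency leaves ~12% of a random population indistinguishable from
a reference cell; four frequencies narrow that to ~0.7%. The narrow,
experimentally accessible range saturates near 4% after three frequencies —
less information is reachable below 25 MHz — and its modal first-choice
frequency is the top of the range.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/depspring.R simulate   --seed 1 --out out/
Rscript inst/cli/depspring.R end-to-end --seed 1 --out out/
Rscript inst/cli/depspring.R classify   --features out/features.csv --permutations 999
```

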