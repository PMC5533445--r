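# bboxnmr

Solution-NMR analysis toolkit for small zinc-binding protein domains,
built around the characterization workflow used for TRIM-family B-box2
domains: backbone dynamics from 15N relaxation, binding-surface mapping
from chemical shift perturbations, shift-based secondary-structure and
zinc-coordination inference, zinc-site restraint generation, and
precision statistics on the resulting multi-model structure ensembles.
Every input class can be simulated with known ground truth, so the whole
chain runs and is testable offline.

## Who it is for

NMR spectroscopists and structural bioinformaticians who have peak lists,
chemical-shift tables, distance-restraint files and multi-model PDB
ensembles for a small (~50-residue) domain and want a scripted,
reproducible version of the standard characterization analyses instead of
a chain of one-off web servers.

## What it computes

**Relaxation and tumbling.** Per-residue rates from monoexponential fits
I(t) = I₀·e^(−Rt) (Levenberg–Marquardt, Monte-Carlo residual-resampling
errors). Rotating-frame rates are converted to R₂ through the tilt angle
θ = arctan(B₁/Ω) of the effective spin-lock field:

    R₁ρ = R₁ cos²θ + R₂ sin²θ

The rotational correlation time τc comes from the R₂/R₁ ratio at a single
field: the isotropic rigid-rotor spectral density
J(ω) = (2/5)·S²·τc/(1+(ωτc)²) makes R₂/R₁ strictly increasing in τc, and
the estimator inverts that relation at the trimmed mean ratio of the
selected residues (closed form √(6·R₂/R₁ − 7)/(4π·ν_N) as the leading
order). The heteronuclear NOE is the saturated/reference intensity ratio.

**Shift-based inference.** Composite amide chemical shift perturbations

    Δδ_comp = sqrt(Δδ_H² + (Δδ_N / 6.5)²)

with an inclusive significance cutoff (default 0.10 ppm), titration
trajectories against the apo reference with fast-exchange monotonicity
flags, chemical-shift-index (CSI) secondary structure from secondary
shifts against a bundled random-coil table, and a logistic CA/CB-shift
score for cysteine zinc coordination.

**Restraints.** Tetrahedral zinc-site restraint generation (Zn–donor,
arm tethers, S–S and His-N–S pairs, with conventional distance bounds,
all configurable), NOE classification by sequence separation
(intra / sequential / medium 1<|i−j|<5 / long ≥5), and violation counting
against an ensemble (violated if any model exceeds a bound by more than
0.5 Å by default).

**Ensemble statistics.** Kabsch superposition, average pairwise RMSD
(backbone N/CA/C or heavy atoms), ordered-region detection by CA RMSF,
a three-state DSSP-style secondary-structure assignment from
Kabsch–Sander hydrogen-bond energies, Shrake–Rupley solvent
accessibility with relative side-chain exposure (buried < 15%), and
single-linkage clustering of perturbed sites into surface patches.

**Synthetic data.** Generators for relaxation decays, 1:1 fast-exchange
titrations (exact binding quadratic), idealized helix/hairpin/helix+tail
coordinate ensembles with planted flexibility, and structure-derived
restraint lists — all pure functions of (parameters, seed).

## Worked example

```r
library(bboxnmr)

## forward-model 15N rates for a 3.4 ns tumbler at 600 MHz
rates <- predict_rates(motion_model(tau_c = 3.4, field_1H = 600))
round(rates, 3)
#>    R1    R2   NOE
#> 2.669 6.034 0.853

## fit synthetic decays and recover the correlation time
r1 <- lapply(1:20, function(i) fit_monoexponential(
  gen_relaxation_series(rates[["R1"]], 100, default_delay_grid("r1"),
                        noise_sigma = 0, seed = i, residue_index = i),
  n_mc = 0))
r2 <- lapply(1:20, function(i) fit_monoexponential(
  gen_relaxation_series(rates[["R2"]], 100, default_delay_grid("r1rho"),
                        noise_sigma = 0, seed = i, residue_index = i),
  n_mc = 0))
estimate_tauc(r1, r2, field_1H = 600)
#> <tauc_estimate> tau_c = 3.40 ns from 16 residues
#>   (excluded: 1, 2, 19, 20) at 600 MHz
```

The printed rates are what a rigid 3.4 ns rotor relaxes at (R₁ ≈ 2.67 s⁻¹,
R₂ ≈ 6.03 s⁻¹, NOE ≈ 0.85); running them back through the fitting and
estimation chain recovers the planted τc exactly, with the 10% trimmed
mean discarding the two residues at each tail of the (here identical)
ratio distribution.

A complete end-to-end run on simulated inputs:

```r
cfg <- demo_config(tempfile(), seed = 1)
report <- run_pipeline(cfg)
report$sections$relaxation$tau_c_ns     # ~3.4
report$sections$csp$significant         # planted binding-site residues
```

A thin command-line wrapper with the same operations ships at
`inst/cli/bboxnmr` (subcommands `pipeline`, `simulate`, `csp`, `csi`,
`zinc-score`, `zinc-restraints`, `restraint-stats`, `ensemble-stats`).

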