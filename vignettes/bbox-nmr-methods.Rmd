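---
title: "Methods: NMR characterization of zinc-binding B-box domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR characterization of zinc-binding B-box domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bboxnmr)
```

This vignette is the package's account of the science it implements: the
models and procedures, the parameters that matter, the design choices
made where the design was genuinely open, and what the synthetic-data
tests do and do not demonstrate about real data.

## The analysis chain

Small zinc-binding domains such as the TRIM-family B-box2 (~45 residues,
one or two tetrahedral Zn²⁺ sites) are characterized in solution by a
standard set of NMR analyses: backbone ¹⁵N relaxation for dynamics and
oligomeric state, amide chemical shift perturbations (CSPs) for binding
surfaces, chemical-shift-based secondary structure and metal-ligation
inference, distance restraints (measured NOEs plus modeled zinc-site
geometry) for structure calculation, and precision/geometry statistics on
the resulting multi-model ensemble. `bboxnmr` implements that chain as
composable functions over five data types: peak lists, shift tables,
structure ensembles, restraint lists and titration series.

## Relaxation and the rotational correlation time

Peak intensities versus relaxation delay are fit to
$I(t) = I_0 e^{-Rt}$ by Levenberg–Marquardt least squares started from a
log-linear regression on the positive intensities. Rate uncertainties
come from Monte-Carlo residual resampling (default 200 draws under a
fixed seed): robust for short decay series, deterministic under the seed,
and free of the linearization assumptions of covariance-matrix errors.
The reduced chi-square uses the supplied spectral noise when available,
else the residual variance.

Off-resonance rotating-frame rates mix $R_1$ and $R_2$ through the tilt
angle $\theta = \arctan(B_1/\Omega)$ of the effective field
($\Omega$ = offset from the spin-lock carrier in Hz, $\theta = 90^\circ$
on resonance):
$R_{1\rho} = R_1\cos^2\theta + R_2\sin^2\theta$. The package inverts this
exactly and propagates the two rate errors in quadrature; resonances with
$\sin^2\theta \le 10^{-6}$ are rejected as too far off-lock to carry
$R_2$ information.

The correlation time is estimated from $R_2/R_1$ at a single field. For
an isotropic rigid rotor with spectral density
$J(\omega) = \tfrac{2}{5}\,S^2\,\tau_c/(1+(\omega\tau_c)^2)$ the ratio is
strictly increasing in $\tau_c$ (verified on a 50-point grid over
0.5–20 ns), so inversion is well posed. Two routes are provided:

* `method = "closed_form"`: the leading-order formula
  $\tau_c \approx \sqrt{6\,\bar\rho - 7}\,/\,(4\pi\nu_N)$, where
  $\bar\rho$ is the trimmed mean ratio and $\nu_N$ the ¹⁵N Larmor
  frequency. Accurate to ~1% above ~3 ns at 600 MHz but biased low for
  fast tumblers (−17% at 1 ns).
* `method = "exact"` (default): numerical inversion of the full
  dipolar + CSA forward model at $\bar\rho$, using the closed form as
  the starting bracket. This keeps the estimator/forward-model round
  trip within 5% across 1–8 ns, which the closed form alone does not.

Exchange-broadened residues (elevated $R_2$) and flexible ones (depressed
ratio) are excluded by a 10% trimmed mean rather than a heteronuclear-NOE
cutoff: trimming is self-contained and needs no extra experiment. A
trimmed mean ratio at or below 7/6 (the formula's root) reports
$\tau_c = 0$ with a warning rather than a complex number.

Forward-model constants: $r_{NH} = 1.02$ Å, $\Delta\sigma_N = -160$ ppm,
$S^2 = 1$. These are conventional values; they cancel to first order in
the $R_2/R_1$ ratio, so the τc estimate is insensitive to their exact
choice.

## Chemical shift perturbations and titrations

The composite amide CSP is
$\Delta\delta_{comp} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_N/6.5)^2}$,
the conventional combination that compresses the ~6.5× wider ¹⁵N scale
onto the ¹H scale. The significance cutoff (default 0.10 ppm) is applied
*inclusively*: a site exactly at the cutoff counts as affected, the
conservative reading when perturbed-residue lists are quoted at the
cutoff level. Side-chain amides (e.g. a Trp indole NE1–HE1) are tracked
as separate sites with the same formula, since they can report binding
independently of the backbone amide of the same residue.

Titration trajectories are CSPs of every point against the apo
reference. Under fast exchange on a 1:1 isotherm the trajectory of every
site is non-decreasing in titrant equivalents; the package flags sites
whose CSP drops by more than a configurable noise floor between
consecutive points as non-monotone (noise, or a process the 1:1
fast-exchange picture does not capture). Kd fitting is deliberately out
of scope.

## Shift-based secondary structure and zinc ligation

CSI classification works on secondary shifts (observed minus random
coil). Thresholds follow classical CSI practice: CA ±0.7 ppm (downfield =
helix), CB +0.7 ppm (strand only — CB is not a helix reporter), HA
±0.1 ppm (upfield = helix). A residue's raw index is the majority vote of
its available atoms, and an element is called only for runs of ≥ 4
consecutive residues with the same non-coil index. The random-coil
reference is a bundled neighbor-uncorrected table (plain TSV, swappable
by path); neighbor corrections shift individual values by tenths of a
ppm, below the ±0.7 ppm thresholds that drive the calls. Because only
differences enter, the classification is invariant to any referencing
offset applied equally to both tables.

Cysteine zinc-ligation scoring uses the diagnostic CA/CB shift signature
of metal-bound thiolates. The score is a logistic function of the signed
distance from the perpendicular bisector between two reference centroids
in (CA, CB) space — free-reduced (59.0, 28.0) ppm and metal-bound
(58.5, 31.5) ppm, steepness 1.5 ppm⁻¹, all configurable. It is 0.5 on the
bisector and monotone along the centroid axis. This is a *screening
surrogate*, documented as such: it reproduces the qualitative ordering of
ligation candidates, not the calibrated posterior probabilities printed
by dedicated predictors, and its defaults make no claim to match any
published probability values.

## Zinc-site restraints

Tetrahedral coordination is encoded purely as heavy-atom distance
bounds — no pseudo-atom placement or software-specific linker mechanics —
so the emitted list is usable by any structure-calculation engine that
can resolve a zinc pseudo-residue "ZN". Per site the default scheme
emits: Zn–donor for every ligand (Zn–SG 2.25–2.40 Å, Zn–NE2 1.95–2.10 Å,
Zn–OD 1.90–2.05 Å), an arm tether per Cys and Asp keeping the ligand
oriented (Zn–CB / Zn–CG, 3.00–3.40 Å — the literal SG(i)–CB(i) pair is a
covalent bond and cannot carry those bounds, so the tether is anchored at
the zinc), all Cys SG–SG pairs (3.55–3.95 Å, the tetrahedral S···S
separation), and every His-donor–Cys-SG pair (3.40–3.80 Å). A
3-Cys + 1-His site therefore yields 13 restraints and a
1-Cys + 1-Asp + 2-His site 8. His coordination defaults to NE2 with ND1
selectable per ligand. All bounds are configuration.

NOE accounting bins by sequence separation $s = |i-j|$: intra ($s=0$),
sequential ($s=1$), medium (1 < s < 5), long ($s \ge 5$). Violation
counting takes the strictest convention: a restraint is violated if *any*
model exceeds a bound by more than the threshold (default 0.5 Å), counted
per restraint with the maximal excess reported.

## Ensemble statistics

Superposition is the standard SVD (Kabsch) construction with the
determinant guard against reflections. Pairwise RMSD statistics use
backbone = {N, CA, C} (the common ensemble-statistics convention; O is
excluded) or all heavy atoms. Ordered regions are residues whose CA RMSF
about the ensemble mean — after superposing all models to model 1 on all
CA atoms — falls below 1.0 Å. This deliberately simple criterion is not
the dihedral-order-parameter algorithm used by some validation suites, so
agreement with published ordered ranges is asserted only as overlap, not
identity; the global fit is also degraded when a long disordered tail
dominates the selection, which the tests acknowledge.

Secondary structure is a three-state DSSP: Kabsch–Sander hydrogen-bond
energy $E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol, bond if $E < -0.5$; helices from two consecutive i→i+4 turns;
strands from parallel/antiparallel bridge pairs; 3₁₀/π helices and bends
collapse into H/E/C. Amide protons absent from the file are rebuilt at
1.01 Å along the bisector of the C(i−1)→N and CA→N directions; prolines
and chain starts donate no bonds. An isolated extended strand has no
ladder partner and is correctly coil.

Accessibility is Shrake–Rupley quadrature on a deterministic
golden-spiral point set (960 points/atom; the isolated-atom error is
below 0.5%), heavy atoms only, probe 1.4 Å, Bondi-style radii. Relative
side-chain exposure divides the side-chain SASA by an extended-context
reference per residue type; side chains under 15% are buried. The
reference is a bundled table of standard extended Gly-X-Gly values rather
than one computed on the fly: computing it internally would require an
all-atom side-chain builder, a rotamer problem well outside this
package's scope, and the bundled table is swappable for any
self-consistent alternative.

Perturbed-site patches are single-linkage clusters (connected components
at an 8 Å cutoff) on the minimum heavy-atom distance between residues
averaged over models — averaging stabilizes the patch membership against
per-model jitter that per-model clustering would amplify.

## The synthetic-data generators

The generators emulate the study conditions of the workflow: relaxation
decays on the measured delay schedules (19 delays 10–646 ms for R₁, 18
delays 6–100 ms for R₁ρ) with Gaussian intensity noise; titrations at
0, 0.25, 0.5, 1.0, 2.0 equivalents with 200 µM protein under fast
exchange, using the exact 1:1 binding quadratic
$f = \big((P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}\big)/(2P)$;
idealized backbones from canonical dihedrals (helix −57/−47; antiparallel
hairpin −139/135 with a type II′ turn) with per-model Gaussian coordinate
jitter and a planted flexible tail; and restraints read off a structure's
own contacts. Every generator is a pure function of (parameters, seed)
and restores the caller's RNG state.

What passing tests show: the estimators invert their own forward models
at stated tolerances, the parsers round-trip, the geometry code matches
closed forms and brute-force oracles, and the pipeline is bit-for-bit
reproducible. What they do not show: behavior under real spectral
artifacts (overlap, lineshape distortion, intermediate exchange), real
side-chain packing (the toy ensembles are backbone + CB), or anisotropic
tumbling — the rigid-rotor model is isotropic by construction, and τc
estimates on anisotropic or exchange-affected systems inherit the usual
caveats of single-field R₂/R₁ analysis.

## Numerical choices and degenerate inputs

* Monoexponential fits require ≥ 3 distinct delays and at least one
  positive intensity; an exact interpolating start (constant or
  noiseless data) is returned directly rather than passed to the
  optimizer.
* Problem sizes in the test suite (ensembles of 3–10 models, 6–40
  residues; 300–400 noise realizations for bias checks) keep the full
  suite under a minute while leaving Monte-Carlo standard errors well
  below the asserted tolerances.
* Restraint output is canonically ordered (res_i, atom_i, res_j, atom_j)
  with fixed two-decimal formatting, so writing is deterministic and
  read∘write is bit-exact.
* Ties in the trimmed mean are resolved by stable ordering; with
  identical ratios the trim discards the first and last residues by
  index, which is irrelevant to the estimate.
* Single-linkage patch clustering on an empty site set returns an empty
  patch list; unresolvable sites and restraint atoms are dropped with
  warnings, never silently.

## Known limitations

Model-free (Lipari–Szabo) per-residue analysis, CPMG dispersion,
anisotropic diffusion tensors, Kd fitting from CSP curves, dihedral
restraint prediction, and structure calculation itself are out of scope.
The zinc-ligation scorer is a surrogate, not a calibrated predictor. The
DSSP implementation collapses helix subtypes and does not report turns or
bends. The ordered-region criterion is RMSF-based and threshold-dependent.
Full NMR-STAR is not parsed — only the assigned-shift and
distance-restraint loops needed here.
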