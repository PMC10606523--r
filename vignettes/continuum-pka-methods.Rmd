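---
title: "Continuum-electrostatics pKa calculations for membrane proteins"
author: "ContinuumPKa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum-electrostatics pKa calculations for membrane proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ContinuumPKa)
```

## The model

The protonation state of an ionizable residue in a protein differs from that
of the free amino acid in water because the protein changes the
electrostatics of charging the group. ContinuumPKa computes that change with
a semi-continuum dielectric model. The pKa of a site is assembled from three
energy components, each obtained from a finite-difference solution of the
linearized Poisson–Boltzmann equation (LPBE)

$$\nabla\cdot\left(\varepsilon(\mathbf r)\,\nabla\phi(\mathbf r)\right)
  - \varepsilon_w \kappa^2(\mathbf r)\,\phi(\mathbf r) = -4\pi C\rho(\mathbf r),$$

with $C = 332.0636$ kcal Å/(mol e²), $\kappa^2$ proportional to the ionic
strength and nonzero only in solvent:

1. **Dielectric response (Born-type) shift.** Each protonation form of the
   site is transferred between a model-compound environment (the residue's
   own cavity in water) and the protein/membrane environment, at identical
   grid placement so the grid self-energy cancels exactly. The pKa shift is
   the difference of the two transfer energies divided by
   $2.303\,RT = 1.364$ kcal/mol. Burying an acid raises its pKa and burying
   a base lowers it; the sign emerges from the thermodynamic cycle computed
   on both protonation forms rather than from a per-class flag.
2. **Background-field shift.** The potential of all permanent partial
   charges (excluding the variable-charge atoms of every titratable site) is
   evaluated against the site's protonation charge difference. The
   model-compound background (the residue's own backbone in water) is
   subtracted, so a fully exposed residue recovers its model pKa.
3. **Site–site interactions.** W[i, j] is the screened interaction of the
   two sites' protonation charge differences in pKa units, used in the
   multi-site titration below. W is symmetrized as (W + Wᵀ)/2; the
   residual asymmetry (a discretization diagnostic) is bounded at 1%.

### The heterogeneous dielectric

Instead of a single protein dielectric constant, the protein interior is
partitioned into four layers of static permittivity 3, 5, 10 and 20. A
voxel inside the solvent-excluded surface (probe radius 1.4 Å) is assigned
the local density of polar side-chain atoms — side-chain oxygens and
nitrogens within a hard 5 Å kernel, divided by the kernel volume — and a
monotone piecewise-linear curve maps that density to a permittivity, which
is then quantized to the nearest of the four levels (ties break upward,
conservatively toward higher screening). The published curve relating polar
density to permittivity is not reproducible from its description, so the
mapping is pluggable; the default breakpoints (0→3, 0.004→5, 0.008→10,
0.015 atoms/Å³→20) place apolar helix cores in the lowest layer and densely
polar loop neighbourhoods in the highest. The four-level quantization, not
the exact curve, carries the model.

The membrane is an implicit slab normal to z: an acyl core (ε = 2.0 by
default, 2.5 for sensitivity checks) flanked by 8 Å headgroup bands
(ε = 20, or 40 — the glycerol-like value) on each leaflet. Protein voxels
take precedence over the slab; membrane voxels carry no mobile ions. The
solvent is ε = 81 with a default ionic strength of 0.2 M and a 2 Å Stern
(ion-exclusion) shell beyond the atom radii.

### The solver

The LPBE is discretized on a node-centred cubic grid with a 7-point stencil
and harmonic-mean face permittivities; charges are spread trilinearly to the
8 surrounding nodes and potentials are read back with the same trilinear
weights. Boundary conditions are Dirichlet values from a Debye-screened
monopole sum over the source charges. The linear system is solved by
red–black SOR (relaxation factor 2/(1 + sin(π/max dims)), relative residual
tolerance 1e-6); non-convergence is an error carrying the residual history,
never a silent result. Production accuracy comes from two-level focusing: a
coarse solve over the whole box (default 1.0 Å spacing, 10–17 Å margins)
supplies the boundary for a fine solve (default 0.5 Å, down to 0.25 Å in
the validation oracles) on a sub-box around the site. On these settings the
solver reproduces the analytic Born transfer energy of a 2 Å unit-charge
sphere between ε = 81 and ε = 4 exteriors within 3%, point-charge
interactions within 2% at ≥4 grid spacings, and the Debye–Hückel screened
form within a few percent.

### Charges and radii

Atom parameters come from a YAML table shipped with the package: a
solvation-style set with charges concentrated on polar and ionizable groups,
apolar carbons neutral, and Pauling van der Waals radii by element (H 1.0,
C 1.7, N 1.5, O 1.4, S 1.85 Å). Every residue variant sums exactly to its
integer formal charge, and each titratable residue (Asp, Glu, Tyr, Cys,
Lys, Arg, His, plus N-/C-termini) carries protonated and deprotonated charge
maps differing by exactly +1 e. Model pKa values follow standard
continuum-pKa conventions: Asp 4.0, Glu 4.4, Tyr 9.6, Cys 8.3, His 6.3,
Lys 10.4, Arg 12.0, N-ter 7.5, C-ter 3.8; all are configurable by editing
the table. Charges of hydrogens absent from the coordinates are collapsed
onto their parent heavy atoms, so heavy-atom-only structures keep exact
formal charges. The table is the package's own set in the tradition of
solvation-calibrated parameterizations; any published set in the same layout
can be swapped in.

## Multi-site titration

With intrinsic pKas and W in hand, the protonation microstates follow the
standard multi-site formalism. In pH units (energy / 2.303 kT):

$$E(\mathbf x, \mathrm{pH}) = \sum_i x_i\,(\mathrm{pH} - \mathrm{p}K_{a,i}^{\rm intr})
 + \tfrac12 \sum_{i\neq j} W_{ij}\,\delta q_i\,\delta q_j,$$

where $x_i \in \{0,1\}$ is protonation and $\delta q_i = x_i - x_i^{\rm ref}$
is the charge deviation from the charged reference state (acids
deprotonated, bases protonated) — consistent with W computed from
charge-difference distributions. Two samplers share this energy:

- `titrateExact()` enumerates all $2^N$ states (N ≤ 20) and returns exact
  Boltzmann-normalized protonation fractions. It is the oracle against
  which the Monte Carlo sampler is validated.
- `titrateMC()` runs Metropolis sampling with single-site flips plus joint
  flips for strongly coupled pairs (|W| > 2 pKa units), 1000 burn-in and
  50000 production scans per pH over 10 batches; the batch-mean standard
  error is reported per site and pH. The schedule was sized on toy systems
  so that MC-derived pKas sit within 0.003 pH units of exact enumeration
  and fractions within 0.01 — near the half-protonation point the
  Metropolis chain mixes very efficiently (flip moves are accepted with
  probability near 1), so errors are smallest exactly where the pKa is
  read off. A shorter schedule (a few thousand scans) does not reliably
  meet the 0.003 bound, which is why the default is 50000.

pKa values are read off the titration curve at the half-protonation point
("graphical assessment"): linear interpolation of the 0.5 crossing between
adjacent grid points of the default 0.0–14.0, step 0.2 pH grid. With
multiple crossings (possible for strongly coupled sites) the crossing
nearest the site's intrinsic pKa is chosen and flagged. On exactly
enumerated curves of 1–5-site toy models this extraction deviates from a
0.001-pH reference grid by well under 0.03 pH units
(`graphicalPkaError()`, recomputed by `scripts/acceptance.R`).

## Ensemble uncertainty

Structural fluctuation dominates the uncertainty of continuum pKa values.
`perFrameComponents()` evaluates the Born and background shifts per
trajectory snapshot, plus pair interaction terms restricted to strongly
interacting pairs (|W| ≥ 0.5 pKa units — weaker couplings are tracked in
the ledgers but excluded from the fluctuation total; the full W is always
used in the titration energy model itself, since the threshold belongs to
the error analysis, not the statistical mechanics). `fluctuationSd()`
reports the sample SD of the per-frame total per site and the median SD
over a chosen site subset. `averagedPka()` titrates the time-averaged
components and attaches SD/√N_eff as the uncertainty, with N_eff the
lag-1-autocorrelation-corrected frame count; averaging per-frame pKas
instead is available via `order = "pka"` and agrees within the reported
uncertainty for weakly coupled systems. Averaging components before
titrating is the default because titration is nonlinear and the slow
variable is the electrostatic environment, not the curve.

## Synthetic fixtures and what passing tests mean

Every pipeline stage is testable without external data:

- `makeBornSphere()` / `makeChargePair()` carry closed-form Born and
  Coulomb energies — the solver oracles.
- `makeHelixInSlab()` builds ideal α-helices (1.5 Å rise, 100° twist,
  canonical radial side-chain offsets) with chosen titratable residues,
  optionally centred in a membrane slab; two phased helices reproduce the
  facing-glutamate geometry of paired transmembrane helix tips (~6–7 Å).
- `makePseudoTrajectory()` adds seeded iid Gaussian jitter per atom. This
  emulates positional fluctuation amplitudes, not dynamics: bonds are not
  preserved, displacements are uncorrelated in time and across atoms. It
  exercises the ensemble statistics (SDs grow monotonically with jitter,
  parameter recovery within uncertainty) but says nothing about
  force-field realism.
- `makeToyCds()` / `syntheticPsbsCds()` build coding sequences with exact
  residue compositions. The PsbS-like fixture (756 nt → 251-residue
  precursor → 41-residue transit peptide → 210-residue mature chain with
  9 Arg, 12 Lys, 4 Tyr, 10 Glu, 7 Asp and no His/Cys) is a synthetic
  stand-in: the census code computes everything from the sequence, while
  the composition itself is the generator's input.

Passing these tests demonstrates that the electrostatics, the statistical
mechanics, and the bookkeeping are correct at the stated tolerances. It
does not validate predictions on real membrane-protein structures, which
depend on equilibrated coordinates, hydrogen-bond geometry and conformational
sampling outside this package's scope (it consumes structure frames; it
does not generate them).

## Numerical choices and degenerate inputs

- Problem sizes in the test-suite and validation runs are deliberately
  modest: 8–20-residue helices, coarse 1.0–1.2 Å / fine 0.5–0.6 Å grids,
  ensembles of 3–6 frames, titration toys of 1–15 sites. The package's
  accuracy-critical claims are checked at the finer oracle settings
  (0.25 Å focused Born; 50000-scan MC).
- Alternate locations keep the highest occupancy; missing occupancy keeps
  the first encountered copy.
- Unknown residues or atom names abort parameterization with a list of
  offenders — never a silent zero charge.
- Empty polar neighbourhoods give density 0 (lowest layer), an empty
  charge set gives zero energy, a curve that never crosses 0.5 raises an
  error pointing at the pH grid, and `titrateExact()` refuses more than 20
  sites, directing to the MC sampler.
- The per-residue formal-charge audit (1e-6 e) runs on every
  parameterization; site charge maps are validated at construction
  (protonated − deprotonated = +1 e exactly).

## Known limitations

- The LPBE is linear; nonlinear salt response is out of scope.
- The solvent-excluded surface is voxelized (probe dilation/erosion at grid
  resolution), so layer boundaries carry O(h) placement error; the Born
  oracle bounds the resulting energy error at the production spacings.
- The dielectric layering quantizes to four levels by design; continuous
  permittivity fields are not supported.
- Conformational relaxation between protonation states, tautomer-resolved
  microstates and proton-binding kinetics are not modelled.
- The single-Tyr site-selection policy of lumen-exposed tyrosines is
  expressed as an explicit whitelist; the package does not guess which
  tyrosines are functionally titratable.

## A worked example

```{r example, eval = FALSE}
slab <- membraneSlab(coreZmin = -9, coreZmax = 9, headThickness = 6,
                     epsCore = 2.0, epsHead = 20)
helix <- makeHelixInSlab(placements = data.frame(type = c("GLU", "LYS"),
                                                 position = c(5, 12)),
                         nRes = 16)
cfg <- pkaConfig(solver = solverSettings(ionicStrength = 0.1))
res <- runPipeline(helix, cfg, outDir = "run1")
ledgerTable(res$ledger)
pkaHalf(res$titration)
```

The README shows the numbers this prints and how to reproduce the
acceptance quantities with `scripts/acceptance.R`.
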