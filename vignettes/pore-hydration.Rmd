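---
title: "Annotating channel conductive state from pore hydration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating channel conductive state from pore hydration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydropore)
```

## The problem

A growing number of ion-channel structures are solved in states whose
functional meaning is unclear. The traditional annotation route — compute a
pore radius profile and compare the narrowest constriction with the radius
of a hydrated ion — fails for *hydrophobic gates*: a pore segment lined by
apolar side chains can expel liquid water ("de-wetting", a vapor lock) even
when it is sterically wide enough for an ion, and such a pore conducts
neither water nor ions. Bestrophin chloride channels are a case in point:
the narrow neck of the pentameric BEST1 pore is lined by three rings of
conserved hydrophobic residues (I76, F80, F84), and widening that neck by a
triple-alanine mutation converts the channel to a constitutively open
state. Whether a given structure is conductive is therefore better judged
from the *behaviour of water in the pore* than from geometry alone.

`hydropore` implements that simulation-based annotation pipeline for
equilibrium water trajectories around a fixed channel structure:

1. a probe-sphere (HOLE-style) pore radius profile `r(z)`;
2. a time-resolved, bulk-normalized axial water density `n(z, t)/n_bulk`;
3. Boltzmann inversion of the time-averaged density into a free-energy
   profile `E(z)`;
4. an open/closed verdict combining the free-energy barrier with the
   de-wetted fraction of frames;
5. independently, reconstruction of a 1-D ion potential of mean force from
   harmonic umbrella-sampling windows via WHAM, with Bayesian-bootstrap
   error bands and a time-fraction convergence check.

Running molecular dynamics itself is out of scope: the package consumes
structures (PDB) and water/ion coordinate time series produced elsewhere.

## Model and conventions

**Units.** Coordinates are Angstrom everywhere (GRO input in nm is
converted on read); times are ns; energies are kJ/mol; temperatures Kelvin.
`k_B = 0.0083144621` kJ/mol/K, so `kT` at the default 310 K is 2.577
kJ/mol — the yardstick against which pore barriers are judged.

**Pore radius.** At a point `p`, the probe radius is
`min_i (|p - x_i| - R_i)` over atoms `i` with hard-sphere radii `R_i`. The
profile maximizes this quantity over the `(x, y)` plane at each `z` by
simulated-annealing Monte Carlo, seeding each slice from the previous
optimum and constraining the centre to move at most 2 A between adjacent
slices, which keeps the centre path continuous through degenerate
(symmetric) slices. The default schedule — displacement scale 1.0 A cooled
by 0.9 over 30 stages of 50 moves — was chosen to converge on fixtures
where an exhaustive 0.05 A grid search of the slice plane is affordable;
the package ships that grid search (`find_pore_profile_grid`) precisely so
the stochastic search can always be validated against a deterministic
optimum. Default hard-sphere radii are the simple element-based set C 1.85,
N 1.75, O 1.65, S 2.00, H 1.00, P 2.10 A with a 2.0 A fallback; structural
models do not record them, so the whole table is user-overridable.

**Density.** Waters are represented by their oxygen atom: the density
observable counts molecules and oxygen tracks the molecular centre well. A
water at axial position `z` counts toward bin `z` iff its radial distance
from the pore centre path is at most `r(z)` (or a fixed cylinder radius;
the counting region is user-selectable because either convention is
defensible). Counts are divided by the slab volume `pi r(z)^2 * dz` and by
the bulk density, so unconfined water sits at 1. Per-frame densities are
computed first and then averaged — the time-resolved map and its average
are consistent by construction, and no temporal smoothing is applied (that
is a plotting decision, not an analysis one). The default bulk density
0.0334 molecules/A^3 (pure water near 310 K) applies only when no bulk
region is supplied for estimation, and is always logged. Default bin width
is 1 A, matching the 1 A umbrella-window spacing so the two kinds of
profile stay comparable.

**Boltzmann inversion.** At equilibrium `n(z) = C exp(-E(z)/kT)`, so
`E(z) = -kT ln n(z) + kT ln C`. The constant is anchored by setting the
free energy of bulk water to zero: `C` is the mean time-averaged normalized
density over user-designated bulk bins (mean-of-bins rather than per-bin
zeroing, for minimal variance). Bins with *zero* observed density over all
frames have no finite inversion — their free energy is only bounded below.
We cap them at `E_cap = -kT ln(1/(F + 1)) + kT ln(n_bulk_bins)` (`F` =
frames used, i.e. one pseudo-count), set a `censored` flag, and report
barriers through such bins as lower bounds. This makes explicit an
assumption that any finite plotted barrier over a de-wetted region must
make somewhere; more frames can only raise the cap.

**Verdict.** A region is called `closed` when its barrier reaches
`2 kT` (about 5.2 kJ/mol at 310 K) *or* the fraction of frames with zero
water in the region reaches 0.5; `open` when both signals are below
threshold; `indeterminate` when they disagree and the deciding quantity
lies within 10% of its threshold. Neither threshold is canonical — they are
exposed configuration with defaults chosen so that a barrier of 10–15
kJ/mol (several kT, the scale reported for hydrophobically gated necks)
classifies closed and a flat profile classifies open. The barrier signal
and the de-wetting signal are deliberately kept separate in the report so
a user can see *why* a call was made.

**WHAM.** Umbrella windows are harmonic biases
`w_i(z) = k_i (z - c_i)^2 / 2`; force constants are accepted in the MD
convention kJ/mol/nm^2 and converted by 0.01 to kJ/mol/A^2. The standard
self-consistent equations are iterated to a tolerance of 1e-6 kJ/mol on
the window free energies (cap 1e5 iterations) — tight enough that
bootstrap noise dominates the remaining solver error. The PMF bin width
defaults to 0.2 A, finer than the 1 A window spacing, because each window
samples its neighbourhood densely. Two numerical choices deserve note:

* *Binning support.* By default the PMF is reconstructed over the span of
  the restraint centres, not the full sample range. Bins beyond the
  outermost windows contain a handful of Gaussian-tail samples weighted by
  an exponentially exploding unbiasing factor; their free energies are
  pure noise and, because the PMF is aligned to minimum 0, a single such
  bin can shift the entire curve. A single window (the unbiased-histogram
  limit) has no span and falls back to the sample range.
* *Error bands.* The Bayesian bootstrap draws Dirichlet(1, ..., 1) weights
  over every window's samples (per-sample weighting — the replicate unit
  is the sample, a choice the output documents), re-solves WHAM, aligns
  each replicate to minimum 0, and reports the per-bin standard deviation.
  Replicates share the full-data binning; 20% replicate failures abort.

Convergence is assessed by splitting each window's time series into
consecutive equal blocks, solving each block on a shared binning, and
reporting the maximum discrepancy between consecutive block PMFs over the
restrained span (each re-aligned to minimum 0 there). Blocks in which some
window is empty are flagged rather than fatal.

**Expected statistical scale of a WHAM PMF.** With independent samples the
window free energies perform a random walk along the window ladder: each
window's mean position carries standard error `sigma/sqrt(n)`, which tilts
the local reconstruction by `k * sigma/sqrt(n)` per window step. Under the
standard layout (36 windows, 1 A spacing, k = 1000 kJ/mol/nm^2, so
`sigma = sqrt(kT/k) = 0.51` A) at 5000 samples per window this integrates
to a min-to-max spread of roughly 1 kJ/mol for a flat true potential,
shrinking as `1/sqrt(n)`. This is a property of the data, not the solver —
an independent re-implementation of WHAM reproduces the package's output
on identical windows to seven decimals — and it sets the floor on how flat
a recovered null profile can be expected to be.

## What the synthetic generators emulate

The `synthetic` module generates every fixture the tests use:

* `make_pore_structure` builds pseudo-atom walls (cylinder or hourglass)
  on rings about the z-axis, with lattice spacing no larger than the atom
  radius so a probe cannot leak between wall atoms. Geometry is known
  exactly, so probe-search results have closed-form oracles.
* `sample_water_trajectory` draws frames as an inhomogeneous Poisson
  process with intensity `n_bulk * exp(-E*(z)/kT) * area(z)`, uniform over
  the cross-section. This is *ideal-gas* sampling: no excluded volume, no
  frame-to-frame correlation. That is legitimate for testing because the
  analysis asserts only the Boltzmann relation between mean density and
  free energy, which ideal sampling satisfies exactly — but it means
  passing tests say nothing about correlated-frame statistics, water
  structure, or finite-size effects in real MD, where effective sample
  sizes are smaller than frame counts.
* `sample_umbrella_windows` draws from the exact biased density by
  inverse-CDF lookup on a 0.01 A grid with an edge-anchored CDF, keeping
  discretization bias (including any systematic sample shift, to which
  WHAM is very sensitive) far below sampling noise.

All generators are deterministic given a seed. Default study conditions
mirror the analysis conventions: 310 K, bulk density 0.0334 /A^3, 36
windows at 1 A spacing with k = 1000 kJ/mol/nm^2.

## Problem sizes used by the tests

The shipped tests validate parameter recovery at sizes a laptop handles in
seconds to a minute: water-density recovery uses 500–2000 frames in a 5 A
cylinder (a 12 kJ/mol Gaussian barrier is then recovered within 1 kJ/mol
per bin); the probe-search oracle comparison runs a 0.05 A exhaustive grid
over a ~800-atom cylinder; WHAM recovery uses the standard 36-window
layout at 2000–5000 samples per window. Headline barriers from real
membrane-protein simulations (a 10–15 kJ/mol water barrier in a closed
neck; a ~100 kJ/mol chloride PMF) require tens of nanoseconds of MD on a
full protein–bilayer system and are inputs this package analyzes, not
quantities it can regenerate.

## Degenerate inputs and tie-breaking

Symmetric pores have degenerate slice optima; the seeded,
continuity-constrained search picks one deterministically per seed, which
is acceptable because `r(z)`, not the centre, is the scientific output.
Slices where no positive probe radius exists are recorded as radius 0 with
a `blocked` flag rather than an error. Zero-area bins are flagged
undefined rather than divided by. Windows without pairwise histogram
overlap yield a PMF flagged `converged = FALSE` with a warning.

## Known limitations

* The probe search assumes the pore axis is (or has been aligned to) z;
  `align_principal_axis` offers a crude principal-axes alignment, but
  curved or branched permeation pathways are not modelled.
* The de-wetting verdict depends on user-chosen region bounds (the paper
  analogue: neck and aperture z-ranges) — these are scientific inputs, not
  derivable from the trajectory.
* Equilibrium water density cannot resolve ion energetics at physiological
  ion concentrations; ion PMFs must come from the umbrella-sampling route.
* Bootstrap error bands assume independent samples; with correlated MD
  data they understate the true uncertainty by roughly the square root of
  the statistical inefficiency.
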