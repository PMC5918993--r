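---
title: "Methods: superposition metrics, interface complementarity and collective motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: superposition metrics, interface complementarity and collective motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajkit)
```

trajkit analyses molecular-dynamics trajectories of multi-domain proteins
and their complexes: how flexible each domain is, how complementary a
domain-domain or protein-protein interface is, how helix pairs that frame a
binding site open and close, which conformational substates a region
visits, and which few collective modes carry the global motion. This
vignette documents the models behind each stage, the tunable parameters and
their defaults, the synthetic ground-truth generator used for validation,
and the numerical and design choices a maintainer should know about.

## Containers and conventions

A `md_structure` is an atom table (serial, name, element, residue, chain,
mass in Da, van der Waals radius in Å) plus one `N × 3` coordinate matrix;
a `md_trajectory` stacks frames over one shared atom table. All coordinates
are Å; no unit conversion happens anywhere. PDB input and output (including
multi-MODEL trajectories) go through bio3d; on reading, masses and radii
are assigned from an element-keyed table (Bondi radii for the common
biomolecular elements) with per-atom-name overrides available, alternate
locations are reduced to the highest-occupancy conformer (ties keep the
first encountered), and author residue numbering is kept as-is. Selections
are conjunctions of predicates (`"chain A and resid 408-420 and name CA"`)
resolved to strictly increasing atom indices.

`discard_equilibration()` implements the standard convention of analysing
only the production tail of a trajectory — e.g. dropping 400 of 1500
frames mirrors discarding a 400 ns equilibration from a 1.5 µs run and
analysing the remaining 1.1 µs.

## Superposition metrics

Superposition uses the Kabsch algorithm with optional mass weighting; the
determinant correction is always applied, so an improper rotation
(reflection) can never be returned. Fits with fewer than three atoms or a
(near-)collinear atom set are rejected as underdetermined. The test suite
checks the optimum against a brute-force oracle: a coarse Euler-angle grid
followed by Nelder–Mead refinement, agreeing with Kabsch to better than
10⁻³ Å on randomized small instances.

The *average structure* is computed iteratively — superpose every frame on
the current average, recompute the mean, repeat — until the mean per-atom
shift falls below `tol` (default 10⁻⁴ Å, at most 100 iterations; these are
conventional values, as the procedure typically converges in a handful of
iterations). RMSD series fit each frame on one selection and measure on
another (needed, for instance, to measure ligand rattling after fitting on
the receptor); histograms default to 0.1 Å bins and are density-normalized.
RMSF is measured about the converged average after per-frame fitting; the
fit and measure selections are again independent, because fitting on a
noisy region partially absorbs its own fluctuation: with 3N coordinate
degrees of freedom, a rigid-body fit removes 6, so profiles measured on
very small atom sets under-estimate σ√3 noticeably while ~60 atoms
recover it to ~2%. Residue aggregation is the root mean square over the
residue's selected atoms.

Two per-residue difference maps compare systems: the displacement map
(RMS distance between average structures after superposition on a chosen
fit region; reported with a 0→4 Å display scale) and the ΔRMSF map
(fluctuation of system B minus system A; −1.2→+1.2 Å display scale).

## Interface complementarity

The solvent-accessible surface area uses deterministic Shrake–Rupley
sampling: a Fibonacci lattice of `sample_points` (default 960) on each
probe-inflated sphere, occluded by the other selected atoms. The probe
radius defaults to 1.4 Å (water). Hydrogens are excluded by default, the
convention of united-style radii sets; `include_h = TRUE` restores them.
Single-sphere and two-sphere configurations reproduce the closed-form
areas to within 1% at the default point count.

The buried area on complex formation is
ΔASA = (ASA_A + ASA_B − ASA_AB) / 2, with the monomer terms computed on
each part in the conformation it has inside the complex (a rigid-body
definition; no relaxation).

The gap volume is the volume of the empty region enclosed between the two
parts. The implementation is a reproducible variant of the classic
sphere-packing procedure: for every facing atom pair (one atom per part) a
gap sphere is seeded midway between the two van der Waals surfaces and
shrunk to the largest radius that penetrates no atom; spheres with radius
in `[min_gap_sphere, max_gap_sphere]` (defaults 1.0 and 5.0 Å — smaller
ones trace thin creases, larger ones bulk solvent) are kept, and the
volume of their union is integrated on a deterministic cubic grid
(`grid_spacing`, default 0.75 Å). This is documented as this package's
own operational definition, not a bit-level replica of any prior program;
a Monte-Carlo point-classification oracle over the identical geometric
region agrees with the grid to within 5%, and halving the grid spacing
moves slab-interface results by under 2%.

The gap index is gap volume / ΔASA (units Å). Low values mean tight,
complementary interfaces; typical protein–protein values run about 1–5,
with obligate interfaces at the low end. When ΔASA falls below
`min_delta_asa` (default 1 Å²) the ratio is reported as an explicit
undefined-gap-index error rather than a numerically exploding value;
`interface_series()` excludes such frames from its mean ± sd summary and
counts them. One geometric consequence worth knowing: a *planar* interface
buries no area once the surface gap exceeds twice the probe radius
(2.8 Å for water), so on the synthetic slab family the gap index is only
defined at separations below that bound — gap volume itself is defined at
any separation and decreases monotonically as the parts approach.

## Helix geometry

A helix axis is fitted to the Cα trace of a residue range in two steps.
First the trace is reduced to local helix origins: at each interior
residue the bisector of the two chain bonds points at the axis, the local
twist follows from the angle between consecutive bisectors, and the local
radius from the radial component of the chain bond; this construction is
exact for an ideal helix, so no winding bias remains even for ranges much
shorter than a full turn multiple (a plain midpoint-smoothing chain leaves
a bias of ~2° on a 13-residue helix, which is why it is not used). A
total-least-squares line through the origin chain gives the axis; its sign
is chosen N→C. The `fit_rms` field records the perpendicular RMS scatter
of the Cα atoms about the axis (≈2.3 Å, the canonical helix radius, for a
real helix).

The pair angle is the arccos of the dot product of the two signed
directions, on [0, 180]°; because directions are oriented, an opening
hinge (26°→44°) is distinguished from its supplementary closing geometry,
and reversing one helix's orientation maps θ to 180° − θ. Per-frame series
exclude frames where either range's `fit_rms` exceeds 2.5 Å (the package's
operationalization of "remains helical"); a plain mean is used, with a
warning if any retained angle comes within 5° of the 0/180 wrap, where
circular statistics would be required. Whether angles should be computed
per-frame-then-averaged or on average structures is a genuinely open
choice; per-frame is the default, and both are available since
`fit_helix_axis()` accepts any structure, including an average.

## Collective motion

PCA follows the essential-dynamics recipe: superpose frames on the
iteratively converged average over the analysis selection (a deterministic
reference, chosen over "first frame" so results do not depend on an
arbitrary frame), centre, weight coordinates by √mass (default; uniform
available), and eigen-decompose the covariance. The covariance uses 1/n
normalisation so the identity "variance of the projection on mode k equals
eigenvalue k" is exact rather than off by n/(n−1). Eigenvalues are clipped
at zero below 10⁻⁸ relative. A separate `fit_selection` lets the fit run
on a rigid core so that localized motion is not partially absorbed into
the superposition — with the default (fit on the analysis selection
itself) a strictly single-atom motion acquires small counter-motions on
every other atom, which is the expected behaviour of any least-squares
frame removal, not an artefact.

`filter_trajectory()` rebuilds frames from any subset of modes (the whole
set reproduces the aligned trajectory to 10⁻⁶ Å; the empty set freezes
the mean), which is how per-eigenvector motions are visualised.
`mode_report()` gives each mode's variance fraction and per-residue
involvement; five modes are reported by default, the customary number for
"the eigenvectors that carry the global motion". Alignment before
covariance is nonlinear, so eigenvalues of a rigidly transformed copy
agree only to ~1% for large-amplitude motion; the suite tests exactly
that bound.

## Substates and contacts

Substate clustering is neighbor-counting on the pairwise frame-RMSD graph
(the GROMOS-style algorithm): frames are superposed once onto the average
over `fit_selection`, pairwise RMSD is measured on `measure_selection`
without per-pair refitting, and clusters are peeled off greedily — the
frame with most neighbors within `cutoff` (default 1.5 Å, configurable;
inclusive comparison) becomes a center, ties break to the lowest frame
index, so the result is fully deterministic. Clusters are relabeled
largest-first; each reports its medoid frame (minimal summed RMSD to
members) and average structure. Pairwise matrices are capped (default
4000 frames) with an error instructing the caller to stride first.

Occupancy criteria: *distance* (minimum heavy-atom cross distance ≤
cutoff, boundary inclusive — every cutoff in the package compares with ≤);
*hbond* (donor–acceptor ≤ 3.5 Å and donor–H⋯acceptor angle ≥ 120° when
hydrogens are present; with no hydrogens the criterion degrades to
distance-only and the result is flagged); *coordination* (ion to O/N ≤
2.6 Å, the Mg²⁺–O convention). These cutoffs are package configuration,
not literature constants — reported observations like "separated by
roughly 11 Å" are distance statements, not defined criteria — and are
therefore exposed in `contact_spec()`.

Ligand mobility separates positional rattling (per-frame ligand RMSD to
the mean pose after fitting frames on the receptor) from internal
flexibility (same after fitting on the ligand itself, zero for a rigid
ligand). Ligand exposure is the ligand's share of the complex's per-atom
accessible area, compared with the ligand in isolation.

## The synthetic generator and what passing tests mean

`build_two_domain_system()` constructs a toy two-domain complex: per
domain one pair of ideal helices (rise 1.5 Å/residue, twist 100°/residue,
radius 2.3 Å, so consecutive Cα sit 3.8 Å apart) at a configured mutual
angle, plus a 7×7 planar grid of carbon "filler" atoms (4 Å spacing)
forming the interface; optionally a ring ligand with two Mg²⁺ ions in an
interface pocket. Helix residue numbering defaults to the four ranges
408–420, 468–475, 910–918, 978–988 so that realistic selections resolve.
The default study conditions are: domain-1 pair at 26° (a closed apo-like
state), domain-2 pair at 44°, interface separation 1.6 Å — chosen because
a *bound* interface must bury area for the gap index to be defined, and
1.6 Å puts the toy's gap index near 3.5, the scale of real non-obligate
interfaces — 300 frames and 0.1 Å isotropic noise. Placement fails if two
components come within 1.5 Å.

`generate_trajectory()` assembles each frame as: hinge-rotated base (a
rigid rotation of one helix about its anchor, following a per-frame angle
schedule), plus a Markov-switched substate displacement on a chosen
selection, plus low-rank collective modes (orthonormal vectors with the
six rigid-body modes projected out, so alignment does not eat them;
Gaussian amplitudes with prescribed variances), plus isotropic Gaussian
noise. One explicitly seeded RNG drives everything; the caller's RNG
stream is untouched, and identical configurations regenerate bit-identical
output. The drawn ground truth (state sequence, mode matrix and
coefficients, hinge schedule) is returned so every downstream recovery
test scores against it directly.

What the generator does *not* emulate: bonded structure and sterics,
anisotropic or correlated thermal noise, solvent, periodic boundaries, and
the slow, glassy convergence of real trajectories. Passing recovery tests
therefore demonstrates that the estimators are correct on data satisfying
their stated statistical assumptions — not that a given real trajectory is
long enough for those estimates to converge.

## Problem sizes and orchestration

The validation suite runs at desk scale by design: PCA recovery uses 5000
frames of the ~215-atom toy system, substate recovery 1000 frames,
surface oracles a 10⁶-point Monte-Carlo sample, the comparative pipeline
70 frames per system with every 12th frame entering the surface stage.
The reference multi-system study (four variants: apo; tighter interface +
opened hinge + stilled ligand; looser interface + noisier second domain;
both) runs through `run_system()`/`compare_systems()`, which validate all
selections before any stage executes, run the stages in a fixed order,
draw no random numbers, and so are bit-reproducible given identical
inputs. `scripts/acceptance.R` regenerates that study and all oracle
agreements from scratch.

## Known limitations

- Surface sampling is O(points × neighbors) in plain R; hundreds of atoms
  per frame are comfortable, tens of thousands are not.
- The gap-volume definition is sphere-union-based; deep interdigitated
  pockets connected to bulk solvent by wide mouths are delimited only by
  the `max_gap_sphere` cutoff, which is a modelling choice, not geometry.
- Angle summaries are plain means; series hugging 0°/180° need circular
  statistics the package only warns about.
- The hydrogen-bond criterion needs explicit hydrogens for its angular
  term; united-atom topologies silently fall back to distance-only (the
  result carries a flag).
- Substate clustering refits frames to one common average, not per pair;
  for very large conformational changes pairwise refitting would give
  slightly different RMSD values.
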