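---
title: "Context-aware mapping and averaging of pleomorphic capsid lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware mapping and averaging of pleomorphic capsid lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticectx)
```

## The problem

Mature retroviral capsids are fullerene-like shells of the capsid protein CA:
a hexamer lattice closed by exactly 12 pentamers, a topological requirement
of any closed surface built from 5- and 6-coordinated units. In vitro
capsid-like particles (CLPs) are pleomorphic — regular tubes, T=1 and T=3
icosahedra, and irregular polyhedra — and in irregular polyhedra every
hexamer sits in a slightly different geometric context (near or far from
pentamers, on surfaces of varying curvature). Averaging all hexamers against
one reference blurs exactly those context-dependent differences.

`latticectx` implements a context-aware analysis: annotate the lattice by
template matching, keep only geometrically consistent connectivity networks,
classify every unit *pair* (dimer) by its pentamer context and tube
orientation, align each unit once per neighbour and merge the measurements
into a correlation-weighted consensus pose, optimize poses toward class-mean
geometry, and average class-wise at the dimer interface. The package also
provides conventional tube subtomogram averaging with Fourier shell
correlation (FSC) resolution estimation, and interface RMSD analysis of
atomic models.

## Conventions

* Orientations are intrinsic ZXZ Euler triplets in degrees,
  `R = Rz(phi) Rx(theta) Rz(psi)`; the unit normal is the rotated z axis, so
  it depends only on `(phi, theta)` and `psi` is the in-plane spin. The
  processing lineage behind this kind of workflow does not pin down a single
  convention; ZXZ is common subtomogram-averaging practice and is fixed
  package-wide.
* Positions are 0-based voxel coordinates; every physical threshold is in
  angstroms and converted through the explicit `voxel_size`.
* Pair geometry: `tilt` is the angle between unit normals (the connectivity
  criterion calls it the normal difference); `curvature` is
  `angle(n_A, B - A) - 90°`, positive when the neighbour dips below A's
  tangential plane, so convex-outward closed shells have positive curvature —
  consistent with the asymmetric acceptance window (−15°..40°); `twist` is
  the signed in-plane rotation difference after parallel transport of B's
  frame onto A's tangential plane. The precise tilt/twist construction is an
  operational definition fixed here and used consistently throughout
  (generator, criteria, class statistics, optimization).

## The synthetic generators

The generators are first-class, tested code: they define the ground truth
every downstream stage is validated against.

* `build_tube(n_around, n_rings, spacing)` rolls a hexagonal lattice onto a
  cylinder; tube hexamers carry the C2 type.
* `build_icosahedron(T, spacing)` places 12 pentamers on the icosahedron
  vertices; for T=3 one hexamer per face, so each hexamer touches three
  pentamers.
* `build_polyhedron(n_units, elongation, seed)` subdivides the icosahedron
  (frequency f, sizes 10f²+2: 12, 42, 92, 162, ...; requests are snapped to
  the nearest feasible size), projects to the sphere, applies a random
  orientation, a prolate stretch along a random axis and a small seeded
  tangential jitter. The 12 degree-5 vertices are the pentamers by
  construction, so closure with exactly 12 pentamers is guaranteed
  topologically.

Defaults were chosen once, as the conditions a practitioner would call
realistic for this system, and are not tuned per experiment: spacing 80 Å
(mid-range of the 60–110 Å connectivity window), voxel size 8 Å for
annotation-scale volumes (between bin4 and bin8 of a 1.328 Å/pixel
acquisition), additive Gaussian noise of 0.1 of the peak unit density for
pipeline volumes, wedge ±60° about the x tilt axis where a wedge is applied.

Each unit is rendered from a coarse pseudo-atom template: two stacked rings
of Gaussian blobs (an outer ring above the mid-plane for the N-terminal
domain layer, a smaller inner ring below it for the C-terminal domain layer)
plus a central blob. The axial asymmetry makes the outward direction
identifiable — with a single flat ring the template is mirror-symmetric
along its normal and alignment cannot distinguish inside from outside. The
C2 hexamer modulates its outer-ring weights with period 3 (opposite blobs
equal), giving three symmetry-independent monomers under C2, as in tube
hexamers. Every unit's in-plane x axis points at a lattice neighbour, as the
dimeric interfaces of a real CA lattice do; twist statistics would be
meaningless under arbitrary spins.

What the generator does **not** emulate: atomic detail (templates are blobs,
so matching accuracy targets are set accordingly), CTF, dose-dependent
filtering, and crowded cellular background. Passing tests therefore
demonstrate the correctness of the geometry, classification, consensus and
averaging machinery — not detection performance on real tomograms.

## Template matching and its scope

`scan_orientations()` evaluates locally normalized cross-correlation of
band-pass-filtered (default 425–30 Å) templates over an orientation net
(directions every 15° by default, in-plane spins every 10°, reduced by the
template's Cn symmetry), then extracts peaks greedily with a minimum mutual
separation. Two numerical choices matter:

* Local standard deviations are floored at a configurable fraction of the
  volume-wide maximum (`variance_floor`). Pure local normalization produces
  unstable, large correlation values in near-empty regions; the floor
  suppresses them. For synthetic volumes with empty background the pipeline
  uses 0.5; for crowded volumes a smaller value is appropriate.
* Wedge-aware *constrained* correlation is deliberately out of scope for the
  scan: the missing wedge is handled where it belongs, in the sorting and
  averaging stages. Matching an unwedged template against a wedge-distorted
  volume produces coherent artifact peaks (elongation ghosts along the beam
  axis) that pass the connectivity criteria; the annotation pipeline
  therefore simulates its volumes without a wedge by default (configurable),
  while the wedge model is exercised in the synthetic module and in
  wedge-weighted averaging. `refine_peaks()` — the alignment-based sorting of
  peaks into pentamers and hexamers, mirroring the binned alignment rounds
  used to sort subvolume types — optionally degrades its templates by the
  acquisition wedge, which is legitimate at that stage.

After the initial scan the pipeline builds connectivity networks, refines
the network members locally (two-stage rotation search, type sorting),
discards non-aligning members by a correlation threshold, removes
duplicates, rebuilds and prunes the networks (every interior unit of a
capsid lattice has at least three validated neighbours; over-coordinated
units lose their longest edges), and finally reconciles unit types with the
lattice topology: a unit whose ring of neighbours closes with five members
is a pentamer, with six a hexamer. Template correlation decides types where
topology is ambiguous (boundaries); topology decides where it is not.

## Connectivity criteria

The five pair criteria use the published thresholds as defaults: spacing
60–110 Å, curvature −15°..40°, normal difference ≤ 45°, and only networks
with strictly more than 20 peaks survive. Two readings were fixed here:
boundary values are inclusive (only the network size is strict), and the
curvature check is applied from both units' tangential planes — stricter
than a one-sided check, but symmetric and deterministic. A caveat worth
knowing: a T=3 shell at 80 Å spacing has true neighbour normal differences
up to 41.8°, so measured edges sit close to the 45° criterion; the criteria
were designed for much larger CLPs (shell radii ≳ 200 Å), where the margins
are comfortable.

## Context classification

Slots around each unit of a pair are numbered 1′–6′ (unit A) and 1″–6″
(unit B), slot 1 being the partner, proceeding around the ring with a fixed
handedness (counterclockwise viewed from outside; the identities 2′ = 6″ and
6′ = 2″ hold for shared neighbours). Groups are evaluated in the order
1, 2, 3, 6, 4, 5 with the first match winning, so more constrained contexts
take precedence; group 4 is read as "at least one unit has a pentamer in
positions 3–5" at its point in the precedence order, which makes the
classification total (every edge receives exactly one group). Orientation
classes for groups 4 and 5 bin the signed angle between the edge and the
local cylinder axis (estimated as the smallest-variance direction of the
neighbourhood's normals; spherical neighbourhoods are degenerate and yield
class "none") into the three hexagonal edge families. Subclass labels beyond
the stated rules (slot combinations within groups 3 and 6, shared-pentamer
counts in groups 1 and 2) are implementation-defined small integers; the
full data-dependent subclass census of a real dataset is deliberately not
hard-coded.

## Consensus alignment

Each unit is aligned once per neighbour against a two-unit reference
(central unit plus that neighbour, both covered by the mask), and the
measurements merge by the correlation-weighted mean of positions and the
normalized correlation-weighted sum of normal vectors. Numerical policies:
measurements with cc ≤ 0 are dropped before the equations (if none remain
the unit keeps its prior pose and is flagged); antipodal normals make the
weighted sum vanish and raise an error rather than return an arbitrary
direction. The normal-vector equation fixes only the axis; the in-plane
angle is combined as the correlation-weighted circular mean after parallel
transport of each frame onto the consensus normal (an addition of this
package — carrying the best single measurement's spin is available behind a
switch).

With equal weights and N independent per-measurement position errors, the
consensus error shrinks like 1/sqrt(N); the acceptance suite verifies this
property at measurement level (ground-truth poses plus Gaussian pose noise
of 1.5 voxels and 8° per axis, 50 trials on a 42-unit polyhedron — the
nearest feasible size to 60 on the 10f²+2 grid), because it is a statistical
property of the estimator, independent of the imaging chain. Volume-level
alignment is verified separately on small noise-free fixtures (recovery of
2-voxel/8° perturbations to within 0.5 voxel and 2°).

Class-geometry optimization minimizes, per classified pair, the z-scored
squared deviations of tilt, twist and distance from their class means
(z-scoring makes angstroms and degrees commensurable; zero or singleton
standard deviations are floored at 0.5° / 0.5 Å). The optimizer is bounded
coordinate descent over each unit's six pose parameters with halving steps —
a candidate step is accepted only if it lowers the objective restricted to
the unit's incident edges, which equals the global change, so the global
objective is non-increasing by construction and the procedure is
deterministic.

## Averaging and resolution

Tube averaging seeds poses from a cylinder parametrization of the annotated
tube (principal-axis fit; ~2x linear oversampling), aligns each subtomogram
to the current reference with a bounded translation/rotation search
(sub-voxel translations by parabolic interpolation of the correlation peak),
removes converged duplicates greedily by descending correlation (cutoff
0.6 of the lattice spacing), applies the correlation threshold, and
symmetrizes the reference with C2. Half-sets are split even/odd and averaged
independently; with a wedge specification the halves are combined by
wedge-mask-weighted Fourier averaging (summed rotated binary wedge masks,
floored to avoid division blow-ups, uncovered frequencies reported as a
coverage fraction). FSC uses one-voxel shells on soft (Gaussian-falloff)
masked maps, and the resolution is the linearly interpolated first crossing
of 0.143; maps that never cross return Nyquist with a flag. The
phase-randomization component of mask-corrected FSC lives in external
methodology and is not implemented; the soft-mask FSC is the stated
stand-in and is validated with a band-limited-signal construction whose
crossing must fall at the band edge.

## Model analysis

Superposition is closed-form Kabsch (SVD) over atoms paired by chain,
residue number and atom name — no sequence-alignment fallback, since class
models share numbering by construction; C-alpha atoms are the default
selection. The interface RMSD matrix superposes each model pair on the
fixed-domain selection and measures RMSD over the measured domain(s)
*without re-fitting*, so it isolates the deviation across the interface; it
is symmetric with a zero diagonal and invariant to global rigid motions of
any input. The test suite validates the implementation against an
independent quaternion-eigenvalue oracle to 1e-9. Comparisons against
deposited pentamer models are possible with user-downloaded coordinate
files; no network access is assumed anywhere in the package.

## Problem sizes

The shipped tests and the acceptance script run at deliberate desk scale,
chosen as the package's own validation conditions: annotation volumes of
48³–72³ voxels at 8 Å/voxel (92-unit polyhedra, 32-unit T=3 shells), tube
averaging on 18-unit tubes with 16³ subtomograms, orientation nets of ~20°
with 30° spins for scans and finer two-stage refinement afterwards, 50-trial
consensus statistics, and 100-point-set superposition checks. These sizes
exercise every code path end-to-end with comfortable determinism; larger
boxes and finer nets scale straightforwardly.

## Known limitations

* Blob templates cap achievable matching contrast; hexamer-vs-pentamer
  discrimination relies on ring size and topology reconciliation, not
  side-chain detail.
* The scan stage is not wedge-aware (see above); annotating heavily wedged
  volumes requires constrained correlation, which is out of scope.
* The twist/tilt operational definitions are package conventions; absolute
  twist values are only comparable within this package.
* No CTF model, no dose filtering, no multi-particle interfaces to external
  refinement programs.
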