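---
title: "Recovering multi-cellular traction with a finite-element mixed boundary value problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering multi-cellular traction with a finite-element mixed boundary value problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tractionfem)
```

## The problem

Adherent cells pull (and push) on the gel they sit on. Traction force
microscopy measures the gel's surface displacement — by correlating bead
images taken with the cells attached and after their removal — and inverts
linear elasticity for the traction that produced it. The classical
inversion kernels (Boussinesq/Cerruti Green's functions, used directly or
through Fourier-transform traction cytometry) assume a semi-infinite
substrate and effectively a single, isolated cell. Neither assumption holds
for the cases this package targets: several cells in close proximity, and
cell clusters whose size rivals or exceeds the gel thickness (a 100 µm
cluster on a 70 µm gel feels the rigid glass below).

`tractionfem` instead solves the gel slab itself with a structured
hexahedral finite-element model, as a *mixed boundary value problem* (MBVP):

* under the cells (the mask), the measured surface displacements are
  prescribed;
* everywhere else on the top surface the *exact* condition is zero
  traction — those displacements are never needed;
* the bottom (bonded to glass) and the four distant lateral walls are
  clamped.

Every surface node therefore carries exactly one prescription per axis,
either a displacement or a force. The solver partitions the stiffness
system accordingly, solves for the unknown displacements, and reads the
cell's nodal forces off as the reactions at the displacement-prescribed
DOFs. Dividing by each node's tributary area gives traction. For a given
mask and displacement field the solution is unique — no regularization
parameter exists anywhere in the scheme — and the finite thickness and the
neighbouring cells are part of the model rather than corrections to it.

The one-dimensional intuition is worth spelling out (`bar_solve_mbvp()`):
a two-spring bar with `u1 = 0`, `u2 = -1` prescribed and the far end free
(`F3 = 0`) yields `F1 = +1`, `F2 = -1`, `u3 = -1`. A clamped point can
carry force; a force-free point can move. Prescribing a mix of
displacements and forces — never both, never neither — always determines
the rest, which is exactly what the traction recovery exploits in 3D.
(A three-node chain has two element stiffnesses; diagrams that attach a
"stiffness" label to each node notwithstanding, the two-element tridiagonal
stiffness matrix is the whole model.)

## Units

kPa for moduli and traction, µm for lengths and displacements, nN for
forces, so that 1 kPa × 1 µm² = 1 nN and no conversion constants appear.

## The element, and why it is not the textbook one

The slab is discretized into axis-aligned 8-node trilinear hexahedra
("small cubes"), node order lexicographic (x fastest), three DOFs per node.
Polyacrylamide is nearly incompressible (measured Poisson ratio ≈ 0.47),
and the fully integrated trilinear element *locks* volumetrically there: in
our experiments the in-plane recovery error under out-of-plane load grew as
ν approached 0.5, the opposite of the physically expected decoupling. The
element therefore uses selective reduced integration (SRI): the shear part
of the material response is integrated with the full 2×2×2 Gauss rule, the
volumetric λ-term with a single centre point. This is the standard locking
cure; the element stays symmetric, has exactly six rigid-body modes, and
passes the uniform-strain patch test to machine precision (asserted in the
tests at 1e-10).

SRI has one known weakness — mild checkerboard "pressure" oscillations
under near-singular loads. The deep-substrate benchmark (below) exercises
precisely such a load at ν = 0.45, where locking is not yet serious, so
that benchmark assembles the fully integrated variant
(`integration = "full"`). Both variants are exposed.

The default vertical spacing is **half** the in-plane grid spacing.
Surface-load problems have their steepest gradients immediately below the
surface; halving the vertical spacing costs 2× DOFs (versus 4× for lateral
refinement) and measurably controls the dominant discretization error of
the out-of-plane coupling experiments (see the decoupling section; the
final error is computed by `scripts/acceptance.R` and the test suite).

## Solvers

Sparse Cholesky (CHOLMOD) for systems up to `direct_max_dofs` total DOFs
(default 1e5), Jacobi-preconditioned conjugate gradient (tolerance 1e-8)
above. The direct threshold is a memory choice: supernodal factors of 3D
elasticity operators grow superlinearly, and ~2×10⁵-DOF factors exceed a
few GB. Factorizations are cached per Dirichlet partition inside a
`fem_context`, which is what makes the iterative whole-field scheme (two
solves per cycle, same two partitions every cycle) cheap.

Reactions are computed variationally as `(K u)` restricted to the
prescribed DOFs, not by stress extrapolation: they are exactly the external
forces required for equilibrium, so global force balance holds to solver
precision and the traction-free region is *identically* zero by
construction.

## The two recovery schemes

`recover_mixed()` is the method proper, described above. If the
displacement field lacks `uz` (2D imaging), `Fz = 0` is prescribed under
the cells instead and only in-plane traction is returned — accepted only
for ν ≥ 0.4, refused otherwise (see the decoupling discussion below).

`recover_whole_field_iterative()` implements the traditional whole-field
alternative for comparison: prescribe the measured (ux, uy) at *every*
surface node, solve, zero all extracellular forces, forward-solve a
corrected displacement field, restore the measured data under the cells
while keeping the computed extracellular displacements, and repeat until
the RMS of the surface nodal forces changes by less than `rms_tol`
(default 5%) between cycles. `Fz = 0` is prescribed at every top node in
the displacement half-cycle: the measured field is in-plane, and carrying
the computed extracellular `uz` forward as a displacement prescription
would only re-impose what the previous forward solve already produced.
On noiseless synthetic data the scheme converges in 2 cycles and agrees
with the mixed scheme to solver precision; the shipped comparison asserts
the two agree within 5% RMS of the peak nodal force.

Convergence of the RMS history is not guaranteed to be monotone and is not
asserted; non-convergence within `max_iter` raises a condition carrying
the history.

## Validation by round trip, and the error ratio

With no experimental ground truth available, validation is synthetic and
closed-loop: `make_two_cell_fixture()` builds the canonical two-cell
geometry (two 20 µm circles, 10 µm edge gap, E = 1 kPa, 70 µm gel — the
configuration of the original validation study), applies a self-equilibrated
in-plane force pattern in each circle, `forward_surface_displacements()`
produces the displacement field those forces cause, and the recovery must
reproduce the forces. The shipped tests assert the maximum node-by-node
force error (over nodes carrying ≥5% of the peak force) is below 1%; with
the direct solver it is in fact at rounding level, which is the uniqueness
proposition made computational.

Because every isolated cell exerts zero net force on the substrate, the
*error ratio* of a cluster,
ε = ‖Σᵢ (F_xi, F_yi)‖ / Σᵢ ‖(F_xi, F_yi)‖,
is a ground-truth-free accuracy diagnostic: 0 for a perfect solution, 1
for a completely unbalanced one. The tests require ε ≤ 0.07 per cluster
for every shipped fixture recovery. Equation form reconstructed from the
defining property (net over sum of magnitudes, in-plane components); ε of
a cluster with no force at all is undefined and returned as `NA` with a
warning.

All RMS summaries (the report's RMS traction, the scheme-comparison and
mesh-study differences, the iterative convergence metric) are taken over
*vector magnitudes* node by node, not per component.

The generator's force patterns are exactly balanced by construction: the
symmetric patterns are built in ± pairs and any floating-point residue of
the per-cluster net is projected out of the loaded nodes. `peak_force`
defaults to 0.5 nN per node — nothing downstream depends on the magnitude,
since the whole pipeline is linear (asserted by the linearity and
superposition tests).

## Out-of-plane forces and the Poisson ratio

As ν → 0.5 the in-plane surface response decouples from out-of-plane
loads, so in-plane traction can be recovered from in-plane displacements
alone with `Fz = 0` prescribed. The decoupling experiment
(`poisson_decoupling_study()`, and target `t2` in
`scripts/acceptance.R`) loads the two-cell fixture with an out-of-plane
force equal in magnitude to the in-plane one at every loaded node
(`|Fz| = k·|F∥|`, k = 1, sign split across each cell so the z-load is
balanced per cluster), forward-solves in 3D, recovers with in-plane data
only, and reports two error measures:

* **pole force error** — the relative error of the summed in-plane force
  of each loaded half-cell (max over the four half-cells). This is the
  integrated quantity a contractile-force measurement cares about; at
  ν = 0.47 and k = 1 it is ≈1.2% on the default mesh (reported by
  `scripts/acceptance.R`), against an acceptance bound of 2%.
* **node-level L2 error** — the aggregate per-node error. Reported for
  honesty but *not* a convergent quantity for this fixture: the loads are
  point forces tied to grid nodes, and their lattice-scale near field
  keeps a per-node discrepancy (~5%) that does not shrink under
  refinement. It measures the fixture's discreteness, not the scheme.

The sweep over ν shows the pole error falling from ν = 0.3 to ν = 0.45 as
theory predicts. Caveat at the default working mesh: at ν = 0.49
near-incompressibility amplifies the vertical discretization error faster
than the physical coupling shrinks, so its error sits slightly above the
ν = 0.45 value (both well under the 2% criterion at ν = 0.47); on the
3.23 µm mesh the theoretical ordering is restored. Below ν = 0.4 the
decoupling genuinely fails and in-plane-only recovery is refused with an
error, rather than silently returning biased forces.

## Mesh convergence study

`mesh_convergence_study()` mirrors the original convergence experiment:
one displacement field, recovered on meshes of spacing 6.45, 4.84 and
3.23 µm, comparing successive recoveries by node-by-node RMS traction
difference (each recovery bilinearly interpolated onto the reference
grid). The shipped fixture is a cluster-scale contractile disk (radius
30 µm, thickness 40 µm — a cluster comparable to the gel thickness, the
regime the method exists for) whose traction ramps to zero over the outer
30% of the radius. That rim width (~9 µm) is deliberately chosen between
the two coarser mesh resolutions, so the 6.45 µm mesh genuinely
under-resolves a feature the 4.84 µm mesh resolves: refinement then has
something to converge on, and the successive differences decrease. Two
notes on why *not* the two-cell fixture: 20 µm cells violate the "<20% of
cell size" mesh-size rule at 6.45 µm (the study warns on such input), and
a per-node constant-force pattern has no mesh-independent traction limit,
so its successive differences need not decrease. The per-spacing ε values
stay below 0.07.

## Region-choice robustness

`region_robustness_study()` recovers the same field under the true mask
and under a generously enlarged one (one dilation ring, or a bounding box
around everything). On consistent data the enlarged problem has the same
unique solution — the extra nodes carry displacements that are already
consistent with zero force there — so the difference inside the true
region is at solver precision, and the tests assert the conservative
bounds 2% (ring) and 6% (bounding box) of peak traction. With noisy or
inconsistent data the enlarged region absorbs error; the bounds are where
practice on measured fields lands.

## Deep-substrate limit (Cerruti benchmark)

On a substrate much deeper and wider than the observation scale the FEM
must reproduce the classical half-space surface response to a tangential
point force, u∥ = F(1+ν)/(πEr) along the force axis.
`deep_substrate_benchmark()` checks this at r = 3–6 grid spacings with
substrate depth 60 spacings (≥10× the largest observation radius) and
walls 48 spacings away. Those numbers matter: the wall clamp depresses the
1/r far field (≈ −10% at r = 6h with walls at 30h), while the discrete
nodal load inflates the near field (≈ +20% at r = 3h with coarse vertical
spacing). At 48h/60h with unit-aspect elements both effects sit within the
10% band. The full model at that size is ~1.7M DOFs, so the benchmark
exploits the load's two exact mirror symmetries and solves a quarter
domain (u_y = u_z = 0 on the x = 0 plane, u_y = 0 on y = 0, F/4 at the
corner node) — verified to reproduce the full-domain solution to solver
precision — in ~440k DOFs.

Comparisons exclude r < 3 spacings, where the lattice point-load
singularity dominates any continuum formula.

## Digital image correlation

`dic_displacement_field()` is a deliberately minimal DIC: normalized
cross-correlation of interrogation windows (default 32 px) over an integer
search range, separable quadratic subpixel refinement on the 3×3 peak
neighbourhood, windows with peak correlation < 0.5 flagged invalid. It
recovers rigid shifts to ±0.1 px and a 1%-per-pixel shear gradient within
10% on synthetic bead images (~600 beads per 192² px, σ = 1.5 px,
generated by `generate_bead_image()`). It does not do iterative subset
deformation, image pyramids, or outlier replacement — real pipelines
with large strains or poor seeding deserve a dedicated DIC package; the
module exists so the whole chain from images to traction can run and be
tested self-contained.

Image orientation is the classic trap: images index from the top-left,
grids from the bottom-left. All image I/O in the package flips rows on
load/save so that in memory `[i, j]` always means (x right, y up),
aligned with masks and displacement grids.

## What the synthetic data does and does not emulate

The generators produce: exactly balanced force patterns at cell and
cluster scale, finite-thickness response (a 20 µm vs 70 µm gel differs by
>5% RMS in surface displacement under identical loads — asserted, to
guard against accidentally implementing a half space), optional Gaussian
displacement noise (seeded), and synthetic bead images. They do not
emulate: spatially correlated DIC error, bead-density inhomogeneity,
drift/rigid-body motion between frames, gel nonlinearity or
viscoelasticity, or out-of-plane imaging artifacts. Passing the round-trip
tests therefore demonstrates the *inverse machinery* is correct and
well-conditioned under the stated conditions; it does not certify accuracy
on any particular experimental data set.

## Numerical choices and degenerate inputs

* Solver tolerance 1e-8 (relative); every solve's residual is checked and
  a failure raises an error rather than returning a degraded field.
* ν = 0.5 exactly is rejected at construction (singular for a displacement
  formulation); values up to 0.49 are accepted.
* Node-in-cluster rule: a node belongs to the cluster whose mask pixel
  contains it; disk rasterization uses centre-in-circle. Ties cannot occur
  on the shipped generators (disjoint circles; first label wins if they
  ever did).
* Masks touching the clamped walls (outer two node rings) are a hard
  error; labelled nodes closer to a wall than half the recommended margin
  (`recommended_margin()`: max of gel thickness, 0.75× mask bounding-box
  diagonal, 30 µm) draw a warning.
* All-zero displacement fields, empty clusters and zero-force clusters are
  handled explicitly (zero traction, `NA` ε with a warning).
* CSV output uses fixed 9-significant-digit formatting and deterministic
  row order; identical inputs produce byte-identical files.

## Problem sizes

The shipped test-and-validation runs use: the full two-cell geometry at
4.84 µm spacing (≈129k DOFs; direct-threshold excluded, solved by PCG in
seconds), the cluster disk at 3.23 µm (≈271k DOFs), the quarter-domain
Cerruti benchmark (≈439k DOFs), and a reduced 12 µm-cell geometry
(≈33k DOFs) for the fast unit tests. These sizes were chosen to exercise
both solver paths while keeping a full suite run in the minutes range on a
single core.

## Known limitations

* Linear, isotropic, homogeneous elasticity only; no large-deformation or
  viscoelastic constitutive behaviour.
* Structured, axis-aligned meshes with uniform per-axis spacing; no local
  refinement under the cells.
* The iterative whole-field scheme is provided for comparison and is not
  regularized; on very noisy data both schemes inherit the noise (an
  optional Gaussian pre-smoothing of the displacement field exists and is
  off by default).
* In-plane-only recovery is restricted to ν ≥ 0.4 by design; compressible
  substrates require measured `uz`.
* ε, the self-equilibration diagnostic, is necessary but not sufficient —
  a wrong-but-balanced field passes it; the round-trip tests are the
  actual accuracy check.
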