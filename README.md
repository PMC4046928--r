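# tractionfem

Finite-element traction force microscopy (TFM) for multi-cellular systems.

## What problem this solves, and for whom

Adherent cells deform the soft gel they grow on; TFM inverts that
deformation — measured by correlating fluorescent-bead images taken with
the cells attached and after trypsinization — for the traction the cells
exerted. The classical inversions build on the Boussinesq/Cerruti
half-space Green's functions and in practice address one isolated cell on
an effectively infinite substrate. This package is for the other cases:
**multiple cells in close proximity and cell clusters comparable to or
larger than the substrate thickness**, where the rigid glass under a
finite gel and the neighbours' fields cannot be ignored.

## The method

The gel slab (Young's modulus *E*, Poisson ratio *ν*, thickness *t*) is
discretized into trilinear hexahedral finite elements and solved as a
**mixed boundary value problem**. Writing the assembled linear system
*K u = f*, every surface node carries one prescription per axis:

* under the cells (an integer-labelled mask): the measured displacements
  *(u_x, u_y[, u_z])*;
* on the rest of the free surface: the exact traction-free condition
  *F_x = F_y = F_z = 0* — displacements there are never needed;
* bottom and distant lateral walls: clamped, *u = 0*.

Partitioning *K* by prescribed/unknown DOFs and solving the reduced system
once determines everything else; the cell's nodal forces are the reactions
*(K u)* at the displacement-prescribed DOFs, and traction is nodal force
over tributary area. The solution of this problem is **unique** — there is
no regularization parameter — and substrate thickness and cell–cell
proximity are part of the model. An iterative whole-field variant
(prescribe *(u_x, u_y)* everywhere, solve, zero the extracellular forces,
forward-solve, restore the measured in-cell data, repeat until the RMS
nodal force changes < 5% per cycle) is included for comparison with the
traditional approach.

Accuracy is reported with the self-equilibration **error ratio** per
cluster, ε = ‖Σᵢ(F_xi, F_yi)‖ / Σᵢ‖(F_xi, F_yi)‖ (0 for an exact
solution), since an isolated cell exerts zero net force on its substrate.

Units throughout: kPa, µm, nN (1 kPa × 1 µm² = 1 nN).

## Worked example: validation by round trip

Prescribe a known, self-equilibrated force field under two synthetic
cells, forward-solve for the surface displacements those forces cause,
then hand only the in-cell displacements to the recovery:

```r
library(tractionfem)

fx <- make_two_cell_fixture(diameter = 12, gap = 6, thickness = 20,
                            spacing = 3, margin = 30)
fx$mask
#> <cluster_mask>  31 x 25 nodes, 2 cluster(s): 1 (13 nodes), 2 (13 nodes)

disp <- forward_surface_displacements(fx$forces, fx$substrate, with_z = FALSE)
res  <- recover_mixed(disp, fx$mask, fx$substrate)
res$report
#> <recovery_report>  RMS traction: 0.04358 kPa
#>  cluster n_nodes  error_ratio        net_fx        net_fy    net_force
#>        1      13 8.793317e-16  3.504141e-15 -3.042729e-16 3.517327e-15
#>        2      13 1.809257e-16 -6.873842e-16  2.263814e-16 7.237027e-16

max(abs(res$traction$fx - fx$forces$fx))
#> [1] 1.22e-15
```

Reading the output: each 12 µm cell covers 13 grid nodes; the recovered
traction field has RMS 0.044 kPa over the cells; ε ≈ 1e-16 and a net
force ≈ 1e-15 nN say the recovered field is self-equilibrated to rounding;
and the prescribed nodal forces (peak 0.5 nN) come back with error
~1e-15 nN — the uniqueness argument, executed. On measured data replace
the generator with `read_displacement_csv()` + `read_mask_image()`; on
bead images start from `dic_displacement_field()`.

The same pipelines are scriptable from a shell via the thin wrapper
`inst/scripts/tfm` (subcommands `forward`, `recover`, `dic`, `study`,
`validate`).

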