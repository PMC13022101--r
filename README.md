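# rmsx

Time-windowed per-residue fluctuation analysis and "flipbook" visualization
of molecular-dynamics (MD) trajectories, in R.

## Who this is for

Researchers analyzing MD trajectories who need to know not just *how
mobile* each residue is (classical RMSF) or *how far* the structure drifted
(RMSD), but **when and where** motion happened.  The package partitions a
trajectory into equal consecutive time windows, computes a standard
root-mean-square fluctuation per residue *within each window*, and
assembles the result into a residues × windows matrix (the **RMSX**
matrix) rendered as a heatmap and as metric-annotated structural snapshots
that ChimeraX or VMD compose into a sequential flipbook.

## The core statistic

For residue $i$ in window $k$ containing $T$ frames, with representative
atom position $r_i(t)$:

$$\mathrm{RMSX}_{ik} = \sqrt{\tfrac{1}{T} \sum_{t \in k}
   \lVert r_i(t) - \langle r_i \rangle_k \rVert^2}$$

where $\langle r_i \rangle_k$ is the mean position over the window.  A
single window spanning the whole range recovers the classical RMSF exactly.
Complementary metrics in the same container:

- **shift map** — $\lVert r_i(t) - r_i(t_{\mathrm{ref}}) \rVert$ per frame
  (cumulative drift from a reference, with optional rigid superposition);
- **per-residue lDDT** — the fraction of short-range reference interatomic
  distances preserved within tolerances {0.5, 1, 2, 4} Å inside a 15 Å
  inclusion radius (local rearrangement, blind to rigid-body motion).

Rigid-body fitting uses the closed-form Kabsch solution, validated against
an independent quaternion-method oracle.

## Worked example

A synthetic 20-residue system, 200 frames at 10 ps, baseline jitter 0.2 Å,
with a fluctuation event (5× amplitude) at residues 10–12 during frames
101–160:

```r
library(rmsx)
spec <- synthetic_spec(
  n_residues = 20, n_frames = 200, dt_ps = 10, sigma = 0.2, seed = 42,
  events = list(list(residues = 10:12, frames = 101:160, multiplier = 5)))
sys  <- generate_trajectory(spec)
plan <- plan_slices(n_frames(sys), n_slices = 10, dt_ps = sys$dt_ps)
print(plan)
#> <SlicePlan> frames [0, 200): 10 slices x 20 frames, 0 dropped
#>   analyzed: 200 frames = 2 ns at 10 ps/frame

mx <- compute_rmsx(sys, plan)
round(mx$values[11, ], 2)           # RMSX row of an event residue, Å
#>  [1] 0.31 0.30 0.33 0.33 0.39 1.37 1.34 1.73 0.31 0.30
```

The event residues sit near the 0.2 × √3 ≈ 0.35 Å baseline except in
slices 6–8 (frames 101–160), where the fluctuation jumps to ~1.4–1.7 Å —
the matrix localizes the event in both residue and time.  The time-averaged
RMSX reproduces the classical RMSF profile:

```r
p <- pearson(mean_rmsx_per_residue(mx), classic_rmsf(sys))
#> mean-RMSX vs classical RMSF: r = 0.997 (R^2 = 0.995)

window_check(sys, candidate_slice_counts = c(4, 8, 16, 32))
#>   n_slices frames_per_slice pearson_r r_squared skipped reason
#> 1        4               50 0.9859092 0.9720170   FALSE
#> 2        8               25 0.9905077 0.9811055   FALSE
#> 3       16               12 0.9849881 0.9702016   FALSE
#> 4       32                6 0.9792639 0.9589578   FALSE
```

Exports with one shared colour scale end to end:

```r
render_heatmap(mx, "rmsx_heatmap.png", palette = "viridis")
snaps <- write_bfactor_snapshots(sys, mx, "snapshots")  # B-factor = RMSX
fb    <- build_flipbook_spec(snaps)
generate_chimerax_script(fb, "flipbook.cxc")
generate_vmd_script(fb, "flipbook.tcl")
```

## Command line

```sh
exec/rmsx synth --residues 20 --frames 200 --seed 1 --out demo
exec/rmsx run --structure demo/structure.pdb --trajectory demo/traj.dcd \
              --slices 10 --out results
exec/rmsx flipbook --snapshots results/A/snapshots --viewer vmd --out results
```

Subcommands: `run`, `all-chains` (per chain + full complex), `shiftmap`,
`lddt`, `window-check`, `flipbook`, `synth`.  Every run writes a
`manifest.json` with the resolved slice plan.

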