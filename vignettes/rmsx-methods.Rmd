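---
title: "Time-windowed fluctuation analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-windowed fluctuation analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmsx)
```

## The problem

Classical summaries of a molecular-dynamics (MD) trajectory answer one
question each.  RMSD against a reference frame says *how far* the structure
has drifted globally at each time point; RMSF says *how mobile* each residue
is on average over the whole run.  Neither says **when** a particular
residue moved.  This package computes a time-windowed RMSF — a
residues × windows matrix we call the RMSX matrix — together with two
complementary per-residue metrics (shift maps and lDDT time series), and
exports every metric both as plots and as B-factor-annotated structural
snapshots that molecular viewers can compose into a sequential "flipbook".

## The model

### Windowed RMSF

The analyzed frame range $[s, e)$ is partitioned into $n$ consecutive,
non-overlapping windows of $T = \lfloor (e-s)/n \rfloor$ frames; frames that
do not fill a window are dropped **from the end**, and the plan reports how
many (`plan_slices()` echoes total frames and the equivalent time in ns).
Within window $k$, for residue $i$ with representative-atom position
$r_i(t)$:

$$\mathrm{RMSX}_{ik} = \sqrt{\tfrac{1}{T}\sum_{t \in k}
  \lVert r_i(t) - \langle r_i \rangle_k \rVert^2},
\qquad \langle r_i\rangle_k = \tfrac{1}{T}\sum_{t\in k} r_i(t).$$

A single window spanning the whole range reduces this to the classical RMSF
by definition, and `compute_rmsx()` with one slice agrees with
`classic_rmsf()` to summation-order tolerance; the test suite asserts this
at `1e-12` against an independently coded literal transcription of the
formula.

### Shift maps

Entry $(i, t)$ is $\lVert r_i(t) - r_i(t_\mathrm{ref})\rVert$, the Euclidean
displacement of the residue from a reference frame, by default after
optimally superposing frame $t$ onto the reference.  Superposition is
disabled with `align = FALSE` for pulling simulations, where drift in the
laboratory frame *is* the signal.  RMSX and shift maps dissociate by
construction: RMSX is reference-free within each window, so a slow drift
spanning many windows inflates the shift map monotonically while leaving
within-window RMSX near its baseline (asserted within 10% on synthetic
drift).

### Per-residue lDDT

For every pair of selected atoms in *different* residues closer than the
inclusion radius $R_0$ in the reference frame, the pair is preserved at
threshold $\tau$ in frame $t$ when $|d_\mathrm{ref} - d_t| < \tau$.  The
residue score is the mean over thresholds of the preserved fraction of its
reference pairs.  Defaults follow the published metric: alpha-carbon atoms,
$R_0 = 15$ Å, $\tau \in \{0.5, 1, 2, 4\}$ Å, distance set fixed by the
reference frame.  Being built from internal distances, the score is exactly
1 under any proper rigid transform.  A residue with no reference contact has
an *undefined* score: it is reported as `NA` and drawn in a distinct grey,
never as 0.  The whole computation is checked against a brute-force
double-loop pair enumeration.

The metric is computed per frame; a `SlicePlan` may be passed to average
scores within each window (the field convention is ambiguous between the
two, so both are available).

### Superposition

Rigid-body fitting uses the closed-form Kabsch solution (SVD of the weighted
covariance, reflection branch corrected to determinant +1).  Correctness is
established against an independent quaternion-method oracle (largest
eigenvalue of Horn's 4×4 key matrix) on 1,000 random point sets at `1e-9`.
Fits with fewer than 3 points or collinear geometry are rejected.  Weights
default to uniform; mass weighting is a caller-supplied weight vector.

The RMSX pre-alignment convention is a package decision (the field's
conventions differ and upstream descriptions are silent): by default the
entire analyzed range is aligned **once** onto its first frame using the
metric selection, which keeps windows comparable.  `align_mode =
"per_window"` instead aligns each window to its own mean structure (one
refinement pass: fit to the window's first frame, then to the resulting
mean); `"none"` assumes a pre-aligned trajectory and is what the analytic
tests use, since their closed forms describe unaligned coordinates.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| selection | `"name CA"` | — | one alpha-carbon per residue; an all-atom mode averages per-atom RMSF within the residue |
| `n_slices` / `frames_per_slice` | 10 slices | frames | 8–16 slices suit ns-scale runs; `window_check()` compares candidates |
| `start_frame`, `end_frame` | full range | frames (0-based half-open; CLI is 1-based) | excludes equilibration |
| `dt_ps` | from file metadata | ps | explicit flag > DCD/TRR metadata > error; needed for ns axes |
| lDDT `r0` | 15 | Å | published inclusion radius |
| lDDT `thresholds` | 0.5, 1, 2, 4 | Å | published tolerance set |
| snapshot `frame_rule` | middle | — | the window's central conformation represents it |
| value range | (0, max) Å; (0, 1) lDDT | — | zero fluctuation is always the palette floor |
| radius map | 0.2–1.5 | Å | linear in the metric, clamped; proportional "worms" scaling needs fixed endpoints |
| spacing | 1.5 × bounding-box width | Å | snapshots separate without dwarfing the structure |

## The window-size heuristic

`window_check()` evaluates candidate slice counts (default 4–128 by powers
of two) by correlating the mean-RMSX-per-slice series with the per-slice
mean of per-frame RMSD.  High correlation indicates windows that track the
dominant motion; candidates that do not fit the range (or leave fewer than
3 slices, where a Pearson r is meaningless) are marked skipped.  The
correlation is a *tuning heuristic*, not a quality score: coupled and
decoupled regimes are both physically legitimate (see below).

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` states a world with closed-form expectations: CA atoms on
a 3.8 Å line or an ideal helix; isotropic Gaussian jitter of s.d.
$\sigma_i$ per coordinate, independent across frames; an optional coherent
sinusoid (amplitude $A_i$, period $P$); window-limited noise-amplitude
events; a constant drift vector; an optional rigid tumble.  The defaults
(30 residues, 200 frames at 10 ps — a typical save interval for ns-scale
runs — $\sigma = 0.3$ Å) were chosen once as representative of a small
stable protein and are not tuned against test outcomes.

Closed forms used as oracles: the Gaussian term contributes
$\sigma\sqrt{3}$ to RMSF; the sinusoid contributes $A/\sqrt{2}$ over whole
periods; independent terms add in quadrature; unaligned shift after $t$
frames of drift $v$ is $v\,t$.  Empirical RMSF converges to these at the
$1/\sqrt{T}$ rate (asserted at $T = 10^2, 10^3, 10^4$).

The generator is deliberately *not* physical: no bonded structure, no
autocorrelated noise, no solvent, no force field.  A green test therefore
establishes that the estimators recover the statistics of a known process —
not that any biological conclusion about a real protein follows.

One empirical finding shaped the decoupled-regime fixture.  For pure
i.i.d. jitter, the per-slice mean RMSD and the per-slice RMSF are estimated
**from the same noise draws**, which induces an intrinsic sampling
correlation of $r \approx 0.6$ regardless of system size or window length —
i.i.d. jitter is *not* a decoupled regime, contrary to first intuition.  The
decoupled regime in the field's sense is motion slow relative to the window
(drift accumulates while within-window fluctuation stays flat), and that is
how the fixture constructs it: fast jitter plus a residue-varying
deformation with period equal to the trajectory length, giving
$|r| \lesssim 0.2$ at 64 slices.

## Numerical choices

- Frame ranges are 0-based half-open internally; the CLI accepts 1-based
  inclusive numbers and converts.  Remainders are dropped from the end for
  both `n_slices` and `frames_per_slice` input (the rule is stated upstream
  only for the latter; mirroring it keeps the two parameterizations
  consistent).
- Insertion codes are rejected; residue identity is
  `(chain_id, residue_id)` with author numbering.
- B-factors are written `%6.2f` clamped to `[0, 999.99]`; round-trip
  precision is 0.01 and tests assert it.  An undefined (NA) metric value is
  written as 0 in the PDB B-factor column — the format has no missing-value
  representation — but stays `NA` in CSV and heatmaps.
- CSV values: 6 significant digits for Å metrics, 4 decimals for lDDT.
- Heatmap interpolation is linear along the time axis only and is
  visual-only; values at original bin centres are unchanged, and exported
  files never contain interpolated values.
- Tie-break for event-localization: `which.max`, the first maximal column.
- Degenerate inputs error early and descriptively: windows shorter than 2
  frames, empty selections, zero-variance correlation inputs, vmin ≥ vmax
  colour ranges, mismatched atom counts.

## Design decisions that were genuinely open

- **Trajectory formats.** PDB (multi-model), DCD (either endianness,
  optional unit-cell blocks) and TRR (single/double precision) are read by
  native readers, cross-validated in both directions against an independent
  MD toolkit during development.  XTC is recognised but rejected with
  guidance: its compressed-coordinate codec is a large, error-prone
  reimplementation that no installed library provides, and DCD/TRR cover
  the interchange need.
- **One RMSX value per residue is broadcast to all atoms of the residue**
  when writing B-factor snapshots; whether upstream tools write per-atom
  values instead is unknown, and the choice is documented rather than
  claimed.
- **Palettes are packaged as 256-entry hex lookup tables** (viridis, magma,
  plasma, inferno, cividis, mako, rocket, turbo) so the heatmap, the
  ChimeraX script and the VMD script provably share identical colour stops;
  relying on each viewer's built-in palettes could not guarantee identity.
- **Viewer scripts are generated, never executed.**  Assertions run on the
  emitted text (model counts, transform counts, colour stops, radius
  endpoints), keeping the test surface hermetic; rendering itself is the
  viewer's job.
- **`run` on a multi-chain system without `--chain`** lists the available
  chains and exits with status 2 instead of prompting — non-interactive by
  default is CI-safe.

## Known limitations

- Frames are materialized in memory (~24 bytes/atom/frame); the intended
  scale is analysis-sized selections (e.g. CA subsets), not solvated boxes.
- No insertion codes, no mmCIF, no bond perception, no binary trajectory
  writing beyond DCD/TRR.
- Overlapping or sliding-stride windows are out of scope; "sliding window"
  phrasing in field usage is implemented as disjoint windows of that length.
- The per-window alignment mode uses one refinement pass toward the window
  mean, not iteration to convergence; for well-behaved windows the
  difference is far below sampling noise.
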