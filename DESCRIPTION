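Package: rmsx
Title: Time-Windowed Fluctuation Analysis and Flipbook Visualization of
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("RMSX", "Maintainers", email = "rmsx@example.org", role = c("aut", "cre"))
Description: Computes time-resolved per-residue fluctuation profiles (RMSX)
    from molecular dynamics trajectories by partitioning a frame range into
    equal consecutive windows and evaluating a standard root-mean-square
    fluctuation within each window.  Complementary per-residue metrics are
    provided: shift maps (Euclidean displacement from a reference frame) and
    per-residue lDDT time series (preservation of short-range interatomic
    distances).  Includes Kabsch least-squares superposition, a window-size
    selection heuristic based on correlating mean RMSX with mean RMSD, CSV
    and B-factor-annotated PDB exporters with a shared colour scale, heatmap
    and triple-plot rendering, generation of ChimeraX and VMD scripts that
    compose metric-annotated snapshots into a sequential "flipbook", and a
    synthetic-trajectory generator with closed-form fluctuation expectations
    for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
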