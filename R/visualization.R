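# Heatmap / triple-plot rendering and viewer-script generation.
#
# Colour identity across outputs is guaranteed by packaged 256-entry palette
# lookup tables (inst/extdata/palettes/<name>.csv); the heatmap, the snapshot
# REMARK headers and both viewer scripts all draw from the same table and the
# same (vmin, vmax).

.palette_names <- c("viridis", "magma", "plasma", "inferno", "cividis",
                    "mako", "rocket", "turbo")

#' Available flipbook palettes
#' @return character vector of palette names.
#' @export
flipbook_palettes <- function() .palette_names

#' Load a packaged palette lookup table
#'
#' @param name one of [flipbook_palettes()].
#' @param n number of colours (interpolated from the 256-entry table when
#'   `n != 256`).
#' @return character vector of hex colours.
#' @export
flipbook_palette <- function(name, n = 256) {
  if (!name %in% .palette_names) {
    stop("unknown palette '", name, "'; allowed: ",
         paste(.palette_names, collapse = ", "))
  }
  path <- system.file("extdata", "palettes", paste0(name, ".csv"),
                      package = "rmsx", mustWork = TRUE)
  hex <- utils::read.csv(path, stringsAsFactors = FALSE)$hex
  if (n == length(hex)) hex else grDevices::colorRampPalette(hex)(n)
}

# Colour stops at 0/25/50/75/100% of the table, shared by all script
# generators and recorded next to (vmin, vmax).
palette_stops <- function(name) {
  hex <- flipbook_palette(name)
  hex[round(c(0, 0.25, 0.5, 0.75, 1) * 255) + 1]
}

#' Render a metric matrix as a heatmap PNG
#'
#' Residues ascend bottom-to-top on y; time bins in ns on x; a colourbar
#' spans the shared value range.  Optional interpolation linearly upsamples
#' along the time axis only (colours at original bin centres are unchanged);
#' exported CSV/PDB values are never interpolated.  Missing values (e.g.
#' lDDT residues without reference contacts) are drawn in a distinct grey.
#'
#' @param matrix a `MetricMatrix`.
#' @param path output PNG path.
#' @param palette palette name.
#' @param interpolate upsample along time for display (default FALSE).
#' @param vrange optional `c(vmin, vmax)`; default [default_value_range()].
#' @param width,height device size in pixels.
#' @return invisibly, a list with the `vmin`, `vmax`, `palette` and
#'   `stops` actually used (the testable colour contract).
#' @export
render_heatmap <- function(matrix, path, palette = "viridis",
                           interpolate = FALSE, vrange = NULL,
                           width = 900, height = 600) {
  stopifnot(inherits(matrix, "MetricMatrix"))
  if (!palette %in% .palette_names) {
    stop("unknown palette '", palette, "'; allowed: ",
         paste(.palette_names, collapse = ", "))
  }
  if (is.null(vrange)) vrange <- default_value_range(matrix)
  cols <- flipbook_palette(palette)
  v <- matrix$values
  x <- matrix$time_axis
  if (interpolate && ncol(v) > 1) {
    xi <- seq(x[1], x[length(x)], length.out = (ncol(v) - 1) * 8 + 1)
    v <- t(apply(v, 1, function(row) stats::approx(x, row, xout = xi)$y))
    x <- xi
  }
  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 2), 1, 2), widths = c(5, 1))
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  # image(): row 1 of z at the left/bottom -> residues ascend bottom-to-top
  graphics::image(x = x, y = seq_len(nrow(v)), z = t(v),
                  zlim = vrange, col = cols, useRaster = FALSE,
                  xlab = "time (ns)", ylab = "residue index",
                  main = toupper(matrix$kind))
  if (anyNA(v)) {
    na_cells <- which(is.na(t(v)), arr.ind = TRUE)
    graphics::points(x[na_cells[, 1]], na_cells[, 2], pch = 15,
                     col = "grey60")
  }
  graphics::par(mar = c(4.5, 1, 2, 3))
  bar <- seq(vrange[1], vrange[2], length.out = 256)
  graphics::image(x = 1, y = bar, z = matrix(bar, 1), zlim = vrange,
                  col = cols, xaxt = "n", xlab = "",
                  ylab = "")
  graphics::mtext(if (matrix$kind == "lddt") "lDDT" else "Å",
                  side = 4, line = 1)
  invisible(list(vmin = vrange[1], vmax = vrange[2], palette = palette,
                 stops = palette_stops(palette)))
}

#' Render the RMSD | heatmap | RMSF triple plot
#'
#' Composite figure: per-frame RMSD on top sharing the heatmap's time axis;
#' the metric heatmap in the centre; the RMSF profile on the right sharing
#' the residue axis (displacement on x, residue index on y).
#'
#' @param rmsd an `RmsdSeries` covering the analyzed range.
#' @param matrix a `MetricMatrix` (time axis in ns).
#' @param rmsf_profile numeric, one value per matrix row.
#' @param path output PNG path.
#' @inheritParams render_heatmap
#' @return invisibly, the colour contract list as in [render_heatmap()].
#' @export
render_triple_plot <- function(rmsd, matrix, rmsf_profile, path,
                               palette = "viridis", vrange = NULL,
                               width = 1000, height = 800) {
  stopifnot(inherits(matrix, "MetricMatrix"))
  if (length(rmsf_profile) != nrow(matrix$values)) {
    stop("axis mismatch: rmsf profile has ", length(rmsf_profile),
         " residues, heatmap has ", nrow(matrix$values))
  }
  tmin <- if (!is.null(matrix$time_edges)) matrix$time_edges[1] else
    matrix$time_axis[1]
  tmax <- if (!is.null(matrix$time_edges))
    matrix$time_edges[length(matrix$time_edges)] else
    matrix$time_axis[length(matrix$time_axis)]
  if (min(rmsd$time_ns) < tmin - 1e-9 || max(rmsd$time_ns) > tmax + 1e-9) {
    stop("axis mismatch: RMSD series spans [", min(rmsd$time_ns), ", ",
         max(rmsd$time_ns), "] ns but the heatmap time axis spans [",
         tmin, ", ", tmax, "] ns")
  }
  if (is.null(vrange)) vrange <- default_value_range(matrix)
  cols <- flipbook_palette(palette)
  nres <- nrow(matrix$values)

  grDevices::png(path, width = width, height = height, type = "cairo")
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(c(1, 0, 2, 3), 2, 2, byrow = TRUE),
                   widths = c(4, 1), heights = c(1, 3))
  graphics::par(mar = c(0.5, 4.5, 2, 0.5))
  graphics::plot(rmsd$time_ns, rmsd$values, type = "l", xlim = c(tmin, tmax),
                 xaxt = "n", xlab = "", ylab = "RMSD (Å)")
  graphics::par(mar = c(4.5, 4.5, 0.5, 0.5))
  graphics::image(x = matrix$time_axis, y = seq_len(nres),
                  z = t(matrix$values), zlim = vrange, col = cols,
                  xlim = c(tmin, tmax), xlab = "time (ns)",
                  ylab = "residue index")
  graphics::par(mar = c(4.5, 0.5, 0.5, 2))
  graphics::plot(rmsf_profile, seq_len(nres), type = "l",
                 ylim = c(1, nres), yaxt = "n",
                 xlab = "RMSF (Å)", ylab = "")
  invisible(list(vmin = vrange[1], vmax = vrange[2], palette = palette,
                 stops = palette_stops(palette)))
}

# ---------------------------------------------------------------------------
# Flipbook spec and viewer scripts

#' Build a flipbook specification from a snapshot set
#'
#' Reads the shared value range and palette back from the snapshots' REMARK
#' headers (they must agree across all snapshots) and fixes the layout and
#' radius mapping used by both viewer scripts.
#'
#' @param snapshots a `SnapshotSet`, or a character vector of snapshot PDB
#'   paths in slice order.
#' @param viewer `"chimerax"` or `"vmd"`.
#' @param spacing distance between consecutive snapshots in Angstroms;
#'   default 1.5 x the bounding-box width of the first snapshot.
#' @param snapshots_per_row layout width (default all in one row).
#' @param radius_range `c(r_min, r_max)` tube radius in Angstroms mapped
#'   linearly from the metric (defaults 0.2, 1.5).
#' @return object of class `FlipbookSpec`.
#' @export
build_flipbook_spec <- function(snapshots, viewer = c("chimerax", "vmd"),
                                spacing = NULL, snapshots_per_row = NULL,
                                radius_range = c(0.2, 1.5)) {
  viewer <- match.arg(viewer)
  paths <- if (inherits(snapshots, "SnapshotSet")) snapshots$paths
           else as.character(snapshots)
  if (length(paths) == 0) stop("no snapshots given")
  if (!all(file.exists(paths))) {
    stop("missing snapshot files: ",
         paste(paths[!file.exists(paths)], collapse = ", "))
  }
  metas <- lapply(paths, parse_snapshot_remark)
  if (any(vapply(metas, is.null, logical(1)))) {
    stop("snapshot(s) lack the FLIPBOOK REMARK header; regenerate them ",
         "with write_bfactor_snapshots()")
  }
  key <- vapply(metas, function(m) sprintf("%s|%.6f|%.6f|%s", m$kind,
                                           m$vmin, m$vmax, m$palette),
                character(1))
  if (length(unique(key)) != 1) {
    stop("snapshots carry different value ranges/palettes; a flipbook ",
         "requires one shared scale (regenerate the set in one run)")
  }
  m <- metas[[1]]
  if (!(m$vmin < m$vmax)) stop("degenerate value range: vmin must be < vmax")
  if (!(radius_range[1] < radius_range[2])) {
    stop("radius_range must satisfy r_min < r_max")
  }
  if (is.null(spacing)) {
    first <- read_pdb(paths[1])
    bbox <- apply(first$coords[, , 1], 2, range)
    spacing <- 1.5 * max(bbox[2, ] - bbox[1, ])
  }
  structure(
    list(paths = paths, palette = m$palette, kind = m$kind,
         vmin = m$vmin, vmax = m$vmax,
         spacing = spacing,
         snapshots_per_row = snapshots_per_row %||% length(paths),
         r_min = radius_range[1], r_max = radius_range[2], viewer = viewer),
    class = "FlipbookSpec"
  )
}

# x/y offset of snapshot k (1-based) in the row layout, Angstroms.
snapshot_offset <- function(spec, k) {
  per_row <- spec$snapshots_per_row
  c(x = ((k - 1) %% per_row) * spec$spacing,
    y = -((k - 1) %/% per_row) * spec$spacing)
}

fmt_num <- function(x) sprintf("%.6f", x)

# Shared "value,color" stop list over (vmin, vmax) at 0/25/50/75/100%.
stop_values <- function(spec) {
  seq(spec$vmin, spec$vmax, length.out = 5)
}

#' Generate a ChimeraX command script composing a flipbook
#'
#' The script opens every snapshot, superposes each onto the first, offsets
#' model k along the layout, colours by the B-factor attribute with an
#' explicit five-stop mapping over `(vmin, vmax)`, applies a worm-style
#' radius mapped linearly from the metric to `(r_min, r_max)`, and saves a
#' transparent-background PNG.  Generation is deterministic: one spec, one
#' byte stream.
#'
#' @param spec a `FlipbookSpec`.
#' @param path output `.cxc` path.
#' @return `path`, invisibly.
#' @export
generate_chimerax_script <- function(spec, path) {
  stopifnot(inherits(spec, "FlipbookSpec"))
  if (!(spec$vmin < spec$vmax)) stop("degenerate value range: vmin must be < vmax")
  stops <- palette_stops(spec$palette)
  sv <- stop_values(spec)
  pal_arg <- paste(sprintf("%s,%s", fmt_num(sv), stops), collapse = ":")
  lines <- c(
    "# flipbook composition script (generated by the rmsx package)",
    sprintf("# palette-stops: %s", paste(stops, collapse = " ")),
    sprintf("# value-range: %s %s", fmt_num(spec$vmin), fmt_num(spec$vmax)),
    sprintf("open %s", spec$paths)
  )
  n <- length(spec$paths)
  if (n > 1) {
    for (k in 2:n) {
      lines <- c(lines, sprintf("matchmaker #%d to #1", k))
    }
    for (k in 2:n) {
      off <- snapshot_offset(spec, k)
      lines <- c(lines, sprintf("move x %s models #%d", fmt_num(off["x"]), k),
                 if (off["y"] != 0)
                   sprintf("move y %s models #%d", fmt_num(off["y"]), k))
    }
  }
  lines <- c(lines,
    sprintf("color byattribute bfactor #%d palette %s", seq_len(n), pal_arg),
    sprintf(
      "cartoon byattribute bfactor #%d range %s,%s worm true radius %s,%s",
      seq_len(n), fmt_num(spec$vmin), fmt_num(spec$vmax),
      fmt_num(spec$r_min), fmt_num(spec$r_max)),
    "set bgColor white",
    "save flipbook.png transparentBackground true"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Generate a VMD Tcl script composing a flipbook
#'
#' Loads each snapshot as its own molecule, offsets it with a per-molecule
#' global transform (VMD has a single scene pivot, so per-molecule matrices
#' emulate per-snapshot pivots), colours by B-factor (Beta) over the shared
#' `(vmin, vmax)`, scales per-residue tube radius linearly from the metric to
#' `(r_min, r_max)`, and defines `flipbook_spacing` / `flipbook_rotate`
#' convenience procedures.
#'
#' @param spec a `FlipbookSpec`.
#' @param path output `.tcl` path.
#' @return `path`, invisibly.
#' @export
generate_vmd_script <- function(spec, path) {
  stopifnot(inherits(spec, "FlipbookSpec"))
  if (!(spec$vmin < spec$vmax)) stop("degenerate value range: vmin must be < vmax")
  stops <- palette_stops(spec$palette)
  n <- length(spec$paths)
  header <- c(
    "# flipbook composition script (generated by the rmsx package)",
    sprintf("# palette-stops: %s", paste(stops, collapse = " ")),
    sprintf("# value-range: %s %s", fmt_num(spec$vmin), fmt_num(spec$vmax)),
    sprintf("set flipbook_vmin %s", fmt_num(spec$vmin)),
    sprintf("set flipbook_vmax %s", fmt_num(spec$vmax)),
    sprintf("set flipbook_rmin %s", fmt_num(spec$r_min)),
    sprintf("set flipbook_rmax %s", fmt_num(spec$r_max)),
    sprintf("set flipbook_spacing %s", fmt_num(spec$spacing)),
    sprintf("set flipbook_palette { %s }",
            paste(sprintf("{%s}", stops), collapse = " "))
  )
  body <- character(0)
  for (k in seq_len(n)) {
    off <- snapshot_offset(spec, k)
    body <- c(body,
      sprintf("mol new {%s} type pdb waitfor all", spec$paths[k]),
      "set m [molinfo top]",
      # per-molecule global matrix emulates a per-snapshot pivot point
      sprintf(paste0("molinfo $m set global_matrix ",
                     "{{{1 0 0 %s} {0 1 0 %s} {0 0 1 0} {0 0 0 1}}}"),
              fmt_num(off["x"]), fmt_num(off["y"])),
      "mol delrep 0 $m",
      "mol representation Tube 0.3 12",
      "mol color Beta",
      "mol addrep $m",
      "mol scaleminmax $m 0 $flipbook_vmin $flipbook_vmax"
    )
  }
  procs <- c(
    "# radius of a residue with metric value v (linear, clamped)",
    "proc flipbook_radius {v} {",
    "  global flipbook_vmin flipbook_vmax flipbook_rmin flipbook_rmax",
    "  set f [expr {($v - $flipbook_vmin) / ($flipbook_vmax - $flipbook_vmin)}]",
    "  if {$f < 0} {set f 0}",
    "  if {$f > 1} {set f 1}",
    "  return [expr {$flipbook_rmin + $f * ($flipbook_rmax - $flipbook_rmin)}]",
    "}",
    "# rebuild each molecule's reps: one Tube per residue, radius from Beta",
    "proc flipbook_apply_radii {} {",
    "  foreach m [molinfo list] {",
    "    while {[molinfo $m get numreps] > 0} {mol delrep 0 $m}",
    "    set sel [atomselect $m \"name CA\"]",
    "    foreach rid [$sel get residue] b [$sel get beta] {",
    "      mol representation Tube [flipbook_radius $b] 12",
    "      mol color Beta",
    "      mol selection \"residue $rid\"",
    "      mol addrep $m",
    "    }",
    "    $sel delete",
    "  }",
    "}",
    "proc flipbook_spacing {d} {",
    "  set k 0",
    "  foreach m [molinfo list] {",
    "    molinfo $m set global_matrix \\",
    "      [list [list [list 1 0 0 [expr {$k * $d}]] {0 1 0 0} {0 0 1 0} {0 0 0 1}]]",
    "    incr k",
    "  }",
    "}",
    "proc flipbook_rotate {axis angle} {",
    "  foreach m [molinfo list] {rotate $axis by $angle}",
    "}",
    "flipbook_apply_radii",
    "display projection orthographic"
  )
  writeLines(c(header, body, procs), path)
  invisible(path)
}
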