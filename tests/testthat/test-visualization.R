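fixture_run <- function(n_res = 5, n_slices = 3, seed = 17,
                        palette = "viridis") {
  sys <- tiny_system(n_residues = n_res, n_frames = n_slices * 4, seed = seed)
  plan <- plan_slices(n_frames(sys), n_slices = n_slices, dt_ps = sys$dt_ps)
  mx <- compute_rmsx(sys, plan, align_mode = "none")
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  snaps <- write_bfactor_snapshots(sys, mx, file.path(dir, "snapshots"),
                                   palette = palette)
  list(sys = sys, plan = plan, mx = mx, dir = dir, snaps = snaps)
}

test_that("packaged palettes load, reject unknown names", {
  expect_setequal(flipbook_palettes(),
                  c("viridis", "magma", "plasma", "inferno", "cividis",
                    "mako", "rocket", "turbo"))
  for (p in flipbook_palettes()) {
    hex <- flipbook_palette(p)
    expect_length(hex, 256)
    expect_true(all(grepl("^#[0-9A-Fa-f]{6}$", hex)))
  }
  expect_error(flipbook_palette("jet"), "unknown palette.*viridis")
})

test_that("render_heatmap writes a PNG and reports the colour contract", {
  f <- fixture_run()
  path <- file.path(f$dir, "h.png")
  info <- render_heatmap(f$mx, path, palette = "plasma",
                         vrange = c(f$snaps$vmin, f$snaps$vmax))
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_equal(info$vmin, f$snaps$vmin)
  expect_equal(info$vmax, f$snaps$vmax)
  expect_equal(info$stops, rmsx:::palette_stops("plasma"))
  expect_error(render_heatmap(f$mx, path, palette = "nope"),
               "unknown palette")
  # lddt colourbar bounds are 0..1
  sysh <- tiny_system(n_residues = 6, n_frames = 4, sigma = 0.3, seed = 2,
                      geometry = "helix")
  ml <- lddt_series(sysh)
  info2 <- render_heatmap(ml, file.path(f$dir, "l.png"))
  expect_equal(c(info2$vmin, info2$vmax), c(0, 1))
})

test_that("interpolation preserves values at original bin centres", {
  f <- fixture_run()
  v <- f$mx$values
  x <- f$mx$time_axis
  xi <- seq(x[1], x[length(x)], length.out = (ncol(v) - 1) * 8 + 1)
  up <- t(apply(v, 1, function(row) stats::approx(x, row, xout = xi)$y))
  expect_equal(up[, match(x, xi)], v, tolerance = 1e-12)
  expect_silent(render_heatmap(f$mx, file.path(f$dir, "i.png"),
                               interpolate = TRUE))
})

test_that("triple plot enforces axis consistency", {
  f <- fixture_run()
  frames <- seq_len(f$plan$total_frames)
  rs <- rmsd_series(f$sys, frames = frames)
  rmsf <- mean_rmsx_per_residue(f$mx)
  path <- file.path(f$dir, "t.png")
  expect_silent(render_triple_plot(rs, f$mx, rmsf, path))
  expect_true(file.exists(path) && file.size(path) > 0)
  expect_error(render_triple_plot(rs, f$mx, rmsf[-1], path),
               "axis mismatch.*residues")
  long <- rs; long$time_ns <- c(long$time_ns, 99)
  long$values <- c(long$values, 0)
  expect_error(render_triple_plot(long, f$mx, rmsf, path), "axis mismatch")
})

test_that("flipbook spec carries order, shared scale and layout", {
  f <- fixture_run(palette = "mako")
  spec <- build_flipbook_spec(f$snaps, viewer = "chimerax")
  expect_equal(spec$paths, f$snaps$paths)
  expect_equal(c(spec$vmin, spec$vmax), c(f$snaps$vmin, f$snaps$vmax),
               tolerance = 1e-6)
  expect_equal(spec$palette, "mako")
  # default spacing = 1.5 x bounding-box width of the first snapshot
  first <- read_pdb(f$snaps$paths[1])
  bbox <- apply(first$coords[, , 1], 2, range)
  expect_equal(spec$spacing, 1.5 * max(bbox[2, ] - bbox[1, ]),
               tolerance = 1e-6)
  over <- build_flipbook_spec(f$snaps, spacing = 50)
  expect_equal(over$spacing, 50)
  # mixed ranges across snapshots violate the shared-scale rule
  lines <- readLines(f$snaps$paths[2])
  lines[1] <- sub("vmax=[0-9.]+", "vmax=99.000000", lines[1])
  writeLines(lines, f$snaps$paths[2])
  expect_error(build_flipbook_spec(f$snaps), "shared scale")
  # missing REMARK suggests regeneration
  writeLines(grep("^REMARK", readLines(f$snaps$paths[3]), value = TRUE,
                  invert = TRUE), f$snaps$paths[3])
  expect_error(build_flipbook_spec(f$snaps$paths[3]),
               "regenerate")
})

test_that("chimerax script structure and palette stops", {
  f <- fixture_run(palette = "magma")
  spec <- build_flipbook_spec(f$snaps)
  path <- file.path(f$dir, "fb.cxc")
  generate_chimerax_script(spec, path)
  txt <- readLines(path)
  expect_length(grep("^open ", txt), 3)
  expect_length(grep("^matchmaker ", txt), 2)
  expect_length(grep("^move x ", txt), 2)
  # explicit stops equal the packaged magma table at 0/25/50/75/100%
  stops_line <- grep("^# palette-stops:", txt, value = TRUE)
  emitted <- strsplit(sub("^# palette-stops: ", "", stops_line), " ")[[1]]
  lut <- flipbook_palette("magma")
  expect_equal(emitted, lut[round(c(0, .25, .5, .75, 1) * 255) + 1])
  expect_true(any(grepl("transparentBackground true", txt)))
  # determinism: same spec -> byte-identical script
  path2 <- file.path(f$dir, "fb2.cxc")
  generate_chimerax_script(spec, path2)
  expect_identical(readLines(path2), txt)
})

test_that("vmd script structure, radius endpoints and cross-viewer identity", {
  f <- fixture_run(palette = "rocket")
  spec <- build_flipbook_spec(f$snaps, viewer = "vmd")
  tcl <- file.path(f$dir, "fb.tcl")
  cxc <- file.path(f$dir, "fb.cxc")
  generate_vmd_script(spec, tcl)
  generate_chimerax_script(spec, cxc)
  t_txt <- readLines(tcl)
  expect_length(grep("^mol new ", t_txt), 3)
  expect_length(grep("^molinfo \\$m set global_matrix", t_txt), 3)
  expect_true(any(grepl("set flipbook_rmin 0.200000", t_txt)))
  expect_true(any(grepl("set flipbook_rmax 1.500000", t_txt)))
  expect_true(any(grepl("proc flipbook_radius", t_txt)))
  expect_true(any(grepl("proc flipbook_spacing", t_txt)))
  expect_true(any(grepl("proc flipbook_rotate", t_txt)))
  # identical colour stops and value range in both viewer scripts
  pick <- function(txt, tag) grep(tag, txt, value = TRUE)
  c_txt <- readLines(cxc)
  expect_identical(pick(t_txt, "^# palette-stops:"),
                   pick(c_txt, "^# palette-stops:"))
  expect_identical(pick(t_txt, "^# value-range:"),
                   pick(c_txt, "^# value-range:"))
})

test_that("degenerate value range is rejected", {
  sys <- tiny_system(n_residues = 4, n_frames = 8, sigma = 0, seed = 1)
  plan <- plan_slices(8, n_slices = 2, dt_ps = sys$dt_ps)
  mx <- compute_rmsx(sys, plan, align_mode = "none")   # all-zero matrix
  snaps <- write_bfactor_snapshots(sys, mx, withr::local_tempdir())
  expect_error(build_flipbook_spec(snaps), "vmin must be < vmax")
  f <- fixture_run()
  spec <- build_flipbook_spec(f$snaps)
  spec$vmin <- spec$vmax
  expect_error(generate_chimerax_script(spec, tempfile()),
               "vmin must be < vmax")
  expect_error(generate_vmd_script(spec, tempfile()), "vmin must be < vmax")
})
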