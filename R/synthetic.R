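# Synthetic structure+trajectory generator with closed-form fluctuation
# expectations.  Motion model per CA atom i at frame t (1-based):
#
#   r_i(t) = base_i + drift * (t - 1) + A_i * sin(2*pi*(t-1)/P) * x_hat + eps
#
# eps ~ N(0, sigma_i * m_i(t)) i.i.d. per coordinate, where m_i(t) is the
# amplitude multiplier of any event covering (i, t), else 1.  An optional
# rigid tumble applies a random rotation+translation to every frame on top.
# Closed forms: the Gaussian term contributes sigma*sqrt(3) to RMSF; the
# sinusoid contributes A/sqrt(2) over whole periods; independent terms add in
# quadrature.

#' Specify a synthetic trajectory
#'
#' @param n_residues residues per chain.
#' @param n_frames stored frames.
#' @param dt_ps picoseconds per stored frame (default 10, a common save
#'   interval).
#' @param geometry `"line"` (CA every 3.8 Angstroms along x) or `"helix"`
#'   (ideal alpha-helix: rise 1.5 A, radius 2.3 A, 100 degrees/residue).
#' @param sigma per-coordinate Gaussian noise s.d. in Angstroms; scalar or
#'   one per residue.
#' @param amplitude sinusoid amplitude along x in Angstroms; scalar or one
#'   per residue.
#' @param period sinusoid period in frames.
#' @param events list of `list(residues =, frames =, multiplier =)`; 1-based
#'   inclusive residue and frame ranges whose noise s.d. is multiplied.
#' @param drift global drift vector in Angstroms per frame.
#' @param tumble apply a random rigid rotation+translation per frame.
#' @param n_chains 1 or 2 (chains A and B, offset 20 Angstroms in y).
#' @param backbone `"ca"` (default) or `"full"` (adds N, C, O at ideal
#'   geometry around each CA).
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_residues = 30, n_frames = 200, dt_ps = 10,
                           geometry = c("line", "helix"), sigma = 0.3,
                           amplitude = 0, period = 50, events = list(),
                           drift = c(0, 0, 0), tumble = FALSE, n_chains = 1,
                           backbone = c("ca", "full"), seed = 1) {
  geometry <- match.arg(geometry); backbone <- match.arg(backbone)
  stopifnot(n_residues >= 2, n_frames >= 1, dt_ps > 0, all(sigma >= 0),
            all(amplitude >= 0), period > 0, length(drift) == 3,
            n_chains %in% 1:2)
  sigma <- rep_len(sigma, n_residues)
  amplitude <- rep_len(amplitude, n_residues)
  for (ev in events) {
    stopifnot(all(ev$residues >= 1), all(ev$residues <= n_residues),
              all(ev$frames >= 1), all(ev$frames <= n_frames),
              ev$multiplier > 0)
  }
  structure(
    list(n_residues = n_residues, n_frames = n_frames, dt_ps = dt_ps,
         geometry = geometry, sigma = sigma, amplitude = amplitude,
         period = period, events = events, drift = as.numeric(drift),
         tumble = isTRUE(tumble), n_chains = n_chains, backbone = backbone,
         seed = as.integer(seed)),
    class = "SyntheticSpec"
  )
}

ca_geometry <- function(spec) {
  i <- seq_len(spec$n_residues) - 1
  if (spec$geometry == "line") {
    cbind(3.8 * i, 0, 0)
  } else {
    ang <- i * 100 * pi / 180
    cbind(1.5 * i, 2.3 * cos(ang), 2.3 * sin(ang))
  }
}

res_names <- c("ALA", "GLY", "SER", "VAL", "LEU", "THR", "LYS", "ASP",
               "GLU", "PHE")

#' Generate the trajectory of a synthetic spec in memory
#'
#' @param spec a `SyntheticSpec`.
#' @return `TrajectorySystem`.
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  nr <- spec$n_residues; nf <- spec$n_frames; nc <- spec$n_chains
  base1 <- ca_geometry(spec)

  # per-chain CA coordinates [nr, 3, nf]
  make_chain <- function(base) {
    mult <- matrix(1, nr, nf)
    for (ev in spec$events) mult[ev$residues, ev$frames] <- ev$multiplier
    co <- array(0, dim = c(nr, 3, nf))
    t0 <- seq_len(nf) - 1
    sin_term <- sin(2 * pi * t0 / spec$period)
    for (f in seq_len(nf)) {
      eps <- matrix(stats::rnorm(nr * 3), nr, 3) * (spec$sigma * mult[, f])
      co[, , f] <- base + eps +
        matrix(spec$drift * t0[f], nr, 3, byrow = TRUE) +
        cbind(spec$amplitude * sin_term[f], 0, 0)
    }
    co
  }
  chains <- lapply(seq_len(nc), function(c) {
    base <- base1
    base[, 2] <- base[, 2] + (c - 1) * 20
    make_chain(base)
  })
  ca <- do.call(function(...) {
    arrs <- list(...)
    out <- array(0, dim = c(nr * nc, 3, nf))
    for (c in seq_len(nc)) out[(c - 1) * nr + seq_len(nr), , ] <- arrs[[c]]
    out
  }, chains)

  chain_ids <- rep(LETTERS[seq_len(nc)], each = nr)
  resnames <- rep(rep_len(res_names, nr), nc)
  resids <- rep(seq_len(nr), nc)

  if (spec$backbone == "ca") {
    atoms <- data.frame(atom_name = "CA", residue_id = resids,
                        residue_name = resnames, chain_id = chain_ids,
                        element = "C", stringsAsFactors = FALSE)
    coords <- ca
  } else {
    # N, CA, C, O placed at fixed offsets from each CA (rigid per residue)
    offs <- rbind(N = c(-1.46, 0.0, 0.0), CA = c(0, 0, 0),
                  C = c(1.52, 0.0, 0.0), O = c(2.15, 1.05, 0.0))
    na_tot <- nr * nc * 4
    coords <- array(0, dim = c(na_tot, 3, nf))
    for (a in 1:4) {
      rows <- seq(a, na_tot, by = 4)
      coords[rows, , ] <- ca + array(rep(offs[a, ], each = nr * nc),
                                     dim = c(nr * nc, 3, nf))
    }
    atoms <- data.frame(
      atom_name = rep(rownames(offs), nr * nc),
      residue_id = rep(resids, each = 4),
      residue_name = rep(resnames, each = 4),
      chain_id = rep(chain_ids, each = 4),
      element = rep(c("N", "C", "C", "O"), nr * nc),
      stringsAsFactors = FALSE)
  }

  if (spec$tumble) {
    for (f in seq_len(nf)) {
      rot <- random_rotation()
      shift <- stats::rnorm(3, sd = 5)
      coords[, , f] <- sweep(coords[, , f] %*% t(rot), 2, shift, `+`)
    }
  }
  trajectory_system(atoms, coords, spec$dt_ps,
                    source_paths = sprintf("synthetic(seed=%d)", spec$seed))
}

# Uniform random rotation (QR of a Gaussian matrix, det corrected to +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  q %*% diag(c(1, 1, det(q)))
}

#' Generate and write a synthetic structure + trajectory pair
#'
#' Writes `structure.pdb` (frame 1), `traj.pdb` (multi-model) and `traj.dcd`
#' into `out_dir`.  With a fixed seed the files are byte-identical across
#' runs.
#'
#' @param spec a `SyntheticSpec`.
#' @param out_dir output directory (created).
#' @return list with `system` and file `paths`.
#' @export
generate <- function(spec, out_dir) {
  sys <- generate_trajectory(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  structure_path <- file.path(out_dir, "structure.pdb")
  write_pdb_frame(sys, 1, path = structure_path)
  traj_pdb <- file.path(out_dir, "traj.pdb")
  write_multimodel_pdb(sys, traj_pdb)
  traj_dcd <- file.path(out_dir, "traj.dcd")
  write_dcd(sys$coords, traj_dcd, dt_ps = sys$dt_ps)
  list(system = sys,
       paths = list(structure = structure_path, traj_pdb = traj_pdb,
                    traj_dcd = traj_dcd))
}

#' Write all frames of a system as a multi-model PDB
#'
#' @param system `TrajectorySystem`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (f in seq_len(n_frames(system))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    write_pdb_frame(system, f, path = tmp)
    body <- readLines(tmp)
    writeLines(body[body != "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Analytic per-residue RMSF expectation of a synthetic spec
#'
#' `sqrt(3 * sigma_i^2 + A_i^2 / 2)`: the isotropic Gaussian term contributes
#' `sigma * sqrt(3)`, the sinusoid `A / sqrt(2)` (valid over whole periods);
#' events are not folded in (the expectation describes baseline windows).
#'
#' @param spec a `SyntheticSpec`.
#' @param window_frames window length the expectation is for; must be a
#'   multiple of the sinusoid period when any amplitude is nonzero.
#' @return numeric vector, one expected RMSF (Angstroms) per residue.
#' @export
expected_rmsf <- function(spec, window_frames = spec$n_frames) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  if (any(spec$amplitude > 0) && window_frames %% spec$period != 0) {
    stop("window (", window_frames, " frames) is not a whole number of ",
         "sinusoid periods (", spec$period, ")")
  }
  sqrt(3 * spec$sigma^2 + spec$amplitude^2 / 2)
}
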