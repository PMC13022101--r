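# In-memory model of a structure + trajectory and the file formats feeding it.
#
# A TrajectorySystem holds an atom table and a dense coordinate array
# [n_atoms x 3 x n_frames] in Angstroms, plus the time step between stored
# frames (dt_ps).  Residue identity is (chain_id, residue_id) with author
# numbering; insertion codes are rejected.

#' Construct a TrajectorySystem
#'
#' @param atoms data.frame with columns `atom_name`, `residue_id` (integer,
#'   author numbering), `residue_name`, `chain_id`, `element`.
#' @param coords numeric array `n_atoms x 3 x n_frames`, Angstroms.
#' @param dt_ps time between stored frames in picoseconds (> 0).
#' @param source_paths character vector of provenance strings.
#' @return object of class `TrajectorySystem`.
#' @export
trajectory_system <- function(atoms, coords, dt_ps, source_paths = character()) {
  required <- c("atom_name", "residue_id", "residue_name", "chain_id", "element")
  if (!is.data.frame(atoms) || !all(required %in% names(atoms))) {
    stop("`atoms` must be a data.frame with columns: ",
         paste(required, collapse = ", "))
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != 3L) {
    stop("`coords` must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(atoms)) {
    stop("coordinate array has ", dim(coords)[1], " atoms but atom table has ",
         nrow(atoms))
  }
  if (!is.numeric(dt_ps) || length(dt_ps) != 1L || is.na(dt_ps) || dt_ps <= 0) {
    stop("`dt_ps` must be a single positive number (picoseconds per frame)")
  }
  atoms$residue_id <- as.integer(atoms$residue_id)
  structure(
    list(atoms = atoms, coords = coords, dt_ps = as.numeric(dt_ps),
         source_paths = as.character(source_paths)),
    class = "TrajectorySystem"
  )
}

#' @export
print.TrajectorySystem <- function(x, ...) {
  cat("<TrajectorySystem> ", n_atoms(x), " atoms, ",
      length(unique(residue_keys(x))), " residues, ",
      n_frames(x), " frames @ ", x$dt_ps, " ps/frame\n", sep = "")
  invisible(x)
}

#' Number of atoms / frames in a system
#' @param system a `TrajectorySystem`
#' @return integer count
#' @export
n_atoms <- function(system) dim(system$coords)[1]

#' @rdname n_atoms
#' @export
n_frames <- function(system) dim(system$coords)[3]

# Unique residue key strings in atom order ("chain|resid").
residue_keys <- function(system, indices = seq_len(n_atoms(system))) {
  paste(system$atoms$chain_id[indices], system$atoms$residue_id[indices],
        sep = "|")
}

# ---------------------------------------------------------------------------
# PDB reading (fixed-column v3.3 coordinate records, multi-model)

#' Read a (possibly multi-model) PDB file
#'
#' Parses ATOM/HETATM records; each MODEL block becomes one frame.  Files
#' without MODEL records yield a single frame.  Insertion codes are not
#' supported and raise an error.
#'
#' @param path PDB file path.
#' @param dt_ps time step to attach (default 1; override via [load_system()]).
#' @return `TrajectorySystem`; B-factors of the first model are attached as
#'   attribute `bfactors`.
#' @export
read_pdb <- function(path, dt_ps = 1) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  atom_model <- match(atom_model, unique(atom_model))
  nf <- max(atom_model)
  per_frame <- tabulate(atom_model, nf)
  if (length(unique(per_frame)) != 1L) {
    stop("models in ", path, " have differing atom counts: ",
         paste(unique(per_frame), collapse = ", "))
  }
  na <- per_frame[1]

  first <- atom_lines[atom_model == 1L]
  icode <- trimws(substr(first, 27, 27))
  if (any(icode != "")) {
    stop("insertion codes are not supported (found in ", path, ")")
  }
  atoms <- data.frame(
    atom_name    = trimws(substr(first, 13, 16)),
    residue_id   = as.integer(substr(first, 23, 26)),
    residue_name = trimws(substr(first, 18, 20)),
    chain_id     = {
      ch <- substr(first, 22, 22)
      ifelse(ch == " ", "A", ch)
    },
    element      = trimws(substr(first, 77, 78)),
    stringsAsFactors = FALSE
  )
  # fall back to first letter of the atom name when the element field is blank
  blank <- atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9]", "", atoms$atom_name[blank]), 1, 1)

  xyz <- cbind(as.numeric(substr(atom_lines, 31, 38)),
               as.numeric(substr(atom_lines, 39, 46)),
               as.numeric(substr(atom_lines, 47, 54)))
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (f in seq_len(nf)) coords[, , f] <- xyz[atom_model == f, , drop = FALSE]

  sys <- trajectory_system(atoms, coords, dt_ps, source_paths = path)
  attr(sys, "bfactors") <- as.numeric(substr(first, 61, 66))
  attr(sys, "remarks") <- lines[startsWith(lines, "REMARK")]
  sys
}

# ---------------------------------------------------------------------------
# DCD (CHARMM/NAMD binary, Fortran sequential records)

# AKMA time unit in picoseconds; DCD stores the integration step in AKMA.
.akma_ps <- 0.04888821

read_dcd_header <- function(con, swap) {
  rd_i <- function(n) readBin(con, "integer", n, size = 4, endian = if (swap) "swap" else "little")
  m <- rd_i(1)
  if (length(m) == 0) stop("empty DCD file")
  if (m != 84) stop("not a DCD file (first record length ", m, ", expected 84)")
  tag <- readChar(con, 4, useBytes = TRUE)
  if (tag != "CORD") stop("not a coordinate DCD (tag '", tag, "')")
  icntrl_raw <- readBin(con, "raw", 80)
  icntrl <- readBin(icntrl_raw, "integer", 20, size = 4,
                    endian = if (swap) "swap" else "little")
  rd_i(1)                                      # trailing marker
  charmm <- icntrl[20] != 0L
  delta <- if (charmm) {
    readBin(icntrl_raw[37:40], "numeric", 1, size = 4,
            endian = if (swap) "swap" else "little")
  } else {
    NA_real_
  }
  ntitle_len <- rd_i(1)
  ntitle <- rd_i(1)
  if (ntitle > 0) readBin(con, "raw", 80 * ntitle)
  rd_i(1)
  if (rd_i(1) != 4) stop("malformed DCD natoms record")
  natoms <- rd_i(1)
  rd_i(1)
  list(nframes = icntrl[1], nsavc = icntrl[3], delta = delta,
       has_cell = charmm && icntrl[11] != 0L, natoms = natoms)
}

#' Read a DCD trajectory
#'
#' Supports CHARMM/NAMD-style DCD with optional unit-cell blocks (skipped) and
#' either byte order.
#'
#' @param path DCD file path.
#' @return list with `coords` (`n_atoms x 3 x n_frames`) and `dt_ps` (from the
#'   stored integration step, `NA` if absent).
#' @export
read_dcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1, size = 4, endian = "little")
  swap <- !identical(first, 84L)
  seek(con, 0)
  hdr <- read_dcd_header(con, swap)
  endian <- if (swap) "swap" else "little"
  na <- hdr$natoms
  frames <- list()
  repeat {
    if (hdr$has_cell) {
      m <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (length(m) == 0) break
      readBin(con, "raw", m + 4)               # 6 doubles + trailing marker
    }
    m <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (length(m) == 0) break
    if (m != 4 * na) stop("malformed DCD frame record (length ", m, ")")
    xyz <- matrix(NA_real_, na, 3)
    for (ax in 1:3) {
      if (ax > 1) {
        m <- readBin(con, "integer", 1, size = 4, endian = endian)
        if (m != 4 * na) stop("malformed DCD frame record")
      }
      xyz[, ax] <- readBin(con, "numeric", na, size = 4, endian = endian)
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
    frames[[length(frames) + 1L]] <- xyz
  }
  if (!length(frames)) stop("DCD file ", path, " contains no frames")
  coords <- array(unlist(frames), dim = c(na, 3, length(frames)))
  dt_ps <- if (is.finite(hdr$delta) && hdr$delta > 0) {
    hdr$delta * max(hdr$nsavc, 1L) * .akma_ps
  } else NA_real_
  list(coords = coords, dt_ps = dt_ps)
}

#' Write a DCD trajectory
#'
#' Emits a little-endian CHARMM-format DCD (version 24, no unit cell).
#'
#' @param coords `n_atoms x 3 x n_frames` array, Angstroms.
#' @param path output path.
#' @param dt_ps time between frames in ps (stored as the AKMA step).
#' @return `path`, invisibly.
#' @export
write_dcd <- function(coords, path, dt_ps = 1) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  na <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wr_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[20] <- 24L
  wr_i(84); writeChar("CORD", con, eos = NULL)
  for (k in seq_len(20)) {
    if (k == 10) {
      writeBin(as.numeric(dt_ps / .akma_ps), con, size = 4, endian = "little")
    } else wr_i(icntrl[k])
  }
  wr_i(84)
  title <- sprintf("%-80s", "generated by the rmsx package")
  wr_i(80 + 4); wr_i(1); writeChar(title, con, eos = NULL); wr_i(80 + 4)
  wr_i(4); wr_i(na); wr_i(4)
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      wr_i(4 * na)
      writeBin(as.numeric(coords[, ax, f]), con, size = 4, endian = "little")
      wr_i(4 * na)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# TRR (GROMACS, XDR big-endian, uncompressed)

.trr_magic <- 1993L

#' Read a TRR trajectory
#'
#' Uncompressed GROMACS TRR, single or double precision.  Velocities and
#' forces are skipped; only positions are returned.  Positions are converted
#' from nm to Angstroms.
#'
#' @param path TRR file path.
#' @return list with `coords` (`n_atoms x 3 x n_frames`, Angstroms) and
#'   `dt_ps` (from successive frame times, `NA` for single-frame files).
#' @export
read_trr <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_i <- function(n = 1) readBin(con, "integer", n, size = 4, endian = "big")
  frames <- list(); times <- numeric()
  repeat {
    magic <- rd_i(1)
    if (length(magic) == 0) break
    if (magic != .trr_magic) stop("not a TRR file (magic ", magic, ")")
    rd_i(1)                                    # format version
    slen <- rd_i(1)                            # tag length incl. NUL
    readBin(con, "raw", (slen %/% 4 + (slen %% 4 > 0)) * 4)
    sz <- rd_i(13)        # ir e box vir pres top sym x v f natoms step nre
    box_size <- sz[3]; x_size <- sz[8]; v_size <- sz[9]; f_size <- sz[10]
    natoms <- sz[11]
    if (x_size == 0) stop("TRR frame without positions in ", path)
    real_sz <- if (x_size %/% (3L * natoms) == 8L) 8L else 4L
    rd_r <- function(n) readBin(con, "numeric", n, size = real_sz, endian = "big")
    t_lambda <- rd_r(2)
    if (box_size > 0) rd_r(9)
    if (sz[4] > 0) rd_r(9)                     # virial
    if (sz[5] > 0) rd_r(9)                     # pressure
    xyz <- matrix(rd_r(3L * natoms), ncol = 3, byrow = TRUE) * 10  # nm -> A
    if (v_size > 0) rd_r(3L * natoms)
    if (f_size > 0) rd_r(3L * natoms)
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t_lambda[1])
  }
  if (!length(frames)) stop("TRR file ", path, " contains no frames")
  coords <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  dt_ps <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  if (isTRUE(dt_ps <= 0)) dt_ps <- NA_real_
  list(coords = coords, dt_ps = dt_ps)
}

#' Write a TRR trajectory
#'
#' Single-precision positions only (converted to nm), zero box, frame times
#' `(0, dt_ps, 2*dt_ps, ...)`.
#'
#' @inheritParams write_dcd
#' @return `path`, invisibly.
#' @export
write_trr <- function(coords, path, dt_ps = 1) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  na <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wr_i <- function(x) writeBin(as.integer(x), con, size = 4, endian = "big")
  wr_f <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "big")
  tag <- "GMX_trn_file"
  for (f in seq_len(nf)) {
    wr_i(.trr_magic); wr_i(13L)
    wr_i(nchar(tag) + 1L)
    raw_tag <- c(charToRaw(tag), as.raw(0))
    pad <- (4 - length(raw_tag) %% 4) %% 4
    writeBin(c(raw_tag, rep(as.raw(0), pad)), con)
    x_size <- 3L * na * 4L
    wr_i(c(0L, 0L, 0L, 0L, 0L, 0L, 0L,        # ir e box vir pres top sym
           x_size, 0L, 0L, na, f - 1L, 0L))
    wr_f(c((f - 1L) * dt_ps, 0))               # time, lambda
    wr_f(t(coords[, , f]) / 10)                # A -> nm, xdr row order
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Loading

.protein_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX", "MSE", "SEC", "PYL"
)

#' Load a structure + trajectory into a TrajectorySystem
#'
#' The structure file (PDB) defines the atom table; the trajectory supplies
#' the frames.  When `trajectory_path` is `NULL` the structure's own models
#' are the frames.  Trajectory formats: multi-model PDB, DCD, TRR.  XTC is
#' recognised but not supported (its compressed coordinate codec is out of
#' scope); convert to DCD or TRR first.
#'
#' @param structure_path PDB structure.
#' @param trajectory_path trajectory file, or `NULL` to use the structure's
#'   models.
#' @param dt_ps_override explicit time step (ps); takes precedence over file
#'   metadata.  If neither is available an error asks for a value.
#' @param selection selection string applied on load (default `"protein"`,
#'   which strips waters, ions and other hetero residues); `NULL` keeps all
#'   atoms.
#' @return `TrajectorySystem`.
#' @export
load_system <- function(structure_path, trajectory_path = NULL,
                        dt_ps_override = NULL, selection = "protein") {
  ref <- read_pdb(structure_path)
  ext <- tolower(tools::file_ext(if (is.null(trajectory_path)) structure_path
                                 else trajectory_path))
  if (is.null(trajectory_path)) {
    traj <- list(coords = ref$coords, dt_ps = NA_real_)
  } else {
    traj <- switch(ext,
      pdb = {
        p <- read_pdb(trajectory_path)
        list(coords = p$coords, dt_ps = NA_real_)
      },
      dcd = read_dcd(trajectory_path),
      trr = read_trr(trajectory_path),
      xtc = stop("XTC is not supported (compressed coordinate codec); ",
                 "convert ", trajectory_path, " to DCD or TRR"),
      stop("unreadable trajectory format '", ext, "' for ", trajectory_path,
           "; expected one of: pdb, dcd, trr")
    )
    if (dim(traj$coords)[1] != n_atoms(ref)) {
      stop("atom-count mismatch: structure ", structure_path, " has ",
           n_atoms(ref), " atoms but trajectory ", trajectory_path, " has ",
           dim(traj$coords)[1])
    }
  }
  dt <- if (!is.null(dt_ps_override)) {
    as.numeric(dt_ps_override)
  } else if (is.finite(traj$dt_ps) && traj$dt_ps > 0) {
    traj$dt_ps
  } else {
    stop("time step unknown: supply dt_ps_override (ps per stored frame); ",
         "the trajectory file carries no usable time metadata")
  }
  sys <- trajectory_system(ref$atoms, traj$coords, dt,
                           source_paths = c(structure_path,
                                            trajectory_path %||% character()))
  if (!is.null(selection)) {
    sel <- select_atoms(sys, selection, allow_empty = TRUE)
    if (length(sel$indices) > 0 && length(sel$indices) < n_atoms(sys)) {
      sys <- subset_system(sys, sel$indices)
    }
  }
  sys
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a system to the given atom indices (all frames kept).
subset_system <- function(system, indices) {
  trajectory_system(system$atoms[indices, , drop = FALSE],
                    system$coords[indices, , , drop = FALSE],
                    system$dt_ps, system$source_paths)
}

#' Split a system by chain
#'
#' @param system `TrajectorySystem` with at least one chain.
#' @return named list of `TrajectorySystem`, one per chain id, in order of
#'   first appearance.  The union of the subsystems' atoms is the parent's.
#' @export
split_chains <- function(system) {
  chains <- unique(system$atoms$chain_id)
  out <- lapply(chains, function(ch) {
    subset_system(system, which(system$atoms$chain_id == ch))
  })
  names(out) <- chains
  out
}

# ---------------------------------------------------------------------------
# Atom selection

#' Select atoms by a predicate string
#'
#' Mini-language: clauses joined by `and`.  Clauses: `name N1 N2 ...`,
#' `chain C1 C2 ...`, `resid A-B` (or `resid N`), `protein`, `all`.
#' The conventional per-residue metric selection is `"name CA"` (one
#' alpha-carbon per residue).
#'
#' @param system `TrajectorySystem`.
#' @param predicate selection string.
#' @param allow_empty if `FALSE` (default) an empty result is an error naming
#'   the predicate.
#' @return object of class `AtomSelection`: list with `predicate` and
#'   `indices` (unique, ascending atom indices).
#' @export
select_atoms <- function(system, predicate, allow_empty = FALSE) {
  at <- system$atoms
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(trimws(predicate), "\\s+and\\s+")[[1]]
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) == 0) next
    keep <- keep & switch(tolower(tok[1]),
      all     = rep(TRUE, nrow(at)),
      protein = at$residue_name %in% .protein_residues,
      name    = {
        if (length(tok) < 2) stop("selection clause 'name' needs arguments")
        toupper(at$atom_name) %in% toupper(tok[-1])
      },
      chain   = {
        if (length(tok) < 2) stop("selection clause 'chain' needs arguments")
        at$chain_id %in% tok[-1]
      },
      resid   = {
        if (length(tok) != 2) stop("selection clause 'resid' needs one range")
        rng <- as.integer(strsplit(tok[2], "-")[[1]])
        if (length(rng) == 1) rng <- c(rng, rng)
        at$residue_id >= rng[1] & at$residue_id <= rng[2]
      },
      stop("unknown selection clause '", tok[1], "' in predicate '",
           predicate, "'")
    )
  }
  idx <- which(keep)
  if (length(idx) == 0 && !allow_empty) {
    stop("empty atom selection for predicate '", predicate, "'")
  }
  structure(list(predicate = predicate, indices = idx),
            class = "AtomSelection")
}

# Resolve a selection argument: NULL -> default "name CA", string -> parsed,
# AtomSelection -> as is, integer vector -> wrapped.
resolve_selection <- function(system, selection) {
  if (is.null(selection)) selection <- "name CA"
  if (inherits(selection, "AtomSelection")) return(selection)
  if (is.numeric(selection)) {
    return(structure(list(predicate = "<indices>",
                          indices = sort(unique(as.integer(selection)))),
                     class = "AtomSelection"))
  }
  select_atoms(system, selection)
}

# ---------------------------------------------------------------------------
# PDB writing

format_atom_name <- function(name) {
  # names up to 3 chars start in column 14; 4-char names fill 13-16
  ifelse(nchar(name) >= 4, substr(name, 1, 4), sprintf(" %-3s", name))
}

#' Write one frame as a fixed-column PDB with B-factor annotation
#'
#' Coordinates go to columns 31-54 (`%8.3f`), B-factors to columns 61-66
#' (`%6.2f`, clamped to `[0, 999.99]`).  `bfactors` may give one value per
#' atom or one per residue (broadcast to the residue's atoms).
#'
#' @param system `TrajectorySystem`.
#' @param frame_index 1-based frame to write.
#' @param bfactors numeric, length `n_atoms` or one per residue; default 0.
#' @param path output path.
#' @param remarks optional character vector written as leading REMARK lines
#'   (must already start with `"REMARK"`).
#' @return `path`, invisibly.
#' @export
write_pdb_frame <- function(system, frame_index, bfactors = NULL, path,
                            remarks = NULL) {
  nf <- n_frames(system)
  if (frame_index < 1 || frame_index > nf) {
    stop("frame_index ", frame_index, " out of range [1, ", nf, "]")
  }
  na <- n_atoms(system)
  keys <- residue_keys(system)
  ukeys <- unique(keys)
  if (is.null(bfactors)) bfactors <- rep(0, na)
  if (length(bfactors) == length(ukeys) && length(ukeys) != na) {
    bfactors <- bfactors[match(keys, ukeys)]
  }
  if (length(bfactors) != na) {
    stop("bfactors must have one value per atom (", na, ") or per residue (",
         length(ukeys), "); got ", length(bfactors))
  }
  b <- pmin(pmax(ifelse(is.na(bfactors), 0, bfactors), 0), 999.99)
  xyz <- system$coords[, , frame_index, drop = FALSE]
  at <- system$atoms
  lines <- sprintf(
    "ATOM  %5d %s%s%3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(na) %% 100000L,
    format_atom_name(at$atom_name), " ",
    substr(at$residue_name, 1, 3),
    substr(at$chain_id, 1, 1),
    at$residue_id %% 10000L, " ",
    xyz[, 1, 1], xyz[, 2, 1], xyz[, 3, 1],
    1.00, b,
    substr(at$element, 1, 2)
  )
  # TER after the last atom of each chain
  chain_rle <- rle(at$chain_id)
  ter_after <- cumsum(chain_rle$lengths)
  out <- character(0)
  if (!is.null(remarks)) {
    stopifnot(all(startsWith(remarks, "REMARK")))
    out <- remarks
  }
  prev <- 0L
  for (k in seq_along(ter_after)) {
    out <- c(out, lines[(prev + 1L):ter_after[k]], "TER")
    prev <- ter_after[k]
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
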