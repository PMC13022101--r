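# Least-squares rigid-body superposition (Kabsch) and RMSD series.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the (weighted) RMSD
#' between paired point sets; the reflection branch is corrected so the
#' rotation determinant is +1.
#'
#' @param mobile,ref `n x 3` matrices of paired points (n >= 3,
#'   non-collinear).
#' @param weights optional non-negative weights, length n (default uniform).
#' @return object of class `RigidTransform`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd_after` (Angstroms).  The fitted coordinates are
#'   `mobile %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n < 3 || nrow(ref) != n || ncol(mobile) != 3 || ncol(ref) != 3) {
    stop("kabsch_fit needs two equal n x 3 point sets with n >= 3")
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, length n, with positive sum")
  }
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  M <- sweep(mobile, 2, cm); R <- sweep(ref, 2, cr)
  sv_m <- svd(M * sqrt(w))$d
  if (sv_m[2] < 1e-8 * max(sv_m[1], 1e-12)) {
    stop("degenerate geometry: points are collinear or coincident")
  }
  H <- t(M * w) %*% R
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cr - as.vector(rot %*% cm)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - R)^2)))
  structure(list(rotation = rot, translation = trans, rmsd_after = rmsd),
            class = "RigidTransform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords `n x 3` matrix.
#' @param transform a `RigidTransform`.
#' @return transformed `n x 3` matrix.
#' @export
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' Superpose every frame of a trajectory onto a reference frame
#'
#' The fit uses only the atoms of `selection`; the resulting transform is
#' applied to all atoms of the frame.
#'
#' @param system `TrajectorySystem`.
#' @param selection selection string, `AtomSelection` or atom indices;
#'   default one alpha-carbon per residue (`"name CA"`).
#' @param reference_frame 1-based frame to align onto (default 1).
#' @param weights optional per-fit-atom weights (e.g. masses).
#' @return a new aligned `TrajectorySystem`.
#' @export
align_trajectory <- function(system, selection = NULL, reference_frame = 1,
                             weights = NULL) {
  sel <- resolve_selection(system, selection)
  idx <- sel$indices
  ref <- system$coords[idx, , reference_frame, drop = TRUE]
  out <- system$coords
  for (f in seq_len(n_frames(system))) {
    tf <- kabsch_fit(out[idx, , f], ref, weights)
    out[, , f] <- apply_transform(out[, , f], tf)
  }
  trajectory_system(system$atoms, out, system$dt_ps, system$source_paths)
}

#' Per-frame RMSD versus a reference frame
#'
#' Each frame is optimally superposed onto the reference on the fit selection
#' before the RMSD is evaluated on that same selection.
#'
#' @inheritParams align_trajectory
#' @param frames 1-based frame indices to evaluate (default all).
#' @return object of class `RmsdSeries`: list with `frame_indices`, `values`
#'   (Angstroms), `time_ns` and `reference_frame`.
#' @export
rmsd_series <- function(system, selection = NULL, reference_frame = 1,
                        frames = seq_len(n_frames(system)), weights = NULL) {
  sel <- resolve_selection(system, selection)
  idx <- sel$indices
  ref <- system$coords[idx, , reference_frame, drop = TRUE]
  vals <- vapply(frames, function(f) {
    kabsch_fit(system$coords[idx, , f], ref, weights)$rmsd_after
  }, numeric(1))
  structure(
    list(frame_indices = frames, values = vals,
         time_ns = (frames - 1) * system$dt_ps / 1000,
         reference_frame = reference_frame),
    class = "RmsdSeries"
  )
}
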