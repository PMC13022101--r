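# Core per-residue metrics: windowed RMSF (RMSX), classical RMSF, shift
# maps, per-residue lDDT time series, Pearson benchmarking, and the
# window_check window-size heuristic.
#
# All metrics operate on one representative atom per residue (the
# alpha-carbon by default) or, in "all-atom mean" mode, on per-atom values
# averaged within the residue.

# ---------------------------------------------------------------------------
# MetricMatrix container

new_metric_matrix <- function(kind, values, residue_labels, time_axis,
                              time_edges = NULL, plan = NULL) {
  kind <- match.arg(kind, c("rmsx", "shift", "lddt"))
  stopifnot(is.matrix(values), nrow(values) == nrow(residue_labels),
            ncol(values) == length(time_axis))
  if (kind %in% c("rmsx", "shift") && any(values < 0, na.rm = TRUE)) {
    stop(kind, " values must be >= 0")
  }
  if (kind == "lddt" &&
      any(values < 0 | values > 1, na.rm = TRUE)) {
    stop("lddt values must lie in [0, 1]")
  }
  structure(
    list(kind = kind, values = values, residue_labels = residue_labels,
         time_axis = time_axis, time_edges = time_edges, plan = plan),
    class = "MetricMatrix"
  )
}

#' @export
print.MetricMatrix <- function(x, ...) {
  cat("<MetricMatrix kind=", x$kind, "> ", nrow(x$values), " residues x ",
      ncol(x$values), " time bins\n", sep = "")
  invisible(x)
}

# Residue label table for a selection: one row per unique (chain, resid).
selection_residues <- function(system, sel) {
  at <- system$atoms[sel$indices, , drop = FALSE]
  keys <- paste(at$chain_id, at$residue_id, sep = "|")
  first <- !duplicated(keys)
  data.frame(chain_id = at$chain_id[first],
             residue_id = at$residue_id[first],
             residue_name = at$residue_name[first],
             stringsAsFactors = FALSE)
}

# Map each selected atom to its residue row (1-based) in selection_residues.
selection_residue_index <- function(system, sel) {
  at <- system$atoms[sel$indices, , drop = FALSE]
  keys <- paste(at$chain_id, at$residue_id, sep = "|")
  match(keys, unique(keys))
}

# ---------------------------------------------------------------------------
# RMSF within a window

#' Per-atom RMSF of a coordinate block
#'
#' `RMSF_i = sqrt(mean_t || r_i(t) - <r_i> ||^2)` with `<r_i>` the mean
#' position over the block's frames.
#'
#' @param coords `n_atoms x 3 x T` array with `T >= 2`.
#' @return numeric vector of per-atom RMSF values (Angstroms).
#' @export
window_rmsf <- function(coords) {
  d <- dim(coords)
  if (length(d) != 3L || d[2] != 3L) stop("coords must be n x 3 x T")
  if (d[3] < 2L) stop("window too short for fluctuation (T = ", d[3],
                      ", need >= 2 frames)")
  mu <- rowMeans(coords, dims = 2)
  dev <- coords - array(mu, dim = d)
  sqrt(rowSums(dev^2, dims = 1) / d[3])
}

# Per-residue RMSF of selected atoms: per-atom RMSF then averaged within the
# residue (a single CA per residue reduces to the per-atom value).
residue_rmsf <- function(coords_sel, res_index) {
  v <- window_rmsf(coords_sel)
  as.vector(tapply(v, res_index, mean))
}

align_for_metric <- function(system, sel, frames, align_mode) {
  sub <- trajectory_system(system$atoms,
                           system$coords[, , frames, drop = FALSE],
                           system$dt_ps, system$source_paths)
  if (align_mode == "none") return(sub)
  align_trajectory(sub, sel$indices, reference_frame = 1)
}

#' Time-windowed per-residue fluctuation matrix (RMSX)
#'
#' Computes a standard per-residue RMSF independently within each window of
#' `plan` and assembles the profiles into a residues x slices matrix.
#'
#' @param system `TrajectorySystem`.
#' @param plan `SlicePlan` over the system's frames.
#' @param selection selection (default `"name CA"`).
#' @param align_mode `"global"` (align the whole analyzed range once onto its
#'   first frame; default), `"per_window"` (each window aligned to its own
#'   mean structure, one refinement pass), or `"none"` (trajectory assumed
#'   pre-aligned).
#' @return `MetricMatrix` with `kind = "rmsx"`.
#' @export
compute_rmsx <- function(system, plan, selection = NULL,
                         align_mode = c("global", "per_window", "none")) {
  align_mode <- match.arg(align_mode)
  sel <- resolve_selection(system, selection)
  res_index <- selection_residue_index(system, sel)
  frames <- analyzed_frames(plan)

  if (align_mode == "global") {
    work <- align_for_metric(system, sel, frames, "global")
  } else {
    work <- align_for_metric(system, sel, frames, "none")
  }
  cs <- work$coords[sel$indices, , , drop = FALSE]

  vals <- vapply(seq_len(plan$n_slices), function(k) {
    rel <- slice_frames(plan, k) - plan$start_frame
    block <- cs[, , rel, drop = FALSE]
    if (align_mode == "per_window") {
      block <- align_window_to_mean(block)
    }
    residue_rmsf(block, res_index)
  }, numeric(max(res_index)))
  vals <- matrix(vals, nrow = max(res_index))

  edges <- slice_time_axis(plan, "edges")
  new_metric_matrix("rmsx", vals, selection_residues(system, sel),
                    time_axis = slice_time_axis(plan, "midpoints"),
                    time_edges = edges, plan = plan)
}

# Align a coordinate block to its mean structure: fit to the first frame,
# then one refinement pass against the mean of the fitted frames.
align_window_to_mean <- function(block) {
  fit_all <- function(block, ref) {
    for (f in seq_len(dim(block)[3])) {
      tf <- kabsch_fit(block[, , f], ref)
      block[, , f] <- apply_transform(block[, , f], tf)
    }
    block
  }
  block <- fit_all(block, block[, , 1])
  fit_all(block, rowMeans(block, dims = 2))
}

#' Classical whole-trajectory RMSF
#'
#' Identical to [compute_rmsx()] with a single window spanning the analyzed
#' range.
#'
#' @inheritParams compute_rmsx
#' @param start_frame,end_frame 0-based half-open range (default all frames).
#' @return numeric vector, one RMSF (Angstroms) per residue of the selection.
#' @export
classic_rmsf <- function(system, selection = NULL, start_frame = 0,
                         end_frame = n_frames(system),
                         align_mode = c("global", "per_window", "none")) {
  align_mode <- match.arg(align_mode)
  plan <- plan_slices(n_frames(system), start_frame, end_frame,
                      n_slices = 1, dt_ps = system$dt_ps)
  m <- compute_rmsx(system, plan, selection, align_mode)
  as.vector(m$values[, 1])
}

#' Axis means of an RMSX matrix
#'
#' `mean_rmsx_per_residue` averages across slices (the time-averaged RMSX per
#' residue); `mean_rmsx_per_slice` averages across residues (the mean-RMSX
#' time series).
#'
#' @param matrix a `MetricMatrix` of kind `rmsx`.
#' @return numeric vector of means along the stated axis.
#' @export
mean_rmsx_per_residue <- function(matrix) {
  stopifnot(inherits(matrix, "MetricMatrix"), matrix$kind == "rmsx")
  rowMeans(matrix$values)
}

#' @rdname mean_rmsx_per_residue
#' @export
mean_rmsx_per_slice <- function(matrix) {
  stopifnot(inherits(matrix, "MetricMatrix"), matrix$kind == "rmsx")
  colMeans(matrix$values)
}

# ---------------------------------------------------------------------------
# Shift map

#' Per-residue shift map (trajectory map)
#'
#' Entry `(i, t)` is the Euclidean displacement of residue i's selected atom
#' from its position in the reference frame, optionally after superposing
#' frame t onto the reference (default on; disable for pulling simulations
#' where lab-frame drift is the signal).
#'
#' @inheritParams compute_rmsx
#' @param reference_frame 1-based reference (default 1).
#' @param align superpose each frame onto the reference first (default TRUE).
#' @param frames 1-based frames to evaluate (default all).
#' @return `MetricMatrix` with `kind = "shift"` (columns = frames).
#' @export
shift_map <- function(system, selection = NULL, reference_frame = 1,
                      align = TRUE, frames = seq_len(n_frames(system))) {
  sel <- resolve_selection(system, selection)
  res_index <- selection_residue_index(system, sel)
  idx <- sel$indices
  ref <- system$coords[idx, , reference_frame, drop = TRUE]
  vals <- vapply(frames, function(f) {
    cur <- system$coords[idx, , f, drop = TRUE]
    if (align) {
      tf <- kabsch_fit(cur, ref)
      cur <- apply_transform(cur, tf)
    }
    d <- sqrt(rowSums((cur - ref)^2))
    as.vector(tapply(d, res_index, mean))
  }, numeric(max(res_index)))
  vals <- matrix(vals, nrow = max(res_index))
  new_metric_matrix("shift", vals, selection_residues(system, sel),
                    time_axis = (frames - 1) * system$dt_ps / 1000)
}

# ---------------------------------------------------------------------------
# Per-residue lDDT

#' Per-residue lDDT time series
#'
#' For every pair of selected atoms in different residues whose distance in
#' the reference frame is below the inclusion radius `r0`, the pair is
#' "preserved" at threshold tau in frame t when
#' `|d_ref - d_t| < tau`.  The score of residue i at frame t is the mean over
#' thresholds of the fraction of i's reference pairs preserved.  Residues
#' with no reference pair score `NA` (flagged, never 0).  Defaults follow the
#' published metric: CA atoms, `r0 = 15` Angstroms, thresholds
#' 0.5, 1, 2, 4 Angstroms.
#'
#' @inheritParams shift_map
#' @param r0 inclusion radius in Angstroms (> 0).
#' @param thresholds ascending positive tolerances in Angstroms.
#' @param per_slice optional `SlicePlan`; when given, per-frame scores are
#'   averaged within each slice and the result has one column per slice.
#' @return `MetricMatrix` with `kind = "lddt"`, values in `[0, 1]` or `NA`.
#' @export
lddt_series <- function(system, selection = NULL, reference_frame = 1,
                        r0 = 15, thresholds = c(0.5, 1, 2, 4),
                        frames = seq_len(n_frames(system)),
                        per_slice = NULL) {
  if (length(thresholds) == 0 || is.unsorted(thresholds, strictly = TRUE) ||
      any(thresholds <= 0)) {
    stop("thresholds must be non-empty, positive and strictly ascending")
  }
  if (r0 <= 0) stop("inclusion radius r0 must be > 0")
  sel <- resolve_selection(system, selection)
  res_index <- selection_residue_index(system, sel)
  n_res <- max(res_index)
  idx <- sel$indices
  ref <- system$coords[idx, , reference_frame, drop = TRUE]

  # pair list fixed by the reference frame: inter-residue, d_ref < r0
  dref <- as.matrix(stats::dist(ref))
  same_res <- outer(res_index, res_index, `==`)
  use <- upper.tri(dref) & dref < r0 & !same_res
  pairs <- which(use, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    vals <- matrix(NA_real_, n_res, length(frames))
  } else {
    d0 <- dref[use]
    ri <- res_index[pairs[, 1]]; rj <- res_index[pairs[, 2]]
    n_pairs_per_res <- tabulate(ri, n_res) + tabulate(rj, n_res)
    vals <- vapply(frames, function(f) {
      cur <- system$coords[idx, , f, drop = TRUE]
      dt <- sqrt(rowSums((cur[pairs[, 1], , drop = FALSE] -
                          cur[pairs[, 2], , drop = FALSE])^2))
      err <- abs(d0 - dt)
      score_num <- numeric(n_res)
      for (tau in thresholds) {
        ok <- err < tau
        score_num <- score_num + tabulate(ri[ok], n_res) +
          tabulate(rj[ok], n_res)
      }
      out <- score_num / (length(thresholds) * n_pairs_per_res)
      out[n_pairs_per_res == 0] <- NA_real_
      out
    }, numeric(n_res))
    vals <- matrix(vals, nrow = n_res)
  }
  time_ns <- (frames - 1) * system$dt_ps / 1000
  if (!is.null(per_slice)) {
    cols <- vapply(seq_len(per_slice$n_slices), function(k) {
      rel <- match(slice_frames(per_slice, k), frames)
      rowMeans(vals[, rel[!is.na(rel)], drop = FALSE])
    }, numeric(n_res))
    vals <- matrix(cols, nrow = n_res)
    time_ns <- slice_time_axis(per_slice, "midpoints")
  }
  new_metric_matrix("lddt", vals, selection_residues(system, sel),
                    time_axis = time_ns, plan = per_slice)
}

# ---------------------------------------------------------------------------
# Pearson correlation and the window-size heuristic

#' Pearson product-moment correlation
#'
#' @param x,y equal-length numeric vectors (length >= 3, each with nonzero
#'   variance).
#' @return list with `r` and `r_squared = r^2`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ: ", length(x),
                                   " vs ", length(y))
  if (length(x) < 3) stop("need at least 3 points for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate series: zero variance")
  }
  r <- stats::cor(x, y)
  list(r = r, r_squared = r^2)
}

#' Compare candidate window sizes against RMSD (window_check)
#'
#' For each candidate slice count: build a plan over the analyzed range,
#' compute the mean-RMSX-per-slice series and the per-slice mean of the
#' per-frame RMSD (relative to the first analyzed frame), and report their
#' Pearson r and R-squared.  Candidates that do not fit the range (or leave
#' fewer than 3 slices for a correlation) are marked skipped, not fatal.
#'
#' @inheritParams compute_rmsx
#' @param candidate_slice_counts integer candidates (default
#'   `c(4, 8, 16, 32, 64, 128)`).
#' @param start_frame,end_frame 0-based half-open analysis range.
#' @return object of class `WindowCheckReport`: data.frame with columns
#'   `n_slices`, `frames_per_slice`, `pearson_r`, `r_squared`, `skipped`,
#'   `reason`.
#' @export
window_check <- function(system, selection = NULL,
                         candidate_slice_counts = c(4, 8, 16, 32, 64, 128),
                         start_frame = 0, end_frame = n_frames(system),
                         align_mode = "global") {
  if (any(candidate_slice_counts < 2)) {
    stop("candidate slice counts must be >= 2")
  }
  sel <- resolve_selection(system, selection)
  range <- end_frame - start_frame
  rs <- rmsd_series(system, sel, reference_frame = start_frame + 1L,
                    frames = (start_frame + 1L):end_frame)
  rows <- lapply(candidate_slice_counts, function(ns) {
    fps <- range %/% ns
    if (fps < 2L) {
      return(data.frame(n_slices = ns, frames_per_slice = NA_integer_,
                        pearson_r = NA_real_, r_squared = NA_real_,
                        skipped = TRUE,
                        reason = "windows shorter than 2 frames"))
    }
    if (ns < 3L) {
      return(data.frame(n_slices = ns, frames_per_slice = fps,
                        pearson_r = NA_real_, r_squared = NA_real_,
                        skipped = TRUE,
                        reason = "fewer than 3 slices for a correlation"))
    }
    plan <- plan_slices(n_frames(system), start_frame, end_frame,
                        n_slices = ns, dt_ps = system$dt_ps)
    mx <- mean_rmsx_per_slice(compute_rmsx(system, plan, sel, align_mode))
    mr <- vapply(seq_len(ns), function(k) {
      mean(rs$values[slice_frames(plan, k) - start_frame])
    }, numeric(1))
    p <- tryCatch(pearson(mx, mr), error = function(e) list(
      r = NA_real_, r_squared = NA_real_))
    data.frame(n_slices = ns, frames_per_slice = fps, pearson_r = p$r,
               r_squared = p$r_squared, skipped = is.na(p$r),
               reason = if (is.na(p$r)) "degenerate correlation" else "")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("WindowCheckReport", class(out))
  out
}
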