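# Partitioning a frame range into equal consecutive windows.
#
# Frame ranges are 0-based half-open [start_frame, end_frame) internally; the
# command-line interface accepts 1-based frame numbers and converts.  When the
# range is not evenly divisible the excess frames at the END are dropped, and
# the plan records how many.

#' Plan a slicing of a frame range into equal windows
#'
#' Exactly one of `n_slices` / `frames_per_slice` must be given.  With
#' `n_slices`, `frames_per_slice = floor(range / n_slices)`; with
#' `frames_per_slice`, `n_slices = floor(range / frames_per_slice)`.  The
#' remainder (`dropped_frames`) is dropped from the end of the range, so the
#' first window always starts at `start_frame`.
#'
#' @param n_frames_available total frames in the trajectory.
#' @param start_frame,end_frame 0-based half-open analysis range; defaults
#'   cover all frames.
#' @param n_slices number of complete windows, or `NULL`.
#' @param frames_per_slice window length in frames, or `NULL`.
#' @param dt_ps time per frame in picoseconds.
#' @return object of class `SlicePlan` with fields `start_frame`, `end_frame`,
#'   `n_slices`, `frames_per_slice`, `dropped_frames`, `slice_bounds` (matrix
#'   of 0-based `[first, last_exclusive)` rows), `dt_ps`, `total_frames`
#'   (analyzed, excluding dropped) and `total_time_ns`.
#' @export
plan_slices <- function(n_frames_available, start_frame = 0,
                        end_frame = n_frames_available,
                        n_slices = NULL, frames_per_slice = NULL, dt_ps) {
  if (is.null(n_slices) == is.null(frames_per_slice)) {
    stop("give exactly one of n_slices or frames_per_slice")
  }
  if (!is.numeric(dt_ps) || dt_ps <= 0) stop("dt_ps must be > 0")
  start_frame <- as.integer(start_frame); end_frame <- as.integer(end_frame)
  if (start_frame < 0 || start_frame >= end_frame ||
      end_frame > n_frames_available) {
    stop("invalid frame range [", start_frame, ", ", end_frame,
         ") for ", n_frames_available, " available frames")
  }
  range <- end_frame - start_frame
  if (!is.null(n_slices)) {
    n_slices <- as.integer(n_slices)
    if (n_slices < 1) stop("n_slices must be >= 1")
    if (n_slices > range) stop("more slices requested (", n_slices,
                               ") than frames in range (", range, ")")
    frames_per_slice <- range %/% n_slices
  } else {
    frames_per_slice <- as.integer(frames_per_slice)
    if (frames_per_slice < 1) stop("frames_per_slice must be >= 1")
    if (frames_per_slice > range) {
      stop("window longer than trajectory: frames_per_slice ",
           frames_per_slice, " > range ", range)
    }
    n_slices <- range %/% frames_per_slice
  }
  dropped <- range - n_slices * frames_per_slice
  first <- start_frame + (seq_len(n_slices) - 1L) * frames_per_slice
  bounds <- cbind(first = first, last_exclusive = first + frames_per_slice)
  total <- n_slices * frames_per_slice
  structure(
    list(start_frame = start_frame, end_frame = end_frame,
         n_slices = n_slices, frames_per_slice = frames_per_slice,
         dropped_frames = dropped, slice_bounds = bounds,
         dt_ps = as.numeric(dt_ps),
         total_frames = total, total_time_ns = total * dt_ps / 1000),
    class = "SlicePlan"
  )
}

#' @export
print.SlicePlan <- function(x, ...) {
  cat(sprintf(
    "<SlicePlan> frames [%d, %d): %d slices x %d frames, %d dropped\n",
    x$start_frame, x$end_frame, x$n_slices, x$frames_per_slice,
    x$dropped_frames))
  cat(sprintf("  analyzed: %d frames = %.6g ns at %g ps/frame\n",
              x$total_frames, x$total_time_ns, x$dt_ps))
  invisible(x)
}

#' Slice boundary times in nanoseconds
#'
#' Edge time of slice k (0-based) is
#' `(start_frame + k * frames_per_slice) * dt_ps / 1000`.
#'
#' @param plan a `SlicePlan`.
#' @param type `"edges"` (length `n_slices + 1`) or `"midpoints"`
#'   (length `n_slices`).
#' @return numeric vector of times in ns, monotonically increasing.
#' @export
slice_time_axis <- function(plan, type = c("edges", "midpoints")) {
  type <- match.arg(type)
  edges <- (plan$start_frame + (0:plan$n_slices) * plan$frames_per_slice) *
    plan$dt_ps / 1000
  if (type == "edges") edges else (edges[-1] + edges[-length(edges)]) / 2
}

# 1-based R frame indices covered by slice k (1-based slice number).
slice_frames <- function(plan, k) {
  b <- plan$slice_bounds[k, ]
  (b[[1]] + 1L):b[[2]]
}

# 1-based frame indices of the whole analyzed (non-dropped) range.
analyzed_frames <- function(plan) {
  (plan$start_frame + 1L):(plan$start_frame + plan$total_frames)
}
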