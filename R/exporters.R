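# Persist metric matrices: long-format CSV and per-slice B-factor-annotated
# PDB snapshots sharing one value range recorded in a REMARK header.

#' Write a metric matrix as a long-format CSV
#'
#' One row per (residue, time bin), header
#' `chain_id,residue_id,residue_name,slice_index,slice_start_ns,slice_end_ns,value`.
#' `slice_index` is 0-based.  Angstrom metrics are written with 6 significant
#' digits, lDDT with 4 decimals; re-parsing reconstructs the matrix at that
#' precision.
#'
#' @param matrix a `MetricMatrix` with at least one residue and one bin.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rmsx_csv <- function(matrix, path) {
  stopifnot(inherits(matrix, "MetricMatrix"))
  v <- matrix$values
  if (nrow(v) == 0 || ncol(v) == 0) stop("refusing to write an empty matrix")
  nb <- ncol(v)
  if (!is.null(matrix$time_edges)) {
    starts <- matrix$time_edges[-length(matrix$time_edges)]
    ends <- matrix$time_edges[-1]
  } else {
    starts <- ends <- matrix$time_axis
  }
  lab <- matrix$residue_labels
  df <- data.frame(
    chain_id = rep(lab$chain_id, nb),
    residue_id = rep(lab$residue_id, nb),
    residue_name = rep(lab$residue_name, nb),
    slice_index = rep(seq_len(nb) - 1L, each = nrow(v)),
    slice_start_ns = rep(starts, each = nrow(v)),
    slice_end_ns = rep(ends, each = nrow(v)),
    value = if (matrix$kind == "lddt") sprintf("%.4f", as.vector(v))
            else formatC(signif(as.vector(v), 6), format = "g", digits = 6)
  )
  df$value[is.na(as.vector(v))] <- "NA"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a metric CSV written by [write_rmsx_csv()]
#'
#' @param path CSV path.
#' @param kind metric kind stored in the reconstructed matrix.
#' @return a `MetricMatrix` (without a plan).
#' @export
read_rmsx_csv <- function(path, kind = "rmsx") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  slices <- sort(unique(df$slice_index))
  first <- df[df$slice_index == slices[1], ]
  vals <- vapply(slices, function(s) df$value[df$slice_index == s],
                 numeric(nrow(first)))
  vals <- matrix(vals, nrow = nrow(first))
  starts <- vapply(slices, function(s) df$slice_start_ns[df$slice_index == s][1],
                   numeric(1))
  ends <- vapply(slices, function(s) df$slice_end_ns[df$slice_index == s][1],
                 numeric(1))
  new_metric_matrix(kind, vals,
                    data.frame(chain_id = first$chain_id,
                               residue_id = first$residue_id,
                               residue_name = first$residue_name,
                               stringsAsFactors = FALSE),
                    time_axis = (starts + ends) / 2,
                    time_edges = if (all(starts[-1] == ends[-length(ends)]))
                      c(starts, ends[length(ends)]) else NULL)
}

# REMARK header carrying the shared scale; parsed back by the flipbook
# builder so downstream scripts reproduce identical colour ranges.
snapshot_remark <- function(kind, vmin, vmax, palette) {
  sprintf("REMARK  99 FLIPBOOK kind=%s vmin=%.6f vmax=%.6f palette=%s",
          kind, vmin, vmax, palette)
}

parse_snapshot_remark <- function(path) {
  lines <- readLines(path, n = 50, warn = FALSE)
  hit <- grep("^REMARK  99 FLIPBOOK ", lines, value = TRUE)
  if (length(hit) == 0) return(NULL)
  kv <- regmatches(hit[1], gregexpr("[a-z]+=[^ ]+", hit[1]))[[1]]
  vals <- sub("^[a-z]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  list(kind = vals[["kind"]], vmin = as.numeric(vals[["vmin"]]),
       vmax = as.numeric(vals[["vmax"]]), palette = vals[["palette"]])
}

#' Default shared value range of a metric matrix
#'
#' `(0, max)` for Angstrom metrics so zero fluctuation is always the palette
#' floor; `(0, 1)` for lDDT.
#'
#' @param matrix a `MetricMatrix`.
#' @return numeric `c(vmin, vmax)`.
#' @export
default_value_range <- function(matrix) {
  if (matrix$kind == "lddt") c(0, 1)
  else c(0, max(matrix$values, na.rm = TRUE))
}

#' Write per-slice B-factor-annotated PDB snapshots
#'
#' Snapshot k is the representative frame of slice k (by `frame_rule`)
#' written with column k of the matrix as per-residue B-factors.  Every
#' snapshot carries the same REMARK-encoded `(vmin, vmax)` and palette so
#' colour and size scales stay consistent across the set.
#'
#' @param system `TrajectorySystem` the matrix was computed from.
#' @param matrix `MetricMatrix` whose columns correspond to the plan's slices
#'   (a plan is required; shift/lddt matrices can be aggregated per slice
#'   first).
#' @param out_dir output directory (created); files `slice_000.pdb`, ...
#' @param frame_rule `"middle"` (default), `"first"` or `"last"` frame of the
#'   slice.
#' @param palette palette name recorded for downstream scripts.
#' @param vrange optional `c(vmin, vmax)` overriding [default_value_range()].
#' @return object of class `SnapshotSet`: list with `paths`, `vmin`, `vmax`,
#'   `palette`, `kind`, `frame_rule`.
#' @export
write_bfactor_snapshots <- function(system, matrix, out_dir,
                                    frame_rule = c("middle", "first", "last"),
                                    palette = "viridis", vrange = NULL) {
  frame_rule <- match.arg(frame_rule)
  stopifnot(inherits(matrix, "MetricMatrix"))
  plan <- matrix$plan
  if (is.null(plan)) {
    stop("matrix carries no SlicePlan; aggregate per slice before writing ",
         "snapshots")
  }
  if (ncol(matrix$values) != plan$n_slices) {
    stop("matrix has ", ncol(matrix$values), " columns but the plan has ",
         plan$n_slices, " slices")
  }
  if (is.null(vrange)) vrange <- default_value_range(matrix)
  if (!(vrange[1] <= min(matrix$values, na.rm = TRUE) &&
        vrange[2] >= max(matrix$values, na.rm = TRUE))) {
    stop("vrange [", vrange[1], ", ", vrange[2],
         "] does not cover the matrix values")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  remark <- snapshot_remark(matrix$kind, vrange[1], vrange[2], palette)

  # broadcast matrix rows (selection residues) onto the system's residues
  keys <- residue_keys(system)
  ukeys <- unique(keys)
  mkeys <- paste(matrix$residue_labels$chain_id,
                 matrix$residue_labels$residue_id, sep = "|")
  row_of <- match(ukeys, mkeys)

  width <- max(3L, nchar(as.character(plan$n_slices - 1L)))
  paths <- vapply(seq_len(plan$n_slices), function(k) {
    fr <- slice_frames(plan, k)
    frame <- switch(frame_rule,
                    first = fr[1],
                    middle = fr[1 + (length(fr) - 1L) %/% 2L],
                    last = fr[length(fr)])
    b <- matrix$values[row_of, k]
    p <- file.path(out_dir, sprintf("slice_%0*d.pdb", width, k - 1L))
    write_pdb_frame(system, frame, bfactors = b, path = p, remarks = remark)
    p
  }, character(1))
  structure(list(paths = paths, vmin = vrange[1], vmax = vrange[2],
                 palette = palette, kind = matrix$kind,
                 frame_rule = frame_rule),
            class = "SnapshotSet")
}
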