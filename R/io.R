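#' @name imaging-io
#' @title Reading and writing images, masks, curves and fits
#' @description NIfTI volumes are handled through the RNifti package. A 4-D
#'   NIfTI dynamic volume `(x, y, z, t)` (or 3-D `(x, y, t)`) is re-indexed
#'   to the package's `(frame, row, col)` convention for a single slice.
#'   ROI masks can be NIfTI byte masks or a compact JSON run-length format;
#'   curves are CSV with a time column; first-pass fits are JSON.
NULL

#' Read a dynamic NIfTI series as a dynamic_series
#'
#' @param path NIfTI file with dimensions `(x, y, t)` or `(x, y, 1, t)`.
#' @param frame_interval Frame spacing (s).
#' @param n_baseline Pre-bolus frames.
#' @return A [dynamic_series()].
#' @export
read_dynamic_nifti <- function(path, frame_interval = 2, n_baseline = 5) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  if (length(d) == 4L) {
    if (d[3] != 1L) stop("expected a single-slice dynamic volume")
    a <- a[, , 1, , drop = TRUE]
    d <- dim(a)
  }
  if (length(d) != 3L) stop("expected an (x, y, t) dynamic volume")
  sig <- aperm(a, c(3, 1, 2))              # (frame, row, col)
  dynamic_series(sig, frame_interval = frame_interval,
                 n_baseline = n_baseline)
}

#' Write a 2-D map (e.g. T1 or a perfusion parameter) as NIfTI
#'
#' @param map Numeric matrix.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(map), path)
  invisible(path)
}

#' Read a 2-D map written by write_map_nifti
#' @param path NIfTI file.
#' @return Numeric matrix.
#' @export
read_map_nifti <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) > 2L) a <- drop(a)
  a
}

#' Read an ROI mask from NIfTI or run-length JSON
#'
#' The JSON run-length format is
#' `{"dim": [rows, cols], "runs": [[start, length], ...], "label": "..."}`
#' with 1-based `start` offsets into the column-major vectorized mask.
#'
#' @param path `.nii`/`.nii.gz` byte mask or `.json` run-length file.
#' @param label Optional label override.
#' @return An [roi_mask()].
#' @export
read_roi <- function(path, label = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "json") {
    j <- jsonlite::fromJSON(path)
    m <- matrix(FALSE, j$dim[1], j$dim[2])
    runs <- matrix(unlist(j$runs), ncol = 2, byrow = !is.matrix(j$runs))
    if (is.matrix(j$runs)) runs <- j$runs
    for (i in seq_len(nrow(runs)))
      m[runs[i, 1] + seq_len(runs[i, 2]) - 1L] <- TRUE
    roi_mask(m, label = if (is.null(label)) j$label %||% "" else label)
  } else {
    m <- as.array(RNifti::readNifti(path))
    if (length(dim(m)) > 2L) m <- drop(m)
    roi_mask(m != 0, label = label %||% "")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an ROI mask as run-length JSON
#'
#' @param roi An [roi_mask()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi_json <- function(roi, path) {
  v <- as.vector(roi$mask)
  d <- diff(c(FALSE, v))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1L
  if (length(ends) < length(starts)) ends <- c(ends, length(v))
  jsonlite::write_json(
    list(dim = dim(roi$mask),
         runs = cbind(starts, ends - starts + 1L),
         label = roi$label),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Write a concentration (or signal) time curve as CSV
#'
#' Columns `time_s` and `value`; an AIF additionally writes `cb_mmol` and
#' `cp_mmol`.
#'
#' @param x Numeric curve or an `aif_curve`.
#' @param path Output `.csv` path.
#' @param times Frame times (s); taken from the object if it carries them.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path, times = NULL) {
  if (inherits(x, "aif_curve")) {
    df <- data.frame(time_s = x$times, cb_mmol = x$cb, cp_mmol = x$cp)
  } else {
    if (is.null(times)) stop("'times' required for a bare curve")
    df <- data.frame(time_s = times, value = x)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a first-pass fit (or Tofts parameters) as JSON
#'
#' @param fit A `first_pass_fit` or `tofts_params` object.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- Filter(function(e) is.numeric(e) || is.logical(e),
                 unclass(fit))
  keep <- keep[names(keep) != "window"]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
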