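#' Spoiled gradient-echo acquisition protocol
#'
#' Container for the acquisition constants shared by the forward SPGR signal
#' model, the variable-flip-angle T1 fit and the signal-to-concentration
#' inversion.
#'
#' @param tr Repetition time (ms). Must be positive.
#' @param te Echo time (ms). Kept for completeness; the pipeline works on
#'   signal ratios in which the `exp(-te/t2s)` factor cancels, so `te` never
#'   enters a computation.
#' @param flip_angles Excitation flip angles (degrees), each in (0, 90].
#' @param frame_interval Temporal spacing of the dynamic frames (s).
#' @param r1 Longitudinal relaxivity of the contrast agent
#'   (s^-1 mmol^-1). Default 3.6, the value for Gd-DOTA at 1.5 T.
#'
#' @return An object of class `spgr_protocol`.
#' @examples
#' p <- spgr_protocol(tr = 19, te = 4, flip_angles = c(5, 10, 20, 40, 60, 80))
#' @export
spgr_protocol <- function(tr = 19, te = 4,
                          flip_angles = c(5, 10, 20, 40, 60, 80),
                          frame_interval = 2, r1 = 3.6) {
  stopifnot(is.numeric(tr), length(tr) == 1L,
            is.numeric(te), length(te) == 1L,
            is.numeric(flip_angles), length(flip_angles) >= 1L,
            is.numeric(frame_interval), length(frame_interval) == 1L,
            is.numeric(r1), length(r1) == 1L)
  if (tr <= 0) stop("'tr' must be positive (ms)")
  if (te < 0) stop("'te' must be non-negative (ms)")
  if (any(flip_angles <= 0 | flip_angles > 90))
    stop("all flip angles must lie in (0, 90] degrees")
  if (frame_interval <= 0) stop("'frame_interval' must be positive (s)")
  if (r1 <= 0) stop("'r1' must be positive (s^-1 mmol^-1)")
  structure(list(tr = tr, te = te, flip_angles = as.numeric(flip_angles),
                 frame_interval = frame_interval, r1 = r1),
            class = "spgr_protocol")
}

#' @export
print.spgr_protocol <- function(x, ...) {
  cat("SPGR protocol: TR", x$tr, "ms, TE", x$te, "ms, flip angles",
      paste(x$flip_angles, collapse = "/"), "deg,",
      "frame interval", x$frame_interval, "s, r1", x$r1, "s^-1 mmol^-1\n")
  invisible(x)
}

#' Time to acquire one dynamic scan
#'
#' Per-frame acquisition time of a partial-Fourier, parallel-accelerated 2-D
#' gradient-echo scan: `tr * n_phase_encodes * partial_fourier / acceleration`.
#' With the lumbar protocol defaults (TR 19 ms, 250 phase-encode lines, 6/8
#' partial Fourier, GRAPPA factor 2) this is 1.78125 s, i.e. two axial slices
#' fit inside the 2-s dynamic frame interval.
#'
#' @param tr Repetition time (ms).
#' @param n_phase_encodes Number of phase-encoding lines.
#' @param partial_fourier Acquired fraction of k-space along phase encoding.
#' @param acceleration Parallel-imaging acceleration factor.
#' @return Scan time in seconds.
#' @examples
#' frame_acquisition_time()  # 1.78125
#' @export
frame_acquisition_time <- function(tr = 19, n_phase_encodes = 250,
                                   partial_fourier = 6 / 8, acceleration = 2) {
  stopifnot(tr > 0, n_phase_encodes > 0,
            partial_fourier > 0, partial_fourier <= 1, acceleration >= 1)
  tr / 1000 * n_phase_encodes * partial_fourier / acceleration
}

#' Read an acquisition protocol from a JSON or YAML config file
#'
#' The file must carry the fields `tr`, `te`, `flip_angles`, `frame_interval`
#' and optionally `r1`; unknown fields are ignored.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return An [spgr_protocol()] object.
#' @export
read_protocol <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::fromJSON(path),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: '", ext, "' (use json or yaml)"))
  req <- c("tr", "te", "flip_angles", "frame_interval")
  missing <- setdiff(req, names(cfg))
  if (length(missing))
    stop("protocol config is missing field(s): ", paste(missing, collapse = ", "))
  spgr_protocol(tr = cfg$tr, te = cfg$te,
                flip_angles = unlist(cfg$flip_angles),
                frame_interval = cfg$frame_interval,
                r1 = if (is.null(cfg$r1)) 3.6 else cfg$r1)
}
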