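#' Steady-state spoiled gradient-echo signal
#'
#' Forward SPGR (FLASH) signal model
#' `S = m0_eff * sin(a) * (1 - E) / (1 - cos(a) * E)` with
#' `E = exp(-tr/t1)`. The equilibrium magnetization and the
#' `exp(-te/t2s)` decay are not separable from a single acquisition and are
#' absorbed into the effective amplitude `m0_eff`.
#'
#' @param m0_eff Effective equilibrium amplitude (arbitrary units).
#' @param t1 Longitudinal relaxation time (ms), positive.
#' @param flip_angle Excitation flip angle (degrees).
#' @param tr Repetition time (ms), positive.
#' @return Signal in the units of `m0_eff`. Vectorized over all arguments.
#' @examples
#' spgr_signal(1, 1000, 40, 19)
#' @export
spgr_signal <- function(m0_eff, t1, flip_angle, tr) {
  if (any(t1 <= 0)) stop("'t1' must be positive (ms)")
  if (any(tr <= 0)) stop("'tr' must be positive (ms)")
  a <- flip_angle * pi / 180
  E <- exp(-tr / t1)
  m0_eff * sin(a) * (1 - E) / (1 - cos(a) * E)
}

#' Variable-flip-angle T1 map
#'
#' Estimates per-voxel pre-contrast T1 (`t10`) and effective amplitude
#' (`m0_eff`) from SPGR images acquired at several flip angles, by
#' least-squares fitting of the SPGR signal equation. Starting values come
#' from the DESPOT1 linearization (`S/sin(a)` regressed on `S/tan(a)`, whose
#' slope is `exp(-tr/t1)`), refined by bounded Levenberg-Marquardt.
#'
#' @param signals Numeric array of per-angle signals. Either a matrix with
#'   one row per flip angle (columns are voxels) or a 3-D array indexed
#'   `(angle, row, col)`.
#' @param protocol An [spgr_protocol()]; `protocol$flip_angles` must match
#'   the first dimension of `signals` and contain at least 3 distinct angles.
#' @param t1_bounds Lower/upper bounds for T1 during refinement (ms).
#' @return An object of class `t1_map` with elements `t10`, `m0_eff`,
#'   `fit_residual` (per-voxel RMS residual) and `converged` (logical).
#'   Degenerate voxels (e.g. all-zero signal) are flagged
#'   `converged = FALSE` with `NA` parameters, never silently zeroed.
#'   Shapes follow the input (vector for matrix input, matrix for 3-D input).
#' @examples
#' p <- spgr_protocol()
#' s <- sapply(1, function(i) spgr_signal(1, 1000, p$flip_angles, p$tr))
#' fit_t1_vfa(s, p)$t10
#' @export
fit_t1_vfa <- function(signals, protocol, t1_bounds = c(50, 5000)) {
  angles <- protocol$flip_angles
  if (length(unique(angles)) < 3L)
    stop("variable-flip-angle T1 fitting needs at least 3 distinct flip angles")
  dims <- dim(signals)
  if (is.null(dims)) dims <- c(length(signals), 1L)
  if (dims[1] != length(angles))
    stop("first dimension of 'signals' (", dims[1],
         ") must match the number of flip angles (", length(angles), ")")
  vox_shape <- dims[-1]
  smat <- matrix(signals, nrow = dims[1])
  nvox <- ncol(smat)
  tr <- protocol$tr
  a <- angles * pi / 180
  sin_a <- sin(a); tan_a <- tan(a); cos_a <- cos(a)

  # DESPOT1 linearization, vectorized across voxels
  y <- smat / sin_a                       # recycles by column
  x <- smat / tan_a
  xm <- colMeans(x); ym <- colMeans(y)
  sxx <- colSums(x^2) - length(a) * xm^2
  sxy <- colSums(x * y) - length(a) * xm * ym
  slope <- sxy / sxx
  slope[!is.finite(slope)] <- NA_real_
  t1_lin <- -tr / log(slope)
  t1_lin[!is.finite(t1_lin) | t1_lin <= 0] <- NA_real_

  t10 <- rep(NA_real_, nvox)
  m0 <- rep(NA_real_, nvox)
  rmse <- rep(NA_real_, nvox)
  conv <- rep(FALSE, nvox)
  for (v in seq_len(nvox)) {
    s <- smat[, v]
    if (!all(is.finite(s)) || max(abs(s)) == 0) next
    t1_0 <- t1_lin[v]
    if (is.na(t1_0)) t1_0 <- 1000
    t1_0 <- min(max(t1_0, t1_bounds[1]), t1_bounds[2])
    E0 <- exp(-tr / t1_0)
    m0_0 <- mean(s * (1 - cos_a * E0) / (sin_a * (1 - E0)))
    if (!is.finite(m0_0) || m0_0 <= 0) m0_0 <- max(s)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(t1 = t1_0, m0 = m0_0),
        lower = c(t1_bounds[1], 0),
        upper = c(t1_bounds[2], Inf),
        fn = function(p) s - spgr_signal(p[2], p[1], angles, tr),
        control = minpack.lm::nls.lm.control(maxiter = 100,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    t10[v] <- fit$par[[1]]
    m0[v] <- fit$par[[2]]
    rmse[v] <- sqrt(mean(fit$fvec^2))
    conv[v] <- TRUE
  }
  reshape <- function(z) if (length(vox_shape) > 1L) array(z, vox_shape) else z
  structure(list(t10 = reshape(t10), m0_eff = reshape(m0),
                 fit_residual = reshape(rmse), converged = reshape(conv)),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  n <- length(x$t10)
  cat("T1 map:", n, "voxel(s),", sum(x$converged), "converged; median T10",
      round(stats::median(x$t10[x$converged], na.rm = TRUE), 1), "ms\n")
  invisible(x)
}

#' Dynamic SPGR image series
#'
#' Wraps a `(frame, row, col)` signal array (a single time curve is accepted
#' and treated as one voxel) with its time axis and the number of pre-bolus
#' baseline frames. Frame times are midpoints `(i - 1/2) * frame_interval`.
#'
#' @param signal Numeric array `(frame, row, col)`, matrix `(frame, voxel)`,
#'   or vector (one voxel).
#' @param frame_interval Temporal spacing between frames (s).
#' @param n_baseline Number of pre-bolus frames (default 5); must be at least
#'   1 and smaller than the number of frames.
#' @param times Optional explicit frame times (s); must be strictly
#'   increasing with constant spacing `frame_interval`.
#' @return An object of class `dynamic_series` with elements `signal`,
#'   `times`, `n_baseline`, `frame_interval`.
#' @export
dynamic_series <- function(signal, frame_interval = 2, n_baseline = 5,
                           times = NULL) {
  if (is.null(dim(signal))) signal <- matrix(signal, ncol = 1L)
  nt <- dim(signal)[1]
  if (n_baseline < 1 || n_baseline >= nt)
    stop("'n_baseline' must be in [1, n_frames - 1]")
  if (is.null(times)) {
    times <- (seq_len(nt) - 0.5) * frame_interval
  } else {
    if (length(times) != nt) stop("'times' length must equal the frame count")
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - frame_interval)) > 1e-8 * frame_interval)
      stop("'times' must be strictly increasing with spacing 'frame_interval'")
  }
  structure(list(signal = signal, times = times,
                 frame_interval = frame_interval,
                 n_baseline = as.integer(n_baseline)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("Dynamic series:", d[1], "frames x", paste(d[-1], collapse = " x "),
      "voxels, dt =", x$frame_interval, "s,", x$n_baseline, "baseline frames\n")
  invisible(x)
}

# Per-voxel baseline signal: mean over the first n_baseline frames.
baseline_signal <- function(series) {
  nb <- series$n_baseline
  sig <- series$signal
  apply(sig, seq_along(dim(sig))[-1], function(v) mean(v[seq_len(nb)]))
}

#' Convert dynamic SPGR signal to contrast-agent concentration
#'
#' Inverts the SPGR signal-ratio relation in closed form. With
#' `ratio = S(t)/S0` (`S0` the mean over the baseline frames),
#' `E10 = exp(-tr/t10)` and `B = ratio * (1 - E10) / (1 - cos(a) * E10)`,
#' the dynamic relaxation factor is `E1 = (1 - B) / (1 - B * cos(a))` and
#' `T1(t) = -tr / log(E1)`. Concentration then follows from the relaxivity
#' relation `C(t) = (1/r1) * (1/T1(t) - 1/T10)` with T1 in seconds. Because
#' only the signal ratio enters, the amplitude scale and the T2* decay
#' cancel.
#'
#' Frames whose ratio falls outside the physically invertible range
#' (`E1` outside (0, 1)) are clamped to `E1` in `(eps, 1 - eps)` and flagged
#' rather than failing, so that noise cannot kill a pixel-wise map. Negative
#' concentrations produced by noise are retained, not floored: baseline noise
#' statistics feed the AIF temporal SNR.
#'
#' @param series A [dynamic_series()].
#' @param t1map A [fit_t1_vfa()] result (or a list with `t10` of matching
#'   voxel shape).
#' @param protocol An [spgr_protocol()].
#' @param flip_angle Flip angle of the dynamic scan (degrees); default 40.
#' @param eps Clamp margin for the invertibility guard.
#' @return An object of class `concentration_series`: `conc` (same shape as
#'   the signal, mmol), `times`, `n_baseline`, `frame_interval`, `flagged`
#'   (logical, which voxel-frames were clamped or had invalid T10),
#'   `n_clamped`.
#' @export
concentration_from_signal <- function(series, t1map, protocol,
                                      flip_angle = 40, eps = 1e-6) {
  sig <- series$signal
  nt <- dim(sig)[1]
  t10 <- t1map$t10
  if (length(t10) != prod(dim(sig)[-1]))
    stop("T1 map voxel count does not match the dynamic series")
  tr <- protocol$tr
  r1 <- protocol$r1
  a <- flip_angle * pi / 180
  ca <- cos(a)

  s0 <- as.vector(baseline_signal(series))
  smat <- matrix(sig, nrow = nt)
  t10v <- as.vector(t10)
  bad_vox <- !is.finite(t10v) | t10v <= 0 | !is.finite(s0) | s0 <= 0

  ratio <- sweep(smat, 2L, s0, `/`)
  E10 <- exp(-tr / t10v)
  B <- sweep(ratio, 2L, (1 - E10) / (1 - ca * E10), `*`)
  E1 <- (1 - B) / (1 - B * ca)
  flagged <- !is.finite(E1) | E1 <= 0 | E1 >= 1
  E1 <- pmin(pmax(E1, eps), 1 - eps)
  t1t <- -tr / log(E1)                    # ms
  conc <- sweep(1 / (t1t / 1000), 2L, 1 / (t10v / 1000), `-`) / r1
  conc[, bad_vox] <- NA_real_
  flagged[, bad_vox] <- TRUE
  dim(conc) <- dim(sig)
  dim(flagged) <- dim(sig)
  structure(list(conc = conc, times = series$times,
                 frame_interval = series$frame_interval,
                 n_baseline = series$n_baseline,
                 flagged = flagged, n_clamped = sum(flagged)),
            class = "concentration_series")
}

#' @export
print.concentration_series <- function(x, ...) {
  d <- dim(x$conc)
  cat("Concentration series:", d[1], "frames x",
      paste(d[-1], collapse = " x "), "voxels;", x$n_clamped,
      "voxel-frame(s) flagged\n")
  invisible(x)
}
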