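#' Region-of-interest mask
#'
#' @param mask Logical (or 0/1) matrix `(row, col)` with at least one `TRUE`
#'   pixel, or a two-column matrix of (row, col) pixel indices together with
#'   `dim`.
#' @param label Free-text label.
#' @param dim Image dimensions, required when `mask` is an index matrix.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "", dim = NULL) {
  if (!is.null(dim)) {
    idx <- as.matrix(mask)
    mask <- matrix(FALSE, dim[1], dim[2])
    mask[idx] <- TRUE
  }
  mask <- mask != 0
  if (!any(mask)) stop("ROI mask must contain at least one pixel")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' Baseline-subtracted dynamic series
#'
#' Subtracts from every frame the per-pixel average over the first
#' `n_baseline` frames, highlighting enhancing vessels against static tissue
#' (used to localize the segmental arteries despite partial-volume dilution).
#'
#' @param series A [dynamic_series()].
#' @return A `dynamic_series` of the same shape containing the subtracted
#'   signal.
#' @export
subtract_baseline_series <- function(series) {
  sig <- series$signal
  nt <- dim(sig)[1]
  if (nt < series$n_baseline)
    stop("series has fewer frames than 'n_baseline'")
  s0 <- as.vector(baseline_signal(series))
  out <- sweep(matrix(sig, nrow = nt), 2L, s0, `-`)
  dim(out) <- dim(sig)
  dynamic_series(out, frame_interval = series$frame_interval,
                 n_baseline = series$n_baseline, times = series$times)
}

#' Pick the segmental-artery pixel inside an ROI
#'
#' On the baseline-subtracted series, returns the ROI pixel whose time curve
#' attains the largest maximum (the single pixel centrally located in the
#' artery shows the clearest first-pass peak). Ties are broken by the lowest
#' row-major (row, then column) index.
#'
#' @param subtracted A baseline-subtracted [dynamic_series()].
#' @param roi An [roi_mask()].
#' @return Integer vector `c(row, col)`.
#' @export
select_sa_pixel <- function(subtracted, roi) {
  sig <- subtracted$signal
  if (length(dim(sig)) != 3L) stop("series must be a (frame, row, col) array")
  m <- roi$mask
  if (!any(m)) stop("ROI mask must contain at least one pixel")
  idx <- which(m, arr.ind = TRUE)
  # row-major order: by row, then column
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  peaks <- apply(idx, 1L, function(rc) max(sig[, rc[1], rc[2]]))
  best <- which.max(peaks)                # first max = lowest row-major index
  c(row = idx[best, 1], col = idx[best, 2])
}

#' Mean concentration time curve over an ROI
#'
#' @param conc A `concentration_series` (or `dynamic_series`; the per-frame
#'   mean of its array is taken either way).
#' @param roi An [roi_mask()].
#' @return Numeric vector, one value per frame.
#' @export
extract_roi_curve <- function(conc, roi) {
  arr <- if (inherits(conc, "concentration_series")) conc$conc else conc$signal
  if (length(dim(arr)) != 3L) stop("series must be a (frame, row, col) array")
  m <- roi$mask
  if (!any(m)) stop("ROI mask must contain at least one pixel")
  nt <- dim(arr)[1]
  mat <- matrix(arr, nrow = nt)
  rowMeans(mat[, as.vector(m), drop = FALSE])
}

#' First-pass fitting window of a bolus curve
#'
#' Returns the contiguous frame indices used to fit the first-pass bolus
#' model: the baseline, the upslope, the peak, and `n_post` points after the
#' peak, never extending into the recirculation (second-pass) portion. The
#' bolus is deemed detectable when the curve maximum exceeds the baseline
#' mean by `k_detect` baseline standard deviations (with a small floor so
#' noiseless curves are handled). The second-pass arrival is taken as the
#' first local minimum after the peak that is followed by a rise of at least
#' `2` baseline SDs (again floored at 0.1% of peak).
#'
#' @param curve Concentration time curve (numeric vector).
#' @param n_baseline Number of baseline frames.
#' @param n_post Number of post-peak points to keep (3 or 4; default 3).
#' @param k_detect Detection threshold in baseline SDs (default 5).
#' @return Integer vector of frame indices, `1:upper`.
#' @export
first_pass_window <- function(curve, n_baseline = 5, n_post = 3,
                              k_detect = 5) {
  stopifnot(n_post >= 0, n_baseline >= 1, n_baseline < length(curve))
  base <- curve[seq_len(n_baseline)]
  b_mean <- mean(base)
  b_sd <- stats::sd(base)
  pk <- which.max(curve)
  amp <- curve[pk] - b_mean
  if (amp <= k_detect * b_sd || amp <= 0)
    stop("no detectable bolus: peak ", signif(curve[pk], 4),
         " does not exceed baseline ", signif(b_mean, 4), " + ",
         k_detect, " x SD (", signif(b_sd, 4), ")")
  upper <- min(pk + n_post, length(curve))
  # cap at second-pass arrival: first post-peak local minimum followed by a
  # rise of >= 2 baseline SDs (floored for noiseless curves)
  rise_thr <- max(2 * b_sd, 1e-3 * amp)
  if (pk + 2 <= length(curve)) {
    post <- curve[pk:length(curve)]
    n <- length(post)
    for (i in 2:(n - 1)) {
      if (post[i] <= post[i - 1] && post[i] <= post[i + 1]) {
        if (max(post[(i + 1):n]) - post[i] >= rise_thr) {
          upper <- min(upper, pk + i - 1)
          break
        }
      }
    }
  }
  seq_len(upper)
}

#' First-pass arterial bolus model
#'
#' Evaluates the first-pass blood-concentration model: a Gaussian bolus plus
#' an exponential washout ramped on by a sigmoid,
#' `Cb(t) = a_gauss/(sigma*sqrt(2*pi)) * exp(-(t - t_center)^2 / (2*sigma))
#'  + alpha_exp * exp(-beta_exp*t) / (1 + exp(-s_sig*(t - tau_sig)))`.
#' Note the Gaussian exponent divides by `2*sigma` (not `2*sigma^2`), so
#' `sigma` is a variance-like width in s^2; the effective Gaussian SD is
#' `sqrt(sigma)`.
#'
#' @param t Time points (s).
#' @param params Named list/vector with `a_gauss`, `t_center`, `sigma`,
#'   `alpha_exp`, `beta_exp`, `s_sig`, `tau_sig`.
#' @return Blood concentration at `t` (mmol).
#' @export
first_pass_model <- function(t, params) {
  p <- as.list(params)
  p$a_gauss / (p$sigma * sqrt(2 * pi)) *
    exp(-(t - p$t_center)^2 / (2 * p$sigma)) +
    p$alpha_exp * exp(-p$beta_exp * t) / (1 + exp(-p$s_sig * (t - p$tau_sig)))
}

fp_par_names <- c("a_gauss", "t_center", "sigma", "alpha_exp",
                  "beta_exp", "s_sig", "tau_sig")

#' Fit the first-pass bolus model to a windowed concentration curve
#'
#' Bounded Levenberg-Marquardt least-squares fit of [first_pass_model()]
#' restricted to the frames in `window`. Initialization is moment-based:
#' the Gaussian center starts at the time of the curve maximum, the width at
#' the squared half-width SD estimate, and the Gaussian area at
#' `peak * sigma * sqrt(2*pi)`; the washout starts at Parker-like values
#' scaled to the observed peak. Fitting the first pass only (window chosen by
#' [first_pass_window()]) keeps the recirculation and venous return out of
#' the arterial input.
#'
#' @param curve Concentration time curve (mmol).
#' @param window Integer frame indices (from [first_pass_window()]).
#' @param times Frame times (s), same length as `curve`.
#' @return An object of class `first_pass_fit`: the 7 named parameters,
#'   `rms_residual`, `window`, and `converged`.
#' @export
fit_first_pass <- function(curve, window, times) {
  stopifnot(length(curve) == length(times), length(window) >= 7)
  tw <- times[window]
  cw <- curve[window]
  pk_i <- which.max(cw)
  peak <- cw[pk_i]
  if (peak <= 0) stop("windowed curve has a non-positive peak")
  t_pk <- tw[pk_i]
  # half-width -> SD -> variance-like sigma
  above <- which(cw >= peak / 2)
  hw <- max(diff(range(tw[above])), diff(tw)[1])
  sigma0 <- max((hw / 2.355)^2, 1)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000,
                                     ftol = 1e-15, ptol = 1e-15)
  # stage 1: Gaussian-only fit anchors the bolus peak
  g1 <- tryCatch(
    minpack.lm::nls.lm(
      par = c(peak * sqrt(2 * pi * sigma0), t_pk, sigma0),
      lower = c(0, min(tw), 1e-3), upper = c(Inf, max(tw) + 20, 1e5),
      fn = function(p) cw - p[1] / sqrt(2 * pi * p[3]) *
        exp(-(tw - p[2])^2 / (2 * p[3])),
      control = ctrl),
    error = function(e) NULL)
  g0 <- if (is.null(g1)) c(peak * sqrt(2 * pi * sigma0), t_pk, sigma0)
        else g1$par
  # stage 2: full model from several washout starting points
  lower <- c(0, min(tw), 1e-3, 0, 0, 1e-3, min(tw) - 10)
  upper <- c(Inf, max(tw) + 20, 1e5, 10 * peak, 1, 10, max(tw) + 20)
  best <- NULL
  for (alpha0 in c(0.1, 0.2, 0.4) * peak) for (s0 in c(0.2, 0.6)) {
    start <- c(g0[1], g0[2], g0[3], alpha0, 0.003, s0,
               g0[2] - sqrt(g0[3]))
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, lower = lower, upper = upper,
        fn = function(p) cw - first_pass_model(
          tw, stats::setNames(as.list(p), fp_par_names)),
        control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (best$deviance < (1e-9 * peak)^2 * length(cw)) break
  }
  if (is.null(best))
    stop("first-pass model fit failed to converge from all starts")
  par <- as.list(best$par)
  names(par) <- fp_par_names
  structure(c(par,
              list(rms_residual = sqrt(best$deviance / length(cw)),
                   window = window, converged = best$info %in% 1:4)),
            class = "first_pass_fit")
}

#' @export
print.first_pass_fit <- function(x, ...) {
  cat("First-pass bolus fit: peak center", round(x$t_center, 2), "s, width",
      round(sqrt(x$sigma), 2), "s (SD); RMS residual",
      signif(x$rms_residual, 3), "\n")
  invisible(x)
}

#' Whole-blood to plasma concentration
#'
#' `Cp = Cb / (1 - hct)` elementwise; the Tofts model is driven by the
#' plasma concentration while MRI measures whole-blood concentration.
#'
#' @param cb Blood concentration curve (mmol).
#' @param hct Hematocrit fraction in `[0, 1)`; default 0.42.
#' @return Plasma concentration curve (mmol).
#' @examples
#' blood_to_plasma(5.8, 0.42)  # 10
#' @export
blood_to_plasma <- function(cb, hct = 0.42) {
  if (hct < 0 || hct >= 1) stop("'hct' must lie in [0, 1)")
  cb / (1 - hct)
}

#' Temporal signal-to-noise ratio of an AIF
#'
#' `SNR = max(curve) / SD(baseline)`: the curve maximum divided by the
#' standard deviation of its first `n_baseline` points.
#'
#' @param curve Concentration time curve.
#' @param n_baseline Number of baseline frames (>= 2).
#' @return SNR (dimensionless). A zero baseline SD yields `Inf` with a
#'   warning rather than an error.
#' @export
aif_snr <- function(curve, n_baseline = 5) {
  if (n_baseline < 2) stop("'n_baseline' must be at least 2 for a baseline SD")
  s <- stats::sd(curve[seq_len(n_baseline)])
  if (s == 0) {
    warning("zero baseline SD: SNR is infinite")
    return(Inf)
  }
  max(curve) / s
}

#' Arterial input function
#'
#' Builds an AIF object from a blood concentration curve: fits the
#' first-pass model on the window chosen by [first_pass_window()], converts
#' to plasma with the hematocrit, and records peak, temporal SNR and the
#' bolus arrival (first frame where the fitted first-pass curve exceeds 10%
#' of its peak). The arrival must fall after the baseline block.
#'
#' By default the curve carried into kinetic fitting is the raw measured
#' one and the first-pass fit serves for characterization (peak, arrival,
#' second-pass-free display). The washout decay constant of the first-pass
#' model is only weakly constrained by a window that ends 3-4 points after
#' the peak, so the fitted curve's extrapolated tail is not quantitatively
#' reliable; `use_fit = TRUE` substitutes it anyway when an explicitly
#' recirculation-free input is wanted.
#'
#' @param cb Measured blood concentration curve (mmol).
#' @param times Frame times (s).
#' @param kind `"aortic"`, `"segmental"` or `"population"`.
#' @param n_baseline Number of baseline frames.
#' @param hct Hematocrit fraction; default 0.42.
#' @param n_post Post-peak points in the fitting window (3 or 4).
#' @param use_fit If `TRUE` the curve carried downstream (`cb`, `cp`) is
#'   the fitted first-pass model evaluated on the full grid; if `FALSE`
#'   (default) the raw measured curve is used and the fit is kept for
#'   characterization.
#' @return An object of class `aif_curve`: `cb`, `cp`, `raw_cb`, `times`,
#'   `hct`, `fit` (a `first_pass_fit`), `window`, `snr`, `peak`,
#'   `arrival_index`, `kind`.
#' @export
estimate_aif <- function(cb, times, kind = c("aortic", "segmental",
                                             "population"),
                         n_baseline = 5, hct = 0.42, n_post = 3,
                         use_fit = FALSE) {
  kind <- match.arg(kind)
  window <- first_pass_window(cb, n_baseline = n_baseline, n_post = n_post)
  fit <- fit_first_pass(cb, window, times)
  fitted_cb <- first_pass_model(times, fit)
  out_cb <- if (use_fit) fitted_cb else cb
  peak <- max(out_cb)
  arrival <- which(fitted_cb > 0.1 * max(fitted_cb))[1]
  if (is.na(arrival) || arrival <= n_baseline)
    stop("bolus arrival (frame ", arrival,
         ") does not fall after the baseline block (", n_baseline, " frames)")
  structure(list(cb = out_cb, cp = blood_to_plasma(out_cb, hct),
                 raw_cb = cb, times = times, hct = hct, fit = fit,
                 window = window, snr = aif_snr(cb, n_baseline),
                 peak = peak, arrival_index = arrival,
                 n_baseline = n_baseline, kind = kind),
            class = "aif_curve")
}

#' @export
print.aif_curve <- function(x, ...) {
  cat(sprintf("AIF (%s): peak %.3f mmol, arrival frame %d (%.1f s), SNR %.1f\n",
              x$kind, x$peak, x$arrival_index, x$times[x$arrival_index],
              x$snr))
  invisible(x)
}

#' Population-normalized (Parker-style) AIF
#'
#' Rescales an AIF so its blood-concentration peak equals `target_peak`
#' (default 6 mmol, the Parker population value), compensating for
#' inflow-effect and partial-volume biases in the patient-specific aortic
#' peak. Times are unchanged; the operation is idempotent at a fixed target.
#'
#' @param aif An [estimate_aif()] object with positive peak.
#' @param target_peak Target blood peak (mmol); default 6.
#' @return An `aif_curve` with `kind = "population"`.
#' @export
normalize_population <- function(aif, target_peak = 6) {
  if (!inherits(aif, "aif_curve")) stop("'aif' must be an aif_curve")
  if (aif$peak <= 0) stop("cannot normalize an AIF with non-positive peak")
  f <- target_peak / aif$peak
  aif$cb <- aif$cb * f
  aif$cp <- blood_to_plasma(aif$cb, aif$hct)
  aif$peak <- max(aif$cb)
  aif$kind <- "population"
  aif
}
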