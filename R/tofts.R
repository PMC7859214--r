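#' Extended (modified) Tofts forward model
#'
#' Tissue concentration of the two-compartment exchange model with a
#' vascular term:
#' `Ct(t) = vp * Cp(t) + Cp(t) (x) Ktrans * exp(-Ktrans * t / ve)`,
#' where `(x)` denotes convolution and `kep = ktrans/ve` is the reflux rate.
#' `ktrans` is expressed per minute (the reporting convention) while `times`
#' are in seconds; the conversion happens internally. The convolution uses
#' the exponential-kernel recursion, exact for piecewise-linear `cp` on a
#' uniform grid (no FFT wrap-around).
#'
#' @param ktrans Transfer constant (min^-1), non-negative.
#' @param ve Extravascular extracellular volume fraction in (0, 1]; may be 0
#'   only when `ktrans = 0`.
#' @param vp Plasma volume fraction in `[0, 1]`.
#' @param cp Plasma concentration curve (mmol) on `times`.
#' @param times Uniformly spaced frame times (s).
#' @return Tissue concentration curve (mmol), same length as `cp`.
#' @examples
#' t <- seq(0, 300, by = 2)
#' cp <- ifelse(t > 20, 5, 0)
#' ct <- tofts_forward(0.05, 0.3, 0.02, cp, t)
#' @export
tofts_forward <- function(ktrans, ve, vp, cp, times) {
  stopifnot(length(cp) == length(times), length(times) >= 2)
  if (ktrans < 0) stop("'ktrans' must be non-negative")
  if (vp < 0 || vp > 1) stop("'vp' must lie in [0, 1]")
  if (ktrans == 0) return(vp * cp)
  if (ve <= 0) stop("'ve' must be positive when ktrans > 0 (kep undefined)")
  kt <- ktrans / 60                        # s^-1
  k <- (ktrans / ve) / 60                  # kep in s^-1
  d <- times[2] - times[1]
  n <- length(cp)
  c0 <- cp[-n]
  m <- (cp[-1] - c0) / d
  kd <- k * d
  E <- exp(-kd)
  if (kd > 1e-8) {
    I1 <- (1 - E) / k
    I2 <- d * (1 - E) / k - (1 - (1 + kd) * E) / k^2
  } else {                                 # series limit for tiny kep*dt
    I1 <- d - k * d^2 / 2
    I2 <- d^2 / 2 - k * d^3 / 3
  }
  a <- c0 * I1 + m * I2
  conv <- c(0, stats::filter(a, E, method = "recursive"))
  vp * cp + kt * conv
}

#' Fit the extended Tofts model to a single tissue curve
#'
#' Bounded Levenberg-Marquardt least squares over `(ktrans, ve, vp)` with
#' `ktrans` in `[0, 10]` min^-1, `ve` in `[1e-6, 1]`, `vp` in `[0, 1]`.
#' Three starting points spanning the physiological range are tried and the
#' best-residual solution kept; `kep = ktrans/ve` is derived, never fitted
#' independently (the model has only three free parameters).
#'
#' @param ct Tissue concentration curve (mmol).
#' @param cp Plasma AIF curve (mmol) on the same time grid.
#' @param times Uniformly spaced frame times (s).
#' @param starts Optional list of numeric `c(ktrans, ve, vp)` starting
#'   points; defaults to three spread over the parameter box.
#' @return An object of class `tofts_params`: `ktrans`, `kep`, `ve`, `vp`
#'   (units min^-1, min^-1, -, -), `rms_residual`, `converged`. If no start
#'   converges, the best-effort parameters are returned with
#'   `converged = FALSE`.
#' @export
fit_tofts_curve <- function(ct, cp, times, starts = NULL) {
  stopifnot(length(ct) == length(cp), length(cp) == length(times))
  if (is.null(starts))
    starts <- list(c(0.02, 0.15, 0.02), c(0.2, 0.5, 0.05), c(1, 0.9, 0.2))
  lower <- c(0, 1e-6, 0)
  upper <- c(10, 1, 1)
  best <- NULL
  best_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = s, lower = lower, upper = upper,
        fn = function(p) ct - tofts_forward(p[1], p[2], p[3], cp, times),
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- fit
      best_conv <- ok
    }
  }
  if (is.null(best))
    return(structure(list(ktrans = NA_real_, kep = NA_real_, ve = NA_real_,
                          vp = NA_real_, rms_residual = NA_real_,
                          converged = FALSE), class = "tofts_params"))
  p <- best$par
  structure(list(ktrans = p[1], kep = p[1] / p[2], ve = p[2], vp = p[3],
                 rms_residual = sqrt(best$deviance / length(ct)),
                 converged = best_conv),
            class = "tofts_params")
}

#' @export
print.tofts_params <- function(x, ...) {
  cat(sprintf(
    "Tofts fit: Ktrans %.4f min^-1, kep %.4f min^-1, ve %.4f, vp %.4f (%s)\n",
    x$ktrans, x$kep, x$ve, x$vp,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

map_summary <- function(maps, conv) {
  do.call(rbind, lapply(names(maps), function(nm) {
    v <- maps[[nm]][conv]
    data.frame(parameter = nm, mean = mean(v), sd = stats::sd(v),
               row.names = NULL)
  }))
}

#' Pixel-wise perfusion parameter maps (PWM)
#'
#' Fits the extended Tofts model independently in every ROI pixel of a
#' concentration series and summarizes the maps as mean +/- SD over the
#' converged pixels (non-converged pixels are excluded from the summary and
#' counted).
#'
#' @param conc A `concentration_series` from [concentration_from_signal()].
#' @param roi An [roi_mask()] inside the image bounds.
#' @param aif An [estimate_aif()] object; its `cp` drives the fit.
#' @return An object of class `parametric_maps` with `maps` (one
#'   `(row, col)` matrix per parameter, `NA` outside the ROI),
#'   `roi_summary` (data frame of mean/sd per parameter over converged
#'   pixels), `roi_summary_all` (over all ROI pixels), `method = "PWM"`,
#'   `n_pixels`, `n_converged`.
#' @export
fit_map_pixelwise <- function(conc, roi, aif) {
  arr <- conc$conc
  stopifnot(length(dim(arr)) == 3L)
  if (!all(dim(roi$mask) == dim(arr)[2:3]))
    stop("ROI dimensions do not match the concentration series")
  idx <- which(roi$mask, arr.ind = TRUE)
  nd <- dim(arr)[2:3]
  maps <- list(ktrans = matrix(NA_real_, nd[1], nd[2]),
               kep = matrix(NA_real_, nd[1], nd[2]),
               ve = matrix(NA_real_, nd[1], nd[2]),
               vp = matrix(NA_real_, nd[1], nd[2]))
  conv <- matrix(FALSE, nd[1], nd[2])
  for (i in seq_len(nrow(idx))) {
    ct <- arr[, idx[i, 1], idx[i, 2]]
    if (!all(is.finite(ct))) next
    f <- fit_tofts_curve(ct, aif$cp, conc$times)
    maps$ktrans[idx[i, , drop = FALSE]] <- f$ktrans
    maps$kep[idx[i, , drop = FALSE]] <- f$kep
    maps$ve[idx[i, , drop = FALSE]] <- f$ve
    maps$vp[idx[i, , drop = FALSE]] <- f$vp
    conv[idx[i, , drop = FALSE]] <- isTRUE(f$converged)
  }
  if (!any(conv)) stop("no ROI pixel produced a converged Tofts fit")
  all_ok <- roi$mask & is.finite(maps$ktrans)
  structure(list(maps = maps,
                 roi_summary = map_summary(maps, conv),
                 roi_summary_all = map_summary(maps, all_ok),
                 method = "PWM", n_pixels = nrow(idx),
                 n_converged = sum(conv), converged_mask = conv),
            class = "parametric_maps")
}

#' ROI-based perfusion parameters (RBM)
#'
#' Averages the concentration curve over the ROI first, then fits the
#' extended Tofts model once; the maps are constant over the ROI.
#'
#' @inheritParams fit_map_pixelwise
#' @return A `parametric_maps` object with `method = "RBM"`; `fit` carries
#'   the single `tofts_params`.
#' @export
fit_roi_based <- function(conc, roi, aif) {
  arr <- conc$conc
  stopifnot(length(dim(arr)) == 3L)
  if (!all(dim(roi$mask) == dim(arr)[2:3]))
    stop("ROI dimensions do not match the concentration series")
  curve <- extract_roi_curve(conc, roi)
  f <- fit_tofts_curve(curve, aif$cp, conc$times)
  if (!isTRUE(f$converged)) stop("ROI-averaged Tofts fit did not converge")
  nd <- dim(arr)[2:3]
  mk <- function(v) {
    m <- matrix(NA_real_, nd[1], nd[2])
    m[roi$mask] <- v
    m
  }
  maps <- list(ktrans = mk(f$ktrans), kep = mk(f$kep),
               ve = mk(f$ve), vp = mk(f$vp))
  structure(list(maps = maps,
                 roi_summary = map_summary(maps, roi$mask),
                 roi_summary_all = map_summary(maps, roi$mask),
                 method = "RBM", n_pixels = sum(roi$mask),
                 n_converged = sum(roi$mask), fit = f),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat("Perfusion maps (", x$method, "): ", x$n_converged, "/", x$n_pixels,
      " pixels converged\n", sep = "")
  print(x$roi_summary, digits = 4)
  invisible(x)
}
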