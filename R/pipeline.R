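#' Full vertebral perfusion analysis pipeline
#'
#' Runs the complete analysis on one axial slice: variable-flip-angle T1
#' map, signal-to-concentration conversion, construction of the three AIF
#' variants (patient aortic AIF_A from the aortic ROI mean; patient
#' segmental-arterial AIF_SA from the maximal-peak pixel of the
#' baseline-subtracted series inside the segmental ROI; population AIF_PA
#' by rescaling AIF_A's blood peak to `target_peak`), and extended Tofts
#' fitting of the vertebral ROI with each requested AIF by the requested
#' method(s).
#'
#' @param vfa Array `(angle, row, col)` of pre-contrast images at
#'   `protocol$flip_angles`.
#' @param dynamic A [dynamic_series()] of the dynamic scan.
#' @param masks List with [roi_mask()] entries `aorta`, `sa_roi`,
#'   `vertebra`.
#' @param protocol An [spgr_protocol()].
#' @param dyn_flip Dynamic-scan flip angle (degrees).
#' @param hct Hematocrit fraction.
#' @param n_post Post-peak points in the AIF fitting window.
#' @param target_peak Population blood peak (mmol).
#' @param use_fit Use the raw measured curve as the working AIF (default)
#'   or substitute the fitted first-pass curve (see [estimate_aif()] for
#'   why the fitted tail is not quantitatively reliable).
#' @param methods Character subset of `c("RBM", "PWM")`.
#' @param aif_kinds Character subset of
#'   `c("aortic", "segmental", "population")`.
#' @return A list of class `perfusion_analysis`: `t1map`, `conc`, `aifs`
#'   (named list of `aif_curve`), `fits` (named list
#'   `fits[[aif_kind]][[method]]` of `parametric_maps`).
#' @export
run_pipeline <- function(vfa, dynamic, masks, protocol, dyn_flip = 40,
                         hct = 0.42, n_post = 3, target_peak = 6,
                         use_fit = FALSE, methods = "RBM",
                         aif_kinds = c("aortic", "segmental", "population")) {
  stopifnot(all(methods %in% c("RBM", "PWM")),
            all(aif_kinds %in% c("aortic", "segmental", "population")))
  t1map <- fit_t1_vfa(vfa, protocol)
  conc <- concentration_from_signal(dynamic, t1map, protocol,
                                    flip_angle = dyn_flip)
  nb <- dynamic$n_baseline
  aifs <- list()
  if (any(c("aortic", "population") %in% aif_kinds)) {
    cb_a <- extract_roi_curve(conc, masks$aorta)
    aifs$aortic <- estimate_aif(cb_a, conc$times, "aortic",
                                n_baseline = nb, hct = hct,
                                n_post = n_post, use_fit = use_fit)
  }
  if ("segmental" %in% aif_kinds) {
    sub <- subtract_baseline_series(dynamic)
    px <- select_sa_pixel(sub, masks$sa_roi)
    cb_s <- conc$conc[, px[1], px[2]]
    aifs$segmental <- estimate_aif(cb_s, conc$times, "segmental",
                                   n_baseline = nb, hct = hct,
                                   n_post = n_post, use_fit = use_fit)
    aifs$segmental$pixel <- px
  }
  if ("population" %in% aif_kinds)
    aifs$population <- normalize_population(aifs$aortic, target_peak)
  aifs <- aifs[intersect(c("population", "aortic", "segmental"), aif_kinds)]
  fits <- lapply(aifs, function(aif) {
    out <- list()
    if ("RBM" %in% methods)
      out$RBM <- fit_roi_based(conc, masks$vertebra, aif)
    if ("PWM" %in% methods)
      out$PWM <- fit_map_pixelwise(conc, masks$vertebra, aif)
    out
  })
  structure(list(t1map = t1map, conc = conc, aifs = aifs, fits = fits),
            class = "perfusion_analysis")
}

#' @export
print.perfusion_analysis <- function(x, ...) {
  cat("Vertebral perfusion analysis\n")
  for (k in names(x$aifs)) print(x$aifs[[k]])
  for (k in names(x$fits)) for (m in names(x$fits[[k]])) {
    cat("--", k, m, "--\n")
    print(x$fits[[k]][[m]]$roi_summary, digits = 4)
  }
  invisible(x)
}
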