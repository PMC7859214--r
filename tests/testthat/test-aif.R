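test_that("baseline subtraction is a per-pixel linear offset removal", {
  sig <- array(7, c(10, 2, 2))
  ds <- dynamic_series(sig, 2, 5)
  sub <- subtract_baseline_series(ds)
  expect_equal(max(abs(sub$signal)), 0)
  # raising one pixel-frame by delta shows up exactly there
  sig[8, 2, 1] <- 7 + 3.5
  sub <- subtract_baseline_series(dynamic_series(sig, 2, 5))
  expect_equal(sub$signal[8, 2, 1], 3.5)
  expect_equal(sum(abs(sub$signal)), 3.5)
})

test_that("segmental-artery pixel selection finds the max-peak pixel", {
  ph <- get_phantom(noiseless = FALSE)
  sub <- subtract_baseline_series(ph$dynamic)
  px <- select_sa_pixel(sub, ph$masks$sa_roi)
  expect_true(ph$masks$sa_pixels$mask[px[1], px[2]])

  # exhaustive-scan oracle on a small constructed series
  set.seed(3)
  sig <- array(rnorm(20 * 4 * 4, 10, 0.01), c(20, 4, 4))
  sig[10, 2, 3] <- 40
  sig[11, 3, 1] <- 35
  ds <- dynamic_series(sig, 2, 5)
  sub <- subtract_baseline_series(ds)
  roi <- roi_mask(matrix(TRUE, 4, 4))
  idx <- which(roi$mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  peaks <- apply(idx, 1, function(rc) max(sub$signal[, rc[1], rc[2]]))
  expect_equal(unname(select_sa_pixel(sub, roi)),
               unname(idx[which.max(peaks), ]))

  # tie broken by lowest row-major index
  sig2 <- array(0, c(8, 3, 3))
  sig2[6, 2, 2] <- 5
  sig2[6, 1, 3] <- 5
  sub2 <- subtract_baseline_series(dynamic_series(sig2, 2, 3))
  expect_equal(unname(select_sa_pixel(sub2, roi_mask(matrix(TRUE, 3, 3)))),
               c(1, 3))
  # single-pixel ROI is a forced choice
  m <- matrix(FALSE, 3, 3); m[3, 2] <- TRUE
  expect_equal(unname(select_sa_pixel(sub2, roi_mask(m))), c(3, 2))
})

test_that("selection is invariant to adding a static image", {
  ph <- get_phantom(noiseless = FALSE)
  px0 <- select_sa_pixel(subtract_baseline_series(ph$dynamic),
                         ph$masks$sa_roi)
  sig <- ph$dynamic$signal
  static <- matrix(runif(prod(dim(sig)[2:3]), 0, 50), dim(sig)[2])
  for (f in seq_len(dim(sig)[1])) sig[f, , ] <- sig[f, , ] + static
  ds <- dynamic_series(sig, ph$dynamic$frame_interval,
                       ph$dynamic$n_baseline, times = ph$dynamic$times)
  expect_equal(select_sa_pixel(subtract_baseline_series(ds),
                               ph$masks$sa_roi), px0)
})

test_that("ROI curve extraction is the per-frame pixel mean", {
  arr <- array(0, c(6, 2, 2))
  arr[, 1, 1] <- 1:6
  arr[, 2, 1] <- seq(2, 12, by = 2)
  cs <- structure(list(conc = arr, times = (1:6) * 2),
                  class = "concentration_series")
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(extract_roi_curve(cs, roi_mask(m)), (1:6) * 1.5)
  m1 <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  expect_equal(extract_roi_curve(cs, roi_mask(m1)), as.numeric(1:6))
  # noiseless phantom aorta ROI returns the generating curve
  ph <- get_phantom()
  res_curve <- extract_roi_curve(
    concentration_from_signal(ph$dynamic,
                              list(t10 = ph$truth$t10_map),
                              ph$spec$protocol, 40),
    ph$masks$aorta)
  expect_lt(max(abs(res_curve - ph$truth$aorta_cb)), 0.05)
})

test_that("first-pass window covers baseline to peak+3 and avoids recirculation", {
  # single-pass curve peaking at index k
  tt <- seq(1, 199, by = 2)
  curve <- exp(-(tt - 51)^2 / 200)
  curve[1:10] <- curve[1:10] + rnorm(10, 0, 1e-4)
  k <- which.max(curve)
  expect_equal(first_pass_window(curve, 5), seq_len(k + 3))
  # recirculation bump inserted after the peak is excluded
  curve2 <- curve
  curve2[(k + 10):(k + 14)] <- curve2[(k + 10):(k + 14)] + 0.5
  w <- first_pass_window(curve2, 5)
  expect_true(max(w) < k + 10)
  # phantom two-pass curve: upper edge at most 4 frames past the peak
  ph <- get_phantom()
  cb <- ph$truth$aorta_cb
  w_ph <- first_pass_window(cb, 5, n_post = 4)
  expect_lte(max(w_ph), which.max(cb) + 4)
  expect_gte(max(w_ph), which.max(cb))
  # flat curve: no detectable bolus
  set.seed(5)
  expect_error(first_pass_window(rnorm(50), 5), "no detectable bolus")
})

test_that("first-pass model fit recovers known parameters on noiseless data", {
  tru <- list(a_gauss = 280, t_center = 30, sigma = 28, alpha_exp = 1.1,
              beta_exp = 0.003, s_sig = 0.45, tau_sig = 27)
  tt <- seq(1, 439, by = 2)
  cb <- first_pass_model(tt, tru)
  w <- first_pass_window(cb, 5)
  fit <- fit_first_pass(cb, w, tt)
  expect_true(fit$converged)
  expect_lt(fit$rms_residual, 1e-6)
  for (nm in names(tru))
    expect_lt(abs(fit[[nm]] - tru[[nm]]) / tru[[nm]], 0.01)
  # fitted curve reproduces the window exactly
  expect_lt(max(abs(first_pass_model(tt[w], fit) - cb[w])), 1e-5)
})

test_that("the fit ignores frames outside the window", {
  ph <- get_phantom()
  cb <- ph$truth$aorta_cb
  w <- first_pass_window(cb, 5)
  f1 <- fit_first_pass(cb, w, ph$times)
  cb2 <- cb
  cb2[(max(w) + 5):length(cb2)] <- cb2[(max(w) + 5):length(cb2)] + 17
  f2 <- fit_first_pass(cb2, w, ph$times)
  expect_identical(unclass(f1)[fp_names <- c("a_gauss", "t_center", "sigma",
                                             "alpha_exp", "beta_exp",
                                             "s_sig", "tau_sig")],
                   unclass(f2)[fp_names])
})

test_that("fitted peak is within 5% of truth in at least 95% of noisy runs", {
  tru <- list(a_gauss = 280, t_center = 30, sigma = 28, alpha_exp = 1.1,
              beta_exp = 0.003, s_sig = 0.45, tau_sig = 27)
  tt <- seq(1, 439, by = 2)
  cb <- first_pass_model(tt, tru)
  peak_true <- max(cb)
  set.seed(202)
  ok <- replicate(200, {
    noisy <- cb + rnorm(length(cb), 0, peak_true / 40)
    fit <- tryCatch({
      w <- first_pass_window(noisy, 5)
      fit_first_pass(noisy, w, tt)
    }, error = function(e) NULL)
    if (is.null(fit)) return(FALSE)
    abs(max(first_pass_model(tt, fit)) - peak_true) / peak_true < 0.05
  })
  expect_gte(mean(ok), 0.95)
})

test_that("plasma conversion and its invariants", {
  expect_equal(blood_to_plasma(5.8, 0.42), 10, tolerance = 1e-12)
  expect_equal(blood_to_plasma(c(1, 2, 3), 0), c(1, 2, 3))
  expect_equal(formals(blood_to_plasma)$hct, 0.42)   # default is 0.42
  expect_error(blood_to_plasma(1, 1), "hct")
  # cp/cb constant across frames
  cb <- runif(30, 0, 6)
  expect_equal(blood_to_plasma(cb, 0.42) / cb, rep(1 / 0.58, 30))
})

test_that("population normalization rescales the blood peak to 6 mmol", {
  ph <- get_phantom()
  cb <- extract_roi_curve(
    concentration_from_signal(ph$dynamic, list(t10 = ph$truth$t10_map),
                              ph$spec$protocol, 40), ph$masks$aorta)
  aif <- estimate_aif(cb, ph$times, "aortic")
  pop <- normalize_population(aif)
  expect_equal(pop$peak, 6, tolerance = 1e-12)
  expect_equal(pop$kind, "population")
  expect_equal(which.max(pop$cb), which.max(aif$cb))
  # idempotent at the same target; identity when already at 6
  pop2 <- normalize_population(pop)
  expect_equal(pop2$cb, pop$cb, tolerance = 1e-12)
  # cp consistency
  expect_equal(pop$cp, pop$cb / (1 - pop$hct), tolerance = 1e-12)
})

test_that("AIF temporal SNR follows the peak-over-baseline-SD definition", {
  curve <- c(rnorm(5, 0, 0), 1, 2, 1)
  curve[1:5] <- c(-0.1, 0.1, -0.1, 0.1, 0)
  expect_equal(aif_snr(curve, 5), 2 / sd(curve[1:5]))
  expect_warning(snr <- aif_snr(c(0, 0, 0, 0, 0, 2), 5), "infinite")
  expect_identical(snr, Inf)
  expect_error(aif_snr(curve, 1), "n_baseline")
})

test_that("the first-pass fit underlies the raw curve at the second pass", {
  ph <- get_phantom()
  cb <- ph$truth$aorta_cb
  aif <- estimate_aif(cb, ph$times, "aortic")
  fitc <- first_pass_model(ph$times, aif$fit)
  # frames around the recirculation bump center
  ctr <- which.min(abs(ph$times -
    (ph$truth$aorta_first_pass$t_center + ph$spec$recirc$lag)))
  idx <- (ctr - 3):(ctr + 3)
  expect_true(all(fitc[idx] < cb[idx]))
})

test_that("AIF estimation enforces a post-baseline arrival", {
  tt <- seq(1, 199, by = 2)
  early <- first_pass_model(tt, list(a_gauss = 100, t_center = 15, sigma = 8,
                                     alpha_exp = 0.5, beta_exp = 0.003,
                                     s_sig = 0.5, tau_sig = 13))
  expect_error(estimate_aif(early, tt, "aortic", n_baseline = 6), "arrival")
  # and the phantom's default bolus arrives after the baseline block
  ph <- get_phantom()
  aif <- estimate_aif(ph$truth$aorta_cb, ph$times, "aortic")
  expect_gt(aif$arrival_index, 5)
})
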