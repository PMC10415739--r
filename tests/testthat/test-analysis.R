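make_noisy_set <- function(n, seed, artifacts = NULL) {
  em <- std_emulsion(n, seed = seed)
  acq <- acquisition_config(n_frames = 60)
  ts <- simulate_trace_set(em, paper_rate_clean(), acq, noise_model(1, 0.01),
                           seed = seed)
  if (!is.null(artifacts)) ts <- inject_artifacts(ts, artifacts, seed = seed)
  ts
}

test_that("QC keeps clean sets and finds labelled artifacts", {
  clean <- make_noisy_set(300, seed = 21)
  qc <- qc_filter(clean)
  expect_equal(length(qc$kept), 300)
  expect_equal(nrow(qc$discarded), 0)

  # determinism: same input, same report
  expect_identical(qc_filter(clean), qc)

  ts <- make_noisy_set(2000, seed = 22,
                       artifacts = artifact_spec(0.1, 0.05, 0.05, 0.5))
  qc <- qc_filter(ts)
  truth <- ts$truth
  neg <- truth$droplet_id[truth$artifact == "negative_slope"]
  caught <- qc$discarded$droplet_id[qc$discarded$reason == "negative_slope"]
  expect_gte(mean(neg %in% caught), 0.95)
  none <- truth$droplet_id[truth$artifact == "none"]
  expect_lte(mean(none %in% qc$discarded$droplet_id), 0.02)
  # kept and discarded partition the input
  expect_setequal(c(qc$kept, qc$discarded$droplet_id), truth$droplet_id)
  expect_length(intersect(qc$kept, qc$discarded$droplet_id), 0)
})

test_that("a flat trace with a 50% step is discarded as a jump", {
  t <- seq(4, 100, 2)
  red <- rep(100, length(t))
  red[t >= 60] <- 150
  traces <- data.frame(droplet_id = "j1", frame = seq_along(t), time_s = t,
                       green_nu = 100, red_nu = red)
  # a companion clean trace so the filter has something to keep
  traces2 <- traces
  traces2$droplet_id <- "ok"
  traces2$red_nu <- 100 + 0.5 * t
  qc <- qc_filter(rbind(traces, traces2))
  expect_identical(qc$discarded$droplet_id, "j1")
  expect_identical(qc$discarded$reason, "intensity_jump")
  expect_identical(qc$kept, "ok")

  expect_error(qc_filter(traces[0, ]), "no traces")
})

test_that("reference normalization rescales and rejects dead reference", {
  red <- c(10, 20, 30)
  expect_equal(reference_normalize(red, rep(50, 3)), red)
  expect_error(reference_normalize(red, c(50, 0, 50)), "reference")

  # common multiplicative wobble shrinks variance
  set.seed(23)
  wobble <- 1 + rnorm(200, 0, 0.05)
  base_red <- 100 + seq_len(200) * 0.3
  red_w <- base_red * wobble
  green_w <- 80 * wobble
  norm <- reference_normalize(red_w, green_w)
  expect_lt(stats::var(norm - base_red), stats::var(red_w - base_red))
})

test_that("slope estimation matches the window formula and normalizes", {
  em <- std_emulsion(40, seed = 24, xi_sd = 0, radius_cv = 0)
  acq <- acquisition_config(n_frames = 60)
  ts <- simulate_trace_set(em, paper_rate_clean(), acq, noise_model(0, 0))

  w <- slope_window(10, 50)
  ss <- estimate_slopes(ts, w)
  # identical noiseless droplets: every normalized slope is exactly 1
  expect_equal(ss$slopes$slope_norm, rep(1, 40))
  expect_equal(mean(ss$slopes$slope_norm), 1, tolerance = 1e-12)

  # two-point estimator equals window_slope applied to the model
  f1 <- to_fluorescence(closed_form_conversion(3.2e4, 250e-9, 200e-9, 10),
                        200e-9, 10, 200)
  f2 <- to_fluorescence(closed_form_conversion(3.2e4, 250e-9, 200e-9, 50),
                        200e-9, 10, 200)
  expect_equal(ss$slopes$slope[1], window_slope(f1, f2, w))

  # regression mode agrees closely on noiseless near-linear data
  sr <- estimate_slopes(ts, w, mode = "regression")
  expect_equal(sr$slopes$slope, ss$slopes$slope, tolerance = 0.05)

  expect_error(estimate_slopes(ts, slope_window(10, 1e5)), "outside")

  # noiseless ensemble at fixed composition: dispersion is numerically nil
  big <- simulate_trace_set(std_emulsion(2000, seed = 25, xi_sd = 0,
                                         radius_cv = 0),
                            paper_rate_clean(), acq, noise_model(0, 0))
  vs <- variability_stats(estimate_slopes(big, w))
  expect_lt(vs$cv, 0.01)
})

test_that("variability statistics match hand computations", {
  expect_error(variability_stats(slope_set(c(1, 1, 1))), "at least 4")

  const <- variability_stats(slope_set(rep(2.5e-4, 10)))
  expect_equal(const$cv, 0)
  expect_equal(const$iqr, 0)
  expect_equal(const$mad, 0)

  ss <- slope_set(c(0.8, 0.9, 1.1, 1.2))
  vs <- variability_stats(ss)
  expect_equal(vs$cv, 0.1825742, tolerance = 1e-6)

  # permutation invariance
  set.seed(26)
  s <- rlnorm(100, 0, 0.3)
  v1 <- variability_stats(slope_set(s))
  v2 <- variability_stats(slope_set(sample(s)))
  expect_equal(v1$cv, v2$cv)
  expect_equal(v1$iqr, v2$iqr)
  expect_equal(v1$mad, v2$mad)

  # MAD lives on the raw slope scale, CV on the normalized scale
  raw <- c(2.0e-4, 2.4e-4, 2.6e-4, 3.0e-4)
  vs2 <- variability_stats(slope_set(raw))
  expect_equal(vs2$mad, mean(abs(raw - mean(raw))))
  expect_lt(vs2$mad, 1e-3)
  expect_gt(vs2$cv, 0.01)

  # Gaussian sample recovery at the dispersion reported for pool droplets
  set.seed(27)
  g <- rnorm(2000, 1, 0.247)
  expect_equal(variability_stats(slope_set(g))$cv, 0.247,
               tolerance = 0.01 / 0.247)
})

test_that("central-peak fit is robust to fast outliers", {
  set.seed(28)
  pure <- slope_set(rnorm(2000, 1, 0.1))
  fit <- central_peak_fit(pure)
  expect_equal(fit$gaussian_cv, 0.10, tolerance = 0.01 / 0.10)

  contaminated <- slope_set(c(rnorm(1900, 1, 0.1), rnorm(100, 1.8, 0.03)))
  fit2 <- central_peak_fit(contaminated)
  plain <- variability_stats(contaminated)$cv
  expect_equal(fit2$gaussian_cv, 0.10, tolerance = 0.015 / 0.10)
  expect_gte(plain, 0.15)

  expect_error(central_peak_fit(slope_set(rnorm(10, 1, 0.1))),
               "at least 20")
  # a point-mass histogram cannot support a Gaussian fit
  expect_error(central_peak_fit(slope_set(rep(1, 30))), "degenerate")
})

test_that("invader concentrations interpolate between anchor intensities", {
  ref <- c(rep(0, 10), rep(600, 10), 300)
  cm <- estimate_invader_concentrations(ref, stock = 500e-9)
  expect_equal(cm$conc_est[21], 250e-9)
  expect_equal(cm$conc_est[1], 0)
  expect_equal(cm$conc_est[11], 500e-9)

  expect_error(estimate_invader_concentrations(rep(5, 20), 500e-9),
               "degenerate")

  # noiseless sinusoidal sweep: per-droplet error < 1% of the stock
  cfg <- emulsion_config(n_droplets = 400, radius_cv = 0,
                         mixing_mode = "sinusoidal")
  prog <- pressure_program(period = 2, droplet_interval = 0.013)
  em <- generate_emulsion(cfg, prog, seed = 29)
  ts <- simulate_trace_set(em, paper_rate_clean(),
                           acquisition_config(n_frames = 50),
                           noise_model(0, 0))
  cm <- estimate_invader_concentrations(ts, 500e-9)
  truth <- em$xi[match(cm$droplet_id, em$droplet_id)] * 500e-9
  expect_lt(max(abs(cm$conc_est - truth)), 0.01 * 500e-9)
})

test_that("rate-constant fitting round-trips and needs curvature", {
  tt <- seq(0, 2700, 10)
  for (k in c(3.2e4, 2.7e4)) {
    f <- to_fluorescence(closed_form_conversion(k, 250e-9, 200e-9, tt),
                         200e-9, 10, 200)
    fit <- fit_rate_constant(tt, f, 250e-9, 200e-9)
    expect_equal(fit$k_hat / k, 1, tolerance = 1e-6)
    expect_equal(fit$background, 10, tolerance = 1e-4)
  }

  # 1% additive noise: k recovered within 2%
  set.seed(30)
  f <- to_fluorescence(closed_form_conversion(3.2e4, 250e-9, 200e-9,
                                              seq(0, 2700, 9)),
                       200e-9, 0, 200)
  fn <- f + rnorm(length(f), 0, 2)
  fit <- fit_rate_constant(seq(0, 2700, 9), fn, 250e-9, 200e-9)
  expect_equal(fit$k_hat / 3.2e4, 1, tolerance = 0.02)

  expect_error(fit_rate_constant(tt, rep(10, length(tt)), 250e-9, 200e-9),
               "conversion")
})

test_that("the cv decomposition sums relative errors first-order", {
  expect_equal(cv_decomposition(0.05, 0.03, 0.02), 0.10)
  expect_equal(cv_decomposition(0, 0, 0), 0)

  # at small independent variations the measured product CV is bracketed
  # by the largest component and the first-order sum
  set.seed(31)
  n <- 4000
  kf <- 1 + rnorm(n, 0, 0.05)
  af <- 1 + rnorm(n, 0, 0.05)
  bf <- 1 + rnorm(n, 0, 0.05)
  v <- kf * af * bf
  cv_meas <- stats::sd(v) / mean(v)
  expect_lt(cv_meas, cv_decomposition(0.05, 0.05, 0.05))
  expect_gt(cv_meas, 0.05)
  # fully correlated variations meet the sum to first order
  v_corr <- kf^3
  expect_equal(stats::sd(v_corr) / mean(v_corr),
               cv_decomposition(0.05, 0.05, 0.05), tolerance = 0.2)
})

test_that("parabola overlay recovers the fluorescence scale and peak", {
  cfg <- emulsion_config(n_droplets = 400, radius_cv = 0,
                         mixing_mode = "sinusoidal")
  prog <- pressure_program(period = 2, droplet_interval = 0.013)
  em <- generate_emulsion(cfg, prog, seed = 32)
  acq <- acquisition_config(n_frames = 50, background_nu = 0)
  ts <- simulate_trace_set(em, paper_rate_clean(), acq, noise_model(0, 0))

  cm <- estimate_invader_concentrations(ts, 500e-9)
  sl <- estimate_slopes(ts, slope_window(10, 90))
  ov <- parabola_overlay(cm, sl, paper_rate_clean(), 500e-9, 400e-9)

  # scale = max_nu / full_scale_conc: 200 n.u. per 200 nM
  expect_equal(ov$scale_factor, 200 / 200e-9, tolerance = 0.01)
  expect_lt(max(abs(ov$residuals)) / mean(sl$slopes$slope), 0.05)

  # the model curve on a 0.05 grid peaks at xi = 0.5
  mc <- model_slope_curve(seq(0, 1, 0.05), paper_rate_clean(),
                          500e-9, 400e-9, slope_window(10, 90))
  expect_equal(mc$xi[which.max(mc$model_slope)], 0.5)

  # 10% multiplicative slope noise: scale still within 3%
  sl_noisy <- sl
  set.seed(33)
  noisy <- sl$slopes$slope * (1 + rnorm(nrow(sl$slopes), 0, 0.10))
  names(noisy) <- sl$slopes$droplet_id
  sl_noisy <- slope_set(noisy, sl$window)
  ov2 <- parabola_overlay(cm, sl_noisy, paper_rate_clean(), 500e-9, 400e-9)
  expect_equal(ov2$scale_factor, 200 / 200e-9, tolerance = 0.03)

  # disjoint ids are an error
  cm_bad <- cm
  cm_bad$droplet_id <- paste0("x", cm_bad$droplet_id)
  expect_error(parabola_overlay(cm_bad, sl, paper_rate_clean(),
                                500e-9, 400e-9), "shared")
})

test_that("pool ensembles vary more than matched clean ensembles", {
  acq <- acquisition_config(n_frames = 30)
  w <- slope_window(10, 50)
  for (seed in c(41, 42)) {
    em_pool <- std_emulsion(800, seed = seed, pool = TRUE)
    em_clean <- std_emulsion(800, seed = seed, pool = FALSE)
    # identical stoichiometry noise by construction (same substreams)
    expect_identical(em_pool$xi, em_clean$xi)
    ts_pool <- simulate_trace_set(em_pool, paper_rate_clean(), acq,
                                  noise_model(0, 0))
    ts_clean <- simulate_trace_set(em_clean, paper_rate_clean(), acq,
                                   noise_model(0, 0))
    cv_pool <- variability_stats(estimate_slopes(ts_pool, w))$cv
    cv_clean <- variability_stats(estimate_slopes(ts_clean, w))$cv
    expect_gt(cv_pool, cv_clean)
  }
})

test_that("calibrated pool kinetics fit slower than clean kinetics", {
  tt <- seq(0, 2700, 15)
  for (seed in c(51, 52)) {
    em_pool <- std_emulsion(300, seed = seed, pool = TRUE,
                            calibration = 2.7 / 3.2)
    # population mean trace of the pool ensemble at (250, 200) nM
    f_pool <- rowMeans(vapply(em_pool$rate_factor, function(rf) {
      closed_form_conversion(rf * 3.2e4, 250e-9, 200e-9, tt)
    }, numeric(length(tt))))
    f_clean <- closed_form_conversion(3.2e4, 250e-9, 200e-9, tt)
    fit_pool <- fit_rate_constant(tt, to_fluorescence(f_pool, 200e-9, 0, 200),
                                  250e-9, 200e-9)
    fit_clean <- fit_rate_constant(tt, to_fluorescence(f_clean, 200e-9, 0, 200),
                                   250e-9, 200e-9)
    expect_lt(fit_pool$k_hat, fit_clean$k_hat)
    expect_equal(fit_pool$k_hat / 2.7e4, 1, tolerance = 0.02)
  }
})
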