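# split a long trace table into per-droplet blocks, preserving frame order
.split_traces <- function(traces) {
  ord <- order(traces$droplet_id, traces$frame)
  tr <- traces[ord, ]
  split(tr, tr$droplet_id)
}

.overall_slope <- function(time_s, red) {
  stats::cov(time_s, red) / stats::var(time_s)
}

#' Quality-control filtering of droplet traces
#'
#' Removes traces that cannot be analysed, mirroring the three discard
#' classes of the droplet-tracking pipeline: traces whose red-channel
#' trend is negative, traces with a significant frame-to-frame intensity
#' jump, and droplets whose reference signal is too low to be usable (the
#' out-of-focus / edge-of-field proxy). The filter is deterministic:
#' identical input yields an identical report.
#'
#' Reasons are assigned in the order low-signal, negative slope, jump,
#' so an attenuated noisy droplet is reported as out of focus even if its
#' noise would also trip the jump test.
#'
#' @param traces long trace data frame (or a `trace_set`).
#' @param jump_threshold maximum admissible frame-to-frame relative
#'   change in the red channel (default 0.25).
#' @param jump_floor denominator floor (n.u., default 25) for the relative change, so
#'   near-background frames do not produce spurious jumps.
#' @param low_signal_threshold minimum admissible mean green intensity.
#' @return an object of class `qc_report`: list with `kept` (character
#'   ids) and `discarded` (data frame: droplet_id, reason).
#' @export
qc_filter <- function(traces, jump_threshold = 0.25, jump_floor = 25,
                      low_signal_threshold = 20) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  if (is.null(traces) || nrow(traces) == 0) {
    stop("no traces to filter", call. = FALSE)
  }
  blocks <- .split_traces(traces)
  ids <- names(blocks)
  reason <- rep(NA_character_, length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (mean(b$green_nu) < low_signal_threshold) {
      reason[i] <- "out_of_focus_or_low_signal"
    } else if (.overall_slope(b$time_s, b$red_nu) < 0) {
      reason[i] <- "negative_slope"
    } else {
      d <- diff(b$red_nu)
      # subtract the smooth kinetic trend (running median is insensitive
      # to a single step) so only abrupt changes count as jumps
      trend <- if (length(d) >= 5) stats::runmed(d, 5) else stats::median(d)
      rel <- abs(d - trend) /
        pmax(b$red_nu[-length(b$red_nu)], jump_floor)
      if (max(rel) > jump_threshold) reason[i] <- "intensity_jump"
    }
  }
  kept <- ids[is.na(reason)]
  if (length(kept) == 0) {
    stop("QC discarded every trace; nothing left to analyse",
         call. = FALSE)
  }
  discarded <- data.frame(droplet_id = ids[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE)
  structure(list(kept = kept, discarded = discarded), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report: %d kept, %d discarded>\n", length(x$kept),
              nrow(x$discarded)))
  if (nrow(x$discarded) > 0) {
    print(table(x$discarded$reason))
  }
  invisible(x)
}

#' Reference-dye normalization of the reporter channel
#'
#' Divides the red channel by the green reference channel frame by frame
#' and rescales by the trace's mean green intensity, so common-mode
#' intensity fluctuations (illumination, focus drift) cancel while the
#' result stays on the normalized-unit scale of the raw red channel.
#' Traces whose reference signal is non-positive anywhere cannot use this
#' path and raise an error; route such traces through QC discard or the
#' raw-channel path instead (the mixing-sweep analysis works on raw red
#' because droplets at low xi carry almost no reference dye).
#'
#' @param red,green equal-length intensity series, n.u.
#' @return normalized red series, n.u.
#' @export
reference_normalize <- function(red, green) {
  stopifnot(length(red) == length(green))
  if (any(green <= 0)) {
    stop("non-positive reference intensity; trace cannot be ",
         "reference-normalized", call. = FALSE)
  }
  red / green * mean(green)
}

#' Build a slope set from raw per-droplet slopes
#'
#' Stores raw slopes together with their mean and the mean-normalized
#' slopes `s / <s>`, which by construction average to 1.
#'
#' @param slopes named (droplet id) or unnamed numeric vector of raw
#'   slopes, n.u./s.
#' @param window the [slope_window()] the slopes were estimated over.
#' @param mode label of the estimator used.
#' @return an object of class `slope_set`: data frame `slopes`
#'   (droplet_id, slope, slope_norm) plus `mean_slope`, `window`, `mode`.
#' @export
slope_set <- function(slopes, window = slope_window(), mode = "two_point") {
  stopifnot(is.numeric(slopes), length(slopes) >= 1)
  ids <- if (is.null(names(slopes))) {
    sprintf("d%05d", seq_along(slopes))
  } else {
    names(slopes)
  }
  m <- mean(slopes)
  if (m == 0) stop("mean slope is zero; cannot normalize", call. = FALSE)
  structure(list(
    slopes = data.frame(droplet_id = ids, slope = unname(slopes),
                        slope_norm = unname(slopes) / m,
                        stringsAsFactors = FALSE),
    mean_slope = m, window = window, mode = mode
  ), class = "slope_set")
}

#' Estimate per-droplet initial slopes
#'
#' Two estimators of the initial slope of the red (reporter) channel over
#' a finite window: `two_point` reads the frames nearest `t1` and `t2`
#' and applies `s = (f2 - f1)/(t2 - t1)`; `regression` least-squares fits
#' all frames inside the window (a robustness option for noisy traces).
#' Slopes are then normalized by their mean.
#'
#' @param traces long trace data frame or `trace_set`.
#' @param window a [slope_window()]; must lie inside the acquisition span.
#' @param mode `"two_point"` or `"regression"`.
#' @param normalize `"none"` (raw red channel) or `"ref"`
#'   (reference-normalized via [reference_normalize()] first).
#' @param ids optional subset of droplet ids (e.g. `qc$kept`).
#' @return a [slope_set()].
#' @export
estimate_slopes <- function(traces, window = slope_window(),
                            mode = c("two_point", "regression"),
                            normalize = c("none", "ref"), ids = NULL) {
  if (inherits(traces, "trace_set")) traces <- traces$traces
  mode <- match.arg(mode)
  normalize <- match.arg(normalize)
  stopifnot(inherits(window, "slope_window"))
  span <- range(traces$time_s)
  if (window$t1 < span[1] || window$t2 > span[2]) {
    stop(sprintf("slope window [%g, %g] s outside acquisition span [%g, %g] s",
                 window$t1, window$t2, span[1], span[2]), call. = FALSE)
  }
  blocks <- .split_traces(traces)
  if (!is.null(ids)) blocks <- blocks[names(blocks) %in% ids]
  if (length(blocks) == 0) stop("no traces selected", call. = FALSE)
  s <- vapply(blocks, function(b) {
    red <- if (normalize == "ref") {
      reference_normalize(b$red_nu, b$green_nu)
    } else {
      b$red_nu
    }
    if (mode == "two_point") {
      i1 <- which.min(abs(b$time_s - window$t1))
      i2 <- which.min(abs(b$time_s - window$t2))
      (red[i2] - red[i1]) / (b$time_s[i2] - b$time_s[i1])
    } else {
      inw <- b$time_s >= window$t1 & b$time_s <= window$t2
      .overall_slope(b$time_s[inw], red[inw])
    }
  }, numeric(1))
  slope_set(s, window, mode)
}

#' Dispersion statistics of a slope distribution
#'
#' The three droplet-to-droplet variability summaries: the coefficient of
#' variation (sample SD over mean) and the interquartile range, both on
#' mean-normalized slopes, and the mean absolute deviation on the raw
#' slope scale (raw slopes are of order 1e-4 n.u./s, so the MAD is
#' numerically much smaller than CV or IQR).
#'
#' @param x a [slope_set()] with at least 4 slopes.
#' @return an object of class `variability_stats`: list with `cv`, `iqr`,
#'   `mad`, `n`.
#' @export
variability_stats <- function(x) {
  stopifnot(inherits(x, "slope_set"))
  s_norm <- x$slopes$slope_norm
  s_raw <- x$slopes$slope
  if (length(s_norm) < 4) {
    stop("need at least 4 slopes for dispersion statistics",
         call. = FALSE)
  }
  structure(list(
    cv = stats::sd(s_norm) / mean(s_norm),
    iqr = unname(diff(stats::quantile(s_norm, c(0.25, 0.75), type = 7))),
    mad = mean(abs(s_raw - mean(s_raw))),
    n = length(s_norm)
  ), class = "variability_stats")
}

#' @export
print.variability_stats <- function(x, ...) {
  cat(sprintf("<variability_stats n=%d: CV=%.4g IQR=%.4g MAD=%.4g>\n",
              x$n, x$cv, x$iqr, x$mad))
  invisible(x)
}

#' Gaussian fit to the central peak of the slope distribution
#'
#' The plain CV of a slope distribution is inflated by fast outliers
#' (normalized slopes above about 1.5); fitting a Gaussian to the
#' histogram of the central peak gives a dispersion estimate robust to
#' that contamination. Nonlinear least squares of
#' `a * exp(-(x - mu)^2 / (2 sigma^2))` on a binned histogram of the
#' normalized slopes below the outlier cut.
#'
#' @param x a [slope_set()] with at least 20 slopes.
#' @param cut outlier cut on normalized slopes (default 1.5).
#' @param bins number of histogram bins (default 30).
#' @return list with `gaussian_mu`, `gaussian_sigma`, `gaussian_cv`
#'   (= sigma/mu) and the `fit` object.
#' @export
central_peak_fit <- function(x, cut = 1.5, bins = 30) {
  stopifnot(inherits(x, "slope_set"))
  s <- x$slopes$slope_norm
  if (length(s) < 20) {
    stop("need at least 20 slopes for a central-peak fit", call. = FALSE)
  }
  s <- s[s < cut]
  if (length(s) < 10 || stats::sd(s) == 0) {
    stop("degenerate histogram after outlier cut", call. = FALSE)
  }
  h <- graphics::hist(s, breaks = bins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)
  start <- list(a = max(h$counts), mu = mean(s), sigma = stats::sd(s))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sigma^2)),
                      data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("central-peak Gaussian fit failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  sigma <- abs(unname(cf["sigma"]))
  mu <- unname(cf["mu"])
  list(gaussian_mu = mu, gaussian_sigma = sigma,
       gaussian_cv = sigma / mu, fit = fit)
}

#' Estimate per-droplet invader concentrations from the reference dye
#'
#' The reference dye is supplied with the invader solution, so its
#' intensity is proportional to the invader-side volume fraction. The
#' anchors are the mean of the `n_anchor` lowest reference intensities
#' (zero invader) and the mean of the `n_anchor` highest (full invader
#' stock); intermediate droplets are linearly interpolated and clipped to
#' `[0, stock]`.
#'
#' @param ref_intensity per-droplet reference intensity: a named numeric
#'   vector, or a trace table / `trace_set` (the per-droplet mean green
#'   is used).
#' @param stock invader stock concentration, molar.
#' @param n_anchor anchor count (default 10).
#' @return an object of class `concentration_map`: data frame
#'   (droplet_id, ref_intensity, conc_est) with attributes `I_min`,
#'   `I_max`, `stock`.
#' @export
estimate_invader_concentrations <- function(ref_intensity, stock,
                                            n_anchor = 10) {
  if (inherits(ref_intensity, "trace_set")) {
    ref_intensity <- ref_intensity$traces
  }
  if (is.data.frame(ref_intensity)) {
    blocks <- .split_traces(ref_intensity)
    ref_intensity <- vapply(blocks, function(b) mean(b$green_nu),
                            numeric(1))
  }
  stopifnot(is.numeric(ref_intensity), stock > 0, n_anchor >= 1)
  if (length(ref_intensity) < n_anchor) {
    stop("need at least n_anchor droplets", call. = FALSE)
  }
  ids <- if (is.null(names(ref_intensity))) {
    sprintf("d%05d", seq_along(ref_intensity))
  } else {
    names(ref_intensity)
  }
  srt <- sort(ref_intensity)
  i_min <- mean(srt[seq_len(n_anchor)])
  i_max <- mean(srt[seq(length(srt) - n_anchor + 1, length(srt))])
  if (i_max == i_min) {
    stop("degenerate anchors: highest and lowest reference intensities ",
         "coincide", call. = FALSE)
  }
  conc <- stock * (ref_intensity - i_min) / (i_max - i_min)
  out <- data.frame(droplet_id = ids,
                    ref_intensity = unname(ref_intensity),
                    conc_est = pmin(stock, pmax(0, unname(conc))),
                    stringsAsFactors = FALSE)
  attr(out, "I_min") <- i_min
  attr(out, "I_max") <- i_max
  attr(out, "stock") <- stock
  class(out) <- c("concentration_map", "data.frame")
  out
}

#' Fit the second-order rate constant to a mean fluorescence trace
#'
#' Least-squares fit of the closed-form bimolecular solution, converted
#' to normalized fluorescence, to a measured (or simulated) mean trace:
#' `f(t) = b + max_nu * F(t; k, I0, R0) / full_scale_conc`. The fitted
#' parameters are the rate constant and the additive background. The
#' trace must span enough curvature (>= 25% conversion of the limiting
#' reactant) for the fit to be identifiable.
#'
#' @param times time points, seconds.
#' @param f fluorescence values, n.u.
#' @param I0,R0 initial concentrations, molar.
#' @param full_scale_conc concentration mapped to `max_nu`, molar.
#' @param max_nu full-scale reading, n.u.
#' @return an object of class `rate_fit`: list with `k_hat` (M^-1 s^-1),
#'   `background`, `residual_norm`, `I0`, `R0`.
#' @export
fit_rate_constant <- function(times, f, I0, R0, full_scale_conc = 200e-9,
                              max_nu = 200) {
  stopifnot(length(times) == length(f), I0 > 0, R0 > 0,
            full_scale_conc > 0)
  scale <- max_nu / full_scale_conc
  conv_span <- (max(f) - min(f)) / (scale * min(I0, R0))
  if (!is.finite(conv_span) || conv_span < 0.25) {
    stop("trace spans too little conversion (< 25%) for a rate fit",
         call. = FALSE)
  }
  # start value from the early slope: s ~ scale * k * I0 * R0
  n_early <- max(3, min(10, length(times)))
  s0 <- .overall_slope(times[seq_len(n_early)], f[seq_len(n_early)])
  k_start <- max(s0 / (scale * I0 * R0), 1)
  df <- data.frame(t = times, y = f)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + scale * closed_form_conversion(k, I0, R0, t),
      data = df, start = list(k = k_start, b = min(f)),
      lower = c(k = 1e-6, b = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop("rate fit did not converge (start k = ",
                             signif(k_start, 3), "): ",
                             conditionMessage(e), call. = FALSE)
  )
  cf <- stats::coef(fit)
  structure(list(k_hat = unname(cf["k"]), background = unname(cf["b"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 I0 = I0, R0 = R0),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit: k_hat = %.4g M^-1 s^-1, residual norm %.3g>\n",
              x$k_hat, x$residual_norm))
  invisible(x)
}

#' First-order decomposition of the initial-velocity CV
#'
#' For `v0 = k [A]0 [B]0`, small independent relative variations add to
#' first order: `dv0/v0 ~ dk/k + d[A]0/[A]0 + d[B]0/[B]0`. Used to
#' apportion the measured slope variability between rate-constant
#' variation (the random-pool sampling effect) and stoichiometry
#' variation (the droplet production process).
#'
#' @param rel_dk,rel_dA,rel_dB non-negative relative variations.
#' @return their sum.
#' @examples
#' cv_decomposition(0.05, 0.03, 0.02) # 0.10
#' @export
cv_decomposition <- function(rel_dk, rel_dA, rel_dB) {
  stopifnot(rel_dk >= 0, rel_dA >= 0, rel_dB >= 0)
  rel_dk + rel_dA + rel_dB
}

#' Finite-window model slopes over a mixing-ratio grid
#'
#' Integrates the bimolecular ODE at each grid xi with the in-droplet
#' concentrations `(xi * stock_A, (1 - xi) * stock_B)` and evaluates the
#' finite-window slope of the product concentration — the model curve the
#' stoichiometry-map data are compared against.
#'
#' @param xi_grid mixing ratios in `[0, 1]`.
#' @param params a [rate_parameters()].
#' @param stock_A,stock_B stock concentrations, molar.
#' @param window a [slope_window()].
#' @return data frame (xi, model_slope) with slopes in M/s.
#' @export
model_slope_curve <- function(xi_grid, params, stock_A, stock_B,
                              window = slope_window(10, 90)) {
  stopifnot(all(xi_grid >= 0 & xi_grid <= 1))
  ms <- vapply(xi_grid, function(xi) {
    conc <- droplet_concentrations(xi, stock_A, stock_B)
    if (conc$A == 0 || conc$B == 0) return(0)
    traj <- integrate_tmsd(params, conc$A, conc$B,
                           c(0, window$t1, window$t2))
    (traj$conc_F[3] - traj$conc_F[2]) / (window$t2 - window$t1)
  }, numeric(1))
  data.frame(xi = xi_grid, model_slope = ms)
}

#' Overlay the mixing parabola on measured slopes
#'
#' Matches the finite-window model slope curve (ODE-integrated on a dense
#' xi grid) to per-droplet measured slopes plotted against estimated
#' invader concentration. Only a single multiplicative scale factor —
#' the conversion between fluorescence units and molar concentration —
#' is fitted; the shape of the curve is fully determined by the model.
#'
#' @param conc_map a `concentration_map` from
#'   [estimate_invader_concentrations()].
#' @param slopes a [slope_set()] aligned by droplet id.
#' @param params a [rate_parameters()].
#' @param stock_A,stock_B stock concentrations, molar.
#' @param window a [slope_window()] (default 10-90 s, the mixing-sweep
#'   window).
#' @param grid_step xi grid step for the model curve (default 0.01).
#' @return list with `scale_factor` (n.u. per molar), `grid` (xi,
#'   model_slope in M/s, overlay_slope in n.u./s), `argmax_xi` (grid
#'   argmax of the model curve), `residuals`, and the matched per-droplet
#'   data frame `data`.
#' @export
parabola_overlay <- function(conc_map, slopes, params, stock_A, stock_B,
                             window = slope_window(10, 90),
                             grid_step = 0.01) {
  stopifnot(inherits(conc_map, "concentration_map"),
            inherits(slopes, "slope_set"))
  df <- merge(conc_map, slopes$slopes, by = "droplet_id")
  if (nrow(df) == 0) {
    stop("no droplet ids shared between concentrations and slopes",
         call. = FALSE)
  }
  stock <- attr(conc_map, "stock")
  df$xi_est <- df$conc_est / stock
  grid <- model_slope_curve(seq(0, 1, by = grid_step), params,
                            stock_A, stock_B, window)
  # model slope at each droplet's estimated xi (linear interpolation)
  m <- stats::approx(grid$xi, grid$model_slope, xout = df$xi_est,
                     rule = 2)$y
  scale <- sum(df$slope * m) / sum(m^2)
  grid$overlay_slope <- scale * grid$model_slope
  list(scale_factor = scale,
       grid = grid,
       argmax_xi = grid$xi[which.max(grid$model_slope)],
       residuals = df$slope - scale * m,
       data = df)
}
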