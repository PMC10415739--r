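#' Acquisition settings for synthetic time-lapse traces
#'
#' Frames are acquired at a fixed interval starting a few seconds after
#' the droplet flow is stopped (the first frames are discarded in real
#' experiments while droplets are still moving). The reference dye
#' (Atto 488 proxy) is supplied with the invader solution, so its
#' intensity is proportional to xi; the reporter channel (ROX proxy) is
#' the TMSD readout.
#'
#' @param frame_interval seconds between frames, > 0.
#' @param start_time time of the first frame, seconds.
#' @param n_frames number of frames, >= 2.
#' @param full_scale_conc reporter concentration mapped to `max_nu`
#'   normalized units, molar.
#' @param max_nu full-scale fluorescence, n.u.
#' @param background_nu reporter-channel offset from imperfect quenching,
#'   n.u.
#' @param green_full_scale green reading of a droplet with xi = 1, n.u.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_interval = 2, start_time = 4,
                               n_frames = 300, full_scale_conc = 200e-9,
                               max_nu = 200, background_nu = 10,
                               green_full_scale = 200) {
  stopifnot(frame_interval > 0, n_frames >= 2, full_scale_conc > 0,
            start_time >= 0, max_nu > 0, background_nu >= 0,
            green_full_scale > 0)
  structure(list(frame_interval = frame_interval, start_time = start_time,
                 n_frames = as.integer(n_frames),
                 full_scale_conc = full_scale_conc, max_nu = max_nu,
                 background_nu = background_nu,
                 green_full_scale = green_full_scale),
            class = "acquisition_config")
}

#' Noise model for synthetic traces
#'
#' Two components: a per-frame multiplicative factor shared by both
#' channels (illumination / focus fluctuation, the component that
#' reference normalization cancels) and independent additive noise per
#' channel and frame (shot/readout noise).
#'
#' @param additive_sd additive noise SD, n.u.
#' @param multiplicative_sd SD of the shared per-frame relative factor.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 1, multiplicative_sd = 0.01) {
  stopifnot(additive_sd >= 0, multiplicative_sd >= 0)
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd),
            class = "noise_model")
}

#' Artifact mix injected into synthetic trace sets
#'
#' The three droplet classes the QC filter is designed to remove:
#' decaying ("negative slope") traces, traces with a sudden intensity
#' step, and out-of-focus droplets (attenuated and noisier in both
#' channels).
#'
#' @param frac_negative_slope,frac_jump,frac_out_of_focus fractions of
#'   droplets assigned to each artifact class; they must sum to <= 1 and
#'   classes never overlap.
#' @param jump_magnitude relative size of the intensity step.
#' @return an object of class `artifact_spec`.
#' @export
artifact_spec <- function(frac_negative_slope = 0, frac_jump = 0,
                          frac_out_of_focus = 0, jump_magnitude = 0.5) {
  fr <- c(frac_negative_slope, frac_jump, frac_out_of_focus)
  stopifnot(all(fr >= 0), jump_magnitude >= 0)
  if (sum(fr) > 1) stop("artifact fractions must sum to <= 1",
                        call. = FALSE)
  structure(list(frac_negative_slope = frac_negative_slope,
                 frac_jump = frac_jump,
                 frac_out_of_focus = frac_out_of_focus,
                 jump_magnitude = jump_magnitude),
            class = "artifact_spec")
}

#' Simulate two-channel fluorescence traces for an emulsion
#'
#' For each droplet the reporter (red) channel follows the deterministic
#' second-order model with `k_eff = rate_factor * k` at the droplet's
#' initial concentrations, converted to normalized units; the reference
#' (green) channel is constant and proportional to xi. Noise is applied
#' as a per-frame multiplicative factor common to both channels plus
#' independent additive noise. The ground truth (xi, k_eff, artifact
#' label) is stored in a separate `truth` table so analyses can be run
#' blind.
#'
#' @param emulsion data frame from [generate_emulsion()].
#' @param params a [rate_parameters()].
#' @param acq an [acquisition_config()].
#' @param noise a [noise_model()].
#' @param seed master seed (substream "noise").
#' @return an object of class `trace_set`: list with `traces` (long data
#'   frame: droplet_id, frame, time_s, green_nu, red_nu) and `truth`
#'   (droplet_id, xi_true, k_eff, artifact).
#' @export
simulate_trace_set <- function(emulsion, params, acq = acquisition_config(),
                               noise = noise_model(), seed = NULL) {
  stopifnot(inherits(params, "rate_parameters"),
            inherits(acq, "acquisition_config"),
            inherits(noise, "noise_model"))
  n <- nrow(emulsion)
  if (n == 0) stop("empty emulsion", call. = FALSE)
  times <- acq$start_time + (seq_len(acq$n_frames) - 1) * acq$frame_interval

  red_model <- matrix(0, n, acq$n_frames)
  for (i in seq_len(n)) {
    k_eff <- emulsion$rate_factor[i] * params$k
    f <- if (emulsion$conc_invader[i] == 0 ||
             emulsion$conc_reporter[i] == 0) {
      rep(0, acq$n_frames)
    } else {
      closed_form_conversion(k_eff, emulsion$conc_invader[i],
                             emulsion$conc_reporter[i], times)
    }
    red_model[i, ] <- to_fluorescence(f, acq$full_scale_conc,
                                      acq$background_nu, acq$max_nu)
  }
  green_model <- matrix(rep(emulsion$xi * acq$green_full_scale,
                            acq$n_frames), n, acq$n_frames)

  if (noise$multiplicative_sd > 0 || noise$additive_sd > 0) {
    noise_draw <- with_substream(seed, "noise", {
      list(mult = matrix(1 + stats::rnorm(n * acq$n_frames, 0,
                                          noise$multiplicative_sd),
                         n, acq$n_frames),
           add_g = matrix(stats::rnorm(n * acq$n_frames, 0,
                                       noise$additive_sd),
                          n, acq$n_frames),
           add_r = matrix(stats::rnorm(n * acq$n_frames, 0,
                                       noise$additive_sd),
                          n, acq$n_frames))
    })
    red <- red_model * noise_draw$mult + noise_draw$add_r
    green <- green_model * noise_draw$mult + noise_draw$add_g
  } else {
    red <- red_model
    green <- green_model
  }

  traces <- data.frame(
    droplet_id = rep(emulsion$droplet_id, each = acq$n_frames),
    frame = rep(seq_len(acq$n_frames), n),
    time_s = rep(times, n),
    green_nu = as.vector(t(green)),
    red_nu = as.vector(t(red)),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    droplet_id = emulsion$droplet_id,
    xi_true = emulsion$xi,
    k_eff = emulsion$rate_factor * params$k,
    artifact = "none",
    stringsAsFactors = FALSE
  )
  structure(list(traces = traces, truth = truth, acq = acq),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d droplets x %d frames>\n",
              nrow(x$truth), length(unique(x$traces$frame))))
  invisible(x)
}

#' Inject QC artifacts into a synthetic trace set
#'
#' Assigns disjoint random subsets of droplets to the three artifact
#' classes of [artifact_spec()]: negative-slope traces get their red
#' channel reflected about its first value (a decaying signal), jump
#' traces get a multiplicative step of `jump_magnitude` at a random
#' interior frame, and out-of-focus traces are attenuated in both
#' channels with extra additive noise. Truth labels are updated.
#'
#' @param trace_set a `trace_set` from [simulate_trace_set()].
#' @param spec an [artifact_spec()].
#' @param seed integer seed (substream "artifacts").
#' @return the modified `trace_set`.
#' @export
inject_artifacts <- function(trace_set, spec, seed = NULL) {
  stopifnot(inherits(trace_set, "trace_set"),
            inherits(spec, "artifact_spec"))
  ids <- trace_set$truth$droplet_id
  n <- length(ids)
  n_neg <- round(spec$frac_negative_slope * n)
  n_jump <- round(spec$frac_jump * n)
  n_oof <- round(spec$frac_out_of_focus * n)
  if (n_neg + n_jump + n_oof == 0) return(trace_set)

  assign <- with_substream(seed, "artifacts", {
    picked <- sample(ids, n_neg + n_jump + n_oof)
    jump_frames <- sample(2:(max(trace_set$traces$frame) - 1),
                          n_jump, replace = TRUE)
    extra <- stats::rnorm(nrow(trace_set$traces), 0, 3)
    list(neg = picked[seq_len(n_neg)],
         jump = picked[n_neg + seq_len(n_jump)],
         oof = picked[n_neg + n_jump + seq_len(n_oof)],
         jump_frames = jump_frames, extra = extra)
  })

  tr <- trace_set$traces
  for (id in assign$neg) {
    sel <- tr$droplet_id == id
    r <- tr$red_nu[sel]
    tr$red_nu[sel] <- 2 * r[1] - r # reflected: monotone decreasing trend
  }
  for (j in seq_along(assign$jump)) {
    id <- assign$jump[j]
    sel <- tr$droplet_id == id
    step_at <- assign$jump_frames[j]
    bump <- tr$frame[sel] >= step_at
    tr$red_nu[sel][bump] <- tr$red_nu[sel][bump] * (1 + spec$jump_magnitude)
  }
  oof_sel <- tr$droplet_id %in% assign$oof
  tr$green_nu[oof_sel] <- tr$green_nu[oof_sel] * 0.15 +
    assign$extra[which(oof_sel)]
  tr$red_nu[oof_sel] <- tr$red_nu[oof_sel] * 0.15 +
    assign$extra[rev(which(oof_sel))]

  trace_set$traces <- tr
  trace_set$truth$artifact[ids %in% assign$neg] <- "negative_slope"
  trace_set$truth$artifact[ids %in% assign$jump] <- "intensity_jump"
  trace_set$truth$artifact[ids %in% assign$oof] <- "out_of_focus"
  trace_set
}

#' Write / read droplet trace tables
#'
#' The on-disk format is a plain CSV with columns `droplet_id`, `frame`,
#' `time_s`, `green_nu`, `red_nu`; intensities are written with six
#' significant digits and round-trip losslessly at that precision. The
#' ground truth, when present, goes to a `<stem>_truth.csv` sidecar so
#' that analysis code can be pointed at the trace table alone.
#'
#' @param trace_set a `trace_set`.
#' @param path CSV path for the trace table.
#' @param truth_path sidecar path; `NULL` derives `<stem>_truth.csv`,
#'   `NA` suppresses the sidecar.
#' @return `read_trace_table` returns a `trace_set` (with `truth = NULL`;
#'   use [read_truth_table()] to load the sidecar explicitly).
#' @export
write_trace_table <- function(trace_set, path, truth_path = NULL) {
  stopifnot(inherits(trace_set, "trace_set"))
  tr <- trace_set$traces
  out <- data.frame(droplet_id = tr$droplet_id, frame = tr$frame,
                    time_s = signif(tr$time_s, 6),
                    green_nu = signif(tr$green_nu, 6),
                    red_nu = signif(tr$red_nu, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(trace_set$truth) &&
      !(length(truth_path) == 1 && is.na(truth_path))) {
    if (is.null(truth_path)) {
      truth_path <- sub("\\.csv$", "_truth.csv", path)
    }
    tt <- trace_set$truth
    tt$xi_true <- signif(tt$xi_true, 6)
    tt$k_eff <- signif(tt$k_eff, 6)
    utils::write.csv(tt, truth_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trace_table
#' @export
read_trace_table <- function(path) {
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) {
                  stop("malformed trace table '", path, "': ",
                       conditionMessage(e), call. = FALSE)
                })
  need <- c("droplet_id", "frame", "time_s", "green_nu", "red_nu")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("trace table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("frame", "time_s", "green_nu", "red_nu")) {
    if (!is.numeric(x[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(x[[col]]))))[1]
      stop("non-numeric value in column '", col, "' near data line ",
           bad, call. = FALSE)
    }
  }
  structure(list(traces = x[need], truth = NULL, acq = NULL),
            class = "trace_set")
}

#' @rdname write_trace_table
#' @export
read_truth_table <- function(truth_path) {
  utils::read.csv(truth_path, stringsAsFactors = FALSE)
}
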