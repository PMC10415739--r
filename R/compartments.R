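#' Emulsion configuration
#'
#' Describes one droplet-production run: how many droplets, their size
#' distribution, the two aqueous stocks merged at the flow-focusing
#' junction (invader side A, reporter side B), the random-pool content of
#' the invader stock, and how the mixing ratio xi is programmed.
#'
#' Defaults follow the compartmentalized TMSD experiments: a 400 nM
#' reporter stock against a 500 nM invader stock, optionally with a 5 uM
#' random 25-mer pool on the invader side (10-fold excess over the
#' invader), droplet radii 10-30 um with a radius CV of a few percent.
#'
#' @param n_droplets number of droplets, >= 1.
#' @param radius_mean mean droplet radius, um.
#' @param radius_cv coefficient of variation of the radius, in `[0, 1)`.
#' @param stock_A invader-side stock concentration, molar.
#' @param stock_B reporter-side stock concentration, molar.
#' @param pool_stock total random-pool concentration in stock A, molar
#'   (0 disables the pool).
#' @param pool_size number of distinct pool sequences in the finite
#'   surrogate pool.
#' @param mixing_mode `"fixed"` (constant xi = 0.5 with optional jitter)
#'   or `"sinusoidal"` (xi follows the pressure program).
#' @param xi_sd droplet-to-droplet Gaussian jitter on xi in fixed mode —
#'   the stoichiometry noise attributed to the production process.
#' @return an object of class `emulsion_config`.
#' @export
emulsion_config <- function(n_droplets = 1000,
                            radius_mean = 15,
                            radius_cv = 0.03,
                            stock_A = 500e-9,
                            stock_B = 400e-9,
                            pool_stock = 0,
                            pool_size = 10000,
                            mixing_mode = c("fixed", "sinusoidal"),
                            xi_sd = 0) {
  mixing_mode <- match.arg(mixing_mode)
  stopifnot(n_droplets >= 1, radius_mean > 0,
            radius_cv >= 0, radius_cv < 1,
            stock_A > 0, stock_B > 0, pool_stock >= 0, pool_size >= 1,
            xi_sd >= 0)
  structure(list(n_droplets = as.integer(n_droplets),
                 radius_mean = radius_mean, radius_cv = radius_cv,
                 stock_A = stock_A, stock_B = stock_B,
                 pool_stock = pool_stock, pool_size = as.integer(pool_size),
                 mixing_mode = mixing_mode, xi_sd = xi_sd),
            class = "emulsion_config")
}

#' Sinusoidal pressure program for the two aqueous inlets
#'
#' Opposing sinusoidal pressures on the invader and reporter inlets keep
#' the total pressure (and hence droplet size) constant while sweeping the
#' mixing ratio. The achieved xi of the droplet generated at time
#' `t_i = i * droplet_interval` is
#' `xi_i = 0.5 + 0.5 * amplitude * sin(2 pi t_i / period + phase)`.
#'
#' @param period oscillation period, seconds (> 0); experiments used
#'   0.1-5 s.
#' @param phase phase offset, radians.
#' @param amplitude fraction of the half-range swept, in `[0, 1]`.
#' @param droplet_interval time between consecutive droplets, seconds.
#' @return an object of class `pressure_program`.
#' @export
pressure_program <- function(period = 2, phase = 0, amplitude = 1,
                             droplet_interval = 0.01) {
  stopifnot(period > 0, amplitude >= 0, amplitude <= 1,
            droplet_interval > 0)
  structure(list(period = period, phase = phase, amplitude = amplitude,
                 droplet_interval = droplet_interval),
            class = "pressure_program")
}

#' Volume of a spherical droplet
#'
#' `V = (4 pi / 3) r^3`, converted from cubic micrometres to litres.
#' Radii of 10-30 um give volumes of roughly 4-110 pl.
#'
#' @param radius droplet radius in um, > 0 (vectorized).
#' @return volume in litres.
#' @examples
#' sphere_volume(10) # ~4.2e-12 L = 4.2 pl
#' @export
sphere_volume <- function(radius) {
  stopifnot(is.numeric(radius))
  if (any(radius <= 0)) stop("radius must be positive", call. = FALSE)
  (4 * pi / 3) * radius^3 * 1e-15
}

#' Expected molecule copy number in a droplet
#'
#' `N_x = N_A * c_x * V(r)`: at the 100 nM-1 uM concentrations used here
#' and 10-30 um radii this is 10^6-10^7 copies, far above the regime of
#' intrinsic reaction-noise effects. The expectation is returned as a
#' real number; discretization (e.g. Poisson sampling) is the caller's
#' choice.
#'
#' @param conc molar concentration, >= 0 (vectorized).
#' @param radius droplet radius, um.
#' @return expected copy number (double).
#' @examples
#' copy_number(500e-9, 10) # ~1.26e6
#' @export
copy_number <- function(conc, radius) {
  stopifnot(is.numeric(conc))
  if (any(conc < 0)) stop("concentration must be non-negative",
                          call. = FALSE)
  AVOGADRO * conc * sphere_volume(radius)
}

#' Mixing-ratio series generated by a sinusoidal pressure program
#'
#' Evaluates the programmed volume fraction xi for `n` consecutively
#' generated droplets at times `t_i = i * droplet_interval`,
#' `i = 0, ..., n-1`.
#'
#' @param n number of droplets.
#' @param program a [pressure_program()].
#' @return numeric vector of xi values in
#'   `[(1 - amplitude)/2, (1 + amplitude)/2]`.
#' @examples
#' mixing_ratio_series(3, pressure_program(amplitude = 0)) # all 0.5
#' @export
mixing_ratio_series <- function(n, program) {
  stopifnot(is.numeric(n), n >= 1, inherits(program, "pressure_program"))
  t <- (seq_len(n) - 1) * program$droplet_interval
  0.5 + 0.5 * program$amplitude *
    sin(2 * pi * t / program$period + program$phase)
}

#' In-droplet concentrations at a given mixing ratio
#'
#' With `xi = V_A / (V_A + V_B)` the volume fraction of the invader-side
#' solution, the droplet concentrations are `[A] = xi * [A]_stock` and
#' `[B] = (1 - xi) * [B]_stock`; the two are linked by
#' `[B] = [B]_stock (1 - [A]/[A]_stock)`.
#'
#' @param xi volume fraction in `[0, 1]` (vectorized).
#' @param stock_A,stock_B stock concentrations, molar.
#' @return list with components `A` and `B` (molar).
#' @examples
#' droplet_concentrations(0.5, 500e-9, 400e-9) # 250 nM, 200 nM
#' @export
droplet_concentrations <- function(xi, stock_A, stock_B) {
  stopifnot(is.numeric(xi))
  if (any(xi < 0 | xi > 1)) stop("xi must lie in [0, 1]", call. = FALSE)
  list(A = xi * stock_A, B = (1 - xi) * stock_B)
}

#' Poisson partitioning of the random pool into one droplet
#'
#' Each distinct pool sequence is encapsulated independently with a
#' Poisson-distributed copy number whose mean is
#' `xi * (pool_stock / pool_size) * N_A * V` — the low-occupancy limit of
#' multinomial partitioning, the standard encapsulation model. This is
#' the mechanism behind droplet-to-droplet undersampling of the pool:
#' each droplet carries a slightly different pool composition.
#'
#' @param pool_stock total pool concentration in the invader stock, molar.
#' @param pool_size number of distinct sequences, >= 1.
#' @param volume droplet volume, litres, > 0.
#' @param xi invader-side volume fraction.
#' @param seed optional integer seed (substream "partition").
#' @return integer vector of per-sequence copy counts, length `pool_size`.
#' @export
sample_pool_partition <- function(pool_stock, pool_size, volume, xi = 0.5,
                                  seed = NULL) {
  stopifnot(pool_size >= 1, pool_stock >= 0, xi >= 0, xi <= 1)
  if (volume <= 0) stop("volume must be positive", call. = FALSE)
  if (pool_stock == 0) return(integer(pool_size))
  lambda <- xi * (pool_stock / pool_size) * AVOGADRO * volume
  with_substream(seed, "partition", stats::rpois(pool_size, lambda))
}

#' Generate a full emulsion of droplet specifications
#'
#' Draws droplet radii from a truncated normal distribution with the
#' configured mean and CV, assigns mixing ratios (constant 0.5 with
#' optional jitter in fixed mode, or the sinusoidal series), computes
#' in-droplet concentrations and expected copy numbers, Poisson-samples
#' the pool composition per droplet, and evaluates each droplet's
#' effective rate factor from its sampled pool.
#'
#' @param config an [emulsion_config()].
#' @param program a [pressure_program()]; required in sinusoidal mode.
#' @param pool_interactions optional data frame with a `ddG` column (one
#'   row per distinct pool sequence, e.g. from [pool_equilibrium()]);
#'   required when `config$pool_stock > 0`.
#' @param seed master seed; substreams "radii", "xi", "partition" are
#'   derived from it.
#' @param model an [energy_model()] for the rate-factor computation.
#' @param calibration optional target population-mean rate factor in
#'   `(0, 1]` (e.g. `2.7 / 3.2`), applied via
#'   [calibrate_rate_factors()].
#' @param keep_pool_counts if TRUE, attach the per-droplet pool count
#'   matrix as attribute `"pool_counts"` (may be large).
#' @return data frame of class `emulsion` with columns `droplet_id`,
#'   `radius_um`, `volume_l`, `xi`, `conc_invader`, `conc_reporter`,
#'   `copies_invader`, `copies_reporter`, `rate_factor`.
#' @export
generate_emulsion <- function(config, program = NULL,
                              pool_interactions = NULL, seed = NULL,
                              model = energy_model(), calibration = NULL,
                              keep_pool_counts = FALSE) {
  stopifnot(inherits(config, "emulsion_config"))
  n <- config$n_droplets

  radii <- with_substream(seed, "radii", {
    r <- stats::rnorm(n, config$radius_mean,
                      config$radius_cv * config$radius_mean)
    while (any(bad <- r <= 0)) { # truncate at zero by resampling
      r[bad] <- stats::rnorm(sum(bad), config$radius_mean,
                             config$radius_cv * config$radius_mean)
    }
    r
  })

  xi <- if (config$mixing_mode == "sinusoidal") {
    if (is.null(program)) {
      stop("sinusoidal mixing requires a pressure program", call. = FALSE)
    }
    mixing_ratio_series(n, program)
  } else {
    with_substream(seed, "xi", {
      pmin(1, pmax(0, 0.5 + stats::rnorm(n, 0, config$xi_sd)))
    })
  }

  vol <- sphere_volume(radii)
  conc <- droplet_concentrations(xi, config$stock_A, config$stock_B)

  rate_factor <- rep(1, n)
  counts_mat <- NULL
  if (config$pool_stock > 0) {
    if (is.null(pool_interactions) ||
        !"ddG" %in% names(pool_interactions)) {
      stop("pool_stock > 0 requires pool_interactions with a ddG column",
           call. = FALSE)
    }
    if (nrow(pool_interactions) != config$pool_size) {
      stop("pool_interactions must have one row per distinct pool sequence",
           call. = FALSE)
    }
    ddg <- pool_interactions$ddG
    rate_factor <- with_substream(seed, "partition", {
      vapply(seq_len(n), function(i) {
        counts <- stats::rpois(config$pool_size,
                               xi[i] * (config$pool_stock /
                                          config$pool_size) *
                                 AVOGADRO * vol[i])
        if (conc$A[i] == 0) return(1.0) # no invader, nothing to sequester
        concs <- counts / (AVOGADRO * vol[i])
        effective_rate_factor(ddg, concs, conc$A[i], model)
      }, numeric(1))
    })
    if (keep_pool_counts) {
      counts_mat <- with_substream(seed, "partition", {
        matrix(stats::rpois(n * config$pool_size,
                            rep(xi, each = config$pool_size) *
                              (config$pool_stock / config$pool_size) *
                              AVOGADRO * rep(vol, each = config$pool_size)),
               nrow = n, byrow = TRUE)
      })
    }
    if (!is.null(calibration)) {
      rate_factor <- calibrate_rate_factors(rate_factor, calibration)
    }
  }

  out <- data.frame(
    droplet_id = sprintf("d%05d", seq_len(n)),
    radius_um = radii,
    volume_l = vol,
    xi = xi,
    conc_invader = conc$A,
    conc_reporter = conc$B,
    copies_invader = copy_number(conc$A, radii),
    copies_reporter = copy_number(conc$B, radii),
    rate_factor = rate_factor,
    stringsAsFactors = FALSE
  )
  class(out) <- c("emulsion", "data.frame")
  if (keep_pool_counts && !is.null(counts_mat)) {
    attr(out, "pool_counts") <- counts_mat
  }
  out
}

#' Write / read an emulsion table as CSV
#'
#' Concentrations are stored in nanomolar in the file for readability and
#' converted back to molar on read.
#'
#' @param emulsion an `emulsion` data frame from [generate_emulsion()].
#' @param path output file.
#' @export
write_emulsion_csv <- function(emulsion, path) {
  out <- data.frame(
    droplet_id = emulsion$droplet_id,
    radius_um = signif(emulsion$radius_um, 6),
    xi = signif(emulsion$xi, 6),
    conc_invader_nM = signif(emulsion$conc_invader * 1e9, 6),
    conc_reporter_nM = signif(emulsion$conc_reporter * 1e9, 6),
    rate_factor = signif(emulsion$rate_factor, 6)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_emulsion_csv
#' @export
read_emulsion_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("droplet_id", "radius_um", "xi", "conc_invader_nM",
            "conc_reporter_nM", "rate_factor")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("emulsion CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    droplet_id = x$droplet_id,
    radius_um = x$radius_um,
    volume_l = sphere_volume(x$radius_um),
    xi = x$xi,
    conc_invader = x$conc_invader_nM * 1e-9,
    conc_reporter = x$conc_reporter_nM * 1e-9,
    copies_invader = copy_number(x$conc_invader_nM * 1e-9, x$radius_um),
    copies_reporter = copy_number(x$conc_reporter_nM * 1e-9, x$radius_um),
    rate_factor = x$rate_factor,
    stringsAsFactors = FALSE
  )
  class(out) <- c("emulsion", "data.frame")
  out
}
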