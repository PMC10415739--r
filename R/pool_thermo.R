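DNA_LETTERS <- c("A", "C", "G", "T")
# integer encoding A=1, C=2, G=3, T=4; Watson-Crick complement is 5 - code
.encode_seq <- function(x) {
  codes <- match(strsplit(toupper(x), "")[[1]], DNA_LETTERS)
  if (anyNA(codes)) {
    stop("sequence contains letters outside {A,C,G,T}: ", x, call. = FALSE)
  }
  codes
}
.decode_seq <- function(codes) paste(DNA_LETTERS[codes], collapse = "")

#' Construct a DNA strand
#'
#' A minimal container for a named DNA sequence (5'->3', alphabet
#' \{A,C,G,T\}), the substrate of the pool-thermodynamics layer.
#'
#' @param id character label.
#' @param sequence character scalar over A/C/G/T, length >= 1.
#' @return an object of class `dna_strand` with fields `id` and `sequence`.
#' @examples
#' dna_strand("inv", "ACGTACGT")
#' @export
dna_strand <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1,
            is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 1) stop("empty sequence", call. = FALSE)
  .encode_seq(sequence) # validates alphabet
  structure(list(id = id, sequence = toupper(sequence)), class = "dna_strand")
}

#' @export
print.dna_strand <- function(x, ...) {
  cat(sprintf("<dna_strand %s: %s (%d nt)>\n", x$id, x$sequence,
              nchar(x$sequence)))
  invisible(x)
}

#' Size of the DNA sequence space for a given strand length
#'
#' The number of distinct DNA sequences of length `n`, `4^n`. A 5-nt
#' toehold spans 1024 sequences; a 25-mer random pool spans about 10^15,
#' so any realistic emulsion samples only a vanishing fraction of it.
#'
#' @param length strand length in nucleotides.
#' @return `4^length` as a double.
#' @examples
#' sequence_space_size(5)   # 1024
#' sequence_space_size(25)  # ~1e15
#' @export
sequence_space_size <- function(length) {
  stopifnot(is.numeric(length), length >= 1)
  4^length
}

#' Thermodynamic model settings
#'
#' Bundles the free-energy backend, the temperature at which Boltzmann
#' factors and equilibrium constants are evaluated, and a descriptive salt
#' context. The default `nearest_neighbor` backend scores the best ungapped
#' antiparallel complementary alignment with a unified dinucleotide stack
#' table (shipped with the package) and a constant duplex-initiation
#' penalty, and sets the intramolecular folding energies of the isolated
#' strands to zero. The `external` backend delegates all three free
#' energies to a user-supplied function `external_fn(invader, strand)`
#' returning `list(dG_AB=, dG_A=, dG_B=)` in kcal/mol, for users with a
#' full secondary-structure engine.
#'
#' @param backend `"nearest_neighbor"` or `"external"`.
#' @param temperature kelvin; default 302.15 K (29 degrees C, the
#'   experiment's imaging temperature).
#' @param salt free-text description of the ionic conditions.
#' @param external_fn required when `backend = "external"`.
#' @return an object of class `energy_model`; `$kT` holds R*T in kcal/mol.
#' @examples
#' energy_model()
#' @export
energy_model <- function(backend = c("nearest_neighbor", "external"),
                         temperature = 302.15,
                         salt = "1x TE, 100 mM NaCl, 12.5 mM MgCl2",
                         external_fn = NULL) {
  backend <- tryCatch(match.arg(backend),
                      error = function(e) stop("unknown energy backend",
                                               call. = FALSE))
  stopifnot(is.numeric(temperature), length(temperature) == 1)
  if (temperature <= 0) stop("temperature must be > 0 K", call. = FALSE)
  if (backend == "external" && !is.function(external_fn)) {
    stop("external backend requires an external_fn", call. = FALSE)
  }
  structure(list(backend = backend, temperature = temperature, salt = salt,
                 kT = R_KCAL * temperature, external_fn = external_fn),
            class = "energy_model")
}

# stack-energy lookup: 4x4 matrix indexed by the two top-strand base codes
.nn_env <- new.env(parent = emptyenv())

nn_table <- function() {
  if (is.null(.nn_env$table)) {
    path <- system.file("extdata", "nn_unified_dG37.tsv",
                        package = "dropletTMSD")
    raw <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stacks <- raw[raw$step != "initiation", ]
    m <- matrix(NA_real_, 4, 4, dimnames = list(DNA_LETTERS, DNA_LETTERS))
    for (i in seq_len(nrow(stacks))) {
      b <- strsplit(stacks$step[i], "")[[1]]
      m[b[1], b[2]] <- stacks$dG_kcal_mol[i]
    }
    if (anyNA(m)) stop("nearest-neighbor table incomplete", call. = FALSE)
    .nn_env$table <- m
    .nn_env$init <- raw$dG_kcal_mol[raw$step == "initiation"]
  }
  list(stacks = .nn_env$table, initiation = .nn_env$init)
}

#' Generate a random oligonucleotide pool
#'
#' Draws `n` sequences of the given length with every position sampled
#' uniformly and independently from \{A,C,G,T\} — the in-silico analogue
#' of a machine-mixed random pool (e.g. N25, 25-mers).
#'
#' @param n number of strands, >= 1.
#' @param length strand length in nucleotides, >= 1.
#' @param seed integer seed; the same seed always reproduces the same pool.
#' @return list of [dna_strand()] objects with ids `pool_000001, ...`.
#' @examples
#' pool <- generate_random_pool(5, 25, seed = 1)
#' pool[[1]]
#' @export
generate_random_pool <- function(n, length, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    stop("length must be a positive count", call. = FALSE)
  }
  n <- as.integer(n); len <- as.integer(length)
  letters_mat <- with_substream(seed, "pool", {
    matrix(sample(DNA_LETTERS, n * len, replace = TRUE), nrow = n)
  })
  seqs <- apply(letters_mat, 1, paste, collapse = "")
  ids <- sprintf("pool_%06d", seq_len(n))
  mapply(dna_strand, ids, seqs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

# Core hybridization scorer: best ungapped antiparallel alignment of the
# invader (5'->3') against each pool strand, scored as the sum of unified
# nearest-neighbor stack energies over adjacent complementary base pairs
# plus one initiation penalty; clamped at 0 when no alignment is stable.
# `pool_mat` is an n x L integer matrix of encoded sequences.
.pool_duplex_dG <- function(inv_codes, pool_mat) {
  nn <- nn_table()
  li <- length(inv_codes)
  lp <- ncol(pool_mat)
  n <- nrow(pool_mat)
  # reverse the pool strands so column j faces invader position j + offset
  rev_mat <- pool_mat[, rev(seq_len(lp)), drop = FALSE]
  best <- rep(0, n) # clamp: unfavourable duplexes count as no interaction
  for (off in (-(lp - 1)):(li - 1)) {
    ia <- max(1, 1 + off):min(li, lp + off) # invader positions in overlap
    ib <- ia - off                          # reversed-strand positions
    k <- length(ia)
    if (k < 2) next
    # complement match per aligned position (n x k logical)
    comp <- rev_mat[, ib, drop = FALSE] ==
      matrix(5 - inv_codes[ia], n, k, byrow = TRUE)
    # stack energy of each invader dinucleotide step in the overlap
    step_e <- nn$stacks[cbind(inv_codes[ia[-k]], inv_codes[ia[-1]])]
    stacked <- comp[, -k, drop = FALSE] & comp[, -1, drop = FALSE]
    e <- nn$initiation +
      as.vector(stacked %*% step_e)
    best <- pmin(best, e)
  }
  best
}

#' Interaction free energy between an invader and one pool strand
#'
#' Computes the binding free energy of the heterodimer relative to the
#' isolated strands, `ddG = dG_AB - (dG_A + dG_B)`, in kcal/mol. Under the
#' nearest-neighbor backend `dG_AB` is the minimum over all ungapped
#' antiparallel alignments of the summed stack energies of adjacent
#' complementary base pairs plus a constant initiation penalty, and
#' `dG_A = dG_B = 0`; the result is clamped at 0 so that a pair with no
#' stable duplex scores as non-interacting rather than being rewarded.
#'
#' @param invader,strand [dna_strand()] objects.
#' @param model an [energy_model()].
#' @return ddG in kcal/mol, always <= 0.
#' @examples
#' m <- energy_model()
#' interaction_ddG(dna_strand("a", "AAAAA"), dna_strand("b", "TTTTT"), m)
#' @export
interaction_ddG <- function(invader, strand, model = energy_model()) {
  stopifnot(inherits(invader, "dna_strand"), inherits(strand, "dna_strand"),
            inherits(model, "energy_model"))
  if (model$backend == "external") {
    g <- model$external_fn(invader, strand)
    return(min(0, g$dG_AB - (g$dG_A + g$dG_B)))
  }
  inv <- .encode_seq(invader$sequence)
  mat <- matrix(.encode_seq(strand$sequence), nrow = 1)
  .pool_duplex_dG(inv, mat)
}

#' Interaction free energies for a whole pool (vectorized)
#'
#' Same model as [interaction_ddG()] evaluated for every member of a pool
#' against one invader, in a single vectorized pass.
#'
#' @param invader a [dna_strand()].
#' @param pool list of [dna_strand()] objects of equal length.
#' @param model an [energy_model()].
#' @return numeric vector of ddG values (kcal/mol), one per pool strand.
#' @export
pool_ddG <- function(invader, pool, model = energy_model()) {
  stopifnot(inherits(invader, "dna_strand"), length(pool) >= 1)
  if (model$backend == "external") {
    return(vapply(pool, function(s) interaction_ddG(invader, s, model),
                  numeric(1)))
  }
  lens <- vapply(pool, function(s) nchar(s$sequence), integer(1))
  if (length(unique(lens)) != 1) {
    stop("pool strands must share a common length for the vectorized path",
         call. = FALSE)
  }
  mat <- t(vapply(pool, function(s) .encode_seq(s$sequence),
                  integer(lens[1])))
  .pool_duplex_dG(.encode_seq(invader$sequence), mat)
}

#' Boltzmann probability that the invader is bound to each pool member
#'
#' Given the interaction free energies of the pool, returns the Boltzmann
#' weights `p(n) = Q^-1 exp(-ddG_n / kT)` with
#' `Q = sum_j exp(-ddG_j / kT)`: the probability that a single invader
#' copy is found in complex with pool member n given that it is bound to
#' exactly one of them. Probabilities sum to one and decrease strictly
#' with increasing ddG.
#'
#' @param ddGs numeric vector of ddG values in kcal/mol; non-empty.
#' @param model an [energy_model()].
#' @return numeric vector of probabilities summing to 1.
#' @examples
#' boltzmann_bound_probabilities(c(-5, -5), energy_model())
#' @export
boltzmann_bound_probabilities <- function(ddGs, model = energy_model()) {
  if (length(ddGs) == 0) stop("empty energy list", call. = FALSE)
  stopifnot(is.numeric(ddGs))
  w <- -ddGs / model$kT
  w <- exp(w - max(w)) # stabilized softmax
  w / sum(w)
}

#' Equilibrium bound fraction of the invader in a two-state binding model
#'
#' Treats a single pairwise equilibrium `A + R <-> C` with
#' `K_eq = (1 M^-1) exp(-ddG / kT)` and solves the mass-balance quadratic
#' exactly for the complex concentration; the returned `theta = [C]/A_tot`
#' is the fraction of invader sequestered by that pool strand at the given
#' total concentrations.
#'
#' @param ddG interaction free energy, kcal/mol.
#' @param invader_conc total invader concentration, molar, > 0.
#' @param strand_conc total pool-strand concentration, molar, > 0.
#' @param model an [energy_model()].
#' @return theta in `[0, 1]`, non-increasing in ddG.
#' @examples
#' two_state_bound_fraction(-10, 500e-9, 5e-6)
#' @export
two_state_bound_fraction <- function(ddG, invader_conc, strand_conc,
                                     model = energy_model()) {
  stopifnot(is.numeric(ddG), is.numeric(invader_conc),
            is.numeric(strand_conc))
  if (any(invader_conc <= 0) || any(strand_conc <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  k_eq <- exp(-ddG / model$kT)
  a <- invader_conc
  r <- strand_conc
  b <- k_eq * (a + r) + 1
  # numerically stable root of K*C^2 - b*C + K*a*r = 0 (smaller root)
  cc <- 2 * k_eq * a * r / (b + sqrt(b^2 - 4 * k_eq^2 * a * r))
  pmin(1, pmax(0, cc / a))
}

#' Pool sequestration statistic mu over the strongest binders
#'
#' Averages the two-state bound fractions `theta` over the
#' `M = round(top_fraction * N)` pool members with the lowest (most
#' favourable) ddG — the fraction of invader expected to be sequestered by
#' the top binders of the pool. Ties are broken by strand id so the
#' selection is stable.
#'
#' @param interactions data frame with columns `ddG` and `theta`
#'   (optionally `strand_id` for tie-breaking), one row per pool member.
#' @param top_fraction fraction of the pool to average over; default 0.10.
#' @return list with `mu`, `M`, `N` and `top_fraction`.
#' @examples
#' df <- data.frame(ddG = c(-8, -2, -1), theta = c(0.9, 0.1, 0.05))
#' pool_sequestration_mu(df, top_fraction = 1 / 3)$mu
#' @export
pool_sequestration_mu <- function(interactions, top_fraction = 0.10) {
  if (is.null(interactions) || nrow(interactions) == 0) {
    stop("empty interaction set", call. = FALSE)
  }
  stopifnot(all(c("ddG", "theta") %in% names(interactions)),
            top_fraction > 0, top_fraction <= 1)
  n <- nrow(interactions)
  m <- max(1L, as.integer(round(top_fraction * n)))
  id <- if ("strand_id" %in% names(interactions)) {
    interactions$strand_id
  } else {
    seq_len(n)
  }
  ord <- order(interactions$ddG, id)
  top <- interactions$theta[ord[seq_len(m)]]
  list(mu = mean(top), M = m, N = n, top_fraction = top_fraction)
}

#' Build a pool equilibrium table for an invader against a pool
#'
#' Convenience wrapper that computes, for each pool member, the
#' interaction ddG, the Boltzmann bound probability and the two-state
#' bound fraction at the supplied concentrations, plus the partition sum
#' and the sequestration statistic mu.
#'
#' @param invader a [dna_strand()].
#' @param pool list of [dna_strand()] objects.
#' @param invader_conc total invader concentration, molar.
#' @param pool_conc total pool concentration, molar (split equally across
#'   members for the per-strand theta).
#' @param model an [energy_model()].
#' @param top_fraction passed to [pool_sequestration_mu()].
#' @return list with `interactions` (data frame: strand_id, sequence, ddG,
#'   p_bound, theta), `partition_sum`, `mu`, `M`, `N`, `top_fraction`.
#' @export
pool_equilibrium <- function(invader, pool, invader_conc = 500e-9,
                             pool_conc = 5e-6, model = energy_model(),
                             top_fraction = 0.10) {
  ddg <- pool_ddG(invader, pool, model)
  p <- boltzmann_bound_probabilities(ddg, model)
  per_strand_conc <- pool_conc / length(pool)
  theta <- two_state_bound_fraction(ddg, invader_conc, per_strand_conc,
                                    model)
  interactions <- data.frame(
    strand_id = vapply(pool, `[[`, character(1), "id"),
    sequence = vapply(pool, `[[`, character(1), "sequence"),
    ddG = ddg, p_bound = p, theta = theta,
    stringsAsFactors = FALSE
  )
  mu <- pool_sequestration_mu(interactions, top_fraction)
  c(list(interactions = interactions,
         partition_sum = sum(exp(-ddg / model$kT))), mu)
}

#' Effective rate factor of one droplet's sampled pool
#'
#' Maps a droplet's sampled pool composition to a multiplicative factor
#' `f` on the clean-system rate constant, `k_eff = f * k0`. The model is
#' `f = 1 - mu_droplet`, where `mu_droplet` is the concentration-weighted
#' equilibrium bound fraction of the invader against the sampled pool:
#' the sum over sequences of the exact pairwise two-state bound fraction
#' at the droplet concentrations, capped at 1. Using the exact quadratic
#' per sequence (rather than a weak-binding sum) respects saturation of
#' the strongest binders, which in a finite surrogate pool carry much
#' higher per-sequence concentrations than any single member of a true
#' random pool. The factor is floored (default 0.01) so that no droplet
#' is assigned a strictly zero rate.
#'
#' @param ddGs numeric vector of sampled interaction energies (kcal/mol);
#'   may be empty (no pool in the droplet).
#' @param concs matching in-droplet per-sequence concentrations, molar.
#' @param invader_conc total invader concentration in the droplet, molar.
#' @param model an [energy_model()].
#' @param floor minimum admissible factor.
#' @return f in `(0, 1]`.
#' @seealso [calibrate_rate_factors()] to pin the population mean.
#' @export
effective_rate_factor <- function(ddGs, concs, invader_conc,
                                  model = energy_model(), floor = 0.01) {
  if (length(ddGs) == 0) return(1.0)
  if (invader_conc <= 0) {
    stop("invader_conc must be positive", call. = FALSE)
  }
  stopifnot(length(ddGs) == length(concs), all(concs >= 0))
  keep <- concs > 0
  if (!any(keep)) return(1.0)
  theta <- two_state_bound_fraction(ddGs[keep], invader_conc,
                                    concs[keep], model)
  mu <- min(1, sum(theta))
  max(floor, 1 - mu)
}

#' Rescale a population of rate factors to a calibrated mean
#'
#' The thermodynamic model fixes the shape of the droplet-to-droplet rate
#' factor distribution but not its absolute scale, which depends on
#' details of the strand-displacement mechanism outside the two-state
#' model. When the clean and pool rate constants are both known, the
#' population mean factor can be calibrated to their ratio (e.g.
#' 2.7/3.2 = 0.84375) while preserving the relative spread. The rescaling
#' is multiplicative, with values clamped into `[floor, 1]` and the scale
#' re-adjusted iteratively so the final mean matches the calibration.
#'
#' @param factors numeric vector of raw per-droplet factors in `(0, 1]`.
#' @param calibration target population mean, in `(0, 1]`.
#' @param floor lower clamp.
#' @param tol convergence tolerance on the mean.
#' @return rescaled factors with `mean(result) == calibration` (to `tol`).
#' @export
calibrate_rate_factors <- function(factors, calibration, floor = 0.01,
                                   tol = 1e-9) {
  stopifnot(is.numeric(factors), length(factors) >= 1)
  if (!is.numeric(calibration) || length(calibration) != 1 ||
      calibration <= 0 || calibration > 1) {
    stop("calibration must lie in (0, 1]", call. = FALSE)
  }
  f <- factors
  for (i in 1:200) {
    cur <- mean(f)
    if (abs(cur - calibration) <= tol) break
    f <- pmin(1, pmax(floor, f * calibration / cur))
  }
  if (abs(mean(f) - calibration) > 100 * tol) {
    # heavy clamping: fall back to an additive shift
    f <- pmin(1, pmax(floor, f + (calibration - mean(f))))
  }
  f
}

#' Read / write DNA strands in FASTA format
#'
#' Thin wrappers around Biostrings for the invader and pool sequences.
#'
#' @param path file path.
#' @return `read_strands_fasta` returns a list of [dna_strand()] objects.
#' @export
read_strands_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  mapply(dna_strand, names(x), as.character(x),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @rdname read_strands_fasta
#' @param strands list of [dna_strand()] objects.
#' @export
write_strands_fasta <- function(strands, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(strands, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(strands, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' A fixed synthetic example invader strand
#'
#' A 25-nt strand used in examples and simulations: a stand-in with the
#' same length and role as a real TMSD invader (5-nt toehold plus 20-nt
#' branch-migration domain), but an arbitrary synthetic sequence — the
#' package does not ship any experimentally used sequence.
#'
#' @return a [dna_strand()].
#' @export
example_invader <- function() {
  dna_strand("invader_synthetic", "TCTCCATGTCAGATCCGTAAGTGCA")
}
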