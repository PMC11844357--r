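#' Frequency grid of prime multiples of a base frequency
#'
#' Builds the stimulus frequency grid used throughout the package: the first
#' `count` prime numbers, each multiplied by `base_hz`. Because primes share
#' no integer multiples, no grid frequency is a harmonic of another, so every
#' sinusoidal component of a sum-of-sines stimulus can be attributed
#' unambiguously to one input channel. The default design uses the first
#' twenty prime multiples of 0.04 Hz (0.08 Hz to 2.84 Hz).
#'
#' @param base_hz Base frequency in Hz; all grid frequencies are prime
#'   multiples of this value. Its reciprocal is the fundamental period that
#'   trial durations must be a multiple of.
#' @param count Number of grid frequencies (number of primes used).
#' @return An object of class `frequency_grid`: a list with `base_hz`,
#'   `primes` (integer multipliers) and `frequencies` (Hz, ascending).
#' @examples
#' g <- build_frequency_grid(0.04, 20)
#' range(g$frequencies)  # 0.08 2.84
#' @export
build_frequency_grid <- function(base_hz, count) {
  if (!is.numeric(base_hz) || length(base_hz) != 1L || base_hz <= 0)
    stop("`base_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(count) || length(count) != 1L || count < 1 ||
      count != round(count))
    stop("`count` must be a positive integer", call. = FALSE)
  p <- first_primes(as.integer(count))
  structure(
    list(base_hz = base_hz, primes = p, frequencies = p * base_hz),
    class = "frequency_grid"
  )
}

# first n primes by trial division; n is small (tens) in every use here
first_primes <- function(n) {
  out <- integer(0)
  cand <- 2L
  while (length(out) < n) {
    if (all(cand %% out[out <= sqrt(cand)] != 0L)) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d prime multiples of %g Hz: %g .. %g Hz\n",
              length(x$frequencies), x$base_hz,
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Stimulus amplitude profile
#'
#' Magnitude (cm) of a sum-of-sines component at frequency `f`, scaled so
#' that both a positional and a velocity bound hold across the grid:
#' `min(velocity_coeff / f, position_cap)`. With the reference coefficients
#' (1.3 cm/s, 2.3 cm) every component satisfies M <= 2.3 cm and peak
#' velocity 2*pi*f*M <= 2.6*pi cm/s; the disturbance profile (0.7 cm/s,
#' 1.5 cm) is kept smaller so the jitter does not dominate the display.
#'
#' @param f Frequency in Hz (vectorized).
#' @param velocity_coeff Velocity-bound coefficient in cm/s (amplitude is
#'   `velocity_coeff / f` where the velocity bound is active).
#' @param position_cap Positional amplitude cap in cm.
#' @return Amplitude(s) in cm.
#' @export
amplitude_profile <- function(f, velocity_coeff = 1.3, position_cap = 2.3) {
  if (!is.numeric(f) || any(f <= 0))
    stop("`f` must be positive", call. = FALSE)
  pmin(velocity_coeff / f, position_cap)
}

#' Sum-of-sines component specification
#'
#' A stimulus signal as a finite list of (frequency, magnitude, phase)
#' sinusoids, g(t) = sum_i M_i sin(2 pi f_i t + phi_i).
#'
#' @param frequencies Component frequencies (Hz).
#' @param magnitudes Component magnitudes (cm), strictly positive.
#' @param phases Component phases (radians).
#' @param group_id Optional label (e.g. "r1".."r4", "d1".."d4").
#' @return An object of class `sos_spec`.
#' @export
sos_spec <- function(frequencies, magnitudes, phases, group_id = NA_character_) {
  n <- length(frequencies)
  if (length(magnitudes) != n || length(phases) != n)
    stop("frequencies, magnitudes and phases must have equal length",
         call. = FALSE)
  if (any(magnitudes <= 0))
    stop("magnitudes must be strictly positive", call. = FALSE)
  if (is.unsorted(frequencies, strictly = TRUE))
    stop("frequencies must be strictly increasing", call. = FALSE)
  structure(
    list(frequencies = as.numeric(frequencies),
         magnitudes = as.numeric(magnitudes),
         phases = as.numeric(phases),
         group_id = group_id),
    class = "sos_spec"
  )
}

#' @export
print.sos_spec <- function(x, ...) {
  cat(sprintf("<sos_spec %s> %d components, %g .. %g Hz\n",
              x$group_id, length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Partition the grid into stimulus frequency groups
#'
#' Splits the grid into `n_groups` disjoint sets of equal size by round-robin
#' over ascending frequency (grid index mod `n_groups`), so each group spans
#' the band from low to high frequencies. The same partition serves the
#' reference groups r1..r4 and the disturbance groups d1..d4; within any one
#' trial the session plan never pairs a reference group with the same-index
#' disturbance group, so the two channels on an axis never share a frequency.
#'
#' @param grid A `frequency_grid`.
#' @param n_groups Number of groups (grid size must be divisible by it).
#' @return A list of `n_groups` integer index vectors into `grid$frequencies`.
#' @export
frequency_groups <- function(grid, n_groups = 4L) {
  stopifnot(inherits(grid, "frequency_grid"))
  n <- length(grid$frequencies)
  if (n %% n_groups != 0L)
    stop("grid size must be divisible by `n_groups`", call. = FALSE)
  lapply(seq_len(n_groups), function(k) seq.int(k, n, by = n_groups))
}

#' Sample a sum-of-sines signal
#'
#' Evaluates g(t) = sum_i M_i sin(2 pi f_i t + phi_i) on a uniform time grid.
#' The duration must contain an integer number of cycles of every component
#' (guaranteed when it is an integer multiple of the base period), so that
#' single-frequency DFT coefficients are leakage-free and recover each
#' component's magnitude and phase exactly.
#'
#' @param spec A [sos_spec()].
#' @param duration Record length in seconds.
#' @param sample_rate Sampling rate in Hz; must be at least twice the highest
#'   component frequency.
#' @param t0 Start time in seconds (phases are referenced to absolute t = 0).
#' @return Numeric vector of `duration * sample_rate` samples (cm).
#' @export
generate_signal <- function(spec, duration, sample_rate, t0 = 0) {
  stopifnot(inherits(spec, "sos_spec"))
  cyc <- spec$frequencies * duration
  if (any(abs(cyc - round(cyc)) > 1e-9))
    stop("duration is not an integer number of cycles of every component; ",
         "spectral leakage would corrupt FRF estimates", call. = FALSE)
  if (sample_rate < 2 * max(spec$frequencies))
    stop("sample_rate below the Nyquist rate of the highest component",
         call. = FALSE)
  n <- round(duration * sample_rate)
  t <- t0 + (seq_len(n) - 1) / sample_rate
  eval_sos(spec, t)
}

# evaluate a sum of sines at arbitrary times
eval_sos <- function(spec, t) {
  out <- numeric(length(t))
  for (i in seq_along(spec$frequencies)) {
    out <- out + spec$magnitudes[i] *
      sin(2 * pi * spec$frequencies[i] * t + spec$phases[i])
  }
  out
}

# The 4-row composition rotation: each reference and disturbance group is
# assigned to each axis exactly once across the four rows, and a reference
# group never shares a row-axis with its same-index disturbance group.
composition_rotation <- function() {
  data.frame(
    rx = c("r1", "r2", "r3", "r4"),
    dx = c("d2", "d1", "d4", "d3"),
    ry = c("r3", "r4", "r1", "r2"),
    dy = c("d4", "d3", "d2", "d1"),
    stringsAsFactors = FALSE
  )
}

#' Build the randomized session plan
#'
#' A session is 16 experimental trials: the 4-row composition rotation
#' crossed with the two preview conditions (0 and 500 ms) and repeated twice,
#' with trial order pseudo-randomized by `rng_seed`. Pooled over the session,
#' every grid frequency is measured at least once as a reference component
#' and at least once as a disturbance component on each axis, in each preview
#' condition.
#'
#' @param grid A `frequency_grid` with 20 frequencies.
#' @param rng_seed Integer seed for the trial-order permutation.
#' @param preview_ms The two preview conditions in milliseconds.
#' @return A data frame of class `session_plan` with columns
#'   `trial, rx, dx, ry, dy, preview_ms`.
#' @export
build_session_plan <- function(grid, rng_seed = 1L, preview_ms = c(0, 500)) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (length(grid$frequencies) != 20L)
    stop("the session plan is defined for the 20-frequency grid",
         call. = FALSE)
  rot <- composition_rotation()
  cells <- do.call(rbind, lapply(preview_ms, function(p)
    cbind(rot, preview_ms = p)))
  cells <- rbind(cells, cells)  # two repetitions of every cell
  ord <- withr_seed(rng_seed, sample.int(nrow(cells)))
  plan <- cells[ord, , drop = FALSE]
  plan <- cbind(trial = seq_len(nrow(plan)), plan)
  rownames(plan) <- NULL
  class(plan) <- c("session_plan", "data.frame")
  plan
}

# run expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Realize the four stimulus specs of one trial
#'
#' Given a trial's composition row, draws component phases and assembles the
#' `sos_spec` for each of rx, dx, ry, dy using the reference and disturbance
#' amplitude profiles.
#'
#' @param grid A `frequency_grid`.
#' @param groups Output of [frequency_groups()].
#' @param composition Named character vector or one-row data frame with
#'   `rx, dx, ry, dy` entries like "r1", "d3".
#' @param ref_profile,dist_profile Length-2 numeric `(velocity_coeff,
#'   position_cap)` for the reference and disturbance amplitude profiles.
#' @param phases Optional list of 4 phase vectors (rx, dx, ry, dy); drawn
#'   uniform on `[0, 2*pi)` from the current RNG stream when `NULL`.
#' @return Named list of four `sos_spec` objects (`rx, dx, ry, dy`).
#' @export
trial_specs <- function(grid, groups, composition,
                        ref_profile = c(1.3, 2.3),
                        dist_profile = c(0.7, 1.5),
                        phases = NULL) {
  comp <- unlist(composition[c("rx", "dx", "ry", "dy")])
  out <- vector("list", 4L)
  names(out) <- c("rx", "dx", "ry", "dy")
  for (i in seq_along(comp)) {
    lab <- comp[[i]]
    gidx <- as.integer(sub("^[rd]", "", lab))
    is_ref <- startsWith(lab, "r")
    f <- grid$frequencies[groups[[gidx]]]
    prof <- if (is_ref) ref_profile else dist_profile
    m <- amplitude_profile(f, prof[1], prof[2])
    ph <- if (is.null(phases)) stats::runif(length(f), 0, 2 * pi)
          else phases[[i]]
    out[[i]] <- sos_spec(f, m, ph, group_id = lab)
  }
  out
}
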