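#' Smooth a frequency-response set
#'
#' Window-averages the magnitude and the unwrapped phase of neighboring
#' frequency points, leaving the first and last grid frequencies unchanged
#' to preserve boundary integrity. Interior points whose full window would
#' run off the grid are also left unchanged.
#'
#' @param frf An `frf_set`.
#' @param window Odd window length (`1` is the identity).
#' @return A smoothed `frf_set`.
#' @export
smooth_frf <- function(frf, window = 3L) {
  stopifnot(inherits(frf, "frf_set"))
  if (window %% 2L == 0L)
    stop("`window` must be odd", call. = FALSE)
  if (window > length(frf$frequencies))
    stop("`window` exceeds the grid length", call. = FALSE)
  if (window == 1L) return(frf)
  mag <- Mod(frf$values)
  ph <- unwrap_phase(Arg(frf$values))
  half <- (window - 1L) %/% 2L
  n <- length(mag)
  mag_s <- mag
  ph_s <- ph
  if (n > 2 * half) {
    for (i in (1L + half):(n - half)) {
      mag_s[i] <- mean(mag[(i - half):(i + half)])
      ph_s[i] <- mean(ph[(i - half):(i + half)])
    }
  }
  frf_set(frf$frequencies, mag_s * exp(1i * ph_s), channel = frf$channel,
          axis = frf$axis, subject_id = frf$subject_id,
          n_pooled = frf$n_pooled)
}

# unwrap a phase sequence (radians) by removing 2*pi jumps
unwrap_phase <- function(ph) {
  if (length(ph) < 2L) return(ph)
  d <- diff(ph)
  jumps <- round(d / (2 * pi))
  ph - c(0, cumsum(jumps)) * 2 * pi
}

#' Gain and phase stability margins of an open loop
#'
#' Computes classical stability margins of a loop transfer function L. The
#' gain crossover is where `|L|` crosses 1 (located by linear interpolation
#' of log-magnitude against log-frequency); the phase margin is
#' `180 + Arg(L)` in degrees there. The phase crossover is where the
#' unwrapped phase crosses -180 degrees; the gain margin is `1/|L|` there.
#' When a crossing does not exist on the evaluation grid the sentinel values
#' `Inf` (gain margin) and `NA` (phase margin) are returned rather than an
#' error. Phase is unwrapped before interpolation because time delays make
#' the wrapped phase cross -180 degrees spuriously.
#'
#' For measured FRFs, smooth with [smooth_frf()] first; for parametric
#' models the loop is evaluated on a dense logarithmic grid (default 1000
#' points over 0.01-20 Hz, covering the stimulus band and the crossover
#' region above it).
#'
#' @param loop A [pathway_model()], a function of frequency (Hz) returning
#'   complex values, or an `frf_set`.
#' @param f_range Evaluation band in Hz for parametric/functional loops.
#' @param n_points Number of log-spaced evaluation frequencies.
#' @return An object of class `stability_margins`: `gain_margin` (ratio,
#'   possibly `Inf`), `phase_margin` (degrees, possibly `NA`),
#'   `gain_crossover_hz`, `phase_crossover_hz`.
#' @export
stability_margins <- function(loop, f_range = c(0.01, 20), n_points = 1000L) {
  if (inherits(loop, "frf_set")) {
    f <- loop$frequencies
    vals <- loop$values
  } else {
    f <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_points))
    vals <- freqresp(loop, f)
  }
  lf <- log(f)
  lmag <- log(Mod(vals))
  ph_deg <- unwrap_phase(Arg(vals)) * 180 / pi
  gc <- interp_crossing(lf, lmag, 0)
  pm <- NA_real_
  gc_hz <- NA_real_
  if (!is.na(gc)) {
    gc_hz <- exp(gc)
    pm <- 180 + lin_interp(lf, ph_deg, gc)
  }
  pc <- interp_crossing(lf, ph_deg, -180)
  gm <- Inf
  pc_hz <- NA_real_
  if (!is.na(pc)) {
    pc_hz <- exp(pc)
    gm <- 1 / exp(lin_interp(lf, lmag, pc))
  }
  out <- list(gain_margin = gm, phase_margin = pm,
              gain_crossover_hz = gc_hz, phase_crossover_hz = pc_hz)
  class(out) <- "stability_margins"
  out
}

#' @export
print.stability_margins <- function(x, ...) {
  cat(sprintf(
    "<stability_margins> GM = %s at %s Hz; PM = %s deg at %s Hz\n",
    if (is.infinite(x$gain_margin)) "Inf" else signif(x$gain_margin, 4),
    if (is.na(x$phase_crossover_hz)) "-" else signif(x$phase_crossover_hz, 4),
    if (is.na(x$phase_margin)) "undefined" else signif(x$phase_margin, 4),
    if (is.na(x$gain_crossover_hz)) "-" else signif(x$gain_crossover_hz, 4)))
  invisible(x)
}

# abscissa of the first downward/upward crossing of y through level,
# by linear interpolation; NA when no crossing
interp_crossing <- function(x, y, level) {
  d <- y - level
  s <- d[-length(d)] * d[-1]
  hit <- which(s <= 0 & d[-length(d)] != d[-1])
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  x[i] + d[i] / (d[i] - d[i + 1]) * (x[i + 1] - x[i])
}

lin_interp <- function(x, y, x0) {
  stats::approx(x, y, xout = x0, rule = 2)$y
}

#' Mean squared tracking error of a trial
#'
#' Mean over retained samples of the squared cursor-target distance summed
#' over axes, `mean(sum_axes (y - r)^2)`, in cm^2, after discarding the
#' initial transient window.
#'
#' @param trial A `trial_record`.
#' @param transient_s Seconds discarded from the start.
#' @return Scalar MSE (cm^2).
#' @export
tracking_error <- function(trial, transient_s = 25) {
  stopifnot(inherits(trial, "trial_record"))
  if (nrow(trial$y) != nrow(trial$r))
    stop("cursor and reference series differ in length", call. = FALSE)
  keep <- trial$t >= transient_s - 1e-12
  if (!any(keep))
    stop("transient window longer than the record", call. = FALSE)
  err <- trial$y[keep, , drop = FALSE] - trial$r[keep, , drop = FALSE]
  mean(rowSums(err^2))
}

#' Counterfactual feedback-gain swap
#'
#' Re-simulates a subject's session with only the feedback-pathway gain
#' replaced, and compares tracking error and stability margins before and
#' after. This probes whether a group's lower feedback gain is a deficit
#' (raising it should help) or a compensation (raising it erodes the
#' stability margin that the lower gain preserves).
#'
#' @param subject A [synthetic_subject()] with a parametric `PB`.
#' @param new_feedback_gain Replacement for `PB$k`.
#' @param grid,groups,plan Stimulus design; defaults rebuild the standard
#'   20-frequency session.
#' @param duration,sample_rate Trial parameters (s, Hz).
#' @param transient_s Transient discard for the MSE (s).
#' @param seed Seed for the stimulus phases (identical for both subjects).
#' @return List: `mse_original`, `mse_swapped` (mean cm^2 over the
#'   no-preview trials), `margins_original`, `margins_swapped`.
#' @export
gain_swap_experiment <- function(subject, new_feedback_gain,
                                 grid = build_frequency_grid(0.04, 20),
                                 groups = frequency_groups(grid),
                                 plan = build_session_plan(grid, 1L),
                                 duration = 75, sample_rate = 80,
                                 transient_s = 25, seed = 1L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  if (subject$PB$structure == "tabulated")
    stop("gain swap requires a parametric feedback pathway", call. = FALSE)
  pb2 <- subject$PB
  pb2$k <- new_feedback_gain
  swapped <- synthetic_subject(subject$PF, pb2, subject$M_preview,
                               subject$remnant_sd,
                               paste0(subject$subject_id, "_swap"),
                               check_grid = grid$frequencies)
  run_mse <- function(subj) {
    trials <- simulate_cohort(subj, plan, grid, groups, duration,
                              sample_rate, seed = seed)
    no_prev <- Filter(function(tr) tr$preview_ms == 0, trials)
    mean(vapply(no_prev, tracking_error, numeric(1),
                transient_s = transient_s))
  }
  list(
    mse_original = run_mse(subject),
    mse_swapped = run_mse(swapped),
    margins_original = stability_margins(subject$PB),
    margins_swapped = stability_margins(swapped$PB)
  )
}
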