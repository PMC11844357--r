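#' Synthetic closed-loop tracking subject
#'
#' A subject is defined by its feedforward pathway cascade `PF` (controller
#' times plant, driven purely by the reference), its feedback pathway cascade
#' `PB` (driven by the perceived cursor-target error), an optional preview
#' filter `M_preview` applied to the reference channel under the preview
#' condition, and an optional white motor remnant added to the displayed
#' cursor. The individual plant and controllers are never represented — only
#' the cascades, which is all the tracking experiment can identify.
#'
#' @param PF,PB [pathway_model()] objects for the feedforward and feedback
#'   pathway cascades.
#' @param M_preview Optional preview filter: a `pathway_model` or a function
#'   of frequency (Hz) returning a complex value. `NULL` means preview
#'   trials behave identically to no-preview trials.
#' @param remnant_sd Standard deviation (cm) of white Gaussian noise added
#'   to the displayed cursor; 0 (default) gives a noise-free linear subject.
#' @param subject_id Label carried through all outputs.
#' @param check_grid Frequencies (Hz) at which closed-loop stability
#'   (`|1 + PB| > 1e-6`) is verified at construction.
#' @return An object of class `synthetic_subject`.
#' @export
synthetic_subject <- function(PF, PB, M_preview = NULL, remnant_sd = 0,
                              subject_id = "S1",
                              check_grid = build_frequency_grid(0.04, 20)$frequencies) {
  stopifnot(inherits(PF, "pathway_model"), inherits(PB, "pathway_model"))
  if (remnant_sd < 0) stop("`remnant_sd` must be nonnegative", call. = FALSE)
  subj <- structure(
    list(PF = PF, PB = PB, M_preview = M_preview,
         remnant_sd = remnant_sd, subject_id = subject_id),
    class = "synthetic_subject"
  )
  denom <- Mod(1 + freqresp(PB, check_grid))
  if (any(denom <= 1e-6))
    stop(sprintf("closed loop ill-conditioned: |1 + PB| <= 1e-6 at %g Hz",
                 check_grid[which.min(denom)]), call. = FALSE)
  subj
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject %s> remnant_sd = %g cm%s\n", x$subject_id,
              x$remnant_sd,
              if (is.null(x$M_preview)) "" else ", with preview filter"))
  cat("  PF: "); print(x$PF)
  cat("  PB: "); print(x$PB)
  invisible(x)
}

#' Closed-loop frequency response of a synthetic subject
#'
#' From the tracking-loop topology, the displayed cursor satisfies
#' `Y = H_yr R + H_yd D` with `H_yr = (PF + PB) / (1 + PB)` and
#' `H_yd = 1 / (1 + PB)`. Under the preview condition with a preview filter
#' M, the reference channel becomes `H_yr = (PF + PB) M / (1 + PB)`; the
#' disturbance channel is unaffected.
#'
#' @param subject A [synthetic_subject()].
#' @param f Frequencies in Hz (vectorized).
#' @param preview Logical; apply the subject's preview filter to the
#'   reference channel.
#' @return List with complex vectors `H_yr` and `H_yd`.
#' @export
closed_loop_response <- function(subject, f, preview = FALSE) {
  stopifnot(inherits(subject, "synthetic_subject"))
  pf <- freqresp(subject$PF, f)
  pb <- freqresp(subject$PB, f)
  denom <- 1 + pb
  bad <- Mod(denom) <= 1e-6
  if (any(bad))
    stop(sprintf("closed loop ill-conditioned: |1 + PB| <= 1e-6 at %g Hz",
                 f[which(bad)[1]]), call. = FALSE)
  h_yr <- (pf + pb) / denom
  if (preview && !is.null(subject$M_preview))
    h_yr <- h_yr * freqresp(subject$M_preview, f)
  list(H_yr = h_yr, H_yd = 1 / denom)
}

#' Simulate one tracking trial at steady state
#'
#' Because the stimuli are finite sums of sinusoids and the subject is
#' linear, the steady-state cursor trajectory is exact by superposition:
#' each reference component of magnitude M and phase phi appears in y as
#' `|H_yr| M sin(2 pi f t + phi + Arg(H_yr))`, and likewise for disturbance
#' components through `H_yd`. No time-stepping is involved, so there is no
#' integration error and no start-up transient in the noise-free path.
#' Optional white remnant noise is drawn from the current RNG stream.
#'
#' @param subject A [synthetic_subject()].
#' @param specs Named list of four [sos_spec()] objects (`rx, dx, ry, dy`),
#'   e.g. from [trial_specs()].
#' @param duration Trial length in seconds (integer number of cycles of
#'   every component).
#' @param sample_rate Sampling rate in Hz.
#' @param preview_ms Preview condition in ms; any value > 0 engages the
#'   subject's preview filter.
#' @return An object of class `trial_record`: `t` (s), matrices `r`, `d`,
#'   `y` (samples x 2 axes, cm), the `specs`, `composition`, `preview_ms`,
#'   `sample_rate` and `subject_id`.
#' @export
simulate_trial <- function(subject, specs, duration = 75, sample_rate = 80,
                           preview_ms = 0) {
  stopifnot(inherits(subject, "synthetic_subject"))
  need <- c("rx", "dx", "ry", "dy")
  if (!all(need %in% names(specs)))
    stop("`specs` must contain rx, dx, ry, dy", call. = FALSE)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  preview <- preview_ms > 0
  axis_out <- function(ref_spec, dist_spec) {
    r <- eval_sos(ref_spec, t)
    d <- eval_sos(dist_spec, t)
    hr <- closed_loop_response(subject, ref_spec$frequencies, preview)$H_yr
    hd <- closed_loop_response(subject, dist_spec$frequencies, FALSE)$H_yd
    y <- numeric(n)
    for (i in seq_along(ref_spec$frequencies)) {
      y <- y + Mod(hr[i]) * ref_spec$magnitudes[i] *
        sin(2 * pi * ref_spec$frequencies[i] * t +
              ref_spec$phases[i] + Arg(hr[i]))
    }
    for (i in seq_along(dist_spec$frequencies)) {
      y <- y + Mod(hd[i]) * dist_spec$magnitudes[i] *
        sin(2 * pi * dist_spec$frequencies[i] * t +
              dist_spec$phases[i] + Arg(hd[i]))
    }
    if (subject$remnant_sd > 0)
      y <- y + stats::rnorm(n, 0, subject$remnant_sd)
    list(r = r, d = d, y = y)
  }
  x <- axis_out(specs$rx, specs$dx)
  yy <- axis_out(specs$ry, specs$dy)
  structure(
    list(t = t,
         r = cbind(x = x$r, y = yy$r),
         d = cbind(x = x$d, y = yy$d),
         y = cbind(x = x$y, y = yy$y),
         specs = specs,
         composition = vapply(specs, function(s) s$group_id, character(1)),
         preview_ms = preview_ms,
         sample_rate = sample_rate,
         subject_id = subject$subject_id),
    class = "trial_record"
  )
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record %s> %g s @ %g Hz, composition %s, preview %g ms\n",
    x$subject_id, length(x$t) / x$sample_rate, x$sample_rate,
    paste(x$composition, collapse = "/"), x$preview_ms))
  invisible(x)
}

#' Simulate a full session (or cohort) from a session plan
#'
#' Runs [simulate_trial()] over every row of the plan for every subject,
#' drawing fresh stimulus phases per trial from a seeded RNG stream so the
#' whole cohort is reproducible from `seed`.
#'
#' @param subjects A [synthetic_subject()] or list of them.
#' @param plan A [build_session_plan()] data frame.
#' @param grid The `frequency_grid` the plan was built on.
#' @param groups Frequency groups from [frequency_groups()].
#' @param duration,sample_rate Trial length (s) and sampling rate (Hz).
#' @param ref_profile,dist_profile Amplitude-profile coefficients, see
#'   [trial_specs()].
#' @param seed Integer seed for phase and remnant draws.
#' @return List of `trial_record` objects (subjects in order, trials within).
#' @export
simulate_cohort <- function(subjects, plan, grid, groups,
                            duration = 75, sample_rate = 80,
                            ref_profile = c(1.3, 2.3),
                            dist_profile = c(0.7, 1.5),
                            seed = 1L) {
  if (inherits(subjects, "synthetic_subject")) subjects <- list(subjects)
  withr_seed(seed, {
    out <- list()
    for (subj in subjects) {
      for (i in seq_len(nrow(plan))) {
        specs <- trial_specs(grid, groups, plan[i, ],
                             ref_profile = ref_profile,
                             dist_profile = dist_profile)
        out[[length(out) + 1L]] <-
          simulate_trial(subj, specs, duration, sample_rate,
                         preview_ms = plan$preview_ms[i])
      }
    }
    out
  })
}
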