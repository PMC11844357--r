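#' Two-channel reference-controller FRFs
#'
#' Reparameterizes the closed-loop responses in terms of a reference
#' controller driven purely by the (previewed) target and a feedback
#' controller driven by the cursor: `PH_B = 1/H_YD - 1` and
#' `PH_R = H_YR / H_YD`. For a subject built from feedforward and feedback
#' cascades these satisfy `PH_R = PF + PB` and `PH_B = PB`.
#'
#' @param H_YR,H_YD Closed-loop `frf_set`s on the same grid and axis.
#' @param eps Near-singularity threshold on `|H_YD|`.
#' @return List of two `frf_set`s: `PH_R` and `PH_B`.
#' @export
reference_controller_frfs <- function(H_YR, H_YD, eps = 1e-8) {
  stopifnot(inherits(H_YR, "frf_set"), inherits(H_YD, "frf_set"))
  check_same_grid(H_YR, H_YD)
  check_nonsingular(H_YD, eps, "H_YD")
  list(
    PH_R = frf_set(H_YR$frequencies, H_YR$values / H_YD$values,
                   channel = "PH_R", axis = H_YR$axis,
                   subject_id = H_YR$subject_id, n_pooled = H_YR$n_pooled),
    PH_B = frf_set(H_YD$frequencies, 1 / H_YD$values - 1,
                   channel = "PH_B", axis = H_YD$axis,
                   subject_id = H_YD$subject_id, n_pooled = H_YD$n_pooled)
  )
}

#' Extract the preview filter from preview vs. no-preview FRFs
#'
#' Under the preview condition the reference controller becomes
#' `PH_P = PH_R * M`, so the preview filter is recovered per frequency as
#' `M = PH_P / PH_R`. The feedback-channel ratio `PH_BP / PH_B` is a
#' diagnostic of the assumption that preview leaves the feedback controller
#' unchanged; it is stored (and a warning is raised when it strays from 1 by
#' more than `warn_tol`), never silently assumed.
#'
#' @param no_preview List with `PH_R` and `PH_B` (no-preview condition).
#' @param preview List with `PH_R` and `PH_B` estimated from preview trials
#'   (interpreted as `PH_P` and `PH_BP`).
#' @param eps Near-singularity threshold on `|PH_R|`.
#' @param warn_tol Warn when `|PH_BP/PH_B - 1|` exceeds this anywhere.
#' @return An object of class `preview_filter`: `frequencies`, complex `M`,
#'   `feedback_ratio`, `axis`, `subject_id`.
#' @export
extract_preview_filter <- function(no_preview, preview, eps = 1e-8,
                                   warn_tol = 0.2) {
  ph_r <- no_preview$PH_R
  ph_p <- preview$PH_R
  check_same_grid(ph_r, ph_p)
  check_nonsingular(ph_r, eps, "PH_R")
  check_nonsingular(no_preview$PH_B, eps, "PH_B")
  m <- ph_p$values / ph_r$values
  ratio <- preview$PH_B$values / no_preview$PH_B$values
  dev <- max(Mod(ratio - 1))
  if (dev > warn_tol)
    warning(sprintf(
      "feedback-channel ratio PH_BP/PH_B deviates from 1 by %.2f at %g Hz; ",
      dev, ph_r$frequencies[which.max(Mod(ratio - 1))]),
      "the preview-leaves-feedback-unchanged assumption may not hold",
      call. = FALSE)
  out <- list(frequencies = ph_r$frequencies, M = m,
              feedback_ratio = ratio, axis = ph_r$axis,
              subject_id = ph_r$subject_id)
  class(out) <- "preview_filter"
  out
}

#' @export
print.preview_filter <- function(x, ...) {
  cat(sprintf(
    "<preview_filter axis %s%s> %d frequencies; |M| %g .. %g, max |PH_BP/PH_B - 1| = %.3g\n",
    x$axis, if (is.na(x$subject_id)) "" else paste0(" ", x$subject_id),
    length(x$frequencies), signif(min(Mod(x$M)), 3),
    signif(max(Mod(x$M)), 3), max(Mod(x$feedback_ratio - 1))))
  invisible(x)
}

#' Smooth a preview filter across frequency
#'
#' Optional 3-point complex moving average of M (endpoints kept); off by
#' default everywhere in the pipeline.
#'
#' @param pf A `preview_filter`.
#' @param window Odd window length.
#' @return A `preview_filter` with smoothed `M`.
#' @export
smooth_preview_filter <- function(pf, window = 3L) {
  stopifnot(inherits(pf, "preview_filter"))
  pf$M <- moving_average_complex(pf$M, window)
  pf
}

moving_average_complex <- function(v, window) {
  if (window %% 2L == 0L) stop("window must be odd", call. = FALSE)
  if (window == 1L) return(v)
  half <- (window - 1L) %/% 2L
  out <- v
  n <- length(v)
  if (n > 2 * half) {
    for (i in (1L + half):(n - half))
      out[i] <- mean(v[(i - half):(i + half)])
  }
  out
}

#' Reconstruct the filtered reference signal
#'
#' Applies an estimated preview filter to a sum-of-sines reference: each
#' component is scaled by `|M(f)|` and phase-shifted by `Arg(M(f))`, then the
#' components are summed on the time grid. With a low-pass, phase-leading M
#' this produces the smoothed, time-advanced trajectory that subjects
#' effectively track under preview.
#'
#' @param pf A `preview_filter` (or any object with `frequencies` and
#'   complex `M`).
#' @param spec A [sos_spec()] whose frequencies all lie on `pf`'s grid.
#' @param duration,sample_rate Time grid (s, Hz).
#' @param t0 Start time (s).
#' @return Numeric vector of samples (cm).
#' @export
filtered_reference <- function(pf, spec, duration, sample_rate, t0 = 0) {
  stopifnot(inherits(spec, "sos_spec"))
  idx <- match_frequency(spec$frequencies, pf$frequencies)
  m <- pf$M[idx]
  fspec <- sos_spec(spec$frequencies,
                    spec$magnitudes * Mod(m),
                    spec$phases + Arg(m),
                    group_id = paste0(spec$group_id, "_filtered"))
  generate_signal(fspec, duration, sample_rate, t0 = t0)
}
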