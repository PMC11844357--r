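#' Construct a frequency-response set
#'
#' Container for complex frequency-response values on the stimulus grid for
#' one channel/axis/subject.
#'
#' @param frequencies Grid frequencies (Hz).
#' @param values Complex values, one per frequency.
#' @param channel Channel label, e.g. `"H_YR"`, `"H_YD"`, `"PF"`, `"PB"`,
#'   `"PH_R"`, `"PH_B"`, `"PH_P"`, `"PH_BP"`, `"M"`.
#' @param axis `"x"` or `"y"`.
#' @param subject_id Subject label.
#' @param n_pooled Integer vector: trials pooled per frequency.
#' @return An object of class `frf_set`.
#' @export
frf_set <- function(frequencies, values, channel = "H_YR", axis = "x",
                    subject_id = NA_character_,
                    n_pooled = rep(1L, length(frequencies))) {
  if (length(values) != length(frequencies))
    stop("one value per frequency required", call. = FALSE)
  if (any(!is.finite(values)))
    stop("FRF values must be finite", call. = FALSE)
  structure(
    list(frequencies = as.numeric(frequencies), values = as.complex(values),
         channel = channel, axis = axis, subject_id = subject_id,
         n_pooled = as.integer(n_pooled)),
    class = "frf_set"
  )
}

#' @export
print.frf_set <- function(x, ...) {
  cat(sprintf("<frf_set %s axis %s%s> %d frequencies, %g .. %g Hz\n",
              x$channel, x$axis,
              if (is.na(x$subject_id)) "" else paste0(" ", x$subject_id),
              length(x$frequencies), min(x$frequencies),
              max(x$frequencies)))
  invisible(x)
}

#' @export
as.data.frame.frf_set <- function(x, ...) {
  data.frame(freq_hz = x$frequencies, re = Re(x$values), im = Im(x$values),
             channel = x$channel, axis = x$axis, subject = x$subject_id,
             n_pooled = x$n_pooled, stringsAsFactors = FALSE)
}

#' Single-frequency DFT under the sine-phasor convention
#'
#' Returns the complex coefficient `c` such that the component of the series
#' at frequency `f` equals `|c| sin(2 pi f t + Arg(c))`. The record must
#' contain an integer number of cycles of `f` (leakage-free condition); this
#' holds by design for any grid frequency over a whole number of base
#' periods.
#'
#' @param series Real sampled series.
#' @param f Analysis frequency (Hz).
#' @param sample_rate Sampling rate (Hz).
#' @param t0 Time of the first sample (s); phases are referenced to absolute
#'   `t = 0`.
#' @return A single complex number.
#' @export
single_frequency_dft <- function(series, f, sample_rate, t0 = 0) {
  n <- length(series)
  cycles <- f * n / sample_rate
  if (abs(cycles - round(cycles)) > 1e-6)
    stop(sprintf(
      "record does not contain an integer number of cycles of %g Hz", f),
      call. = FALSE)
  t <- t0 + (seq_len(n) - 1) / sample_rate
  # for x = M sin(2*pi*f*t + phi): (2/n) * sum(x * exp(-i*2*pi*f*t)) = -i*M*e^(i*phi)
  1i * (2 / n) * sum(series * exp(-1i * 2 * pi * f * t))
}

#' Estimate closed-loop FRFs from pooled trials
#'
#' For one subject and one preview condition, pools all trials and computes
#' per axis, at every grid frequency: `H_YR = DFT(y)/DFT(r)` from the trials
#' where that frequency belonged to the axis's reference set, and
#' `H_YD = DFT(y)/DFT(d)` from the trials where it belonged to the
#' disturbance set. Repeated measurements are combined by the complex mean
#' (phasor averaging). The initial transient window is discarded before any
#' DFT.
#'
#' @param trials List of `trial_record`s from one subject.
#' @param grid The `frequency_grid` the stimuli were built on.
#' @param preview_ms Which preview condition to pool (0 or 500).
#' @param transient_s Seconds discarded from the start of each record.
#' @return Named list of four `frf_set`s: `H_YR_x`, `H_YD_x`, `H_YR_y`,
#'   `H_YD_y`.
#' @export
estimate_frfs <- function(trials, grid, preview_ms = 0, transient_s = 25) {
  stopifnot(inherits(grid, "frequency_grid"))
  trials <- Filter(function(tr) tr$preview_ms == preview_ms, trials)
  if (length(trials) == 0L)
    stop("no trials in the requested preview condition", call. = FALSE)
  subject_id <- trials[[1]]$subject_id
  freqs <- grid$frequencies
  out <- list()
  for (axis in c("x", "y")) {
    acc <- list(
      r = replicate(length(freqs), complex(0), simplify = FALSE),
      d = replicate(length(freqs), complex(0), simplify = FALSE)
    )
    for (tr in trials) {
      sr <- tr$sample_rate
      keep <- tr$t >= transient_s - 1e-12
      if (!any(keep))
        stop("transient window longer than the record", call. = FALSE)
      t0 <- tr$t[keep][1]
      yv <- tr$y[keep, axis]
      for (chan in c("r", "d")) {
        spec <- tr$specs[[paste0(chan, axis)]]
        inp <- if (chan == "r") tr$r[keep, axis] else tr$d[keep, axis]
        for (f in spec$frequencies) {
          num <- single_frequency_dft(yv, f, sr, t0)
          den <- single_frequency_dft(inp, f, sr, t0)
          if (Mod(den) <= 1e-12)
            stop(sprintf("stimulus power absent at %g Hz (%s axis, %s)",
                         f, axis, chan), call. = FALSE)
          j <- match_frequency(f, freqs)
          acc[[chan]][[j]] <- c(acc[[chan]][[j]], num / den)
        }
      }
    }
    for (chan in c("r", "d")) {
      n_pooled <- lengths(acc[[chan]])
      if (any(n_pooled == 0L)) {
        miss <- freqs[which(n_pooled == 0L)[1]]
        stop(sprintf(
          "coverage error: %g Hz never measured in the %s channel on axis %s",
          miss, if (chan == "r") "reference" else "disturbance", axis),
          call. = FALSE)
      }
      vals <- vapply(acc[[chan]], mean, complex(1))
      name <- paste0(if (chan == "r") "H_YR_" else "H_YD_", axis)
      out[[name]] <- frf_set(freqs, vals,
                             channel = if (chan == "r") "H_YR" else "H_YD",
                             axis = axis, subject_id = subject_id,
                             n_pooled = n_pooled)
    }
  }
  out
}
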