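#' Isolate the open-loop feedback pathway
#'
#' Inverts the closed-loop disturbance response: since `H_YD = 1/(1 + PB)`,
#' the feedback pathway cascade is `PB = 1/H_YD - 1`.
#'
#' @param H_YD An `frf_set` of the closed-loop disturbance response.
#' @param eps Near-singularity threshold on `|H_YD|`; values at or below it
#'   raise an error rather than being regularized, since silent
#'   regularization would bias downstream model fits.
#' @return An `frf_set` with channel `"PB"`.
#' @export
isolate_feedback <- function(H_YD, eps = 1e-8) {
  stopifnot(inherits(H_YD, "frf_set"))
  check_nonsingular(H_YD, eps, "H_YD")
  frf_set(H_YD$frequencies, 1 / H_YD$values - 1, channel = "PB",
          axis = H_YD$axis, subject_id = H_YD$subject_id,
          n_pooled = H_YD$n_pooled)
}

#' Isolate the open-loop feedforward pathway
#'
#' From the closed-loop responses, the feedforward pathway cascade is
#' `PF = H_YR/H_YD - 1/H_YD + 1` (equivalently `(H_YR - 1)/H_YD + 1`).
#'
#' @param H_YR,H_YD `frf_set`s of the closed-loop reference and disturbance
#'   responses on the same grid and axis.
#' @param eps Near-singularity threshold on `|H_YD|`.
#' @return An `frf_set` with channel `"PF"`.
#' @export
isolate_feedforward <- function(H_YR, H_YD, eps = 1e-8) {
  stopifnot(inherits(H_YR, "frf_set"), inherits(H_YD, "frf_set"))
  check_same_grid(H_YR, H_YD)
  check_nonsingular(H_YD, eps, "H_YD")
  pf <- H_YR$values / H_YD$values - 1 / H_YD$values + 1
  frf_set(H_YR$frequencies, pf, channel = "PF", axis = H_YR$axis,
          subject_id = H_YR$subject_id, n_pooled = H_YR$n_pooled)
}

check_nonsingular <- function(frf, eps, what) {
  bad <- Mod(frf$values) <= eps
  if (any(bad))
    stop(sprintf("near-singular %s: |%s| <= %g at %g Hz", what, what, eps,
                 frf$frequencies[which(bad)[1]]), call. = FALSE)
  invisible(TRUE)
}

check_same_grid <- function(a, b) {
  if (length(a$frequencies) != length(b$frequencies) ||
      any(abs(a$frequencies - b$frequencies) > 1e-9) ||
      !identical(a$axis, b$axis))
    stop("FRF sets must share the same grid and axis", call. = FALSE)
  invisible(TRUE)
}
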