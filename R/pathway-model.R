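#' Parametric pathway transfer-function models
#'
#' A `pathway_model` is a transfer-function-with-delay structure evaluable at
#' any frequency, representing the cascade of a controller and the motor
#' plant. Available structures (s = j*2*pi*f):
#'
#' * `gain_delay`: `k * exp(-s*tau)` — a pure gain with time delay, the
#'   structure that describes the feedforward pathway when the controller is
#'   a good inverse model of the plant.
#' * `leaky_integrator_delay`: `k / (s + a) * exp(-s*tau)` — the McRuer
#'   crossover-style scaled leaky integrator with delay that describes the
#'   error-driven feedback pathway; `a` (rad/s) is the integrator pole.
#' * `first_order_delay`: `k * a / (s + a) * exp(-s*tau)` — a first-order
#'   lag with unit-normalized DC gain `k` (an inverse model that fails to
#'   cancel one plant mode).
#' * `second_order_delay`: `k * wn^2 / (s^2 + 2*zeta*wn*s + wn^2) *
#'   exp(-s*tau)` — a second-order lag (two uncancelled modes).
#' * `tabulated`: nonparametric per-frequency complex values.
#'
#' @param structure One of `"gain_delay"`, `"leaky_integrator_delay"`,
#'   `"first_order_delay"`, `"second_order_delay"`, `"tabulated"`.
#' @param k Gain (dimensionless), `k >= 0`.
#' @param tau Time delay in seconds, `tau >= 0`.
#' @param a Pole in rad/s (`> 0`), for the first-order structures.
#' @param wn,zeta Natural frequency (rad/s) and damping ratio for
#'   `second_order_delay`.
#' @param frequencies,values Grid (Hz) and complex values for `tabulated`.
#' @return An object of class `pathway_model`.
#' @seealso [freqresp()] to evaluate the model at frequencies.
#' @export
pathway_model <- function(structure = c("gain_delay", "leaky_integrator_delay",
                                        "first_order_delay",
                                        "second_order_delay", "tabulated"),
                          k = NULL, tau = NULL, a = NULL,
                          wn = NULL, zeta = NULL,
                          frequencies = NULL, values = NULL) {
  structure <- match.arg(structure)
  if (structure == "tabulated") {
    if (is.null(frequencies) || is.null(values) ||
        length(frequencies) != length(values))
      stop("tabulated models need matching `frequencies` and `values`",
           call. = FALSE)
    obj <- list(structure = structure,
                frequencies = as.numeric(frequencies),
                values = as.complex(values))
  } else {
    if (is.null(k) || is.null(tau) || k < 0 || tau < 0)
      stop("`k` and `tau` must be supplied and nonnegative", call. = FALSE)
    obj <- list(structure = structure, k = k, tau = tau)
    if (structure %in% c("leaky_integrator_delay", "first_order_delay")) {
      if (is.null(a) || a <= 0)
        stop("`a` must be supplied and positive for ", structure,
             call. = FALSE)
      obj$a <- a
    }
    if (structure == "second_order_delay") {
      if (is.null(wn) || is.null(zeta) || wn <= 0 || zeta <= 0)
        stop("`wn` and `zeta` must be supplied and positive", call. = FALSE)
      obj$wn <- wn
      obj$zeta <- zeta
    }
  }
  class(obj) <- "pathway_model"
  obj
}

#' Evaluate a pathway model's frequency response
#'
#' @param model A [pathway_model()] (or a function mapping frequency in Hz to
#'   a complex value).
#' @param f Frequencies in Hz (vectorized).
#' @return Complex vector of the response at `s = j*2*pi*f`.
#' @export
freqresp <- function(model, f) {
  if (is.function(model)) return(as.complex(model(f)))
  stopifnot(inherits(model, "pathway_model"))
  s <- 1i * 2 * pi * f
  switch(model$structure,
    gain_delay = model$k * exp(-s * model$tau),
    leaky_integrator_delay = model$k * exp(-s * model$tau) / (s + model$a),
    first_order_delay =
      model$k * model$a * exp(-s * model$tau) / (s + model$a),
    second_order_delay =
      model$k * model$wn^2 * exp(-s * model$tau) /
        (s^2 + 2 * model$zeta * model$wn * s + model$wn^2),
    tabulated = {
      idx <- match_frequency(f, model$frequencies)
      model$values[idx]
    }
  )
}

# match requested frequencies to a stored grid within tolerance
match_frequency <- function(f, grid_f, tol = 1e-9) {
  idx <- vapply(f, function(fi) {
    j <- which(abs(grid_f - fi) < tol)
    if (length(j) != 1L)
      stop(sprintf("frequency %g Hz not on the model's grid", fi),
           call. = FALSE)
    j
  }, integer(1))
  idx
}

# number of free parameters of a parametric structure
n_params <- function(structure) {
  switch(structure,
    gain_delay = 2L,
    leaky_integrator_delay = 3L,
    first_order_delay = 3L,
    second_order_delay = 4L,
    stop("no parameter count for structure ", structure, call. = FALSE)
  )
}

#' @export
print.pathway_model <- function(x, ...) {
  if (x$structure == "tabulated") {
    cat(sprintf("<pathway_model tabulated> %d frequencies\n",
                length(x$frequencies)))
  } else {
    par <- x[setdiff(names(x), "structure")]
    cat(sprintf("<pathway_model %s> %s\n", x$structure,
                paste(names(par), signif(unlist(par), 4),
                      sep = " = ", collapse = ", ")))
  }
  invisible(x)
}
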