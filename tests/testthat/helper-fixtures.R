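# Shared fixtures: the standard stimulus design and the two study groups'
# published best-fit pathway parameters, used as simulator ground truth.

std_grid <- function() build_frequency_grid(0.04, 20)
std_groups <- function(grid = std_grid()) frequency_groups(grid)
std_plan <- function(seed = 1L, grid = std_grid())
  build_session_plan(grid, rng_seed = seed)

group_truth <- list(
  control = list(ff = list(k = 0.6, tau = 0.185),
                 fb = list(k = 1.3, tau = 0.123, a = 0.5)),
  ataxia  = list(ff = list(k = 0.6, tau = 0.245),
                 fb = list(k = 1.0, tau = 0.144, a = 0.5))
)

make_subject <- function(group = "control", M_preview = NULL,
                         remnant_sd = 0, id = group) {
  p <- group_truth[[group]]
  synthetic_subject(
    pathway_model("gain_delay", k = p$ff$k, tau = p$ff$tau),
    pathway_model("leaky_integrator_delay", k = p$fb$k, tau = p$fb$tau,
                  a = p$fb$a),
    M_preview = M_preview, remnant_sd = remnant_sd, subject_id = id)
}

# simulate a session and return the no-preview pathway FRFs for one axis
isolated_pathways <- function(subject, axis = "x", seed = 1L,
                              plan = std_plan(seed)) {
  grid <- std_grid()
  trials <- simulate_cohort(subject, plan, grid, std_groups(grid),
                            seed = seed)
  est <- estimate_frfs(trials, grid, preview_ms = 0)
  list(
    PF = isolate_feedforward(est[[paste0("H_YR_", axis)]],
                             est[[paste0("H_YD_", axis)]]),
    PB = isolate_feedback(est[[paste0("H_YD_", axis)]]),
    est = est, trials = trials
  )
}

# closed-form + root-finding oracle for margins of the leaky-integrator
# loop L = k e^(-s tau) / (s + a); independent of the interpolation path
leaky_margin_oracle <- function(k, tau, a) {
  gm <- Inf; pm <- NA_real_
  phase <- function(w) -w * tau - atan(w / a)       # radians
  if (k > a) {
    w_gc <- sqrt(k^2 - a^2)
    pm <- 180 + phase(w_gc) * 180 / pi
  }
  g <- function(w) w * tau + atan(w / a) - pi
  if (g(1e-6) < 0 && g(1e4) > 0) {
    w_pc <- stats::uniroot(g, c(1e-6, 1e4), tol = 1e-12)$root
    gm <- sqrt(w_pc^2 + a^2) / k
  }
  list(gain_margin = gm, phase_margin = pm)
}

# simulate a session with/without a planted preview filter and extract
# the nonparametric preview-filter estimate
extract_for <- function(M_preview, seed = 10, axis = "x") {
  g <- std_grid()
  subj <- make_subject("control", M_preview = M_preview)
  trials <- simulate_cohort(subj, std_plan(seed), g, std_groups(g),
                            seed = seed)
  e0 <- estimate_frfs(trials, g, preview_ms = 0)
  e5 <- estimate_frfs(trials, g, preview_ms = 500)
  extract_preview_filter(
    reference_controller_frfs(e0[[paste0("H_YR_", axis)]],
                              e0[[paste0("H_YD_", axis)]]),
    reference_controller_frfs(e5[[paste0("H_YR_", axis)]],
                              e5[[paste0("H_YD_", axis)]]))
}

# independent sum-of-sines evaluator (time-shift checks)
eval_sos_oracle <- function(spec, t) {
  Reduce(`+`, lapply(seq_along(spec$frequencies), function(i)
    spec$magnitudes[i] * sin(2 * pi * spec$frequencies[i] * t +
                               spec$phases[i])))
}

# tabulated frf_set from a parametric model, on the standard grid
tabulate_model <- function(model, grid = std_grid(), channel = "PF",
                           axis = "x", subject_id = NA_character_) {
  frf_set(grid$frequencies, freqresp(model, grid$frequencies),
          channel = channel, axis = axis, subject_id = subject_id)
}
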