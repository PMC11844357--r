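test_that("FRF smoothing averages magnitude and unwrapped phase", {
  f5 <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  vals <- complex(modulus = c(2, 1, 4, 2, 1),
                  argument = c(0.1, -0.2, 0.3, -0.4, 0.5))
  frf <- frf_set(f5, vals, channel = "PB")
  expect_equal(smooth_frf(frf, 1)$values, vals)
  const <- frf_set(f5, rep(2 * exp(1i * 0.3), 5), channel = "PB")
  expect_equal(smooth_frf(const, 3)$values, const$values, tolerance = 1e-12)
  sm <- smooth_frf(frf, 3)
  mag <- Mod(vals); ph <- Arg(vals)  # no wrap crossings in this fixture
  expect_equal(Mod(sm$values), c(2, mean(mag[1:3]), mean(mag[2:4]),
                                 mean(mag[3:5]), 1), tolerance = 1e-12)
  expect_equal(Arg(sm$values), c(0.1, mean(ph[1:3]), mean(ph[2:4]),
                                 mean(ph[3:5]), 0.5), tolerance = 1e-12)
  expect_error(smooth_frf(frf, 2), "odd")
})

test_that("margins use sentinels when no crossover exists", {
  m <- stability_margins(pathway_model("gain_delay", k = 0.5, tau = 0))
  expect_identical(m$gain_margin, Inf)
  expect_true(is.na(m$phase_margin))
  expect_true(is.na(m$gain_crossover_hz))
})

test_that("margins match the closed form for a delayed integrator", {
  # L = e^(-0.3 s)/s: |L| = 1 at 1 rad/s, PM = 90 - 0.3 * 180/pi deg;
  # phase = -180 deg at w = pi/0.6, GM = pi/0.6
  L <- function(f) {
    s <- 1i * 2 * pi * f
    exp(-0.3 * s) / s
  }
  m <- stability_margins(L)
  expect_equal(m$phase_margin, 90 - 0.3 * 180 / pi, tolerance = 1e-3)
  expect_equal(m$gain_crossover_hz, 1 / (2 * pi), tolerance = 1e-4)
  expect_equal(m$gain_margin, pi / 0.6, tolerance = 1e-3)
})

test_that("interpolated margins agree with the root-finding oracle", {
  set.seed(14)
  for (i in 1:25) {
    k <- runif(1, 0.8, 3)
    tau <- runif(1, 0.08, 0.3)
    a <- runif(1, 0.1, 0.6)
    loop <- pathway_model("leaky_integrator_delay", k = k, tau = tau, a = a)
    m <- stability_margins(loop)
    o <- leaky_margin_oracle(k, tau, a)
    expect_lt(abs(m$phase_margin - o$phase_margin), 0.1)
    expect_lt(abs(m$gain_margin - o$gain_margin), 0.01)
  }
})

test_that("margin monotonicity in delay and gain", {
  pm_of <- function(tau) stability_margins(
    pathway_model("leaky_integrator_delay", k = 1.3, tau = tau,
                  a = 0.5))$phase_margin
  pms <- vapply(seq(0.05, 0.3, by = 0.05), pm_of, numeric(1))
  expect_true(all(diff(pms) < 0))
  gm_of <- function(k) stability_margins(
    pathway_model("leaky_integrator_delay", k = k, tau = 0.144,
                  a = 0.5))$gain_margin
  gms <- vapply(seq(0.8, 2, by = 0.2), gm_of, numeric(1))
  expect_true(all(diff(gms) < 0))
})

test_that("tracking error matches sinusoid power and the Parseval form", {
  g <- std_grid(); groups <- std_groups(g)
  set.seed(15)
  specs <- trial_specs(g, groups, c(rx = "r1", dx = "d2", ry = "r3",
                                    dy = "d4"))
  # perfect tracking: y identical to r
  perfect <- synthetic_subject(pathway_model("gain_delay", k = 1, tau = 0),
                               pathway_model("gain_delay", k = 0, tau = 0))
  tr <- simulate_trial(perfect, specs)
  tr$y <- tr$r
  expect_equal(tracking_error(tr), 0)
  # a single residual sinusoid of amplitude A on one axis has power A^2/2
  tr1 <- tr
  tr1$y[, "x"] <- tr1$r[, "x"] + 1.7 * sin(2 * pi * 0.2 * tr1$t)
  expect_equal(tracking_error(tr1), 1.7^2 / 2, tolerance = 1e-9)
  # analytic expectation for a closed-loop subject
  subj <- make_subject("ataxia")
  tr2 <- simulate_trial(subj, specs)
  expected <- 0
  for (ax in c("x", "y")) {
    rs <- specs[[paste0("r", ax)]]
    ds <- specs[[paste0("d", ax)]]
    hr <- closed_loop_response(subj, rs$frequencies)$H_yr
    hd <- closed_loop_response(subj, ds$frequencies)$H_yd
    expected <- expected + sum(Mod(hr - 1)^2 * rs$magnitudes^2 / 2) +
      sum(Mod(hd)^2 * ds$magnitudes^2 / 2)
  }
  expect_equal(tracking_error(tr2), expected, tolerance = 1e-9)
  bad <- tr2
  bad$y <- bad$y[-1, ]
  expect_error(tracking_error(bad), "length")
})

test_that("feedback gain swap responds as the loop algebra dictates", {
  subj <- make_subject("ataxia")
  plan <- std_plan(1)
  res_same <- gain_swap_experiment(subj, group_truth$ataxia$fb$k,
                                   plan = plan, seed = 2)
  expect_equal(res_same$mse_original, res_same$mse_swapped)
  expect_equal(res_same$margins_original$gain_margin,
               res_same$margins_swapped$gain_margin)
  res_up <- gain_swap_experiment(subj, group_truth$control$fb$k,
                                 plan = plan, seed = 2)
  expect_lt(res_up$margins_swapped$gain_margin,
            res_up$margins_original$gain_margin)
  expect_lt(res_up$margins_swapped$phase_margin,
            res_up$margins_original$phase_margin)
})
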