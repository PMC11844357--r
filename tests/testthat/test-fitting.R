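test_that("the frequency-domain error behaves as a squared norm", {
  g <- std_grid()
  m <- pathway_model("gain_delay", k = 0.62, tau = 0.185)
  data <- tabulate_model(m)
  expect_equal(fd_error(m, data), 0)
  # data exactly on the model: perturbing k by delta adds 20 * delta^2
  # (the delay phasor has unit modulus at every frequency)
  m2 <- pathway_model("gain_delay", k = 0.62 + 0.05, tau = 0.185)
  expect_equal(fd_error(m2, data), 20 * 0.05^2, tolerance = 1e-12)
  empty <- frf_set(numeric(0), complex(0))
  expect_equal(fd_error(m, empty), 0)
})

test_that("multi-start fitting recovers generating parameters", {
  data <- tabulate_model(pathway_model("gain_delay", k = 0.62, tau = 0.185))
  fit <- fit_model(data, "gain_delay", n_restarts = 100, seed = 1)
  expect_lt(abs(fit$params[["k"]] - 0.62), 1e-6)
  expect_lt(abs(fit$params[["tau"]] - 0.185), 1e-6)
  expect_lt(fit$fd_error, 1e-10)
  leaky <- tabulate_model(pathway_model("leaky_integrator_delay", k = 1.3,
                                        tau = 0.123, a = 0.5))
  fit2 <- fit_model(leaky, "leaky_integrator_delay", n_restarts = 100,
                    seed = 2)
  expect_lt(abs(fit2$params[["k"]] - 1.3), 1e-4)
  expect_lt(abs(fit2$params[["tau"]] - 0.123), 1e-4)
  expect_lt(abs(fit2$params[["a"]] - 0.5), 1e-4)
})

test_that("the optimizer never loses to a brute-force grid search", {
  # data from a gain+delay model plus a fixed deterministic perturbation,
  # so the global minimum is not trivially zero
  g <- std_grid()
  w <- 2 * pi * g$frequencies
  vals <- 0.9 * exp(-1i * w * 0.21) +
    0.05 * complex(argument = seq(0, 3, length.out = 20))
  data <- frf_set(g$frequencies, vals)
  fit <- fit_model(data, "gain_delay", n_restarts = 60, seed = 5)
  # vectorized exhaustive search on k in [0,2] x tau in [0,0.6] at 1e-3
  taus <- seq(0, 0.6, by = 1e-3)
  ks <- seq(1e-3, 2, by = 1e-3)
  c_dd <- sum(Mod(vals)^2)
  best_grid <- Inf
  for (tau in taus) {
    ph <- exp(-1i * w * tau)
    s <- Re(sum(ph * Conj(vals)))
    err <- ks^2 * 20 - 2 * ks * s + c_dd
    best_grid <- min(best_grid, min(err))
  }
  expect_lte(fit$fd_error, best_grid + 1e-12)
})

test_that("leave-one-out cross-validation matches hand computation", {
  g <- std_grid()
  w <- 2 * pi * g$frequencies
  tau <- 0.15
  # homogeneous noise-free group: CVE is numerically zero
  grp <- lapply(1:3, function(i)
    tabulate_model(pathway_model("gain_delay", k = 0.6, tau = tau),
                   subject_id = paste0("s", i)))
  cv <- cross_validate(grp, "gain_delay", n_restarts = 30, seed = 7)
  expect_lt(cv$CVE, 1e-10)
  expect_equal(cv$CVE, mean(cv$VE))
  # two subjects differing only in gain: fitting on the other subject
  # recovers its gain exactly, so VE_j = 20 (k1 - k2)^2 for both
  k1 <- 0.5; k2 <- 0.8
  pair <- list(
    tabulate_model(pathway_model("gain_delay", k = k1, tau = tau),
                   subject_id = "a"),
    tabulate_model(pathway_model("gain_delay", k = k2, tau = tau),
                   subject_id = "b"))
  cv2 <- cross_validate(pair, "gain_delay", n_restarts = 30, seed = 8)
  expect_equal(cv2$CVE, 20 * (k1 - k2)^2, tolerance = 1e-6)
  # an outlier subject produces the largest VE
  grp3 <- c(grp, list(
    tabulate_model(pathway_model("gain_delay", k = 1.4, tau = 0.4),
                   subject_id = "outlier")))
  cv3 <- cross_validate(grp3, "gain_delay", n_restarts = 30, seed = 9)
  expect_equal(names(which.max(cv3$VE)), "outlier")
  expect_error(cross_validate(grp[1], "gain_delay"), "at least 2")
})

test_that("model selection prefers parsimony within the CVE tolerance", {
  reports <- list(
    list(structure = "gain_delay", fd_error = 1e-12, CVE = 1.0e-9),
    list(structure = "first_order_delay", fd_error = 1e-13, CVE = 1.02e-9),
    list(structure = "second_order_delay", fd_error = 1e-13, CVE = 0.99e-9))
  reports <- lapply(reports, function(r) {
    class(r) <- "fit_report"; r
  })
  sel <- select_model(reports, delta = 0.05)
  expect_equal(sel$structure, "gain_delay")
  # a clear CVE gap overrides parsimony
  reports[[1]]$CVE <- 1
  sel2 <- select_model(reports, delta = 0.05)
  expect_equal(sel2$structure, "first_order_delay")
  expect_equal(select_model(reports[2], delta = 0.05)$structure,
               "first_order_delay")
})

test_that("selection on cross-validated synthetic groups is structure-true", {
  # feedforward generated by gain+delay: gain+delay wins over richer lags
  grp_ff <- lapply(1:3, function(i)
    tabulate_model(pathway_model("gain_delay", k = 0.6, tau = 0.185),
                   subject_id = paste0("c", i)))
  reports_ff <- lapply(c("gain_delay", "first_order_delay",
                         "second_order_delay"), function(st)
    cross_validate(grp_ff, st, n_restarts = 40, seed = 11))
  expect_equal(select_model(reports_ff)$structure, "gain_delay")
  # feedback generated by the leaky integrator: gain+delay cannot zero the
  # residual, and the CVE gap exceeds the parsimony tolerance
  grp_fb <- lapply(1:3, function(i)
    tabulate_model(pathway_model("leaky_integrator_delay", k = 1.3,
                                 tau = 0.123, a = 0.5),
                   subject_id = paste0("c", i), channel = "PB"))
  reports_fb <- lapply(c("gain_delay", "leaky_integrator_delay",
                         "first_order_delay"), function(st)
    cross_validate(grp_fb, st, n_restarts = 40, seed = 12))
  expect_equal(select_model(reports_fb)$structure, "leaky_integrator_delay")
})
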