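test_that("frequency grid is the first prime multiples of the base", {
  g <- std_grid()
  expect_equal(length(g$frequencies), 20)
  expect_equal(min(g$frequencies), 0.08)
  expect_equal(max(g$frequencies), 2.84)
  expect_equal(build_frequency_grid(0.04, 1)$frequencies, 0.08)
  # independent trial-division oracle for the prime multipliers
  primes <- (2:100)[vapply(2:100, function(n)
    n < 4 || all(n %% 2:floor(sqrt(n)) != 0), logical(1))]
  expect_equal(g$primes, primes[1:20])
  expect_equal(build_frequency_grid(0.04, 10)$frequencies[10], 29 * 0.04)
  expect_error(build_frequency_grid(-1, 5), "positive")
  expect_error(build_frequency_grid(0.04, 0), "positive integer")
})

test_that("no grid frequency is an integer multiple of another", {
  f <- std_grid()$frequencies
  for (i in seq_along(f)) {
    for (j in seq_along(f)) {
      if (i == j) next
      ratio <- f[j] / f[i]
      if (ratio >= 2) expect_gt(abs(ratio - round(ratio)), 1e-9)
    }
  }
  expect_true(!is.unsorted(f, strictly = TRUE))
})

test_that("amplitude profile takes the lesser branch and honors both bounds", {
  expect_equal(amplitude_profile(0.08, 1.3, 2.3), 2.3)      # cap active
  expect_equal(amplitude_profile(1.3, 1.3, 2.3), 1.0)       # velocity branch
  expect_equal(amplitude_profile(2.84, 0.7, 1.5), 0.7 / 2.84)
  # branch crossover at f = velocity_coeff / cap
  fc <- 1.3 / 2.3
  expect_equal(amplitude_profile(fc, 1.3, 2.3), 2.3, tolerance = 1e-12)
  expect_lt(amplitude_profile(fc * 1.01, 1.3, 2.3), 2.3)
  expect_error(amplitude_profile(0), "positive")
  # bound conservation over the whole grid, both profiles
  f <- std_grid()$frequencies
  m_r <- amplitude_profile(f, 1.3, 2.3)
  m_d <- amplitude_profile(f, 0.7, 1.5)
  expect_true(all(m_r <= 2.3 + 1e-12))
  expect_true(all(2 * pi * f * m_r <= 2.6 * pi + 1e-9))
  expect_true(all(m_d <= 1.5 + 1e-12))
  expect_true(all(2 * pi * f * m_d <= 1.4 * pi + 1e-9))
})

test_that("generated signals round-trip through the single-frequency DFT", {
  one <- sos_spec(0.08, 2.3, 0, "r1")
  x <- generate_signal(one, 25, 80)
  expect_lte(max(abs(x)), 2.3 + 1e-12)
  c0 <- single_frequency_dft(x, 0.08, 80)
  expect_equal(Mod(c0), 2.3, tolerance = 1e-9)
  expect_equal(Arg(c0), 0, tolerance = 1e-9)
  # value at t = 0 is sum(M * sin(phi))
  set.seed(11)
  for (rep in 1:5) {
    g <- std_grid()
    idx <- sort(sample(20, 5))
    spec <- sos_spec(g$frequencies[idx],
                     amplitude_profile(g$frequencies[idx]),
                     runif(5, 0, 2 * pi), "r1")
    x <- generate_signal(spec, 25, 80)
    expect_equal(x[1], sum(spec$magnitudes * sin(spec$phases)),
                 tolerance = 1e-12)
    for (i in 1:5) {
      ci <- single_frequency_dft(x, spec$frequencies[i], 80)
      expect_lt(Mod(ci - spec$magnitudes[i] * exp(1i * spec$phases[i])),
                1e-9)
    }
  }
  expect_error(generate_signal(one, 24.9, 80), "integer number of cycles")
  expect_error(generate_signal(sos_spec(2.84, 1, 0), 25, 4), "Nyquist")
})

test_that("session plan realizes the rotation in both preview conditions", {
  g <- std_grid()
  plan <- std_plan(42)
  expect_equal(nrow(plan), 16)
  expect_equal(sum(plan$preview_ms == 0), 8)
  expect_equal(sum(plan$preview_ms == 500), 8)
  # the first rotation row appears with no preview
  expect_true(any(plan$rx == "r1" & plan$dx == "d2" & plan$ry == "r3" &
                    plan$dy == "d4" & plan$preview_ms == 0))
  # two seeds: same multiset of cells, different orderings
  p1 <- std_plan(1); p2 <- std_plan(2)
  key <- function(p) sort(paste(p$rx, p$dx, p$ry, p$dy, p$preview_ms))
  expect_equal(key(p1), key(p2))
  expect_false(identical(paste(p1$rx, p1$preview_ms),
                         paste(p2$rx, p2$preview_ms)))
  # pooled coverage: every frequency in both roles on both axes,
  # in each preview condition
  groups <- std_groups(g)
  for (pv in c(0, 500)) {
    sub <- plan[plan$preview_ms == pv, ]
    for (col in c("rx", "dx", "ry", "dy")) {
      gidx <- as.integer(sub("^[rd]", "", sub[[col]]))
      covered <- sort(unique(unlist(groups[gidx])))
      expect_equal(covered, 1:20)
    }
  }
})

test_that("trial specs apply the channel-appropriate amplitude profile", {
  g <- std_grid(); groups <- std_groups(g)
  set.seed(3)
  specs <- trial_specs(g, groups, c(rx = "r1", dx = "d2", ry = "r3",
                                    dy = "d4"))
  expect_equal(specs$rx$magnitudes,
               amplitude_profile(specs$rx$frequencies, 1.3, 2.3))
  expect_equal(specs$dx$magnitudes,
               amplitude_profile(specs$dx$frequencies, 0.7, 1.5))
  expect_length(specs$rx$frequencies, 5)
  # reference and disturbance sets on one axis are disjoint
  expect_length(intersect(specs$rx$frequencies, specs$dx$frequencies), 0)
  expect_length(intersect(specs$ry$frequencies, specs$dy$frequencies), 0)
  # the four reference groups partition the grid
  all_r <- sort(unlist(lapply(groups, function(i) g$frequencies[i])))
  expect_equal(all_r, g$frequencies)
})
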