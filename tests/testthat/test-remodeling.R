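test_that("daily stimulus is the cycle-weighted power mean", {
  expect_equal(daily_stimulus(matrix(2, 1, 1), 1, m = 4), 2)
  expect_equal(daily_stimulus(matrix(c(1, 1, 1), 1), c(6000, 2000, 2000),
                              m = 4), 10)
  expect_equal(daily_stimulus(matrix(0, 1, 3), c(6000, 2000, 2000)), 0)
  expect_equal(equilibrium_stimulus(matrix(c(1, 1, 1), 1)), 10)
  expect_equal(equilibrium_stimulus(matrix(c(2, 0, 0), 1)),
               2 * 6000^(1 / 4), tolerance = 1e-12)
  # floor keeps unloaded elements positive
  expect_equal(equilibrium_stimulus(matrix(0, 1, 3)), 1e-6)
  expect_error(daily_stimulus(matrix(-1, 1, 3), c(1, 1, 1)))
})

test_that("disuse sigmoid has the closed-form values and saturates safely", {
  expect_equal(disuse_activation_frequency(1, 1), 0.1 / (1 + exp(5)),
               tolerance = 1e-12)
  expect_equal(disuse_activation_frequency(0, 1), 0.1 / (1 + exp(-5)),
               tolerance = 1e-12)
  expect_equal(disuse_activation_frequency(1e9, 1), 0)
  expect_equal(disuse_activation_frequency(1e9, 1e-6), 0)
  phis <- seq(0, 3, by = 0.05)
  fa <- disuse_activation_frequency(phis, 1)
  expect_true(all(diff(fa) < 0))
  expect_true(all(fa > 0 & fa < 0.1))
  expect_error(disuse_activation_frequency(1, 0))
})

test_that("specific surface matches the quintic and vanishes at both ends", {
  expect_equal(specific_surface(0), 0)
  expect_equal(specific_surface(1), 0, tolerance = 1e-10)
  expect_equal(specific_surface(0.5), 3.9125, tolerance = 1e-12)
  p <- seq(0, 1, by = 0.01)
  expect_true(all(specific_surface(p) >= 0))
  expect_error(specific_surface(1.5))
})

test_that("BMU geometric rates match the closed forms and balance at equilibrium", {
  prm <- remodeling_params()
  expect_equal(resorption_rate("cancellous", prm),
               pi * 0.05 * 0.65 * 0.01 / 4, tolerance = 1e-12)
  expect_equal(resorption_rate("cortical", prm), pi * 0.2^2 * 0.01 / 4,
               tolerance = 1e-12)
  expect_equal(resorption_rate("cortical", remodeling_params(v = 1e-9)),
               pi * 0.2^2 * 1e-9 / 4)
  qr <- resorption_rate("cortical", prm)
  expect_equal(filling_rate(qr, 24, 64), qr * 24 / 64, tolerance = 1e-12)
  expect_equal(filling_rate(qr, 5, 5), qr)
  # equilibrium closure: constant history gives zero porosity rate
  c0 <- 0.0123
  for (cl in c("cortical", "cancellous")) {
    tm <- prm[[cl]]
    qr <- resorption_rate(cl, prm)
    qf <- filling_rate(qr, tm["T_R"], tm["T_F"])
    h <- bmu_history(rep(c0, 3), tm["T_R"], tm["T_I"], tm["T_F"])
    ct <- bmu_counts(h)
    expect_equal(ct$n_r, rep(c0 * tm[["T_R"]], 3))
    expect_equal(ct$n_f, rep(c0 * tm[["T_F"]], 3))
    expect_equal(porosity_rate(ct$n_r, ct$n_f, qr, qf), rep(0, 3),
                 tolerance = 1e-16)
  }
  expect_true(porosity_rate(1, 0, 1e-4, 1e-4) > 0)
})

test_that("ring-buffer window integrals equal brute-force sums exactly", {
  set.seed(11)
  for (tms in list(c(24, 8, 64), c(60, 57, 197), c(3, 2, 5))) {
    len <- sum(tms)
    n_days <- len + 57
    full <- matrix(runif(2 * (len + n_days)), nrow = 2)
    h <- bmu_history(full[, 1], tms[1], tms[2], tms[3])
    for (d in 2:(len + n_days)) h <- bmu_push(h, full[, d])
    ct <- bmu_counts(h)
    for (e in 1:2) {
      bf <- brute_force_counts(full[e, ], tms[1], tms[2], tms[3])
      expect_identical(ct$n_r[e], bf$n_r)
      expect_identical(ct$n_f[e], bf$n_f)
    }
  }
})

test_that("a unit impulse reaches the filling window after exactly T_R + T_I days", {
  tr <- 5L; ti <- 3L; tf <- 7L
  h <- bmu_history(0, tr, ti, tf)
  h <- bmu_push(h, 1)      # impulse on day 1
  seen_r <- bmu_counts(h)$n_r
  expect_equal(seen_r, 1)  # immediate effect on the resorbing pool
  first_f <- NA
  for (day in 2:(tr + ti + tf + 2)) {
    h <- bmu_push(h, 0)
    if (is.na(first_f) && bmu_counts(h)$n_f > 0) first_f <- day
  }
  expect_equal(first_f - 1L, tr + ti)   # delay relative to the impulse day
  # and it leaves the resorbing window after T_R days
  h2 <- bmu_history(0, tr, ti, tf)
  h2 <- bmu_push(h2, 1)
  for (day in 2:tr) {
    h2 <- bmu_push(h2, 0)
    expect_equal(bmu_counts(h2)$n_r, 1)
  }
  h2 <- bmu_push(h2, 0)
  expect_equal(bmu_counts(h2)$n_r, 0)
})

test_that("electrical modulation scales activation only inside the window", {
  prot <- stimulation_protocol(amplitude = 0.7, start_day = 101,
                               duration_days = 100)
  fa <- 9.9331e-2
  expect_equal(es_modulated_activation(fa, 1, 150, prot), 0.3 * fa,
               tolerance = 1e-12)
  expect_equal(es_modulated_activation(fa, 1, 150, prot), 2.97993e-2,
               tolerance = 1e-4)
  expect_equal(es_modulated_activation(fa, 0, 150, prot), fa)
  expect_equal(es_modulated_activation(fa, 1, 100, prot), fa)  # before window
  expect_equal(es_modulated_activation(fa, 1, 201, prot), fa)  # after window
  prot0 <- stimulation_protocol(amplitude = 0, start_day = 101)
  expect_equal(es_modulated_activation(fa, 1, 150, prot0), fa)
  expect_equal(es_modulated_activation(fa, 0.5, 150, NULL), fa)
})

test_that("homeostasis: at the equilibrium stimulus nothing drifts", {
  st <- frozen_state(phi_ratio = 1, class = "cancellous", porosity = 0.4)
  rho0 <- st$rho
  sim <- run_simulation(st, 400)
  expect_lt(max(abs(sim$state$rho - rho0)), 1e-12)
})

test_that("total disuse drives monotone bone loss, gated by the filling delay", {
  prm <- remodeling_params(fe_update_interval = 1e6)
  st <- frozen_state(phi_ratio = 0, class = "cortical", porosity = 0.05,
                     params = prm)
  sim <- run_simulation(st, 250)
  rho <- sim$timeseries$mean_rho_cortical
  expect_true(all(diff(rho) < 1e-15))
  # before the elevated activation reaches the filling window the loss rate
  # approaches Q_R * N_R - Q_F * N_F(equilibrium), with N_R saturated after
  # T_R days at fa(0) * Sr(P)
  fa_hi <- disuse_activation_frequency(0, 1)
  fa_eq <- disuse_activation_frequency(1, 1)
  tr <- prm$cortical[["T_R"]]; ti <- prm$cortical[["T_I"]]
  day <- tr + 5
  p_then <- 1 - sim$timeseries$mean_rho_cortical[day] / 1.8
  qr <- resorption_rate("cortical", prm)
  qf <- filling_rate(qr, tr, prm$cortical[["T_F"]])
  rate_pred <- -(qr * fa_hi * specific_surface(p_then) * tr -
                   qf * fa_eq * specific_surface(0.05) *
                     prm$cortical[["T_F"]]) * 1.8
  rate_obs <- sim$timeseries$mean_rho_cortical[day + 1] -
    sim$timeseries$mean_rho_cortical[day]
  expect_equal(rate_obs, rate_pred, tolerance = 0.05)
})

test_that("day stepping is deterministic and a zero-day run is the identity", {
  pair <- small_femur_pair()
  prm <- remodeling_params(fe_update_interval = 5)
  s1 <- simulate_remodeling(pair$implanted, pair$intact, params = prm,
                            days = 12)
  s2 <- simulate_remodeling(pair$implanted, pair$intact, params = prm,
                            days = 12)
  expect_identical(s1$timeseries, s2$timeseries)
  expect_identical(s1$state$rho, s2$state$rho)
  s0 <- simulate_remodeling(pair$implanted, pair$intact, params = prm,
                            days = 0)
  expect_equal(s0$state$day, 0L)
  expect_equal(s0$state$rho, s0$inputs$material$rho)
  expect_equal(nrow(s0$timeseries), 0L)
})

test_that("porosity stays inside the clamp bounds under extreme disuse", {
  prm <- remodeling_params(fe_update_interval = 1e6)
  st <- frozen_state(phi_ratio = 0, class = "cancellous", porosity = 0.9,
                     params = prm)
  sim <- run_simulation(st, 600)
  expect_true(all(sim$state$porosity <= 0.99 + 1e-15))
  expect_true(all(sim$state$porosity >= 0.01 - 1e-15))
  expect_true(all(sim$state$rho >= 1.8 * 0.01 - 1e-12))
})
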