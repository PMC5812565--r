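# MSD computation, log-log transform, power-law fitting and the derived
# diffusion coefficients.

test_that("ensemble MSD plumbing is exact on constructed trajectories", {
  dl <- derive_step_length(0.2e-3, 1e-3)
  k <- 1:10                                   # one hop right per step
  ball <- fake_trajectory(k * 1e-3, matrix(k * dl, ncol = 1),
                          matrix(0, 10, 1))
  m <- ensemble_msd(ball)
  expect_equal(m$msd_um2, k^2 * dl^2)         # ballistic: k^2 dl^2

  still <- fake_trajectory(k * 1e-3, matrix(0, 10, 3), matrix(0, 10, 3))
  expect_true(all(ensemble_msd(still)$msd_um2 == 0))

  # ensemble averaging is an unweighted mean across replicates
  t2 <- fake_trajectory(k * 1e-3, matrix(2 * k * dl, ncol = 1),
                        matrix(0, 10, 1))
  m2 <- ensemble_msd(list(ball, t2))
  expect_equal(m2$msd_um2, (k^2 + 4 * k^2) / 2 * dl^2)
  expect_identical(attr(m2, "n_ensembles"), 2L)

  bad <- fake_trajectory(k * 2e-3, matrix(0, 10, 1), matrix(0, 10, 1))
  expect_error(ensemble_msd(list(ball, bad)), "grids differ")
})

test_that("free lattice MSD agrees with the closed form", {
  n <- 1000
  msd <- free_lattice_msd(n, measure_ms = 1, n_side = 100, seed = 5,
                          n_record = 25)
  expected <- 4 * 0.2e-3 * msd$time_ms
  expect_true(all(abs(msd$msd_um2 - expected) <= 3 * expected * sqrt(2 / n)))
})

test_that("log-log transform is the exact arithmetic identity", {
  t <- exp(seq(0, 7, length.out = 30))
  D <- 3e-4
  flat <- loglog_profile(data.frame(time_ms = t, msd_um2 = 4 * D * t))
  expect_equal(flat$log_msd_t, rep(log(4 * D), 30))
  half <- loglog_profile(data.frame(time_ms = t, msd_um2 = 4 * D * t^0.5))
  expect_equal(coef(lm(log_msd_t ~ log_t, half))[[2]], -0.5, tolerance = 1e-12)
  plat <- loglog_profile(data.frame(time_ms = t, msd_um2 = rep(2, 30)))
  expect_equal(coef(lm(log_msd_t ~ log_t, plat))[[2]], -1, tolerance = 1e-12)
  expect_warning(
    z <- loglog_profile(data.frame(time_ms = t, msd_um2 = c(0, 4 * t[-1]))),
    "non-positive")
  expect_identical(nrow(z), 29L)
})

test_that("fit_alpha inverts exact power laws to machine precision", {
  for (alpha in c(0, 0.25, 0.5, 0.75, 1)) {
    fit <- fit_alpha(powerlaw_profile(alpha, D = 2e-4))
    expect_equal(fit$alpha, alpha, tolerance = 1e-9)
    expect_equal(fit$D_fit, 2e-4, tolerance = 1e-9)
  }
  f1 <- fit_alpha(powerlaw_profile(1, D = 0.2e-3))
  expect_identical(f1$regime, "normal")
  f0 <- fit_alpha(powerlaw_profile(0.25))
  expect_identical(f0$regime, "anomalous")
  expect_error(fit_alpha(powerlaw_profile(1, n = 5)), "fit-domain")
  expect_error(fit_alpha(powerlaw_profile(1, t_min = 1, t_max = 5)),
               "fit-domain")
})

test_that("a changepoint curve is classified transition with its crossover", {
  t <- exp(seq(0, log(2000), length.out = 80))
  tc <- 100
  msd <- ifelse(t <= tc, 4e-4 * t^0.5, 4e-4 * tc^0.5 * (t / tc))
  fit <- fit_alpha(data.frame(time_ms = t, msd_um2 = msd))
  expect_identical(fit$regime, "transition")
  # within one sliding-window width (window_frac of the log span)
  win <- exp(0.2 * log(2000))
  expect_lt(fit$crossover_time_ms, tc * win)
  expect_gt(fit$crossover_time_ms, tc / win)
  expect_equal(fit$alpha, 0.5, tolerance = 0.1)
  expect_equal(fit$crossover_length_um2, 4e-4 * tc^0.5 * 1, tolerance = 0.5)
})

test_that("alpha above one from noise is reported as normal", {
  t <- exp(seq(0, 8, length.out = 40))
  set.seed(2)
  msd <- 4 * 1e-4 * t^1.02 * exp(rnorm(40, 0, 0.01))
  fit <- fit_alpha(data.frame(time_ms = t, msd_um2 = msd))
  expect_identical(fit$alpha, 1)
  expect_identical(fit$regime, "normal")
  expect_lte(fit$alpha, 1.05)
})

test_that("apparent, instantaneous and effective coefficients obey Eqs", {
  expect_equal(apparent_diffusion(0.3, 1, 17), 0.3)
  expect_equal(apparent_diffusion(1, 0.5, 4), 0.5)
  expect_equal(instantaneous_diffusion(1, 0.5, 4), 0.25)
  expect_equal(instantaneous_diffusion(2, 0, 100), 0)
  expect_error(apparent_diffusion(1, 0.5, 0), "positive")

  # D_inst = alpha * D_app identically
  set.seed(3)
  for (i in 1:20) {
    a <- runif(1); D <- runif(1, 0, 1e-2); t <- runif(1, 0.1, 5000)
    expect_equal(instantaneous_diffusion(D, a, t),
                 a * apparent_diffusion(D, a, t), tolerance = 1e-12)
  }

  # D_app -> 0 with time when alpha = 0
  expect_lt(apparent_diffusion(1, 0, 1e6), apparent_diffusion(1, 0, 1e3))

  fitn <- fit_alpha(powerlaw_profile(1, D = 0.2e-3))
  expect_equal(effective_diffusion(fitn), 0.2e-3)
  expect_equal(fitn$D_eff_nm2_us, 0.2, tolerance = 1e-6)
  fita <- fit_alpha(powerlaw_profile(0.5, D = 1))
  expect_equal(effective_diffusion(fita, t_obs = 2000), 2000^(-0.5),
               tolerance = 1e-6)
  expect_equal(2000^(-0.5), 0.02236, tolerance = 1e-3)
})

test_that("generic power-law fitting recovers parameters and rejects junk", {
  t <- seq(1, 50)
  msd <- 4 * 0.3 * t^0.7
  for (m in c("loglog", "nls")) {
    cf <- coef(fit_msd_powerlaw(t, msd, method = m))
    expect_equal(unname(cf["alpha"]), 0.7, tolerance = 1e-6)
    expect_equal(unname(cf["D"]), 0.3, tolerance = 1e-6)
  }
  set.seed(4)
  noisy <- msd * (1 + rnorm(50, 0, 0.02))
  cf <- coef(fit_msd_powerlaw(t, noisy))
  expect_lt(abs(cf["alpha"] - 0.7), 0.05)
  expect_error(fit_msd_powerlaw(t, -msd), "positive")
  expect_error(fit_msd_powerlaw(1:2, c(1, 2)), "3 points")
})
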