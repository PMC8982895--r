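test_that("the default schedule has 18 strictly increasing days", {
  grid <- default_time_grid()
  expect_length(grid, 18)
  expect_equal(grid, c(-1, 7:14, 17, 21, 24, 28, 31, 35, 38, 42, 44))
  expect_true(all(diff(grid) > 0))
})

test_that("an empty sparse phase truncates the schedule at day 14", {
  grid <- default_time_grid(list(sparse = numeric(0)))
  expect_equal(max(grid), 14)
})

test_that("true time-effect templates behave as documented", {
  f0 <- make_true_f("zero")
  expect_equal(f0(default_time_grid()), rep(0, 18))
  fl <- make_true_f("linear", list(slope = 1))
  expect_equal(fl(44) - fl(7), 37)
  fp <- make_true_f("plateau")
  expect_lt(abs(fp(44) - fp(30)), abs(fp(20) - fp(7)))
  fr <- make_true_f("rise")
  expect_true(all(diff(fr(seq(7, 44, by = 1))) > 0))
  expect_error(make_true_f("wiggle"), "arg")
})

test_that("noiseless simulation reproduces the mean structure exactly", {
  cfg <- sim_config(n_per_group = 2, sigma = 0, sigma_phi = 0, seed = 73)
  sim <- simulate_dataset(cfg)
  d <- sim$data$data
  mu <- ifelse(d$group == 0, sim$truth$mu[[1]](d$day),
               sim$truth$mu[[2]](d$day))
  expect_equal(d$value, mu, tolerance = 1e-12)
})

test_that("the generative truth is centered and shifted by beta", {
  cfg <- sim_config(seed = 1)
  grid <- default_time_grid()
  expect_equal(mean(cfg$f[[1]](grid)), 0, tolerance = 1e-12)
  expect_equal(mean(cfg$f[[2]](grid)), 0, tolerance = 1e-12)
  expect_equal(mean(cfg$beta[1] + cfg$beta[2] + cfg$f[[2]](grid)) -
                 mean(cfg$beta[1] + cfg$f[[1]](grid)), cfg$beta[2])
})

test_that("simulation is bit-reproducible from the seed", {
  a <- simulate_dataset(sim_config(seed = 79, missing_rate = 0.2))
  b <- simulate_dataset(sim_config(seed = 79, missing_rate = 0.2))
  expect_identical(a$data$data, b$data$data)
  expect_identical(a$truth$phi, b$truth$phi)
  c <- simulate_dataset(sim_config(seed = 80, missing_rate = 0.2))
  expect_false(identical(a$data$data$value, c$data$data$value))
})

test_that("residual noise has the configured spread", {
  # ~10^4 draws once the truth is subtracted out
  cfg <- sim_config(n_per_group = 300, sigma = 5, sigma_phi = 0, seed = 83)
  sim <- simulate_dataset(cfg)
  d <- sim$data$data
  resid <- d$value - ifelse(d$group == 0, sim$truth$mu[[1]](d$day),
                            sim$truth$mu[[2]](d$day))
  expect_gt(length(resid), 1e4)
  expect_lt(abs(stats::sd(resid) - 5) / 5, 0.03)
})

test_that("intercept spread matches sigma_phi at Monte-Carlo scale", {
  cfg <- sim_config(n_per_group = 2000, sigma = 0, sigma_phi = 5, seed = 89,
                    schedule = list(daily = 7, sparse = numeric(0)))
  sim <- simulate_dataset(cfg)
  expect_lt(abs(stats::sd(sim$truth$phi) - 5) / 5, 0.05)
})

test_that("dropout never removes the baseline measurement", {
  cfg <- sim_config(n_per_group = 30, missing_rate = 0.5, seed = 97)
  sim <- simulate_dataset(cfg)
  d <- sim$data$data
  n_baseline <- sum(d$day == -1)
  expect_equal(n_baseline, 60)
  expect_lt(sim$data$n, 60 * 18) # some non-baseline days dropped
})

test_that("single-replicate recovery reports one row", {
  rep1 <- recovery_experiment(sim_config(n_per_group = 2, sigma = 1,
                                         sigma_phi = 1, seed = 101),
                              smm_control(gamma = 0.5), replicates = 1,
                              dict_args = list(n_knots = 4, n_fourier = 2,
                                               n_powers = 2, haar_levels = 2))
  expect_equal(nrow(rep1$replicates), 1)
  expect_equal(rep1$summary$n_ok, 1)
})

test_that("noiseless in-span recovery has numerically zero bias", {
  # equal slopes so that the group contrast is carried by beta1 alone and
  # the estimand is identified (f1 - f0 = 0)
  cfg <- sim_config(n_per_group = 2, beta = c(50, 4),
                    f_templates = list(allograft = make_true_f("linear",
                                                               list(slope = 0.3)),
                                       autograft = make_true_f("linear",
                                                               list(slope = 0.3))),
                    sigma = 0, sigma_phi = 0, seed = 103)
  rep1 <- recovery_experiment(cfg, smm_control(gamma = 1e-8, tol = 1e-9),
                              replicates = 2,
                              dict_args = list(n_knots = 0, n_fourier = 0,
                                               n_powers = 1, haar_levels = 0))
  expect_lt(abs(rep1$summary$bias), 1e-5)
  expect_lt(rep1$summary$mean_mise, 1e-8)
})

test_that("recovery experiments are reproducible from the base seed", {
  cfg <- sim_config(n_per_group = 2, sigma = 1, sigma_phi = 1, seed = 107)
  args <- list(n_knots = 2, n_fourier = 1, n_powers = 1, haar_levels = 1)
  a <- recovery_experiment(cfg, replicates = 2, dict_args = args)
  b <- recovery_experiment(cfg, replicates = 2, dict_args = args)
  expect_identical(a$replicates, b$replicates)
})
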