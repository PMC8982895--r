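simple_design <- function(data, dict) build_design(dict, data)

test_that("E-step reproduces the closed-form single-mouse BLUP", {
  d <- make_data(c("m1", "m1"), c(0, 0), c(0, 10), c(1, 1))
  dict <- default_dictionary(c(0, 3, 7, 10), n_knots = 0, n_fourier = 0,
                             n_powers = 1, haar_levels = 0)
  des <- simple_design(d, dict)
  es <- e_step(c(1, 1), sigma2 = 1, sigma2_phi = 1, design = des)
  expect_equal(unname(es$W), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(es$phi), 2 / 3, tolerance = 1e-12)
  # zero residual
  es0 <- e_step(c(0, 0), 2, 3, des)
  expect_equal(unname(es0$phi), 0)
  expect_equal(unname(es0$W), 2 / (2 + 2 / 3), tolerance = 1e-12)
  # shrinkage-free limit
  esL <- e_step(c(1, 3), 1, 1e8, des)
  expect_equal(unname(esL$phi), 2, tolerance = 1e-4)
  # degenerate branch
  esD <- e_step(c(1, 3), 1, 0, des)
  expect_equal(unname(esD$phi), 0)
  expect_equal(unname(esD$W), 0)
})

test_that("E-step equals the Woodbury BLUP on random 5-mouse instances", {
  set.seed(11)
  for (rep in 1:5) {
    n_i <- sample(2:6, 5, replace = TRUE)
    days <- lapply(n_i, function(k) sort(sample(0:44, k)))
    d <- longitudinal_data(data.frame(
      mouse_id = rep(paste0("m", 1:5), n_i),
      group = rep(c(0, 0, 1, 1, 1), n_i),
      day = unlist(days),
      value = stats::rnorm(sum(n_i))))
    dict <- default_dictionary(0:44, 0, 1, 1, 0)
    des <- simple_design(d, dict)
    res <- stats::rnorm(d$n)
    s2 <- stats::runif(1, 0.5, 2)
    s2p <- stats::runif(1, 0.5, 2)
    blup <- s2p * t(des$Z) %*%
      solve(s2p * tcrossprod(des$Z) + s2 * diag(d$n), res)
    expect_equal(unname(e_step(res, s2, s2p, des)$phi), as.vector(blup),
                 tolerance = 1e-10)
  }
})

test_that("M-step matches the printed variance updates by hand", {
  d <- make_data(c("m1", "m1"), c(0, 0), c(0, 10), c(1, 1))
  dict <- default_dictionary(c(0, 3, 7, 10), 0, 0, 1, 0)
  des <- simple_design(d, dict)
  ms <- m_step(ehat = c(0, 0), phi = 0.5, sigma2_prev = 1, eta_prev = 1,
               design = des)
  expect_equal(ms$sigma2_phi, 0.25 + 1 / 3, tolerance = 1e-12)
  ms2 <- m_step(ehat = c(0.1, -0.1), phi = 0.5, sigma2_prev = 1,
                eta_prev = 1, design = des)
  expect_equal(ms2$sigma2, (0.02 + 2 / 3) / 2, tolerance = 1e-12)
  # degenerate limit
  ms0 <- m_step(c(0, 0), 0, 1e-10, 1, des)
  expect_lt(ms0$sigma2, 1e-9)
  expect_lt(ms0$sigma2_phi, 1e-9)
})

test_that("lasso update soft-thresholds a single column and obeys KKT", {
  des <- list(F = matrix(1, 4, 1))
  lam <- lasso_update(rep(2, 4), des, weights = 0.5, sigma2 = 1)
  expect_equal(unname(lam), 1.5, tolerance = 1e-8)
  # full shrinkage under huge weights
  lam0 <- lasso_update(rep(2, 4), des, weights = 1e6, sigma2 = 1)
  expect_identical(unname(lam0), 0)
  # KKT certificate at the solver tolerance
  expect_lt(kkt_violation(lam, rep(2, 4), des, 0.5), 1e-6)
})

test_that("unpenalized lasso on a full-rank design is least squares", {
  set.seed(21)
  Fm <- cbind(stats::rnorm(20), stats::rnorm(20), stats::rnorm(20))
  u <- stats::rnorm(20)
  des <- list(F = Fm)
  lam <- lasso_update(u, des, weights = rep(0, 3), sigma2 = 1)
  ols <- as.vector(solve(crossprod(Fm), crossprod(Fm, u)))
  expect_equal(unname(lam), ols, tolerance = 1e-7)
  expect_lt(max(abs(crossprod(Fm, u - Fm %*% lam))), 1e-5)
})

test_that("the coordinate-descent solution matches glmnet on random problems", {
  skip_if_not_installed("glmnet")
  set.seed(31)
  for (rep in 1:3) {
    n <- 40; p <- 12
    Fm <- matrix(stats::rnorm(n * p), n, p)
    u <- stats::rnorm(n, sd = 2)
    r <- stats::runif(p, 0.5, 2)
    s2 <- 1.3
    lam <- lasso_update(u, list(F = Fm), weights = r, sigma2 = s2)
    g <- glmnet::glmnet(Fm, u, alpha = 1, standardize = FALSE,
                        intercept = FALSE,
                        penalty.factor = r,
                        lambda = s2 * mean(r), thresh = 1e-14,
                        maxit = 1e7)
    expect_equal(unname(lam), as.vector(g$beta), tolerance = 1e-5)
  }
})

test_that("least-squares step reproduces hand OLS with its inference", {
  d <- make_data(paste0("m", 1:4), c(0, 0, 1, 1), c(1, 2, 1, 2), 1:4)
  dict <- default_dictionary(c(0, 1, 2, 3), 0, 0, 1, 0)
  des <- simple_design(d, dict)
  ls <- ls_step(c(1, 2, 3, 4), rep(0, 4), rep(0, 4), des)
  expect_equal(unname(ls$beta), c(1.5, 2.0), tolerance = 1e-12)
  tab <- ls$table
  expect_equal(tab$estimate[tab$term == "Group"], 2.0, tolerance = 1e-12)
  expect_equal(tab$std_error[tab$term == "Group"], sqrt(0.5), tolerance = 1e-10)
  expect_equal(tab$t_value[tab$term == "Group"], 2 / sqrt(0.5),
               tolerance = 1e-10)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # exact fit: zero residuals, zero SEs
  u_exact <- as.vector(des$X %*% c(1, 2))
  ls2 <- ls_step(u_exact, rep(0, 4), rep(0, 4), des)
  expect_equal(unname(ls2$beta), c(1, 2), tolerance = 1e-12)
  expect_equal(unname(ls2$table$std_error), c(0, 0), tolerance = 1e-12)
  # single-group data is a rank error
  d1 <- make_data(paste0("m", 1:4), rep(0, 4), c(1, 2, 1, 2), 1:4)
  expect_error(ls_step(1:4, rep(0, 4), rep(0, 4), simple_design(d1, dict)),
               "rank")
})

test_that("noiseless data with in-span time effects is recovered", {
  # truth: centered linear time effects, exactly in the span of power_1
  cfg <- sim_config(n_per_group = 3, beta = c(100, 4),
                    f_templates = list(allograft = make_true_f("linear",
                                                               list(slope = 0.5)),
                                       autograft = make_true_f("linear",
                                                               list(slope = 0.2))),
                    sigma = 0, sigma_phi = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  dict <- default_dictionary(sim$data$data$day, 0, 0, 1, 0)
  fit <- fit_smm(sim$data, dict, smm_control(gamma = 1e-8, tol = 1e-10))
  obs <- sim$data$data
  pred <- vapply(seq_len(nrow(obs)),
                 function(i) predict(fit, obs$day[i], obs$group[i]),
                 numeric(1))
  mu <- ifelse(obs$group == 0, sim$truth$mu[[1]](obs$day),
               sim$truth$mu[[2]](obs$day))
  expect_lt(sqrt(mean((pred - mu)^2)), 1e-4)
})

test_that("estimated f matches the design rows and block structure", {
  sim <- simulate_dataset(sim_config(n_per_group = 3, sigma = 2,
                                     sigma_phi = 1, seed = 9))
  dict <- default_dictionary(sim$data$data$day, 4, 2, 2, 2)
  fit <- fit_smm(sim$data, dict, smm_control(gamma = 0.1))
  f0 <- estimate_f(fit, 0)
  f1 <- estimate_f(fit, 1)
  ro <- fit$design$row_order
  Fl <- as.vector(fit$design$F %*% fit$state$lambda)
  f_eval <- ifelse(ro$group == 0, f0(ro$day), f1(ro$day))
  expect_equal(f_eval, Fl, tolerance = 1e-10)
})

test_that("prediction is additive in the random intercept", {
  sim <- simulate_dataset(sim_config(n_per_group = 2, sigma = 1,
                                     sigma_phi = 2, seed = 13))
  fit <- fit_smm(sim$data, default_dictionary(sim$data$data$day, 4, 2, 2, 2),
                 smm_control(gamma = 0.5))
  id <- names(fit$design$n_i)[1]
  t_eval <- c(7, 20, 44)
  diff <- predict(fit, t_eval, 0, mouse_id = id) - predict(fit, t_eval, 0)
  expect_equal(diff, rep(unname(fit$state$phi[1]), 3), tolerance = 1e-12)
  expect_error(predict(fit, 7, 0, mouse_id = "ghost"), "unknown mouse")
})

test_that("a fully penalized fit reduces to constants", {
  sim <- simulate_dataset(sim_config(n_per_group = 2, sigma = 1,
                                     sigma_phi = 1, seed = 17))
  fit <- fit_smm(sim$data, default_dictionary(sim$data$data$day, 4, 2, 2, 2),
                 smm_control(gamma = 1e8))
  expect_true(all(fit$state$lambda == 0))
  f0 <- estimate_f(fit, 0)
  expect_equal(f0(c(0, 10, 40)), rep(0, 3))
  b <- fit$state$beta
  expect_equal(predict(fit, 33, 1), unname(b[1] + b[2]), tolerance = 1e-12)
})

test_that("objective is zero at a perfect constant fit", {
  d <- toy_data(n_per_group = 2, days = c(0, 10, 20, 30),
                values = list(rep(2, 4), rep(2, 4), rep(2, 4), rep(2, 4)))
  fit <- fit_smm(d, default_dictionary(d$data$day, 0, 1, 1, 1),
                 smm_control(gamma = 1e6))
  expect_lt(objective_value(fit), 1e-10)
})

test_that("EM with frozen lambda maximizes the marginal likelihood", {
  # pure random-intercept data; huge gamma freezes lambda at zero
  cfg <- sim_config(n_per_group = 3,
                    f_templates = list(allograft = "zero", autograft = "zero"),
                    beta = c(10, 2), sigma = 1.5, sigma_phi = 2, seed = 23,
                    schedule = list(daily = 7:10, sparse = c(20, 30)))
  sim <- simulate_dataset(cfg)
  fit <- fit_smm(sim$data, default_dictionary(sim$data$data$day, 0, 1, 1, 0),
                 smm_control(gamma = 1e10, tol = 1e-12, max_iter = 5000))
  d <- sim$data$data
  oracle <- ml_oracle(d$value, cbind(1, d$group), d$mouse_id,
                      start = c(fit$state$sigma2, fit$state$sigma2_phi))
  expect_equal(fit$state$sigma2, oracle$sigma2, tolerance = 1e-4)
  expect_equal(fit$state$sigma2_phi, oracle$sigma2_phi, tolerance = 1e-4)
  expect_equal(unname(fit$state$beta), oracle$beta, tolerance = 1e-4)
})

test_that("larger gamma never increases the L1 norm of the coefficients", {
  sim <- simulate_dataset(sim_config(seed = 3, sigma = 2, sigma_phi = 2))
  dict <- default_dictionary(sim$data$data$day)
  l1 <- vapply(c(0.05, 0.5, 2), function(g) {
    sum(abs(fit_smm(sim$data, dict, smm_control(gamma = g))$state$lambda))
  }, numeric(1))
  expect_true(l1[3] <= l1[2] + 1e-10)
  expect_true(l1[2] <= l1[1] + 1e-10)
  expect_gt(l1[1], 0) # the weakly penalized fit is active
})

test_that("variances stay positive along the EM trace on noisy data", {
  sim <- simulate_dataset(sim_config(n_per_group = 3, sigma = 3,
                                     sigma_phi = 3, seed = 29))
  fit <- fit_smm(sim$data, default_dictionary(sim$data$data$day, 4, 2, 2, 2),
                 smm_control(gamma = 0.5))
  expect_true(all(fit$trace$sigma2 > 0))
  expect_true(all(fit$trace$sigma2_phi > 0))
  expect_true(fit$converged)
})

test_that("the KKT certificate holds at the converged fit", {
  sim <- simulate_dataset(sim_config(n_per_group = 3, sigma = 2,
                                     sigma_phi = 2, seed = 37))
  dict <- default_dictionary(sim$data$data$day)
  fit <- fit_smm(sim$data, dict, smm_control(gamma = 0.3, tol = 1e-10))
  st <- fit$state
  u <- fit$y - as.vector(fit$design$X %*% st$beta) -
    as.vector(fit$design$Z %*% st$phi)
  expect_lt(kkt_violation(st$lambda, u, fit$design, st$sigma2 * fit$weights),
            1e-6)
})

test_that("the literal-residual variant (no fixed-effect subtraction) differs as expected", {
  sim <- simulate_dataset(sim_config(n_per_group = 3, sigma = 2,
                                     sigma_phi = 2, seed = 41))
  dict <- default_dictionary(sim$data$data$day, 4, 2, 2, 2)
  fit_std <- fit_smm(sim$data, dict, smm_control(gamma = 0.5))
  fit_lit <- fit_smm(sim$data, dict,
                     smm_control(gamma = 0.5, subtract_beta = FALSE))
  # the literal variant leaves the fixed-effect mean in the E-step residual,
  # so the intercepts (and their variance) absorb the population level
  expect_gt(fit_lit$state$sigma2_phi, 100 * fit_std$state$sigma2_phi)
  expect_gt(mean(abs(fit_lit$state$phi)), mean(abs(fit_std$state$phi)))
})
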