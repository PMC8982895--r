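#' Control parameters for the penalized EM algorithm
#'
#' @param gamma nonnegative tuning parameter scaling the Lasso penalty;
#'   larger values give sparser coefficient vectors and smoother fitted
#'   trajectories. The analyses this package supports typically tune gamma
#'   on a grid in \[0, 2\]; 0.5 is a sensible middle value.
#' @param max_iter maximum number of EM iterations.
#' @param tol convergence threshold on the largest relative parameter change
#'   across (beta, lambda, sigma2, sigma2_phi) between consecutive
#'   iterations; per block the change is max|new - old| / (1 + max|old|).
#' @param lasso_tol inner coordinate-descent threshold on the largest
#'   coefficient change within one sweep.
#' @param lasso_max_sweeps iteration cap for the inner solver.
#' @param subtract_beta subtract the current fixed effects X beta from the
#'   residuals entering the E-step and the M-step (default TRUE, the
#'   standard EM for this model, so that sigma2 estimates residual rather
#'   than residual-plus-group-mean variance). FALSE gives the literal
#'   variant in which the E/M residuals are y - F lambda and
#'   y - Z phi - F lambda.
#' @param init_lambda optional warm start for the coefficient vector
#'   (length 2M), used by [gamma_sweep()].
#'
#' @return list of class `smm_control`.
#' @export
smm_control <- function(gamma = 0.5, max_iter = 500, tol = 1e-6,
                        lasso_tol = 1e-8, lasso_max_sweeps = 100000,
                        subtract_beta = TRUE, init_lambda = NULL) {
  stopifnot(gamma >= 0, max_iter >= 1, tol > 0, lasso_tol > 0)
  structure(list(gamma = gamma, max_iter = max_iter, tol = tol,
                 lasso_tol = lasso_tol, lasso_max_sweeps = lasso_max_sweeps,
                 subtract_beta = subtract_beta, init_lambda = init_lambda),
            class = "smm_control")
}

#' E-step: BLUP of the random intercepts
#'
#' With eta = sigma2 / sigma2_phi, the conditional variance of the intercept
#' of mouse i is W_i = sigma2 / (n_i + eta) and its conditional mean is
#' phi_i = (W_i / sigma2) * (sum of the residual over mouse i's rows),
#' i.e. the usual random-intercept BLUP
#' n_i sigma2_phi / (n_i sigma2_phi + sigma2) * (mouse-i residual mean).
#'
#' @param residual length-n residual vector (response minus current fixed
#'   and nonparametric parts).
#' @param sigma2 residual variance (> 0).
#' @param sigma2_phi random-intercept variance (>= 0); 0 gives the
#'   degenerate branch phi = 0, W = 0.
#' @param design design matrices from [build_design()].
#' @return list with `phi` and `W`, both length N.
#' @export
e_step <- function(residual, sigma2, sigma2_phi, design) {
  stopifnot(sigma2 > 0, sigma2_phi >= 0)
  n_i <- design$n_i
  if (sigma2_phi == 0) {
    z <- rep(0, length(n_i))
    names(z) <- names(n_i)
    return(list(phi = z, W = z))
  }
  eta <- sigma2 / sigma2_phi
  sums <- as.vector(crossprod(design$Z, residual))
  W <- sigma2 / (n_i + eta)
  phi <- sums / (n_i + eta)
  names(phi) <- names(n_i)
  names(W) <- names(n_i)
  list(phi = phi, W = W)
}

#' M-step: variance component updates
#'
#' sigma2_phi = (1/N) sum_i \[phi_i^2 + sigma2_prev / (n_i + eta_prev)\];
#' sigma2 = (1/n) \[sum_i ehat_i' ehat_i +
#'                  sum_i n_i sigma2_prev / (n_i + eta_prev)\].
#'
#' @param ehat length-n residual vector (response minus fixed part, minus
#'   Z phi, minus F lambda).
#' @param phi length-N random-intercept vector from the E-step.
#' @param sigma2_prev,eta_prev previous residual variance and ratio
#'   eta = sigma2 / sigma2_phi.
#' @param design design matrices from [build_design()].
#' @return list with `sigma2` and `sigma2_phi`.
#' @export
m_step <- function(ehat, phi, sigma2_prev, eta_prev, design) {
  stopifnot(sigma2_prev > 0, eta_prev >= 0)
  n_i <- design$n_i
  W_prev <- sigma2_prev / (n_i + eta_prev)
  sigma2_phi <- mean(phi^2 + W_prev)
  sigma2 <- (sum(ehat^2) + sum(n_i * W_prev)) / sum(n_i)
  list(sigma2 = sigma2, sigma2_phi = sigma2_phi)
}

#' Weighted-Lasso update of the basis coefficients
#'
#' Minimizes (1/n) ||u - F lambda||^2 + 2 sigma2 sum_k r_k |lambda_k| by
#' cyclic coordinate descent with soft-thresholding, warm-started from
#' `warm_start`. The returned solution satisfies the KKT stationarity
#' conditions: |F_k'(u - F lambda)| / n <= sigma2 r_k (+ tolerance) for
#' inactive coordinates, with equality at sign(lambda_k) for active ones.
#'
#' @param partial_residual length-n vector u (response minus fixed effects
#'   and random intercepts).
#' @param design design matrices from [build_design()].
#' @param weights penalty vector r of length 2M from [penalty_weights()].
#' @param sigma2 current residual variance.
#' @param warm_start starting coefficient vector (length 2M; default zeros).
#' @param tol,max_sweeps inner solver controls.
#' @return named numeric vector lambda of length 2M.
#' @export
lasso_update <- function(partial_residual, design, weights, sigma2,
                         warm_start = NULL, tol = 1e-8, max_sweeps = 100000) {
  p <- ncol(design$F)
  stopifnot(length(weights) == p)
  if (is.null(warm_start)) warm_start <- rep(0, p)
  fit <- cd_lasso(design$F, partial_residual, sigma2 * weights,
                  warm_start, tol, as.integer(max_sweeps))
  if (!fit$converged) {
    # Coefficient changes can stall on flat directions of collinear
    # designs; accept the iterate if it already satisfies stationarity.
    viol <- kkt_violation(fit$lambda, partial_residual, design,
                          sigma2 * weights)
    if (viol > 1e-6) {
      stop("inner Lasso solver did not converge in ", max_sweeps,
           " sweeps; max KKT violation ", format(viol))
    }
  }
  lambda <- as.numeric(fit$lambda)
  names(lambda) <- colnames(design$F)
  lambda
}

#' Largest KKT stationarity violation of a Lasso solution
#'
#' @param lambda coefficient vector (length 2M).
#' @param partial_residual the vector u the Lasso was fitted to.
#' @param design design matrices from [build_design()].
#' @param thresholds full per-coordinate thresholds sigma2 * r.
#' @return nonnegative scalar; 0 means the KKT conditions hold exactly.
#' @export
kkt_violation <- function(lambda, partial_residual, design, thresholds) {
  grad <- as.vector(crossprod(design$F, partial_residual -
                                design$F %*% lambda)) / nrow(design$F)
  active <- lambda != 0
  v_inactive <- if (any(!active)) {
    max(pmax(abs(grad[!active]) - thresholds[!active], 0))
  } else 0
  v_active <- if (any(active)) {
    max(abs(grad[active] - sign(lambda[active]) * thresholds[active]))
  } else 0
  max(v_inactive, v_active)
}

#' Least-squares update and inference for the fixed effects
#'
#' Solves X'X beta = X'(response - F lambda - Z phi) and reports classical
#' least-squares standard errors s^2 (X'X)^-1 with s^2 = RSS / (n - 2),
#' t statistics, and two-sided p-values on n - 2 degrees of freedom.
#'
#' @param response length-n response vector.
#' @param f_contrib length-n vector F lambda.
#' @param phi_expanded length-n vector Z phi.
#' @param design design matrices from [build_design()].
#' @return list with `beta` (named length-2) and `table` (data.frame term,
#'   estimate, std_error, t_value, p_value).
#' @export
ls_step <- function(response, f_contrib, phi_expanded, design) {
  X <- design$X
  if (length(unique(X[, 2])) < 2L) {
    stop("rank error: both groups must be present for the group contrast")
  }
  u <- response - f_contrib - phi_expanded
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, u))
  res <- u - X %*% beta
  n <- length(u)
  df <- n - 2L
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  est <- as.vector(beta)
  tval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf))
  pval <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  list(beta = stats::setNames(est, c("(Intercept)", "Group")),
       table = data.frame(term = c("(Intercept)", "Group"),
                          estimate = est, std_error = se,
                          t_value = tval, p_value = pval,
                          row.names = NULL),
       s2 = s2, df = df)
}

# Penalized objective monitored in the trace:
# (1/n)||y - X beta - F lambda - Z phi||^2 + 2 sigma2 sum r_k |lambda_k|.
penalized_objective <- function(y, design, beta, lambda, phi, sigma2,
                                weights) {
  res <- y - design$X %*% beta - design$F %*% lambda - design$Z %*% phi
  mean(res^2) + 2 * sigma2 * sum(weights * abs(lambda))
}

#' Penalized objective value of a fitted model
#'
#' (1/n)||y - X beta - F lambda - Z phi||^2 +
#' 2 sigma2 sum_k r_{n,k} |lambda_k|, evaluated at the fit's final state.
#'
#' @param fit an `smm_fit`.
#' @return scalar.
#' @export
objective_value <- function(fit) {
  stopifnot(inherits(fit, "smm_fit"))
  st <- fit$state
  penalized_objective(fit$y, fit$design, st$beta, st$lambda, st$phi,
                      st$sigma2, fit$weights)
}

# ANOVA-style initialization of the variance components. sigma2_phi starts
# at the between-mouse variance of the mouse means (centered within group);
# sigma2 starts at the residual variance of a two-way decomposition on
# mouse and (group, day) cells, so that the initial sigma2 is free of the
# time-effect variance. A pooled within-mouse variance would fold the time
# trend into sigma2 and, because the Lasso threshold scales with sigma2,
# could freeze the algorithm at the all-zero coefficient vector. Falls back
# to the pooled within-mouse variance when the two-way fit is saturated.
# Both components are floored to keep the E-step defined on degenerate data.
init_variances <- function(data) {
  idx <- mouse_index(data)
  y <- response_vector(data)
  g_mouse <- tapply(data$data$group, idx, `[`, 1)
  means <- tapply(y, idx, mean)
  centered <- means - tapply(means, g_mouse, mean)[as.character(g_mouse)]
  sigma2_phi <- if (data$N > 2) {
    sum(centered^2) / max(data$N - 2L, 1L)
  } else 0

  cell <- interaction(data$data$group, data$data$day, drop = TRUE)
  Xf <- stats::model.matrix(~ idx + cell)
  fit2 <- stats::lm.fit(Xf, y)
  dfree <- data$n - fit2$rank
  if (dfree >= 1L) {
    sigma2 <- sum(fit2$residuals^2) / dfree
  } else {
    within <- unlist(tapply(y, idx, function(v) v - mean(v)))
    sigma2 <- sum(within^2) / max(data$n - data$N, 1L)
  }
  list(sigma2 = max(sigma2, 1e-8), sigma2_phi = max(sigma2_phi, 1e-8))
}

rel_change <- function(new, old) {
  max(abs(new - old)) / (1 + max(abs(old)))
}

#' Fit the semiparametric mixed-effects model
#'
#' Fits y_ij = beta0 + beta1 g_i + f_{g_i}(t_ij) + phi_i + eps_ij, with
#' phi_i ~ N(0, sigma2_phi), eps_ij ~ N(0, sigma2) and f_g a sparse
#' combination of dictionary functions, by a penalized EM algorithm. Each
#' iteration runs, in order: (1) E-step on y - X beta - F lambda giving the
#' intercept BLUPs; (2) M-step on y - X beta - Z phi - F lambda updating
#' the variances; (3) weighted-Lasso update of lambda on
#' y - X beta - Z phi at the new sigma2; (4) least-squares update of beta
#' with t-based inference. Iteration stops when the largest relative
#' parameter change is below `tol` or `max_iter` is reached.
#'
#' Initialization: beta0 = grand mean, beta1 = 0, lambda = 0, phi = 0, and
#' an ANOVA-style split of the total variance. With gamma = 0 the model is
#' not identified (unpenalized f_g absorbs the group contrast) and the fit
#' is flagged accordingly.
#'
#' @param data a `longidata` object with both groups present.
#' @param dict a `basis_dictionary`; default built from the observed days.
#' @param control an [smm_control()] list.
#' @return An object of class `smm_fit`: list with `state` (beta, lambda,
#'   phi, sigma2, sigma2_phi, eta, W, iter), `fixed_effects` table,
#'   `dictionary`, `design`, `weights`, `converged`, `trace`, `gamma`,
#'   `response`, `y`, `identified`.
#' @export
fit_smm <- function(data, dict = NULL, control = smm_control()) {
  stopifnot(inherits(data, "longidata"), inherits(control, "smm_control"))
  if (is.null(dict)) dict <- default_dictionary(data$data$day)
  design <- build_design(dict, data)
  y <- response_vector(data)
  n <- data$n
  weights <- penalty_weights(dict, data, control$gamma)

  beta <- c(mean(y), 0)
  lambda <- if (!is.null(control$init_lambda)) {
    stopifnot(length(control$init_lambda) == 2 * dict$M)
    as.numeric(control$init_lambda)
  } else rep(0, 2 * dict$M)
  phi <- rep(0, data$N)
  v0 <- init_variances(data)
  sigma2 <- v0$sigma2
  sigma2_phi <- v0$sigma2_phi
  W <- rep(0, data$N)
  ls <- NULL

  # Warm-up pass for lambda at the initial variance estimates. Entering the
  # loop with lambda = 0 would make the first M-step fold the whole
  # unexplained time effect into sigma2, and because the Lasso threshold
  # scales with sigma2 this can make the all-zero coefficient vector an
  # absorbing state. One solve at the ANOVA-initialized sigma2 gives the
  # M-step a residual with the time trend already removed.
  if (is.null(control$init_lambda)) {
    lambda <- lasso_update(y - as.vector(design$X %*% beta), design, weights,
                           sigma2, warm_start = lambda,
                           tol = control$lasso_tol,
                           max_sweeps = control$lasso_max_sweeps)
  }
  # Complete the initialization with one least-squares pass so that the
  # first E-step residual is free of the fixed effects and of the warm-up
  # time effect; otherwise the intercept BLUPs absorb the group contrast
  # (unshrunk when sigma2 is small relative to sigma2_phi) and a degenerate
  # allocation can persist.
  beta <- unname(ls_step(y, as.vector(design$F %*% lambda), 0, design)$beta)

  trace <- vector("list", control$max_iter)
  converged <- FALSE
  last_change <- NA_real_

  for (h in seq_len(control$max_iter)) {
    beta_old <- beta; lambda_old <- lambda
    sigma2_old <- sigma2; sigma2_phi_old <- sigma2_phi

    Xb <- as.vector(design$X %*% beta)
    Fl <- as.vector(design$F %*% lambda)
    fixed_part <- if (control$subtract_beta) Xb else 0

    es <- e_step(y - fixed_part - Fl, sigma2, sigma2_phi, design)
    phi <- es$phi; W <- es$W
    Zphi <- as.vector(design$Z %*% phi)

    eta_prev <- if (sigma2_phi > 0) sigma2 / sigma2_phi else Inf
    ehat <- y - fixed_part - Zphi - Fl
    ms <- m_step(ehat, phi, sigma2, eta_prev, design)
    sigma2 <- max(ms$sigma2, 1e-12)
    if (ms$sigma2_phi < 1e-12) {
      warning("sigma2_phi collapsed below 1e-12; floored")
      sigma2_phi <- 1e-12
    } else sigma2_phi <- ms$sigma2_phi

    lambda <- lasso_update(y - Xb - Zphi, design, weights, sigma2,
                           warm_start = lambda, tol = control$lasso_tol,
                           max_sweeps = control$lasso_max_sweeps)
    Fl <- as.vector(design$F %*% lambda)

    ls <- ls_step(y, Fl, Zphi, design)
    beta <- unname(ls$beta)

    if (!all(is.finite(c(beta, lambda, sigma2, sigma2_phi)))) {
      cond <- simpleError("divergence: non-finite values during EM iteration")
      cond$trace <- do.call(rbind, trace[seq_len(h - 1)])
      stop(cond)
    }

    last_change <- max(rel_change(beta, beta_old),
                       rel_change(lambda, lambda_old),
                       rel_change(sigma2, sigma2_old),
                       rel_change(sigma2_phi, sigma2_phi_old))
    trace[[h]] <- data.frame(
      iter = h,
      objective = penalized_objective(y, design, beta, lambda, phi,
                                      sigma2, weights),
      max_rel_change = last_change,
      sigma2 = sigma2, sigma2_phi = sigma2_phi,
      beta1 = beta[2], active_set = sum(lambda != 0))
    if (last_change <= control$tol) { converged <- TRUE; break }
  }

  iters <- sum(!vapply(trace, is.null, logical(1)))
  structure(
    list(state = list(beta = stats::setNames(beta, c("(Intercept)", "Group")),
                      lambda = lambda, phi = phi,
                      sigma2 = sigma2, sigma2_phi = sigma2_phi,
                      eta = sigma2 / sigma2_phi, W = W, iter = iters),
         fixed_effects = ls$table, dictionary = dict, design = design,
         weights = weights, converged = converged,
         trace = do.call(rbind, trace[seq_len(iters)]),
         gamma = control$gamma, control = control,
         response = data$response, y = y,
         identified = control$gamma > 0),
    class = "smm_fit")
}

#' @export
print.smm_fit <- function(x, ...) {
  cat("Semiparametric mixed-effects model (gamma =", x$gamma, ")\n")
  cat("  response:", x$response, " n =", length(x$y),
      " mice =", length(x$state$phi), "\n")
  cat("  ", if (x$converged) "converged" else "NOT converged",
      "after", x$state$iter, "EM iterations\n")
  if (!x$identified) {
    cat("  NOTE: gamma = 0 fit; the group effect is not identified\n")
  }
  cat("  sigma2 =", format(x$state$sigma2, digits = 4),
      " sigma2_phi =", format(x$state$sigma2_phi, digits = 4),
      " active basis coefficients:", sum(x$state$lambda != 0), "\n\n")
  print(x$fixed_effects, row.names = FALSE)
  invisible(x)
}

#' Fixed-effects table of a fitted model
#'
#' @param fit an `smm_fit` or `lmm_fit`.
#' @return data.frame with columns term, estimate, std_error, t_value,
#'   p_value.
#' @export
fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "smm_fit") || inherits(fit, "lmm_fit"))
  fit$fixed_effects
}

#' Reconstruct the estimated group time-effect function
#'
#' Returns f_hat_g(t) = sum_k lambda\[block g, k\] psi_k(t), evaluated
#' through the dictionary's stored rescaling.
#'
#' @param fit an `smm_fit`.
#' @param group 0 (allograft) or 1 (autograft).
#' @return a function of days.
#' @export
estimate_f <- function(fit, group) {
  stopifnot(inherits(fit, "smm_fit"), group %in% c(0, 1))
  M <- fit$dictionary$M
  block <- if (group == 0) seq_len(M) else M + seq_len(M)
  lam <- fit$state$lambda[block]
  dict <- fit$dictionary
  function(t) as.vector(eval_dictionary(dict, t) %*% lam)
}

#' Predict from a fitted semiparametric mixed model
#'
#' Population prediction beta0 + beta1 g + f_hat_g(t); when `mouse_id` is
#' given, the subject-level prediction adds that mouse's estimated random
#' intercept.
#'
#' @param object an `smm_fit`.
#' @param t days at which to predict.
#' @param group 0 or 1.
#' @param mouse_id optional id of a training-set mouse.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.smm_fit <- function(object, t, group, mouse_id = NULL, ...) {
  stopifnot(group %in% c(0, 1))
  f <- estimate_f(object, group)
  out <- object$state$beta[1] + object$state$beta[2] * group + f(t)
  if (!is.null(mouse_id)) {
    ids <- names(object$design$n_i)
    if (!mouse_id %in% ids) stop("unknown mouse_id: ", mouse_id)
    out <- out + object$state$phi[match(mouse_id, ids)]
  }
  unname(out)
}

#' Fitted population trajectories on a dense grid
#'
#' @param fit an `smm_fit` or `lmm_fit`.
#' @param days grid of days; default 200 points over the training range.
#' @return data.frame with columns group, day, fitted.
#' @export
fitted_trajectories <- function(fit, days = NULL) {
  if (is.null(days)) {
    rng <- range(fit$design$row_order$day)
    days <- seq(rng[1], rng[2], length.out = 200)
  }
  do.call(rbind, lapply(c(0, 1), function(g) {
    data.frame(group = g, day = days,
               fitted = predict(fit, days, group = g))
  }))
}

# In-sample RMSE against the full fitted values (fixed + nonparametric +
# random intercept).
insample_rmse <- function(fit) {
  st <- fit$state
  fitted <- as.vector(fit$design$X %*% st$beta) +
    as.vector(fit$design$F %*% st$lambda) +
    as.vector(fit$design$Z %*% st$phi)
  sqrt(mean((fit$y - fitted)^2))
}
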