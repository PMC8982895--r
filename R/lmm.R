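#' Fit the linear mixed-model baseline
#'
#' The parametric comparison model
#' y_ij = beta0 + beta1 g_i + beta2 t_ij + beta3 t_ij g_i + phi_i + eps_ij
#' with a mouse-level random intercept, fit by the same EM machinery as the
#' semiparametric model but with the fixed 4-column design (1, g, t, t*g)
#' and no penalty: E-step BLUP of phi on y - X beta, M-step variance
#' updates, ordinary least squares for beta on y - Z phi. Inference uses
#' classical least-squares standard errors with n - 4 degrees of freedom.
#'
#' @param data a `longidata` object with both groups present and at least
#'   two distinct days.
#' @param control an [smm_control()] list (gamma is ignored).
#' @return An object of class `lmm_fit`: list with `state` (beta, phi,
#'   sigma2, sigma2_phi, W, iter), `fixed_effects`, `design`, `converged`,
#'   `trace`, `response`, `y`.
#' @export
fit_lmm <- function(data, control = smm_control()) {
  stopifnot(inherits(data, "longidata"), inherits(control, "smm_control"))
  df <- data$data
  if (length(unique(df$group)) < 2L) {
    stop("rank error: both groups must be present")
  }
  if (length(unique(df$day)) < 2L) {
    stop("rank error: at least two distinct days are required")
  }
  X <- cbind(`(Intercept)` = 1, Group = df$group, Day = df$day,
             `Group:Day` = df$group * df$day)
  idx <- mouse_index(data)
  n <- data$n
  Z <- matrix(0, n, data$N, dimnames = list(NULL, levels(idx)))
  Z[cbind(seq_len(n), as.integer(idx))] <- 1
  design <- list(Z = Z, n_i = data$n_i, X = X,
                 row_order = df[, c("mouse_id", "group", "day")])
  y <- response_vector(data)

  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) stop("rank error: collinear fixed-effects design")

  beta <- as.vector(solve(XtX, crossprod(X, y)))
  phi <- rep(0, data$N)
  v0 <- init_variances(data)
  sigma2 <- v0$sigma2
  sigma2_phi <- v0$sigma2_phi
  W <- rep(0, data$N)

  trace <- vector("list", control$max_iter)
  converged <- FALSE

  for (h in seq_len(control$max_iter)) {
    beta_old <- beta; sigma2_old <- sigma2; sigma2_phi_old <- sigma2_phi

    Xb <- as.vector(X %*% beta)
    fixed_part <- if (control$subtract_beta) Xb else 0
    es <- e_step(y - fixed_part, sigma2, sigma2_phi, design)
    phi <- es$phi; W <- es$W
    Zphi <- as.vector(Z %*% phi)

    eta_prev <- if (sigma2_phi > 0) sigma2 / sigma2_phi else Inf
    ms <- m_step(y - fixed_part - Zphi, phi, sigma2, eta_prev, design)
    sigma2 <- max(ms$sigma2, 1e-12)
    sigma2_phi <- max(ms$sigma2_phi, 1e-12)

    beta <- as.vector(solve(XtX, crossprod(X, y - Zphi)))

    if (!all(is.finite(c(beta, sigma2, sigma2_phi)))) {
      stop("divergence: non-finite values during EM iteration")
    }
    change <- max(rel_change(beta, beta_old),
                  rel_change(sigma2, sigma2_old),
                  rel_change(sigma2_phi, sigma2_phi_old))
    trace[[h]] <- data.frame(iter = h, max_rel_change = change,
                             sigma2 = sigma2, sigma2_phi = sigma2_phi,
                             beta1 = beta[2])
    if (change <= control$tol) { converged <- TRUE; break }
  }

  res <- y - as.vector(X %*% beta) - as.vector(Z %*% phi)
  dfree <- n - 4L
  s2 <- sum(res^2) / dfree
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = dfree, lower.tail = FALSE)
  terms <- colnames(X)

  iters <- sum(!vapply(trace, is.null, logical(1)))
  structure(
    list(state = list(beta = stats::setNames(beta, terms), phi = phi,
                      sigma2 = sigma2, sigma2_phi = sigma2_phi, W = W,
                      iter = iters),
         fixed_effects = data.frame(term = terms, estimate = beta,
                                    std_error = se, t_value = tval,
                                    p_value = pval, row.names = NULL),
         design = design, converged = converged,
         trace = do.call(rbind, trace[seq_len(iters)]),
         response = data$response, y = y),
    class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (random intercept, group-by-day interaction)\n")
  cat("  response:", x$response, " n =", length(x$y),
      " mice =", length(x$state$phi), "\n")
  cat("  ", if (x$converged) "converged" else "NOT converged",
      "after", x$state$iter, "EM iterations\n")
  cat("  sigma2 =", format(x$state$sigma2, digits = 4),
      " sigma2_phi =", format(x$state$sigma2_phi, digits = 4), "\n\n")
  print(x$fixed_effects, row.names = FALSE)
  invisible(x)
}

#' @rdname predict.smm_fit
#' @export
predict.lmm_fit <- function(object, t, group, mouse_id = NULL, ...) {
  stopifnot(group %in% c(0, 1))
  b <- object$state$beta
  out <- b[1] + b[2] * group + b[3] * t + b[4] * t * group
  if (!is.null(mouse_id)) {
    ids <- names(object$design$n_i)
    if (!mouse_id %in% ids) stop("unknown mouse_id: ", mouse_id)
    out <- out + object$state$phi[match(mouse_id, ids)]
  }
  unname(out)
}

lmm_insample_rmse <- function(fit) {
  st <- fit$state
  fitted <- as.vector(fit$design$X %*% st$beta) +
    as.vector(fit$design$Z %*% st$phi)
  sqrt(mean((fit$y - fitted)^2))
}

#' Compare a semiparametric and a linear mixed-model fit
#'
#' Tabulates group-effect estimates and standard errors, residual and
#' intercept variances, and in-sample RMSE for both models fitted to the
#' same dataset.
#'
#' @param smm an `smm_fit`.
#' @param lmm an `lmm_fit`.
#' @return data.frame with one row per model.
#' @export
compare_fits <- function(smm, lmm) {
  stopifnot(inherits(smm, "smm_fit"), inherits(lmm, "lmm_fit"))
  if (length(smm$y) != length(lmm$y) ||
      max(abs(smm$y - lmm$y)) > 0 ||
      !identical(names(smm$design$n_i), names(lmm$design$n_i))) {
    stop("consistency error: the two fits use different datasets")
  }
  smm_tab <- smm$fixed_effects
  lmm_tab <- lmm$fixed_effects
  data.frame(
    model = c("SMM", "LMM"),
    group_estimate = c(smm_tab$estimate[smm_tab$term == "Group"],
                       lmm_tab$estimate[lmm_tab$term == "Group"]),
    group_se = c(smm_tab$std_error[smm_tab$term == "Group"],
                 lmm_tab$std_error[lmm_tab$term == "Group"]),
    sigma2 = c(smm$state$sigma2, lmm$state$sigma2),
    sigma2_phi = c(smm$state$sigma2_phi, lmm$state$sigma2_phi),
    rmse = c(insample_rmse(smm), lmm_insample_rmse(lmm))
  )
}
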