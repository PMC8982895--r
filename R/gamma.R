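#' Sweep the tuning parameter gamma
#'
#' Fits the semiparametric model at each value of a gamma grid, warm-starting
#' the coefficient vector from the previous grid point, and records the
#' group-effect estimate, its standard error, t statistic and p-value, a
#' significance flag at `alpha`, the active-set size, and the in-sample
#' RMSE. Failed fits are marked and the sweep continues.
#'
#' @param data a `longidata` object.
#' @param dict a `basis_dictionary`; default built from the observed days.
#' @param grid increasing nonnegative gamma values (default 0 to 2 by 0.05).
#' @param control an [smm_control()] list; its gamma is ignored.
#' @param alpha significance level for the flag (default 0.05).
#' @param warm_start warm-start each fit's lambda from the previous grid
#'   point (default TRUE).
#' @return An object of class `gamma_sweep`: list with `records`
#'   (data.frame gamma, beta1, se, t, p, significant, active_set, rmse, df,
#'   converged, failed), `alpha`, `response`.
#' @export
gamma_sweep <- function(data, dict = NULL, grid = seq(0, 2, by = 0.05),
                        control = smm_control(), alpha = 0.05,
                        warm_start = TRUE) {
  stopifnot(length(grid) >= 1, all(grid >= 0), !is.unsorted(grid, strictly = TRUE))
  if (is.null(dict)) dict <- default_dictionary(data$data$day)

  records <- vector("list", length(grid))
  lam_prev <- NULL
  for (i in seq_along(grid)) {
    ctl <- control
    ctl$gamma <- grid[i]
    ctl$init_lambda <- if (warm_start) lam_prev else NULL
    rec <- tryCatch({
      fit <- fit_smm(data, dict, ctl)
      lam_prev <- fit$state$lambda
      tab <- fit$fixed_effects
      g <- tab[tab$term == "Group", ]
      data.frame(gamma = grid[i], beta1 = g$estimate, se = g$std_error,
                 t = g$t_value, p = g$p_value,
                 significant = g$p_value < alpha,
                 active_set = sum(fit$state$lambda != 0),
                 rmse = insample_rmse(fit), df = length(fit$y) - 2L,
                 converged = fit$converged, failed = FALSE,
                 message = "")
    }, error = function(e) {
      data.frame(gamma = grid[i], beta1 = NA_real_, se = NA_real_,
                 t = NA_real_, p = NA_real_, significant = NA,
                 active_set = NA_integer_, rmse = NA_real_, df = NA_integer_,
                 converged = FALSE, failed = TRUE,
                 message = conditionMessage(e))
    })
    records[[i]] <- rec
  }
  structure(list(records = do.call(rbind, records), alpha = alpha,
                 response = data$response),
            class = "gamma_sweep")
}

#' @export
print.gamma_sweep <- function(x, ...) {
  r <- x$records
  cat("Gamma sweep on", x$response, ":", nrow(r), "grid points in [",
      min(r$gamma), ",", max(r$gamma), "]\n")
  cat("  failed fits:", sum(r$failed), "\n")
  ok <- r[!r$failed, ]
  cat("  group effect range: [", format(min(ok$beta1), digits = 4), ",",
      format(max(ok$beta1), digits = 4), "]  significant at",
      x$alpha, ":", sum(ok$significant), "/", nrow(ok), "\n")
  invisible(x)
}

#' Smoothness/fit trade-off report for a gamma sweep
#'
#' Tabulates active-set size and in-sample RMSE against gamma, flags the
#' grid endpoints (gamma = 0 saturates the data; the largest gamma is the
#' smoothest fit) and marks the conventional default gamma = 0.5 when it is
#' on the grid.
#'
#' @param sweep a `gamma_sweep`.
#' @param default_gamma value to mark (default 0.5).
#' @return data.frame with one row per successful grid point: gamma,
#'   active_set, rmse, endpoint ("overfit" / "oversmoothed" / ""),
#'   is_default.
#' @export
smoothness_report <- function(sweep, default_gamma = 0.5) {
  stopifnot(inherits(sweep, "gamma_sweep"))
  ok <- sweep$records[!sweep$records$failed, ]
  if (nrow(ok) < 2L) stop("need at least 2 successful fits")
  data.frame(
    gamma = ok$gamma,
    active_set = ok$active_set,
    rmse = ok$rmse,
    endpoint = ifelse(ok$gamma == min(ok$gamma), "overfit",
                      ifelse(ok$gamma == max(ok$gamma), "oversmoothed", "")),
    is_default = ok$gamma == default_gamma
  )
}

#' Significance boundary for the group effect across gamma
#'
#' For each grid point, the critical magnitude t_{1 - alpha/2, df} * SE(gamma)
#' that the group-effect estimate must exceed to be significant at `alpha`;
#' mirrors the horizontal-line annotation of coefficient-versus-gamma plots.
#'
#' @param sweep a `gamma_sweep`.
#' @param alpha significance level (default the sweep's alpha).
#' @return data.frame gamma, critical, significant.
#' @export
significance_boundary <- function(sweep, alpha = NULL) {
  stopifnot(inherits(sweep, "gamma_sweep"))
  if (is.null(alpha)) alpha <- sweep$alpha
  ok <- sweep$records[!sweep$records$failed, ]
  critical <- stats::qt(1 - alpha / 2, df = ok$df) * ok$se
  data.frame(gamma = ok$gamma, critical = critical,
             significant = abs(ok$beta1) > critical)
}

#' Plot the group-effect estimate against gamma
#'
#' @param sweep a `gamma_sweep`.
#' @param boundary add the significance-boundary curve (default TRUE).
#' @return a ggplot object.
#' @export
plot_gamma_sweep <- function(sweep, boundary = TRUE) {
  ok <- sweep$records[!sweep$records$failed, ]
  p <- ggplot2::ggplot(ok, ggplot2::aes(x = gamma, y = beta1)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(gamma), y = "group effect estimate",
                  title = paste("Group effect vs. gamma:", sweep$response))
  if (boundary) {
    b <- significance_boundary(sweep)
    p <- p + ggplot2::geom_line(data = b,
                                ggplot2::aes(x = gamma,
                                             y = critical),
                                colour = "red", linetype = 2)
  }
  p
}

#' Plot fitted population trajectories over the observations
#'
#' @param fit an `smm_fit` or `lmm_fit`.
#' @param data the `longidata` the model was fitted to.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(fit, data) {
  traj <- fitted_trajectories(fit)
  traj$group <- factor(traj$group, levels = c(0, 1),
                       labels = c("allograft", "autograft"))
  obs <- data$data
  obs$group <- factor(obs$group, levels = c(0, 1),
                      labels = c("allograft", "autograft"))
  ggplot2::ggplot() +
    ggplot2::geom_line(data = obs,
                       ggplot2::aes(x = day, y = value,
                                    group = mouse_id),
                       colour = "grey60", linetype = 2) +
    ggplot2::geom_line(data = traj,
                       ggplot2::aes(x = day, y = fitted),
                       colour = "red", linewidth = 1) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "day", y = data$response)
}
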