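#' Dictionary of candidate basis functions
#'
#' The nonparametric time effect of each group is represented as a sparse
#' linear combination of a dictionary \{psi_1, ..., psi_M\} of candidate
#' functions: cubic B-splines, Fourier pairs, power functions and Haar step
#' functions. Observed days are affinely rescaled to \[0, 1\] before
#' evaluation (numerical conditioning of the power and Fourier families);
#' the rescaling is stored with the dictionary and applied consistently at
#' prediction time. The constant function is deliberately excluded: it is
#' exactly confounded with the model intercept.
#'
#' @param times numeric vector of observed days (at least 4 distinct values).
#' @param n_knots number of interior B-spline knots, placed at empirical
#'   quantiles of `times` (0 disables the family). Cubic B-splines with k
#'   interior knots contribute k + 4 functions.
#' @param n_fourier number of Fourier pairs sin(2*pi*j*s), cos(2*pi*j*s),
#'   j = 1..n_fourier, on the rescaled argument s.
#' @param n_powers number of power functions s, s^2, ..., s^n_powers.
#' @param haar_levels number of dyadic Haar levels; level l contributes the
#'   2^l indicators of the dyadic intervals of width 2^-l.
#'
#' @return An object of class `basis_dictionary`: list with `functions`
#'   (each a list with `kind`, `params`, `label`, `fun` acting on the
#'   rescaled argument), `M`, `t_min`, `t_max`.
#' @export
default_dictionary <- function(times, n_knots = 8, n_fourier = 4,
                               n_powers = 2, haar_levels = 3) {
  times <- as.numeric(times)
  if (length(unique(times)) < 4L) {
    stop("insufficient support: need at least 4 distinct times")
  }
  t_min <- min(times)
  t_max <- max(times)
  s_obs <- (times - t_min) / (t_max - t_min)

  funs <- list()

  if (n_knots > 0) {
    interior <- unname(stats::quantile(s_obs, probs = seq_len(n_knots) /
                                         (n_knots + 1)))
    knots <- c(rep(0, 4), interior, rep(1, 4))
    n_b <- n_knots + 4L
    for (j in seq_len(n_b)) {
      funs[[length(funs) + 1L]] <- list(
        kind = "cubic_spline", params = list(knots = knots, index = j),
        label = sprintf("bspline_%d", j),
        fun = local({
          j0 <- j; k0 <- knots
          function(s) {
            sc <- pmin(pmax(s, 0), 1)
            splines::splineDesign(k0, sc, ord = 4, outer.ok = TRUE)[, j0]
          }
        })
      )
    }
  }
  if (n_fourier > 0) {
    for (j in seq_len(n_fourier)) {
      funs[[length(funs) + 1L]] <- list(
        kind = "fourier_sin", params = list(frequency = j),
        label = sprintf("fourier_sin_%d", j),
        fun = local({ j0 <- j; function(s) sin(2 * pi * j0 * s) })
      )
      funs[[length(funs) + 1L]] <- list(
        kind = "fourier_cos", params = list(frequency = j),
        label = sprintf("fourier_cos_%d", j),
        fun = local({ j0 <- j; function(s) cos(2 * pi * j0 * s) })
      )
    }
  }
  if (n_powers > 0) {
    for (p in seq_len(n_powers)) {
      funs[[length(funs) + 1L]] <- list(
        kind = "power", params = list(exponent = p),
        label = sprintf("power_%d", p),
        fun = local({ p0 <- p; function(s) s^p0 })
      )
    }
  }
  if (haar_levels > 0) {
    for (l in seq_len(haar_levels)) {
      for (m in seq_len(2^l)) {
        funs[[length(funs) + 1L]] <- list(
          kind = "haar", params = list(level = l, shift = m),
          label = sprintf("haar_L%d_%d", l, m),
          fun = local({
            lo <- (m - 1) / 2^l; hi <- m / 2^l; last <- (m == 2^l)
            function(s) as.numeric(s >= lo & (s < hi | (last & s <= hi)))
          })
        )
      }
    }
  }
  if (length(funs) == 0L) stop("dictionary is empty: enable at least one family")
  labels <- vapply(funs, `[[`, character(1), "label")
  stopifnot(!anyDuplicated(labels))

  structure(list(functions = funs, M = length(funs),
                 t_min = t_min, t_max = t_max),
            class = "basis_dictionary")
}

#' @export
print.basis_dictionary <- function(x, ...) {
  kinds <- table(vapply(x$functions, `[[`, character(1), "kind"))
  cat("Basis dictionary: M =", x$M, "functions on days [",
      x$t_min, ",", x$t_max, "]\n")
  for (k in names(kinds)) cat("  ", k, ": ", kinds[[k]], "\n", sep = "")
  invisible(x)
}

#' @export
labels.basis_dictionary <- function(object, ...) {
  vapply(object$functions, `[[`, character(1), "label")
}

#' Restrict a dictionary to a subset of its functions
#'
#' Useful for nesting checks (e.g. a dictionary holding only the linear
#' function reproduces the linear mixed model) and for saturating designs
#' built from a single Haar level.
#'
#' @param dict a `basis_dictionary`.
#' @param which integer indices or labels of the functions to keep.
#' @return a `basis_dictionary` with the selected functions.
#' @export
subset_dictionary <- function(dict, which) {
  stopifnot(inherits(dict, "basis_dictionary"))
  if (is.character(which)) {
    which <- match(which, labels.basis_dictionary(dict))
    if (anyNA(which)) stop("unknown basis labels")
  }
  funs <- dict$functions[which]
  if (length(funs) == 0L) stop("dictionary is empty after subsetting")
  structure(list(functions = funs, M = length(funs),
                 t_min = dict$t_min, t_max = dict$t_max),
            class = "basis_dictionary")
}

#' Evaluate a dictionary at arbitrary days
#'
#' @param dict a `basis_dictionary`.
#' @param days numeric vector of days (original scale).
#' @param warn warn when `days` fall outside the dictionary's time range
#'   (values are still computed, with the rescaled argument clamped by the
#'   spline family and extrapolated by the analytic families).
#' @return numeric matrix, length(days) x M, columns labelled.
#' @export
eval_dictionary <- function(dict, days, warn = TRUE) {
  stopifnot(inherits(dict, "basis_dictionary"))
  if (warn && (any(days < dict$t_min) || any(days > dict$t_max))) {
    warning("evaluating dictionary outside its time range [",
            dict$t_min, ", ", dict$t_max, "]")
  }
  s <- (days - dict$t_min) / (dict$t_max - dict$t_min)
  out <- vapply(dict$functions, function(f) f$fun(s),
                numeric(length(days)))
  out <- matrix(out, nrow = length(days), ncol = dict$M)
  colnames(out) <- labels.basis_dictionary(dict)
  out
}

#' Empirical norms of the dictionary functions
#'
#' Computes ||psi_k||_n = sqrt((1/n) sum_i sum_j psi_k(t_ij)^2), summing
#' over all observations of all mice regardless of group.
#'
#' @param dict a `basis_dictionary`.
#' @param data a `longidata` object.
#' @param which optional integer or character selection of functions.
#' @return named numeric vector of norms.
#' @export
empirical_norm <- function(dict, data, which = NULL) {
  stopifnot(inherits(data, "longidata"))
  Psi <- eval_dictionary(dict, data$data$day, warn = FALSE)
  norms <- sqrt(colMeans(Psi^2))
  if (!is.null(which)) norms <- norms[which]
  norms
}

#' Penalty weights for the weighted Lasso
#'
#' The per-coefficient penalty is r_{n,k} = ||psi_k||_n * gamma *
#' sqrt(log(2M)/n); the two blocks (allograft, autograft) share the norm of
#' the underlying function, so the returned vector of length 2M repeats the
#' M norms.
#'
#' @param dict a `basis_dictionary`.
#' @param data a `longidata` object.
#' @param gamma nonnegative tuning parameter; larger values shrink more
#'   coefficients to zero, giving smoother fitted trajectories.
#' @return numeric vector of length 2M.
#' @export
penalty_weights <- function(dict, data, gamma) {
  stopifnot(gamma >= 0)
  norms <- empirical_norm(dict, data)
  rep(norms, 2) * gamma * sqrt(log(2 * dict$M) / data$n)
}

#' Build the estimator's design matrices
#'
#' Constructs the block design F = diag(F0, F1) (n x 2M; rows of allograft
#' mice carry the basis values in columns 1..M and zeros in columns
#' M+1..2M, and symmetrically for autograft rows), the observation-to-mouse
#' incidence Z (n x N), and the fixed-effects design X = (1, g).
#'
#' @param dict a `basis_dictionary`.
#' @param data a `longidata` object.
#' @return list with `F`, `Z`, `X`, `row_order` (data.frame mouse_id, group,
#'   day), `n_i`, `M`.
#' @export
build_design <- function(dict, data) {
  stopifnot(inherits(data, "longidata"))
  df <- data$data
  Psi <- eval_dictionary(dict, df$day)
  n <- data$n
  M <- dict$M

  Fm <- matrix(0, n, 2 * M)
  g0 <- df$group == 0
  Fm[g0, seq_len(M)] <- Psi[g0, , drop = FALSE]
  Fm[!g0, M + seq_len(M)] <- Psi[!g0, , drop = FALSE]
  colnames(Fm) <- c(paste0("allo:", colnames(Psi)),
                    paste0("auto:", colnames(Psi)))

  idx <- mouse_index(data)
  Z <- matrix(0, n, data$N, dimnames = list(NULL, levels(idx)))
  Z[cbind(seq_len(n), as.integer(idx))] <- 1

  X <- cbind(`(Intercept)` = 1, Group = df$group)

  list(F = Fm, Z = Z, X = X,
       row_order = df[, c("mouse_id", "group", "day")],
       n_i = data$n_i, M = M)
}
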