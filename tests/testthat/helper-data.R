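# Small fixtures built in code.

# A longidata object from explicit vectors.
make_data <- function(mouse_id, group, day, value, response = "THC") {
  longitudinal_data(
    data.frame(mouse_id = mouse_id, group = group, day = day, value = value),
    response_name = response
  )
}

# Balanced two-group toy: n_days per mouse on an integer grid, deterministic
# values unless supplied.
toy_data <- function(n_per_group = 2, days = c(-1, 7, 10, 14, 21),
                     values = NULL, response = "THC") {
  ids <- c(paste0("a", seq_len(n_per_group)), paste0("b", seq_len(n_per_group)))
  grp <- rep(c(0, 1), each = n_per_group)
  df <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(mouse_id = ids[i], group = grp[i], day = days,
               value = if (is.null(values)) 100 + grp[i] * 5 + seq_along(days)
                       else values[[i]])
  }))
  longitudinal_data(df, response_name = response)
}

# Write a CSV fixture into a temp file and return its path.
write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Direct numerical maximizer of the Gaussian marginal likelihood of the
# random-intercept model y = X beta + Z phi + eps (phi ~ N(0, s2p),
# eps ~ N(0, s2)), profiling beta by GLS; the independent oracle for the
# EM fixed point.
ml_oracle <- function(y, X, mouse, start = c(1, 1)) {
  mouse <- as.factor(mouse)
  Z <- stats::model.matrix(~ mouse - 1)
  negll <- function(par) {
    s2 <- exp(par[1]); s2p <- exp(par[2])
    V <- s2 * diag(length(y)) + s2p * tcrossprod(Z)
    cV <- chol(V)
    Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
    Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
    beta <- solve(crossprod(X, Vi_X), crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
    as.numeric(sum(log(diag(cV))) + 0.5 * crossprod(r, Vi_r))
  }
  opt <- stats::optim(log(start), negll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  s2 <- exp(opt$par[1]); s2p <- exp(opt$par[2])
  V <- s2 * diag(length(y)) + s2p * tcrossprod(Z)
  beta <- solve(crossprod(X, solve(V, X)), crossprod(X, solve(V, y)))
  list(sigma2 = s2, sigma2_phi = s2p, beta = as.vector(beta))
}
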