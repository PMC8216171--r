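# Dense REML machinery for mixed models y = X b + sum_k u_k + e with
# u_k ~ N(0, sigma2_k * K_k) and e ~ N(0, sigma2_e * I), where each K_k is an
# n x n observation-level covariance structure (Z G Z' already formed).
# Sized for n of a few hundred: every likelihood evaluation factorizes the
# full n x n covariance.

# -2 * restricted log-likelihood, including constants and the log|X'X|
# correction that makes the criterion invariant to reparameterization of the
# fixed effects. sigma2: c(components..., residual) matching Klist order.
neg2_reml <- function(y, X, Klist, sigma2) {
  n <- length(y)
  p <- qr(X)$rank
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Klist)) V <- V + sigma2[k] * Klist[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NA_real_)
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  yPy <- drop(crossprod(r, Vi_r))
  (n - p) * log(2 * pi) + logdetV + logdetX - logdet_xtx(X) + yPy
}

logdet_xtx <- function(X) {
  2 * sum(log(abs(diag(qr.R(qr(X))))))
}

# Profiled criterion: variances written sigma2_e * (gamma_1 K_1 + ... + I),
# with sigma2_e maximized analytically. Returns -2 loglik at the profile.
neg2_reml_profiled <- function(y, X, Klist, log_gamma) {
  n <- length(y)
  p <- qr(X)$rank
  gamma <- exp(log_gamma)
  V0 <- diag(1, n)
  for (k in seq_along(Klist)) V0 <- V0 + gamma[k] * Klist[[k]]
  ch <- tryCatch(chol(V0), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdetV0 <- 2 * sum(log(diag(ch)))
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(1e10)
  logdetX0 <- 2 * sum(log(diag(chx)))
  beta <- backsolve(chx, forwardsolve(t(chx), crossprod(X, Vi_y)))
  r <- y - X %*% beta
  yP0y <- drop(crossprod(r, backsolve(ch, forwardsolve(t(ch), r))))
  if (yP0y <= 0) return(1e10)
  s2e <- yP0y / (n - p)
  (n - p) * log(2 * pi) + (n - p) * log(s2e) + (n - p) +
    logdetV0 + logdetX0
}

# Fast path for exactly one K: rotate by the eigenvectors of K so every
# criterion evaluation is O(n p^2).
reml_1k_eigen <- function(y, X, K) {
  eg <- eigen(K, symmetric = TRUE)
  U <- eg$vectors
  lam <- pmax(eg$values, 0)
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  n <- length(y)
  p <- qr(X)$rank
  crit <- function(log_gamma) {
    g <- exp(log_gamma)
    w <- 1 + g * lam          # diag of V0 in rotated basis
    sw <- sqrt(w)
    Xs <- Xt / sw
    ys <- yt / sw
    XtViX <- crossprod(Xs)
    chx <- tryCatch(chol(XtViX), error = function(e) NULL)
    if (is.null(chx)) return(1e10)
    beta <- backsolve(chx, forwardsolve(t(chx), crossprod(Xs, ys)))
    r <- ys - Xs %*% beta
    yP0y <- drop(crossprod(r))
    if (yP0y <= 0) return(1e10)
    s2e <- yP0y / (n - p)
    (n - p) * log(2 * pi) + (n - p) * log(s2e) + (n - p) +
      sum(log(w)) + 2 * sum(log(diag(chx)))
  }
  opt <- stats::optimize(crit, interval = c(-25, 15), tol = 1e-10)
  # check the lower boundary (gamma -> 0)
  if (crit(-30) <= opt$objective + 1e-9) {
    list(log_gamma = -Inf, objective = crit(-30))
  } else {
    list(log_gamma = opt$minimum, objective = opt$objective)
  }
}

# REML fit over one or more observation-level covariance structures.
# Returns variances (components + residual), fixed effects, -2 loglik.
reml_fit_engine <- function(y, X, Klist, n_restarts = 4L) {
  n <- length(y)
  p <- qr(X)$rank
  nk <- length(Klist)
  if (stats::var(y) < 1e-24) {
    return(list(sigma2 = rep(0, nk + 1L), beta = rep(NA_real_, ncol(X)),
                neg2ll = NA_real_, converged = TRUE, degenerate = TRUE))
  }
  if (nk == 1L) {
    sol <- reml_1k_eigen(y, X, Klist[[1L]])
    lg <- sol$log_gamma
    best <- list(par = lg, value = sol$objective)
  } else {
    starts <- list(rep(log(0.5), nk), rep(log(0.05), nk), rep(log(2), nk))
    extra <- max(n_restarts - length(starts), 0L)
    if (extra > 0) {
      old <- .Random.seed_save()
      set.seed(20260929L)
      starts <- c(starts, replicate(extra, stats::runif(nk, -4, 2),
                                    simplify = FALSE))
      .Random.seed_restore(old)
    }
    fits <- lapply(starts, function(s)
      stats::optim(s, function(lg) neg2_reml_profiled(y, X, Klist, lg),
                   method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  }

  lg <- if (nk == 1L) best$par else best$par
  gamma <- exp(lg)
  gamma[!is.finite(gamma)] <- 0
  gamma[gamma < 1e-8] <- 0            # project to the zero boundary
  # recover sigma2_e at the chosen gamma, then solve fixed effects
  V0 <- diag(1, n)
  for (k in seq_len(nk)) V0 <- V0 + gamma[k] * Klist[[k]]
  ch <- chol(V0)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
  XtViX <- crossprod(X, Vi_X)
  beta_cov0 <- solve(XtViX)
  beta <- drop(beta_cov0 %*% crossprod(X, Vi_y))
  r <- y - X %*% beta
  yP0y <- drop(crossprod(r, backsolve(ch, forwardsolve(t(ch), r))))
  s2e <- yP0y / (n - p)
  sigma2 <- c(gamma * s2e, s2e)
  list(sigma2 = sigma2, beta = beta, beta_cov = beta_cov0 * s2e,
       neg2ll = neg2_reml(y, X, Klist, sigma2),
       converged = TRUE, degenerate = FALSE)
}

# Asymptotic SEs of the variance components from the observed information
# (central finite differences of the restricted log-likelihood).
reml_component_se <- function(y, X, Klist, sigma2) {
  q <- length(sigma2)
  f <- function(s) -0.5 * neg2_reml(y, X, Klist, s)
  h <- pmax(1e-4 * abs(sigma2), 1e-7)
  H <- matrix(NA_real_, q, q)
  f0 <- f(sigma2)
  for (i in seq_len(q)) {
    for (j in i:q) {
      si <- sigma2
      if (i == j) {
        if (si[i] - h[i] >= 0) {
          sp <- si; sp[i] <- sp[i] + h[i]
          sm <- si; sm[i] <- sm[i] - h[i]
          H[i, i] <- (f(sp) - 2 * f0 + f(sm)) / h[i]^2
        } else {
          # forward difference at the zero boundary
          sp <- si; sp[i] <- sp[i] + h[i]
          s2 <- si; s2[i] <- s2[i] + 2 * h[i]
          H[i, i] <- (f(s2) - 2 * f(sp) + f0) / h[i]^2
        }
      } else {
        spp <- si; spp[i] <- spp[i] + h[i]; spp[j] <- spp[j] + h[j]
        spm <- si; spm[i] <- spm[i] + h[i]; spm[j] <- max(spm[j] - h[j], 0)
        smp <- si; smp[i] <- max(smp[i] - h[i], 0); smp[j] <- smp[j] + h[j]
        smm <- si; smm[i] <- max(smm[i] - h[i], 0); smm[j] <- max(smm[j] - h[j], 0)
        di <- (spp[i] - smp[i]); dj <- (spp[j] - spm[j])
        H[i, j] <- H[j, i] <- (f(spp) - f(spm) - f(smp) + f(smm)) / (di * dj)
      }
    }
  }
  info <- -H
  se <- rep(NA_real_, q)
  ok <- tryCatch({
    ci <- solve(info)
    d <- diag(ci)
    se[d > 0] <- sqrt(d[d > 0])
    TRUE
  }, error = function(e) FALSE)
  se
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
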