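# REML for the one-way random-intercept model y_ij = x_j' beta + b_j + e_ij,
# with covariates constant within group. The restricted likelihood
# factorizes exactly into (i) within-group contrasts, iid N(0, sigma2_e)
# with N - J degrees of freedom, and (ii) the REML criterion of the
# group-means regression ybar_j ~ N(x_j' beta, sigma2_b + sigma2_e / k_j).
# Profiling sigma2_e leaves a one-dimensional search over the variance
# ratio gamma = sigma2_b / sigma2_e, making each fit cheap enough for
# bootstrap loops of ~10^5 refits.

ri_reml <- function(y, group, x = NULL) {
  group <- as.factor(group)
  J <- nlevels(group)
  N <- length(y)
  if (J < 2L) stop("need at least 2 groups")
  k <- as.numeric(table(group))
  ybar_by <- tapply(y, group, mean)
  ssw <- sum((y - ybar_by[group])^2)
  ybar <- as.numeric(ybar_by)
  if (is.null(x)) {
    Xm <- matrix(1, J, 1)
  } else {
    xg <- tapply(x, group, function(v) v[1])
    if (any(tapply(x, group, function(v) max(v) - min(v)) > 1e-10))
      stop("covariate must be constant within group")
    if (max(xg) - min(xg) < 1e-12) stop("zero variance in the covariate")
    Xm <- cbind(1, as.numeric(xg))
  }
  p <- ncol(Xm)
  if (J <= p) stop("too few groups for the fixed effects")

  crit <- function(log_gamma) {
    g <- exp(log_gamma)
    u <- g + 1 / k                       # Var(ybar_j) / sigma2_e
    w <- 1 / u
    XtWX <- crossprod(Xm * w, Xm)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(list(obj = 1e10))
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xm * w, ybar)))
    r <- drop(ybar - Xm %*% beta)
    rss <- sum(r^2 * w)
    s2e <- (ssw + rss) / (N - p)
    obj <- if (s2e <= 0 || !is.finite(s2e)) 1e10 else
      (N - p) * (log(2 * pi) + log(s2e) + 1) + sum(log(u)) +
      2 * sum(log(diag(ch)))
    list(obj = obj, beta = beta, s2e = s2e, ch = ch)
  }
  opt <- stats::optimize(function(lg) crit(lg)$obj, c(-30, 15), tol = 1e-10)
  lg <- opt$minimum
  # boundary: accept gamma = 0 when it does at least as well
  at0 <- crit(-Inf)
  sol <- if (at0$obj <= opt$objective + 1e-9) {
    lg <- -Inf
    at0
  } else crit(lg)
  gamma <- if (is.finite(lg)) exp(lg) else 0
  if (gamma < 1e-10) gamma <- 0
  s2e <- sol$s2e
  s2b <- gamma * s2e
  beta_cov <- chol2inv(sol$ch) * s2e
  list(beta = drop(sol$beta), beta_cov = beta_cov,
       sigma2_group = s2b, sigma2_resid = s2e,
       loglik = -0.5 * sol$obj,
       loglik_null = -0.5 * at0$obj,     # gamma = 0 (no group variance)
       n = N, n_groups = J, p = p, group_sizes = k)
}

#' Repeatability (intraclass correlation) of brood identity
#'
#' Estimates the fraction of phenotypic variance explained by a grouping
#' factor (here brood identity) from a Gaussian random-intercept mixed model
#' fitted by REML: \eqn{R = V_{group} / (V_{group} + V_{resid})}.
#' Uncertainty is quantified by parametric bootstrap: \code{n_boot}
#' re-simulations from the fitted model, each refitted, giving the SE and a
#' percentile confidence interval. The p-value tests \eqn{V_{group} = 0} by
#' a boundary-corrected likelihood-ratio test (50:50 mixture of a point mass
#' and chi-square 1).
#'
#' @param phenos phenotype data frame.
#' @param trait trait column name (default \code{"total"}).
#' @param group grouping column name (default \code{"brood"}); rows with
#'   missing group are dropped.
#' @param n_boot number of parametric bootstrap replicates (>= 2 for a CI).
#' @param seed integer RNG seed for the bootstrap.
#' @param conf confidence level of the percentile interval.
#' @return List of class \code{"repeatability_estimate"}: \code{R},
#'   \code{SE}, \code{CI}, \code{p}, \code{V_group}, \code{V_resid},
#'   \code{n_boot}, \code{seed}, \code{boot} (the bootstrap draws).
#' @export
estimate_repeatability <- function(phenos, trait = "total", group = "brood",
                                   n_boot = 1000L, seed = 1L, conf = 0.95) {
  y <- phenos[[trait]]
  g <- phenos[[group]]
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(as.factor(g[keep]))
  sizes <- table(g)
  if (sum(sizes >= 2) < 2)
    stop("need at least 2 groups with at least 2 members each")
  if (n_boot < 2) stop("n_boot must be >= 2 for a confidence interval")
  fit <- ri_reml(y, g)
  R_hat <- with(fit, if (sigma2_group + sigma2_resid == 0) 0 else
    sigma2_group / (sigma2_group + sigma2_resid))
  d <- max(0, 2 * (fit$loglik - fit$loglik_null))
  p <- 0.5 * stats::pchisq(d, df = 1, lower.tail = FALSE)

  set.seed(seed)
  mu <- fit$beta[1]
  J <- fit$n_groups
  idx <- as.integer(g)
  boot <- vapply(seq_len(n_boot), function(b) {
    bj <- stats::rnorm(J, 0, sqrt(fit$sigma2_group))
    ystar <- mu + bj[idx] + stats::rnorm(length(y), 0, sqrt(fit$sigma2_resid))
    f <- ri_reml(ystar, g)
    if (f$sigma2_group + f$sigma2_resid == 0) 0 else
      f$sigma2_group / (f$sigma2_group + f$sigma2_resid)
  }, numeric(1))
  ci <- unname(stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  structure(list(R = R_hat, SE = stats::sd(boot), CI = ci, p = p,
                 V_group = fit$sigma2_group, V_resid = fit$sigma2_resid,
                 n_boot = n_boot, seed = seed, boot = boot),
            class = "repeatability_estimate")
}

#' @export
print.repeatability_estimate <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f, SE = %.3f, CI = [%.3f, %.3f], P = %.3g (%d bootstraps)\n",
              x$R, x$SE, x$CI[1], x$CI[2], x$p, x$n_boot))
  invisible(x)
}

#' Parent-offspring regression with a family random intercept
#'
#' Regresses offspring phenotype on the phenotype of one parent (mother,
#' father, or the midparent mean), fitted as a Gaussian mixed model with a
#' family (brood) random intercept by REML. The parent value is constant
#' within family; slope inference uses a t statistic with residual-based
#' degrees of freedom (n - 2). The midparent regression is restricted to
#' families with both parental phenotypes known; the father regression to
#' families with a known, phenotyped sire.
#'
#' @param phenos phenotype table containing parental generation records
#'   (\code{generation == "P"}) and offspring records carrying \code{dam},
#'   \code{sire} and \code{brood} labels.
#' @param parent \code{"mother"}, \code{"father"} or \code{"midparent"}.
#' @param trait trait column name.
#' @return List of class \code{"po_regression"}: \code{slope}, \code{SE},
#'   \code{t}, \code{p}, \code{intercept}, \code{n_families}, \code{n},
#'   \code{V_family}, \code{V_resid}.
#' @export
parent_offspring_regression <- function(phenos,
                                        parent = c("mother", "father", "midparent"),
                                        trait = "total") {
  parent <- match.arg(parent)
  po <- parent_offspring_frame(phenos, parent, trait)
  if (length(unique(po$family)) < 3)
    stop("parent phenotypes available for fewer than 3 families")
  fit <- ri_reml(po$y, po$family, po$x)
  slope <- fit$beta[2]
  se <- sqrt(fit$beta_cov[2, 2])
  df <- fit$n - fit$p
  tval <- slope / se
  structure(list(slope = slope, SE = se, t = tval,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 df = df,
                 intercept = fit$beta[1],
                 n_families = fit$n_groups, n = fit$n,
                 V_family = fit$sigma2_group, V_resid = fit$sigma2_resid),
            class = "po_regression")
}

# offspring (y) / parent value (x) / family frame for one regression type
parent_offspring_frame <- function(phenos, parent, trait) {
  pval <- stats::setNames(phenos[[trait]], phenos$id)
  off <- phenos[phenos$generation == "F1" & !is.na(phenos$brood), , drop = FALSE]
  x <- switch(parent,
    mother = pval[off$dam],
    father = ifelse(is.na(off$sire), NA_real_, pval[off$sire]),
    midparent = {
      xm <- pval[off$dam]
      xf <- ifelse(is.na(off$sire), NA_real_, pval[off$sire])
      (xm + xf) / 2
    })
  keep <- !is.na(x) & !is.na(off[[trait]])
  data.frame(y = off[[trait]][keep], x = unname(x[keep]),
             family = off$brood[keep], stringsAsFactors = FALSE)
}

#' @export
print.po_regression <- function(x, ...) {
  cat(sprintf("slope = %.3f +/- %.3f, t = %.3f, P = %.3g (%d families, %d offspring)\n",
              x$slope, x$SE, x$t, x$p, x$n_families, x$n))
  invisible(x)
}
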