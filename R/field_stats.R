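#' One-way ANOVA on square-root-transformed concentrations
#'
#' Wild-collected cyanogen concentrations are right-skewed; the comparison of
#' populations therefore applies a square-root transformation before a
#' one-way ANOVA. Group means and SDs are reported on the raw scale.
#'
#' @param values nonnegative concentrations.
#' @param group group labels (>= 2 groups, each with >= 2 values).
#' @param transform \code{"sqrt"} (default) or \code{"none"}.
#' @return List of class \code{"anova_result"}: \code{F}, \code{df_between},
#'   \code{df_within}, \code{p}, \code{transform}, \code{group_stats} (raw
#'   means/SDs/n), and the fitted \code{aov} object for downstream Tukey
#'   comparisons.
#' @export
sqrt_anova <- function(values, group, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("need at least 2 groups")
  if (any(table(group) < 2)) stop("every group needs at least 2 values")
  if (transform == "sqrt" && any(values < 0))
    stop("negative values are incompatible with the sqrt transform")
  y <- if (transform == "sqrt") sqrt(values) else values
  fit <- stats::aov(y ~ group, data = data.frame(y = y, group = group))
  tab <- summary(fit)[[1]]
  if (stats::var(y) == 0) {  # constant data: define F = 0, p = 1
    tab[1, "F value"] <- 0
    tab[1, "Pr(>F)"] <- 1
  }
  gs <- data.frame(group = levels(group),
                   n = as.vector(table(group)),
                   mean = as.vector(tapply(values, group, mean)),
                   sd = as.vector(tapply(values, group, stats::sd)))
  structure(list(F = tab[1, "F value"],
                 df_between = tab[1, "Df"], df_within = tab[2, "Df"],
                 p = tab[1, "Pr(>F)"],
                 transform = transform, group_stats = gs, aov = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.3f, P = %.4g  [%s scale]\n",
              x$df_between, x$df_within, x$F, x$p, x$transform))
  print(x$group_stats, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparisons after [sqrt_anova()], using the studentized-range
#' distribution in the Tukey-Kramer form (valid for unequal group sizes).
#' Differences are on the analysis (transformed) scale.
#'
#' @param anova an [sqrt_anova()] result.
#' @return Data frame of class \code{"tukey_result"}: \code{pair},
#'   \code{diff}, \code{lwr}, \code{upr}, \code{p_adj}.
#' @export
tukey_hsd <- function(anova) {
  stopifnot(inherits(anova, "anova_result"))
  tk <- stats::TukeyHSD(anova$aov)[["group"]]
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Two-way factorial ANOVA with interaction
#'
#' Tests main effects of two crossed factors and their interaction (e.g.
#' plant origin, watering treatment and origin x treatment for greenhouse
#' host plants).
#'
#' @param values response values.
#' @param factor_A,factor_B factor labels, each with >= 2 levels.
#' @param transform \code{"none"} (default; the greenhouse responses are
#'   approximately normal) or \code{"sqrt"}.
#' @return Data frame of class \code{"factorial_anova"} with one row per
#'   term: \code{term}, \code{df}, \code{F}, \code{p} (plus residual df as
#'   attribute \code{df_resid}).
#' @export
factorial_anova <- function(values, factor_A, factor_B,
                            transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  A <- droplevels(as.factor(factor_A))
  B <- droplevels(as.factor(factor_B))
  if (nlevels(A) < 2 || nlevels(B) < 2) stop("both factors need >= 2 levels")
  if (any(table(A, B) == 0))
    stop("empty factor-combination cell; interaction not estimable")
  y <- if (transform == "sqrt") {
    if (any(values < 0)) stop("negative values with sqrt transform")
    sqrt(values)
  } else values
  fit <- stats::aov(y ~ A * B)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  keep <- terms != "Residuals"
  out <- data.frame(term = c("factor_A", "factor_B", "interaction"),
                    df = tab[keep, "Df"],
                    F = tab[keep, "F value"],
                    p = tab[keep, "Pr(>F)"], row.names = NULL)
  attr(out, "df_resid") <- tab[!keep, "Df"]
  class(out) <- c("factorial_anova", "data.frame")
  out
}

#' Hedges' g standardized mean difference
#'
#' Standardized difference between two group means using the pooled SD and
#' the small-sample bias correction \eqn{J = 1 - 3 / (4 df - 1)} with
#' \eqn{df = n_1 + n_2 - 2}.
#'
#' @param group1,group2 numeric vectors (each n >= 2).
#' @return Hedges' g (positive when \code{group1} has the larger mean).
#' @export
hedges_g <- function(group1, group2) {
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(group1) + (n2 - 1) * stats::var(group2)) / df
  if (sp2 <= 0) stop("zero pooled SD")
  J <- 1 - 3 / (4 * df - 1)
  J * (mean(group1) - mean(group2)) / sqrt(sp2)
}

#' Pearson correlation with t test
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return List: \code{r}, \code{t}, \code{df}, \code{p}, \code{n}.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(x))
}

#' Zero-truncated weighted kernel density estimate
#'
#' Gaussian-kernel density for nonnegative concentration data, accounting
#' for the skew towards near-zero values: each kernel is renormalized by its
#' mass on \eqn{[0, \infty)} so no probability leaks below zero, and
#' observations may carry nonnegative weights (normalized to sum one).
#' Default bandwidth is the normal-reference rule
#' \eqn{h = 0.9 \min(SD, IQR/1.34) n^{-1/5}}.
#'
#' @param values nonnegative observations (n >= 2).
#' @param weights optional nonnegative weights, not all zero.
#' @param bandwidth kernel SD; default the normal-reference rule.
#' @param n_grid number of evaluation points.
#' @param grid_max upper end of the grid (default max(values) + 3 bandwidths).
#' @return List of class \code{"density_estimate"}: \code{grid},
#'   \code{density}, \code{bandwidth}, \code{weights}. The density
#'   integrates to 1 over \eqn{[0, \infty)} (trapezoid rule, within 1e-3
#'   when the grid covers the support).
#' @export
truncated_weighted_kde <- function(values, weights = NULL, bandwidth = NULL,
                                   n_grid = 512L, grid_max = NULL) {
  n <- length(values)
  if (n < 2) stop("need n >= 2")
  if (any(values < 0)) stop("values must be nonnegative")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights must match values in length")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative and not all zero")
  w <- weights / sum(weights)
  if (is.null(bandwidth)) {
    s <- stats::sd(values)
    iqr <- stats::IQR(values) / 1.34
    spread <- min(s, if (iqr > 0) iqr else s)
    if (spread == 0) spread <- max(stats::sd(values), 1e-8)
    bandwidth <- 0.9 * spread * n^(-1 / 5)
  }
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (is.null(grid_max)) grid_max <- max(values) + 3 * bandwidth
  grid <- seq(0, grid_max, length.out = n_grid)
  # per-kernel truncation mass on [0, Inf): pnorm(x_i / h)
  mass <- stats::pnorm(values / bandwidth)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm(g, mean = values, sd = bandwidth) / mass),
    numeric(1))
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 weights = w), class = "density_estimate")
}

#' Range-quarter skew summary
#'
#' Summarizes the skew of a toxicity distribution by the fraction of
#' individuals in the lower and upper quarters of the observed range:
#' values \eqn{\le min + 0.25 (max - min)} and
#' \eqn{\ge min + 0.75 (max - min)} (the "lower/highest 25% of toxicity
#' values" read as quarters of the range, since quantile quarters would hold
#' 25% by construction), plus the fraction below an absolute threshold.
#'
#' @param values numeric vector (n >= 2, non-constant).
#' @param threshold absolute concentration threshold (default 0.5 % dry
#'   mass).
#' @return List of class \code{"skew_summary"}: \code{range_min},
#'   \code{range_max}, \code{frac_lower_quarter}, \code{frac_upper_quarter},
#'   \code{frac_below_threshold}, \code{threshold}, \code{n}.
#' @export
range_quartile_summary <- function(values, threshold = 0.5) {
  if (length(values) < 2) stop("need n >= 2")
  rmin <- min(values); rmax <- max(values)
  if (rmax - rmin == 0) stop("constant data: range is zero")
  lo <- rmin + 0.25 * (rmax - rmin)
  hi <- rmin + 0.75 * (rmax - rmin)
  structure(list(range_min = rmin, range_max = rmax,
                 frac_lower_quarter = mean(values <= lo),
                 frac_upper_quarter = mean(values >= hi),
                 frac_below_threshold = mean(values < threshold),
                 threshold = threshold, n = length(values)),
            class = "skew_summary")
}

#' Detection-limit summary
#'
#' Fraction of samples with a concentration above a detection limit, and the
#' mean over the detected subset (reported as \code{NA} when nothing is
#' detected).
#'
#' @param values nonnegative concentrations (n >= 1).
#' @param limit detection limit (>= 0; default 0, i.e. any positive signal).
#' @return List: \code{frac_detected}, \code{mean_detected}, \code{n},
#'   \code{n_detected}.
#' @export
detection_summary <- function(values, limit = 0) {
  if (length(values) < 1) stop("need n >= 1")
  if (limit < 0) stop("limit must be >= 0")
  det <- values > limit
  list(frac_detected = mean(det),
       mean_detected = if (any(det)) mean(values[det]) else NA_real_,
       n = length(values), n_detected = sum(det))
}
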