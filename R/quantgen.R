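#' Broad-sense heritability from variance components
#'
#' \eqn{H^2 = V_G / V_P}. Two denominator conventions are supported: the
#' reporting convention of the source analysis excludes the feeding-treatment
#' variance from V_P (treatment variance is unlikely to represent natural
#' variation), i.e. \eqn{V_P = V_G + V_{mat} + V_{sex} + V_R}; the
#' \code{"full"} convention sums every component including V_trm.
#'
#' @param components named numeric vector (or the \code{components} field of
#'   an [fit_animal_model()] result) with entries \code{V_G}, \code{V_mat},
#'   \code{V_sex}, \code{V_trm}, \code{V_R} (missing entries count as 0).
#' @param denominator \code{"exclude_treatment"} (default) or \code{"full"}.
#' @return Heritability in [0, 1].
#' @export
broad_sense_heritability <- function(components,
                                     denominator = c("exclude_treatment", "full")) {
  denominator <- match.arg(denominator)
  get0c <- function(nm) if (nm %in% names(components)) unname(components[nm]) else 0
  vg <- get0c("V_G")
  vp <- vg + get0c("V_mat") + get0c("V_sex") + get0c("V_R") + get0c("V_brood")
  if (denominator == "full") vp <- vp + get0c("V_trm")
  if (vp <= 0) {
    if (vg == 0) return(0)
    stop("zero phenotypic variance denominator")
  }
  vg / vp
}

#' Mean-scaled evolvability
#'
#' \eqn{e_\mu = 100 \, V_G / \mu^2}, the expected percent change in the
#' trait mean per generation under unit-strength selection (selection on the
#' trait as strong as selection on fitness itself).
#'
#' @param V_G genetic variance, trait units squared.
#' @param mu trait mean (> 0), trait units.
#' @return Evolvability in percent.
#' @export
mean_scaled_evolvability <- function(V_G, mu) {
  if (V_G < 0) stop("V_G must be >= 0")
  if (mu <= 0) stop("trait mean must be > 0")
  100 * V_G / mu^2
}

#' Maternal-effect coefficient under Falconer's dilution model
#'
#' Estimates \eqn{m = \beta_{mo} - \beta_{fo}}, the difference between the
#' mother-offspring and father-offspring regression slopes, with a
#' brood-level (cluster) bootstrap confidence interval: broods are resampled
#' with replacement and both regressions refitted jointly on each resample,
#' so the dependence between the two slopes is preserved. Note the two
#' slopes may rest on different family subsets (father-offspring requires a
#' known, phenotyped sire); the subset sizes are reported.
#'
#' @param phenos phenotype table (see [parent_offspring_regression()]).
#' @param trait trait column name.
#' @param n_boot number of cluster bootstrap replicates.
#' @param seed integer RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return List of class \code{"maternal_effect_estimate"}: \code{m},
#'   \code{m_CI}, \code{beta_mo}, \code{beta_fo}, \code{beta_mid} (each a
#'   [parent_offspring_regression()] fit), \code{n_boot}, \code{seed},
#'   \code{boot}.
#' @export
maternal_effect_coefficient <- function(phenos, trait = "total",
                                        n_boot = 1000L, seed = 1L,
                                        conf = 0.95) {
  mo <- parent_offspring_regression(phenos, "mother", trait)
  fo <- parent_offspring_regression(phenos, "father", trait)
  mid <- tryCatch(parent_offspring_regression(phenos, "midparent", trait),
                  error = function(e) NULL)
  m_hat <- mo$slope - fo$slope

  fr_mo <- parent_offspring_frame(phenos, "mother", trait)
  fr_fo <- parent_offspring_frame(phenos, "father", trait)
  broods <- unique(c(fr_mo$family, fr_fo$family))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    bs <- sample(broods, replace = TRUE)
    slope_of <- function(fr) {
      pieces <- lapply(seq_along(bs), function(i) {
        rows <- fr[fr$family == bs[i], , drop = FALSE]
        if (nrow(rows) > 0) rows$family <- paste0("bs", i)
        rows
      })
      d <- do.call(rbind, pieces)
      if (is.null(d) || nrow(d) == 0 || length(unique(d$family)) < 3 ||
          max(d$x) - min(d$x) < 1e-12) return(NA_real_)
      ri_reml(d$y, d$family, d$x)$beta[2]
    }
    slope_of(fr_mo) - slope_of(fr_fo)
  }, numeric(1))
  boot_ok <- boot[is.finite(boot)]
  ci <- unname(stats::quantile(boot_ok, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  structure(list(m = m_hat, m_CI = ci,
                 beta_mo = mo, beta_fo = fo, beta_mid = mid,
                 n_boot = n_boot, n_boot_ok = length(boot_ok),
                 seed = seed, boot = boot_ok),
            class = "maternal_effect_estimate")
}

#' @export
print.maternal_effect_estimate <- function(x, ...) {
  cat(sprintf("m = beta_mo - beta_fo = %.3f - (%.3f) = %.3f, CI = [%.3f, %.3f]\n",
              x$beta_mo$slope, x$beta_fo$slope, x$m, x$m_CI[1], x$m_CI[2]))
  cat(sprintf("  mother-offspring : %d families\n", x$beta_mo$n_families))
  cat(sprintf("  father-offspring : %d families (known sires only)\n",
              x$beta_fo$n_families))
  invisible(x)
}

#' Compound selection-response projection
#'
#' Cumulative percent change in the trait mean after \code{g} generations of
#' proportional per-generation change \code{e_mu * beta} (evolvability times
#' selection strength), compounded multiplicatively:
#' \eqn{100 ((1 + e_\mu \beta / 100)^g - 1)}.
#'
#' @param e_mu mean-scaled evolvability, percent per generation.
#' @param beta selection strength as a proportion of unit strength (1 =
#'   selection as strong as selection on fitness).
#' @param g number of generations (>= 0).
#' @return Cumulative percent change.
#' @export
project_compound_response <- function(e_mu, beta = 1, g) {
  if (g < 0) stop("g must be >= 0")
  100 * ((1 + e_mu / 100 * beta)^g - 1)
}

#' Selection-response trajectory with maternal transmission
#'
#' Iterates the per-generation response recursion of Falconer's dilution
#' model, \eqn{R_t = h^2 S + m R_{t-1}} (default form; an alternative
#' recursion can be plugged in), accumulating the total response over
#' \code{g} generations and the ratio to the maternal-effect-free
#' (\code{m = 0}) trajectory. For \eqn{0 < m < 1} the cumulative response
#' approaches \eqn{1 / (1 - m)} times the breeder's-equation response.
#'
#' @param h2 heritability (per-generation direct response factor).
#' @param m maternal-effect coefficient, |m| < 1.
#' @param beta selection differential S per generation (trait units, or 1
#'   for a unit differential).
#' @param g number of generations (>= 1).
#' @param recursion optional function \code{(R_prev, h2, S, m) -> R_t}
#'   replacing the default \code{h2 * S + m * R_prev}.
#' @return List of class \code{"response_projection"}: per-generation
#'   \code{trajectory}, \code{cumulative} responses, \code{cumulative_m0}
#'   (same with m = 0), \code{excess_ratio} (final ratio to the m = 0
#'   response), and the inputs.
#' @export
falconer_response_trajectory <- function(h2, m, beta = 1, g,
                                         recursion = NULL) {
  if (abs(m) >= 1) stop("|m| must be < 1 (otherwise the recursion diverges)")
  if (g < 1) stop("g must be >= 1")
  step <- recursion %||f% function(R_prev, h2, S, m) h2 * S + m * R_prev
  traj <- numeric(g)
  traj0 <- numeric(g)
  Rp <- 0; Rp0 <- 0
  for (t in seq_len(g)) {
    Rp <- step(Rp, h2, beta, m)
    Rp0 <- step(Rp0, h2, beta, 0)
    traj[t] <- Rp
    traj0[t] <- Rp0
  }
  structure(list(trajectory = traj, cumulative = cumsum(traj),
                 cumulative_m0 = cumsum(traj0),
                 excess_ratio = sum(traj) / sum(traj0),
                 h2 = h2, m = m, beta = beta, g = g),
            class = "response_projection")
}

`%||f%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.response_projection <- function(x, ...) {
  cat(sprintf("Cumulative response after %d generations: %.4f (m = %.2f)\n",
              x$g, x$cumulative[x$g], x$m))
  cat(sprintf("  m = 0 reference: %.4f; excess ratio %.3f\n",
              x$cumulative_m0[x$g], x$excess_ratio))
  invisible(x)
}
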