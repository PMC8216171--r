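#' Specify an animal model
#'
#' @param trait phenotype column to analyse: \code{"total"},
#'   \code{"linamarin"} or \code{"lotaustralin"}.
#' @param fixed_effects subset of \code{c("sex", "treatment")}.
#' @param random_effects ordered subset of \code{c("animal",
#'   "maternal_identity", "brood")}. \code{"animal"} requires a relationship
#'   matrix; \code{"maternal_identity"} requires dam labels; \code{"brood"}
#'   requires brood labels.
#' @return list of class \code{"model_spec"}.
#' @details The study's primary model ("Model 1") is
#'   \code{model_spec(fixed_effects = c("sex", "treatment"),
#'   random_effects = "animal")}; "Model 2" adds \code{"maternal_identity"}.
#' @export
model_spec <- function(trait = c("total", "linamarin", "lotaustralin"),
                       fixed_effects = c("sex", "treatment"),
                       random_effects = "animal") {
  trait <- match.arg(trait)
  fixed_effects <- intersect(c("sex", "treatment"), fixed_effects)
  bad <- setdiff(random_effects, c("animal", "maternal_identity", "brood"))
  if (length(bad) > 0)
    stop("unknown random effect(s): ", paste(bad, collapse = ", "))
  if (length(random_effects) == 0)
    stop("at least one random effect is required")
  structure(list(trait = trait, fixed_effects = fixed_effects,
                 random_effects = random_effects), class = "model_spec")
}

# Build response, fixed design and observation-level covariance structures.
build_model_frame <- function(phenos, A, spec) {
  y <- phenos[[spec$trait]]
  if (is.null(y)) stop("trait column not found: ", spec$trait)
  n <- length(y)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (fe in spec$fixed_effects) {
    v <- factor(phenos[[fe]])
    v <- droplevels(v)
    if (nlevels(v) > 1) {
      M <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(M) <- paste0(fe, levels(v)[-1])
      X <- cbind(X, M)
    }
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is singular")

  Klist <- list()
  for (re in spec$random_effects) {
    K <- switch(re,
      animal = {
        if (is.null(A)) stop("random effect 'animal' requires a relationship matrix")
        missing <- setdiff(phenos$id, rownames(A))
        if (length(missing) > 0)
          stop("phenotyped individual(s) absent from the relationship matrix: ",
               paste(utils::head(missing, 5), collapse = ", "))
        A[phenos$id, phenos$id]
      },
      maternal_identity = {
        if (is.null(phenos$dam)) stop("random effect 'maternal_identity' requires dam labels")
        g <- factor(ifelse(is.na(phenos$dam), paste0(".self.", phenos$id),
                           phenos$dam))
        Z <- stats::model.matrix(~ 0 + g)
        tcrossprod(Z)
      },
      brood = {
        if (is.null(phenos$brood)) stop("random effect 'brood' requires brood labels")
        g <- factor(ifelse(is.na(phenos$brood), paste0(".self.", phenos$id),
                           phenos$brood))
        Z <- stats::model.matrix(~ 0 + g)
        tcrossprod(Z)
      })
    Klist[[re]] <- K
  }
  list(y = y, X = X, Klist = Klist)
}

#' Fit a pedigree-based REML animal model
#'
#' Maximizes the restricted log-likelihood of a mixed model in which the
#' individual-level genetic effect has covariance \code{V_G * A} (A the
#' additive relationship matrix), optionally plus a maternal-identity or
#' brood random effect, with fixed effects of sex and feeding treatment.
#' Variance components are constrained nonnegative (boundary estimates are
#' projected to zero); asymptotic standard errors come from the observed
#' information matrix. Variances explained by the fixed effects (V_sex,
#' V_trm) are computed as the population variance of each effect's
#' linear-predictor contribution across the observations.
#'
#' @param phenos phenotype data frame with columns \code{id}, the trait, and
#'   any fixed-/random-effect columns the spec needs (\code{sex},
#'   \code{treatment}, \code{dam}, \code{brood}).
#' @param A additive relationship matrix from
#'   [additive_relationship_matrix()] covering every phenotyped id (may be
#'   \code{NULL} for models without the \code{"animal"} term).
#' @param spec a [model_spec()].
#' @return Object of class \code{"animal_model_fit"}: variance
#'   \code{components} (V_G, V_mat, V_sex, V_trm, V_R and their sum V_P),
#'   \code{component_SEs}, \code{fixed_coefficients} with SEs,
#'   \code{restricted_loglik}, \code{converged}, \code{degenerate},
#'   \code{n_obs}, \code{n_broods}.
#' @export
fit_animal_model <- function(phenos, A = NULL, spec = model_spec()) {
  mf <- build_model_frame(phenos, A, spec)
  fit <- reml_fit_engine(mf$y, mf$X, mf$Klist)

  nk <- length(mf$Klist)
  comp_names <- vapply(spec$random_effects, function(re)
    switch(re, animal = "V_G", maternal_identity = "V_mat", brood = "V_brood"),
    character(1))
  sigma2 <- stats::setNames(fit$sigma2, c(comp_names, "V_R"))

  if (fit$degenerate) {
    comps <- c(V_G = 0, V_mat = 0, V_sex = 0, V_trm = 0, V_R = 0)
    if ("V_brood" %in% comp_names) comps["V_brood"] <- 0
    ses <- stats::setNames(rep(NA_real_, length(sigma2)), names(sigma2))
    fixed <- NULL
    ll <- NA_real_
  } else {
    ses <- stats::setNames(reml_component_se(mf$y, mf$X, mf$Klist, fit$sigma2),
                           names(sigma2))
    fixed <- data.frame(estimate = fit$beta,
                        SE = sqrt(diag(fit$beta_cov)),
                        row.names = colnames(mf$X))
    ll <- -0.5 * fit$neg2ll
    comps <- c(V_G = unname(sigma2["V_G"] %||% 0),
               V_mat = unname(sigma2["V_mat"] %||% 0),
               V_sex = 0, V_trm = 0,
               V_R = unname(sigma2["V_R"]))
    if ("V_brood" %in% names(sigma2))
      comps <- c(comps, V_brood = unname(sigma2["V_brood"]))
  }

  out <- structure(list(spec = spec, components = comps,
                        component_SEs = ses,
                        sigma2 = sigma2,
                        fixed_coefficients = fixed,
                        X = mf$X,
                        restricted_loglik = ll,
                        converged = isTRUE(fit$converged),
                        degenerate = isTRUE(fit$degenerate),
                        n_obs = length(mf$y),
                        n_broods = if (!is.null(phenos$brood))
                          length(unique(stats::na.omit(phenos$brood))) else NA_integer_),
                   class = "animal_model_fit")
  if (!out$degenerate) {
    for (fe in spec$fixed_effects) {
      v <- fixed_effect_variance(out, fe)
      if (fe == "sex") out$components["V_sex"] <- v
      if (fe == "treatment") out$components["V_trm"] <- v
    }
  }
  out$components <- c(out$components,
                      V_P = sum(out$components[setdiff(names(out$components), "V_P")]))
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' @export
print.animal_model_fit <- function(x, ...) {
  cat("REML animal model fit (trait:", x$spec$trait, ")\n")
  cat("  n_obs:", x$n_obs, " broods:", x$n_broods,
      " converged:", x$converged, "\n")
  cat("  restricted log-likelihood:", format(x$restricted_loglik), "\n")
  tab <- data.frame(estimate = x$components,
                    ratio_VP = x$components / x$components["V_P"])
  print(round(tab, 5))
  invisible(x)
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML criterion (restricted log-likelihood, constants
#' included) of an animal-model specification at a supplied vector of
#' variance components, exposed so that optimizer output can be audited
#' against grid searches and random probes.
#'
#' @inheritParams fit_animal_model
#' @param components named numeric vector: one variance per random effect in
#'   \code{spec$random_effects} (names \code{V_G}, \code{V_mat},
#'   \code{V_brood}) plus \code{V_R}; all >= 0 and \code{V_R > 0}.
#' @return Scalar restricted log-likelihood.
#' @export
restricted_loglik <- function(phenos, A = NULL, spec = model_spec(), components) {
  mf <- build_model_frame(phenos, A, spec)
  comp_names <- vapply(spec$random_effects, function(re)
    switch(re, animal = "V_G", maternal_identity = "V_mat", brood = "V_brood"),
    character(1))
  need <- c(comp_names, "V_R")
  if (!all(need %in% names(components)))
    stop("components must carry: ", paste(need, collapse = ", "))
  sigma2 <- unname(components[need])
  if (any(sigma2 < 0)) stop("variance components must be >= 0")
  if (sigma2[length(sigma2)] <= 0) stop("V_R must be > 0")
  -0.5 * neg2_reml(mf$y, mf$X, mf$Klist, sigma2)
}

#' Boundary-corrected likelihood-ratio test for one variance component
#'
#' Tests whether a single variance component is zero by comparing the
#' restricted log-likelihoods of nested fits. Because the null value lies on
#' the boundary of the parameter space, the test statistic is referred to an
#' equal mixture of a point mass at zero and a chi-square with one degree of
#' freedom: \eqn{p = \tfrac12 P(\chi^2_1 \ge 2\Delta\ell)}, giving p = 0.5
#' at zero improvement.
#'
#' @param full,reduced fits from [fit_animal_model()]; \code{reduced} must
#'   drop exactly one random effect from \code{full}.
#' @return p-value.
#' @export
lrt_variance_component <- function(full, reduced) {
  stopifnot(inherits(full, "animal_model_fit"),
            inherits(reduced, "animal_model_fit"))
  dropped <- setdiff(full$spec$random_effects, reduced$spec$random_effects)
  if (length(dropped) != 1L ||
      !all(reduced$spec$random_effects %in% full$spec$random_effects) ||
      !identical(full$spec$fixed_effects, reduced$spec$fixed_effects) ||
      !identical(full$spec$trait, reduced$spec$trait))
    stop("models are not nested by removal of exactly one variance component")
  d <- 2 * (full$restricted_loglik - reduced$restricted_loglik)
  d <- max(d, 0)
  0.5 * stats::pchisq(d, df = 1, lower.tail = FALSE)
}

#' Variance explained by a fixed effect
#'
#' Variance, across the observations used in the fit, of the linear-predictor
#' contribution of one fixed effect's estimated coefficients (population
#' variance, denominator n). For two equal-frequency sexes differing by d
#' this equals d^2/4.
#'
#' @param fit an [fit_animal_model()] result.
#' @param effect \code{"sex"} or \code{"treatment"}.
#' @return Scalar variance.
#' @export
fixed_effect_variance <- function(fit, effect = c("sex", "treatment")) {
  effect <- match.arg(effect)
  if (!(effect %in% fit$spec$fixed_effects)) stop("effect not in model: ", effect)
  cols <- grep(paste0("^", effect), colnames(fit$X))
  if (length(cols) == 0) return(0)
  contrib <- fit$X[, cols, drop = FALSE] %*%
    fit$fixed_coefficients$estimate[cols]
  v <- drop(contrib)
  mean((v - mean(v))^2)
}
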