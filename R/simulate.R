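#' Simulation configuration for the common-garden breeding design
#'
#' Bundles and validates the parameters of the synthetic breeding-design
#' generator. Defaults emulate the study conditions of the common-garden
#' experiment this package models: 20 full-sib broods (14 smaller broods of
#' which 8 have a known sire, plus 6 large broods split equally across four
#' host-plant feeding treatments), one paternal half-sib brood pair, a trait
#' mean of 0.772 % dry mass, additive-genetic variance 0.0093 and residual
#' variance 0.071 (% dry mass)^2.
#'
#' @param n_broods number of full-sib broods (>= 1).
#' @param offspring_per_brood scalar, per-brood vector of length
#'   \code{n_broods}, or range \code{c(lo, hi)} sampled uniformly per brood.
#' @param n_shared_sire_pairs number of brood pairs sharing one sire
#'   (paternal half-sib links); at most \code{floor(n_broods / 2)}.
#' @param n_unknown_sire_broods number of broods whose sire is materialized
#'   as a distinct phantom founder (single-mating assumption).
#' @param n_treatment_broods number of broods whose offspring are split
#'   equally across the \code{treatment_effects} levels; the remaining broods
#'   are reared on the standard diet.
#' @param mu trait mean, % dry mass.
#' @param V_A additive-genetic variance, (% dry mass)^2.
#' @param V_mat maternal-identity variance, (% dry mass)^2. Mutually
#'   exclusive with \code{m_transmission}.
#' @param m_transmission Falconer maternal-transmission coefficient: the dam
#'   contributes \code{m * (dam phenotype - mu)} to each offspring.
#' @param sex_effect additive shift applied to males, % dry mass.
#' @param treatment_effects named numeric vector of diet-treatment shifts
#'   (% dry mass); \code{NULL} disables treatments.
#' @param V_R residual variance, (% dry mass)^2.
#' @param lotaustralin_fraction mean fraction of total cyanogens that is
#'   lotaustralin (remainder linamarin).
#' @param lotaustralin_dispersion Beta concentration of the per-individual
#'   lotaustralin fraction (larger = tighter around the mean; the two
#'   compounds stay strongly but not perfectly correlated); 0 fixes the
#'   fraction exactly.
#' @param seed integer RNG seed; one seed drives all draws.
#' @return A validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_broods = 20L,
                       offspring_per_brood = NULL,
                       n_shared_sire_pairs = 1L,
                       n_unknown_sire_broods = 6L,
                       n_treatment_broods = 6L,
                       mu = 0.772,
                       V_A = 0.0093,
                       V_mat = 0,
                       m_transmission = 0,
                       sex_effect = 0.059,
                       treatment_effects = c(dry_dry = -0.045, dry_wet = -0.015,
                                             wet_dry = 0.015, wet_wet = 0.045),
                       V_R = 0.071,
                       lotaustralin_fraction = 0.25,
                       lotaustralin_dispersion = 200,
                       seed = 1L) {
  if (is.null(offspring_per_brood)) {
    # study layout: 14 small broods (avg 8 full sibs), 6 large treatment
    # broods (avg 29 full sibs)
    n_small <- max(n_broods - n_treatment_broods, 0L)
    offspring_per_brood <- c(rep(8L, n_small),
                             rep(29L, n_broods - n_small))
  }
  if (!is.null(treatment_effects) && is.null(names(treatment_effects)))
    names(treatment_effects) <- paste0("trt", seq_along(treatment_effects))
  cfg <- list(n_broods = as.integer(n_broods),
              offspring_per_brood = offspring_per_brood,
              n_shared_sire_pairs = as.integer(n_shared_sire_pairs),
              n_unknown_sire_broods = as.integer(n_unknown_sire_broods),
              n_treatment_broods = as.integer(n_treatment_broods),
              mu = mu, V_A = V_A, V_mat = V_mat,
              m_transmission = m_transmission,
              sex_effect = sex_effect,
              treatment_effects = treatment_effects,
              V_R = V_R,
              lotaustralin_fraction = lotaustralin_fraction,
              lotaustralin_dispersion = lotaustralin_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_broods < 1L) stop("n_broods must be >= 1")
    if (any(offspring_per_brood < 1)) stop("offspring_per_brood must be >= 1")
    if (!(length(offspring_per_brood) %in% c(1L, 2L, n_broods)))
      stop("offspring_per_brood must be a scalar, a range c(lo, hi), ",
           "or one count per brood")
    if (V_A < 0 || V_mat < 0 || V_R < 0)
      stop("variance components must be nonnegative")
    if (V_mat > 0 && m_transmission != 0)
      stop("V_mat and m_transmission are mutually exclusive maternal-effect ",
           "modes; set one of them to zero")
    if (n_shared_sire_pairs > floor(n_broods / 2))
      stop("n_shared_sire_pairs exceeds floor(n_broods / 2)")
    if (n_unknown_sire_broods > n_broods)
      stop("n_unknown_sire_broods exceeds n_broods")
    if (n_treatment_broods > n_broods)
      stop("n_treatment_broods exceeds n_broods")
    if (lotaustralin_fraction < 0 || lotaustralin_fraction > 1)
      stop("lotaustralin_fraction must be in [0, 1]")
    if (lotaustralin_dispersion < 0)
      stop("lotaustralin_dispersion must be >= 0")
  })
  cfg
}

# per-individual lotaustralin fractions: Beta around the mean fraction, or
# exactly the mean when dispersion is zero
draw_lot_fraction <- function(n, frac, dispersion) {
  if (dispersion == 0 || frac == 0 || frac == 1) return(rep(frac, n))
  stats::rbeta(n, frac * dispersion, (1 - frac) * dispersion)
}

brood_sizes <- function(cfg) {
  k <- cfg$offspring_per_brood
  if (length(k) == cfg$n_broods) return(as.integer(k))
  if (length(k) == 1L) return(rep(as.integer(k), cfg$n_broods))
  # range: uniform draw per brood
  as.integer(sample(seq(k[1], k[2]), cfg$n_broods, replace = TRUE))
}

#' Generate a two-generation full-sib/half-sib pedigree
#'
#' Builds founders (dams and sires, assumed unrelated and non-inbred) and one
#' full-sib brood per dam. The requested number of brood pairs share a sire
#' (paternal half-sibs); broods with an unknown father receive a distinct
#' phantom founder sire each, so full sibs remain full sibs in the
#' relationship matrix. Phantom sires carry ids prefixed \code{"PS"}.
#'
#' @param config a [sim_config()].
#' @return A validated, topologically ordered pedigree table with columns
#'   \code{id}, \code{dam}, \code{sire}, \code{sex}, \code{generation},
#'   \code{brood} (offspring only), and logical \code{sire_known}.
#' @export
make_pedigree <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  nb <- cfg$n_broods
  sizes <- brood_sizes(cfg)

  dam_ids <- sprintf("D%02d", seq_len(nb))
  # sire assignment: first the shared-sire pairs, then unknown-sire broods,
  # then singly mated known sires
  sire_of_brood <- character(nb)
  sire_known <- rep(TRUE, nb)
  b <- 1L
  shared_ids <- character(0)
  for (p in seq_len(cfg$n_shared_sire_pairs)) {
    sid <- sprintf("S%02d", p)
    sire_of_brood[b] <- sid; sire_of_brood[b + 1L] <- sid
    shared_ids <- c(shared_ids, sid)
    b <- b + 2L
  }
  unknown <- integer(0)
  if (cfg$n_unknown_sire_broods > 0L) {
    unknown <- seq(from = b, length.out = min(cfg$n_unknown_sire_broods,
                                              nb - b + 1L))
    sire_of_brood[unknown] <- sprintf("PS%02d", unknown)
    sire_known[unknown] <- FALSE
    b <- b + length(unknown)
  }
  rest <- setdiff(seq_len(nb), which(sire_of_brood != ""))
  sire_of_brood[rest] <- sprintf("S%02d", cfg$n_shared_sire_pairs +
                                   seq_along(rest))
  sire_ids <- unique(sire_of_brood)

  founders <- data.frame(
    id = c(dam_ids, sire_ids),
    dam = NA_character_, sire = NA_character_,
    sex = c(rep("female", nb), rep("male", length(sire_ids))),
    generation = "P",
    brood = NA_character_,
    sire_known = NA,
    stringsAsFactors = FALSE)

  off <- do.call(rbind, lapply(seq_len(nb), function(j) {
    k <- sizes[j]
    data.frame(
      id = sprintf("B%02d_%02d", j, seq_len(k)),
      dam = dam_ids[j], sire = sire_of_brood[j],
      sex = sample(c("female", "male"), k, replace = TRUE),
      generation = "F1",
      brood = sprintf("B%02d", j),
      sire_known = sire_known[j],
      stringsAsFactors = FALSE)
  }))
  ped <- rbind(founders, off)
  validate_pedigree(ped)
}

#' Simulate common-garden phenotypes over a pedigree
#'
#' Generates per-individual total cyanogen concentrations under the additive
#' generative model: phenotype = mu + sex effect + treatment effect +
#' breeding value + maternal term + residual. Breeding values are drawn
#' multivariate normal with covariance \code{V_A * A} (A the additive
#' relationship matrix). The maternal term is either a dam-level normal
#' deviate with variance \code{V_mat}, or, in Falconer transmission mode,
#' \code{m * (dam phenotype - mu)}; founders receive phenotypes first so the
#' Falconer mode is well defined. Offspring of the designated treatment
#' broods are split equally (remainders at random) across the treatment
#' levels; all other individuals receive the standard diet (\code{"std"},
#' effect 0).
#'
#' @param pedigree a pedigree from [make_pedigree()] (or any validated
#'   pedigree carrying \code{brood} and \code{generation} columns).
#' @param config the [sim_config()] used for the pedigree.
#' @return A phenotype table: \code{id}, \code{brood}, \code{dam},
#'   \code{sire}, \code{sex}, \code{generation}, \code{treatment},
#'   \code{linamarin}, \code{lotaustralin}, \code{total} (% dry mass;
#'   \code{total = linamarin + lotaustralin} exactly). Negative draws are
#'   truncated at zero (concentrations are nonnegative).
#' @export
simulate_breeding_phenotypes <- function(pedigree, config) {
  cfg <- validate_sim_config(config)
  ped <- if (inherits(pedigree, "pedigree_table")) pedigree else
    validate_pedigree(pedigree)
  set.seed(cfg$seed + 1L)
  n <- nrow(ped)
  ids <- ped$id

  # breeding values: L z with L' L ... chol gives upper triangular R, use t(R)
  a <- numeric(n)
  if (cfg$V_A > 0) {
    A <- additive_relationship_matrix(ped)
    R <- chol(A)
    a <- sqrt(cfg$V_A) * drop(crossprod(R, stats::rnorm(n)))
  }

  # treatment assignment: within-brood equal splits for the first
  # n_treatment_broods broods (study design: eggs divided equally)
  treatment <- rep("std", n)
  broods <- unique(stats::na.omit(ped$brood))
  trt_broods <- utils::head(broods, cfg$n_treatment_broods)
  trt_levels <- names(cfg$treatment_effects)
  if (!is.null(cfg$treatment_effects) && length(trt_levels) > 0) {
    for (bj in trt_broods) {
      rows <- which(!is.na(ped$brood) & ped$brood == bj)
      reps <- ceiling(length(rows) / length(trt_levels))
      lab <- sample(rep(trt_levels, reps))[seq_along(rows)]
      treatment[rows] <- lab
    }
  }
  trt_eff <- c(std = 0, cfg$treatment_effects)[treatment]

  sex_eff <- ifelse(ped$sex == "male", cfg$sex_effect, 0)
  resid <- stats::rnorm(n, 0, sqrt(cfg$V_R))

  # maternal term, in pedigree (topological) order so dams precede offspring
  pheno <- numeric(n)
  has_dam <- !is.na(ped$dam)
  mat_term <- numeric(n)
  if (cfg$V_mat > 0) {
    dams <- unique(ped$dam[has_dam])
    dev <- stats::setNames(stats::rnorm(length(dams), 0, sqrt(cfg$V_mat)),
                           dams)
    mat_term[has_dam] <- dev[ped$dam[has_dam]]
    pheno <- cfg$mu + sex_eff + trt_eff + a + mat_term + resid
  } else if (cfg$m_transmission != 0) {
    pos <- stats::setNames(seq_len(n), ids)
    for (i in seq_len(n)) {
      m_i <- 0
      if (has_dam[i]) {
        d <- pos[[ped$dam[i]]]
        if (d >= i) stop("Falconer mode requires dam phenotypes to be ",
                         "generated before offspring; dam ", ped$dam[i],
                         " lacks a phenotype")
        m_i <- cfg$m_transmission * (pheno[d] - cfg$mu)
      }
      pheno[i] <- cfg$mu + sex_eff[i] + trt_eff[i] + a[i] + m_i + resid[i]
      mat_term[i] <- m_i
    }
  } else {
    pheno <- cfg$mu + sex_eff + trt_eff + a + resid
  }

  total <- pmax(pheno, 0)
  lot <- draw_lot_fraction(n, cfg$lotaustralin_fraction,
                           cfg$lotaustralin_dispersion) * total
  lin <- total - lot
  total <- lin + lot   # re-sum so the composition identity is exact
  out <- data.frame(id = ids, brood = ped$brood, dam = ped$dam,
                    sire = ped$sire, sex = ped$sex,
                    generation = ped$generation,
                    treatment = treatment,
                    linamarin = lin, lotaustralin = lot,
                    total = total,
                    stringsAsFactors = FALSE)
  # phantom sires have no phenotype record
  out <- out[!startsWith(out$id, "PS"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a wild-collected field sample of butterfly toxin concentrations
#'
#' Draws right-skewed nonnegative total cyanogen concentrations from a gamma
#' or log-normal law parameterized by mean and SD (method of moments), with
#' an optional point mass at exact zero representing below-detection samples.
#'
#' @param n sample size (>= 1).
#' @param mean,sd mean and SD of the positive component, % dry mass.
#' @param family \code{"gamma"} or \code{"lognormal"}.
#' @param p_zero probability of an exact zero (below detection limit).
#' @param population label recorded in the \code{population} column.
#' @param lotaustralin_fraction mean fraction of the total that is
#'   lotaustralin.
#' @param lotaustralin_dispersion Beta concentration of the per-individual
#'   fraction; 0 fixes it exactly.
#' @param seed integer RNG seed.
#' @return Data frame: \code{id}, \code{population}, \code{linamarin},
#'   \code{lotaustralin}, \code{total}, all concentrations >= 0 and
#'   \code{total = linamarin + lotaustralin} exactly.
#' @export
simulate_field_population <- function(n, mean, sd, family = c("gamma", "lognormal"),
                                      p_zero = 0, population = "pop",
                                      lotaustralin_fraction = 0.25,
                                      lotaustralin_dispersion = 200,
                                      seed = 1L) {
  family <- match.arg(family)
  if (n < 1) stop("n must be >= 1")
  if (mean <= 0 || sd < 0) stop("positive-component mean must be > 0, sd >= 0")
  if (p_zero < 0 || p_zero > 1) stop("p_zero must be in [0, 1]")
  if (lotaustralin_fraction < 0 || lotaustralin_fraction > 1)
    stop("lotaustralin_fraction must be in [0, 1]")
  set.seed(seed)
  total <- if (sd == 0) rep(mean, n) else if (family == "gamma") {
    shape <- (mean / sd)^2
    stats::rgamma(n, shape = shape, rate = shape / mean)
  } else {
    s2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  }
  if (p_zero > 0) total[stats::runif(n) < p_zero] <- 0
  if (lotaustralin_dispersion < 0) stop("lotaustralin_dispersion must be >= 0")
  lot <- draw_lot_fraction(n, lotaustralin_fraction,
                           lotaustralin_dispersion) * total
  lin <- total - lot
  data.frame(id = sprintf("%s_%03d", population, seq_len(n)),
             population = population,
             linamarin = lin, lotaustralin = lot, total = lin + lot,
             stringsAsFactors = FALSE)
}

#' Simulate host-plant leaf cyanogen samples
#'
#' Draws per-leaf-sample total cyanogen content (gamma by moments; constant
#' when SD is zero) for one or more collection sites, optionally crossed with
#' plant origin and watering-treatment factors for the greenhouse design.
#'
#' @param site_means data frame with columns \code{site}, \code{mean},
#'   \code{sd} (ug/mg) and optionally \code{origin} and \code{treatment}.
#' @param n_per_site integer vector of samples per row of \code{site_means}
#'   (recycled if scalar).
#' @param seed integer RNG seed.
#' @return Data frame with \code{id}, \code{site}, optional \code{origin} and
#'   \code{treatment}, and \code{total_cyanogens} >= 0.
#' @export
simulate_hostplants <- function(site_means, n_per_site, seed = 1L) {
  stopifnot(is.data.frame(site_means),
            all(c("site", "mean", "sd") %in% names(site_means)))
  if (any(site_means$mean < 0)) stop("site means must be >= 0")
  if (any(site_means$sd < 0)) stop("negative SD rejected")
  n_per_site <- rep_len(as.integer(n_per_site), nrow(site_means))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(site_means)), function(r) {
    m <- site_means$mean[r]; s <- site_means$sd[r]; k <- n_per_site[r]
    vals <- if (s == 0 || m == 0) rep(m, k) else {
      shape <- (m / s)^2
      stats::rgamma(k, shape = shape, rate = shape / m)
    }
    d <- data.frame(id = sprintf("%s_P%03d", site_means$site[r], seq_len(k)),
                    site = site_means$site[r],
                    total_cyanogens = vals,
                    stringsAsFactors = FALSE)
    for (col in c("origin", "treatment"))
      if (col %in% names(site_means)) d[[col]] <- site_means[[col]][r]
    d
  }))
  rownames(out) <- NULL
  out
}
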