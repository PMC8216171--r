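# Shared fixtures: small pedigrees and quick simulation configs.

# two unrelated parents and their full-sib offspring, plus a maternal
# half-sib brood via a second dam sharing the sire
nuclear_pedigree <- function() {
  data.frame(
    id   = c("d1", "s1", "d2", "o1", "o2", "h1"),
    dam  = c(NA, NA, NA, "d1", "d1", "d2"),
    sire = c(NA, NA, NA, "s1", "s1", "s1"),
    sex  = c("female", "male", "female", "unknown", "unknown", "unknown"),
    stringsAsFactors = FALSE)
}

# random multi-generation pedigree: founders plus `n_extra` individuals whose
# parents are drawn from earlier individuals (dams from females, sires from
# males), giving assorted full-sib / half-sib / parent-offspring /
# grandparent links for the kinship cross-check
random_pedigree <- function(n_founders = 8, n_extra = 16, seed = 1) {
  set.seed(seed)
  sex <- c(rep(c("female", "male"), length.out = n_founders),
           sample(c("female", "male"), n_extra, replace = TRUE))
  id <- sprintf("I%02d", seq_len(n_founders + n_extra))
  dam <- rep(NA_character_, n_founders + n_extra)
  sire <- rep(NA_character_, n_founders + n_extra)
  for (i in (n_founders + 1):(n_founders + n_extra)) {
    prev <- seq_len(i - 1)
    fem <- prev[sex[prev] == "female"]
    mal <- prev[sex[prev] == "male"]
    dam[i] <- id[if (length(fem) == 1) fem else sample(fem, 1)]
    sire[i] <- id[if (length(mal) == 1) mal else sample(mal, 1)]
  }
  data.frame(id = id, dam = dam, sire = sire, sex = sex,
             stringsAsFactors = FALSE)
}

# small, fast breeding-design config without fixed effects (pure
# additive-genetic + residual), for estimator checks
recovery_config <- function(seed, n_broods = 20L, offspring = 16L,
                            V_A = 0.0093, V_R = 0.071,
                            V_mat = 0, m = 0) {
  sim_config(n_broods = n_broods, offspring_per_brood = offspring,
             n_shared_sire_pairs = 1L, n_unknown_sire_broods = 0L,
             n_treatment_broods = 0L, sex_effect = 0,
             treatment_effects = NULL,
             V_A = V_A, V_mat = V_mat, m_transmission = m, V_R = V_R,
             seed = seed)
}

# restricted log-likelihood of the intercept-only iid model (the reduced
# model when the single variance component is dropped), on the same
# reparameterization-invariant scale the package uses
null_model_loglik <- function(phenos, trait = "total") {
  y <- phenos[[trait]]
  n <- length(y); p <- 1
  rss <- sum((y - mean(y))^2)
  s2 <- rss / (n - p)
  -0.5 * (n - p) * (log(2 * pi) + log(s2) + 1)
}

simulate_design <- function(cfg) {
  ped <- make_pedigree(cfg)
  list(ped = ped,
       phenos = simulate_breeding_phenotypes(ped, cfg),
       A = additive_relationship_matrix(ped))
}
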