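test_that("degenerate data yields zero components and a flag", {
  ph <- data.frame(id = sprintf("i%02d", 1:20),
                   brood = rep(c("b1", "b2"), each = 10),
                   total = rep(0.5, 20))
  fit <- fit_animal_model(ph, NULL,
                          model_spec(fixed_effects = character(0),
                                     random_effects = "brood"))
  expect_true(fit$degenerate)
  expect_equal(unname(fit$components["V_P"]), 0)
})

test_that("REML on a balanced one-way layout matches the ANOVA closed form", {
  # balanced full-sib families treated as iid groups: when the ANOVA
  # estimator is interior, REML equals sigma2_b = (MSB - MSW) / k
  set.seed(31)
  J <- 12; k <- 8
  g <- rep(sprintf("f%02d", 1:J), each = k)
  y <- rep(rnorm(J, 0, sqrt(0.4)), each = k) + rnorm(J * k, 0, 1)
  ph <- data.frame(id = sprintf("i%03d", seq_along(y)), brood = g, total = y)
  fit <- fit_animal_model(ph, NULL,
                          model_spec(fixed_effects = character(0),
                                     random_effects = "brood"))
  gm <- tapply(y, g, mean)
  msb <- k * sum((gm - mean(y))^2) / (J - 1)
  msw <- sum((y - gm[g])^2) / (J * (k - 1))
  expect_gt(msb, msw)  # interior case
  expect_equal(unname(fit$sigma2["V_brood"]), (msb - msw) / k,
               tolerance = 1e-6)
  expect_equal(unname(fit$sigma2["V_R"]), msw, tolerance = 1e-6)
})

test_that("optimizer solution matches a dense grid search on a small pedigree", {
  cfg <- recovery_config(seed = 17, n_broods = 5L, offspring = 5L,
                         V_A = 0.02, V_R = 0.06)
  d <- simulate_design(cfg)
  spec <- model_spec(fixed_effects = character(0))
  fit <- fit_animal_model(d$phenos, d$A, spec)
  grid_a <- seq(1e-4, 0.06, length.out = 60)
  grid_e <- seq(0.01, 0.12, length.out = 60)
  ll <- outer(grid_a, grid_e, Vectorize(function(va, ve)
    restricted_loglik(d$phenos, d$A, spec, c(V_G = va, V_R = ve))))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(unname(fit$sigma2["V_G"]) - grid_a[best[1]]),
            diff(grid_a[1:2]))
  expect_lt(abs(unname(fit$sigma2["V_R"]) - grid_e[best[2]]),
            diff(grid_e[1:2]))
  # and the optimizer's criterion beats every grid point
  expect_gte(restricted_loglik(d$phenos, d$A, spec,
                               c(fit$sigma2["V_G"], fit$sigma2["V_R"])),
             max(ll) - 1e-8)
})

test_that("restricted likelihood limits and equivariances hold", {
  cfg <- recovery_config(seed = 23, n_broods = 6L, offspring = 5L)
  d <- simulate_design(cfg)
  spec <- model_spec(fixed_effects = character(0))

  # sigma2_A = 0 reduces to the independent-errors restricted likelihood
  s2 <- 0.07
  n <- nrow(d$phenos); p <- 1
  y <- d$phenos$total
  rss <- sum((y - mean(y))^2)
  # log|V| + log|X'V^-1 X| - log|X'X| collapses to (n - p) log s2 here
  ll_iid <- -0.5 * ((n - p) * log(2 * pi) + (n - 1) * log(s2) + rss / s2)
  expect_equal(restricted_loglik(d$phenos, d$A, spec,
                                 c(V_G = 0, V_R = s2)),
               ll_iid, tolerance = 1e-8)

  # scaling data by c and variances by c^2 shifts the criterion by the
  # Jacobian term -(n - p) log c only
  cc <- 2.5
  ph2 <- d$phenos; ph2$total <- cc * ph2$total
  l1 <- restricted_loglik(d$phenos, d$A, spec, c(V_G = 0.01, V_R = 0.07))
  l2 <- restricted_loglik(ph2, d$A, spec,
                          c(V_G = 0.01 * cc^2, V_R = 0.07 * cc^2))
  expect_equal(l2, l1 - (n - 1) * log(cc), tolerance = 1e-8)

  # invariance to fixed-effect reparameterization: recoding the sex factor
  cfg2 <- sim_config(seed = 29, n_broods = 6L, offspring_per_brood = 6L,
                     n_shared_sire_pairs = 0L, n_unknown_sire_broods = 0L,
                     n_treatment_broods = 0L, treatment_effects = NULL)
  d2 <- simulate_design(cfg2)
  spec2 <- model_spec(fixed_effects = "sex")
  l3 <- restricted_loglik(d2$phenos, d2$A, spec2, c(V_G = 0.01, V_R = 0.07))
  ph3 <- d2$phenos
  ph3$sex <- factor(ph3$sex, levels = c("male", "female"))  # flipped baseline
  l4 <- restricted_loglik(ph3, d2$A, spec2, c(V_G = 0.01, V_R = 0.07))
  expect_equal(l3, l4, tolerance = 1e-8)
})

test_that("REML fit is invariant to row order and relabeling", {
  cfg <- recovery_config(seed = 41, n_broods = 8L, offspring = 6L)
  d <- simulate_design(cfg)
  spec <- model_spec(fixed_effects = character(0))
  fit1 <- fit_animal_model(d$phenos, d$A, spec)
  set.seed(1)
  perm <- sample(nrow(d$phenos))
  fit2 <- fit_animal_model(d$phenos[perm, ], d$A, spec)
  expect_equal(fit1$sigma2, fit2$sigma2, tolerance = 1e-6)
  expect_equal(fit1$restricted_loglik, fit2$restricted_loglik,
               tolerance = 1e-6)
})

test_that("LRT p-values follow the 50:50 chi-square mixture", {
  mk <- function(ll, res) {
    structure(list(spec = structure(list(trait = "total",
                                         fixed_effects = character(0),
                                         random_effects = res),
                                    class = "model_spec"),
                   restricted_loglik = ll), class = "animal_model_fit")
  }
  full <- mk(-10, c("animal", "brood"))
  red <- mk(-10, "brood")
  expect_equal(lrt_variance_component(full, red), 0.5)
  red2 <- mk(-10 - 2.706 / 2, "brood")
  expect_equal(lrt_variance_component(full, red2), 0.05, tolerance = 1e-3)
  # non-nested specs rejected
  other <- mk(-9, c("maternal_identity"))
  expect_error(lrt_variance_component(full, other), "not nested")
})

test_that("LRT holds its nominal size under the null", {
  # V_A = 0: rejection rate at alpha = 0.05 stays within the binomial band
  rej <- vapply(1:200, function(r) {
    cfg <- recovery_config(seed = 60000 + r, n_broods = 10L, offspring = 6L,
                           V_A = 0, V_R = 0.071)
    d <- simulate_design(cfg)
    spec_full <- model_spec(fixed_effects = character(0),
                            random_effects = c("animal"))
    full <- fit_animal_model(d$phenos, d$A, spec_full)
    red <- null_model_loglik(d$phenos)
    p <- 0.5 * pchisq(max(0, 2 * (full$restricted_loglik - red)), 1,
                      lower.tail = FALSE)
    p < 0.05
  }, logical(1))
  # boundary tests are conservative at small n; the rate should not exceed
  # the nominal level beyond binomial noise
  expect_lt(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("fixed-effect variances match their closed forms", {
  cfg <- sim_config(n_broods = 10L, offspring_per_brood = 10L,
                    n_shared_sire_pairs = 0L, n_unknown_sire_broods = 0L,
                    n_treatment_broods = 10L, sex_effect = 0.2,
                    treatment_effects = c(a = -0.1, b = 0.1, c = 0.3, d = 0.5),
                    seed = 77)
  d <- simulate_design(cfg)
  fit <- fit_animal_model(d$phenos, d$A, model_spec())
  # brute-force recomputation from the design matrix and coefficients
  for (eff in c("sex", "treatment")) {
    cols <- grep(paste0("^", eff), colnames(fit$X))
    pred <- drop(fit$X[, cols, drop = FALSE] %*%
                   fit$fixed_coefficients$estimate[cols])
    expect_equal(fixed_effect_variance(fit, eff),
                 mean((pred - mean(pred))^2))
  }
  # two equal-frequency sexes with effect d have variance d^2 / 4
  ph <- data.frame(id = sprintf("i%02d", 1:40),
                   brood = rep(c("b1", "b2", "b3", "b4"), each = 10),
                   sex = rep(c("female", "male"), 20),
                   total = rnorm(40))
  ph$total <- ph$total + ifelse(ph$sex == "male", 0.3, 0)
  fit2 <- fit_animal_model(ph, NULL, model_spec(fixed_effects = "sex",
                                                random_effects = "brood"))
  dd <- fit2$fixed_coefficients["sexmale", "estimate"]
  expect_equal(fixed_effect_variance(fit2, "sex"), dd^2 / 4)
  expect_error(fixed_effect_variance(fit2, "treatment"), "not in model")
})

test_that("maternal variance is recovered and trades off against V_G", {
  # data generated with dam-level variance: Model2 assigns it to V_mat and
  # Model1's V_G absorbs approximately V_G + V_mat
  reps <- 30
  out <- vapply(1:reps, function(r) {
    cfg <- recovery_config(seed = 7000 + r, n_broods = 16L, offspring = 10L,
                           V_A = 0, V_mat = 0.012, V_R = 0.06)
    d <- simulate_design(cfg)
    m1 <- fit_animal_model(d$phenos, d$A, model_spec(fixed_effects = character(0)))
    m2 <- fit_animal_model(d$phenos, d$A,
                           model_spec(fixed_effects = character(0),
                                      random_effects = c("animal", "maternal_identity")))
    c(vg1 = unname(m1$components["V_G"]),
      vg2 = unname(m2$components["V_G"]),
      vm2 = unname(m2$components["V_mat"]))
  }, numeric(3))
  vm <- out["vm2", ]
  se <- sd(vm) / sqrt(reps)
  expect_lt(abs(mean(vm) - 0.012), 2 * se + 0.003)
  # the trade-off: V_G(Model1) ~ V_G(Model2) + V_mat(Model2)
  expect_lt(abs(mean(out["vg1", ]) - mean(out["vg2", ] + out["vm2", ])),
            0.004)
})
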