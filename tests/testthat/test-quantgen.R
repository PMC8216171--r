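test_that("heritability and evolvability follow their definitions", {
  comps <- c(V_G = 0.0093, V_mat = 0, V_sex = 0.0009, V_trm = 0.0009,
             V_R = 0.069)
  expect_equal(broad_sense_heritability(comps),
               0.0093 / (0.0093 + 0.0009 + 0.069))
  expect_equal(broad_sense_heritability(comps, denominator = "full"),
               0.0093 / sum(comps))
  expect_equal(broad_sense_heritability(c(V_G = 0, V_R = 1)), 0)
  expect_equal(broad_sense_heritability(c(V_G = 0.4, V_mat = 0, V_sex = 0,
                                          V_R = 0)), 1)
  expect_equal(mean_scaled_evolvability(0.0063, 0.577),
               100 * 0.0063 / 0.577^2)
  expect_equal(mean_scaled_evolvability(0, 2), 0)
  expect_error(mean_scaled_evolvability(0.01, 0), "mean")
})

test_that("heritability and evolvability are scale consistent", {
  # multiplying phenotypes by c scales variances by c^2 and the mean by c,
  # leaving both metrics unchanged
  comps <- c(V_G = 0.01, V_mat = 0.002, V_sex = 0.001, V_trm = 0.003,
             V_R = 0.07)
  mu <- 0.772
  for (cc in c(0.5, 3)) {
    expect_equal(broad_sense_heritability(comps * cc^2),
                 broad_sense_heritability(comps))
    expect_equal(mean_scaled_evolvability(0.01 * cc^2, mu * cc),
                 mean_scaled_evolvability(0.01, mu))
  }
})

test_that("repeatability equals the closed-form ICC on balanced data and 1 when exact", {
  # zero within-group variance, unequal group means -> R = 1
  ph <- data.frame(id = sprintf("i%02d", 1:12),
                   brood = rep(c("a", "b", "c"), each = 4),
                   total = rep(c(0.3, 0.6, 0.9), each = 4))
  r1 <- estimate_repeatability(ph, n_boot = 10, seed = 1)
  expect_equal(r1$R, 1, tolerance = 1e-6)

  # balanced groups: R = (MSB - MSW) / (MSB + (k - 1) MSW) when interior
  set.seed(5)
  J <- 10; k <- 6
  g <- rep(sprintf("g%02d", 1:J), each = k)
  y <- rep(rnorm(J, 0, 0.6), each = k) + rnorm(J * k)
  ph2 <- data.frame(id = seq_along(y), brood = g, total = y)
  est <- estimate_repeatability(ph2, n_boot = 10, seed = 2)
  gm <- tapply(y, g, mean)
  msb <- k * sum((gm - mean(y))^2) / (J - 1)
  msw <- sum((y - gm[g])^2) / (J * (k - 1))
  expect_equal(est$R, (msb - msw) / (msb + (k - 1) * msw), tolerance = 1e-6)

  # cross-check variance components against lme4 on the same data
  lf <- lme4::lmer(total ~ (1 | brood), data = ph2, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(est$V_group, vc[1], tolerance = 1e-6)
  expect_equal(est$V_resid, vc[2], tolerance = 1e-6)

  expect_error(estimate_repeatability(ph2[1:6, ], n_boot = 10), "2 groups")
  expect_error(estimate_repeatability(ph2, n_boot = 1), "n_boot")
})

test_that("bootstrap CIs are deterministic under a fixed seed and well ordered", {
  set.seed(8)
  g <- rep(sprintf("g%02d", 1:12), each = 5)
  y <- rep(rnorm(12, 0, 0.4), each = 5) + rnorm(60)
  ph <- data.frame(id = seq_along(y), brood = g, total = y)
  a <- estimate_repeatability(ph, n_boot = 200, seed = 99)
  b <- estimate_repeatability(ph, n_boot = 200, seed = 99)
  expect_identical(a$CI, b$CI)
  expect_true(a$CI[1] >= 0 && a$CI[1] <= a$CI[2] && a$CI[2] <= 1)
  expect_true(a$R >= 0 && a$R <= 1)
})

test_that("parent-offspring regressions recover copied values and h2/2", {
  # offspring identical to the parent value -> slope exactly 1
  fams <- sprintf("f%02d", 1:15)
  pv <- seq(0.2, 1.6, length.out = 15)
  ph <- rbind(
    data.frame(id = paste0("d", 1:15), brood = NA, dam = NA, sire = NA,
               sex = "female", generation = "P", total = pv),
    data.frame(id = paste0("s", 1:15), brood = NA, dam = NA, sire = NA,
               sex = "male", generation = "P", total = rnorm(15, 1, 0.3)),
    data.frame(id = paste0("o", rep(1:15, each = 3), letters[1:3]),
               brood = rep(fams, each = 3), dam = rep(paste0("d", 1:15), each = 3),
               sire = rep(paste0("s", 1:15), each = 3),
               sex = "unknown", generation = "F1",
               total = rep(pv, each = 3)))
  mo <- parent_offspring_regression(ph, "mother")
  expect_equal(mo$slope, 1, tolerance = 1e-8)

  # purely additive inheritance: each parental slope approaches h2 / 2
  cfg <- recovery_config(seed = 314, n_broods = 60L, offspring = 12L,
                         V_A = 0.03, V_R = 0.05)
  d <- simulate_design(cfg)
  h2 <- 0.03 / 0.08
  mo2 <- parent_offspring_regression(d$phenos, "mother")
  fo2 <- parent_offspring_regression(d$phenos, "father")
  expect_lt(abs(mo2$slope - h2 / 2), 3 * mo2$SE)
  expect_lt(abs(fo2$slope - h2 / 2), 3 * fo2$SE)

  expect_error(parent_offspring_regression(ph[1:31, ], "mother"), "3 families")
})

test_that("maternal-effect coefficient is the slope difference with a sound bootstrap", {
  # identical mother and father values force m = 0 exactly
  fams <- sprintf("f%02d", 1:12)
  pv <- seq(0.3, 1.4, length.out = 12)
  mk <- function(par_prefix, sex) {
    data.frame(id = paste0(par_prefix, 1:12), brood = NA, dam = NA, sire = NA,
               sex = sex, generation = "P", total = pv)
  }
  set.seed(6)
  off <- data.frame(id = paste0("o", rep(1:12, each = 4), letters[1:4]),
                    brood = rep(fams, each = 4),
                    dam = rep(paste0("d", 1:12), each = 4),
                    sire = rep(paste0("s", 1:12), each = 4),
                    sex = "unknown", generation = "F1",
                    total = rep(pv, each = 4) * 0.4 + rnorm(48, 0.5, 0.1))
  ph <- rbind(mk("d", "female"), mk("s", "male"), off)
  me <- maternal_effect_coefficient(ph, n_boot = 50, seed = 3)
  expect_equal(me$m, 0, tolerance = 1e-8)
  expect_equal(me$m, me$beta_mo$slope - me$beta_fo$slope)

  # deterministic under seed
  me2 <- maternal_effect_coefficient(ph, n_boot = 50, seed = 3)
  expect_identical(me$m_CI, me2$m_CI)
})

test_that("compound projection follows the multiplicative formula", {
  expect_equal(project_compound_response(1.55, 1, 6),
               100 * (1.0155^6 - 1))
  # one generation returns e * beta
  expect_equal(project_compound_response(2.0, 0.5, 1), 1.0)
  expect_equal(project_compound_response(1.55, 1, 2), 3.124, tolerance = 1e-3)
  expect_equal(project_compound_response(1.55, 1, 0), 0)
  # monotone nondecreasing in g for positive e * beta
  vals <- vapply(0:10, function(g) project_compound_response(1.55, 1, g),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("maternal-transmission trajectories bracket the breeder's equation", {
  h2 <- 0.115
  # m = 0 equals the cumulative breeder's-equation response exactly
  tr0 <- falconer_response_trajectory(h2, 0, 1, 10)
  expect_equal(tr0$cumulative, h2 * (1:10))
  expect_equal(tr0$excess_ratio, 1)

  # m = 0.25 exceeds the m = 0 trajectory for every g >= 2 and approaches
  # the geometric-series ratio 1 / (1 - m)
  tr <- falconer_response_trajectory(h2, 0.25, 1, 400)
  expect_true(all(tr$cumulative[2:400] > tr$cumulative_m0[2:400]))
  expect_equal(tr$excess_ratio, 1 / 0.75, tolerance = 1e-2)
  # closed form per generation: R_t = h2 * (1 - m^t) / (1 - m)
  expect_equal(tr$trajectory[1:5],
               h2 * (1 - 0.25^(1:5)) / 0.75, tolerance = 1e-10)

  expect_error(falconer_response_trajectory(h2, 1, 1, 5), "diverges")

  # pluggable recursion
  alt <- falconer_response_trajectory(h2, 0.25, 1, 5,
                                      recursion = function(R, h2, S, m) h2 * S)
  expect_equal(alt$cumulative, h2 * (1:5))
})
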