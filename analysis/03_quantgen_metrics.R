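#!/usr/bin/env Rscript
# Step 3 — derived quantitative-genetic metrics.
#
# From the Model 1 fit: broad-sense heritability (both denominator
# conventions) and mean-scaled evolvability. From the raw common-garden
# offspring: brood repeatability (ICC) with 1,000 parametric bootstraps,
# parent-offspring regressions, and the Falconer maternal-effect
# coefficient m = beta_mo - beta_fo with a 1,000-draw cluster bootstrap CI.

suppressPackageStartupMessages(library(cyanoquant))

seed <- 20260929L
ped <- read_pedigree_table("results/data/pedigree.csv")
phenos <- read_phenotype_table("results/data/common_garden.csv")
A <- additive_relationship_matrix(ped)

fit <- fit_animal_model(phenos, A, model_spec())
V_G <- unname(fit$components["V_G"])
mu <- mean(phenos$total)

h2_text <- broad_sense_heritability(fit$components)
h2_full <- broad_sense_heritability(fit$components, denominator = "full")
e_mu <- mean_scaled_evolvability(V_G, mu)
message(sprintf("V_G = %.4f, mu = %.3f", V_G, mu))
message(sprintf("H2 = %.3f (treatment excluded) / %.3f (full V_P)",
                h2_text, h2_full))
message(sprintf("e_mu = %.2f%% per generation under unit selection", e_mu))

off <- phenos[phenos$generation == "F1", ]
icc <- estimate_repeatability(off, n_boot = 1000, seed = seed)
print(icc)

me <- maternal_effect_coefficient(phenos, n_boot = 1000, seed = seed)
message("parent-offspring regressions and maternal-effect coefficient:")
print(me$beta_mo); print(me$beta_fo)
if (!is.null(me$beta_mid)) print(me$beta_mid)
print(me)

metrics <- data.frame(
  metric = c("V_G", "mu", "H2_excl_treatment", "H2_full_VP", "e_mu_percent",
             "repeatability_R", "repeatability_SE", "repeatability_CI_lo",
             "repeatability_CI_hi", "repeatability_p",
             "beta_mother_offspring", "beta_father_offspring",
             "beta_midparent", "m", "m_CI_lo", "m_CI_hi"),
  value = c(V_G, mu, h2_text, h2_full, e_mu,
            icc$R, icc$SE, icc$CI[1], icc$CI[2], icc$p,
            me$beta_mo$slope, me$beta_fo$slope,
            if (is.null(me$beta_mid)) NA else me$beta_mid$slope,
            me$m, me$m_CI[1], me$m_CI[2]))
write.csv(metrics, "results/quantgen_metrics.csv", row.names = FALSE)
message("wrote results/quantgen_metrics.csv")
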