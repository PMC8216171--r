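#!/usr/bin/env Rscript
# Step 5 — field-survey statistics.
#
# Population comparisons of wild butterflies and host plants along the
# rainfall gradient (square-root ANOVA + Tukey HSD), the greenhouse
# origin x watering factorial, zero-truncated density estimates, skew and
# detection summaries, compound correlation, and the parent-vs-offspring
# generation contrast (Hedges' g).

suppressPackageStartupMessages(library(cyanoquant))

field <- read_phenotype_table("results/data/field_butterflies.csv")
plants <- read.csv("results/data/field_hostplants.csv")
greenhouse <- read.csv("results/data/greenhouse_hostplants.csv")
phenos <- read_phenotype_table("results/data/common_garden.csv")
dir.create("results", showWarnings = FALSE)

## Panamanian butterflies: population ANOVA on the sqrt scale ---------------
pan <- field[startsWith(field$population, "Panama"), ]
for (trait in c("total", "lotaustralin")) {
  an <- sqrt_anova(pan[[trait]], pan$population)
  message(sprintf("%s: F(%d,%d) = %.2f, P = %.3g", trait,
                  an$df_between, an$df_within, an$F, an$p))
}
an_tot <- sqrt_anova(pan$total, pan$population)
write.csv(tukey_hsd(an_tot), "results/field_butterfly_tukey.csv",
          row.names = FALSE)

## host plants along the gradient -------------------------------------------
an_pl <- sqrt_anova(plants$total_cyanogens, plants$site)
message(sprintf("host plants: F(%d,%d) = %.2f, P = %.3g",
                an_pl$df_between, an_pl$df_within, an_pl$F, an_pl$p))
write.csv(tukey_hsd(an_pl), "results/hostplant_tukey.csv", row.names = FALSE)

## greenhouse factorial ------------------------------------------------------
fa <- factorial_anova(greenhouse$total_cyanogens, greenhouse$origin,
                      greenhouse$treatment)
message("greenhouse origin x watering ANOVA:")
print(as.data.frame(fa), row.names = FALSE)
write.csv(as.data.frame(fa), "results/greenhouse_anova.csv",
          row.names = FALSE)

## distribution shape --------------------------------------------------------
dens <- do.call(rbind, lapply(split(pan, pan$population), function(d) {
  k <- truncated_weighted_kde(d$total)
  data.frame(population = d$population[1], grid = k$grid,
             density = k$density)
}))
write.csv(dens, "results/field_density_grids.csv", row.names = FALSE)

sk <- range_quartile_summary(pan$total, threshold = 0.5)
message(sprintf("range %.2f-%.2f%%: %.0f%% of individuals in the lower range quarter, %.0f%% in the upper, %.0f%% below 0.5%%",
                sk$range_min, sk$range_max, 100 * sk$frac_lower_quarter,
                100 * sk$frac_upper_quarter, 100 * sk$frac_below_threshold))

ecu <- field[startsWith(field$population, "Ecuador"), ]
det <- detection_summary(ecu$linamarin, limit = 0)
message(sprintf("Ecuador: linamarin detected in %.0f%% of samples; mean of detected = %.3f%%",
                100 * det$frac_detected, det$mean_detected))

## compound correlation and generation contrast ------------------------------
r <- pearson_correlation(phenos$linamarin, phenos$lotaustralin)
message(sprintf("linamarin vs lotaustralin: r = %.3f, P = %.3g", r$r, r$p))
g <- hedges_g(phenos$total[phenos$generation == "P"],
              phenos$total[phenos$generation == "F1"])
message(sprintf("parental vs offspring generation, Hedges' g = %.3f", g))
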