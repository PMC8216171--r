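#!/usr/bin/env Rscript
# Step 1 — generate the study's data layer.
#
# Produces (i) a two-generation full-sib/half-sib common-garden breeding
# design (20 broods, ~322 pedigreed individuals, 6 broods split across four
# host-plant feeding treatments, one paternal half-sib brood pair), (ii)
# wild-collected butterfly samples from the three Panamanian rainfall-
# gradient populations and the two Ecuadorian altitude populations, and
# (iii) host-plant leaf samples for the same gradient. All tables go to
# results/data/ as CSV.

suppressPackageStartupMessages(library(cyanoquant))

seed <- 20260929L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

## common-garden breeding design -------------------------------------------
cfg <- sim_config(seed = seed)
ped <- make_pedigree(cfg)
phenos <- simulate_breeding_phenotypes(ped, cfg)
write_pedigree_table(ped, "results/data/pedigree.csv")
write_phenotype_table(phenos, "results/data/common_garden.csv")
message(sprintf("breeding design: %d pedigree rows, %d phenotyped (%d broods)",
                nrow(ped), nrow(phenos),
                length(unique(na.omit(phenos$brood)))))

## field butterflies ---------------------------------------------------------
# site-level mean/SD on the % dry mass scale; the Ecuadorian populations are
# dominated by below-detection zeros
field <- rbind(
  simulate_field_population(34, 1.064, 0.709, population = "Panama_Dry",
                            seed = seed + 1),
  simulate_field_population(28, 1.271, 0.631, population = "Panama_Int",
                            seed = seed + 2),
  simulate_field_population(30, 0.907, 0.521, population = "Panama_Wet",
                            seed = seed + 3),
  simulate_field_population(21, 0.063, 0.030, p_zero = 0.71,
                            population = "Ecuador_Low", seed = seed + 4),
  simulate_field_population(21, 0.063, 0.030, p_zero = 0.71,
                            population = "Ecuador_High", seed = seed + 5))
write_phenotype_table(field, "results/data/field_butterflies.csv")
message(sprintf("field butterflies: %d records, %d populations",
                nrow(field), length(unique(field$population))))

## host plants ---------------------------------------------------------------
sites <- data.frame(site = c("Dry", "Intermediate", "Wet"),
                    mean = c(11.850, 21.544, 18.005),
                    sd = c(10.073, 13.586, 7.953))
plants <- simulate_hostplants(sites, c(20, 11, 20), seed = seed + 6)
write.csv(plants, "results/data/field_hostplants.csv", row.names = FALSE)

# greenhouse 2x2 origin x watering design (63 leaves per cell); drought
# concentrates cyanogens, origin shifts the baseline
grid <- expand.grid(origin = c("dry_origin", "wet_origin"),
                    treatment = c("dry", "wet"), stringsAsFactors = FALSE)
grid$site <- paste(grid$origin, grid$treatment, sep = "_")
grid$mean <- c(16, 20, 11, 14)
grid$sd <- 6
greenhouse <- simulate_hostplants(grid[, c("site", "mean", "sd",
                                           "origin", "treatment")],
                                  63, seed = seed + 7)
write.csv(greenhouse, "results/data/greenhouse_hostplants.csv",
          row.names = FALSE)
message(sprintf("host plants: %d field, %d greenhouse leaf samples",
                nrow(plants), nrow(greenhouse)))
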