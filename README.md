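# cyanoquant

Quantitative-genetic and field-survey analysis of **biosynthesized
cyanogenic toxicity** in *Heliconius erato* butterflies.

*Heliconius* butterflies advertise cyanide-releasing defenses (the
cyanogenic glucosides linamarin and lotaustralin, synthesized de novo and
measured as % of body dry mass) with warning coloration. Whether such
defenses can evolve depends on how much of their variation is genetic.
This package implements the full analysis chain for that question, for
researchers working with common-garden breeding designs and field
surveys of chemical-defense traits:

- **pedigrees** — validation, topological ordering, and the additive
  (numerator) relationship matrix $A$ by the tabular method, with an
  independent recursive kinship oracle;
- **animal models** — REML estimation of mixed models with a
  pedigree-structured genetic effect ($\mathrm{Var}(a) = V_G A$), an
  optional maternal-identity random effect, and sex/diet fixed effects;
  boundary-corrected likelihood-ratio tests for variance components;
- **quantitative-genetic metrics** — broad-sense heritability
  $H^2 = V_G/V_P$, mean-scaled evolvability $e_\mu = 100\,V_G/\mu^2$,
  brood repeatability (ICC) with parametric bootstrap, parent-offspring
  regressions, the Falconer maternal-effect coefficient
  $m = \beta_{mo} - \beta_{fo}$ with cluster-bootstrap CI, and compound /
  maternal-transmission selection-response projections;
- **field statistics** — square-root ANOVA with Tukey-Kramer HSD,
  two-way factorials, Hedges' g, Pearson correlation, zero-truncated
  weighted kernel densities, range-quarter skew and detection summaries;
- **a synthetic-data generator** reproducing the study conditions
  (20 full-sib broods, ~322 pedigreed individuals, paternal half-sib
  links, four-diet feeding treatments, right-skewed field samples), so
  the whole chain is testable without external data.

The numbered scripts under `analysis/` run the chain end to end:
`01_simulate_data.R` → `02_animal_models.R` → `03_quantgen_metrics.R` →
`04_selection_response.R` → `05_field_statistics.R`, writing tables under
`results/`.

## Worked example

```r
library(cyanoquant)

cfg <- sim_config(seed = 20260929)      # the study's breeding design
ped <- make_pedigree(cfg)               # ~322 pedigreed individuals
phe <- simulate_breeding_phenotypes(ped, cfg)
A   <- additive_relationship_matrix(ped)

fit <- fit_animal_model(phe, A, model_spec())   # Model 1
print(fit)
#> REML animal model fit (trait: total )
#>   n_obs: 319  broods: 20  converged: TRUE
#>   restricted log-likelihood: -74.93007
#>       estimate ratio_VP
#> V_G    0.00994  0.09910
#> V_mat  0.00000  0.00000
#> V_sex  0.00317  0.03157
#> V_trm  0.00082  0.00819
#> V_R    0.08640  0.86115
#> V_P    0.10033  1.00000
```

The genetic variance recovered from this synthetic replicate (V_G =
0.0099; the generating value is 0.0093) converts into the evolutionary
potential of the trait:

```r
V_G <- fit$components["V_G"]
broad_sense_heritability(fit$components)        # 0.100 (treatment excluded)
e <- mean_scaled_evolvability(V_G, mean(phe$total))
e                                               # 1.54 (% per generation)
project_compound_response(e, beta = 1, g = 6)   # 9.6 (% change per year)
```

so under unit-strength selection the mean toxicity of this population
could shift by ~9.6% within a year (six generations). Brood repeatability
and maternal effects from the same data:

```r
estimate_repeatability(phe[phe$generation == "F1", ], n_boot = 1000,
                       seed = 20260929)
#> Repeatability R = 0.034, SE = 0.031, CI = [0.000, 0.107], P = 0.0733 (1000 bootstraps)

maternal_effect_coefficient(phe, n_boot = 1000, seed = 20260929)
#> m = beta_mo - beta_fo = 0.142 - (0.155) = -0.013, CI = [-0.245, 0.289]
#>   mother-offspring : 20 families
#>   father-offspring : 14 families (known sires only)
```

(This replicate was generated without maternal transmission, and the
estimated m is correspondingly near zero; simulating with
`m_transmission = 0.25` recovers slopes near 0.25/0.)

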