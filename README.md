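# swimherit

Quantitative-genetic analysis of critical swimming speed in Nile tilapia
(*Oreochromis niloticus*), for fish breeders and quantitative geneticists
working with full-sib/half-sib challenge-test designs.

Selective breeding of tilapia for non-aerated smallholder ponds raises a
physiological question: do fish with high aerobic capacity — indexed by
the critical swimming speed *U*crit from an incremental-velocity swim
test early in life — grow better or worse under chronic night-time
hypoxia later in life? Answering it requires heritabilities for swim
traits and genetic correlations between early swim performance and
harvest traits, estimated from a pedigree of full-sib families (each
reared in its own hapa net enclosure, which confounds common environment
with family) and half-sib links across sires.

`swimherit` implements the whole chain:

* **Phenotypes** — Brett-style critical swimming speed
  *U*crit = *U*₋₁ + (*t*/Δ*t*)Δ*U* from fatigue level and
  time-in-level against a measured speed schedule; relative *U*crit
  (SL s⁻¹); elliptical surface area SA = ¼π·SL·H; daily growth
  coefficient DGC = 100·(HW^⅓ − Wstart^⅓)/days; Table-1-style
  descriptive statistics.
* **Pedigree** — validated, topologically sorted pedigrees; the
  numerator relationship matrix **A** by the tabular method; inbreeding
  coefficients; sparse **A**⁻¹ by Henderson's rules.
* **Animal models** — univariate and bivariate REML fits of
  **y** = **Xb** + **Z**₁**a** + **Z**₂**c** + **e** with
  **a** ~ N(0, **A**σ²ₐ) and the hapa effect **c**, through sparse
  mixed-model equations with the residual variance profiled out
  analytically; heritability h² = σ²ₐ/σ²ₚ, hapa ratio c² = σ²_c/σ²ₚ,
  genetic/phenotypic correlations, delta-method SEs, likelihood-ratio
  tests (including a genetic covariance constrained to zero).
* **Simulator** — the full mating design (31 sires × 58 dams → 60
  full-sib families, 25 offspring each, 30 test days of 50 fish),
  breeding values with Mendelian sampling, fatigue-encoded swim records,
  grow-out records; used for parameter-recovery validation since the
  original data are not publicly deposited.
* **Pipeline** — `run_analysis()` runs the four univariate *U*crit
  variants and the six bivariate fits from one YAML/`list` config and
  writes CSV/JSON/markdown tables. A thin CLI lives in
  `inst/scripts/swimherit`.

## Worked example

Simulate a study-sized dataset, write it out as raw CSV inputs and run
the full analysis:

```r
library(swimherit)

dat <- simulate_dataset(sim_config_study(seed = 1))
dir <- tempdir()
write.csv(dat$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
ped <- as.data.frame(dat$pedigree)[, c("animal", "sire", "dam")]
ped[is.na(ped)] <- "0"
write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE)

report <- run_analysis(list(
  phenotypes = file.path(dir, "phenotypes.csv"),
  pedigree   = file.path(dir, "pedigree.csv"),
  out_dir    = file.path(dir, "report")))

print(report$fits_univariate$ucrit_abs)
#> Univariate REML animal model: ucrit_abs
#>   sigma_a2 = 11.04  sigma_c2 = 6.017e-05  sigma_e2 = 8.713  sigma_p2 = 19.75
#>   h2 = 0.559 (SE NA)   c2 = 0.000 (SE NA)
#>   logLik = -4072.973   n = 1493   converged: TRUE

report$table3[, c("trait", "rg", "se_rg", "rp")]
#>      trait      rg se_rg      rp
#>      wtest  0.8538 0.168  0.4873
#>     sltest  0.9929 0.208  0.4694
#>      htest  0.7788    NA  0.3970
#>    sa_test  0.9155 0.133  0.5207
#>         hw -0.0724 0.385 -0.0113
#>        dgc -0.4326 0.158 -0.2039
```

This replicate shows the structure the method is built to detect: a
substantial heritability for absolute *U*crit (here 0.56 against a
simulated-truth ratio of 0.48 — single-dataset estimates of h² in a
60-family design carry SEs around 0.17, and the hapa variance sits on
the zero boundary here, which is also why its SE is withheld), strongly
positive genetic correlations with body size at testing, and negative
genetic correlations with harvest weight and growth in the non-aerated
pond. `report$lrt_results` holds the likelihood-ratio tests; in this
replicate the additive effect is significant for absolute *U*crit
(χ² = 12.0, p = 5e-4) and the genetic covariance with growth is
significantly negative (χ² = 6.0, p = 0.014).

The selection calculator quantifies the trade-off: culling on high
*U*crit drags harvest weight through the negative correlation,

```r
predict_correlated_response(selected_proportion = 0.10,
                            h2_x = 0.48, h2_y = 0.25, rg = -0.21,
                            sd_py = 88.1)
#> $selection_intensity    1.754983
#> $correlated_response   -11.23  # grams per generation
#> $direct_response        38.65
#> $relative_efficiency    -0.29
```

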