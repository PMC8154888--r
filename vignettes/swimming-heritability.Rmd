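---
title: "Quantitative genetics of critical swimming speed: models, simulator and design choices"
author: "swimherit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of critical swimming speed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package estimates

`swimherit` estimates the genetic architecture of swimming performance in
juvenile Nile tilapia (*Oreochromis niloticus*) from incremental-velocity
swim challenge tests, together with its genetic relationships to body size
at testing and to growth during pond grow-out.

## Phenotypes

Critical swimming speed is derived from the fatigue observation of a
Brett-type test in which flow speed is raised one propeller level at a
time, each level held for a fixed duration $\Delta t$ (30 min by
default):

$$U_{crit} = U_{-1} + \frac{t}{\Delta t}\,\Delta U ,$$

where $U_{-1}$ (cm s$^{-1}$) is the last fully maintained speed,
$\Delta U$ the increment to the level in which the fish fatigued and $t$
the minutes swum in that level. Relative $U_{crit}$ divides by standard
length at testing (SL s$^{-1}$). Lateral surface area is approximated by
an ellipse, $SA = \frac{\pi}{4}\,SL \times H$, and pond growth by the
daily growth coefficient
$DGC = 100\,(HW^{1/3} - W_{start}^{1/3})/\text{days}$, which is roughly
insensitive to size-dependent growth scaling.

A fish that fatigues exactly at a level boundary is recorded with
$t = \Delta t$ of the completed level rather than $t = 0$ of the next.
The two encodings give the same $U_{crit}$; fixing the convention makes
the statistic continuous across boundaries and lets the simulator's
encoder (`encode_swim_test()`) invert the calculation exactly. The flow
speeds per propeller setting are an input (`read_speed_schedule()`); the
packaged default schedule (levels 1–10 at 17–89 cm s$^{-1}$, 8 cm s$^{-1}$
increments) is synthetic and is marked as such.

## The animal model

Each trait is analysed with the linear mixed model

$$\mathbf{y} = \mathbf{X}\mathbf{b} + \mathbf{Z}_1\mathbf{a} +
  \mathbf{Z}_2\mathbf{c} + \mathbf{e},$$

with fixed effects $\mathbf{b}$ (test day for flume traits; sex for DGC;
age at harvest as covariate for harvest weight; optionally body weight or
standard length at testing as covariate for absolute $U_{crit}$), additive
genetic effects $\mathbf{a} \sim N(0, \mathbf{A}\sigma_a^2)$ with
$\mathbf{A}$ the pedigree numerator relationship matrix, a
common-environment ("hapa") effect
$\mathbf{c} \sim N(0, \mathbf{I}\sigma_c^2)$ shared by full sibs reared in
one net enclosure, and residuals
$\mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2)$. Heritability is
$h^2 = \sigma_a^2/\sigma_p^2$ and the hapa ratio
$c^2 = \sigma_c^2/\sigma_p^2$, with
$\sigma_p^2 = \sigma_a^2+\sigma_c^2+\sigma_e^2$.

Bivariate fits stack two traits with covariances
$\mathbf{A} \otimes \mathbf{G}_0$, $\mathbf{I} \otimes \mathbf{C}_0$ and
$\mathbf{I} \otimes \mathbf{R}_0$ for 2×2 blocks $\mathbf{G}_0,
\mathbf{C}_0, \mathbf{R}_0$; the genetic correlation $r_g$ is the
standardised off-diagonal of $\mathbf{G}_0$. Each trait keeps its own
record set: fish missing one trait still contribute to the other, and the
residual covariance applies only to fish carrying both. The
common-environment term can be confined to one trait — used for the
$U_{crit}$–DGC pair, where fitting it on both traits does not converge
because DGC's family variance is nearly empty once the genetic covariance
is in the model.

## REML machinery

The restricted likelihood is evaluated through sparse mixed-model
equations: with $\mathbf{W} = [\mathbf{X}\;\mathbf{Z}]$ and
$\mathbf{M} = \mathbf{W}'\mathbf{R}^{-1}\mathbf{W} +
\mathrm{diag}(\mathbf{0}, \mathbf{G}^{-1})$,

$$-2\ell_R = (n-p)\log 2\pi + \log|\mathbf{R}| + \log|\mathbf{G}| +
  \log|\mathbf{M}| - \log|\mathbf{X}'\mathbf{X}| +
  \mathbf{y}'\mathbf{P}\mathbf{y}.$$

$\mathbf{A}^{-1}$ is built directly from the pedigree by Henderson's
rules with inbreeding, and $\log|\mathbf{A}|$ falls out of the same
recursion as $\sum_i \log d_i$ over Mendelian-sampling variances. The
$-\log|\mathbf{X}'\mathbf{X}|$ term makes $\ell_R$ invariant to the
fixed-effect coding, which the test suite asserts by refitting under
treatment and sum contrasts. $\mathbf{M}$ is reassembled every iteration
as a fixed linear combination of precomputed sparse components, so the
symbolic Cholesky analysis is done once and only numeric factorisations
repeat; a 1,500-record univariate fit takes well under a second and a
bivariate fit a couple of seconds.

Variances are optimised on the log scale and correlations through a
$\tanh$ transform (so every 2×2 block stays positive semi-definite by
parameterisation, never by post-hoc truncation), with a quasi-Newton
optimiser (`nlminb`), relative-tolerance $10^{-8}$, at most 500
iterations, and variance bounds at $10^{-10}$ of the trait variance.
Estimates within $10^{-6}$ of the bound are flagged as boundary values;
correlations within 0.005 of $\pm 1$ are flagged as pinned.
Non-convergence is reported in the result, not thrown. Standard errors
come from the delta method applied to the inverse observed information,
computed by central finite differences on the transformed scale (step
$10^{-3}$; differencing on the variance scale directly is numerically
fragile because the log-likelihood is several thousand in magnitude).
SEs are withheld (NA) at boundary solutions, where the one-sided
curvature does not estimate a sampling variance.

Likelihood-ratio tests report $\chi^2 = \max(0, 2\Delta\ell_R)$ on one
degree of freedom, both for random effects and for a genetic covariance
constrained to zero (`fix_ra = 0`). The one-df convention is
conservative for variance components, which sit on the boundary of the
parameter space under the null; a 50:50 $\chi^2_0$:$\chi^2_1$ mixture is
available (`boundary_mixture = TRUE`) but off by default to match
standard practice in this literature.

# The synthetic-data generator

Real data for this design are not publicly deposited, so every pipeline
stage is validated against a generator that emulates the experimental
structure:

* **Mating design.** 31 sires and 58 dams produce 60 full-sib families
  (12 sires × 1 dam, 12 × 2, 4 × 3, 3 × 4); two dams are used twice with
  different sires, adding two maternal half-sib links. Each family is
  reared in its own hapa, confounding the common-environment effect with
  family. 25 offspring per family gives 1,500 tested fish.
* **Breeding values.** Founders are drawn from $N(0, \mathbf{G}_0)$;
  descendants are parent averages plus Mendelian-sampling deviates with
  covariance $d_i\,\mathbf{G}_0$,
  $d_i = 1 - 0.25(1+F_s) - 0.25(1+F_d)$, so realised covariances converge
  to $\mathbf{A} \otimes \mathbf{G}_0$.
* **Test days.** 30 days of 50 fish. Days are filled round-robin: 24 days
  take 10 fish from each of 5 families, then 6 days take 5 fish from each
  of 10 families, so every family is spread over three days and every
  day mixes families from across the design. The schedule matters:
  in an earlier layout that confined disjoint six-family blocks to
  three-day windows, the 30 test-day fixed effects absorbed all
  between-block family contrasts and measurably degraded variance
  separation. Day effects are drawn $N(0, 3.4^2)$ for flume traits; 3.4
  cm s$^{-1}$ makes the total SD of simulated $U_{crit}$ match the
  observed 5.5 cm s$^{-1}$ given the 18.45 (cm s$^{-1}$)$^2$ phenotypic
  variance.
* **Phenotypes.** Each trait is mean + day effect + breeding value +
  family effect + residual, composed exactly (the parts are attached to
  the table for verification). $U_{crit}$ values are then encoded as
  fatigue level and time-in-level through the speed schedule, and the
  analysis pipeline re-derives them from those raw records, closing the
  loop.
* **Grow-out bookkeeping.** The study configuration
  (`sim_config_study()`) thins harvest records to 79.9% survival at
  random, marks 7 swim records as lost, records sex for ~64% of
  harvested fish, and back-derives stocking weight from harvest weight
  and DGC so that the growth coefficient recomputes exactly from the raw
  fields.

Calibrated configurations set the true parameters to the estimates this
package's models produce on the real design: `sim_config_ucrit()`
(σ²ₐ = 8.90, σ²_c = 0.43, σ²ₑ = 9.12, h² = 0.48) and
`sim_config_pair()` for the $U_{crit}$–Wtest pair (r_g = 0.78, hapa on
both) and the $U_{crit}$–DGC pair (r_g = −0.63, hapa on $U_{crit}$
only). Quantities not reported for the companion traits are fill-ins
chosen once on domain grounds: body-weight-type traits get h² = 0.35 and
c² = 0.10, height 0.30/0.10, harvest weight 0.25/0.05, DGC h² = 0.30
with no hapa variance; the companion-trait residual correlations are
then solved so the implied phenotypic correlations match the observed
ones (0.44 for Wtest, −0.24 for DGC — the latter lands at r_e ≈ 0, which
is also why the DGC pair carries no residual-correlation fill-in). In the
six-trait study configuration the correlations among companion traits
use single-factor structures (guaranteeing positive semi-definite
matrices), except the HW–DGC pair, which is set high (0.85 genetic, 0.90
residual) because DGC is computed from HW.

What the generator does **not** emulate: the 18-generation ancestry of
the real founders (founders are unrelated and non-inbred; extra
generations can be simulated but are off by default), size-selective
mortality during grow-out (survival thinning is random), the
pre-selection of "relatively bigger" fingerlings for testing, water
quality dynamics, and measurement error in the image-derived body
measures. Passing recovery tests therefore demonstrates correctness of
the estimation machinery on data with the study's covariance structure,
not robustness to these unmodelled features of real data.

# What parameter recovery can and cannot show

Across 50 replicates of the full design, bivariate genetic correlations
are recovered with small bias (mean $\hat r_g \approx 0.75$ at truth
0.78; $\approx -0.58$ at truth −0.63). The univariate heritability of
absolute $U_{crit}$ is recovered with a noticeable downward mean bias:
$\approx 0.41$ at truth 0.482, with per-replicate SD ≈ 0.16 matching the
SE reported for designs of this size.

This bias is a property of constrained REML on this design, not of the
implementation: the sparse-MME likelihood agrees with a dense-matrix
REML evaluation to seven significant figures, a structurally equivalent
sire–dam–family fit with `lme4` shows the same mean on the same data,
and multi-start optimisation finds no competing optima. The mechanism is
truncation transfer. The true hapa variance is small (c² ≈ 0.02) and the
design confounds it heavily with sire genetics — 24 of 31 sires
contribute one or no half-sib family — so the unconstrained estimate of
$\sigma_c^2$ would often be negative. The non-negativity constraint
clips those replicates; because $\hat\sigma_a^2$ and $\hat\sigma_c^2$
are strongly negatively correlated (a unit of family variance
misattributed to the hapa displaces several units of additive variance),
the clipping inflates $\hat\sigma_c^2$ (mean ≈ 0.8 at truth 0.43) and
deflates $\hat\sigma_a^2$ (mean ≈ 7.5 at truth 8.90). Fitting 30
test-day effects on families that each appear on only three days costs a
further ~0.04 of $h^2$. Single estimates on real data from such designs
inherit exactly this sampling behaviour, which is worth keeping in mind
when comparing point estimates across studies.

# Worked analysis

```{r}
library(swimherit)

dat <- simulate_dataset(sim_config_study(seed = 1))
dir <- tempdir()
write.csv(dat$phenotypes, file.path(dir, "phenotypes.csv"),
          row.names = FALSE)
ped <- as.data.frame(dat$pedigree)[, c("animal", "sire", "dam")]
ped[is.na(ped)] <- "0"
write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE)

report <- run_analysis(list(
  phenotypes = file.path(dir, "phenotypes.csv"),
  pedigree = file.path(dir, "pedigree.csv"),
  out_dir = file.path(dir, "report")))
report$table2   # variance components for the four Ucrit model variants
report$table3   # genetic/phenotypic correlations with the six companions
```

The selection calculator is deliberately input-explicit: predicting the
correlated change in harvest weight under selection on $U_{crit}$
requires the harvest-weight heritability, which univariate tables for
swim traits do not provide; `predict_correlated_response()` takes every
input as an argument rather than guessing from a fitted object.

```{r}
predict_correlated_response(selected_proportion = 0.10, h2_x = 0.48,
                            h2_y = 0.25, rg = -0.21, sd_py = 88.1)
```

# Known limitations

* Dense tabular $\mathbf{A}$ is built for inbreeding whenever some
  parent has known parents; fine to a few thousand animals, not intended
  for national-evaluation scale.
* SEs use the observed information; average-information SEs (as in
  dedicated REML software) can differ in small samples. SE magnitudes
  are reported but not validated against external software.
* Only univariate and bivariate models are implemented; no BLUP ranking
  reports, genomic relationship matrices, or >2-trait fits.
* The one-df LRT convention understates significance for variance
  components at the boundary (see above).
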