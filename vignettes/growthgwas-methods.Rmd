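---
title: "Modelling early growth and its genetics: methods and design choices"
author: "growthgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling early growth and its genetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthgwas)
```

# The problem

A child's BMI trajectory is not monotone: it rises steeply to a maximum
around nine months of age (the *adiposity peak*, AP), falls to a minimum at
five to six years (the *adiposity rebound*, AR) and rises again into
adulthood. Six scalar phenotypes summarise this trajectory per child: peak
height velocity (PHV, cm/month) and peak weight velocity (PWV, kg/month) in
infancy, and the age and BMI coordinates of the AP and the AR. These derived
traits, rather than BMI at fixed ages, are the phenotypes of a two-stage
genome-wide association analysis implemented by this package. Because the
individual-level cohort data behind such analyses are restricted, the
package pairs every analysis stage with a synthetic-cohort generator whose
ground truth is known, so that each stage is testable end to end.

# Growth models

## Log-BMI trajectory models

BMI trajectories are modelled separately in two age windows, as linear mixed
models of log BMI on centred age $a$:

* **infancy** (2 weeks to 18 months, centred at 0.75 y — chosen because it
  is close to the average age at AP):
  $\log \mathrm{BMI} = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3 +
  \beta_4\,\mathrm{sex} + u_0 + u_1 a + \varepsilon$
* **childhood** (18 months to 13 years, centred at 7.25 y, shortly after the
  average AR), adding $\beta_5\, a\!\times\!\mathrm{sex}$ and
  $\beta_6\, a^2\!\times\!\mathrm{sex}$.

Each child contributes a random intercept $u_0$ (baseline BMI) and a random
linear slope $u_1$; $(u_0, u_1)$ is bivariate normal. Estimation is by
maximum likelihood (`lme4::lmer`, `REML = FALSE`) so that log-likelihoods
are comparable across fixed-effect structures; per-child random effects are
empirical-Bayes predictions. Children need at least three in-window
measurements; the fit is refused below 20 children. Sex is coded 0 = female,
1 = male throughout.

`individual_curves()` collapses fixed plus random effects into one cubic per
child. The AP is the maximum of the infancy curve on ages 0.25–1.25 y, the
AR the minimum of the childhood curve on 2.5–8.5 y. Candidates are the real
roots of the curve derivative — computed with the numerically stable
quadratic formula, which matters when the cubic coefficient is tiny — plus
the window endpoints; ties are broken toward the earliest age, and a
boundary flag records extrema pinned to a window edge (such children are
retained by default; exclusion is a caller-side filter). BMI values are
back-transformed with `exp()` from the log-scale prediction, exactly.

## Reed1 model and peak velocities

Infant size from birth to 24 months follows the first-order Reed model
$y(t) = a + b t + c \ln t + d / t$ ($t$ in months), which is linear in its
four parameters on the basis $\{1, t, \ln t, 1/t\}$. Ages are floored at
0.25 months (~1 week) because $\ln t$ and $1/t$ are undefined at birth; the
effect on fits is negligible since the earliest routine visit is near two
weeks. Rather than a full nonlinear random-effects fit, the package uses a
two-stage scheme: $(c, d)$ are estimated per sex stratum by pooled least
squares with the per-subject $\{1, t\}$ terms projected out (Frisch–Waugh),
then $(a, b)$ per subject given $(c, d)$. This respects the
three-measurement minimum per child, is exact in the noiseless limit, and
runs at desk scale; it is a deliberate simplification relative to a full
NLME fit, and the shared-$(c,d)$ assumption is the main approximation.

The growth velocity is $v(t) = b + c/t - d/t^2$ with stationary point
$t^\ast = 2d/c$, a maximum precisely when $d > 0$. PHV and PWV are the
maximum of $v$ over 0.25–24 months (stationary point plus endpoints;
endpoint maxima are boundary-flagged).

# Association, meta-analysis, and downstream statistics

Every trait except the two ages is natural-log transformed to reduce
skewness, then z-scored within study, so effects are in SD units per effect
allele. All traits are adjusted for sex and gestational age, except BMI-AR
and Age-AR which are adjusted for sex only (gestational effects are not
detectable at the rebound); z-scoring precedes covariate adjustment.
Per-SNP association is ordinary least squares on additive dosage, with
two-sided p-values from the t distribution at exact residual degrees of
freedom. Principal-component covariates are omitted because the synthetic
cohorts carry no population structure; extra covariate columns pass through
unchanged. QC removes SNPs with MAF < 1%, imputation info < 0.4 (IMPUTE
dialect; r² < 0.3 for MACH), Hardy–Weinberg P < 1e-4, or call rate < 95%.

Studies are combined by inverse-variance fixed-effects weighting;
heterogeneity is summarised by Cochran's $Q$ and $I^2$. *Double genomic
control* divides by the inflation factor
$\lambda = \mathrm{median}(\chi^2)/0.4549$ twice — within each study and
again on the meta-level statistics — and never shrinks statistics when
$\lambda \le 1$. Follow-up selection uses $P < 10^{-7}$, or $P < 10^{-5}$
for SNPs flagged in/near candidate genes, plus an explicit override list;
combined-stage tiers are genome-wide ($P < 5\times10^{-8}$, strict) and
suggestive ($P < 5\times10^{-6}$). A DerSimonian–Laird random-effects
combination is available as a sensitivity option but the fixed-effects
result is the package's primary surface.

The downstream statistics are closed-form implementations:
$h^2 = 2f(1-f)\beta^2$; the Li–Ji effective number of tests from the
eigenvalues of the phenotype correlation matrix (tiny negative eigenvalues
clipped at zero, and fractional parts guarded against floating-point floor
errors); the gtx-style summary-statistic risk-score effect with downward
elimination of the largest-effect SNP while $P_{het} < 0.05$; the 20% /
nominal-significance conditional-independence rule; and chi-square power via
the noncentrality parameter $\mathrm{NCP} = n\,2f(1-f)\,b^2 r^2$. The
minimum detectable effect inverts the power function by bisection on
(0, 5] SD to tolerance 1e-10. At the discovery-stage design
($n = 6222$, MAF 0.22, $r^2 = 0.8$, $\alpha = 5\times10^{-8}$, 80% power)
this formula yields a minimum detectable effect of ~0.152 SD; we note that
substantially smaller published figures for this design are not reproducible
from the standard NCP formula with these parameters.

## Winner's curse

Effects selected by a significance threshold are biased away from zero. The
bias-reduced estimate maximises the conditional likelihood
$\log\varphi\!\big((\hat\beta-\beta)/s\big) -
\log\!\big[\Phi(\beta/s - z_c) + \Phi(-\beta/s - z_c)\big]$
over $\beta$ (bounded 1-D optimisation, tolerance 1e-9 on the argument),
where $z_c$ is the z-threshold of the selection alpha. The conditional MLE
is the default output; it reduces the *mean bias* of selected estimates but
overcorrects individual estimates near the threshold, which is why the
compromise estimator $(\hat\beta + \hat\beta_{MLE})/2$ is reported
alongside — in the package's own calibration simulation (true effects
uniform on 0.02–0.10 SD, SE 0.02, selection at $P<10^{-5}$) the naive mean
bias ≈ +0.019, the MLE ≈ −0.017, the compromise ≈ +0.002. The tests
therefore assert bias-magnitude reduction, not mean-absolute-error
reduction.

## Local false discovery rate

Stage-1 z-values are modelled by Efron's two-groups model with a
*theoretical* N(0,1) null: the marginal density is estimated by Poisson
regression of histogram counts (120 bins spanning the data) on a natural
spline (7 df, Lindsey's method), and $\pi_0$ by central matching — the
median of $\hat f(z)/\varphi(z)$ over $|z|<1$ — capped at 1. The choice of
the theoretical null and central matching (rather than an empirical MLE
null) is deliberate: the synthetic pipeline's statistics are exactly
calibrated, so the theoretical null is correct there, and it keeps the
estimator dependency-free.

# The synthetic cohort

The generator emulates the study design the pipeline targets: multiple
independent cohorts of term-born singletons (gestational age 37–41 weeks,
roughly centred on 39–40), sex ratio 0.51, visits at 0, 0.04, 0.25, 0.5,
0.75, 1, 1.5, 2, 3, 4, 5, 6, 7, 8, 10 and 13 years with 15% independent
dropout per visit and ±4% multiplicative age jitter (child-health-clinic
density with realistic irregularity).

Log-BMI observations are generated *from the two polynomial mixed models
themselves* (defaults put the mean AP at 0.75 y / 17.5 kg/m² and the mean AR
near 5.5 y / 15.5 kg/m², with random-effect SDs giving an Age-AP SD of
~0.09 y and Age-AR SD of ~0.5 y); height follows per-child Reed curves
(newborn ~50 cm, PHV ~6.4 cm/month shortly after birth) extended linearly
at 6.5 cm/y beyond 24 months; weight is *derived* as
$\mathrm{BMI}\times(\mathrm{height}/100)^2$ so that every record satisfies
the BMI identity exactly. Measurement noise defaults: SD 0.05 on log-BMI
(≈5% of BMI) and 0.5 cm on height; the cohorts behind such analyses do not
publish per-cohort error magnitudes, so these are package defaults chosen
once and configurable.

Genotypes are Binomial(2, MAF) per SNP — Hardy–Weinberg by construction —
with optional fractional dosages for SNPs with info < 1; panel SNPs carry no
LD. Causal effects are injected *on the latent derived traits, on the scale
the GWAS analyses them* (log scale for the four log-transformed traits): a
SNP with effect $\beta$ shifts the latent trait of each carrier by
$\mathrm{dosage}\times\beta\times\mathrm{SD}_0$, where $\mathrm{SD}_0$ is
the within-study SD of the baseline latent trait. For BMI-AP, BMI-AR and PWV
this is an exact shift of the relevant random intercept; for PHV an exact
shift of the Reed slope; for the two age traits the random slope is moved in
closed form so the curve's stationary point lands on the shifted age
(clamped just inside the search window). Between-study heterogeneity adds a
Normal(0, `between_study_sd`) shift to each causal effect per study.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: LD between SNPs, population stratification and
relatedness, imputation uncertainty beyond a scalar info score, cohort-
specific measurement protocols, secular trends, informative (non-random)
visit schedules and dropout, and the discontinuity between the infancy and
childhood models at 18 months is an artifact of simulating from the two
fitted models rather than one biological process. Effect recovery is also
slightly attenuated relative to the injected value because derived traits
are empirical-Bayes estimates with estimation noise; at the default noise
levels the attenuation is well inside one standard error at n = 4000.

# Numerical choices and degenerate inputs

* Extremum ties break to the earliest age; window-edge extrema are flagged,
  not dropped.
* The derivative roots use the cancellation-free quadratic formula.
* Monomorphic SNPs yield flagged records without estimates; zero-variance
  traits and non-positive values under log are hard errors naming the
  offender.
* Genomic control warns below 100 records; local fdr refuses fewer than
  1000 values.
* `m_eff` uses an eigenvalue tolerance of 1e-9 so exact multiplicities
  survive floating point.
* All file output serialises floating point at 15 significant digits, so
  read–write round trips are stable to 12.
* Default seed 20190904; every stochastic operation takes an explicit seed
  and derives independent child streams for genotypes, growth and study
  shifts.

# Problem sizes used in the checks

The packaged checks run the pipeline at sizes chosen to make their
statistical assertions sharp while staying desk-scale: effect recovery at
one study of 4000 children; type-I error over 1000 null SNPs at 2000
children; genomic-control calibration over four studies of 800 children and
40000 (tests) or 20000 (acceptance script) null SNPs, generated and scanned
one study at a time; Cochran's-Q calibration over four studies of 400
children and 5000 SNPs. At these sizes the 95% Monte-Carlo band of
$\lambda$ is about ±0.03 and of the type-I rate about ±0.014.

# Known limitations

* The two-stage Reed fit shares $(c, d)$ within a sex stratum; real cohorts
  show individual curvature differences that this absorbs into residuals.
* The pipeline's stage-2 follow-up is simulated by the same machinery as
  stage 1; no separate genotyping-error model exists.
* `h2_grs` is defined as $\hat\alpha^2 \sum_i w_i^2\, 2f_i(1-f_i)$ (unit
  trait variance, independent HWE SNPs); other definitions exist and none is
  canonical.
* No X-chromosome handling, kinship correction, imputation, LD clumping, or
  annotation: candidate-gene and override flags are explicit configuration.
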