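---
title: "Two-sample Mendelian randomization in causalmr: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization in causalmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalmr)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
from two independent GWAS: one reporting each variant's association with
the exposure ($\hat\beta_{Xj}$, $\sigma_{Xj}$), one with the outcome
($\hat\beta_{Yj}$, $\sigma_{Yj}$). Under the instrumental-variable
assumptions — the variant is associated with the exposure, independent of
confounders, and affects the outcome only through the exposure — each
variant provides a ratio (Wald) estimate
$\hat\theta_j = \hat\beta_{Yj} / \hat\beta_{Xj}$ of the causal effect
$\theta$, with first-order standard error
$\sigma_{Yj}/|\hat\beta_{Xj}|$ (the no-measurement-error approximation:
uncertainty in $\hat\beta_{Xj}$ is ignored in the ratio SE; with
genome-wide-significant instruments at biobank sample sizes the induced
attenuation is below 2% in the regimes simulated here and is visible in
the recovery studies as a mean IVW estimate of about 0.297 for a true
effect of 0.3).

The estimators, each implemented from its definition:

* **IVW** — inverse-variance weighted mean of the ratios with weights
  $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, algebraically identical to
  weighted least squares of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through
  the origin. Heterogeneity is measured by Cochran's
  $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $k-1$ degrees of
  freedom. The *multiplicative random-effects* standard error inflates the
  fixed-effect one by $\max(1, \sqrt{Q/(k-1)})$: "random-effect IVW" is
  often reported without stating the flavour, and the multiplicative form
  with a floor at 1 is the dominant convention — heterogeneity can widen the interval but never narrow it.
  The floor makes the test slightly conservative (the unit suite measures
  a null rejection rate near 4% at $\alpha = 0.05$).
* **MR-Egger** — the same weighted regression with a free intercept, after
  orienting every row so $\hat\beta_{Xj} \ge 0$. A nonzero intercept is
  evidence of directional horizontal pleiotropy; the slope remains a
  consistent causal estimate if instrument strength is independent of the
  direct effects (InSIDE). Inference uses the $t$ distribution on $k-2$
  degrees of freedom with the same multiplicative dispersion floor.
* **Weighted median** — the 50% point of the weight-ordered ratio
  estimates (linear interpolation of cumulative-weight midpoints),
  consistent while valid instruments carry more than half the weight. Its
  standard error is a parametric bootstrap: betas resampled from normals
  centred at their observed values, 1000 draws by default, seed required.
* **MR-PRESSO** — leave-one-out residual sum of squares compared against
  datasets simulated under the no-pleiotropy model; per-variant outlier
  tests Bonferroni-adjusted across instruments; an outlier-corrected IVW
  estimate; and a distortion p comparing the observed corrected-minus-raw
  displacement against the same displacement on the simulated datasets
  (the distortion convention is this package's choice; descriptions of
  the method in the literature leave it open).
* **Multivariable MR** — weighted regression of outcome betas on several
  exposures' beta columns without intercept, giving each exposure's
  *direct* effect conditional on the others; rank-deficiency (collinear
  exposures) is an error naming the offending exposures.

## Instrument processing

Instruments are selected at $p < 5\times10^{-8}$ (a relaxed
$5\times10^{-6}$ is available per trait for phenotypes with few hits),
clumped greedily by ascending p-value (ties broken lexicographically by
variant id for determinism) so that no kept pair within 10 Mb has
$r^2 \ge 0.001$, strength-filtered at $F = (\hat\beta/\sigma)^2 > 10$, and
screened against a user-supplied confounder-association table at
$p < 5\times10^{-8}$. A trait whose candidate instruments all fail the
F threshold is flagged *outcome-only* and never used as an exposure. The
F-statistic uses the squared Wald z because per-variant $R^2$ and sample
sizes are not consistently available across published GWAS.

Harmonization aligns outcome effects to the exposure's effect allele:
direct match, allele swap (negate, reflect frequency), strand complement,
or complement-plus-swap; anything else is dropped as `allele_mismatch`.
Palindromic variants (A/T, C/G) carry no strand information in their
alleles, so they are oriented by allele frequency when both sides lie
outside the ambiguity window [0.42, 0.58] — the de-facto standard default
— and dropped as `palindromic_ambiguous` otherwise, including when either
frequency is missing. No proxy-variant substitution is attempted. Every
exclusion is recorded with a reason so instrument flow is auditable from
selection to estimation.

## Primary-method rule and significance labels

IVW is the primary
method; when the Egger intercept test indicates pleiotropy
($p < 0.05$, strictly) MR-Egger becomes primary. Labels: *significant*
below the Bonferroni-corrected level $0.05/5 = 0.01$, *nominal* below
0.05, *null* otherwise. The number of tests in the correction is a
configuration field (default 5).

One property of the compound rule deserves note: under a true null with
no pleiotropy, the Egger intercept and slope estimators are strongly
anti-correlated (the regressor values are all positive after
orientation), so conditional on the intercept test firing spuriously the
Egger slope test fires with high probability. The compound rule therefore
rejects a true-null causal effect at roughly 8% rather than 5%. The
pipeline keeps the rule as stated for reported estimates; the mediator
screen (below) uses IVW p-values for its criterion verdicts so its error
rates stay near nominal.

## Mediation

The screen applies four criteria in order, short-circuiting at the first
failure and auditing every verdict: (1) the candidate affects the outcome
in UVMR; (2) it retains a direct outcome effect controlled for the
exposure in MVMR; (3) the exposure affects the candidate but not vice
versa (both tested at the nominal level); (4) the indirect effect
$a \times b$ points the same way as the total effect. Effects: $a$
(exposure to mediator) and the total effect come from UVMR under the
primary-method rule; $b$ is the MVMR direct effect. The indirect effect
is $a b$ with delta-method SE $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$; the
mediation proportion is $ab/\text{total}$, reported in percent with a
95% interval that treats the total as fixed and floors a negative lower
endpoint at 0% only when the point estimate is positive — the common
reporting style for mediated proportions. A full ratio-of-normals
interval is deliberately out of scope.

## The synthetic-data generator

Everything is generated at the summary-statistics level; no individual
genotypes are ever simulated, because two-sample MR consumes only summary
data. Per-variant standard errors follow the binomial-information formula
$1/\sqrt{2\,n\,\mathrm{maf}(1-\mathrm{maf})}$ with effective sample size
$n$; true instrument effects are drawn from $N(0, \sigma_x^2)$ and
rejection-sampled (simple and exact, rather than truncated-normal
inversion) until they pass the selection threshold at the exposure sample
size; observed effects add sampling noise; outcome effects are
$\theta\,\beta_{\text{true}} + \alpha + \varepsilon$. The pleiotropy term
$\alpha$ is defined in the exposure-increasing allele orientation (a
directional mean must survive Egger's orientation step to be detectable),
optionally correlated with instrument strength to break InSIDE, with
planted-invalid and planted-outlier variants available for the breakdown
and outlier studies.

Default study conditions: 50 instruments per trait (30 per trait in the
mediation scenario, typical of lifestyle-exposure GWAS), effective sample
sizes of $10^5$ on both sides (the scale of the psychiatric GWAS that
motivate the pipeline), minor allele frequencies uniform on (0.1, 0.4),
$\sigma_x = 0.05$ on the log-odds scale. Full tables add LD blocks of 5
variants (within-block $r^2 \sim U(0.2, 0.99)$, zero between blocks, one
planted index per signal block plus null filler blocks) and scrambled
allele representations including ~16% palindromic pairs, so clumping and
harmonization do real work. In `generate_pair()` the observed index
effects are additionally re-drawn until they pass the selection threshold
— this makes the planted instrument list exactly recoverable by the
selection pipeline, which is what the recovery tests need; the
calibration studies use `simulate_harmonized()`, which conditions only
the true effects.

The mediation scenario plants exposure → mediator ($a = 0.2$), mediator →
outcome ($b = 0.4$) and direct ($0.32$) paths — true proportion
$0.08/0.4 = 20\%$ — plus two decoys with real outcome effects: one with
no exposure path and one that also causes the exposure (reverse path
0.15, strong enough for the reverse test to detect and weak enough that
the decoy's variants stay below the exposure's selection threshold). In
tables that instruments are selected from, non-instrument variants are
conditioned to stay below the threshold so each trait's planted
instrument set is exactly what selection recovers; the outcome table is
left unconditioned (conditioning it would truncate precisely the
strongest instruments' outcome effects and bias every slope toward zero).

What the generator does *not* emulate: realistic human LD maps, allele
frequency spectra, polygenicity, population stratification, or sample
overlap between the two GWAS. Passing tests therefore demonstrate that
the estimators and the screen behave as designed under their own
assumptions — not that those assumptions hold in any particular pair of
real GWAS.

## Simulation design notes

* **Weighted-median breakdown study** (40% invalid instruments): the
  planted pleiotropy is large with *balanced* signs (magnitude 0.15,
  Rademacher). With 40% of weight shifted in one direction, any
  median-type estimator sits near the 0.83 weight-quantile of the valid
  ratios and is biased by about one ratio-SD, so a directional design
  cannot demonstrate the "stays near the truth" property for any faithful
  implementation; with balanced contamination the weighted median is
  consistent while IVW's error grows several-fold (the acceptance study
  measures a median-error ratio around 7). The per-replicate bootstrap SE
  slightly understates total spread (it cannot see the randomness of the
  sign imbalance), which is why the breakdown property is asserted over
  the ensemble of 500 sets rather than per replicate.
* **Block-level recovery**: with sampling noise, a tight LD partner
  ($r^2 \to 1$) of a planted index variant can legitimately be observed
  as more significant and become the clump sentinel. Recovery is
  therefore asserted at LD-block granularity — exactly one kept variant
  per planted block, none from null blocks.
* **Problem sizes** (also used by `scripts/acceptance.R`): 2000 null
  replicates at $k=50$ for IVW calibration and coverage; 500 replicates
  × 200 simulations for MR-PRESSO global-p uniformity at $k=20$; 500
  replicates for effect recovery and the weighted-median study (250
  bootstrap draws each); 200 replicates for the planted-outlier study
  (300 MR-PRESSO simulations each); 100 replicates of the full mediation
  screen at 30 instruments per trait.

## Numerical and API choices

* All stochastic components require a seed; the pipeline derives
  per-stage streams from one root seed by stage-name hashing, so a run is
  reproducible end to end and report files are byte-identical across
  reruns (numbers serialized at 6 significant digits).
* P-values of exactly zero in input files are clamped to the smallest
  positive double with a warning (GWAS exports underflow); missing allele
  frequency or sample size is kept as missing, never imputed.
* Ties in clumping are broken by variant id; the clump window is
  inclusive; an absent LD pair is treated as $r^2 = 0$ and a variant with
  itself as 1.
* Degenerate inputs: a single instrument degenerates IVW to the Wald
  ratio (flagged); MR-Egger requires 3 instruments, MR-PRESSO 4; an
  exposure whose instruments all fail the F threshold yields an
  `outcome_only` pair result with no estimates; estimation failures
  inside a matrix run are caught per pair and recorded.

## Known limitations

Sample-overlap correction (LD-score-based) is out of scope, as are proxy
instruments, penalized weighted-median variants, mode-based estimators,
and any VCF/BGEN input. The no-measurement-error ratio SE omits
second-order terms. The mediation proportion interval treats the total
effect as fixed, so its endpoints ignore uncertainty in the denominator;
reported proportions can differ by a few tenths of a percentage point
from what other interval constructions would give. The MR-PRESSO global
p is mildly anticonservative (mean simulated null p near 0.48 rather
than 0.50), a property of parametric constructions that simulate around
fitted rather than true means; the null-calibration study bounds the
effect with a Kolmogorov-Smirnov uniformity check.
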