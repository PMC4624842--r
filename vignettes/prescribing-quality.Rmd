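---
title: "Measuring antibiotic prescribing quality and its attitudinal determinants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antibiotic prescribing quality and its attitudinal determinants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqpa)
```

## The measurement problem

Antibiotic overuse and misuse in primary care drive resistance, and the
physician is the decision-maker. `aqpa` implements a complete analysis
pipeline for quantifying, at the level of the individual prescriber, (i) the
quality of antibiotic prescribing from routinely collected dispensing data,
and (ii) the effect of the prescriber's knowledge and attitudes on that
quality. It is built around three layers:

1. **Indicator engine** — twelve validated ESAC (European Surveillance of
   Antimicrobial Consumption) prescription-quality indicators per
   physician-year, computed from ATC-coded monthly dispensing volumes in
   defined daily doses (DDD) and yearly patient-panel sizes.
2. **AQPA classifier** — the binary outcome *Appropriate Quality
   Prescription of Antibiotics*: at least half (6 of 12) of a
   physician-year's indicators better than a national reference standard.
3. **Attitude model** — a longitudinal random-intercept logistic regression
   of AQPA on each questionnaire item (visual-analog-scale scores 0–10),
   summarised as interquartile odds ratios (IqOR).

A synthetic-cohort generator with known ground truth ties the layers
together so the whole chain is testable without access to confidential
prescribing data.

## The twelve indicators

Volumes are population-standardised as DDD per 1000 panel patients per day
(DID): for a yearly total $D$ dispensed to a panel of $P$ patients,
$\mathrm{DID} = 1000\, D / (P \cdot d)$ with $d$ the true calendar length of
the year (366 in leap years; DID is defined per day, so calendar-true
denominators are used).

| indicator | definition | units |
|---|---|---|
| `j01_did` | all systemic antibacterials (J01) | DID |
| `j01c_did`, `j01d_did`, `j01f_did`, `j01m_did` | penicillins, cephalosporins, macrolides/lincosamides/streptogramins, quinolones | DID |
| `j01ce_pct`, `j01cr_pct`, `j01dd_de_pct`, `j01ma_pct` | share of total J01 DDDs: beta-lactamase-sensitive penicillins, penicillin/inhibitor combinations, 3rd/4th-generation cephalosporins, fluoroquinolones | % |
| `j01_bn_ratio` | broad-spectrum (J01CR + J01DC + J01DD + J01F without erythromycin) over narrow-spectrum (J01CE + J01DB + erythromycin) DDDs | ratio |
| `j01_sv`, `j01m_sv` | winter-over-summer excess, $100(\mathrm{DDD}_{winter}/\mathrm{DDD}_{summer} - 1)$, for J01 and J01M | % |

Group membership is decided by ATC prefix, so substance-level (7-character)
and chemical-subgroup (5-character) codes can be mixed in one extract. The
broad/narrow ratio is a plain quotient, not $\times 100$: narrow-spectrum
use in southern-European cohorts sits near half a percent of total volume,
which makes ratios of order $10^2$ and keeps them commensurable with
published national values.

**Seasonal years.** The two seasonal-variation indicators are computed on a
July-to-June year (winter = October–March). An extract covering calendar
years $Y_0 \dots Y_1$ supports complete seasonal years only from
$Y_0{+}1$ onward, so the seasonal year starting July of $Y{-}1$ is assigned
to analysis year $Y$ and both indicators are undefined for the boundary
year $Y_0$. This assignment is a declared convention of the package: the
choice is genuinely open (monthly extracts do not dictate it), and this rule
maximises the number of complete seasonal cycles inside a three-year window.

**Undefined values.** A zero denominator (no J01 volume for a share, no
narrow-spectrum volume for the ratio, no summer volume for seasonal
variation) makes the indicator *undefined* (`NA`), never 0: a physician who
dispensed nothing is not thereby a median-quality prescriber. Undefined
values propagate explicitly into classification.

## The AQPA rule

Each indicator is compared with a national reference value
(`reference_standard()` ships the Spanish values) under a declared
direction-of-better: lower is better for every indicator except the
narrow-spectrum penicillin share `j01ce_pct`, where higher consumption
reflects more conservative prescribing. The direction table is shipped as
data and can be overridden from a CSV config, because no published table of
directions exists — the set here follows antimicrobial-stewardship logic
(less volume, fewer broad-spectrum and reserve agents, flatter seasonality)
and the observed contrast that a *lower* narrow-spectrum share counts among
the unfavourable comparisons.

Two further conventions are deliberately strict:

* **Ties.** A value exactly equal to the reference is counted *worse*: the
  outcome requires values better *than* the reference.
* **Undefined indicators** count toward neither side, and the AQPA
  threshold stays at an absolute 6 of 12 (not half of the defined ones).
  With undefined or tied indicators a physician-year can satisfy neither
  "≥ 6 better" nor "≥ 6 worse"; `classify_aqpa()` therefore returns the
  full `n_better` / `n_worse` / `n_undefined` triple so the complementary
  rule can be applied downstream if wanted.

## The attitude model

For item $k$ with VAS score $x_{i}$ (constant over a physician's follow-up
years — the questionnaire is administered once), physician $i$, year $t$:

$$\operatorname{logit} P(\mathrm{AQPA}_{it} = 1 \mid u_i)
  = \beta_0 + \beta_k x_i + \gamma^\top z_i + u_i,
  \qquad u_i \sim N(0, \sigma_u^2),$$

with covariates $z_i$ = on-call duty (0/1), night shifts (0/1) and mean
panel size. One model is fitted per item; a joint multi-item model is
deliberately not fitted — the single-item screen mirrors the standard
reporting layout and avoids collinearity decisions that would otherwise be
arbitrary.

Fitting is by maximum likelihood through `lme4::glmer`. The likelihood is
integrated over the scalar random intercept by **adaptive Gauss–Hermite
quadrature with 9 nodes** rather than the Laplace approximation: with
$\sigma_u \approx 1$–1.5 and only three observations per physician, the
finite-difference Hessian of the Laplace fit is frequently degenerate
(standard errors collapse by two orders of magnitude and lme4 reports "very
large eigenvalue"), whereas the 9-node quadrature is stable at negligible
extra cost. If lme4's convergence checks fail, the fit is retried with the
derivative-free `bobyqa` optimizer; a fit that still fails is *flagged*, its
item reported as failed in the screen, and no estimates are propagated. The
`mean_panel` covariate is rescaled to thousands of patients before fitting
for conditioning.

**Interquartile odds ratio.** To express effects on the scale of realistic
contrast in the cohort, the coefficient is rescaled to the interquartile
shift of the item's score distribution: $\mathrm{IqOR} =
\exp\{\beta_k (q_{75} - q_{25})\}$, with Wald confidence limits
$\exp\{(\beta_k \pm 1.96\,\mathrm{SE}) (q_{75} - q_{25})\}$. Quartiles use
the median-unbiased definition (`quantile(type = 8)`) on scores snapped to
the 0.5-step VAS grid. An IqOR of exactly 1 arises when $\beta_k = 0$;
equal quartiles are a degenerate exposure and an error. Because most
protective attitudes give IqOR < 1, `percent_change()` renders those as the
inverse, $100(1/\mathrm{IqOR} - 1)$, read as the percent increase in the
odds of AQPA when exposure *falls* from the 75th to the 25th percentile;
the magnitude is symmetric under inversion. Percent changes are computed
from unrounded IqORs: recomputing them from a rounded two-decimal IqOR can
differ by a few points, which is why the rendering carries the unrounded
value through.

**Item retention.** Test–retest reproducibility is the single-measure,
absolute-agreement intraclass correlation from the two-way
subjects-by-administrations decomposition (ICC(A,1)); the variant is a
declared convention, since "the ICC" is ambiguous. Items are retained when
ICC is strictly above 0.5. P-values in the screen are unadjusted by
default, matching the single-item reporting convention; a
Benjamini–Hochberg column is available with `adjust = TRUE`.

## The synthetic cohort

`generate_cohort()` emulates a three-year regional primary-care cohort.
Defaults are fixed once, at the study conditions where those are known and
at field-realistic values where they are not:

* **1428 physicians, years 2008–2010**, log-normal panels with median 1329
  patients (`sdlog = 0.35`, a plausible dispersion for regional panel
  registers; panels jitter ±3% year to year).
* **Questionnaire**: 16 items on the 0.5-step VAS grid. Items 1–11 are the
  analysed knowledge/attitude items, with Beta-on-[0,10] distributions
  calibrated so their discretised quartiles reproduce the observed item
  quartiles (`vas_beta_from_quartiles()` fits shapes by grid search in
  log-shape space; every default target is achieved within the stated
  ±0.5-unit tolerance). Items 12–16 are filler items with test–retest
  reliability 0.3, so the ICC retention step reproduces the 11-of-16
  outcome. Retest scores (100 physicians, mirroring a pilot-sized
  subsample) are correlated copies at the item's reliability.
* **Latent quality**: $q_i = \sum_k \theta_k (x_{ik} - \bar x_k) + u_i$
  with $u_i \sim N(0, 1)$. The true effects $\theta_k$ (per VAS unit) are
  back-calculated from published-scale interquartile odds ratios (e.g.
  $-0.22$ for the strongest fear item, $+0.17$ for the knowledge item,
  zero for three null items), making the generator's effect sizes
  realistic in both sign and magnitude. No physician-level variance is
  reported anywhere to calibrate $\sigma_u$ against; 1.0 is a convention
  to be reported with results.
* **Prescribing**: monthly DDD totals per substance are negative-binomial
  (size 30) around an expected volume `baseline_did` (15.6 DID at $q = 0$)
  scaled by panel size, a winter multiplier of 1.25 on October–March, and
  $e^{-0.10 q}$ (volume falls as quality rises). The class mix over 13 J01
  cells (shares roughly matching a southern-European profile: 42%
  penicillin/inhibitor combinations, 13% fluoroquinolones, under 0.5%
  narrow-spectrum agents) is tilted on the log scale by $\pm 0.25 q$ away
  from broad-spectrum cells and toward narrow-spectrum ones. AQPA is
  **never drawn directly**: it emerges from the simulated prescriptions
  through the indicator engine and classifier, so an end-to-end test
  exercises every stage, not just the model.
* Monthly expected volume is flat across months apart from the winter
  multiplier (months are not day-length-weighted). This makes the expected
  seasonal-variation indicator exactly $100(w - 1)$ for winter multiplier
  $w$, a closed form the tests check against.
* DDD totals are integer negative-binomial draws under R's Mersenne–Twister
  with a fixed seed, so identical config + seed reproduces the cohort
  exactly, across platforms.

What the generator does **not** emulate: indication-linked prescribing (no
diagnosis is attached to a record), responder/non-responder mailing waves,
patient-level heterogeneity within a panel, secular trends across the three
years, and correlation between questionnaire items (items are drawn
independently). Passing tests therefore demonstrate that the pipeline
recovers known effects under a plausible data-generating process — not that
the specific published effect magnitudes would be recovered from the real,
confidential cohort.

## Problem sizes and numerical tolerances in the test suite

The suite checks the indicator engine against an independent per-record-loop
oracle (200 randomised small cohorts, exact to $10^{-12}$), parameter
recovery of the attitude model (200 replicates of 1000 physicians × 3
years: absolute bias of $\hat\beta$ below 0.02, 95% CI coverage within
95% ± 3 points), the null calibration of the Wald test (500 replicates at
300 physicians: rejection rate 5% ± 2 points), the closed-form seasonal
expectation (1000-physician cohort, mean `j01_sv` within 2 points of 25),
and an exhaustive threshold/tie/monotonicity grid for the classifier. These
replicate counts and cohort sizes were chosen so Monte-Carlo error sits
well inside each tolerance band.

## Known limitations

* The bundled J01 code list is a representative ~30-substance subset, not
  the full WHO register; ingest accepts any grammatically valid ATC code,
  but unlisted substances only contribute to groups by prefix.
* A single fixed reference standard is applied to all years; year-specific
  national references, if wanted, must be applied by running the classifier
  per year with different standards.
* Wald intervals (coefficient scale, then exponentiated) are the only CI
  method; profile or bootstrap intervals are out of scope.
* The model assumes the exposure is constant within physician; a
  time-varying questionnaire would need a different data layout.
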