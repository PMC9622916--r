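---
title: "Blood pressure, polygenic bladder-cancer risk, and their interaction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood pressure, polygenic bladder-cancer risk, and their interaction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpgrs)
```

# The question and the estimands

Bladder cancer has a substantial polygenic component, and systolic blood
pressure (SBP) has been associated with aggressive urothelial carcinoma
(UC) in men. `bpgrs` implements the analysis that asks whether the two act
together more strongly than separately — on the *additive* scale, which is
the scale relevant to public health (who gains most from intervention), and
on the *multiplicative* scale on which Cox models are naturally
parameterized.

Three estimands are produced per outcome (total, non-aggressive,
aggressive UC):

1. adjusted cause-specific hazard ratios for SBP, DBP and the weighted
   genetic risk score (wGRS), per SD and in clinical categories;
2. the relative excess risk due to interaction,
   $\mathrm{RERI} = RR_{11} - RR_{10} - RR_{01} + 1$, with a delta-method
   confidence interval, and the likelihood-ratio test for the product term;
3. 20-year absolute risks from age 60 per joint exposure group, with death
   as a competing event.

# The genetic risk score

The score is a dosage-weighted sum over 18 bladder-cancer susceptibility
variants identified in European-ancestry GWAS, divided by the number of
SNPs: $\mathrm{wGRS}_i = \sum_x \beta_x d_{ix} / 18$ with
$\beta_x = \ln(OR_x)$. The division only rescales the score — z-scores and
group splits are invariant to it — but is retained so raw scores are on the
conventional per-SNP scale.

Numerical choices:

* The bundled weight table prints $\ln(OR)$ to six decimals. The loader
  always recomputes $\ln(OR)$ at full floating-point precision from the OR
  column and validates the printed value to $10^{-6}$, so rounding is never
  compounded and transcription errors in either column fail loudly.
* Missing genotypes: the default policy excludes the individual (the
  motivating study excluded 405 men without genotype data); an alternative
  imputes the Hardy–Weinberg expectation $2\cdot\mathrm{EAF}$ per missing
  call. Standardization and group splits happen *after* exclusions, on the
  scored sample — the source analysis does not state the order, and the
  analysis-sample convention keeps z-scores interpretable for the people
  actually modeled.
* z-scores use the $n-1$ sample SD (conventional; the source is silent).
* Quartile boundaries: a value equal to a cut point falls in the lower
  group. This is deterministic, and with heavy ties it degrades gracefully
  (group sizes differ by at most the number of tied boundary values).
* VCF input uses the `DS` dosage field when present, otherwise hard `GT`
  calls. A variant whose ALT allele is the table's *other* allele is
  flipped ($d \mapsto 2-d$); alleles matching neither orientation are an
  error, not a silent drop.

# Survival models

All models are cause-specific Cox proportional-hazards fits with **attained
age as the time scale**: a person enters the risk set at baseline age
(left truncation) and leaves at exit age; competing events are censored at
their event age. Exit age is entry age plus follow-up years. Fitting is
delegated to `survival::coxph` with Efron tie handling (the modern default;
the source is silent on ties) and a convergence tolerance of $10^{-9}$;
the package's own test suite verifies the partial likelihood against
brute-force risk-set enumeration on a small left-truncated dataset.

Adjustment follows the motivating analysis: smoking in 5 categories
(never, ex, and three pack-year bands of current smokers), BMI quartiles,
physical-activity tertiles, education in 5 categories; complete cases per
model. Reference categories are the lowest level throughout. Trend tests
re-enter the ordered categories as a single 1..k term and use a two-sided
Wald test. Proportional hazards are checked with scaled Schoenfeld
residuals (`survival::cox.zph`); the pipeline logs violations rather than
failing, since the diagnostic is advisory.

One deliberate robustness choice: when an *adjustment* factor level
contains no events, its log-HR diverges to $-\infty$. The remaining
coefficients are valid limits, so the fit is kept with a warning naming the
term; divergence in an *exposure* term is still an error (separation).

# Interaction

**Additive.** The cohort is partitioned into four joint groups — reference
is normal BP (SBP < 140 mmHg, or DBP < 90) combined with the lower half of
the score; the median split is taken once and held fixed across BP
sensitivity cuts (130/150 mmHg). From the joint-group Cox fit,
$\mathrm{RERI} = e^{b_{11}} - e^{b_{10}} - e^{b_{01}} + 1$ with
delta-method variance $g^\top \Sigma g$, gradient
$g = (-e^{b_{10}}, -e^{b_{01}}, e^{b_{11}})$ over the three-term
sub-covariance, following the Hosmer–Lemeshow construction on the
relative-risk scale (not log-RERI), matching the method the source cites.
The Wald p-value uses $\mathrm{RERI}/\mathrm{SE}$. A nonparametric
bootstrap (`reri_bootstrap`) is provided as an optional cross-check of the
delta-method SE and is exercised in the acceptance suite.

**Continuous scale.** Both exposures are z-scored on the analysis sample
and the sample is restricted to $|z| \le 2$ — applied *jointly* to both
exposures (the source is ambiguous; the joint restriction keeps the four
implied "corners" inside the data). For increments $(\delta_1, \delta_2)$,

$$\mathrm{RERI}(\delta) = e^{\beta_1\delta_1+\beta_2\delta_2+\beta_3\delta_1\delta_2}
 - e^{\beta_1\delta_1} - e^{\beta_2\delta_2} + 1,$$

with the analogous delta-method gradient. The default increment is +1 SD in
each exposure; the source does not state the increments behind its
continuous-scale estimate, so that particular magnitude is not a
reproduction target and the increment is an explicit argument.

**Multiplicative.** The restricted model (main effects) is nested in the
full model (plus product term); the LR statistic
$2(\ell_{full}-\ell_{restricted})$ is referred to $\chi^2_{df}$ with df =
number of added terms. Identical term sets are treated as a degenerate
comparison (statistic 0, p 1) rather than an error.

SBP and DBP are analyzed separately (never as a combined 140/90 OR-rule),
with cut points 140 and 90 mmHg respectively.

# Absolute risk

Within each joint group, cause-specific hazards for the outcome and for
death are estimated as occurrence/exposure rates on 1-year attained-age
bands (events in a band divided by person-years in it), then plugged into
the piecewise-exponential competing-risk integral

$$\mathrm{risk} = \sum_j S_{j-1}\,\frac{h_{1j}}{h_{1j}+h_{2j}}
  \left(1 - e^{-(h_{1j}+h_{2j})w_j}\right),
  \qquad S_j = S_{j-1}e^{-(h_{1j}+h_{2j})w_j}.$$

This is the cause-specific-hazard variant of the Gail-type crude-risk
calculation; the source cites the method without details, so this variant
is the package's documented choice. Bands with zero person-years carry rate
0 with a logged note; a $0/0$ band contributes nothing. The construction
satisfies, and the tests assert, the exact two-cause decomposition
$\mathrm{risk}_1 + \mathrm{risk}_2 + S_{\mathrm{end}} = 1$, and 1-year
versus monthly bands agree to $<10^{-3}$ for smooth hazards.

Two further choices: hazards are crude within-group (no covariate
adjustment — the motivating absolute risks are presented by group, not
model-standardized), and death hazards are group-specific by default
because blood pressure affects mortality; `shared_death = TRUE` switches to
a common death hazard. No confidence intervals are produced (none are
reported in the source).

# The synthetic cohort generator

The generator's defaults *are* the stated world of the motivating study:

| Parameter | Default | Basis |
|---|---|---|
| n | 10,576 men | study analysis set |
| baseline age | Normal(59, 7) truncated to 45–73 y | published mean/SD/range; shape is the package's choice |
| administrative censoring | 27 y | 1991–96 baseline to end-2018 follow-up |
| SBP, DBP | bivariate normal, 144 (19) / 88 (10) mmHg, r = 0.7 | published marginals; correlation chosen (only marginals published) |
| covariate categories | published cohort proportions | smoking 5 levels, BMI N(26.3, 3.5²) with in-sample quartiles, activity tertiles, education 5 levels |
| baseline hazards | rate₆₀·e^{slope·(age−60)}; UC slope 0.08/y, death slope 0.09/y | age-increasing incidence; Gompertz-like mortality |
| rate₆₀ | 3.15·10⁻⁴ (non-aggr UC), 1.61·10⁻⁴ (aggr UC), 7.5·10⁻³ (death) | calibrated once by hazard integration so expected events ≈ 248/127 and mean follow-up ≈ 20 y |
| missingness | 405 genotype, 10 BMI, 24 education | published exclusion tallies; masking only, applied after event simulation |

Event times are piecewise-exponential on 1-year attained-age bands with
competing causes; the first of {non-aggressive UC, aggressive UC, death,
administrative censoring} ends follow-up. Effects enter the hazards
multiplicatively, with exposures standardized by their *theoretical*
moments so that injected log-HRs are exact truths for parameter-recovery
tests. Alternatively, an interaction is injected by assigning joint-group
relative risks directly (`joint_rr`), which makes the true RERI known in
closed form — the design choice that lets acceptance tests check coverage
against truth rather than against another estimator.

`expected_event_counts()` integrates the configured hazards over the
entry-age distribution, collapsing each cause's hazard multiplier to its
mean $E[e^{lp}]$ (closed form for normal exposures, direct summation for
categories). That independence approximation is accurate for the small
default effect sizes and serves as the oracle for simulated event counts.

What the generator does **not** emulate: linkage disequilibrium between the
18 variants (independent Binomial(2, EAF) draws), emigration as a separate
censoring cause (only death + administrative censoring; the published split
is unreported), antihypertensive-treatment dynamics, calendar-time effects,
and confounding between genotype and environment (independent by default).
A green test suite therefore establishes that the *methods* are correct and
calibrated under the stated world — not that the generator reproduces every
feature of the motivating cohort data, whose individual records are not
publicly deposited.

# Numerical and testing choices

* Replicate-based acceptance checks (type-I error 0.05 ± 0.02; CI coverage
  ≥ 93%; delta-method SE within 10% of a 1,000-replicate bootstrap SD) run
  at reduced replicate counts / cohort sizes chosen to fit a CI time
  budget; the thresholds are unchanged from their design values.
* The Cox oracle test uses untied event times so that Efron, Breslow and
  the exact partial likelihood coincide, and asserts agreement to
  $10^{-10}$ at both the MLE and the null.
* Seeds fully determine generator output; the pipeline writes a manifest
  (seed, version, exclusion tallies) and its CSV outputs are byte-stable
  across reruns.

# Known limitations

Aggressive-UC analyses at the default cohort size rest on ~120 events;
joint-group estimates are correspondingly noisy, exactly as in the
motivating study. The delta-method CI for RERI is symmetric and can be
anticonservative for very small event counts (the bootstrap cross-check is
provided for that reason). The absolute-risk estimator inherits the
rare-event granularity of 1-year bands: groups with little exposure time in
a band get a zero rate rather than a smoothed one.
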