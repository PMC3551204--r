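---
title: "Joint modelling of physiological aging trajectories and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of physiological aging trajectories and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmaging)
```

## The model

`spmaging` analyses longitudinal measurements of one physiological index
(body-mass index, diastolic blood pressure, serum cholesterol, ventricular
rate, ...) jointly with mortality. The index $Y_t$ of one person follows
mean-reverting stochastic dynamics

$$dY_t = a(t)\,(Y_t - f_1(t))\,dt + \sigma_1\,dW_t,$$

where $f_1(t)$ is the *allostatic set point* — the level the index is
forced toward by homeostatic regulation under persistent external
disturbances — and $a(t) < 0$ is the *adaptive capacity*, the strength of
that negative feedback (larger magnitude = faster return to the set
point). Mortality is informative about the hidden trajectory through a
U-shaped conditional hazard

$$\mu(t, Y_t) = \mu_0(t) + Q(t)\,\bigl(Y_t - f_0(t)\bigr)^2,$$

minimised on the *physiological norm* $f_0(t)$: $\mu_0(t)$ is the
mortality a person would face if the index tracked the norm exactly, and
$Q(t) \ge 0$ measures how sharply risk rises with deviations (an inverse
proxy for stress resistance). The gap $|f_1 - f_0|$ is the allostatic
load.

The fitted version uses linear $a(t) = a_Y + b_Y t$ and
$Q(t) = a_Q + b_Q t$, a Gompertz baseline
$\mu_0(t) = a_{\mu 0} e^{b_{\mu 0} t}$, a cubic norm $f_0(t)$ (fixed
during likelihood maximisation, estimated beforehand from long-lived
subjects), a linear offset $f_1 = f_0 + a_{f0d} + b_{f0d}\,t$, and
normal initial values $N(f_1(t_0), \sigma_0^2)$ — ten free parameters
per group.

### Population-average dynamics

Among survivors the conditional law of $Y_t$ stays Gaussian with mean
$m(t)$ and variance $\gamma(t)$, and

$$\frac{dm}{dt} = a(t)\,(m - f_1(t)) \;-\; 2\gamma(t)\,Q(t)\,(m - f_0(t)).$$

The two terms are the two feedback mechanisms shaping observed average
trajectories: homeostatic adaptation toward $f_1$, and *mortality
selection* — people far from the norm die sooner, pulling the survivor
mean toward $f_0$. The variance needs a companion equation to close the
system; we use

$$\frac{d\gamma}{dt} = 2a(t)\,\gamma + \sigma_1^2 - 2Q(t)\,\gamma^2,$$

whose three terms are feedback contraction, diffusion, and the
variance shrinkage from conditioning a Gaussian on survival under an
exponential-quadratic weight. Because the variance equation is our own
closure rather than a published formula, it is treated as a hypothesis
and *validated by simulation*: `integrate_mean_trajectory()` (fixed-step
4th-order Runge-Kutta, step 0.25 y) is required to agree with survivor
ensembles of 50,000 independently simulated trajectories
(`simulate_ensemble()`, Euler step 0.1 y) within 3 Monte-Carlo standard
errors at every integer age from 40 to 90, for three parameter sets
including age-increasing and age-decreasing $Q(t)$. The ensemble oracle
deliberately uses a fine Euler step: it approximates the continuous
dynamics that the ODE describes, whereas the cohort generator works on
the one-year grid shared with the likelihood (below) — comparing the ODE
with a one-year-step ensemble would measure the discretisation gap, not
the correctness of the equations.

## The likelihood

Estimation uses a discrete-time conditional-Gaussian filter on an
integer-year age grid (exam and event ages rounded to the nearest year;
when two exams round to the same year the first is kept). Per subject:

* the first usable exam ($\ge$ 40 years; the norm is only estimable
  from age 40) contributes the entry density $N(f_1(t_0), \sigma_0^2)$.
  Conditioning on survival to entry is implicit — no survival terms
  accrue before it (standard delayed-entry treatment);
* observations are treated as exact: each later exam contributes the
  predictive Gaussian density and resets the belief to $(y, 0)$;
* each whole year lived multiplies in the one-year survival factor
  under the current belief. With $k = 1 + 2Q\gamma$,
  $$E\left[e^{-\mu(t, Y)}\right] = e^{-\mu_0}\,k^{-1/2}
  e^{-Q\,(m - f_0)^2/k},$$
  and survivors keep a Gaussian belief with
  $m^* = f_0 + (m - f_0)/k$, $\gamma^* = \gamma / k$ (the conjugate
  update; verified against numerical quadrature to relative error
  below $10^{-8}$), followed by the one-year dynamics step
  $m' = m + a(m - f_1)$, $\gamma' = (1+a)^2 \gamma + \sigma_1^2$;
* a death in year $T$ contributes $1 - E[e^{-\mu(T, Y)}]$ under the
  belief at $T$ — the within-year death probability consistent with the
  survival factor, so probability mass is conserved inside each year.

A first-order (linearised) alternative to the conjugate selection
update, $m^* = m - 2\gamma Q (m - f_0)$, differs from it only at
$O((Q\gamma)^2)$; we use the exact conjugate form throughout because it
is the closed-form moment of the exponential-quadratic weight (the
quadrature check above is the arbiter).

With $Q \equiv 0$ and no deaths the filter reduces to an exact
linear-Gaussian state-space likelihood, which the tests verify against
an independently coded recursion to $10^{-10}$; a three-node toy
subject is checked against brute-force numerical integration of the
trajectory law. The cohort likelihood is the sum over subjects; a
compiled kernel (with exact forward-sensitivity gradients) mirrors the
readable R implementation and the two are asserted to agree.

Missing index values at attended exams drop the observation term but
keep the survival terms. Subjects with no usable exam are excluded and
counted, not fatal.

## Estimation and the group tests

`fit_group()` maximises the cohort log-likelihood subject to the shape
constraints: $a(t) < 0$, $Q(t) \ge 0$ and $f_1(t)$ inside per-index
plausibility bounds on the age window [40, 110], $\mu_0 \ge 0$,
$\sigma_0, \sigma_1 \ge 0$. Because $a$, $Q$ and $\Delta f_0$ are
linear in age, constraining their two *endpoint values* on the window
constrains them everywhere, so the whole problem becomes box-constrained
and is solved with `nlminb` (PORT) using the analytic gradients. Numerical
choices that matter:

* **Scaling.** The parameters span five orders of magnitude; the
  optimiser is given per-component scales (without them it stalls).
* **Starts.** The default start is moment-based: a lag regression of
  exam-to-exam changes for $a$ and $\sigma_1$, the spread of first
  values for $\sigma_0$, a crude Gompertz fit of person-year death
  rates for $\mu_0$. The likelihood can have a second basin in which
  the Gompertz baseline absorbs the mortality that belongs to the
  quadratic term, so the second start places $Q$ at a moment scale
  (half the crude death rate over the mean squared deviation from the
  norm); further starts are seeded perturbations. A restart polish
  re-launches from the incumbent until the objective stops improving,
  which cures premature PORT stops on ridges. Seeded runs are exactly
  reproducible.
* **f1 bounds.** Default plausibility bounds per index role (BMI
  15-45 kg/m², DBP 50-120 mmHg, SCH 120-350 mg/dl, VR 40-120 bpm),
  overridable. The $\Delta f_0$ endpoints use the slightly conservative
  box $[\text{lo} - \min f_0, \text{hi} - \max f_0]$, which guarantees
  feasibility on the whole window; returned fits are re-checked on a
  half-year grid.
* **Standard errors** come from the numerical Hessian at the optimum,
  computed in a scaled space; they are reported for recovery checks and
  can be singular when a parameter sits on a boundary.

The norm $f_0(t)$ is estimated first (`fit_norm_polynomial()`): a
least-squares cubic through the age-binned mean trajectory of subjects
whose lifespan exceeds 90 years (deaths after 90 or censoring beyond
90 — a censored 95-year-old has demonstrably lived past 90), refusing to
fit on fewer than five populated bins.

`fit_two_groups()` compares carriers of few vs. many pro-survival
alleles: the unrestricted model gives each group its own ten parameters;
each restricted model equates one pair across groups — baseline hazard
$(a_{\mu 0}, b_{\mu 0})$, quadratic term $(a_Q, b_Q)$, adaptive
capacity $(a_Y, b_Y)$, or allostatic trajectory $(a_{f0d}, b_{f0d})$ —
and refits jointly (18 parameters). `likelihood_ratio_test()` refers
$2\Delta\ell$ to $\chi^2_2$. Whether restricted fits should re-estimate
$f_0$ is an open choice; $f_0$ stays fixed throughout here, which keeps
the four tests comparisons of the *dynamic* and *hazard* components
only.

The $\chi^2$ reference presumes interior regularity. When the true
$Q(t)$ is small relative to its sampling noise, estimates pile on the
$Q \ge 0$ boundary and the quadratic-term test becomes conservative —
real behaviour of boundary LRTs, not a defect of the implementation.
The calibration study in the test suite therefore simulates its null at
a well-identified interior parameter set ($a_Q = 4\times 10^{-3}$,
every parameter several SEs inside its bounds at the study sizes); the
boundary regime is exercised separately by a death-free cohort whose
fitted $Q$ is asserted to be driven to zero and reported in
`bounds_active`.

## The empirical machinery

The descriptive arm pools all exam measurements and averages them in
the fixed age bins `<35`, `35-39`, ..., `85-89`, `90+`; bins with fewer
than 10 observations are suppressed. Group means are compared per bin
with Welch's unequal-variance test (the underlying study annotates its
figures with a p-value test of equal bin means but does not name the
test; Welch over pooled measurements — ignoring within-subject
correlation, as the pooled SEs do — is our documented choice), and
p-values map to the band symbols `""` ($p \ge 0.05$), `*`, `#`, `!`,
`!!` ($p < 10^{-4}$).

Stratifications (`stratify()`): short-lived = died at 75 or earlier
(censored excluded); longest-lived = lifespan beyond 97.44 years;
healthy/unhealthy is a *measurement-level* split at the onset of
unhealthy life (the earliest of first cancer, CVD, diabetes);
dose = carrier count $<14$ vs $\ge 14$; APOE-e4 carriage = genotype
containing allele 4.

The dose itself (`polygenic_score()`) counts, over the 27-SNP panel,
the SNPs carrying at least one minor allele (0-27). A missing genotype
counts as non-carrier by default (conservative); `require_complete`
drops incomplete subjects instead. `fit_cox_dose()` regresses
cause-specific mortality on the integer score in a left-truncated Cox
model on the age scale (entry at biospecimen collection), adjusted for
sex, decade of birth (categorical) and ever-smoking, with Efron tie
handling; competing causes are censored at the death age and `other`
includes unknown causes.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the analyses
assume, not any particular study's records: genotypes are
Hardy-Weinberg draws at the panel minor-allele frequencies
(independent loci — no linkage disequilibrium); entry ages are uniform
on 40-60; exams are biennial with 10% missing values; administrative
censoring at 100. Two mortality modes:

* **spm**: yearly Euler dynamics for the index; each year death occurs
  with probability $1 - e^{-\mu(t, Y_t)}$. Death is simulated on the
  same one-year grid the likelihood uses, so generator and estimator
  share the discretisation and recovery tests measure estimation error,
  not discretisation mismatch. A death drawn in year $[t, t+1)$ is
  recorded at age $t + U(0, 0.5)$: rounding returns it to year $t$
  (grid preserved) while survival-time follow-up stays positive.
* **ph**: continuous event times by inverse transform of a Gompertz
  cumulative hazard multiplied by $e^{\beta \cdot \text{dose}}$ and
  covariate effects, with cause-specific components sharing one
  Gompertz slope (which keeps the all-cause inversion closed-form and
  makes cause assignment a simple multinomial). These data satisfy the
  Cox model assumptions exactly, which is what the dose-recovery
  studies require; the yearly Bernoulli grid would attenuate the
  per-allele effect through grouping and ties.

Default group parameters are *illustrative*: a BMI-like index whose
norm peaks near age 55 in the low-dose group and near 75 in the
high-dose group, with the high-dose group given stronger adaptive
capacity, a lower baseline hazard and an age-decreasing quadratic term.
No fitted real-data parameter values are published for this model
family, so the defaults encode the qualitative contrasts only. The
proportional-hazards defaults (Gompertz level $8.5\times 10^{-5}$,
slope 0.085, censoring at 100) were chosen once so that roughly 86% of
~1500 subjects die — the event/censoring balance of the genotyped
mortality table that serves as simulation ground truth; cause weights
0.29/0.19/0.52 match its event mix, and the per-allele log hazard
ratios (total −0.057; CVD −0.047, cancer −0.030, other −0.071) are the
published effect sizes used as generating truth. Disease onsets default
to Gompertz first-passage times independent of the index; a coupling
hook (onset log-rate shifted by the deviation from the norm) exists but
is off by default, because the stratification machinery only needs
onsets to exist.

What passing tests on these cohorts does **not** show: robustness to
real-data features the generator omits — linkage disequilibrium between
loci, measurement error in the index, informative exam attendance,
secular (birth-cohort) trends in the index, non-Gompertz baselines, or
dependence of onsets on the trajectory. Conclusions about those require
real data.

## Problem sizes used in the checks

The shipped studies use sizes chosen to make each check decisive at
desk scale: survivor ensembles of 50,000 trajectories; parameter
recovery with 20 replicate cohorts of n = 2000 (each parameter's mean
estimate within 2 per-fit SEs of truth; relative bias of $a_Y$,
$b_{\mu 0}$, $\sigma_1$ under 10%); LRT null calibration with 100
replicate pairs of n = 500 per group (rejection rates at
$\alpha = 0.05$ required in [0.02, 0.09]) and power with 20 pairs of
n = 1500 per group against a doubled Gompertz level; Cox dose recovery
averaged over replicate cohorts of n = 1500. The acceptance script
averages 50 replicates.

## Known limitations

One index at a time (no vector SPM); constant $\sigma_1$; quadratic
hazards only; observations treated as exact (no measurement-error
layer); the one-year grid makes within-year timing of exams and deaths
irrelevant by construction; the variance closure is validated by
simulation rather than derived in print; Hessian standard errors are
unreliable at constraint boundaries.
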