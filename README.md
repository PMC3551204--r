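# spmaging

Joint modelling of longitudinal physiological indices and mortality for
aging research: who ages how, and what longevity-associated alleles do
to the trajectory.

Epidemiological cohorts that examine participants every couple of years
accumulate two intertwined kinds of information: the age trajectory of
physiological indices (body-mass index, diastolic blood pressure, serum
cholesterol, ventricular rate) and survival. Average trajectories of
such indices are non-monotonic — they rise to a mid-life peak and then
decline — and the decline partly reflects *mortality selection*: people
whose index strays far from its optimum die earlier and drop out of the
average. Analysing the trajectories without the deaths (or vice versa)
therefore misleads. `spmaging` implements a quadratic-hazard stochastic
process model that treats both at once, plus the empirical machinery
around it (age-binned trajectory comparison between strata, and
polygenic-score survival analysis), and a synthetic-cohort generator so
the whole pipeline is testable without access-controlled data.

## The model

One person's index $Y_t$ is mean-reverting with negative feedback
(*adaptive capacity*) $a(t) = a_Y + b_Y t < 0$ toward an *allostatic set
point* $f_1(t)$:

$$dY_t = a(t)\,(Y_t - f_1(t))\,dt + \sigma_1 dW_t ,$$

and dies at rate minimised on the *physiological norm* $f_0(t)$:

$$\mu(t, Y_t) = a_{\mu 0} e^{b_{\mu 0} t} + \bigl(a_Q + b_Q t\bigr)\,
(Y_t - f_0(t))^2 .$$

$f_0$ is a cubic in age fitted to the binned mean trajectory of
long-lived subjects (lifespan > 90) and held fixed;
$f_1 = f_0 + a_{f0d} + b_{f0d}t$. The likelihood is a conditional-
Gaussian filter on a one-year age grid with exact observations,
closed-form one-year survival factors, and a death term that conserves
within-year probability mass. Fitting is constrained maximum likelihood
(a(t) negative, Q(t) non-negative, f1 within plausibility bounds, all
on ages 40–110); groups — e.g. carriers of `<14` vs `>=14` of 27
pro-survival alleles — are compared with likelihood-ratio tests of
equal baseline hazards, quadratic terms, adaptive capacities, and
allostatic trajectories. Alongside the model sit the descriptive tools:
pooled age-bin means with SEs (bins `<35`, `35-39`, …, `90+`; bins with
fewer than 10 observations suppressed), Welch per-bin group tests with
the band symbols `*`, `#`, `!`, `!!`, lifespan/health/dose/APOE
stratifications, and a left-truncated Cox model of the polygenic
carrier-count score against total and cause-specific mortality.

See `vignettes/spm-methods.Rmd` for the full account (variance closure,
filter, optimiser, generator assumptions, limitations).

## Worked example

```r
library(spmaging)

cfg <- simulation_config(n_subjects = 400, seed = 11)
cohort <- simulate_cohort(cfg)
print(cohort)
#> spm_cohort: 400 subjects, 6475 exam records (BMI),
#>   genotypes for 400 subjects at 27 SNPs

# dose-group trajectories: mid-life bin, low- vs high-dose carriers
tab <- trajectory_table(cohort, scheme = "dose", index = "BMI")
subset(tab, bin == "60-64")
#>    index group   bin   n     mean         se            p band
#> 7    BMI   <14 60-64 232 28.05694 0.14817942 1.527602e-27   !!
#> 20   BMI  >=14 60-64 590 26.04835 0.08498965 1.527602e-27   !!

# norm trajectory from the long-lived
f0 <- fit_norm_polynomial(cohort, "BMI")
#> Norm trajectory f0(t): cubic fitted to long-lived binned means
#>   coefficients (low->high degree): 27.4579, -0.11243, 0.00251088, -1.50649e-05

# polygenic dose vs total mortality, left-truncated Cox
co_ph <- simulate_cohort(simulation_config(n_subjects = 1500, seed = 12,
                                           mode = "ph"))
fit_cox_dose(co_ph, "total")
#> Cox dose model, cause = total: 1337 events, 163 censored
#>   beta = -0.0528 (SE 0.0109), p = 1.34e-06, HR = 0.949 (95% CI 0.928-0.969)
```

Reading the output: in this synthetic cohort the low-dose group runs
about 2 BMI units above the high-dose group at ages 60–64 (`!!` =
p < 1e-4 for equal bin means); the fitted norm cubic peaks in late
mid-life; and each additional pro-survival allele multiplies the total
mortality rate by ≈ 0.95 (the cohort was generated with per-allele
effects of that size, so the Cox fit is recovering its generating
truth).

The `analysis/` directory holds the numbered drivers that run the full
study on synthetic cohorts — `01_simulate_cohort.R` (generate + validate),
`02_trajectories.R` (stratified trajectory tables), `03_spm_fits.R`
(norm fit, two-group model fits, the four LRTs), `04_dose_survival.R`
(cause-specific Cox) — each writing its tables under `results/`.

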