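# srwassess

Population-dynamics assessment tools for the southwestern Atlantic southern
right whale (*Eubalaena australis*), a population hunted from the
seventeenth century until 1973 and still recovering from severe depletion.
The package is aimed at quantitative ecologists and stock-assessment
scientists who need to reconstruct a catch history from uncertain archival
sources, turn repeated aerial counts of a breeding ground into an annual
index of arrivals, and estimate pre-exploitation abundance, depletion and
recovery with a Bayesian state-space production model.

## What it implements

**Catch reconstruction.** Archival whaling returns (often reported as oil:
1 tun = 8 barrels, 1 cask = 6.5 barrels, ~60 barrels per right whale) yield
a low and a high annual catch series. The effective removals in year *y*
are

    C_y = C_y,min + pi * (C_y,max - C_y,min),      pi in [0, 1]

inflated by era-specific struck-and-lost factors (SLR1 for 1771–1850, SLR2
for 1851–1973, none outside).

**Relative-abundance index.** Daily whale counts from repeated flights are
modelled as negative-binomial with a log-link quadratic in Julian day and a
categorical year effect (no whales before day 100). Because individuals
stay only part of the season (residence ~ N(60 d, 8.66 d)), occupancy is
deconvolved into cumulative arrivals via

    A_x = W_x + sum_{k=1..x} p_k A_{x-k},          A_0 = 0,

and the season total A_320 is the index for the year; its joint log-scale
covariance is obtained by resampling the GLM coefficients.

**State-space production model.** An age/sex-aggregated theta-logistic
state process

    N~_{y+1} = max{ N_c, N_y + Rmax N_y [1 - (N_y/K)^z] - C_y SLR_y }
    N_y | N~_y ~ lognormal(log N~_y, sigma^2)

with N fixed at K before exploitation, a 72-whale floor N_c from mtDNA
haplotype counts (24 x 3), and the shape z solved from P_MSY via
P_MSY = (1+z)^(-1/z). The model is parameterised *backwards*: a prior sits
on a recent abundance and K is back-solved per draw by bisection. Fitting
is by sampling-importance-resampling with catchability integrated out
analytically (GLS estimate q̂ under a flat log-q prior), a multivariate
lognormal likelihood for the index and a univariate lognormal likelihood
for the one absolute estimate (4,245, SE 245, in 2010). Fifteen named
scenario configurations, Bayes-factor model averaging and posterior
predictive checks complete the workflow, and a synthetic-data module
generates full assessment datasets with known truth.

## Worked example

```r
library(srwassess)

oil_to_whales(480, "tun")                         # 64 whale equivalents

synth <- generate_assessment_dataset(default_truth(), seed = 1)
eff   <- effective_catches(synth$catch_bounds, pi = 0.5)
sum(eff$catch_effective)                          # 87,239 effective removals

dat <- synthetic_assessment_data(synth, n_rep = 500, seed = 2)
round(dat$index$A[1:5])
#  1999 2000 2005 2006 2007
#  1258 1209 1240 1316 1549

fit <- run_sir(dat, n_importance = 20000, n_out = 20000, seed = 3)
fit$n_unique                                      # 795 unique draws
summarize_posterior(fit)
```

which prints (truth: K back-solved at 65,394; Rmax 0.012; q 0.36):

```
   parameter     mean   median     q2.5    q97.5
1      r_max 1.55e-02 1.54e-02 4.14e-03 2.77e-02
2          k 6.55e+04 6.48e+04 3.66e+04 9.57e+04
5       qhat 3.50e-01 3.53e-01 3.11e-01 3.93e-01
6      n_min 2.11e+03 2.01e+03 9.45e+02 3.45e+03
7     n_2021 5.04e+03 5.00e+03 4.15e+03 5.95e+03
10    p_2021 8.18e-02 7.94e-02 4.80e-02 1.39e-01
```

The posterior covers the truth for every parameter: pre-exploitation
abundance ~65,000 whales, a bottleneck of ~2,000, current depletion ~8%,
and roughly a third of the population visiting the surveyed breeding
ground each year. A posterior predictive check
(`posterior_predictive_check(fit)`) places 11 of the 17 index points
inside the interquartile predictive band and all 17 inside the 95% band.

Scenario runs, model averaging and checks are also available from the
command line:

```sh
exec/assess run --synthetic 3 --config base --draws 200000 --out runs/base
exec/assess average --runs runs --out runs/averaged
exec/assess ppc --run runs/base --out ppc.csv
```

## Documentation

The methods vignette (`vignettes/assessment-methods.Rmd`) describes the
model, its assumptions, the synthetic world and the numerical choices in
detail.
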