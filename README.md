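# dyadRecip

Stationary and dynamical reciprocity in directed social-event networks.

`dyadRecip` analyses temporal, directed networks of hosting events —
family *i* hosts family *j* on day *t* — recorded through intermittent
interviews, the situation typical of ethnographic field studies of food
sharing or communal drinking in small communities. It answers two
questions about reciprocity that require different machinery:

* **Stationary reciprocity (contingency).** Does the long-run rate at
  which *i* hosts *j* predict the rate at which *j* hosts *i*, after
  controlling for kinship, household distance and family traits? Modelled
  at the risk-day level with a crossed-random-effects logistic regression

  logit P(*i* hosts *j* at *t*) = α<sub>i</sub> + α<sub>j</sub> +
  α<sub>ij</sub> + **X**β,

  with host, guest and dyad random intercepts (via `lme4`), AIC model
  selection, permutation significance, and variance-explained accounting
  for the dyad component.

* **Conditional-action reciprocity.** Does "*i* hosts *j*" raise the
  probability of the return event "*j* hosts *i*" within a few days,
  beyond the pair's stationary rates? Estimated by the
  windowing-corrected ratio

  R̂<sub>ij</sub>(Δt) = N<sub>hh</sub> N<sub>oo</sub> /
  (N<sub>ho</sub> N<sub>oh</sub>),

  where the four N are sums of h/o indicator products over day pairs at
  lag Δt and o<sub>ij</sub>(t) marks the days an event could have been
  recorded at all. Class-averaged, null-renormalized curves are tested
  against a three-level hierarchy of stationary null models (one rate per
  host; per host × kin stratum; per ordered pair) with Monte-Carlo
  bands and upper-tail p-values.

Because raw field data of this kind are rarely deposited, the package
ships a synthetic village-and-events generator (`makeVillage`,
`simulateEvents`, `simulateInterviews`, `simulateStudy`) with known
ground truth — kin-structured demography and settlement, heterogeneous
host propensities, seasonal activity, guest under-reporting, and an
injectable conditional-reciprocity kernel — so the whole pipeline is
testable end to end.

## Worked example

```r
library(dyadRecip)

study  <- simulateStudy(simParams(seed = 1))   # 35 families, 112 days
relmat <- familyRelatedness(study$village)

study$panel
#> EventPanel: 1190 ordered dyads x 112 days
#>    1107 hosting events on 96352 risk days (rate 1.149%)

null <- fitNull(study$panel, relmat, "full_heterogeneous")
ens  <- sampleNull(null, observable(study$panel), 999, seed = 38)
classCurve(study$panel, ens, relmat, "not_close_kin", lags = 1:3)
#> ReciprocityCurve [not_close_kin vs full_heterogeneous null, 999 realizations]
#>   pooled (lags 1-3): R = 1.37 (null mean 1), p = 0.115, 99 pairs
```

Read: among the 99 ordered non-close-kin pairs with hosting observed in
both directions, the short-lag (≤3 day) conditional return probability is
1.37× its stationary expectation for this realization, with an
upper-tail Monte-Carlo p of 0.115 against a null preserving every
pairwise stationary rate. (The generator's default kernel is a 3-fold
hazard boost; single 112-day realizations recover it noisily, which is
exactly what the power experiments in the test suite quantify.) The
stationary side works the same way:

```r
distmat <- familyDistances(study$village)
tab  <- assembleDesign(study$panel, study$village, relmat, distmat)
fitA <- fitHierLogistic(tab, standardSpecs("A")$A, nAGQ = 0)
round(varComponents(fitA), 2)
#>  dyad guest  host
#>  2.43  0.00  1.43
round(oddsRatios(fitA)["guestOnly"], 3)
#> guestOnly
#>     0.363
```

The guest-only odds ratio below one quantifies guest under-reporting
(the generator's default reporting probability is 0.38). `runFull()`
executes the whole pipeline — summaries, the regression ladder A–F,
curves for all three null levels and kin classes — from a single config
list or YAML file and writes a structured report.

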