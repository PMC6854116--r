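# coniferisk

Risk models for predicting which non-native conifer-specialist insects
will cause **high-impact invasions** — tree mortality at the population or
regional scale (levels 6–9 of a nine-level impact scale) — on novel North
American conifer hosts. The package is written for forest-invasion
ecologists and biosecurity analysts who want to score insect × host
combinations before the damage is observable.

## The model

Three logistic submodels, selected by AICc multimodel inference, each
predict the probability of high impact for an insect–host pair:

* **Host evolutionary history** — quadratic in x = log₁₀(divergence time,
  mya) between the novel host and the insect's closest native host,
  fitted per feeding guild: logit P = β₀ + β₁x + β₂x². Folivore risk
  peaks at ≈ 2.7 mya, sap-feeder risk at ≈ 15 mya; both curves collapse
  towards zero for very recently or very anciently diverged hosts.
* **Host traits** — shade tolerance + drought tolerance of the novel host
  (reference levels low/none); predictions span 0.014–0.259.
* **Insect evolutionary history** — presence of a native congener on the
  shared host (P drops from 0.102 to 0.013), on hosts with adequately
  documented insect faunas.

The submodels pool into a composite risk in logit units:

    R(t,i) = logit(P̄…) + (1/N) Σₘ [ logit(P̂ₘ) − logit(P̄ₘ) ]

summing over the N ∈ {1,2,3} submodels available for the pair, where P̄ₘ
is submodel m's training prevalence and P̄… = 0.072 the overall
high-impact prevalence. Supporting machinery: AICc/Akaike weights and
ΔAICc ≤ 2 confidence sets, G² likelihood-ratio tests, Nagelkerke R²,
Blomberg's K randomization test for phylogenetic signal, equal-count
calibration bins, 10-fold cross-validation and ROC/AUC, and a synthetic
census generator (58 insects × 49 hosts × 221 pairs by default) that
exercises the full pipeline without the archived field data.

## Worked example

```r
library(coniferisk)

# a sap-feeder on a host diverged ~16 my from its closest native host
sap <- published_guild_model("sap_feeder")
predict_guild_risk(sap, c(5, 16, 50))
#> [1] 0.000 0.117 0.000

# the host is shade-tolerant and drought-intolerant ...
predict_host_trait_risk("high", "low")
#> [1] 0.209

# ... and no native congener feeds on it
predict_congener_risk(c(0, 1))
#> [1] 0.102 0.013

# composite risk for that pair (baselines from the study census)
ctx <- composite_context(
  c(host_traits = 0.072, host_evolution = 0.084, insect_evolution = 0.069),
  overall_baseline = 0.072)
r <- composite_risk(c(host_traits = 0.209,
                      host_evolution = predict_guild_risk(sap, 16),
                      insect_evolution = 0.102), ctx)
round(c(r$risk_logit, r$risk_prob), 3)
#> [1] -1.883  0.132
```

A pair that is unremarkable on every axis sits at the 0.072 baseline;
this one — intermediate divergence, vulnerable host, no competing
congener — is boosted to a 13% chance of a high-impact invasion.

The end-to-end analysis lives in `analysis/01_simulate_census.R` through
`analysis/05_validation.R`: simulate a census, quantify phylogenetic
signal of host traits, rank the candidate model sets, score composite
risks with a 10-bin calibration table, and cross-validate. Each script
prints what it found and writes tables under `results/`.

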