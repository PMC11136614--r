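# lcscomp

Latent change score (LCS) structural equation models for the head-to-head
comparison of two generative theories of psychopathology:

- **Common cause** — one latent liability (a general *p* factor over symptom
  domains, or a single depression factor over symptom parcels) drives all
  developmental change; downstream indicators change only because the
  liability changes.
- **Dynamic mutualism** — several distinct symptom domains drive *each
  other's* change through reciprocal coupling, and the positive manifold
  emerges from those interactions rather than from a shared cause.

The package is aimed at researchers in developmental psychopathology and
longitudinal methodology who want to translate these verbal theories into
fully specified SEMs, fit them to wide panel data (with missingness), and
arbitrate between them with information criteria — or to study how well
that arbitration works on synthetic cohorts where the generating truth is
known.

## The models

Both theories are expressed as latent change score models. For a construct
`y` measured at waves `t = 1..W`, the autoregression between successive
occasions is fixed to 1 so the residual becomes an explicit change factor:

```
y[t] = 1 * y[t-1] + Δy[t]
Δy[t] = α[t] + φ[t] * y[t-1] + Σ_src γ[src,t] * y_src[t-1] + ζ[t]
```

`α` is the mean change over the interval, `φ` (self-feedback) regresses a
construct's change on its own previous level, and `γ` (coupling) regresses
it on *another* construct's previous level — the mutualism mechanism,
analogous to the M matrix of the mutualism model of intelligence. The
change residuals `ζ` carry the variance of change; their covariances are
fixed to zero under the common-cause reading and free under mutualism.
The common-cause models place a single LCS chain on the liability (with a
higher-order *p* factor over four correlated first-order domains in the
42-item adolescent design, or a one-factor model over two symptom parcels
in the older-adult design); the mutualism models place one coupled chain
per domain with no superordinate factor.

Estimation is plain maximum likelihood with full-information handling of
missing cells (FIML): each row contributes the Gaussian log-density of its
observed subset. Model comparison uses the χ² test against the saturated
model, RMSEA (with 90% CI), CFI, SRMR, AIC/BIC, and Akaike/Schwarz weights;
longitudinal measurement invariance is tested with the ΔCFI > .01 rule and
repaired by a sequential partial-invariance search.

## Worked example

Simulate a mutualism-world cohort on a direct-score bivariate design,
then run the study-shaped comparison:

```r
library(lcscomp)

cfg    <- config_bivariate_direct(n = 1500, waves = 4,
                                  world = "mutualism", seed = 42)
cohort <- simulate_cohort(cfg)
study  <- run_study(cohort, seed = 1)
study$comparison[, c("model", "chisq", "df", "cfi", "aic", "bic",
                     "akaike_weight")]
#>          model     chisq df    cfi   aic   bic akaike_weight
#> 1 common_cause 1.028e+03 21 0.8992 28596 28718    8.961e-215
#> 2    mutualism 9.175e-09  0 1.0000 27610 27844     1.000e+00
```

The data were generated with reciprocal coupling, and the comparison says
so: the mutualism model takes essentially all of the Akaike weight (the
normalized probability of being the best model in the compared set). The
fitted coupling parameters recover the generating value `γ = 0.2`, with
standardized effects `β` computed from the model-implied SDs:

```r
est <- tidy(study$fits$mutualism)
est[grepl("^gamma_", est$label), ][1:4, ]
#>              label    b    se beta    z p.value
#> 1 gamma_mot_aff_w2 0.19 0.019 0.25  9.9 3.7e-23
#> 2 gamma_mot_aff_w3 0.23 0.028 0.34  8.1 6.2e-16
#> 3 gamma_mot_aff_w4 0.24 0.044 0.38  5.4 6.3e-08
#> 4 gamma_aff_mot_w2 0.20 0.019 0.28 11.0 3.9e-28
```

Model bookkeeping is available without any data. The preregistered
older-adult common-cause model (two parcels over five waves plus a
baseline age covariate, 11 observed variables):

```r
lcs_model("share_cc")
#> <lcs_spec> share_cc
#>   variables: 11 observed + 9 latent
#>   free parameters: 31  df: 46
```

`autoplot(study$comparison)` draws the normalized-probability bars, and
`invariance_sequence()` / `partial_invariance_search()` run the
measurement-invariance workflow on any measurement-layer model.

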