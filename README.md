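# sdmfuse

Species distribution models (SDMs) for rare and cryptic species are usually
starved of data: ground surveys are sparse, biased toward easily accessed
places, and prone to false negatives. `sdmfuse` implements a multi-source
modelling workflow that pools three streams of information about
presence/absence at sites in a small study area:

1. **Ground-survey records** — certain presences (weight 1.00);
2. **Aerial thermal-imagery detections** — presences carrying the detection
   algorithm's confidence class (1.00 / 0.90 / 0.50), plus randomly
   generated absences at weight 0.90;
3. **Expert elicitation** — habitat-suitability probabilities stated by
   experts immersed in imagery of the sites, weighted 1.00 / 0.75 / 0.50 by
   the expert's own confidence.

The package was built around a koala case study (a riverside urban parkland
with six habitat covariates: longitude, latitude, foliage projective cover,
a remnant-*Eucalyptus* indicator, and distances to the nearest path and to
fresh water), but every stage is generic.

## The models

**Survey models (G, GT).** Confidence-weighted logistic regression, where
the weights *w<sub>i</sub>* are prior case weights multiplying per-record
log-likelihood contributions:

&nbsp;&nbsp;&nbsp;&nbsp; max<sub>β</sub> Σ<sub>i</sub> w<sub>i</sub> [ y<sub>i</sub> log p<sub>i</sub> + (1 − y<sub>i</sub>) log(1 − p<sub>i</sub>) ], &nbsp; p<sub>i</sub> = logit<sup>−1</sup>(x<sub>i</sub>′β).

G uses the ground-survey data only; GT adds the thermal-imagery records.
Covariates are always centred and scaled by the means and SDs of the base
(G) dataset so that coefficients are commensurate across models.

**Expert model (E).** Confidence-weighted Beta regression with a Gaussian
random intercept per expert, fit by marginal maximum likelihood with
adaptive Gauss–Hermite quadrature:

&nbsp;&nbsp;&nbsp;&nbsp; y<sub>ij</sub> ~ Beta(μ<sub>ij</sub>φ, (1 − μ<sub>ij</sub>)φ), &nbsp; logit(μ<sub>ij</sub>) = x<sub>i</sub>′β + u<sub>j</sub>, &nbsp; u<sub>j</sub> ~ N(0, σ²).

**Fusion (G_E, GT_E).** Per coefficient, survey (o) and expert (e)
estimates are pooled by inverse-variance weighting:

&nbsp;&nbsp;&nbsp;&nbsp; β̂<sub>c</sub> = (β<sub>o</sub>s<sub>o</sub><sup>−2</sup> + β<sub>e</sub>s<sub>e</sub><sup>−2</sup>) / (s<sub>o</sub><sup>−2</sup> + s<sub>e</sub><sup>−2</sup>), &nbsp;&nbsp; s<sub>c</sub>² = (s<sub>o</sub><sup>−2</sup> + s<sub>e</sub><sup>−2</sup>)<sup>−1</sup>,

with t confidence intervals at v<sub>c</sub> = v<sub>o</sub> + v<sub>e</sub>
degrees of freedom. The fused precision is strictly higher than either
parent's for every coefficient.

**Evaluation.** High-confidence thermal records (weight ≥ 0.90) form the
validation set; GT and GT_E are assessed by leave-one-out cross-validation
(the survey parent is refit per fold), G and G_E by direct prediction.
Predicted probabilities ≥ 0.4 classify as presence (a cutoff below 0.5,
because finding presences is the conservation priority), and each model is
reported with accuracy, sensitivity, specificity and RMSPE.

A synthetic-data module (`simulate_study()` and friends) generates a park
landscape, survey records with observer bias and confidence classes, and an
expert panel with the exact statistical structure the models assume, so the
whole pipeline is testable end to end and parameter recovery can be checked
against known truth.

## Worked example

```r
library(sdmfuse)

study <- simulate_study(seed = 42)   # landscape + surveys + experts + grid
res <- run_study(study$observations, study$covariates,
                 study$elicitations, study$grid)
print(res)
#> Multi-source species distribution study
#>   G n = 26, GT n = 68, E n = 60; validation n = 48; cutoff = 0.40
#>
#> Predictive performance:
#>  model accuracy sensitivity specificity rmspe
#>      G    0.562       0.786       0.471 0.530
#>     GT    0.583       0.857       0.471 0.494
#>    G_E    0.583       1.000       0.412 0.532
#>   GT_E    0.625       1.000       0.471 0.525
```

Each row is one model evaluated on the same validation set: adding thermal
records (GT) and expert information (G_E, GT_E) raises sensitivity — here
to 1.0, i.e. every true presence found — and the combined GT_E model is the
most accurate. The fused coefficients come with tight intervals:

```r
print(res$combined$GT_E)
#> Combined model GT_E (inverse-variance pooled; v_c = 110.1)
#>             Estimate Std. Error   lower   upper
#> (Intercept)   0.8049     0.1302  0.5468  1.0630
#> ...
#> dist_water   -0.7819     0.1716 -1.1219 -0.4418
```

`dist_water` is significantly negative: presence probability rises toward
the river, which matches the generating truth of the simulation. The
`surfaces` element holds per-model probability predictions over a regular
grid for mapping, and `plot(res$combined$GT_E)` draws the
coefficient-interval dot plot.

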