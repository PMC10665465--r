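# angiodiv

Spatial and temporal diversification dynamics of plant genus assemblages.

`angiodiv` is for macroevolution and macroecology researchers who want to
test, at the genus level, whether diversity gradients track
diversification *rates* or lineage *ages* — e.g. the classic question of
whether tropical floras are rich because lineages diversify faster there
or because they have been accumulating longer. The package implements the
full analysis chain as tested R functions:

* **Supermatrix terminal selection** — per-(species, marker) sequence
  screening (longest, then published, then most recent), genus monophyly
  assessment against a reference species-level tree with largest
  genus-pure-clade extraction, and greedy composite-terminal selection
  that maximizes marker coverage with a minimal congeneric species set.
* **Rate extraction from dated trees** — exponential-change rate regimes
  anchored to branches (λ(t) = λ₀·e^{b·t}, μ(t) = μ₀·e^{z·t}), tip rates
  at the present, rates through time for arbitrary tip subsets with
  segment discretization, stem ages, crown-node attachment of unsampled
  genera, stochastic polytomy resolution, and per-tip sampling fractions
  f = 1/richness.
* **Assemblage macroecology** — occurrence quality control (granularity
  overlap rules; per-region source-count thresholds; introduced-range
  removal), per-unit means of genus age, speciation and net
  diversification rate, global quartile decompositions, and ten-degree
  latitudinal belts assigned by strict area majority.
* **Spatial statistics** — the modified t-test of association with a
  Dutilleul-style effective sample size (F = (ESS−2)·r²/(1−r²) against
  F(1, ESS−2)), reduced major axis regression (slope = sign(r)·s_y/s_x),
  quadratic and lowess latitudinal fits, a richness-preserving null
  model (999 replicates by default, distribution-free empirical p), and
  Wilcoxon/Mann–Whitney group comparisons with Holm adjustment.
* **A synthetic-data generator** — birth-death trees with Poisson rate
  shifts, geographic units with lognormal areas (mean 329,670 km², sd
  198,191 km²), and latitude-structured occupancy with known ground
  truth, encoding an equator-peaked richness gradient with older/slower
  genera at low latitudes and younger/faster genera at high latitudes.

See the methods vignette (`vignettes/diversification-gradients.Rmd`) for
the models, assumptions, parameter defaults and limitations.

## Worked example

Simulate a study-scale dataset (300 genera, 60 geographic units) under
the old/slow-tropics scenario, run it through quality control and
assemblage summaries, and test the richness–rate relationship with
spatial correction:

```r
library(angiodiv)

cfg <- simulation_config(seed = 11, n_tips = 300, n_units = 60)
ds  <- simulate_dataset(cfg)

accepted <- ds$records[resolve_overlap(ds$records), ]
inc <- qc_filter(accepted, ds$units)
asm <- assemblage_summary(inc, ds$profiles, ds$units)
asm <- asm[asm$richness > 0, ]

modified_ttest(asm$richness, asm$mean_netdiv,
               asm[c("centroid_lat", "centroid_lon")])
#> Modified t-test of spatial association
#>   correlation coefficient = -0.565, Fstat = 0.468
#>   effective sample size = 16.164 (n = 60), df = 14.164
#>   F(1, df) = 6.626, p = 0.0219

richness_null(inc, ds$profiles, "cor_richness_netdiv",
              n_reps = 999, seed = 12)
#> Richness-preserving null model (999 replicates, seed 12)
#>   observed statistic = -0.56455
#>   null mean = 0.0065817 (sd 0.1407)
#>   empirical p = 0.001, t-test p = 0

rma_fit(asm$mean_netdiv, log(asm$richness))
#> Reduced major axis regression (n = 60)
#>   slope = -111.78, intercept = 4.054, r2 = 0.2890
```

Reading the output: richness and mean net diversification rate are
*negatively* correlated across units (r = −0.565) — rich equatorial
assemblages are dominated by old, slowly diversifying genera — and the
association stays significant (p = 0.022) after the effective sample
size shrinks from 60 units to ~16 spatially independent ones. The null
model shows the pattern cannot arise from random placement of genera
under the observed richness gradient (empirical p = 0.001), and the
model-II regression quantifies the decline of log richness with mean
rate.

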