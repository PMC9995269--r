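# defoprecip

Observational attribution of precipitation change to tropical forest loss,
with a synthetic ground-truth generator for end-to-end validation.

## The problem

Tropical forests sustain regional rainfall through moisture recycling, and
their clearing can reduce precipitation over and around the deforested
area. Measuring that effect from gridded observations is confounded by
everything pixels share: climate trends, El Niño anomalies, dataset
biases. `defoprecip` implements a moving-window nearest-neighbour design
that removes shared signals by construction: every pixel with forest loss
is contrasted against its own window neighbours that lost strictly less
forest, so only the effect of the pixel's *excess* loss remains.

The package is for researchers in land–atmosphere interaction and
ecohydrology who want a tested, seedable implementation of this estimator
— pairing, sensitivity estimation, seasonal and loss-binned variants, and
scenario projection — together with a synthetic generator that makes every
stage verifiable by parameter recovery.

## The estimator

For analysis windows $S$ (start years) and $E$ (end years), a pixel $i$
and its eligible neighbours $C(i)$ (in-mask window neighbours with
strictly less loss):

- excess loss: $\Delta F_i = F_i - \overline{F}_{C(i)}$ (percentage
  points; pixels with $\Delta F_i \ge 0.1$ pp enter the analysis);
- precipitation contrast:
  $\Delta P_i = (\bar P_E - \bar P_S)_i - \overline{(\bar P_E - \bar P_S)}_{C(i)}$
  (mm/month);
- sensitivity: the median over pairs of $\Delta P_i / \Delta F_i$
  (mm/month per pp), with mean-based standard error, plus a relative
  variant (% per pp) and Welch-*t* / Mann–Whitney tests of deforested
  versus control changes.

Scenario projection multiplies projected pp loss by the estimated
sensitivity — linearly, with loss capped at 30 pp, or with a
piecewise (loss-binned) sensitivity — and aggregates regionally with
cos-latitude weights and ±1 SE bands.

## Worked example

Generate a synthetic tropics-like domain (256 × 256 fine pixels aggregated
to a 64 × 64 analysis grid, 15 years of monthly precipitation) with an
injected sensitivity of −0.25 mm/month per pp, then recover it:

```r
library(defoprecip)

cfg <- synth_config(beta = -0.25, sigma = 10, seed = 1)
bundle <- simulate_bundle(cfg)

loss    <- loss_between(bundle$cover, 2003:2007, 2013:2017)
pairs   <- find_pairs(loss, bundle$mask)          # 3x3 window, >= 0.1 pp excess
records <- pair_delta_p(pairs, bundle$precip, 2003:2007, 2013:2017)
estimate_sensitivity(records)
#> # A tibble: 1 x 9
#>       n median_sens median_sens_rel mean_sens    se se_rel boot_se_median      p_t     p_mw
#>   <int>       <dbl>           <dbl>     <dbl> <dbl>  <dbl>          <dbl>    <dbl>    <dbl>
#> 1  1154      -0.250          -0.151    -0.190 0.130 0.0789             NA 7.88e-76 1.19e-60
```

From 1,154 deforested-pixel/control pairs the median sensitivity is
−0.250 mm/month per percentage point of forest loss — the injected truth —
equivalently −0.151% of local precipitation per pp; both tests reject "no
difference between deforested and control changes" overwhelmingly.
Projecting the bundle's future-loss scenario with this estimate, capping
pixel loss at the observationally well-sampled 30 pp:

```r
baseline <- period_mean(bundle$precip, 2003:2007)
proj <- project_capped(bundle$future, estimate_sensitivity(records), cap = 30)
regional_summary(proj, list(domain = bundle$mask), baseline = baseline)
#> # A tibble: 1 x 6
#>   region    dp dp_lower dp_upper dp_rel n_pixels
#>   <chr>  <dbl>    <dbl>    <dbl>  <dbl>    <int>
#> 1 domain -1.30    -1.98   -0.625 -0.791     3720
```

i.e. a domain-mean decline of 1.30 mm/month (−0.79% of the baseline),
with the ±1 SE band spanning −1.98 to −0.63 mm/month.

`run_pipeline(pipeline_config(cfg))` chains the same stages for every
configured analysis scale, adds seasonal and loss-binned estimates and all
three projection modes, and writes CSV/JSON outputs with a deterministic
manifest. See the vignette (`vignettes/deforestation-precipitation.Rmd`)
for the model, the generator's design and its limitations.

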