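# stepsel

Habitat selection of sympatric predators from GPS telemetry.

`stepsel` implements the complete space-use workflow used to compare an
apex predator (dingo, 2-h collar fixes) and a mesopredator (feral cat,
4-h fixes) on a shared semi-arid landscape:

- **Landscape mapping** — buffered roads (10 m) and hydrological features
  (20 m), a two-class grassland/woodland vegetation layer, and a
  continuous vegetation-cover index cut into low/moderate/high classes by
  Jenks natural-breaks optimization (exact dynamic programme, in C++).
- **Fix screening** — analysis-window clipping (up to 70 days before the
  annual bait drop, discarding the first 24 h after release), a two-tier
  speed filter (single-step gallop > 16 / 3.2 km h⁻¹; sustained trot
  > 8.75 / 2.0 km h⁻¹), an elevation filter (± 100 m of the site
  reference), and moving/resting classification (> 20 m / > 35 m
  displacement cutoffs from stationary-collar error rates).
- **Home ranges** — fixed-kernel utilisation distributions with the
  bivariate-normal reference bandwidth h = sqrt((s²ₓ + s²ᵧ)/2) · n^(−1/6),
  95% (seasonal) and 50% (core) isopleths by cumulative highest-density
  cells, asymptote (sampling-adequacy) analysis, 100% minimum convex
  polygons, and linear-model comparisons of log₁₀ areas.
- **Second-order selection** — a used–available resource selection
  function: observed home-range compositions against n = 1000 random
  circles equal in area to the median seasonal home range, placed in the
  species availability region (MCP plus a median-circle-radius buffer
  around every fix), fitted by logistic regression with available records
  weighted n_used / n_available (e.g. 0.016:1 for 16 used ranges).
- **Third-order selection** — step-selection functions: each observed
  step versus K = 20 control steps resampled from the species' empirical
  step-length and turning-angle distributions, attributed with a 4-level
  road × vegetation factor (reference: off-road grassland), hydrology and
  cover terms, and fitted by conditional logistic regression

  L(β) = Σ_strata [ x_used′β − log Σ_j exp(x_j′β) ],

  maximized by Newton iteration (equivalently a stratified Cox model with
  one event per stratum). Coefficients are log odds ratios relative to
  the reference habitat state; a penalized-Laplace variant adds a
  per-individual random vegetation slope.
- **Autocorrelation sensitivity** — per-stratum deviance residuals,
  per-animal-centered ACF with ±1.96/√n bounds, first-non-significant-lag
  selection (converted to hours on the species schedule), and systematic
  thinning + refit.
- **Synthetic generator** — landscapes (thresholded smooth random fields,
  sparse road networks, scattered hydrology) and correlated-random-walk
  trajectories that select among gamma / von Mises candidate steps with
  probability ∝ exp(x′β), so every estimator can be checked by parameter
  recovery against known coefficients.

## Worked example

Simulate a landscape and five dingoes with known selection coefficients
(on-road-grassland 1.5, woodland 0.3, on-road-woodland 1.0, hydrology
0.5, high cover 0.4, low cover −0.3), screen the fixes, build choice
sets and refit:

```r
library(stepsel)

map <- simulate_landscape(sim_landscape_config(seed = 1))
pop <- simulate_population(map, "dingo", 5,
                           base_config = sim_animal_config("dingo", n_steps = 250),
                           sd_slope = 0, seed = 2)

steps <- NULL
for (tr in pop$tracks) {
  params <- screening_params("dingo", window_end = max(tr$fixes$timestamp) + 1)
  steps <- rbind(steps, build_steps(screen_track(tr, params, ref_elev = 500)))
}

dists <- empirical_move_dists(steps, "dingo")
cs    <- build_choice_sets(steps, dists, map, K = 20, seed = 3)
fit   <- fit_clogit(cs)
summary(fit)
```

```
Conditional logistic step-selection function (1239 strata)
         term    beta     se odds_ratio  ci_lo ci_hi       z         p
 onroad_grass  1.6540 0.2353     5.2300 3.2980 8.293  7.0320 2.041e-12
 offroad_wood  0.3873 0.2253     1.4730 0.9472 2.291  1.7190 8.559e-02
  onroad_wood  1.0670 0.3219     2.9050 1.5460 5.460  3.3140 9.211e-04
        hydro  0.7171 0.1534     2.0490 1.5170 2.767  4.6760 2.926e-06
   cover_high  0.3011 0.1933     1.3510 0.9252 1.974  1.5580 1.193e-01
    cover_low -0.2190 0.4221     0.8034 0.3512 1.837 -0.5187 6.039e-01
logLik -3736.84, null (beta = 0) -3772.16
```

Every generating coefficient is recovered within sampling error (e.g.
on-road grassland: 1.65 ± 0.24 against a truth of 1.5, odds ratio 5.2);
`residuals(fit)`, `confint(fit)` and `plot(fit)` give the per-stratum
deviance residuals, Wald intervals and a coefficient plot. The full
file-to-file study (simulate → screen → homerange → broadscale → ssf →
autocorr → report) runs as

```sh
Rscript scripts/pipeline.R all --outdir my-run --seed 1
```

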