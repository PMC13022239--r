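# pigwater

Subset ARMAX modelling of hourly drinking-water consumption in fattening
pigs.

Barn-level water meters are one of the cheapest continuously recorded
signals on a commercial pig farm, and drinking behaviour reacts early to
disease, heat stress, feed and water-system problems. This package
implements the full statistical workflow that turns raw flowmeter readings
into an hourly consumption model with prediction intervals usable for
early-warning monitoring:

* **cleaning** — drop cooling/cleaning usage records, aggregate 20-minute
  readings into clock hours, divide by the (declining) pig count, exclude
  negative values and values above 10 L/pig/h, keep removed records as
  missing hours;
* **design** — sine/cosine pairs of the first four harmonics of the 24-h
  cycle (periods 24, 12, 8, 6 h), outside temperature (°C), ammonia (ppm)
  and fattening day;
* **estimation** — subset ARMAX(24, 24) with active AR/MA lags
  {1, 2, 22, 23, 24}, fitted by CSS-initialized **exact** Gaussian maximum
  likelihood through a state-space innovations filter (stationary
  initialization, missing values marginalized, innovation variance
  concentrated out), with Wald pruning and AIC/AICc/BIC order selection;
* **forecasting** — one-step and multi-step predictions with 95% intervals
  and standardized forecast errors, scored by RMSE;
* **diagnostics** — Ljung-Box (df = number of pooled lags), Shapiro-Wilk
  (seeded subsampling above n = 5000), hourly profiles with a hot
  (May–October) / cold (November–April) split, hour-of-day ANOVA, harmonic
  overlays.

The model is a regression with subset-ARMA errors,

```
X_t = mu + eta' Y_t + u_t,
u_t = sum_{i in A} phi_i u_{t-i} + eps_t + sum_{i in A} theta_i eps_{t-i},
eps_t ~ N(0, sigma^2),   A = {1, 2, 22, 23, 24},
```

where `X_t` is consumption in mL/pig/h and `Y_t` stacks the harmonic, trend
and environment covariates.

Because barn records of this kind are proprietary, the package ships a
seeded synthetic generator with two modes: **model-truth** (the exact
equation above with a published coefficient set as ground truth, for
estimator validation) and **farm-realistic** (a calibrated non-negative
consumption surface — logistic growth trend from 2.35 to 8.05 L/pig/day,
two-peak diurnal shape, end-of-batch ramp-down — plus persistent ARMA noise,
sensor corruption with a fault ledger, and interleaved non-drinking usage
records, for pipeline testing). See the methods vignette
(`vignettes/water-consumption-armax.Rmd`) for the model, the generator
calibration and the design decisions.

## Worked example

Simulate one 9-week batch from the exact model-truth equation and ask the
fitter to recover the generator's coefficients:

```r
library(pigwater)

batch <- simulate_batch(batch_config(mode = "model-truth", duration_weeks = 9,
                                     corruption = no_corruption(), seed = 3))
X    <- build_design(batch$clean)          # S1..S4, C1..C4, T, NH3, N
spec <- barn_truth_model()$spec            # subset lags {1,2,22,23,24}
fit  <- fit_ml(spec, batch$clean$consumption, X)
print(fit)
#> Subset ARMAX(24, 24) fit: logLik -2144.514 on 1512 obs (k = 23)
#>   AIC 4335.03  AICc 4335.77  BIC 4457.41  sigma 0.9979
#>      estimate     se
#> ...
#> ar1    1.1299 0.0881
#> ar2   -0.3303 0.0474
#> ar22  -0.2549 0.0542
#> ar23   0.9371 0.0993
#> ar24  -0.5337 0.0670
#> ...
head(wald_tests(fit), 4)
#>   term        description     estimate        se           z      p_value
#> 1   mu          Intercept  0.009355769 0.4295119  0.02178233 9.826216e-01
#> 2   S1 Sine (period 24 h) -0.100357022 0.2396165 -0.41882355 6.753451e-01
#> 3   S2 Sine (period 12 h) -0.471815986 0.2056035 -2.29478603 2.174539e-02
#> 4   S3  Sine (period 8 h)  0.479946524 0.1059018  4.53199797 5.842841e-06
```

The generator's AR block is (1.1045, −0.3326, −0.2183, 0.8993, −0.4818) and
its innovation SD is 1: the fit returns it to within roughly one standard
error, and `sigma = 0.9979`. Note the warning such fits can emit — the true
AR polynomial has a root at modulus 1.002, so single 9-week series sit close
to the stationarity boundary and individual harmonic coefficients are noisy;
averages over replicate batches centre on the truth (that is exactly what
the acceptance suite checks).

## The full analysis

The numbered drivers under `analysis/` replay the whole study on synthetic
data (simulate → clean → describe → fit → forecast → check), writing tables
under `results/`:

```sh
Rscript analysis/01_simulate.R     # 6 barns x 2 batches, seeded
Rscript analysis/02_preprocess.R   # cleaning report + fault-ledger scoring
Rscript analysis/03_descriptive.R  # profiles, seasonal split, ANOVA, harmonics
Rscript analysis/04_fit.R          # subset ARMAX(24,24) on the train split
Rscript analysis/05_forecast.R     # held-out one-step forecasts + 95% PIs
Rscript analysis/06_diagnostics.R  # Ljung-Box, Shapiro-Wilk, correlogram
```

A recent run cleans 30,240 simulated hours (7.4% non-drinking usage removed;
negative/extreme fault recall 1.000 against the generator ledger), fits the
22-coefficient subset model on 13,833 training hours, and scores the six
held-out batches at one-step RMSEs of 52–73 mL/pig/h with empirical 95%
interval coverage of 94.6–96.4%. On this deliberately misspecified
farm-realistic data (multiplicative noise, product-form mean surface) the
residual Ljung-Box and Shapiro-Wilk tests correctly reject, and the fit is
flagged as sitting at the stationarity boundary — see the vignette's
discussion of what the generator does and does not share with real barns.

The same chain is available as one call:
`run_pipeline(run_config(...), out_dir)`.

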