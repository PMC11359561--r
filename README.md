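# convformer

Long-horizon (24–96 h) point **and** interval forecasting of PM2.5 from
hourly multi-station air-quality and meteorology series, for air-quality
modellers and environmental-health analysts who need not just a forecast
but a calibrated uncertainty band around it.

## What it does

Given a network of monitoring stations with coordinates and categorized
points of interest (POIs), and per-station hourly series, the pipeline:

1. **Clusters stations by POI composition.** Each station's profile
   `S*ᵢ ∈ ℕᴷ` counts POIs per category within 1 km (haversine distance,
   equatorial radius 6378.137 km). Average-linkage agglomeration on the
   normalized Euclidean distance
   `d(p,q) = √Σₖ((pₖ−qₖ)/sₖ)²` groups stations with similar surroundings;
   stations in the target's cluster with Pearson `r ≥ 0.5` against the
   target's PM2.5 contribute their PM2.5 as extra features.
2. **Screens features**: candidates with `|r| < 0.1` against target PM2.5
   are dropped.
3. **Preprocesses gaps**: forward fill (≤ 4 h), averaged stochastic
   imputation (5–72 h), row deletion (> 72 h, windows never span the cut);
   min–max scaling to (0, 1) fitted on the chronological 70 % training
   slice of the 7:1:2 split.
4. **Forecasts with a ConvFormer**: convolution + max pooling over the
   `D × M` window, a sinusoidal positional encoding, an encoder-only
   multi-head self-attention stack, and a single linear head emitting all
   τ horizon steps at once (direct multi-output,
   `softmax(QKᵀ/√d_k)V` attention). Implemented in plain R with
   hand-written backpropagation and Adam; gradient-checked in the tests.
5. **Builds prediction intervals by Gaussian KDE** on the training-split
   forecast errors, per horizon step:
   `f̂(x) = (1/Nh) Σ K((x−eᵢ)/h)`, bandwidth by 5-fold cross-validated
   grid search around the Silverman reference; equal-tailed error
   quantiles `(l_α, u_α)` shift the point forecast:
   `[ŷ + l_α, ŷ + u_α]`.
6. **Evaluates** with RMSE, MAE, R², PICP (coverage) and PINAW
   (normalized width), plus the relative-improvement arithmetic used in
   multi-model comparison reports.

Because real multi-station datasets of this kind are typically not
redistributable, the package includes a seeded synthetic generator (shared
latent AR(1) + diurnal process, graded-correlation covariates, planted POI
clusters, injected gaps) that stands in for them in all tests.

## Worked example

```r
library(convformer)

cfg <- run_config(
  synthetic = TRUE,
  generator = list(n_hours = 6000L, n_stations = 10L, n_poi = 800L),
  window_d = 24L, horizons = 12L,
  model = list(conv_kernel = c(3L, 2L), conv_channels = 8L, d_model = 16L,
               n_heads = 2L, n_layers = 1L, d_ff = 32L, batch_size = 32L,
               max_epochs = 2L, patience = 2L,
               max_train_windows = 600L, max_val_windows = 200L),
  max_test_windows = 400L, seed = 42L)
res <- run_pipeline(cfg, out_dir = "example_run")

m <- res$results$h012$metrics
res$correlated$station_id
res$screening$dropped$feature
```

Output (about a minute on one CPU):

```
correlated stations: S9, S5, S7, S3
features kept: PM2.5, PM10, CO, O3, wind_speed, wind_direction,
               temperature, pressure, PM2.5_S9, PM2.5_S5, PM2.5_S7, PM2.5_S3
dropped: NO2, SO2, humidity
point: MAE 8.185  RMSE 10.242  R2 -0.422
alpha 0.85: PICP 0.8985  PINAW 0.6824
alpha 0.90: PICP 0.9406  PINAW 0.7728
alpha 0.95: PICP 0.9767  PINAW 0.9134
```

Reading this: the station screen picked the four strongly correlated
neighbours; the three pure-noise covariates (NO2, SO2, humidity) were
dropped by the `|r| < 0.1` screen; and the KDE intervals *cover* at or
above their nominal levels (0.8985 ≥ 0.85, …) even though the
two-epoch toy model's point forecast is still poor (negative R²) — the
interval calibration depends on residual stationarity, not on model
quality. Train longer (raise `max_epochs`, drop the window caps) for
competitive point accuracy.

Every stage is also scriptable through the CLI dispatcher:

```sh
Rscript -e 'convformer::cfk_cli()' simulate --seed 1 --out data/
Rscript -e 'convformer::cfk_cli()' cluster --stations data/stations.csv \
    --pois data/pois.csv --k 2 --target S1 --panel data/panel.csv --out clust/
Rscript -e 'convformer::cfk_cli()' run --config run.yaml --out results/
```

## Layout

```
R/                  implementation (one file per pipeline stage)
tests/testthat/     unit + property + acceptance suites, with
                    independent brute-force oracles in helper-fixtures.R
vignettes/          methods vignette (model, assumptions, design choices)
scripts/acceptance.R  the acceptance report
inst/extdata/       published benchmark table used as worked-example input
```
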