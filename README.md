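# anthesis

Automated detection and diurnal quantification of rice panicle flowering
(spikelet anthesis) in RGB canopy time-lapse imagery.

Rice flowers for only 1–2.5 hours a day, usually around noon, and the
timing matters: heat at anthesis reduces fertility, so breeders screen for
early-morning-flowering lines by watching plots in person. A fixed camera
photographing the canopy every five minutes turns this into an image
analysis problem: find the windows of each frame that contain the bright,
speckled texture of extruded anthers, count them, and read the daily
flowering curve off the series.

`anthesis` implements the full pipeline:

* dense multi-scale **SIFT** descriptors (grid spacing M = 15 px, support
  radii r = 4, 6, 8, 10 px; 4×4 patches × 8 orientation bins = 128 dims,
  L2-normalized, 0.2-clipped),
* a **bag-of-visual-words** encoding over a k = 600 vocabulary trained by
  restarted Lloyd k-means,
* a linear SVM on a **homogeneous kernel map** of the χ² kernel
  K(x,y) = Σᵢ 2xᵢyᵢ/(xᵢ+yᵢ), so window histograms are classified at
  linear-SVM speed with kernel-SVM geometry,
* **non-overlapping sliding-window** scanning with connected-block region
  counting — FBN (flowering block number) and FCBN (flowering connected
  block number, a proxy for the number of flowering panicles),
* **time-series** assembly: diurnal curves, daily peak times, and Pearson
  correlation of FBN/FCBN against manually counted panicles (FPN),
* a seeded **synthetic canopy generator** with exact ground truth, so the
  entire pipeline is testable without field imagery, and
* protocol helpers for the **training-set-size** and **image-resolution**
  experiments.

## A worked example

Simulate a flowering day, train a detector on 30 + 30 labeled synthetic
patches, and scan the series:

```r
library(anthesis)

# a one-day series: 97 frames (08:00-16:00, every 5 min), Poisson counts
# peaking at noon with amplitude 12
series <- simulate_series(days = 1, peak_time = 12, amplitude = 12,
                          spec = canopy_spec(seed = 1), seed = 21)

# training database: 30 positive + 30 negative patches from 3 canopies
db   <- build_training_db(30, 30, seed = 42)
desc <- do.call(rbind, lapply(db$patch, function(p)
  dense_multiscale_sift(p$luminance)$descriptors))
cb    <- train_codebook(desc, k = 600, n_restarts = 8, seed = 42)
model <- train_flower_model(db, cb, seed = 42)

fs <- detect_series(series, model, cb)   # renders frames on demand
correlate_counts(fs)
#> # A tibble: 2 × 3
#>   metric_pair     n     r
#>   <chr>       <int> <dbl>
#> 1 fpn_fbn        97 0.981
#> 2 fpn_fcbn       97 0.922
daily_peaks(fs, "fcbn")
#> # A tibble: 1 × 3
#>   date       metric peak_time
#>   <date>     <chr>  <dttm>
#> 1 2013-08-24 fcbn   2013-08-24 11:50:00
```

The correlation of ~0.92 between the true panicle count (FPN) and the
detected region count (FCBN) says the detector's region counts track the
real flowering dynamics almost linearly; the detected daily peak (11:50)
sits within ten minutes of the configured noon peak. `autoplot(fs)` draws
the diurnal FBN/FCBN/FPN curves, and `detect_image()` +
`write_overlay()` produce per-image overlays with flowering blocks tinted
and region boxes outlined.

A thin command-line interface over the same functions lives in
`inst/cli/anthesis.R` (`simulate`, `train`, `detect`, `scan-series`,
`experiment`), driven by a flat key = value config file with a mandatory
seed; every output CSV carries a config-hash + seed audit stamp.

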