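# plumeMI

How should a navigator with a limited coding budget sample a turbulent
odor plume? `plumeMI` answers this with Shannon mutual information: it
measures how many bits about the *sampling location* a discretized odor
measurement carries, and compares strategies that spend a fixed budget on
concentration resolution, on a second spatially separated sensor, or on
repeated samples in time.

The core objects are a location variable $L$ (one of $|L|$ grid positions,
uniform prior) and a code word $M$ built from quantized concentration
samples. An encoding strategy
$S(n_\mathrm{bits};\,r_\mathrm{spat},\,r_\mathrm{temp})$ discretizes each
sample into $2^{n_\mathrm{bits}}$ levels and applies that quantizer to
$r_\mathrm{spat}$ sensors at $r_\mathrm{temp}$ time points. The
information of a strategy is the plug-in estimate of

$$I(L;M) = H(L) - \sum_m p(m)\,H(L\mid m),$$

bias-corrected by extrapolating subset estimates linearly in $1/N$ to the
infinite-data intercept. Quantizer boundaries come either from histogram
equalization (equal-quantile bins of the pooled single-sample
distribution) or from a greedy search that adds, one at a time, the
cutpoint maximizing location information.

Because the original planar laser-induced fluorescence recordings are not
publicly available, the package includes two seedable synthetic plume
generators — a Gaussian-puff advection model with a meandering crosswind
and a camera-noise floor, and an analytically tractable on/off whiff
surrogate with known marginals — plus preset scenarios mimicking fast
(10 cm/s), slow (5 cm/s) and boundary-layer-like flow regimes, and the
two canonical 16-location sampling grids.

## Worked example

```r
library(plumeMI)

params <- presetScenario("fast_flow_analog", seed = 1L)
params@durationS <- 120
movie <- simulatePuffPlume(params)
movie
#> PlumeMovie 'fast_flow_analog': 64 x 120 px, 1800 frames @ 15 Hz, 2.5 mm/px
#>   source pixel (row, col) = (33, 8); mean c = 0.1028, max c = 20.85

grid <- gridPreset("narrow")   # 16 locations, 2.2-13.3 cm downstream
sweep <- sweepConcentrationBits(movie, grid, "single", nBitsRange = 1:6,
                                jitterRadius = 0L, repetitions = 5L)
sweep[, c("nBits", "totalBits", "miRaw", "miDebiased")]
#>   nBits totalBits  miRaw miDebiased
#> 1     1         1 0.0386     0.0386
#> 2     2         2 0.1032     0.1025
#> 3     3         3 0.1117     0.1094
#> 4     4         4 0.1205     0.1166
#> 5     5         5 0.1298     0.1230
#> 6     6         6 0.1381     0.1222
```

Single-sample information saturates after a few bits of concentration
resolution: the sixth bit adds essentially nothing. Spending the same six
bits on two sensors (three bits each) more than doubles the information,
and knowing *which* sensor saw which sample matters:

```r
spatial <- sweepConcentrationBits(movie, grid, "spatial", nBitsRange = 3L,
                                  jitterRadius = 0L, repetitions = 5L)
spatial[, c("nBits", "totalBits", "labeled", "miDebiased")]
#>   nBits totalBits labeled miDebiased
#> 1     3         6    TRUE      0.263
#> 2     3         6   FALSE      0.179

thr <- binarizationThresholdSweep(movie, grid)
sprintf("median %.4f, optimal threshold %.4f (MI %.3f vs %.3f bits)",
        thr$pooledMedian, thr$optimalThreshold,
        thr$miAtOptimal, thr$miAtMedian)
#> "median 0.0049, optimal threshold 0.0267 (MI 0.111 vs 0.039 bits)"
```

Even a one-bit code recovers most of the single-sample information —
provided the threshold sits well above the median, where the informative
high-concentration whiffs are. All values are in bits; with 16 locations
the ceiling is $\log_2 16 = 4$ bits. See the vignette
(`vignettes/plume-information.Rmd`) for the model, estimator and design
conventions.

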