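---
title: "Quantifying location information in odor-plume samples"
author: "plumeMI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying location information in odor-plume samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumeMI)
```

## The question

An animal navigating toward an odor source samples a turbulent plume: a
signal that is positively skewed and intermittent, with short whiffs of
high concentration separated by long blanks. A sensory system with a
limited coding budget must decide how to spend its bits — on resolving the
concentration of a single sample finely, on comparing two spatially
separated sensors, or on accumulating several samples over time. `plumeMI`
quantifies these trade-offs with Shannon mutual information (MI): how many
bits about the *sampling location* does a discretized odor measurement
carry?

The model is a discrete channel. The location $L$ is one of $|L|$ grid
positions with a uniform prior, so $H(L) = \log_2 |L|$ bits. A measurement
$M$ is a code word formed from $r_\mathrm{spat} \times r_\mathrm{temp}$
quantized concentration samples. The information is

$$ I(L;M) \;=\; H(L) - \sum_m p(m)\, H(L \mid m), $$

estimated by plugging empirical frequencies into the entropies
(`pluginMutualInformation()`). An encoding strategy
$S(n_\mathrm{bits};\, r_\mathrm{spat},\, r_\mathrm{temp})$
(`EncodingScheme`) discretizes each sample into $2^{n_\mathrm{bits}}$
levels and applies that quantizer to $r_\mathrm{spat}$ sensors at
$r_\mathrm{temp}$ time points; its total budget is the product of the
three. A starred scheme ($n^*$) uses greedy information-maximizing bin
boundaries instead of histogram equalization.

## Stimulus data

The analysis operates on `PlumeMovie` objects: planar concentration fields
$c(y, x, t)$ normalized to the source concentration, with frame rate,
pixel pitch and source position as metadata. Imported camera data pass
through `normalizeConcentration()`, which divides background-subtracted
images by the background-subtracted flatfield and the source calibration
coefficient, clips negative (over-subtracted) values to zero, and masks
pixels with nonpositive flatfield as invalid rather than letting them
produce infinities.

Because the original wind-tunnel recordings are not publicly deposited,
the package ships two seedable generators that stand in for them:

* **Gaussian-puff plume** (`simulatePuffPlume()`): puffs are released at
  the source as a Poisson process, advected downstream at the mean wind
  speed plus a shared Ornstein–Uhlenbeck crosswind meander; each puff's
  radius grows linearly with age while its mass decays exponentially, and
  the field is the sum of Gaussian kernels. Additive Gaussian sensor noise
  (`noiseSd`, default 1% of the source-mean signal, clipped at zero)
  emulates the camera-noise floor of fluorescence imaging; without it,
  arbitrarily small concentrations would be artifactually informative
  about location, which no real detector delivers. The model reproduces
  the statistics the analysis assumes — positive skew, downstream decay of
  the time-averaged field, and intermittency that falls with distance on
  the centerline — but makes no claim of Navier–Stokes fidelity: its
  spectra, fine-scale filament structure and absolute MI values are not
  those of a real plume, so passing tests support the *estimators and
  orderings*, not quantitative predictions for any particular flow.
* **On/off whiff surrogate** (`simulateSurrogateField()`): each pixel is a
  two-state renewal process (blank = 0; whiff = a log-normal amplitude
  held for the whiff's duration), with exponential durations, so the
  indicator process is Markov with correlation time
  $\tau_c = \mu_\mathrm{on}\mu_\mathrm{off}/(\mu_\mathrm{on}+\mu_\mathrm{off})$.
  Switching is shared across pixels within blocks of side
  `correlationLengthCm`; per-pixel whiff probabilities $q$ are realized by
  thinning whiff events. Frames point-sample the state at frame centers,
  as snapshot imaging does. Its closed-form marginals make it the fixture
  of choice for unit tests.

Three `presetScenario()` parameter sets mimic the qualitative regimes of
the reference conditions: 10 cm/s and 5 cm/s free-stream analogs, and a
"boundary-flow-like" analog (10 cm/s, larger puff growth, weaker meander)
that is more diffusive and less intermittent. The fast/slow presets use a
stronger meander (3 and 2 cm/s s.d.) than puff growth (0.3 and 0.25 cm/s)
so that plume wandering, not diffusion, dominates — that is what makes
downstream sampling intermittent. Default synthetic movies use 2.5 mm
pixels on a 30 × 16 cm domain at 15 Hz; this is coarser than the 0.74 mm
of the reference imaging but resolves every grid spacing and sensor
offset used here while keeping a four-minute movie in memory.

Sampling geometry is a `SamplingGrid` of locations in cm relative to the
source; `gridPreset()` ships the two canonical 16-location grids (narrow:
x ∈ {2.2, 5.9, 9.6, 13.3} cm, y ∈ ±{1.5, 4.4} cm; wide: x ∈ {5.6, 11.1,
16.7, 22.2} cm, y ∈ ±{1.1, 2.6} cm). Grid coordinates map to pixels via
column = source column + round(x/pixel), rounding half away from zero; the
same convention in y gives the row. Two-sensor schemes place the pair
symmetrically about the grid point, `sensorSpacing` pixels apart (default
4), across (transverse) or along (longitudinal) the flow.

## Quantizer design

Two boundary-design strategies are implemented on *single-sample*
statistics and reused unchanged for multi-sample schemes:

* `equalizedBoundaries()` — histogram equalization: cutpoints at the
  $k/2^{n_\mathrm{bits}}$ quantiles of the single-sample distribution
  pooled over all grid locations, so the word marginal $p(m)$ is as
  uniform as ties allow. A cutpoint is placed at the midpoint between the
  sample at the quantile rank and the next strictly larger distinct value.
  This midpoint convention makes bin occupancies equal to within one
  sample on tie-free data, and lets massive ties (the spike of zeros or
  noise-floor values typical of plume data) collapse into a single
  *separating* cutpoint instead of a degenerate one; duplicate cutpoints
  are removed and the effective bin count recorded.
* `greedyBoundaries()` — iterative location-information maximization: the
  candidate set is 512 pooled-quantile positions (robust to heavy skew,
  unlike a uniform concentration grid); the first cut maximizes plug-in
  $I(L;M)$ of the binarized code by exhaustive search over the candidates,
  and each further cut maximizes $I(L;M)$ holding previous cuts fixed — a
  binary subdivision of one existing bin, so the partitions nest and MI is
  non-decreasing in the cut count. Ties are broken toward the lowest
  candidate value, making the search deterministic.

`discretize()` assigns bin index = number of cutpoints ≤ value (a value
equal to a cutpoint goes to the upper bin). Words are composed by
`formWords()`: unlabeled sensor pairs are replaced by their sorted
multiset at each time, and order-ignored codes by the sorted multiset of
time tokens — deterministic coarsenings, so by the data-processing
inequality they can never gain information (asserted in the tests on raw
plug-in values; after debiasing the inequality can apparently reverse
because ordered codes, having larger alphabets, carry more bias).

Temporal draws slide over every admissible start frame with overlap, which
maximizes the draw count; overlapping draws are correlated but leave the
plug-in estimate's expectation per draw unchanged. The default
inter-sample interval is 24 frames (1.6 s at 15 Hz).

## Bias correction

The plug-in MI estimator is upward-biased, to first order linearly in
$1/N$. `debiasByExtrapolation()` re-estimates MI on random subsets of the
draws (defaults: fractions 1, 1/2, 1/4, 1/8 of the data, 10 random
subsets per fraction, averaged — averaging chosen over single nested
subsets for variance reduction), fits a least-squares line of MI against
$1/N$, and reports the intercept as the bias-corrected information. The
reported `miDebiased` is clamped to $[0, \mathrm{miRaw}]$ — information is
nonnegative and the bias is upward, so excursions outside that interval
are extrapolation noise — while the unclamped intercept is kept in
`miExtrapolated` for diagnostics. Debiasing is applied only to schemes
with more than one total bit; one-bit codes are reported raw. For jitter
envelopes the slope is fitted once at the center placement and
$\mathrm{slope}/N$ subtracted at the other placements (the slope varies
little under sub-cm shifts); per-placement refits are available behind
`perPlacementDebias`.

Two caveats, both visible in the test suite. First, when draws are
strongly autocorrelated (long whiffs relative to the frame interval) the
MI-versus-$1/N$ curve flattens and the extrapolation under-corrects; the
estimator treats draws as exchangeable. Second, when the true bias is far
below the sampling noise (tiny alphabets at moderate $N$), the
extrapolation's own noise exceeds the bias it removes, and the debiased
estimate is *not* closer to the truth in absolute error on average — the
package's tests document this regime honestly rather than hiding it. A
guard warns when the word alphabet exceeds a tenth of the draws per
location and errors when it exceeds the draw count outright.

## Pipeline analyses

* `sweepConcentrationBits()` — MI versus bits per sample for the three
  resource families $S(n;1,1)$, $S(n;2,1)$ (labeled and unlabeled) and
  $S(n;1,2)$.
* `binarizationThresholdSweep()` — MI of the one-bit code parametric in
  the threshold, reporting the pooled median (the equalization cutpoint)
  and the information-optimal threshold; with default thresholds the
  arg-max coincides with the first greedy cut.
* `twoSensorAllocationComparison()` — eight total bits split as
  $S(4;2,1)$, $S(2;2,2)$, $S(1;2,4)$, for both sensor orientations and
  both binning methods.
* `miVsInterval()` — $S(5;1,2)$ over a range of inter-sample intervals.
  The asymptote is the mean MI over the top quartile of probed intervals
  (the notion of an "asymptotic value" needs an operational definition;
  this one is robust to noise in individual long-interval estimates), and
  $\tau_{80}$ is the smallest probed interval whose MI reaches 80% of it.
  An alternative reading — 80% of the *incremental* information of the
  second sample — is available as `definition = "incremental"`; the
  default ("asymptote") matches the plainer reading of the curve. When no
  probed interval reaches the criterion the result is flagged unresolved
  rather than erroring.
* `temporalAllocationComparison()` — a fixed total budget (default ten
  bits) split across consecutive samples, with ordered and order-ignored
  MI and the pooled code-word entropies, i.e. the lossless-compression
  bounds. If the movie cannot support the budget the function drops to
  the largest feasible total (messaged), keeping the same
  divisor-structured allocation family.
* `jitteredAnalysis()` — any per-placement analysis repeated over all
  rigid offsets within a pixel radius (default 3, i.e. 49 placements),
  reported as center value plus min/max envelope, matching the shaded
  presentation convention. Boundaries are recomputed per placement by
  default (each placement is its own experiment); `freezeBoundaries`
  reuses the center design.

## Numerical conventions and edge cases

Ties at a cutpoint go to the upper bin. Greedy ties go to the lowest
candidate. Jitter envelopes are min/max, not variances. Movies store
frames as height × width × time so per-pixel time series are contiguous.
A zero inter-sample interval duplicates the same frame and provably adds
no information (tested). Degenerate generator settings (zero puffs,
all-zero whiff probability) return all-zero movies with a warning rather
than failing. All randomness is seeded: the generators embed their seed in
their parameter objects, and the subsampling in `debiasByExtrapolation()`
takes an explicit seed, so every pipeline table is bit-for-bit
reproducible.

## Problem sizes used in the tests

Unit tests run on 4 × 4 surrogate fields (hundreds to a few thousand
frames); the end-to-end checks use a 120-second fast-flow-analog movie
(1800 frames, 64 × 120 px) and a 20 000-frame surrogate for the
$\tau_{80}$ recovery, sizes at which every ordering asserted is stable
across seeds. The worked-example quantities (the 2 × 2 MI table, the
skewed-entropy value, the 30-pixel grid offset) are exact and
data-independent.

## Limitations

The puff model is a phenomenological stand-in: it reproduces orderings
(two sensors beat one at matched budget, transverse beats longitudinal,
thresholds above the median are more informative, MI saturates with
resolution) but not absolute information rates of any measured flow. The
surrogate's whiffs are rectangular with a single held amplitude, so its
within-whiff concentration dynamics are simpler than reality. Entropy
estimation is plug-in only — small-sample estimators such as NSB or
Chao–Shen are deliberately out of scope — so all estimates inherit the
plug-in regime requirements enforced by the alphabet guard.
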