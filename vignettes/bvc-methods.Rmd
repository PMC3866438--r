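---
title: "Models and methods behind bvctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bvctools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`bvctools` analyses boundary-coding neurons recorded during open-field
foraging: boundary vector cells (BVCs), which fire whenever an
environmental boundary lies at a preferred distance in a preferred
allocentric direction from the animal, head direction (HD) cells, and
boundary-off cells, which fire everywhere *except* where an associated
BVC would.  Because no public recordings accompany this analysis chain,
every stage is paired with a generative simulator so that the whole
pipeline can be validated by parameter recovery on synthetic data.  This
vignette documents the models, the tunable parameters, the numerical
conventions, and what the synthetic validation does and does not show.

## Coordinate conventions

One allocentric frame is used everywhere: origin at the floor centre,
x increasing east, y north, angles in radians counter-clockwise from
east, distances in cm, rates in Hz.  Position tracking is sampled at
50 Hz (0.02 s per sample).

## Environments

`make_standard_environment()` builds the five standard floors: a 150 cm
walled circle, a 100 × 100 cm walled square, a 155 cm unwalled elevated
platform, and a three-platform array either pushed `together`
(150 × 50 cm) or 10 cm `apart`.  Boundary elements are `wall` or `drop`
segments; circular perimeters are kept analytic (exact ray-circle
intersection) rather than polygonised.  Wall height (50 cm) and platform
elevation (30 cm) are metadata only; all geometry is two-dimensional.
In the `apart` configuration animals cross the gaps unaided, so the
floor is the connected 170 × 50 cm union and each platform's four edges
are drop elements, the gap-facing ones tagged `gap_edge`.

`insert_barrier()` adds a free-standing 50 × 3 cm barrier (50 cm tall in
the real apparatus) as four wall elements.  The two 3 cm end faces exist
geometrically but the classification criterion concerns only the 50 cm
faces.  The barrier's position is configurable and defaults to the floor
centre, the natural reading of "central region".

## The generative BVC model

The firing rate at position $p$ integrates over allocentric directions
$\theta$:

$$ f(p) \propto \int_0^{2\pi}
   \exp\!\left(-\frac{(d(p,\theta)-d_{\text{pref}})^2}{2\sigma_{\text{rad}}^2}\right)
   \exp\!\left(-\frac{\Delta(\theta,\phi_{\text{pref}})^2}{2\sigma_{\text{ang}}^2}\right)
   d\theta, \qquad
   \sigma_{\text{rad}} = \sigma_0\left(\frac{d_{\text{pref}}}{\beta}+1\right) $$

where $d(p,\theta)$ is the distance to the first boundary along
direction $\theta$ and $\Delta$ is the wrapped angular difference.  The
linear broadening of the radial tuning with preferred distance follows
the standard BVC parametrisation; defaults are $\sigma_0 = 12$ cm,
$\beta = 180$ cm, $\sigma_{\text{ang}} = 0.2$ rad, all configurable via
`bvc_params()`.  The integral is evaluated on 360 rays (1° steps, well
below the angular tuning width).  The surface is normalised so its
maximum over the environment equals `a_max` (default 10 Hz); this makes
the 40%-of-peak classification criterion scale-free.  Firing is
heading-independent by construction.

HD cells use circular-Gaussian tuning
`a_max * exp(kappa * (cos(hd - mu) - 1))`; boundary-off cells fire at
`baseline * (1 - suppression * bvc_rate / a_max)`, floored at zero.

## Trajectories and spike trains

`simulate_trajectory()` generates a smooth random forage: heading
diffuses with bounded Gaussian increments (`turn_sd`, default
1.2 rad/√s), speed follows a positive mean-reverting process around
`speed_mean` (default 18 cm/s, τ = 1 s), and a step that would leave the
floor rotates the heading away from the blocked direction in 30°
increments, preferring the side the current turn favours — which makes
the walker skirt along walls and barriers the way foraging rodents do.
The head keeps `wall_clearance` = 5 cm from the perimeter (a head cannot
reach the wall line) but `barrier_clearance` = 0 from a free-standing
barrier, which animals investigate closely; the bins directly abutting
the barrier would otherwise never be sampled.  These defaults were fixed
against the generator's own quality targets — ≥95% of reachable 3 cm
bins visited in a 27-minute trial (measured ≈ 99%), interior coarse-bin
dwell ratios below 5 (measured 2–3), and ≈60 visited 18.5 cm bins in the
eroded circle — and then left alone.  Trial duration defaults to 1620 s
(27 min), consistent with trials that divide into three 9-minute
segments.

`generate_spikes()` draws an inhomogeneous Poisson train by thinning a
homogeneous train at the trajectory-wide maximum rate; the optional
theta factor `1 + depth·cos(2π f₀ t)` is evaluated in continuous time at
the candidate spike times, so 8 Hz modulation is not quantised to the
20 ms tracking grid.  All stochastic operations take explicit integer
seeds and restore the caller's RNG state.

What the generator does *not* emulate: place/grid cells, conjunctive
boundary-by-direction coding, slow rate drift, theta phase precession,
bursting, or behavioural asymmetries such as corner preferences.
Passing recovery tests on these synthetics therefore shows the pipeline
is correct and well-calibrated for cells that obey the BVC/HD/off
models, not that it is robust to every failure mode of real recordings.

## Rate maps and smoothing

Locational maps use square bins (default 3 cm) with bin edges anchored
on integer multiples of the bin size from the floor centre, so the
origin is always a bin corner; this single deterministic convention also
makes an 18.5 cm grid over the clearance-eroded 150 cm circle contain
exactly 60 reachable cells, matching the matched-bin correction below.
Spikes are assigned to the bin of the temporally nearest position sample
(≤10 ms error at 50 Hz).  Smoothing is a 5 × 5 boxcar applied to counts
and dwell separately before division — numerically stable where
occupancy is thin; smoothing the rate directly is available via
`smooth_mode = "rate"`.  Two renormalisations keep the boxcar honest:

* at map borders the kernel is renormalised over the visited bins in the
  window, so perimeter rates (where BVC fields live) are not diluted by
  empty bins;
* when the environment carries a barrier, window members whose
  centre-to-centre line crosses the barrier footprint are excluded.  The
  animal cannot cross the barrier and boundary-driven firing differs
  sharply on its two sides; pooling across a 3 cm barrier otherwise
  halves the estimated rate in exactly the abutting bins the
  classification criterion inspects (we measured the systematic dilution
  directly — it equals the dwell-weighted prediction, not sampling
  noise).

Directional maps use 60 bins of 6°, smoothed with a circular 5-bin
boxcar.  `windowed_rate_map()` restricts both samples and spikes to
`[t0, t1)` for segment analyses.

Speed filtering discards samples above 2 m/s.  A sample's speed for
filtering is the *smaller* of its two adjacent-interval speeds: an
isolated teleported sample is far from both neighbours and flags itself,
while its well-tracked neighbours survive; a centred difference would
straddle the jump and keep the artefact.  The centred-difference speed
is retained for run extraction, where a smooth estimate is wanted.

## The field-repetition criterion

Classification composes three steps:

1. **Eligibility.**  The cell must fire at or near the perimeter in the
   baseline trial: its field peak lies in the outer portion of a
   circular floor (at or beyond 75% of the radius, boundary inclusive;
   within two bin widths of a wall for rectangular floors) *and* at
   least half of its firing mass (dwell-weighted rate) falls within the
   outer band (nearest quarter of the inradius).  The second condition
   matters: a diffusely firing cell — an HD cell, say — has a noisy peak
   that lands in the outer annulus almost half the time by area alone,
   and a near-uniform map trivially exceeds 40% of its own peak
   everywhere, so peak position alone cannot encode "fires at the
   perimeter".  Ineligible cells yield a labelled "not eligible"
   outcome, not an error.
2. **Predicted side.**  The preferred direction is the direction from
   the baseline field to the nearest perimeter point, with the field
   located by the rate-weighted centroid of bins at or above half the
   peak (robust to single-bin noise; the raw argmax with its documented
   row-major tie rule remains available as `field_peak()`).  The
   predicted side of the barrier is the face opposite the preferred
   direction: a south-tuned cell doubles its field on the barrier's
   north side.
3. **Coverage.**  Abutting bins are the visited bins whose square
   touches the predicted 50 cm face (infinitesimally displaced to the
   predicted side, so tangency from the far side does not count), whose
   centre is on the predicted half, and whose centre is not inside the
   footprint; bins beyond the barrier ends are excluded, and partially
   overlapping end bins count as bins (bin-count, not centimetre,
   convention).  Coverage is the percentage of abutting bins at or above
   40% of the map's locational peak rate; at 50% or more the cell is a
   BVC.  Coverage is computed on the smoothed (barrier-aware) map,
   consistent with maps whose close-ups the criterion was illustrated
   on.

The boundary-off criterion mirrors this with the inequality inverted:
the fraction of abutting bins at or *below* 40% of the median
visited-bin rate, flagged at ≥50%.  No published formula exists for
boundary-off cells; this operationalisation is this package's own and
both fractions are configurable.

## Spatial statistics

Selectivity is peak rate over global mean rate.  Information rate is the
Skaggs formula $\sum_i p_i \lambda_i \log_2(\lambda_i/\bar\lambda)$ in
bits/s with $0\log 0 = 0$.  Because information depends strongly on bin
count, `matched_bin_stats()` compares locational and directional coding
on *unsmoothed* maps with matched bin numbers: 60 directional bins of 6°
against a coarse locational grid — 18.5 cm in the 150 cm circle, 14 cm
in the 100 cm square (≈60 visited bins either way), or a searched bin
size for other floors.  Only bin matching and unsmoothed maps are
implemented; distributive-hypothesis corrections are out of scope.

`mc_field_peak_null()` draws `n` points uniformly in a disk of radius
`R` per replicate (inverse-CDF radius $r = R\sqrt{u}$ — exact,
rejection-free), records the mean distance to centre, and repeats 10⁶
times.  The closed forms $E = 2R/3$ and $\mathrm{Var} = R^2/(18n)$
anchor the tests.  Convergence is declared when mean, median and 95th
percentile each move by less than one unit in the checked decimal (two
by default) between the first half of the replicates and the full
sample; a strict equality of rounded values is a coin flip at 10⁶
replicates because the 95th percentile's Monte Carlo error sits almost
exactly at the second decimal.  `percentile_of()` uses the strictly-less
rank; ties have measure zero.

## Temporal statistics

Theta modulation is scored from the 500 ms spike-train autocorrelogram
of spikes emitted during runs (≥0.5 s above 5 cm/s).  The lag bin width
is 4 ms, chosen so the spectral Nyquist frequency is exactly 125 Hz and
the "whole spectrum" band is 0–125 Hz.  The mean-subtracted
autocorrelogram is zero-padded to ≥4 s (frequency resolution ≈0.24 Hz,
no taper by default; a Hann taper is available), transformed, and the
score is the mean power in a 2 Hz band centred on the spectral peak
within 6–12 Hz divided by the mean power over 0–125 Hz.  The theta peak
is located per cell, not fixed.

## Problem sizes used in validation

The test-suite simulations use 27-minute trials at 50 Hz (81 000
samples) for trajectory-quality, classification and information
checks — the same trial length the analyses assume — with populations of
20 BVCs (preferred distances 4–12 cm, random preferred directions,
barrier perpendicular to each cell's true direction), 20 HD cells and 5
boundary-off cells; theta scoring uses 10-minute constant-rate trains
across ≥10 seeds; the Monte Carlo null uses the full 10⁶ replicates.
Under these conditions classification sensitivity for simulated BVCs is
≥0.9 with HD false positives ≤0.1, locational information exceeds
directional for every simulated BVC population by sign test (and the
reverse for HD cells), and the theta score at modulation depth 0.8
exceeds the unmodulated score more than three-fold.

## Known limitations

* The eligibility gate and the boundary-off criterion involve two
  conventional fractions (half the firing mass near the perimeter; 40%
  of the median rate) that are defensible but not canonical; both are
  exposed as arguments.
* Geometry is 2-D; wall height never enters the model.
* The generator's behavioural realism is limited (no thigmotactic
  corner-dwelling, no rearing, no inter-trial rate drift), so recovery
  rates here bound performance on idealised data only.
* `matched_bin_stats()` auto-selects a bin size only by visited-bin
  count; in severely under-sampled trials the matched grid can be
  coarse enough to hide genuine locational structure.
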