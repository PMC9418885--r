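---
title: "Models and methods behind slbquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slbquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

slbquant quantifies three kinds of measurement made on supported-lipid-
bilayer (SLB) models of the bacterial outer membrane: AFM breakthrough
force spectroscopy, AFM topographic imaging, and dynamic light scattering
(DLS) of vesicle suspensions. Because no public raw data exist for such
experiments, the package pairs every analysis stage with a synthetic-data
generator whose ground truth is recorded exactly; all quantitative claims
the package makes about itself are parameter-recovery statements on that
synthetic data, computed by the test suite and the acceptance script.

## Force spectroscopy

### Generative model

An approach curve is sampled on a uniform separation grid (default step
`ds = 0.02` nm) running from free travel down to the force setpoint
(10 nN). The model is piecewise linear: zero force before contact,
elastic loading at the scenario's contact stiffness after contact, and
for each membrane layer present an instantaneous one-sample rupture -
the force drops to the baseline and rises again only after the tip has
advanced by the layer's rupture thickness. Layer presence is Bernoulli
per curve (the LPS oligosaccharide layer is present in 95% of curves in
the LPS-DMPC scenario), and rupture forces and thicknesses are drawn from
per-layer normal distributions anchored to the published values
(1.3 ± 0.3 nN for gel-phase DMPC, 0.34 ± 0.08 nN fluid-phase,
1.4 ± 0.5 nN for the LPS-DMPC bilayer step, 2.03 ± 0.41 nN for OM-DMPC).
Two scenario-specific shapes extend the basic stack: OM-DMPC loading
begins with a soft elastic-compression prelude (stiffness ratio 0.1 up to
0.3 nN), and the LPS-vesicle scenario is a fixed three-regime curve -
soft loading from 30 nm, ten-fold stiffer loading from 12 nm, and a
single rupture near 6 nN down to the substrate.

Drawn rupture forces and thicknesses are realised *on the sampling grid*:
the yield is placed at the first grid sample whose ramp force reaches the
drawn value and the thickness is rounded to a whole number of samples,
and the truth record stores these realised values. This makes the
noise-free oracle exact - a noise-free curve equals its piecewise
analytic form at every sample, and detection can be required to match
truth to machine precision rather than to within a sample.

Elastic loading is linear in indentation; the separation convention is
tip-sample separation in nm decreasing during approach, with the hard
substrate contact at 0 nm and slightly negative values standing for
substrate indentation. Gaussian force noise (default 0.05 nN; 0.02 nN for
the fluid-phase scenario, whose rupture force is only 0.34 nN) is added
to every sample. All randomness flows from one integer master seed
through a counter-based splitting rule (`sub_seed()`), so batches are
bit-identical across reruns and each batch element is reproducible alone.

### Detection

Curves are preprocessed with a running median (default window 5 samples)
and baseline-subtracted using the far-separation region. Step detection
walks the filtered first difference with hysteresis: a one-sample drop
exceeding `max(min_force/2, 7 sigma_d)` opens an event, where `sigma_d`
is the standard deviation of one-sample differences of the *filtered*
far-field noise; the event closes at recontact - the last sample at the
post-drop baseline before force rises and stays above `4 sigma_a`
(filtered amplitude noise). The 7-sigma trigger was set from the measured
false-trigger tail of median-filtered Gaussian noise so that spurious
events stay below ~0.05 per 2000-sample curve while events above the
0.1 nN analysis gate are retained; its cost is that the lowest-force tail
of the alpha population (below roughly 0.15 nN at the default noise) is
missed, which raises the apparent beta-without-alpha fraction above the
generative 5% absence rate.

The rupture force at yield is estimated by fitting the loading line to
the filtered samples of the current ramp (excluding the half-window the
median filter clips off a sawtooth peak) and evaluating the line at the
yield sample. Reading the filtered value at the yield sample directly
would be biased low by `floor(w/2)` loading samples plus a
min-of-order-statistics noise term - at the 0.34 nN scale that bias
exceeds the 5% recovery budget - whereas the local line fit is exact on
noise-free data and unbiased under noise. The published gates (rupture
force > 0.1 nN, thickness > 0.1 nm) are applied to the force at yield and
the yield-to-recontact distance; gating on the drop magnitude instead is
available via `gate_on = "drop"`.

The contact point is located by a changepoint fit: within a window around
the first persistent threshold crossing, the force is modelled as zero
above the contact separation and linear below it, and the sample
minimising the residual sum of squares is reported. For scenarios with a
gradual elastic prelude the reported contact reflects the onset of
measurable loading rather than the first molecular contact - with a
0.06 nN/nm prelude under 0.05 nN noise the two genuinely differ.

### Classification and summaries

Within a multi-step curve, every event but the last is alpha and the last
is beta; a single-step curve is beta below the gamma force gate and gamma
above it. The gate is fitted as the midpoint between the two means of a
two-component Gaussian mixture over single-step forces, and falls back to
a fixed 1.7 nN when the batch has fewer than 20 single-step events, when
the mixture's BIC prefers one component, or when the two means are closer
than 0.5 nN - a single-scenario batch is unimodal and the mixture
midpoint would split it artificially. Batch summaries report the mean and
sd of the final rupture force, the mean step count, population counts and
centroids, and the fraction of bilayer ruptures without a preceding alpha
event; `tidy()` exposes the per-event force-thickness table behind the
population scatter map.

## Height-image analysis

### Generator

Scenes compose, bottom-up: a substrate plane at 0 nm with fine texture;
blob-shaped phase regions carved from smoothed Gaussian random fields by
exact pixel-count quantiles, so realised coverages match requested ones
to one pixel; per-class plateau heights (4 nm fluid, 5 nm solid, ~6 nm
OM-DMPC) with Gaussian texture per class (0.08 nm for smooth phases,
0.77 nm for the smooth-DMPC roughness scenario, 1.16 nm for rough LPS
domains); an optional stripe sinusoid (15 nm period, 0.4 nm amplitude)
on the lipid phases; spherical-cap vesicles; and finally per-scanline
linear tilt/offset artifacts (offset sd 0.3 nm, tilt sd 0.5 nm across
the row). The default frame is 512 x 512 pixels over 2 x 2 um.

Vesicle cap sizes follow the equal-area-disc-at-half-maximum convention
shared with the detector: the drawn diameter *is* the half-max diameter,
the cap height is 0.4 of it, and the sphere radius follows from the two.
Diameters are drawn from a lognormal with mean 29 nm and sd 22 nm. A
normal left-truncated at a detectability floor cannot have both this mean
and this sd (its mean is pushed near 36 nm), and the published 29 ± 22 nm
is itself a detected-in-images statistic, so the generator draws the
naturally positive lognormal and lets caps smaller than about a pixel go
undetected, which leaves the detected population mean near 29 nm.

### Levelling

`flatten_map()` removes scan-line artifacts in two passes. Pass one
aligns rows through adjacent-row differences: consecutive scanlines share
almost the same phase layout, so their difference cancels the surface
structure and isolates the per-row artifact increment, which is fitted
per row (least squares with two rounds of 4-MAD outlier trimming at phase
boundaries) and accumulated. Pass two removes what the difference scheme
cannot see: the map is segmented into height levels, each row's
polynomial is refitted on the *residuals from the per-class plateau
heights*, and a robust global plane is fitted on the same residual field
- fitting heights directly would let phase structure that correlates
with position masquerade as tilt. The pass iterates (up to four times)
because a badly misaligned first segmentation misassigns pixels in
shifted rows; it settles in one or two iterations. Finally the lowest
well-populated height level - the substrate where present, else the
dominant plateau - is shifted to 0 nm. Flattening is idempotent to well
below 1e-6 nm RMS, and on synthetic scenes the levelled map matches the
artifact-free truth to a few hundredths of a nm RMS.

### Segmentation, coverage, roughness, texture

Pixels are assigned to height levels by multi-level Otsu thresholding of
the height histogram (deterministic, hence the default; a Gaussian
mixture is available). With `n_classes = "auto"` the class count is the
number of well-separated modes of a kernel density over heights - a
variance-elbow rule was rejected because splitting a unimodal Gaussian
still reduces within-class variance by two thirds. Levels are named
substrate / fluid / solid by height order. Two texture classes refine the
levels: *rough* marks lipid pixels whose 5 x 5 local variance exceeds 3x
a smooth reference (the 20th percentile of lipid local variance, which
stays anchored on the smooth population even when rough domains cover
most of the lipid), followed by a morphological opening that discards the
thin high-variance bands every plateau step edge produces; *bump* marks
connected components protruding above the top plateau. Coverage fractions
are pixel counts over the lipid area (the convention in which the 65/35
solid/fluid split is stated) or the whole frame. R_q is the RMS height
deviation about the mean over a mask.

Stripe periodicity comes from the 2D power spectrum of the
plane-detrended, Hann-windowed field: the dominant wavelength is the
strongest non-DC bin (reported only when it exceeds 20x the mean
spectral power - white noise peaks at ~12x by extreme-value statistics),
and the sinusoid-equivalent amplitude is recovered from the unwindowed
spectrum by Parseval bookkeeping over the peak's neighbourhood. A 15 nm
period in a 2 um frame lies at radial index ~133, so the one-bin
tolerance is about 0.11 nm there.

## Dynamic light scattering

The forward model is the Siegert relation
`g2 = 1 + beta |g1|^2` with `g1(tau) = sum_i w_i exp(-q^2 D_i tau)`,
`q = 4 pi n sin(theta/2) / lambda`, and `D_i = kB T / (3 pi eta d_i)` for
spheres - evaluated by one shared code path for both the generator and
the inversion, so round-trip tests cannot hide a model mismatch. The
instrument defaults are the standard goniometer geometry (457 nm, 90 degrees); water
viscosity (Vogel equation) and refractive index are tabulated by
temperature rather than hard-coded. The default lag grid is 240
log-spaced channels over 1e-7 to 1 s, a multi-tau correlator layout.

`invert_mem()` maximises the entropy `S = -sum p_i log(p_i / m_i)`
(uniform prior m) subject to `chi^2 <= chi2_target x n_lags` on a
60-point log-spaced diameter grid spanning 1-1000 nm. The constrained
problem is solved along a regularisation path: for a trial multiplier the
penalised objective `chi^2 - alpha S` is minimised by exponentiated-
gradient (multiplicative) updates with a backtracking line search -
multiplicative updates keep weights positive and let vanished grid nodes
regrow, where a quasi-Newton step through a softmax parametrisation was
found to freeze mass at saturated nodes - and alpha is bisected (40
steps) to the largest value whose solution still meets the constraint.
Stopping is at a relative objective change of 1e-10 or 5000 inner
iterations; everything is deterministic given the inputs. When even the
near-unregularised fit cannot reach the target (which happens for about
half of random noise realisations when the target equals the expected
chi-square of the truth), the best iterate is returned flagged
non-converged; the recovered distribution is still usable and the flag is
reported by `glance()`.

Weights are intensity weights - what DLS measures; an optional `d^-6`
conversion to number weights is available but off by default. A mode at
the top of the grid is flagged (`at_upper_edge`), the signature of a
decay-free correlogram.

The practical resolution of this inversion is bounded by the conditioning
of the Laplace transform, not by the solver: at a signal-to-noise of ~100
(1% noise on g2), components four-fold apart in diameter merge into a
single mode lying between them, and reliable two-mode recovery to one
grid cell needs either wider separation (ten-fold) together with noise
near 0.1%, as the test suite demonstrates. Exact numerical agreement with
any particular commercial MEM implementation is not claimed.

## Pipeline and problem sizes

`run_pipeline()` chains generation, detection, classification and
summarising per scenario and compares recovered statistics to the stored
truth, with one structured log line per stage and a config hash in the
report; outputs are CSV/JSON plus a readable text report, and reruns
under the same config are bit-identical. The default problem sizes are
the experimental ones: 400 curves per force-spectroscopy batch (100 for the
vesicle-compression scenario, matching its rarer events), 512 x 512
pixel 2 x 2 um frames, and 240-channel correlograms; unit tests use
smaller frames (128-256 px) except where an estimate is
resolution-limited at that size, and the rough-domain overlap test runs
at the full 512 px frame because boundary-band losses scale with
perimeter over area.

## What passing tests do and do not show

The generator emulates the features the analyses measure: discrete
rupture steps on piecewise-elastic loading, multi-level plateaus with
stationary Gaussian texture, ideal sinusoidal stripes, ideal spherical
caps, row-wise linear artifacts, and exponential correlogram decays with
additive white noise. Real data violate most of these in ways the
synthetic tests cannot probe: force noise is coloured and drifts,
ruptures have finite width and tip-speed dependence, AFM images carry
tip-convolution, creep and nonlinear bow, LPS domains are not stationary
Gaussian texture, and DLS noise is heteroscedastic and correlated across
channels. Parameter recovery here therefore validates the estimators
against their own generative assumptions - it bounds algorithmic bias
and variance, and cannot certify accuracy on instrument data.
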