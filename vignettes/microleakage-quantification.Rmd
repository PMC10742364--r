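---
title: "Quantifying dye-penetration microleakage by interface curve fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dye-penetration microleakage by interface curve fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakfit)
```

## The measurement problem

When a provisional crown is cemented onto a prepared abutment (in vitro, a
standardized milled die), the luting cement seals the gap between the two.
Microleakage -- seepage along the cement--die interface -- is classically
assessed by immersing aged specimens in methylene blue, sectioning them, and
scoring how far the dye travelled from the margin. Ordinal scoring is quick
but coarse and subjective. `leakfit` instead measures the *distance* the dye
travelled along the interface, on an RGB photograph of the cut surface, in
three stages:

1. **Segmentation.** A pixel is dye-positive when its channels satisfy
   `R <= 110`, `G <= 160` and `150 <= B <= 200` (all three at once). These
   box bounds select penetrated methylene blue against die, cement and
   resin; they are configurable via `dye_threshold()`.
2. **Marker placement.** The dye band is reduced to ordered single-pixel
   markers along the interface: dye pixels are projected onto their
   principal axis, partitioned into bins of `bin_width` pixels, and each
   occupied bin contributes its centroid, rounded to the nearest pixel. The
   trace is oriented starting from the margin anchor supplied as specimen
   metadata. Marker placement is fully automated so that repeated runs of
   the same image give identical traces.
3. **Curve fit and arc length.** A fourth-order polynomial
   $y = ax^4 + bx^3 + cx^2 + dx + e$ is fitted to the markers by least
   squares, and the penetration distance is the arc length
   $s = \int_a^b \sqrt{1 + (dy/dx)^2}\,dx$ between the margin-end and
   far-end markers, converted to millimetres by the calibration factor
   (default 0.0013028 mm/pixel, a microscope-graticule calibration). If the
   trace reaches the die-center landmark, or the converted distance reaches
   the cap (default 7.18 mm, the margin-to-die-center distance), the
   specimen is recorded as complete penetration at exactly the cap value.

A quartic is flexible enough to follow the gently curved margins of a
sectioned crown while remaining a single global model with an easily
integrated derivative; the package deliberately offers no spline or
piecewise alternative.

## The local frame

The quartic is a function $y = f(x)$, which cannot represent a
near-vertical interface in raw image coordinates. `fit_interface_curve()`
therefore rotates the markers into their principal-axis frame (abscissa
along the least-squares line through the markers, origin at their centroid)
before fitting. Arc length is invariant under rigid transformations, so for
any interface that is already single-valued in image coordinates the
measured distance is unchanged -- this invariance is asserted by the test
suite to 1e-3 px. The `frame = "image"` option fits in raw coordinates,
which is convenient when the coefficients themselves are of interest.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `r_max`, `g_max`, `b_min`, `b_max` | 110, 160, 150, 200 | 8-bit channel | selects methylene blue |
| `mm_per_pixel` | 0.0013028 | mm/px | graticule calibration of the assumed capture setup |
| `cap_mm` | 7.18 | mm | margin-to-die-center distance; complete penetration |
| `degree` | 4 | -- | interface model; reduced to $n-1$ when markers are scarce |
| `bin_width` | 5 | px | marker bin size; suppresses sub-pixel jitter |
| `n_thickness_stations` | 3 | -- | stations for cement thickness |
| `delamination_policy` | `"exclude"` | -- | see below |
| `alpha` | 0.05 | -- | normality-gate level |

**Bin width and end bias.** Because each marker is a bin centroid, the
first and last markers sit roughly half a bin inside the true ends of the
dye front, so the measurement is short by about `bin_width` pixels in
total. With the default 5 px bins this is negligible for penetrations on
the millimetre scale (under 0.5 % beyond ~1500 px of arc) but visible on
very short fronts; the test suite uses `bin_width = 1` for fixtures a few
hundred pixels long. Choose `bin_width` small relative to the expected
penetration, and large enough to smooth segmentation jitter (3--8 px for
typical captures).

**Integration bounds.** The bounds are the local-frame abscissae of the
first and last markers. When dye reaches the occlusal region without a
die-center landmark being supplied, the metric cap (`cap_mm`) still
applies, so the cap remains meaningful in landmark-free workflows.

**Delaminated specimens** (restoration fully debonded during aging) are a
failure mode, not a measurement: they are flagged in metadata, never
inferred from pixels, and either excluded from the statistics (default) or
entered at the cap distance (`delamination_policy = "assign_cap"`). Both
conventions appear in the literature; exclusion is the default because a
delaminated specimen no longer has the interface being measured.

## Cement thickness

`measure_cement_thickness()` measures the cement band between two fitted
interfaces (die-side and restoration-side) at stations evenly spaced *in
arc length* along the die curve, endpoints inclusive (margin, midpoint,
occlusal middle for the default three). Thickness at a station is the
distance along the local normal to the die curve until it crosses the
restoration curve, in micrometres. Both choices -- arc-length spacing and
die-side normals -- are the package's own: spacing in arc length matches
how penetration itself is measured, and the die-normal gap is the
physically meaningful cement-film thickness. A station whose normal misses
the restoration curve's fitted extent (plus a small overhang allowance of
5 px or 2 % of its span, whichever is larger) is excluded with a warning.

## Statistics

The statistical workflow mirrors standard practice for capped,
non-normal microleakage data:

* `sample_size_oneway()` computes the a-priori minimum balanced total N for
  a one-way fixed-effects comparison from the noncentral F distribution
  (noncentrality $\lambda = f^2 N$, df $(k-1, N-k)$). With Cohen's
  $f = 0.5$, $\alpha = 0.05$, power 0.8 and $k = 3$ it returns
  `r sample_size_oneway(0.5, 0.05, 0.8, 3)`.
* `shapiro_gate()` runs Shapiro--Wilk per group; any $p < \alpha$ flags the
  nonparametric path. A zero-variance group (all specimens at the cap) is
  treated as non-normal with a warning rather than an error, because
  cap-saturated groups are a realistic outcome.
* `kruskal_wallis()` is the tie-corrected midrank omnibus test (delegated
  to `stats::kruskal.test`); an all-identical study returns $H = 0$,
  $p = 1$ rather than NaN.
* `dunn_bonferroni()` computes Dunn's pairwise z statistics on the joint
  midranks with the tie correction and multiplies two-sided p-values by
  $k(k-1)/2$, clipped at 1. It is validated against an independent
  direct-formula computation and against the identity $z^2 = H$ for two
  tie-free groups.

## The synthetic-scene generator

Real specimen images of this kind are not publicly deposited, so the
package ships a generator whose scenes have *analytic* ground truth:
a polynomial die--cement interface, a cement band of constant or linearly
wedged thickness, a restoration region, and a dye band painted along the
interface from the margin over an exact arc-length extent. The cut-off
abscissa is found by root-solving on a composite-Simpson arc-length oracle
(4096 panels) that shares no code with the adaptive quadrature used for
measurement, so generator and pipeline are independent routes to the same
quantity; the suite requires them to agree to 1e-4 relative.

Default scene conditions, chosen once as a realistic desk-scale emulation:
a 1400 x 2000 px canvas (a reduced-resolution stand-in for 6000 x 4000
captures), a gently curved quadratic interface, a 100 um cement gap, a
3 px dye band, and a 1500 px dye extent (about 2.0 mm at the default
calibration, mid-range for provisional restorations). The `"stepped"`
texture adds a 40 px period, 6 px amplitude square wave to the
restoration interface and lets the dye band widen into the grooves,
emulating the staircase morphology of additively manufactured fitting
surfaces (roughly 52 um layers with 8 um ridges at the default
calibration); `"smooth"` emulates milled or moulded surfaces. Sensor noise
is independent Gaussian per channel, clipped to [0, 255] -- the simplest
model that stresses the threshold box.

What the generator does *not* emulate: uneven illumination, varnish
regions, cracks, partial dye fading, chromatic sensor effects, or
thermocycling-induced degradation. Passing the synthetic suite therefore
demonstrates the geometry and calibration chain, not robustness to every
photographic artefact of real captures.

`generate_group_study()` simulates specimen-level outcomes directly:
penetration values drawn from a normal distribution, truncated below at 0
and capped at the complete-penetration distance, with independent
delamination indicators.

## Numerical choices

* Quadrature: `stats::integrate`, relative tolerance 1e-8 -- the integrand
  is smooth, so cost is negligible.
* Fit: QR least squares on raw powers of the centred local abscissa;
  centring keeps the design well conditioned at realistic extents.
* Centroid rounding: nearest pixel, exact halves toward the smaller index,
  for determinism.
* Degenerate traces: one marker or none maps to `status = "no_dye"`;
  2--4 markers reduce the fitted degree to $n-1$ and record it.
* Normal-ray root finding (thickness): sign-change scan at 0.5 px
  resolution refined by `uniroot` to 1e-8, nearest crossing kept.

## Verification problem sizes

The shipped test-suite checks run at sizes chosen to exercise each claim
meaningfully: 50 seeded scenes at the default canvas (alternating smooth
and stepped, channel noise 0--8) for ground-truth recovery within 2 %
(0.5 % noiseless); 10,000 simulated null studies of 15 specimens per group
for the 0.05 +/- 0.01 level of the omnibus test and the family-wise error
of the pairwise procedure; 20,000 Monte-Carlo replicates for the power of
the design returned by `sample_size_oneway()`.

## Known limitations

* The dye threshold is a fixed box in RGB; images captured under very
  different illumination or white balance need their own threshold (or a
  prior colour normalisation, out of scope here).
* The quartic is a global model: interfaces with inflection-rich geometry
  beyond degree 4 will be smoothed, biasing arc length slightly downward.
* The margin anchor and die-center landmark are metadata, not detected.
* Cement thickness requires both interface traces; the dye threshold alone
  yields only the die-side trace, so thickness on real images needs a
  second segmentation step supplied by the user.
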