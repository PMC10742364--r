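# leakfit

Quantitative measurement of dye-penetration microleakage on cross-section
images of cemented crown specimens.

In vitro, the sealing ability of a provisional crown is assessed by aging
the cemented specimen, immersing it in methylene blue, sectioning it, and
measuring how far the dye travelled along the cement–die interface from the
margin. `leakfit` replaces subjective ordinal scoring of such sections with
a reproducible distance measurement:

1. **Segment** penetrated dye by per-channel RGB thresholds
   (`R ≤ 110`, `G ≤ 160`, `150 ≤ B ≤ 200` by default);
2. **Trace** the dye band with ordered single-pixel markers along the
   die–cement interface (per-bin centroids on the dye region's principal
   axis);
3. **Fit** a fourth-order polynomial *y = ax⁴ + bx³ + cx² + dx + e* to the
   markers and report the arc length

   *s = ∫ₐᵇ √(1 + (dy/dx)²) dx*

   converted to millimetres (default 0.0013028 mm/pixel). Dye reaching the
   die-center landmark — or a converted distance at the cap — is recorded
   as complete penetration at exactly 7.18 mm.

The package also measures cement-layer thickness between two fitted
interfaces at evenly spaced arc-length stations, ships the matching
statistical workflow (noncentral-F a-priori sample size, Shapiro–Wilk
normality gate, Kruskal–Wallis omnibus test, Dunn pairwise comparisons with
Bonferroni correction), and includes a synthetic cross-section generator
with analytic ground truth so the whole chain is testable without specimen
images.

## Worked example

Generate a synthetic specimen with a known 1500 px dye front on a stepped
(3D-printed-like) interface, then measure it end to end:

```r
library(leakfit)

sc    <- generate_cross_section(scene_spec(dye_extent_px = 1500,
                                           texture = "stepped",
                                           noise_sd = 4, seed = 42))
mask  <- classify_dye_pixels(sc$image)
trace <- extract_interface_markers(mask, sc$ground_truth$margin_anchor)
trace
#> <marker_trace: 300 markers, margin end at (900, 3)>

measure_penetration(trace)
#> <penetration_result: measured, 1.9476 mm (1495.0 px)>

sc$ground_truth$true_penetration_mm
#> [1] 1.954200
```

The measured 1.9476 mm is within 0.4 % of the generator's analytic ground
truth; the 1495.0 px arc length times the 0.0013028 mm/pixel calibration
gives the millimetre value exactly.

Group-level statistics on simulated specimen outcomes (three manufacturing
groups, 15 specimens each):

```r
gs <- generate_group_study(15, list(printed = list(mean = 2.2, sd = 2.2),
                                    milled  = list(mean = 4.7, sd = 2.4),
                                    moulded = list(mean = 6.8, sd = 1.3)),
                           seed = 42)
rep <- study_report(gs)
rep
#> <test_report: H = 12.39 (df 2), p = 0.002036; 3 pairwise comparisons>
rep$pairwise
#>    group1  group2          z        p_raw  p_adjusted
#> 1 printed  milled -0.8793595 0.3792063892 1.000000000
#> 2 printed moulded -3.3918152 0.0006943126 0.002082938
#> 3  milled moulded -2.5124557 0.0119894161 0.035968248
```

The omnibus test rejects at the 0.05 level and the adjusted pairwise
p-values single out the printed-vs-moulded and milled-vs-moulded contrasts;
values are capped at 7.18 mm, so `complete_penetration` counts accompany
each group summary.

For batch work there is a thin CLI (`exec/leakfit`) with subcommands
`measure`, `study`, `simulate`, `stats` and `power`, and `run_study()`
turns a manifest CSV of images plus margin anchors into per-specimen rows,
group summaries and the full test report.

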