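---
title: "Measuring motion quality in the lower cervical spine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motion quality in the lower cervical spine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervseq)
```

## The problem and the model

Cine-fluoroscopy of an actively performed flexion-to-extension movement
yields, after vertebra tracking, a rotation angle per vertebra per frame.
For the lower cervical spine the analysis works with three motion segments
— C4-C5, C5-C6, C6-C7 — whose relative angle is the difference of the
adjacent vertebral rotations. Their sum is the rotation of the C4–C7 block,
identically (the sum telescopes to `theta(C4) − theta(C7)`), and the
package maintains that identity *exactly* at every stage: the block series
is always computed as the elementwise sum of the segment series, never
re-estimated.

Quantity of motion (segmental range of motion, sROM, and the block total,
tROM) is known to vary strongly between repeated sessions, and maximal
segmental rotation often occurs away from the movement endpoints. The
package therefore reports two ROM conventions: `endpoint`
(`|last − first|`, comparable with static radiograph studies) and
`extremal` (`max − min` along the whole path, the default). Extremal can
never be smaller than endpoint; both are kept because the literature mixes
them and printed cohort tables do not state which was used.

The *sequence of segmental contributions* (SSC) re-expresses each
segment's motion as a function of cumulative block rotation rather than
time: with `x` the running C4–C7 rotation, the curve shows how many degrees
each segment contributes as the block extends. In young asymptomatic
adults the terminal phase of extension shows a characteristic
cranial-to-caudal order of contribution peaks (C4-C5, then C5-C6, then
C6-C7); the classifier in this package makes that ordering claim
operational.

## SSC curve construction

Segment angle series are smoothed with a Savitzky–Golay filter (window 5
frames, order 2 by default; `sg_window = 1` disables smoothing). The
smoothed series are differenced per frame and re-binned onto a uniform grid
in cumulative rotation (0.1° cells by default, last cell partial).
Because a real block trace can transiently move backwards, grid placement
uses the *running maximum* of the block series: frames where the block
regresses deposit their (possibly negative) contributions at the
furthest-reached coordinate. This folding keeps the x axis strictly
increasing while conserving every segment's integral exactly: the sum of
`rate × cell width` over the grid equals the segment's net (smoothed)
rotation to floating-point accuracy. With smoothing disabled the integral
equals the raw net rotation; with the default filter the difference stays
well below 0.1° even for noisy recordings, because the filter only
perturbs the few frames at the series ends.

Two y-representations are stored per cell: `rate` (degrees of segmental
rotation per degree of block rotation — the three rates sum to one wherever
the block moves forward) and `contribution_per_frame` (degrees per frame,
the quantity conventionally plotted and the scale on which peak
significance is defined). The conversion uses the time actually spent in
each cell, so acceleration of the movement does not distort either
representation.

If the net block rotation is below `min_rotation` (3° by default) the
recording is flagged `insufficient motion` instead of producing a curve;
the flag propagates to the classifier as a negative call with that reason.
The floor exists because with only a couple of degrees of cumulative
motion, contribution peaks are dominated by tracking noise.

## Peak significance and classification

Peaks are local maxima of the contribution-per-frame curve, scored by
topographic prominence (height above the highest saddle towards taller
terrain). Prominence rather than raw height is used everywhere, for two
reasons: a shoulder on a monotone rise should not count as a contribution
peak, and late in extension *every* segment's baseline contribution is
elevated, so raw heights there overstate how much a late ripple stands
out. A peak is significant when its prominence reaches
`significance_threshold`, 0.3° per frame by default — contributions below
that are treated as noise-level.

Classification restricts attention to the terminal phase — the final
`terminal_phase_fraction` (default 0.5) of cumulative rotation, i.e. the
second half of extension, which is also the window covered by
neutral-start protocols. Per segment the most prominent in-phase peak is
selected (selection is deliberately threshold-independent; significance is
then required of the selected peak, which makes the outcome monotone in
the threshold: raising it can only turn `+` into `-`). The normal sequence
is present (`+`) iff all three selected peaks are significant, strictly
ordered C4-C5 < C5-C6 < C6-C7 in cumulative rotation, no two within
`tie_tolerance` (0.5°) of each other, and no later C4-C5 peak has
prominence ≥ `trailing_c45_max_ratio` (0.5) of the selected one. A small
late C4-C5 peak is explicitly normal; the 50% ratio operationalises "much
smaller", which no published number pins down, and is echoed in every
output so analyses are comparable. Ties are classified `-` with reason
`tie` rather than guessing an order: the pattern is an ordering claim and
is undefined under coincidence. Every negative call carries
machine-readable reasons (`no-significant-peak:<segment>`,
`order-violation`, `tie`, `trailing-c45-too-large`,
`insufficient-motion`).

## The synthetic generator

The generator emulates the acquisition protocol of a seated, actively
performed movement recorded at 10 frames per second with 1024×1024 frames;
the default recording length of 52 frames covers the extension half of a
~10 s flexion-extension cycle. How the 10 s split between flexion and
extension is not standardised, so the frame count is a parameter rather
than a constant.

Each segment's contribution along cumulative rotation is modelled as a
broad baseline plus a Gaussian bump at that segment's peak centre
(Gaussian purely for smoothness and controllable width — published curves
are smooth and unimodal per contribution episode but name no functional
form). The three raw profiles are balanced by Sinkhorn iteration into
per-frame fractions that sum to one at every frame step while each
segment's integral equals its prescribed total. By construction the block
then advances uniformly over frames, additivity is exact, and each
segment's recorded range equals its total. Noiseless peak locations land
within one frame-grid step of the requested centres provided the bumps are
separated by roughly three widths; strongly overlapping bumps shift
because of the pointwise normalisation, and centres closer than the grid
resolution are rejected outright. Noise is i.i.d. Gaussian on the
per-frame segmental increments — the simplest model that reproduces
frame-to-frame jitter, including occasional negative motion at realistic
magnitudes.

Two presets define the study conditions. `young_consistent_spec()` uses
segment totals (14, 11, 10)° — tROM 35° — with peak centres at 55/70/85%
of the movement, widths 1.8°, and a trailing C4-C5 bump at 30% of the main
one. The scale sits roughly one reported aging slope (≈ 0.11° per segment
per year over ~35 years) above the elderly cohort averages.
`elderly_inconsistent_spec()` uses the elderly T2 column averages
(9.3, 7.1, 5.9)°, a randomly drawn non-identity permutation of the peak
order, and 0.15° frame noise. With these settings the elderly preset never
shows the normal sequence (reduced totals push some peaks below the
significance floor and the order is wrong), which is the designed
behaviour, not a fit to any measured rate.

What the phantoms do *not* model: soft tissue, exposure variation,
geometric distortion, out-of-plane motion, vertebral shape variation.
Passing the ground-truth-recovery tests therefore shows the estimator is
correct and noise-stable, not that it matches any particular clinical
image quality.

## Tracking

Each vertebra is a rigid body; its pose per frame is an in-plane rotation
about the annotated contour centroid plus a translation. The similarity
score is normalized cross-correlation of the pixels under the (dilated)
contour against the reference frame — contrast-invariant, the standard
choice for fluoroscopy template matching. The search is a coarse grid
(±2° in 0.5° steps, ±8 px in 4 px steps around the previous frame's pose —
inter-frame motion at 10 fps is small for an instructed fluent movement)
followed by Nelder–Mead refinement. All frames are pre-smoothed with a
1.5 px Gaussian before matching; without it, pixel noise roughens the NCC
landscape enough that the refinement stalls near coarse-grid points.
Contours are dilated 3 px outward when sampling so the body edges — which
carry the rotation signal — are included. Frames whose best score falls
below 0.4, or that cannot be scored at all (featureless template), are
marked *lost* and reported; they are never silently interpolated. Manual
pose corrections are supported and logged, mirroring the check-and-adjust
step of the clinical workflow.

On default phantoms the tracker's mean absolute angular error is about
0.1° (bounded at 0.2° in the tests) with sub-0.1 px translation error —
comfortably below the 0.3° significance floor, so tracking error cannot by
itself create or destroy significant peaks. The original clinical
contour-following software is not re-implemented here; only ground-truth
recovery on phantoms is claimed.

## Alignment, eligibility, statistics

Cobb angles are signed angles between endplate lines, wrapped to
(−90°, 90°], lordosis positive (kyphotic segments negative). The C2–C7
lordosis uses the inferior endplates of C2 and C7 — the standard
convention, since "from C2 to C7" underdetermines the endplates. The
angle is invariant under rigid transforms and uniform scaling of the
landmarks and antisymmetric under swapping the lines (up to the
unavoidable ±90° wrap for perpendicular lines). Eligibility implements
the cohort screen: age 55–70, Neck Disability Index ≤ 4 points, no
analysed segment with Kellgren grade 4.

Inter-observer reliability uses ICC(A,k) — two-way, absolute agreement,
average measures — computed from the ANOVA mean squares
`(MSR − MSE) / (MSR + (MSC − MSE)/n)`. Spearman correlations use average
ranks for ties and a permutation p-value: full enumeration of all `n!`
permutations for `n ≤ 8` (the cohort sizes here), Monte-Carlo with at
least 99 999 seeded draws up to `n = 30`. Exactness is preferred over the
t-approximation because at `n = 10` the approximation is visibly off and
reproducibility matters more than speed. Which variable pairings (T1, T2,
pooled; tROM vs per-segment grades) underlie any particular published
p-value is ambiguous, so pairings are an explicit argument and no bare
p-value is treated as a regression target. Test-retest variability is
summarised per individual as the SD of the two sessions
(`|T1 − T2|/√2`) and the coefficient of variation `SD/mean`.

Printed-table style summaries round half-away-from-zero at the printed
precision (the tables' one-decimal style), but rounding is applied only to
the printed strings — stored values keep full precision. One transcribed
cell is knowingly inconsistent: the elderly table's T1 C6-C7 average
prints 5.8 while its own column averages 6.84; the package reports the
column-derived value and the discrepancy is documented rather than
patched. Bracketed ranges are reproduced as column min/max but not
asserted against the printed brackets, several of which conflict with
their own columns.

## Numerical choices and problem sizes

Grid cells of 0.1° in cumulative rotation; simplex tolerances of
`reltol = 1e-9`; Sinkhorn balancing to column sums within 1e-13;
floating-point micro-maxima (prominence < 1e-9) are discarded before peak
analysis. The test-suite phantoms are 160–220 px with 10–26 frames and the
classifier separation runs use 200 recordings per condition — sizes chosen
so the whole validation remains quick on a laptop while every rate of
interest is still measured on a meaningful sample.

## Limitations

The pipeline analyses sagittal rotation of C4–C7 during extension only.
Flexion-phase sequences, upper cervical segments (C0–C3), translations,
coupled motions and the instantaneous centre of rotation are out of scope.
The phantom renderer is a geometric stand-in, not a fluoroscopy simulator,
and equivalence with any particular clinical tracking software cannot be
claimed — only ground-truth recovery under the stated noise model. The
trailing-peak ratio (0.5) and the tie tolerance (0.5°) are package
conventions where the clinical definition is qualitative; both are
configurable and echoed in all outputs.
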