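# cervseq

Quality-of-motion analysis for the lower cervical spine (C4–C7) from
dynamic flexion–extension fluoroscopy.

Quantity of cervical motion — segmental range of motion (sROM) and total
C4–C7 range (tROM) — is notoriously variable between sessions and between
raters, which makes it a poor definition of "physiological" motion. A more
stable descriptor is the *sequence of segmental contributions* (SSC): when
each motion segment's per-frame rotation is plotted against the cumulative
rotation of the C4–C7 block, young asymptomatic individuals show a
characteristic cranial-to-caudal peak order in the terminal phase of
extension — C4-C5 contributes maximally first, then C5-C6, then C6-C7. This
package implements the full analysis pipeline needed to measure that
pattern, together with the cohort statistics used to study its presence in
an elderly population:

- **Synthetic ground truth** — a generator of per-frame segmental
  kinematics with controllable peak structure (and a phantom renderer that
  turns them into lateral-view image stacks), so every downstream stage can
  be validated without clinical recordings.
- **Vertebra tracking** — rigid 2D template tracking (rotation +
  translation per frame) of annotated vertebral contours by normalized
  cross-correlation, with coarse-grid search plus simplex refinement, lost
  frame reporting and manual pose correction.
- **Kinematics** — segmental angle series
  `theta(upper) − theta(lower)`, cumulative block rotation (which equals
  the sum of the three segmental angles identically), SSC curves on a
  uniform cumulative-rotation grid with conservation of every segment's net
  rotation, and endpoint/extremal ROM summaries.
- **Sequence classification** — prominence-based peak detection with the
  0.3°-per-frame significance floor, terminal-phase restriction, tie
  handling, the trailing-C4-C5 allowance, and machine-readable reason codes
  for every negative call.
- **Alignment and eligibility** — signed Cobb angles (lordosis positive)
  from endplate landmarks; the age 55–70 / NDI ≤ 4 / Kellgren ≤ 3
  inclusion screen.
- **Cohort statistics** — two-way absolute-agreement average-measures ICC
  from the ANOVA mean squares, Spearman correlation with exact permutation
  p-values (full enumeration for n ≤ 8), test-retest coefficients of
  variation, and printed-table style summaries. Transcriptions of the
  elderly-cohort tables ship as plain-text fixtures.

Everything is tidyverse-native: data-frame in, tibble out, `autoplot()`
methods for curves and recordings, `tidy()`/`glance()` for classifications.

## Worked example

```r
library(cervseq)

rec   <- generate_profile(young_consistent_spec(seed = 42))
curve <- build_ssc(rec)          # contribution vs cumulative C4-C7 rotation
classify_sequence(curve)
#> <sequence_classification> +
#>   selected peaks:
#>     C4-C5 at 18.85 deg (height 0.62 deg/frame)
#>     C5-C6 at 24.35 deg (height 0.62 deg/frame)
#>     C6-C7 at 29.85 deg (height 0.59 deg/frame)
```

The `+` says the normal extension sequence is present: the three selected
peaks are all significant (≥ 0.3° per frame prominence), they fall in the
terminal half of extension, and their positions along cumulative rotation
are strictly ordered C4-C5 → C5-C6 → C6-C7.

```r
rom_summary(rec)
#> # A tibble: 4 × 4
#>   measure      rom_deg method   timepoint
#> 1 C4-C5          14.0  extremal <NA>
#> 2 C5-C6          11.0  extremal <NA>
#> 3 C6-C7          10.00 extremal <NA>
#> 4 tROM (C4-C7)   35    extremal <NA>
```

Cohort tables are summarised the way the clinical tables print them
(rounded mean with bracketed range):

```r
summarize_cohort_table(load_cohort_table("rom"))$columns[, c("column", "formatted")]
#>   column      formatted
#> 1 trom_t1     25.8 [13.1;55.8]
#> 2 srom_c45_t1 11.2 [4.9;23.9]
#> 3 srom_c56_t1 7.9 [0.2;20.9]
#> ...
```

A rendered phantom closes the loop from pixels back to angles:

```r
stack <- render_frames(rec, phantom_spec(size = 220))
poses <- track_sequence(stack, templates_from_stack(stack))
classify_sequence(build_ssc(segmental_angles(poses)))
```

A thin command-line wrapper covers the same pipeline
(`simulate`, `render`, `track`, `analyze`, `classify`, `report`); see
`?cervseq_cli` and `inst/scripts/cervseq`.

## Scope notes

Only sagittal-plane rotation of C4–C7 during extension is analysed; upper
cervical segments, translations, coupled motions and the instantaneous
centre of rotation are out of scope. Kellgren grades and NDI scores are
consumed as inputs, never derived from images. See the methods vignette
(`vignettes/motion-quality.Rmd`) for the model, parameter and design
discussion.
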