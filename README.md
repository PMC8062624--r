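# octchoroid

Choroid boundary segmentation and scleral en-face analysis for wide-field
swept-source OCT volumes.

The choroid is perfused by the posterior ciliary arteries; their short
branches (SPCAs) cross the sclera and enter the choroid around the
posterior pole. With 12 × 12 mm swept-source OCT these entry sites are
visible as hyporeflective dots in en-face slices of the sclera — but only
after the choroid–sclera interface has been segmented and flattened. This
package implements that pipeline end to end, for clinicians and image
analysts studying SPCA topography and for anyone needing a reproducible
choroid segmentation of large OCT volumes:

* **Segmentation.** Both choroid boundaries are detected per B-scan from a
  single two-step enhancement of the raw intensities,
  `I_raw = (I/255)^4`, `I_expenh = (I_raw / (2 Σ_{k=x..p} I_raw(k,y)))^n`
  with `n = 10`, and the depth weighting `I_nonlin = x² I_expenh` — the
  tail-relative ratio boosts the last strong reflector in each A-scan and
  compensates depth attenuation. The CIB (choroid inner boundary) uses the
  chain on the vertically flipped B-scan, the COB (choroid–sclera
  interface) in the original orientation, each followed by mid-gray
  binarization, morphological cleaning, per-column extreme-point
  extraction, tensor-voting interpolation, and robust LOESS smoothing
  across B-scans.
* **Flattening and en-face extraction.** Integer (bit-exact, invertible)
  per-A-scan shifts put the COB on a plane; scleral slices and 5–30-slice
  substack projections are read below it.
* **Topography.** SPCA entry-site marks are assigned to the nine 4 × 4 mm
  sectors of the posterior pole (nasal/temporal resolved by laterality),
  with the fewer-than-10-arteries exclusion rule and cohort summaries.
* **Validation statistics.** Dice coefficient
  `DC = 2|C_x ∩ C_y| / (|C_x| + |C_y|)` between segmentations per A-scan;
  Pearson agreement between observers on radial mark positions
  `Z = √(X² + Y²)` with the very-weak…very-strong qualification bins.
* **Synthetic phantoms.** Layered volumes with exact ground-truth
  surfaces, speckle, attenuation, choroidal vessel lumens and oblique
  scleral SPCA tracks, so the whole pipeline is testable without clinical
  data.

## Worked example

```r
library(octchoroid)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 256 x 256 x 64 phantom
seg <- segment_volume(ph$volume)
glance(seg)
#> # A tibble: 1 × 5
#>   n_ascans mean_thickness_px sd_thickness_px n_clamped n_empty_bscans
#>      <int>             <dbl>           <dbl>     <int>          <int>
#> 1    16384              48.7           0.552         0              0

dice_report(seg, list(cib = ph$truth$cib_true, cob = ph$truth$cob_true),
            boundary = "band")
#> <dice_report> band: mean DC 0.9812 (SD 0.0015) over 64 B-scans
```

The phantom's true choroid band is 50 px thick; the segmentation recovers
a 48.7 px band with a Dice overlap of 0.981 against ground truth and a
CIB mean absolute error of 0.29 px at speckle variance 0.15.

```r
marks <- ph$truth$spca_marks_true          # 14 planted SPCA entry sites
tidy(compute_distribution(marks, laterality = "OD"))
#> # A tibble: 9 × 5
#>   cell_row cell_col sector            count percentage
#>      <int>    <int> <chr>             <int>      <dbl>
#> 1        0        0 superior-temporal     2      14.3
#> 2        0        1 superior              2      14.3
#> 3        0        2 superior-nasal        0       0
#> 4        1        0 temporal              2      14.3
#> 5        1        1 central               4      28.6
#> 6        1        2 nasal                 0       0
#> 7        2        0 inferior-temporal     1       7.14
#> 8        2        1 inferior              0       0
#> 9        2        2 inferior-nasal        3      21.4
```

Counts are marks per 4 × 4 mm sector; percentages are of all marks in the
eye. Simulated repeat readings (0.2 mm jitter, 5% dropout) give

```r
obs <- dplyr::bind_rows(
  perturb_marks(marks, 0.2, 0.05, seed = 11, observer_id = "o1", trial_id = 1L),
  perturb_marks(marks, 0.2, 0.05, seed = 12, observer_id = "o1", trial_id = 2L))
agreement_analysis(obs, mode = "auto", max_dist_mm = 2)
#> <agreement_report> auto: median r = 0.9975 (very strong correlation) over 1 eye(s)
```

i.e. the intra-observer correlation of radial mark positions is 0.9975,
"very strong" on the qualification bins.

A thin CLI wraps the same functions
(`exec/octchoroid simulate|segment|enface|sectors|validate|agree`).

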