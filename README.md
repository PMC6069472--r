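# painface

Automatic assessment of procedural pain in infants from facial video.

Infants in neonatal intensive care cannot report pain; bedside scales such
as the Neonatal Infant Pain Scale (NIPS) depend on trained observers and
are impractical for continuous monitoring. The facial actions that signal
neonatal pain — brow bulge, eye squeeze, vertical mouth stretch,
nasolabial furrowing, lateral head shaking — are measurable geometric and
textural events. `painface` implements a dynamic facial-representation
pipeline that turns per-frame 68-point facial landmarks and grayscale
frames into a subject-independent pain / no-pain decision, and a synthetic
cohort generator so the whole pipeline is testable without clinical data.

## The method

Per video (one epoch of one subject), four feature streams are computed:

| Stream | Content | Length |
|---|---|---|
| `dface` (DG_DisFace) | 11 facial deformation distances per frame (eyebrow–eye *d_eb*, eyelid *d_el*, eyebrow–mouth *d_mb*, eye–mouth *d_em*, nose–mouth *d_nm*, mouth width/height *d_mw*, *d_mh*), each summarised over time | 11 × 48 = 528 |
| `dpose` (DG_DisPose) | 8 boundary-to-component head-pose distances per frame | 8 × 48 = 384 |
| `gradient` (DA_Gradient) | mean Sobel gradient magnitude of 31 landmark-riding 32 × 32 patches per frame | 31 × 48 = 1488 |
| `lbptop` (DA_LBP-TOP) | LBP-TOP uniform-pattern histograms (59 bins × 3 orthogonal planes = 177) of the 31 patch volumes | 31 × 177 = 5487 |

Frame-level signals x are Butterworth-smoothed (first order, 1 Hz cutoff,
zero phase) to s and differentiated twice to v and a; each of s, v, a
yields 16 descriptors (state, variability, peak time, durations, segment
counts, area), i.e. 48 values per signal. Each stream is embedded by
Supervised Locality Preserving Projections (within-class kNN heat-kernel
graph; generalized eigenproblem `X L Xᵀ a = λ X D Xᵀ a`), classified by an
RBF-kernel SVM, and the streams are fused by majority voting with a
confidence tie-break. Evaluation is leave-one-subject-out with pooled
accuracy and trapezoidal (Mann–Whitney) AUC. Ground truth follows NIPS:
totals 0–7, pain iff ≥ 3, severity none/moderate/severe at 0–2 / 3–4 / >4,
and the seven-epoch T0–T6 segmentation of a procedure video.

See `vignette("painface-methods")` for assumptions, parameter defaults and
numerical conventions.

## Worked example

```r
library(painface)

spec <- cohort_spec(n_subjects = 6, epochs_per_subject = 4,
                    frames_per_epoch = 40, seed = 42)
cohort <- simulate_cohort(spec)
instances <- cohort_instances(cohort, streams = c("dface", "dpose"))
result <- loso_evaluate(instances, streams = c("dface", "dpose"))
print(result)
#> <LOSO evaluation: 24 instances, 6 subjects, streams dface+dpose>
#>   overall accuracy: 1.0000
#>   AUC: 1.0000
head(result$predictions, 4)
#>   subject_id epoch_id   label predicted  confidence vote_dface vote_dpose
#> 1        S01       T0 no_pain   no_pain -0.06927832    no_pain    no_pain
#> 2        S01       T1    pain      pain  0.05341248       pain       pain
#> 3        S01       T2    pain      pain  0.05717808       pain       pain
#> 4        S01       T6 no_pain   no_pain -0.06349238    no_pain    no_pain
```

Each row is one held-out epoch: the true NIPS-derived label, the fused
prediction, the signed fused confidence (positive leans pain) and the
per-stream votes. With the generator's default effect sizes the cohort is
cleanly separable, so a subject-independent evaluation recovers every
epoch; lowering the effect magnitudes in `cohort_spec()` degrades accuracy
toward chance, which is the behaviour the test suite verifies.

Appearance streams need rendered frames; `cohort_instances()` renders them
on the fly when `"gradient"` or `"lbptop"` is requested. A thin CLI over
the same functions lives at `inst/cli/painface.R`
(`simulate` / `extract` / `loso`, with `--side left|right|whole` for
hemiface models and `--subgroup preterm|male|...` for subgroup models).

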