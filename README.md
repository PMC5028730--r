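# emogait

Emotion recognition from marker-free skeletal gait recordings.

A person's walk changes with their affective state — cadence, arm swing and
stride amplitude all shift with mood. A Kinect-v2 depth camera reports the
3D positions of 25 skeletal joints at 30 Hz while a person walks back and
forth along a 6 m footpath, and `emogait` turns such recordings into a
cross-validated answer to questions like *"can induced anger be told apart
from this person's neutral walk?"*

For movement scientists and affective-computing researchers, the package
provides the complete pipeline plus a synthetic gait generator that makes
every stage verifiable without real recordings.

## Method

Given a recording `R ∈ ℝ^{T×75}` (T frames, 25 joints × x,y,z in camera
coordinates), the pipeline computes:

1. **Joint selection** — 14 trunk/limb joints, giving a `T×42` motion
   matrix.
2. **Body-centered transform** — each frame re-expressed relative to its own
   SpineBase position (translation invariant; the camera-frame SpineBase
   depth track is kept as the walker's footpath position).
3. **Smoothing** — each channel convolved with the 5-tap Gaussian kernel
   `c = [1, 4, 6, 4, 1]/16` (mirror-padded edges).
4. **Differencing** — per-frame displacement, `T−1` rows.
5. **Segmentation** — turning frames dropped via the smoothed SpineBase
   depth change (dead band + trim), straight runs of ≥ 40 frames kept and
   tagged `front` (approaching camera) or `back`.
6. **Fourier features** — per segment and channel, the main frequency
   `f* = k*·f_s/N` with `k* = argmax_{1≤k≤⌊N/2⌋} |X_k|` and its phase
   `arg X_{k*}`; averaged within orientation and concatenated into the
   168-value record descriptor
   `[front freqs | front phases | back freqs | back phases]`.
7. **Z-score + PCA** (components up to 95% cumulative variance), then
   **stratified, subject-grouped 10-fold cross-validation** of four
   classifiers: Gaussian naive Bayes, random forest (100 trees), RBF-SVM
   and linear SVM. Accuracy is the pooled proportion correct.

The synthetic generator emulates the study geometry: a walker translating
along the depth axis of a 6 m footpath, turning at the ends (with inflated
sensor noise), limbs oscillating at the stride frequency with contralateral
phase opposition, and class-dependent cadence/amplitude shifts standing in
for emotion effects.

## Worked example

```r
library(emogait)
set.seed(1)

# a 10-subject cohort: neutral walks vs "angry" walks with +0.15 Hz cadence
# and 1.3x arm swing
effects <- list(emotion_effect("neutral"),
                emotion_effect("angry", delta_freq = 0.15,
                               amp_scale_arms = 1.3))
records <- simulate_cohort(10, gait_params(), effects, seed = 42)

tab <- build_feature_table(records)
print(tab)
#> <feature_table> 20 instances x 168 features
#>   labels: angry=10, neutral=10

task <- make_binary_task(tab, "angry", "neutral")
report <- cross_validate(task, "naive_bayes", k = 10, seed = 42)
print(report)
#> <cv_report> angry vs neutral | naive_bayes | 10-fold CV (seed 42)
#>   pooled accuracy: 0.8000 (n = 20)
#>          predicted
#> truth     angry neutral
#>   angry       9       1
#>   neutral     3       7
```

Each of the 20 records passed the full preprocessing chain and yielded its
168 Fourier features; naive Bayes then recovered the induced cadence shift
in 16 of the 20 held-out predictions (80% pooled accuracy). Larger cohorts
give tighter estimates: at 59 subjects the same effect is detected with
~0.9 accuracy by every classifier family.

Batch processing of a directory of skeleton CSVs, including report and
manifest output, is available via `run_pipeline()` or the thin command-line
wrapper `inst/scripts/gaitpipe.R` (subcommands `simulate`, `features`,
`evaluate`, `run`).

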