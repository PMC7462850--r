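---
title: "Methods: whole-slide prostate cancer screening in wsiscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-slide prostate cancer screening in wsiscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its models and of the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The screening model

A whole slide is classified in three stages.

**Semantic segmentation on sparse annotations.** Training data are square
patches extracted *strictly inside* pathologist-drawn polygons of five
classes: cancer (adenocarcinoma), benign glands, other tissue types,
high-grade PIN and other. Because annotations are non-exhaustive,
unannotated tissue carries no label and is never sampled, and each patch's
target map is the single class of its enclosing polygon, one-hot at every
pixel. This is a deliberately biased but clean supervision signal; the
multi-class design exists so that benign mimickers of cancer (high-grade
PIN above all) compete with the cancer class at the softmax instead of
being folded into a catch-all negative. In the final evaluation all
non-cancer classes are grouped.

The reference architecture is a U-Net deepened to five encoder levels
(filters doubling up to 1024) with spatial dropout 0.25 after each encoder
block; a fully convolutional DenseNet (five dense blocks, growth 16, four
layers per block, Tiramisu-style transitions) and a small patch classifier
are the comparison families. Optimization is SGD (momentum 0.9 — the
conventional default, as the momentum is not otherwise constrained) with
categorical cross-entropy, batch size 3 and learning rate 5e-4. Validation
loss governs early stopping; patch-level cancer Dice (segmentation) or
accuracy (classifier) is logged as the monitor and can be switched to via
`train_config(monitor = )`. Maximum epochs (100) and patience (10) are
exposed configuration with these defaults.

**Whole-slide inference.** The slide is rendered at the analysis
magnification (5x, equal to the training magnification; magnification `m`
means `10/m` microns per pixel under the 40x = 0.25 um/px convention),
tiled on a non-overlapping grid, and every tile containing at least 5%
tissue is classified; the 5% rule is our choice, as no threshold is
otherwise fixed. Non-tissue tiles receive a fixed background distribution
(all mass on "other"), so the map is a proper per-pixel distribution
everywhere. Edge tiles are reflectively padded and cropped back. An
overlap-and-average mode exists for seam suppression but the plain grid is
the default.

**Slide scoring.** From the likelihood map we take the tumor probability
map `TPM` (cancer channel) and the tumor area `TA` (pixels where cancer
strictly exceeds every other class; exact ties are excluded by the strict
inequality). The slide score is

$$T07 = \frac{\sum (TPM \ge 0.7)}{\sum TA},$$

the 0.7 bin of a 10-bin cumulative histogram of TPM over TA. The full
feature vector (cumulative histogram, TA size, mean/sd/variance of TPM) is
implemented, and greedy MRMR ranking with the mutual-information-difference
objective is available to select among them; T07 is the selected feature
and the score the pipeline thresholds. Design points fixed here:

* **Empty TA convention.** The T07 quotient is undefined when TA is empty;
  we define T07 = 0 (no tumor-argmax pixel means no evidence of cancer),
  which is the right screening semantics.
* **Statistics domain.** Whether first-order statistics are taken over TA
  or over all tissue is ambiguous; TA is the default because it matches
  the T07 normalization, and `stats_domain = "tissue"` switches.
* **MRMR estimation.** Features are discretized into 3 equal-frequency
  bins and mutual information is the plug-in estimate — robust at the
  small slide counts this stage sees. The greedy ranking is exactly
  testable against exhaustive recomputation at these sizes.
* **Threshold rule.** A slide is called cancer when `score >= threshold`
  (inclusive), and `tune_threshold()` optimizes accuracy (best-accuracy
  point) or the minimum threshold with sensitivity 1 (screening point) on
  a tuning set.

**Evaluation.** ROC curves are built over all unique score thresholds and
integrated trapezoidally, which makes the AUC exactly the Mann-Whitney
pair statistic, ties included. Confidence intervals are percentile
bootstrap over prediction indices (2000 resamples by default; resamples
with one class only are redrawn; BCa was considered and rejected as beyond
what the resampling design specifies). Operating points are P1
(specificity 1), P2 (sensitivity 1) and P3 (best plain accuracy at
observed prevalence); accuracy ties at P3 resolve toward the lower
threshold, i.e. higher sensitivity. Dice and Jaccard use the convention
that two empty masks score 1, needed for all-negative validation patches.

## Style normalization

Scanner and stain differences are modeled as a domain translation problem:
a cycle-consistent GAN is trained, unpaired, between a handful of slides
from each domain (five per domain at full scale), with least-squares
adversarial losses (weight 1.0) and cycle-consistency L1 (weight 10.0);
patches are sampled from tissue only, with rotation/mirror augmentation;
the learning rate starts at 5e-4 and halves every 20 epochs over 150
epochs of 50 iterations with batch size 4. Only the foreign-to-development
generator is used downstream, applied to whole slides by sliding window
with 32 px overlap and linear ramp blending; identity loss is omitted (only
the two stated loss weights are modeled).

Four implementation choices deviate from common defaults and deserve
their rationale:

* **Residual generators.** The generator predicts a residual added to its
  input (`G(x) = x + delta(x)`), so it is near-identity at initialization.
  Scanner styles are mostly smooth color remappings; the residual form
  reaches a usable translation within a CPU-scale iteration budget where a
  from-scratch generator does not, and it is standard practice in stain
  transfer.
* **No instance normalization in the generator (default).** Instance
  normalization erases a patch's absolute color — precisely the signal a
  style translator must read. With it enabled we measured translations
  that mapped tumor regions to stroma colors, destroying downstream
  detection; `cyclegan_config(gen_instnorm = TRUE)` restores it for
  experimentation.
* **Adam for the GAN only.** The adversarial game does not converge under
  plain SGD at desk scale; Adam with beta1 = 0.5, the optimizer of the
  original cycle-consistent translation recipe, is used for generators and
  discriminators. The segmentation networks keep SGD.
* **A color-remapping generator for the desk-scale study.** The reference
  U-Net generator (`gen_kind = "unet"`) is implemented and remains the
  default, but in the packaged study the unpaired translation it learned
  merged the degraded tumor color cluster into the neighboring tissue
  cluster, so normalized slides lost exactly the class being screened for.
  `gen_kind = "color"` — 1x1 convolutions for the global color transform
  plus one 3x3 stage for local deblurring — matches the structure of
  scanner-style degradations and restores the tumor cluster correctly;
  the study uses it.

The **domain gap** quantifies style distance as the mean over RGB channels
of the Wasserstein-1 distance between intensity histograms (256 bins); a
uniform +s shift in one channel contributes exactly s/3. In the
normalization study the gap is measured as a *paired re-scan comparison*:
the same held-out slides rendered in both styles, patches cut at identical
tissue coordinates. Unpaired measurement confounds style with tissue
composition (different slides contain different class mixtures), which we
found dominates the statistic at desk scale.

## The synthetic cohort generator

No clinical WSIs ship with the package, so the generator is itself a
tested module that emulates the statistical structure the pipeline relies
on:

* slides are 2-level pyramids, default 4096 x 4096 px at 0.97 um/px, with
  near-white background and 2-4 elliptical tissue pieces of pale stroma;
* five region classes are placed as non-overlapping star-shaped polygons
  with per-class procedural textures (base H&E-like color plus a blob
  field of nucleus-colored spots; density and blob size differ by class).
  Classes are separable mainly by color — by design, so that a small CNN
  without pretraining can learn them;
* annotations are sparse: per class, regions are annotated until 30-60% of
  the class's area is covered, always at least one region per present
  class; cancer slides carry at least one cancer region, normal slides
  none;
* cohort labels are Bernoulli draws at 25% prevalence (the cohort
  structure the screening setting assumes); per-slide seeds derive from
  one master seed by splitmix-style hashing, so any slide can be
  regenerated independently and bit-identically;
* scanner styles are parametric (hue rotation, saturation/brightness/
  contrast scales, blur or unsharp, additive noise), applied color first,
  then blur/sharpen, then noise. The built-in `scanner_b` is deliberately
  strong — washed-out, desaturated, brighter, lower contrast — because
  inter-center differences are not quantified anywhere we can copy from;
  the parameters were chosen (once) so that a model trained on the
  development style measurably degrades on it, which is the phenomenon the
  normalization study needs to exhibit. This is a testability choice, not
  a fidelity claim.

What the generator does *not* emulate: nucleus-level morphology, gland
architecture, compression artifacts, annotation noise, or inter-observer
variability. Passing the end-to-end tests therefore shows that the
pipeline's machinery is correct and that its stages compose; it does not
show clinical performance on real H&E slides.

## Desk-scale study conditions

The packaged experiments (`run_screening_study()`,
`run_normalization_study()`, also run by `scripts/acceptance.R` and the
acceptance tests) use these problem sizes, chosen once as the largest the
pipeline runs comfortably on a single CPU:

* 60 slides of 1024 x 1024 px (the generator's minimum slide size), 25%
  prevalence, development style; 40 train / 20 held out, with a
  deterministic swap if the held-out set happens to be single-class;
* patches of 32 px at 5x, grid stride 16, at most 40 patches per slide;
  15% of patches form the validation split; class-balanced oversampling by
  the capped-ceiling rule, with one augmentation draw (brightness/contrast/
  saturation +/-20%, right-angle rotations, mild noise and blur) per
  training copy — the augmentation envelope is what lets the model tolerate
  the small residual color error a normalizing generator leaves behind;
* a reduced U-Net (depth 3, 12 base filters, dropout 0.1) trained with
  batch 8, learning rate 0.01, up to 12 epochs of 40 steps, patience 3 —
  the desk-scale stand-in for the full configuration, whose exact
  hyperparameters are GPU-scale;
* the foreign-scanner experiment re-renders the 20 held-out slides in
  `scanner_b` (the re-scanning situation: same tissue, different scanner),
  trains the desk-scale cycle-GAN (16 px patches, 50 epochs x 50
  iterations, residual color-remapping generators with 16 filters) on 5
  slides per domain, and rescores after sliding-window normalization;
* bootstrap calibration uses a binormal score model with true AUC 0.8
  (equal-variance normals separated by sqrt(2) * qnorm(0.8)), 100 + 100
  slides per replication, 500 replications, 2000 resamples each.

## Numerical and degenerate-input choices

* Coordinates are 0-based, top-left origin, half-open regions `[x, x+w)`,
  everywhere.
* Patch-footprint containment is checked at the four corners plus centre
  by the boundary-inclusive even-odd rule; `strict = TRUE` rasterizes the
  footprint. The corner test is exact for convex polygons and
  conservative in practice for the star-shaped regions used here.
* Tissue masks: Otsu on HSV saturation OR grey intensity below 0.9 x
  white, computed at width <= 1024, components under 64 px removed, holes
  filled. An all-white slide gives an empty mask; an all-dark slide a full
  one.
* The autodiff core routes max-pool gradients to the first maximal entry
  (fixed tie order) and is verified against central finite differences in
  the test suite, which is the correctness anchor for everything trained.
* Pyramid TIFFs store 8-bit samples; metadata (mpp, level geometry) lives
  in a JSON sidecar because baseline TIFF tags cannot carry it portably.
  A write/read round trip quantizes intensities by at most one grey level.
* Training aborts with a diagnostic on a non-finite loss rather than
  continuing silently.

## Known limitations

* The base-R network stack is minutes-per-study, not seconds; it exists
  for testability and faithfulness of the algorithms, not throughput.
* The synthetic textures make color the dominant class cue; real H&E
  separability rests on morphology that these cohorts do not model.
* Sliding-window GAN normalization cannot restore information destroyed by
  blur or clipping; the domain gap shrinks but does not vanish.
* Vendor-proprietary slide formats are out of scope; the package reads
  and writes plain pyramidal TIFF.
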