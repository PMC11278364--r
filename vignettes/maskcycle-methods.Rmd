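---
title: "Annotation-preserving image translation for wheat head segmentation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-preserving image translation for wheat head segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Semantic segmentation of wheat heads (the grain-bearing spikes at the top of
wheat stems) needs per-pixel labels, and per-pixel annotation of field
imagery is expensive. `maskcycle` implements a pipeline that manufactures a
large annotated training set from a *single* manually labelled frame:

1. **Cut-and-paste synthesis.** Foreground cutouts are extracted from the
   labelled frame as 8-connected components of its mask and composited at
   random positions, scales, rotations and flips onto background-only
   frames. Because the composite is constructed, its mask is exact and
   free. The resulting dataset is called ΔS.
2. **Mask-preserving translation.** Composites look nothing like real field
   images, so a segmenter trained on ΔS degrades badly on real data (the
   *domain gap*). A modified CycleGAN translates ΔS towards the appearance
   of unlabelled real frames (ΔR) while preserving the annotation, giving
   ΔGAN.
3. **Segmentation.** A U-Net is trained on ΔS (model A, the baseline) and
   on ΔGAN (model B) with binary cross-entropy.
4. **Pseudo-labelling.** Model B predicts masks for an unlabelled pool; the
   most confident predictions (ΔPL) are selected and used, together with
   ΔGAN, to fine-tune B into the final model C.
5. **Evaluation.** Dice and IoU per image, macro-averaged per dataset, with
   comparison tables of percentage-point deltas (B vs A) and IoU ratios
   (C vs A).

# The mask-preserving cycle

A standard CycleGAN learns two generators between unpaired domains,
constrained by adversarial losses and cycle-consistency losses. Used
naively for ΔS to ΔR translation it rearranges content: wheat heads appear
or vanish, and the original mask no longer matches the translated image.

The modification is structural. The source domain S carries **4-channel**
samples: three image channels normalised to [-1, 1] plus the mask mapped
{0 → -1, 1 → +1}. The generator `G_SR` maps 4 channels to 3 (a realistic
image, no mask); `G_RS` maps 3 channels back to 4 (image *and* mask). The
S-side cycle loss is the mean absolute difference over **all four**
channels at equal weight, so the mask must be recreated at the end of the
S → R → S cycle; the only way the generators can achieve that cheaply is to
leave the semantic layout where the mask says it is. The reverse cycle
R → S → R constrains the image channels alone. The source discriminator
`D_S` judges the full image+mask concatenation (the reverse generator's
output lives in the 4-channel space, so its adversary must too); `D_R`
judges 3-channel images.

Losses and update rule per step, for a source sample `x` and real sample
`y`:

* generator objective: `LS(D_R(G_SR(x)), 1) + LS(D_S(G_RS(y)), 1) +
  λ (L1_S(x, G_RS(G_SR(x))) + L1_R(y, G_SR(G_RS(y))))`, with least-squares
  adversarial terms `LS(d, t) = mean((d − t)²)` and λ = `lambdaCycle`;
* discriminators: `½ (LS(D(real), 1) + LS(D(fake), 0))`, with fakes drawn
  through a replay buffer of up to 50 past generations — a discriminator
  that only ever sees the newest fake oscillates.

Translated datasets **copy the original mask file byte-for-byte**
(`buildGanDataset`): the annotation of a translated sample is never the
output of a network.

## Architecture and optimiser choices

The reference CycleGAN recipe is followed where the pipeline's protocol is
silent: residual encoder–decoder generators (7×7 reflection-padded stem,
two stride-2 downsampling convolutions, `nResBlocks` residual blocks, two
upsample+conv stages, 7×7 tanh head) with instance normalisation, 4-layer
patch discriminators, N(0, 0.02) initialisation, Adam with betas
(0.5, 0.999), λ = 10, replay buffer 50, least-squares adversarial loss, no
identity-mapping term in the objective. The stated protocol values are 60
epochs and learning rate 2e-4. Upsampling is nearest-neighbour followed by
a 3×3 convolution rather than a transposed convolution — the standard
checkerboard-free variant. The training resolution is a config knob:
256 px crops at study scale, 64 px in the package's own demonstration
runs.

Two deliberate departures from the most common CycleGAN implementation
follow from measured failure modes, both documented here because they are
load-bearing:

* **No normalisation inside the discriminators.** Instance normalisation
  in a discriminator cancels per-channel means — it blinds the adversary
  to exactly the global colour statistics that separate a synthetic domain
  from a realistic one. Under that blindness the generator's colour
  mapping is unconstrained.
* **A reconstruction warm-start** (`warmupSteps`, default 100): before the
  adversarial epochs, each generator's image channels are fitted by L1 to
  reproduce its own input. Without it, roughly half of the random
  initialisations settled into a *stable* contrast-inverted mapping —
  foreground rendered darker than background while the real domain has it
  brighter — which satisfies the cycle loss perfectly, survives hundreds
  of further adversarial steps, and poisons every dataset translated
  afterwards (a segmenter trained on it learns inverted cues and scores
  near zero on real frames). The warm-start anchors the initial mapping to
  be positively correlated with its input, after which the adversarial
  phase adjusts appearance instead of choosing a sign. It is an
  initialisation phase, not a loss term: the adversarial objective itself
  contains no identity component.

Everything runs on a small CPU tensor engine written for this package
(im2col convolutions against BLAS, hand-derived backward passes, Adam and
SGD). The engine is validated in the test suite by numerical
differentiation and by a sliding-window convolution oracle. Bit-exact
reruns are promised for single-threaded, fixed-seed execution; with a
threaded BLAS, losses reproduce within floating-point tolerance.

# The segmenter

A standard U-Net stands in for the customised variant the original
protocol delegates to: `depth` encoder stages of two 3×3 conv+ReLU layers,
2×2 max pooling, channel doubling per stage, a bottleneck, bilinear-upsample
decoder stages with skip concatenation, and a 1×1 sigmoid head. Input
dimensions must be divisible by 2^depth; the model errors rather than pads,
so dataset geometry stays explicit. He initialisation.

Training follows the stated recipe: binary cross-entropy (probabilities
clipped at 1e-7), SGD with learning rate 0.01, weight decay 0.001,
momentum 0.95, and a step scheduler `lr(e) = 0.01 · 0.1^⌊e/5⌋` (0-based
epoch index): epochs 0–4 at 0.01, 5–9 at 0.001, and so on. 45 epochs per
phase at study scale. Two implementation choices make that recipe stable:
gradients are averaged over mini-batches (`batchSize`, default 4) — at
momentum 0.95 a per-image step is an effective 20× learning rate — and the
global gradient norm is clipped (`gradClip`, default 1.0; measured
per-image gradient norms have median ≈ 0.3 with spikes to ≈ 3.6, so the
cap truncates outliers, not typical steps). Without both, training can
fall into the constant-output BCE saddle (≈ 0.69 loss, probability ≈ 0.5
everywhere) and never recover. An `norm = "instance"` U-Net variant exists
but is not the default: instance normalisation makes the segmenter largely
invariant to global colour shifts, which blunts exactly the domain
sensitivity this pipeline studies.

After every epoch the model is scored on the validation split by mean
Dice, and the parameters of the best epoch are returned — `TrainHistory`
records the trace and enforces that invariant. Ties at the binarisation
threshold count as foreground, so `p ≥ t` is the single thresholding rule
everywhere. Augmentation is limited to an optional random horizontal flip,
off by default.

# Pseudo-label selection

The original selection of 99 of 360 candidate predictions was manual. The
automated proxy scores a candidate as
`½ (mean p over predicted foreground + mean (1 − p) over predicted
background)`, each term 0 when its region is empty — confident,
well-separated probability maps score near 1, and pushing foreground
confidence up can never lower the score. Selection modes: `top_k` (with
deterministic, locale-independent score-then-path ordering),
`score_threshold`, and `manual_review_list`; every run also writes an HTML
contact-sheet gallery of all candidates so a human can audit or override
the automated choice. The proxy is *not* claimed to reproduce the manual
selection; it is the hook a curator would start from.

# What the fixtures emulate — and what they do not

Real inputs (a wheat-field video, background videos, external benchmark
imagery) are not required anywhere: the `fixtures` module procedurally
generates the three empirical distributions the pipeline needs.

* **Backgrounds** are band-limited value noise in a green–brown field
  palette at wavelength `textureScale` (16 px default); an infinite
  wavelength degenerates to a constant frame, which the tests exploit.
* **Annotated frames** add 6–14 textured ellipses with semi-axes 6–18 px
  (at the 256 px default), random centres and orientations; blobs may
  overlap (masks are unions, as overlapping wheat heads would be) and are
  clipped at frame borders. The mask is exact by construction: membership
  of each pixel centre in the ellipse union, verified in the tests against
  a scalar per-pixel oracle.
* **Real-domain frames** are annotated-frame renderings under a global
  appearance shift — hue rotation, Gaussian blur, additive noise — with
  the mask withheld (ΔR) or retained (the held-out test set, standing in
  for manually annotated test frames).

The default shift is hue 60°, blur σ = 1 px, noise sd 0.02. The hue
magnitude was chosen by dose–response against the phenomenon the fixtures
exist to model: the defining property of the study's domain gap is that the
baseline segmenter collapses on real-domain data. At hue 30° a baseline
U-Net trained on composites still scored ~0.88 Dice on shifted test frames
(no meaningful gap); at 60° it scored ~0.27, the same order of degradation
the benchmark table reports for its baseline on external data; at 90° the
collapse was total (~0.00), which no realistic appearance shift produces.
60° is therefore the default, fixed once.

What passing tests consequently show: the translation stage closes a
*global appearance* gap well enough to restore segmenter performance, the
mask survives translation bitwise, and every arithmetic contract holds.
What they do not show: performance on real wheat imagery. The fixtures
have no perspective, no occluding canopy, no lighting structure, no
annotation noise, and their domain shift is exactly global — none of the
content-level differences (head density, row layout, growth stage) that
make the real problem hard are present.

# Numerical choices and conventions

* Coordinates are 0-based (row, col) in paste instances; transforms are
  applied about the cutout centre; RGB is resampled bilinearly; alpha is
  resampled bilinearly then binarised at 0.5; compositing is hard (no
  feathering) so masks stay exactly consistent with visible pixels —
  realism is the GAN's job, not the compositor's.
* Connected components use 8-connectivity (diagonal joins belong to one
  wheat head).
* Later pastes occlude earlier ones in RGB; the emitted mask is the union.
* Mask channel binarisation threshold is 0 (midpoint of [-1, 1]);
  probability binarisation threshold is 0.5; both send exact ties to
  foreground.
* Both-empty mask pairs score Dice = IoU = 1 (the standard convention).
* Comparison tables compute at stored precision; rounding (1 decimal for
  percentage deltas, 3 for metrics and ratios) is applied only at render
  time. Two published delta figures are known to disagree with their own
  table's arithmetic at the second decimal; the package computes from the
  table and does not special-case them.
* Dataset splits are deterministic: the first `round(n · trainFraction)`
  composites are the train split.
* Seeds: every public generator is a pure function of (config, seed);
  corpus writers derive per-frame child seeds from the master seed, so
  regenerated corpora are byte-identical.

# Problem sizes

Study-scale defaults (`pipelineConfigs("study")`) mirror the full
protocol: 11,000 composites split 10,000/1,000, 60 GAN epochs, 45
segmenter epochs per phase, depth-4/base-64 U-Net, 99 pseudo-labels.
The package's tests and its reproduction script run
`pipelineConfigs("demo")`: 64 px fixtures, 200 composites (180/20), a
base-8 generator with 2 residual blocks warmed up for 100 reconstruction
steps and trained 3 adversarial epochs on 60 source samples against 40
real frames, a depth-3/base-8 U-Net trained 3 epochs per phase, 11 of 40
frames pseudo-labelled, 12 held-out test frames —
sizes chosen so the whole pipeline, including training, completes in
minutes on one CPU while still exhibiting the baseline collapse and its
repair by translation.

# Known limitations

* The demonstration-scale result is directional (model B at least matches
  model A on shifted fixtures); absolute scores on real wheat imagery are
  out of reach without the original data and GPU-scale training.
* The confidence proxy for pseudo-label selection rewards confident
  predictions, not correct ones; a systematically confident failure mode
  would be selected. The review gallery exists for exactly that reason.
* Single-image batches: batch statistics, batch-norm-style regularisation
  and gradient noise at larger batch sizes are unexplored here.
* The engine is CPU-only and unthreaded by design; study-scale training is
  expressible but slow.
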