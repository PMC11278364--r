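# maskcycle

Semantic segmentation of wheat heads — the grain-bearing spikes in field
imagery — normally requires large sets of per-pixel annotations that are
slow and expensive to produce. `maskcycle` implements an
annotation-efficient alternative for plant-phenotyping researchers: starting
from a **single manually labelled frame**, it manufactures a large annotated
training set, closes the gap between synthetic and real appearance with a
mask-preserving generative translation, and trains a U-Net segmenter that is
finally sharpened with pseudo-labels.

The pipeline has five stages:

1. **Cut-and-paste synthesis (ΔS).** Wheat-head cutouts are extracted from
   the labelled frame as 8-connected mask components and composited onto
   background frames at random positions, scales, rotations and flips. The
   mask of every composite is exact by construction.
2. **Mask-preserving CycleGAN (ΔGAN).** Two generators translate between
   the synthetic domain S and the realistic domain R. The S-domain sample
   is the *concatenation of image and mask* — 4 channels — and the cycle
   S → R → S is penalised with an L1 loss over **all four channels**, so
   the mask must be recreated at the end of the cycle:

   ```
   L = LS(D_R(G_SR(x)), 1) + LS(D_S(G_RS(y)), 1)
       + λ [ ‖x − G_RS(G_SR(x))‖₁  +  ‖y − G_SR(G_RS(y))‖₁ ]
   ```

   with least-squares adversarial terms, λ = 10, and the 4-channel x ∈ S.
   Translated datasets copy the original mask files byte-for-byte — the
   annotation is never rewritten by a network.
3. **Segmentation.** A U-Net trained with binary cross-entropy; SGD with
   learning rate 0.01, weight decay 0.001, momentum 0.95, step scheduler
   ×0.1 every 5 epochs; the best epoch is chosen by validation Dice.
   Model A is trained on ΔS (the baseline), model B on ΔGAN.
4. **Pseudo-labelling (ΔPL).** Model B predicts masks for an unlabelled
   pool; candidates are scored by prediction confidence, the best are
   selected (top-k / threshold / manual review list, with an HTML review
   gallery), and B is fine-tuned into model C on ΔGAN + ΔPL.
5. **Evaluation.** Per-image Dice `2|A∩B|/(|A|+|B|)` and IoU `|A∩B|/|A∪B|`,
   macro-averaged; comparison tables of percentage-point deltas (B − A)
   and IoU ratios (C / A).

No field data is required to run any of it: a procedural fixture module
generates annotated frames (textured ellipses with exact masks),
backgrounds, and "real-domain" frames (the same content under a hue/blur/
noise appearance shift) so the full pipeline runs end-to-end on any
machine. The networks run on a small CPU tensor engine built into the
package and verified against numerical gradients in the test suite.

## Worked example

```r
library(maskcycle)

## one labelled 64 px frame, three background frames
cfg <- fixtureConfig(seed = 7, imageHeight = 64, imageWidth = 64,
                     blobsPerFrame = c(4, 9), blobAxes = c(4, 10),
                     nBackgroundFrames = 3, nRealFrames = 3, nTestFrames = 2)
frame <- makeAnnotatedFrame(cfg)
frame
#> AnnotatedSample: 64 x 64 px, 805 foreground px ( 19.7 % )

## cut out its wheat heads and paste them onto a fresh background
cuts <- extractCutouts(frame, minArea = 8)
length(cuts)
#> [1] 3
synth <- synthesisConfig(nImages = 1, headsPerImage = c(6, 6),
                         scaleRange = c(0.8, 1.25), seed = 2)
inst <- sampleInstances(synth, length(cuts), dims = c(64, 64))
composite <- renderPaste(makeBackground(cfg, seed = 8), cuts, inst)
composite
#> AnnotatedSample: 64 x 64 px, 1224 foreground px ( 29.9 % )
```

The first frame carries 805 foreground pixels across its generated blobs;
the composite pastes six jittered cutouts and reports the exact pixel
count of their union — that mask is the free annotation the rest of the
pipeline feeds on. `runWheatPipeline(pipelineConfigs("demo", seed = 1),
workDir)` then runs every stage at the package's demonstration scale
(200 composites, 64 px, a few epochs each) in a few CPU-minutes; in that
run the baseline model A scored 0.175 mean Dice on the held-out shifted
test frames, the translation-trained model B scored 0.826, and the
pseudo-label fine-tuned model C 0.852 — the collapse across the domain gap
and its repair by mask-preserving translation, in miniature.
`pipelineConfigs("study")` holds the full-scale settings (11,000
composites, 60 GAN epochs, 45 segmenter epochs per phase).

A command-line wrapper over the same functions is included at
`inst/cli/maskcycle.R` (subcommands `fixtures`, `synthesize`, `train-gan`,
`translate`, `train-seg`, `pseudolabel`, `evaluate`, `report`).

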