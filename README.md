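# protoseg

Few-shot semantic segmentation of grayscale image volumes in R, trained
without manual annotations. One annotated support slice defines a target
structure; the model segments that structure in query slices — including
organ classes never seen during training.

The package is aimed at methods researchers in biomedical image analysis
who want a fully inspectable, CPU-scale implementation of this family of
models: every mathematical component is a plain R function with a
brute-force-tested contract, and a bundled synthetic phantom generator
makes the complete pipeline — self-supervision, episodic training,
unseen-class evaluation — runnable end to end in minutes with no external
data.

## The method

* **Adaptive local prototypes.** Support features are average-pooled over
  non-overlapping windows of size `(αH, αW)`; a window's prototype counts
  for the class when its mask occupancy reaches a threshold τ, and a
  mask-weighted global prototype is the fallback. Background gets its own
  prototype set from the complement mask.
* **Cosine allocation.** Query pixels are matched to prototypes by scaled
  cosine similarity `D^k(x,y) = 20·cos(F_q(x,y), P_k)`; per-pixel softmax
  weighting over the prototype axis fuses the maps,
  `PM(x,y) = Σ_k D^k·softmax_k D^k`, and the mask is the
  foreground/background argmax.
* **Multi-scale auxiliary head.** The per-pixel best prototype, the
  foreground map and the query features are concatenated and fed to a
  small top-down pyramid emitting predictions at several scales — used
  only as a training signal.
* **Adversarial mask refinement.** A discriminator with dual-attentive
  fusion (separate attention paths for the mask and its inverse) scores
  (image, mask) pairs; the segmenter earns reward when its predicted mask
  is scored support-like. Losses: `L_P = ℓ_pro + ℓ_align + 0.3·ℓ_fpn +
  0.02·L_adv` for the generator, `L_G = BCE(s(I_s,M_s),1) +
  0.5·BCE(s(I_q,M̂_q),0)` for the discriminator, alternating SGD updates.
* **Annotation-free episodes.** Training pairs are minted by graph-based
  oversegmentation: one superpixel becomes the pseudo-foreground, and an
  affine+gamma transformed view of the slice becomes the query.
* **Volumetric evaluation.** Eligible slices of support and query volumes
  are split into 9 chunks; each query slice pairs with the centre slice of
  its support chunk; Dice (%) is computed on the restacked volume.

Since the R stack ships no deep-learning framework, the package includes a
minimal reverse-mode autodiff tape over plain arrays; all gradients are
validated against finite differences in the test suite.

## A worked example

```r
library(protoseg)

# three synthetic volumes: 4 "organ" classes + background distractors
volumes <- desk_phantom_set(n_volumes = 3, seed = 1)

# hold out class 1; train on annotation-free superpixel episodes
sp <- split_classes(1:4, n_folds = 4, fold = 1)
stream <- ssl_stream(volumes, exclude_classes = sp$test, seed = 7)

model <- protoseg_model(backbone = backbone_config("tiny_cnn"),
                        gnet = discriminator_config(growth = 8), seed = 7)
model$train_classes <- sp$train
model <- train_protoseg(model, stream,
                        train_config(epochs = 4, episodes_per_epoch = 150,
                                     lr0 = 0.01, clip = 3, seed = 7))

evaluate_model(model, volumes, sp$test)
```

```
<protoseg_eval> fold NA - 3 volumes
  class 1: 54.84%
  mean DSC: 54.84%
```

54.8% Dice on a class the model never saw in training, from one annotated
support slice per query volume. The same evaluation before training prints
`class 1: 16.06%` — an untrained cosine matcher with zero-bias
initialisation is nearly intensity-blind — so essentially all of the
segmentation ability here was learned from pseudo-labels. `desk_experiment()` packages this
whole protocol (including the untrained baseline and the `alloc`/`multiscale`/
`adversarial` ablation variants) as one call.

A thin command-line front end for the same workflow lives at
`inst/cli/protoseg.R` (subcommands `simulate`, `train`, `evaluate`,
`predict`, NIfTI in and out).

## Scientific background

The methods vignette
(`vignettes/prototype-adversarial-few-shot.Rmd`) documents the model, the
loss system, the self-supervision rules, the phantom generator's scope and
limits, and all numerical choices.
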