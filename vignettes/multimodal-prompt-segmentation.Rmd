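---
title: "Multi-modal prompt-based lesion segmentation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-modal prompt-based lesion segmentation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Prostate-cancer (PCa) lesions are read from three registered MRI
modalities: T2-weighted anatomy (lesions subtly hypointense), diffusion-
weighted imaging (DWI, lesions hyperintense), and the apparent diffusion
coefficient map (ADC, lesions strongly hypointense -- low ADC reflects the
high cellular density of tumours).  Promptable segmentation backbones
(an image encoder, a bounding-box prompt encoder and a mask decoder,
pre-trained at scale and kept frozen) segment what a user's box indicates,
but they accept a single 3-channel image and need a human to draw the box.
`segfuse` implements the two components that turn such a frozen backbone
into a fully automatic multi-modal lesion segmenter:

* a **multi-modal fusion module (MFM)** that merges per-modality image
  embeddings into one fused embedding for the decoder, and
* a **prompt generation module (PGM)** that replaces the hand-drawn box by
  coarse prompt-free segmentation, morphological post-processing, and
  iterative box refinement.

Everything is testable at desk scale on a synthetic phantom; externally
converted pre-trained weights can be plugged in through
`backbone_from_arrays()`.

## The model

With `x_t`, `x_d`, `x_a` the registered T2W/DWI/ADC slices, the encoder
`E` produces four embeddings on a `g x g` grid with `C` channels:

```
f_all = E([x_a, x_d, x_t])        # channel-stacked input
f_m   = E([x_m, x_m, x_m])        # each modality, channel-tripled
```

The MFM applies three multi-head cross-attention (MHCA) blocks, each with
the stacked embedding as query and one modality as key and value:

```
f_m' = MHCA_m(query = f_all, key = f_m, value = f_m),  m in {t, d, a}
```

followed by a two-stage multi-scale modality attention (MSMA).  Stage 1
computes per-channel significance scores `(alpha1, beta1, gamma1)` from
`f_t' + f_d' + f_a'` and weights the three features; stage 2 recomputes
scores from the stage-1 weighted sum and weights the **original** `f_m'`
again; the fused embedding is the sum of the stage-2 weighted features.
The reuse of the original cross-attended features in stage 2 is the
residual path of the fusion block.

The prompt-guided model decodes `D(f', P(b))` with a box prompt `b`; the
prompt-free variant simply decodes `D(f')` with no prompt feature.  The
two MFMs (prompt-guided and prompt-free) never share parameters.  The
backbone (`E`, `P`, `D`) is frozen throughout; only the MFMs train.

**PGM.**  (1) The prompt-free model yields a coarse probability map,
thresholded at 0.5.  (2) A morphological open--close (3x3 square) removes
discrete outliers, a closing with a disk of radius 2 merges adjacent
connected areas, and the mask is split into single-lesion components
(8-connectivity, minimum area 10 px at 128-px scale, scaled by
`(size/128)^2`).  (3) Each component's minimum enclosing rectangle,
expanded outward by 15%, seeds an iterative refinement: encode the box,
decode from the fused embedding, threshold at 0.5, recompute the box at
10% expansion -- until the Dice coefficient between consecutive masks
reaches 0.95, with a safety cap of 10 iterations and a degenerate-collapse
guard that returns the previous mask if a decode comes back empty.

**Loss.**  The unweighted sum of mean-per-pixel binary cross-entropy and
Dice loss `1 - (2*sum(p*y) + eps) / (sum(p) + sum(y) + eps)` with
`eps = 1e-6`, averaged over the mini-batch.  The smoothing in both
numerator and denominator makes the loss exactly zero at perfect binary
agreement, which the closed-form tests exploit.

**Training protocol.**  Two phases with the backbone frozen: first the
prompt-free MFM, which is then frozen while the prompt-guided MFM trains.
Boxes for the guided phase are simulated from the annotations with random
independent corner perturbation.  Adam (`beta1 = 0.9`, `beta2 = 0.999`)
with weight decay 0.01; random rotation augmentation; the checkpoint best
on validation global DSC is kept.

## Scale presets and parameters

| parameter | paper scale | tiny scale | notes |
|---|---|---|---|
| input size | 1024 px | 128 px | stride-16 patches in both |
| embedding grid | 64 x 64 | 8 x 8 | |
| channels `C` | 256 | 32 | prompt feature has length `C` |
| decoder output | 256 x 256 | 32 x 32 | 4x the grid side, upsampled to input resolution by the caller |
| attention heads | 8 | 2 | must divide `C` |
| learning rate | 1e-5 | 1e-3 | the tiny stand-in trains from scratch at small width, so the tiny preset raises the rate |
| batch size | 8 | 4 | |
| epochs | 30 | <= 10 | |
| box perturbation | 0--20 px | 0--2 px | scaled with image size (20 px at 1024 is 2.5 px at 128) |

The `tiny` preset is the default; `paper` exists for users who load
externally converted pre-trained weights.

## The stand-in backbone

No pre-trained foundation backbone is shipped.  The packaged stand-in is a
small network honouring every shape contract: a linear stride-16 patch
embedding with a residual MLP and fixed 2-D sinusoidal positional
encodings (encoder); a linear map over sinusoidal box features (prompt
encoder); and a prompt-conditioned per-token MLP that emits a 4x4 logit
block per token (decoder).  Box features are the scaled Fourier
coefficients of the box's row/column interval indicators on the same
frequency basis as the positional encoding, so the decoder's fixed gating
channel -- the dot product of the prompt feature with each token's
positional encoding -- evaluates a soft "inside the box" map; the prompt
feature additionally conditions the decoder FiLM-style (an additive shift
and a per-channel scale).

`pretrain_backbone()` plays the role of the foundation model's
pre-training, at phantom scale: it jointly trains encoder, prompt encoder
and decoder on (i) box-prompted decoding where the target is the mask
*inside* the box -- including heavily jittered and purely random boxes, so
the box semantics ("segment what the box indicates") are actually
learned; (ii) box-prompted decoding of random per-channel blends of two
embedding views, which makes the frozen decoder robust to the
embedding-distribution shift that a freshly initialized fusion module
introduces; and (iii) prompt-free decoding of the stacked input and of
channel-tripled single modalities.  Gaussian feature noise (sigma 0.3) is
added to embeddings before decoding.  The prompt-free paths are
deliberately down-weighted (`pf_weight = 0.15`): a promptable backbone is
primarily trained *with* prompts, so its prompt-free head is compara-
tively weak -- which is also what gives the box prompt genuine information
content downstream.  For empty-in-box targets the Dice term saturates
near 1 with a vanishing gradient, so those examples are supervised by
up-weighted BCE alone.

After pre-training the backbone is frozen; the freeze contract is
enforced by checksums in the training loops and tested explicitly.

## The phantom generator

Each slice is a bright circular gland (mean intensity 0.55) on a dark
background (0.15) with elliptical lesions (axis ratio 0.6--1.0, random
orientation, semi-major axis 6--14 px at 128-px scale) placed entirely
inside the gland.  Lesion contrast offsets are ADC -0.35, DWI +0.30,
T2W -0.10 -- making ADC the most informative channel, mirroring the
clinical reading -- with additive Gaussian noise (sigma 0.05) and clipping
to [0, 1].  Generation is bit-reproducible from (spec, seed); slices of a
case share a gland centre; splits are assigned at case level in the 7:1:2
ratio.

What the phantom does **not** emulate: MR physics (no k-space, bias
fields, coil profiles, or b-value dependence), anatomy (no zonal
structure, no neighbouring organs), registration error between modalities,
or the heterogeneous textures of real lesions.  Passing the end-to-end
tests therefore demonstrates that the machinery -- fusion, prompting,
refinement, training dynamics -- works as specified, not that the tiny
model would segment clinical MRI.

## Study sizes and numerical choices

The packaged study (`phantom_study()`) uses 200 slices (20 cases x 10
slices), 32 backbone pre-training epochs, and at most 10 epochs per
fusion phase -- sizes chosen so the whole experiment runs in minutes on a
laptop CPU while leaving clear headroom between the three prompting modes.
Other numerical choices:

* probability threshold fixed at 0.5 (an Otsu histogram threshold is
  available behind `threshold_mask(method = "otsu")` for exploration, but
  the fixed threshold is the documented behaviour);
* significance scores are per-channel vectors normalized by softmax across
  the modality axis, giving the testable sum-to-one invariant; MSMA pools
  globally (1x1) and locally (adaptive grid of at most 4x4 regions), a
  shared bottleneck with reduction ratio 4 emits `3C` logits per branch,
  and branch logits are summed before the softmax;
* MHCA is plain pre-LN cross-attention -- no residual add of the query and
  no feed-forward sublayer;
* the stacked input uses channel order [ADC, DWI, T2W] (configurable);
* box expansion is total (half per side), rounded outward and clamped;
* the prompt-guided MFM warm-starts from the trained prompt-free MFM --
  the two remain distinct parameter sets, but the guided epochs are then
  spent learning to exploit the prompt rather than re-learning fusion;
* Wilcoxon signed-rank comparisons drop zero differences, use the exact
  distribution for n <= 25 and the continuity-corrected normal
  approximation otherwise; both-empty Dice is 1.0 by default (a correct
  "no lesion" call scores perfectly), exposed as a flag;
* intensity normalization is 0.5--99.5 percentile clipping per slice
  (robust to MRI outliers), bilinear resizing for images and
  nearest-neighbour for masks.

## Known limitations

* The stand-in backbone is orders of magnitude smaller than a real
  foundation model; its role is to preserve contracts and training
  dynamics, not representational power.
* Global DSC pools pixels over a dataset, so large lesions dominate;
  per-image DSC feeds the statistics instead, and lesion-level metrics are
  out of scope.
* The fusion module is fixed to three modalities (the stacked query
  assumes exactly the T2W/DWI/ADC triple).
* Multi-lesion slices are segmented per component at prompting time, but
  the guided training phase draws one box around the full annotation.
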