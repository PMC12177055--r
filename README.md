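# segfuse

Fully automatic prostate-cancer lesion segmentation from registered
multi-modal MRI (T2W, DWI, ADC), built around a *frozen* promptable
segmentation backbone — an image encoder `E`, a bounding-box prompt
encoder `P` and a mask decoder `D` — extended with two small trainable
components:

* a **multi-modal fusion module (MFM)**: three multi-head cross-attention
  blocks with the channel-stacked embedding as query and each modality as
  key/value,

  ```
  f_all = E([x_a, x_d, x_t]),   f_m = E([x_m, x_m, x_m])
  f_m'  = MHCA_m(query = f_all, key = f_m, value = f_m)
  ```

  followed by two-stage multi-scale modality attention: per-channel
  significance scores `(α, β, γ)` (softmax across modalities, so
  `α + β + γ = 1` per channel) computed from `f_t' + f_d' + f_a'` weight
  the features in stage 1; stage-2 scores from the stage-1 sum weight the
  original `f_m'` again, and `f' = f_t'^(2) + f_d'^(2) + f_a'^(2)` feeds
  the decoder;

* a **prompt generation module (PGM)** replacing the hand-drawn box:
  coarse prompt-free segmentation `D(f')`, a morphological open–close
  with per-lesion splitting, minimum enclosing rectangles expanded by
  15 %, and iterative box refinement (decode → threshold 0.5 → re-box at
  10 % expansion, until consecutive-mask DSC ≥ 0.95, capped at 10
  iterations).

Training is two-phase with the backbone frozen throughout: the prompt-free
MFM first, then (frozen) the prompt-guided MFM, with the loss
`L = BCE + DiceLoss` and Adam. Segmentations are scored by the Dice
similarity coefficient `DSC = 2|A∩B| / (|A|+|B|)`, pooled globally over a
dataset (`2ΣTP / (2ΣTP + ΣFP + ΣFN)`) as the headline metric, and
per-image DSC feeds paired Wilcoxon signed-rank comparisons with
Benjamini–Hochberg correction.

The package is aimed at methods researchers who want the full pipeline —
fusion, prompting, refinement, training protocol, evaluation — runnable
and testable on a laptop: a synthetic multi-modal phantom generator
(bright gland, lesions hypointense on ADC, hyperintense on DWI, subtly
hypointense on T2W) makes every component exercisable without any
clinical data, and an adapter (`backbone_from_arrays()`) accepts
externally converted pre-trained backbone weights at the full 1024-px
scale.

## A worked example

```r
library(segfuse)

# one synthetic slice: the ADC channel is darkest inside the lesion
tr <- generate_slice(phantom_spec(seed = 7))
round(c(adc_lesion = mean(tr$adc[tr$mask == 1]),
        adc_gland  = mean(tr$adc[tr$mask == 0 & tr$t2w > 0.3])), 3)
#> adc_lesion  adc_gland
#>      0.192      0.548

# global vs per-image DSC use different pooling
t1 <- matrix(0L, 3, 3); t1[1, ] <- 1L; p1 <- t1; p1[2, 1] <- 1L
t2 <- matrix(0L, 3, 3); t2[3, 1:2] <- 1L; p2 <- matrix(0L, 3, 3)
rec <- rbind(eval_record(p1, t1, "c", 1), eval_record(p2, t2, "c", 2))
c(global = dsc_global(rec), mean_per_image = mean(rec$dsc))
#>         global mean_per_image
#>      0.6666667      0.4285714

# the full desk-scale study: 200 phantom slices, frozen backbone,
# two-phase fusion training, then three prompting modes on validation
st <- phantom_study(seed = 11)   # ~6 minutes on one CPU core
st$metrics
#> # A tibble: 3 × 2
#>   method      global_dsc
#>   <chr>            <dbl>
#> 1 gt_boxes         0.801
#> 2 pgm_boxes        0.749
#> 3 prompt_free      0.720
```

Prompting with unperturbed ground-truth boxes beats the prompt-free
branch, and the PGM's automatically generated boxes land between the two
— automation costs part of, but not all of, the prompt advantage.

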