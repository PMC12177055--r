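# Loss, box perturbation, Adam, and the two-phase frozen-backbone training
# protocol: pre-train the stand-in backbone, freeze it, train the
# prompt-free fusion module, freeze it, train the prompt-guided one.

#' Combined binary cross-entropy + Dice segmentation loss
#'
#' The unweighted sum of mean-per-pixel BCE (predictions clipped to
#' `[1e-7, 1 - 1e-7]`) and Dice loss
#' `1 - (2 * sum(y_hat * y) + eps) / (sum(y_hat) + sum(y) + eps)` with
#' `eps = 1e-6`.  For a list of prediction/target pairs the batch loss is
#' the mean over samples.  The loss is zero exactly at perfect binary
#' agreement (up to the clipping epsilon).
#'
#' @param y_hat Probability matrix in `[0, 1]`, or a list of them.
#' @param y Binary target matrix of the same shape, or a list of them.
#' @return A non-negative scalar.
#' @export
loss_total <- function(y_hat, y) {
  if (is.list(y_hat)) {
    stopifnot(is.list(y), length(y_hat) == length(y))
    return(mean(mapply(loss_total, y_hat, y)))
  }
  if (!identical(dim(y_hat), dim(y))) stop("shape mismatch between ",
                                           "prediction and target",
                                           call. = FALSE)
  p <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  eps <- 1e-6
  dice <- 1 - (2 * sum(y_hat * y) + eps) / (sum(y_hat) + sum(y) + eps)
  bce + dice
}

# Loss and gradient w.r.t. logits (numerically stable form used in training).
loss_grad_logits <- function(logits, y) {
  p <- sigmoid(logits)
  n <- length(y)
  sp <- log1p(exp(-abs(logits))) + pmax(-logits, 0)   # -log sigmoid(logits)
  bce <- mean(y * sp + (1 - y) * (logits + sp))
  eps <- 1e-6
  num <- 2 * sum(p * y) + eps
  den <- sum(p) + sum(y) + eps
  dice <- 1 - num / den
  dp_dice <- -(2 * y * den - num) / den^2
  dlog <- (p - y) / n + dp_dice * p * (1 - p)
  list(loss = bce + dice, dlogits = dlog)
}

#' Randomly perturb a bounding box
#'
#' Each corner coordinate is shifted by an integer drawn uniformly from
#' `[-p, p]` (independently per coordinate), emulating the variability of
#' hand-drawn boxes; the result is clamped to the image and kept
#' non-degenerate.
#'
#' @param b A [bbox()].
#' @param image_size Image side in pixels.
#' @param max_shift Maximum absolute shift `p` in pixels (paper scale: 20).
#' @return A valid [bbox()].
#' @export
perturb_box <- function(b, image_size, max_shift = 20L) {
  p <- as.integer(max_shift)
  d <- if (p > 0L) sample(seq.int(-p, p), 4L, replace = TRUE) else rep(0L, 4L)
  x1 <- min(max(b[["x_min"]] + d[1], 0), image_size - 1)
  y1 <- min(max(b[["y_min"]] + d[2], 0), image_size - 1)
  x2 <- max(min(b[["x_max"]] + d[3], image_size), x1 + 1)
  y2 <- max(min(b[["y_max"]] + d[4], image_size), y1 + 1)
  bbox(x1, y1, x2, y2)
}

# ---- Adam -------------------------------------------------------------------

adam_state <- function(params) {
  list(m = param_zeros_like(params), v = param_zeros_like(params), t = 0L)
}

adam_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps, wd) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    pm <- vector("list", length(p)); names(pm) <- names(p)
    pv <- pm
    for (nm in names(p)) {
      r <- adam_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr_t, beta1, beta2,
                    eps, wd)
      out[[nm]] <- r$p; pm[[nm]] <- r$m; pv[[nm]] <- r$v
    }
    list(p = out, m = pm, v = pv)
  } else {
    g <- g + wd * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    list(p = p - lr_t * m / (sqrt(v) + eps), m = m, v = v)
  }
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  r <- adam_rec(params, grads, state$m, state$v, lr_t, beta1, beta2, eps,
                weight_decay)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

#' Training configuration
#'
#' The `paper` preset carries the full-scale training settings (Adam with
#' `beta1 = 0.9`, `beta2 = 0.999`, learning rate 1e-5, weight decay 0.01,
#' batch size 8, 30 epochs, box perturbation 0-20 px at 1024-px scale).
#' The `tiny` preset trains the small stand-in from scratch, so it raises
#' the learning rate to 1e-3, uses batch 4, at most 10 epochs, and scales
#' the box perturbation with image size (0-2 px at 128).  Augmentation is
#' random rotation from \{0, +-10, +-20\} degrees, applied jointly to all
#' modalities (bilinear) and the mask (nearest).
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param epochs,learning_rate,batch_size,weight_decay,box_perturb_px,seed
#'   Optional overrides.
#' @return An object of class `train_config`.
#' @export
train_config <- function(preset = c("tiny", "paper"), epochs = NULL,
                         learning_rate = NULL, batch_size = NULL,
                         weight_decay = 0.01, box_perturb_px = NULL,
                         seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(epochs = 10L, lr = 1e-3, batch = 4L, perturb = 2L)
  } else {
    list(epochs = 30L, lr = 1e-5, batch = 8L, perturb = 20L)
  }
  cfg <- list(preset = preset,
              epochs = as.integer(epochs %||% def$epochs),
              learning_rate = learning_rate %||% def$lr,
              batch_size = as.integer(batch_size %||% def$batch),
              weight_decay = weight_decay,
              beta1 = 0.9, beta2 = 0.999,
              box_perturb_px = as.integer(box_perturb_px %||% def$perturb),
              rotate_angles = c(-20, -10, 0, 10, 20),
              seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$box_perturb_px >= 0)
  structure(cfg, class = "train_config")
}

rotate_triple <- function(triple, angle) {
  if (angle == 0) return(triple)
  modality_triple(rotate_image(triple$t2w, angle),
                  rotate_image(triple$dwi, angle),
                  rotate_image(triple$adc, angle),
                  mask = if (is.null(triple$mask)) NULL else
                    as_binary_mask(rotate_image(triple$mask, angle,
                                                "nearest")),
                  spacing = triple$spacing, case_id = triple$case_id,
                  slice_index = triple$slice_index)
}

# Tight box (no expansion) around a non-empty mask.
tight_box <- function(mask) box_from_mask(mask, expand_frac = 0)

# Zero a mask outside a box (box prompts select what to segment).
mask_in_box <- function(mask, b) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  rows <- (b[["y_min"]] + 1L):b[["y_max"]]
  cols <- (b[["x_min"]] + 1L):b[["x_max"]]
  out[rows, cols] <- mask[rows, cols]
  as_binary_mask(out)
}

# Random box for negative prompt examples during pre-training.
random_box <- function(image_size) {
  w <- sample(12:48, 1L)
  h <- sample(12:48, 1L)
  x1 <- sample(0:(image_size - w), 1L)
  y1 <- sample(0:(image_size - h), 1L)
  bbox(x1, y1, x1 + w, y1 + h)
}

# Token embeddings of the four encoder views of a slice.
embed_triple <- function(model, triple) {
  cfg <- model$config
  enc <- model$params$encoder
  list(
    all = encoder_forward(stack_modalities(triple, cfg), enc, cfg)$out,
    t = encoder_forward(stack_single_modality(triple$t2w), enc, cfg)$out,
    d = encoder_forward(stack_single_modality(triple$dwi), enc, cfg)$out,
    a = encoder_forward(stack_single_modality(triple$adc), enc, cfg)$out
  )
}

# Forward pass of one slice through fusion + decoder.
forward_slice <- function(model, triple, which = c("mfm_pf", "mfm_g"),
                          f_p = NULL, emb = NULL) {
  which <- match.arg(which)
  cfg <- model$config
  emb <- emb %||% embed_triple(model, triple)
  fus <- mfm_fwd(emb$all, emb$t, emb$d, emb$a, model$params[[which]], cfg)
  dec <- decoder_forward(fus$out, f_p, model$params$decoder, cfg)
  list(prob = dec$prob, fused = fus$out, emb = emb)
}

# Prediction at image resolution.
prob_to_mask_fullres <- function(prob, input_size) {
  upsample_nearest(threshold_mask(prob), input_size %/% nrow(prob))
}

global_dsc_counts <- function(pred, truth) {
  c(tp = sum(pred == 1L & truth == 1L),
    fp = sum(pred == 1L & truth == 0L),
    fn = sum(pred == 0L & truth == 1L))
}

# Validation global DSC for one phase.
validate_phase <- function(model, slices, which, use_gt_boxes = FALSE) {
  cfg <- model$config
  tot <- c(tp = 0, fp = 0, fn = 0)
  for (tr in slices) {
    if (use_gt_boxes) {
      if (is.null(tr$mask) || sum(tr$mask) == 0) next
      fp <- prompt_forward(tight_box(tr$mask), model$params$prompt,
                           cfg)$out
      res <- forward_slice(model, tr, which, f_p = fp)
    } else {
      res <- forward_slice(model, tr, which)
    }
    pred <- prob_to_mask_fullres(res$prob, cfg$input_size)
    tot <- tot + global_dsc_counts(pred, tr$mask)
  }
  den <- as.numeric(2 * tot["tp"] + tot["fp"] + tot["fn"])
  if (den == 0) 1 else as.numeric(2 * tot["tp"]) / den
}

#' Pre-train the stand-in backbone on phantom data
#'
#' A deployment at clinical scale transfers a frozen pre-trained foundation
#' backbone; this
#' package's CPU-scale analog is a small backbone pre-trained here on
#' phantom slices, then frozen.  The encoder, prompt encoder and decoder
#' are optimized jointly on prompt-free decoding of the stacked input,
#' box-prompted decoding (tight ground-truth boxes with small jitter), and
#' prompt-free decoding of channel-tripled single modalities, so that the
#' frozen decoder later accepts both fused embeddings and prompt features.
#'
#' Two augmentations stand in for the breadth of a real foundation-model
#' pre-training corpus: Gaussian noise of standard deviation
#' `feature_noise` is added to the embedding before decoding (making the
#' frozen decoder robust to the feature-distribution shift introduced by a
#' freshly initialized fusion module), and with `neg_box` each slice also
#' contributes a random background box whose target is the empty mask
#' (teaching the decoder that the box prompt selects what to segment).
#'
#' @param model An `sf_model` from [model_init()].
#' @param slices List of [modality_triple()] with masks (training split).
#' @param epochs,learning_rate,batch_size Optimization settings.
#' @param feature_noise Embedding-noise standard deviation (0 disables).
#' @param neg_box Include negative background-box examples?
#' @param pf_weight Relative weight of the prompt-free decode paths.  A
#'   promptable backbone is primarily trained with prompts, so its
#'   prompt-free head is deliberately under-trained (default 0.15); the
#'   prompt-free fusion phase then has real work to do, and the box prompt
#'   carries genuine information.
#' @param seed RNG seed for shuffling and jitter.
#' @return The model with a trained, frozen backbone.
#' @export
pretrain_backbone <- function(model, slices, epochs = 32L,
                              learning_rate = 1e-3, batch_size = 4L,
                              feature_noise = 0.3, neg_box = TRUE,
                              pf_weight = 0.15, seed = 1L) {
  stopifnot(inherits(model, "sf_model"), length(slices) > 0)
  cfg <- model$config
  groups <- c("encoder", "prompt", "decoder")
  withr::with_seed(as.integer(seed), {
    params <- model$params[groups]
    state <- adam_state(params)
    mods <- c("t2w", "dwi", "adc")
    for (ep in seq_len(epochs)) {
      idx <- sample(length(slices))
      for (chunk in split(idx, ceiling(seq_along(idx) / batch_size))) {
        grads <- param_zeros_like(params)
        for (i in chunk) {
          tr <- slices[[i]]
          y <- downsample_mask(tr$mask, 4L)
          ec <- encoder_forward(stack_modalities(tr, cfg), params$encoder,
                                cfg, want_cache = TRUE)
          tok <- ec$out
          if (feature_noise > 0) {
            tok <- tok + matrix(stats::rnorm(length(tok), 0, feature_noise),
                                nrow(tok), ncol(tok))
          }
          dtok <- matrix(0, nrow(tok), ncol(tok))
          # prompt-free path (down-weighted)
          dc <- decoder_forward(tok, NULL, params$decoder, cfg,
                                want_cache = TRUE)
          lg <- loss_grad_logits(dc$logits, y)
          db <- decoder_backward(pf_weight * lg$dlogits, dc,
                                 params$decoder, cfg)
          grads$decoder <- param_map2(grads$decoder, db$params, `+`)
          dtok <- dtok + db$dtok
          # box-prompted path: target is the mask inside the box
          run_box <- function(b, grads) {
            yb <- downsample_mask(mask_in_box(tr$mask, b), 4L)
            pc <- prompt_forward(b, params$prompt, cfg, want_cache = TRUE)
            dc2 <- decoder_forward(tok, pc$out, params$decoder, cfg,
                                   want_cache = TRUE)
            if (sum(yb) == 0) {
              # empty-in-box target: the Dice term saturates near 1 with a
              # vanishing gradient, so supervise with up-weighted BCE only
              p2 <- sigmoid(dc2$logits)
              lg2 <- list(dlogits = 8 * (p2 - yb) / length(yb))
            } else {
              lg2 <- loss_grad_logits(dc2$logits, yb)
            }
            db2 <- decoder_backward(lg2$dlogits, dc2, params$decoder, cfg)
            grads$decoder <- param_map2(grads$decoder, db2$params, `+`)
            dtok <<- dtok + db2$dtok
            grads$prompt <- param_map2(grads$prompt,
                                       prompt_backward(db2$dfp, pc), `+`)
            grads
          }
          if (sum(tr$mask) > 0) {
            grads <- run_box(perturb_box(tight_box(tr$mask),
                                         cfg$input_size, 2L), grads)
          }
          if (neg_box) {
            grads <- run_box(random_box(cfg$input_size), grads)
            if (sum(tr$mask) > 0) {
              grads <- run_box(perturb_box(tight_box(tr$mask),
                                           cfg$input_size,
                                           max(4L, cfg$input_size %/% 12L)),
                               grads)
            }
          }
          grads$encoder <- param_map2(grads$encoder,
                                      encoder_backward(dtok, ec,
                                                       params$encoder), `+`)
          # one channel-tripled single modality per sample
          m <- mods[1L + (i %% 3L)]
          ec1 <- encoder_forward(stack_single_modality(tr[[m]]),
                                 params$encoder, cfg, want_cache = TRUE)
          dc1 <- decoder_forward(ec1$out, NULL, params$decoder, cfg,
                                 want_cache = TRUE)
          lg1 <- loss_grad_logits(dc1$logits, y)
          db1 <- decoder_backward(pf_weight * lg1$dlogits, dc1,
                                  params$decoder, cfg)
          grads$decoder <- param_map2(grads$decoder, db1$params, `+`)
          grads$encoder <- param_map2(grads$encoder,
                                      encoder_backward(db1$dtok, ec1,
                                                       params$encoder), `+`)
          # a random per-channel blend of the two views: trains the frozen
          # decoder on the family of mixed embeddings a fusion module emits
          lam <- stats::runif(ncol(tok))
          tokm <- sweep(ec$out, 2, lam, "*") +
            sweep(ec1$out, 2, 1 - lam, "*")
          # box-prompted mixture decode: the guided branch must be
          # robust to fused-embedding distribution shift
          if (sum(tr$mask) > 0) {
            bmix <- perturb_box(tight_box(tr$mask), cfg$input_size, 4L)
            pcm <- prompt_forward(bmix, params$prompt, cfg,
                                  want_cache = TRUE)
            dcb <- decoder_forward(tokm, pcm$out, params$decoder, cfg,
                                   want_cache = TRUE)
            lgb <- loss_grad_logits(dcb$logits, y)
            dbb <- decoder_backward(lgb$dlogits, dcb, params$decoder, cfg)
            grads$decoder <- param_map2(grads$decoder, dbb$params, `+`)
            grads$prompt <- param_map2(grads$prompt,
                                       prompt_backward(dbb$dfp, pcm), `+`)
            grads$encoder <- param_map2(
              grads$encoder,
              encoder_backward(sweep(dbb$dtok, 2, lam, "*"), ec,
                               params$encoder), `+`)
            grads$encoder <- param_map2(
              grads$encoder,
              encoder_backward(sweep(dbb$dtok, 2, 1 - lam, "*"), ec1,
                               params$encoder), `+`)
          }
        }
        grads <- param_map(grads, function(g) g / length(chunk))
        st <- adam_step(params, grads, state, learning_rate,
                        weight_decay = 0)
        params <- st$params
        state <- st$state
      }
    }
    model$params[groups] <- params
    freeze(model, groups)
  })
}

# Shared MFM training loop for the two phases.
train_mfm_phase <- function(dataset, model, which, config, guided,
                            init = NULL) {
  stopifnot(inherits(dataset, "phantom_dataset"),
            inherits(model, "sf_model"), inherits(config, "train_config"),
            all(c("encoder", "prompt", "decoder") %in% model$frozen))
  cfg <- model$config
  train <- dataset_split(dataset, "train")
  val <- dataset_split(dataset, "val")
  if (guided) train <- Filter(function(tr) sum(tr$mask) > 0, train)
  if (length(train) == 0) stop("empty training split", call. = FALSE)
  frozen_sums <- vapply(model$params[model$frozen], param_checksum,
                        numeric(1))

  withr::with_seed(config$seed, {
    if (!is.null(init)) model$params[[which]] <- init
    params <- model$params[[which]]
    state <- adam_state(params)
    history <- list()
    best <- list(dsc = -Inf, params = params, epoch = 0L)
    # the backbone is frozen and the rotation set is discrete, so the
    # embeddings of every augmentation variant can be computed once
    variants <- lapply(train, function(tr0) {
      lapply(config$rotate_angles, function(a) {
        tr <- rotate_triple(tr0, a)
        if (guided && sum(tr$mask) == 0) tr <- tr0  # rotation lost the lesion
        list(emb = embed_triple(model, tr),
             y = downsample_mask(tr$mask, 4L),
             box = if (sum(tr$mask) > 0) tight_box(tr$mask) else NULL)
      })
    })
    for (ep in seq_len(config$epochs)) {
      idx <- sample(length(train))
      ep_loss <- 0; n_seen <- 0L
      for (chunk in split(idx, ceiling(seq_along(idx) / config$batch_size))) {
        grads <- param_zeros_like(params)
        for (i in chunk) {
          var <- variants[[i]][[sample(length(config$rotate_angles), 1L)]]
          y <- var$y
          emb <- var$emb
          fus <- mfm_fwd(emb$all, emb$t, emb$d, emb$a, params, cfg,
                         want_cache = TRUE)
          fp_cache <- NULL
          if (guided) {
            b <- perturb_box(var$box, cfg$input_size,
                             config$box_perturb_px)
            fp_cache <- prompt_forward(b, model$params$prompt, cfg)
          }
          dc <- decoder_forward(fus$out, fp_cache$out, model$params$decoder,
                                cfg, want_cache = TRUE)
          lg <- loss_grad_logits(dc$logits, y)
          ep_loss <- ep_loss + lg$loss; n_seen <- n_seen + 1L
          db <- decoder_backward(lg$dlogits, dc, model$params$decoder, cfg)
          mb <- mfm_bwd(db$dtok, fus, params)
          grads <- param_map2(grads, mb$params, `+`)
        }
        grads <- param_map(grads, function(g) g / length(chunk))
        st <- adam_step(params, grads, state, config$learning_rate,
                        beta1 = config$beta1, beta2 = config$beta2,
                        weight_decay = config$weight_decay)
        params <- st$params
        state <- st$state
      }
      mtmp <- model; mtmp$params[[which]] <- params
      vd <- validate_phase(mtmp, val, which, use_gt_boxes = guided)
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = ep_loss / n_seen,
                                      val_dsc = vd)
      if (is.finite(vd) && vd > best$dsc) {
        best <- list(dsc = vd, params = params, epoch = ep)
      }
    }
    # freeze contract: backbone (and any previously frozen group) untouched
    stopifnot(identical(frozen_sums,
                        vapply(model$params[model$frozen], param_checksum,
                               numeric(1))))
    model$params[[which]] <- best$params
    structure(list(model = model,
                   phase = if (guided) "prompt_guided" else "prompt_free",
                   history = dplyr::bind_rows(history),
                   best_epoch = best$epoch,
                   best_val_dsc = best$dsc,
                   config = config),
              class = "sf_fit")
  })
}

#' Phase 1: train the prompt-free fusion module
#'
#' With the backbone frozen, optimizes only the prompt-free MFM on the
#' training split (BCE + Dice, Adam, rotation augmentation; slices without
#' lesions are kept, so background is supervised too).  Per-epoch training
#' loss and validation global DSC are logged and the best-validation
#' parameters are retained.
#'
#' @param dataset A `phantom_dataset` (case-level splits).
#' @param model An `sf_model` with a frozen backbone
#'   (see [pretrain_backbone()]).
#' @param config A [train_config()].
#' @return An `sf_fit`: the updated model, history tibble, best epoch.
#' @export
train_promptfree <- function(dataset, model, config = train_config("tiny")) {
  train_mfm_phase(dataset, model, "mfm_pf", config, guided = FALSE)
}

#' Phase 2: train the prompt-guided fusion module
#'
#' Freezes the prompt-free MFM from phase 1, then optimizes only the
#' prompt-guided MFM.  Box prompts are simulated from the expert (phantom)
#' annotations with random corner perturbation; only lesion-containing
#' slices are used (a box prompt requires a lesion).  Validation uses
#' unperturbed ground-truth boxes.
#'
#' @param dataset A `phantom_dataset`.
#' @param fit The `sf_fit` from [train_promptfree()] (or a model with a
#'   trained `mfm_pf`).
#' @param config A [train_config()].
#' @param warm_start Initialize the prompt-guided MFM from the trained
#'   prompt-free one (default TRUE) instead of from scratch.  The two
#'   modules remain distinct parameter sets; warm starting only transfers
#'   the phase-1 solution as the phase-2 starting point so the guided
#'   epochs are spent learning to exploit the prompt.
#' @return An `sf_fit` with the fully trained model.
#' @export
train_guided <- function(dataset, fit, config = train_config("tiny"),
                         warm_start = TRUE) {
  model <- if (inherits(fit, "sf_fit")) fit$model else fit
  model <- freeze(model, "mfm_pf")
  train_mfm_phase(dataset, model, "mfm_g", config, guided = TRUE,
                  init = if (warm_start) model$params$mfm_pf else NULL)
}

#' @export
print.sf_fit <- function(x, ...) {
  cat("<sf_fit> phase=", x$phase, ", ", nrow(x$history), " epochs, best ",
      "val global DSC = ", signif(x$best_val_dsc, 4), " (epoch ",
      x$best_epoch, ")\n", sep = "")
  invisible(x)
}
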