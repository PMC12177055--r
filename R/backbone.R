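#' Backbone configuration (scale presets)
#'
#' Defines the shape contracts of the promptable segmentation backbone: the
#' image encoder maps a 3-channel `input_size` x `input_size` image to a
#' `grid_size` x `grid_size` x `embed_dim` embedding (patch stride 16), the
#' prompt encoder maps a bounding box to a length-`embed_dim` feature, and
#' the mask decoder emits a probability map of side `4 * grid_size`.  The
#' `paper` preset carries the full-scale foundation-backbone shapes
#' (1024 -> 64x64x256 -> 256x256); the `tiny` preset (128 -> 8x8x32 -> 32x32)
#' is CPU-trainable in minutes and is the package default.
#'
#' @param preset `"tiny"` or `"paper"`.
#' @param input_size,grid_size,embed_dim,n_heads Optional overrides.
#' @param stack_order Channel order for the stacked multi-modal input
#'   (default ADC, DWI, T2W).
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(preset = c("tiny", "paper"),
                            input_size = NULL, grid_size = NULL,
                            embed_dim = NULL, n_heads = NULL,
                            stack_order = c("adc", "dwi", "t2w")) {
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(input_size = 128L, grid_size = 8L, embed_dim = 32L, n_heads = 2L)
  } else {
    list(input_size = 1024L, grid_size = 64L, embed_dim = 256L, n_heads = 8L)
  }
  cfg <- list(
    preset = preset,
    input_size = as.integer(input_size %||% def$input_size),
    grid_size = as.integer(grid_size %||% def$grid_size),
    embed_dim = as.integer(embed_dim %||% def$embed_dim),
    n_heads = as.integer(n_heads %||% def$n_heads),
    stack_order = stack_order
  )
  cfg$patch <- cfg$input_size %/% cfg$grid_size
  cfg$prompt_dim <- cfg$embed_dim
  cfg$decoder_hidden <- 2L * cfg$embed_dim
  stopifnot(cfg$patch == 16L,
            cfg$embed_dim %% cfg$n_heads == 0L,
            cfg$embed_dim %% 4L == 0L,
            setequal(cfg$stack_order, c("adc", "dwi", "t2w")))
  structure(cfg, class = "backbone_config")
}

#' Kaiming (He) fan-in initialization
#'
#' Weights are drawn from N(0, 2/fan_in), the standard initialization for
#' ReLU networks; biases start at zero.
#'
#' @param fan_in,fan_out Matrix dimensions (fan_in rows, fan_out columns).
#' @return A `fan_in` x `fan_out` numeric matrix.
#' @export
kaiming_matrix <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

# ---- token <-> grid layout -------------------------------------------------
# Tokens are stored as an N x C matrix, N = grid^2, ordered row-major over
# the grid (token k covers grid row (k-1) %/% g + 1, column (k-1) %% g + 1).

grid_to_tokens <- function(a) {
  g <- dim(a)[1]
  matrix(aperm(a, c(2, 1, 3)), g * g, dim(a)[3])
}

tokens_to_grid <- function(tok, g) {
  aperm(array(tok, c(g, g, ncol(tok))), c(2, 1, 3))
}

# Linear indices extracting stride-16 patches from an H x W x 3 array into
# an N x (patch^2 * 3) matrix, one row per token.
patchify <- function(x, cfg) {
  p <- cfg$patch; g <- cfg$grid_size; H <- dim(x)[1]
  stopifnot(dim(x)[1] == cfg$input_size, dim(x)[2] == cfg$input_size,
            dim(x)[3] == 3L)
  base <- as.vector(outer(seq_len(p), (seq_len(p) - 1L) * H, "+"))
  base <- as.vector(outer(base, (0:2) * H * H, "+"))    # within-patch offsets
  out <- matrix(0, g * g, p * p * 3L)
  xv <- as.vector(x)
  k <- 0L
  for (r in seq_len(g)) {
    row0 <- (r - 1L) * p
    for (cc in seq_len(g)) {
      k <- k + 1L
      out[k, ] <- xv[base + row0 + (cc - 1L) * p * H]
    }
  }
  out
}

# Fixed 2-D sinusoidal positional encoding added to encoder tokens, so that
# downstream consumers (notably prompt-conditioned decoding) see
# position-aware features.
positional_encoding <- function(cfg) {
  g <- cfg$grid_size; C <- cfg$embed_dim
  nf <- C %/% 4L
  r <- (rep(seq_len(g), each = g) - 0.5) / g
  cc <- (rep(seq_len(g), times = g) - 0.5) / g
  k <- seq_len(nf)
  0.5 * cbind(sin(2 * pi * outer(r, k)), cos(2 * pi * outer(r, k)),
              sin(2 * pi * outer(cc, k)), cos(2 * pi * outer(cc, k)))
}

# Sinusoidal features of a box on the same frequency basis as the token
# positional encoding: per axis, the scaled Fourier coefficients of the
# interval indicator 1[u_min, u_max], laid out block-wise to match
# positional_encoding().  The dot product of these features with a token's
# positional encoding evaluates the truncated Fourier series of
# I_rows(r) + I_cols(c) at that token, so box membership is an exactly
# linear functional of (prompt feature) x (positional encoding).  The four
# raw normalized corners are appended.
box_features <- function(bbox, input_size, nf) {
  u <- as.numeric(bbox[c("x_min", "y_min", "x_max", "y_max")]) / input_size
  k <- seq_len(nf)
  coef <- function(lo, hi) {
    list(sin = (cos(2 * pi * k * lo) - cos(2 * pi * k * hi)) / (pi * k),
         cos = (sin(2 * pi * k * hi) - sin(2 * pi * k * lo)) / (pi * k))
  }
  cy <- coef(u[2], u[4])   # row interval  [y_min, y_max]
  cx <- coef(u[1], u[3])   # col interval  [x_min, x_max]
  # PE block order: sin(k r), cos(k r), sin(k c), cos(k c)
  c(cy$sin, cy$cos, cx$sin, cx$cos, u)
}

# ---- parameter initialization ----------------------------------------------

init_encoder <- function(cfg) {
  C <- cfg$embed_dim; pin <- cfg$patch^2 * 3L
  list(W0 = kaiming_matrix(pin, C), b0 = numeric(C),
       W1 = kaiming_matrix(C, C), b1 = numeric(C),
       W2 = kaiming_matrix(C, C), b2 = numeric(C))
}

# The prompt map starts at (twice) the identity on the indicator-Fourier
# features -- the factor 2 cancels the 0.5 amplitude of the positional
# encoding, so the decoder's fixed gating channel PE %*% f_p initially
# evaluates the box-membership series directly -- plus a small random part
# that lets training reshape it.
init_prompt <- function(cfg) {
  C <- cfg$embed_dim
  Wp <- rbind(2 * diag(C), matrix(0, 4L, C)) +
    0.05 * kaiming_matrix(C + 4L, C)
  list(Wp = Wp, bp = numeric(C))
}

init_decoder <- function(cfg) {
  C <- cfg$embed_dim; H <- cfg$decoder_hidden
  list(Wprj = kaiming_matrix(C, C), Wscale = kaiming_matrix(C, C) * 0.1,
       p_null = stats::rnorm(C, 0, sqrt(2 / C)),
       W1 = kaiming_matrix(C + 1L, H), b1 = numeric(H),
       W2 = kaiming_matrix(H, H), b2 = numeric(H),
       W3 = kaiming_matrix(H, 16L), b3 = numeric(16L))
}

#' Initialize a full model from scratch
#'
#' Builds backbone (encoder, prompt encoder, mask decoder) and the two
#' multi-modal fusion modules (prompt-free and prompt-guided; their
#' parameters are never shared) with Kaiming initialization.  The backbone
#' starts unfrozen; [pretrain_backbone()] trains and freezes it.
#'
#' @param config A [backbone_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `sf_model`.
#' @export
model_init <- function(config = backbone_config("tiny"), seed = 1L) {
  stopifnot(inherits(config, "backbone_config"))
  withr::with_seed(as.integer(seed), {
    structure(
      list(config = config,
           params = list(encoder = init_encoder(config),
                         prompt = init_prompt(config),
                         decoder = init_decoder(config),
                         mfm_pf = init_mfm(config),
                         mfm_g = init_mfm(config)),
           frozen = character()),
      class = "sf_model")
  })
}

#' Stack a single-channel image three times along the channel dimension
#'
#' The image encoder expects 3-channel input; single-modality images are
#' channel-tripled so one encoder serves both the stacked multi-modal input
#' and each individual modality.
#'
#' @param x A 2-D numeric matrix.
#' @return An `nrow(x)` x `ncol(x)` x 3 array with identical channels.
#' @export
stack_single_modality <- function(x) {
  if (!is.matrix(x)) stop("input must be a single-channel 2-D image",
                          call. = FALSE)
  array(x, c(dim(x), 3L))
}

# Stacked multi-modal input in the configured channel order.
stack_modalities <- function(triple, cfg) {
  a <- array(0, c(dim(triple$t2w), 3L))
  for (i in 1:3) a[, , i] <- triple[[cfg$stack_order[i]]]
  a
}

# ---- encoder ----------------------------------------------------------------

encoder_forward <- function(x3, enc, cfg, want_cache = FALSE) {
  P <- patchify(x3, cfg)
  t0 <- sweep(P %*% enc$W0, 2, enc$b0, "+")
  pre <- sweep(t0 %*% enc$W1, 2, enc$b1, "+")
  h <- relu(pre)
  f <- t0 + sweep(h %*% enc$W2, 2, enc$b2, "+") + positional_encoding(cfg)
  if (want_cache) list(out = f, P = P, t0 = t0, pre = pre, h = h) else
    list(out = f)
}

encoder_backward <- function(df, cache, enc) {
  dW2 <- t(cache$h) %*% df
  db2 <- colSums(df)
  dh <- df %*% t(enc$W2)
  dpre <- dh * (cache$pre > 0)
  dW1 <- t(cache$t0) %*% dpre
  db1 <- colSums(dpre)
  dt0 <- df + dpre %*% t(enc$W1)
  list(W0 = t(cache$P) %*% dt0, b0 = colSums(dt0),
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

#' Encode a 3-channel image into the embedding grid
#'
#' Stride-16 patchification followed by a linear patch embedding, a small
#' residual MLP and fixed sinusoidal positional encodings.  Deterministic
#' given parameters.
#'
#' @param x A `input_size` x `input_size` x 3 array.
#' @param model An `sf_model` (its encoder parameters are used).
#' @return A `grid_size` x `grid_size` x `embed_dim` array.
#' @export
encode_image <- function(x, model) {
  cfg <- model$config
  if (length(dim(x)) != 3L || dim(x)[1] != cfg$input_size ||
      dim(x)[2] != cfg$input_size || dim(x)[3] != 3L) {
    stop("input must be ", cfg$input_size, "x", cfg$input_size, "x3",
         call. = FALSE)
  }
  tokens_to_grid(encoder_forward(x, model$params$encoder, cfg)$out,
                 cfg$grid_size)
}

# ---- prompt encoder ---------------------------------------------------------

#' Create a bounding box
#'
#' Boxes are axis-aligned, in 0-based half-open pixel coordinates
#' (`x` = column, `y` = row): a box covers columns `[x_min, x_max)` and rows
#' `[y_min, y_max)`.
#'
#' @param x_min,y_min,x_max,y_max Integer pixel coordinates.
#' @return A named numeric vector of class `bbox`.
#' @export
bbox <- function(x_min, y_min, x_max, y_max) {
  b <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  structure(b, class = "bbox")
}

validate_bbox <- function(b, input_size) {
  if (!all(c("x_min", "y_min", "x_max", "y_max") %in% names(b))) {
    stop("bounding box must have x_min, y_min, x_max, y_max", call. = FALSE)
  }
  if (b[["x_min"]] >= b[["x_max"]] || b[["y_min"]] >= b[["y_max"]]) {
    stop("degenerate bounding box (zero area)", call. = FALSE)
  }
  if (b[["x_min"]] < 0 || b[["y_min"]] < 0 ||
      b[["x_max"]] > input_size || b[["y_max"]] > input_size) {
    stop("bounding box outside image bounds", call. = FALSE)
  }
  invisible(b)
}

prompt_forward <- function(b, pr, cfg, want_cache = FALSE) {
  feat <- box_features(b, cfg$input_size, cfg$embed_dim %/% 4L)
  fp <- as.vector(feat %*% pr$Wp) + pr$bp
  if (want_cache) list(out = fp, feat = feat) else list(out = fp)
}

prompt_backward <- function(dfp, cache) {
  list(Wp = outer(cache$feat, dfp), bp = dfp)
}

#' Encode a bounding-box prompt into a prompt feature
#'
#' Box corners, normalized to the unit square, are expanded into sinusoidal
#' position features and passed through a learned linear map to a vector of
#' length `embed_dim` (the prompt feature of the promptable backbone).
#'
#' @param b A [bbox()] in image pixel coordinates.
#' @param model An `sf_model`.
#' @return A numeric vector of length `embed_dim`.
#' @export
encode_prompt <- function(b, model) {
  cfg <- model$config
  validate_bbox(b, cfg$input_size)
  prompt_forward(b, model$params$prompt, cfg)$out
}

# ---- mask decoder -----------------------------------------------------------

# Token logits (N x 16) to a (4g) x (4g) image: each token emits its 4x4
# block, blocks tile the grid row-major.
token_logits_to_image <- function(L, g) {
  matrix(aperm(array(t(L), c(4L, 4L, g, g)), c(1, 4, 2, 3)), 4L * g, 4L * g)
}

image_to_token_logits <- function(img, g) {
  t(matrix(aperm(array(img, c(4L, g, 4L, g)), c(1, 3, 4, 2)), 16L, g * g))
}

# Prompt conditioning is FiLM-style: the prompt feature yields an additive
# shift and a per-channel scale; the scale interacts multiplicatively with
# the positional-encoding channels of the tokens, which is what allows a
# box prompt to select a spatial region.  Prompt-free decoding substitutes
# a learned null-prompt shift (scale 1).
decoder_forward <- function(tok, fp, dec, cfg, want_cache = FALSE) {
  C <- cfg$embed_dim
  if (is.null(fp)) {
    prj <- dec$p_null
    scl <- rep(1, C)
    u <- numeric(nrow(tok))
  } else {
    if (length(fp) != C) stop("prompt feature must have length ", C,
                              call. = FALSE)
    prj <- as.vector(fp %*% dec$Wprj)
    scl <- 1 + as.vector(fp %*% dec$Wscale)
    # fixed gating channel: the prompt's box-membership series evaluated
    # at every token position
    u <- as.vector(positional_encoding(cfg) %*% fp)
  }
  fin <- cbind(sweep(sweep(tok, 2, scl, "*"), 2, prj, "+"), u)
  pre1 <- sweep(fin %*% dec$W1, 2, dec$b1, "+")
  h1 <- relu(pre1)
  pre2 <- sweep(h1 %*% dec$W2, 2, dec$b2, "+")
  h2 <- relu(pre2)
  L <- sweep(h2 %*% dec$W3, 2, dec$b3, "+")
  logits <- token_logits_to_image(L, cfg$grid_size)
  out <- list(prob = sigmoid(logits), logits = logits)
  if (want_cache) c(out, list(fin = fin, pre1 = pre1, h1 = h1, pre2 = pre2,
                              h2 = h2, fp = fp, tok = tok, scl = scl))
  else out
}

# Returns gradients for decoder params, the input tokens, and (when a prompt
# was supplied) the prompt feature.
decoder_backward <- function(dlogits_img, cache, dec, cfg) {
  dL <- image_to_token_logits(dlogits_img, cfg$grid_size)
  dW3 <- t(cache$h2) %*% dL
  db3 <- colSums(dL)
  dh2 <- dL %*% t(dec$W3)
  dpre2 <- dh2 * (cache$pre2 > 0)
  dW2 <- t(cache$h1) %*% dpre2
  db2 <- colSums(dpre2)
  dh1 <- dpre2 %*% t(dec$W2)
  dpre1 <- dh1 * (cache$pre1 > 0)
  dW1 <- t(cache$fin) %*% dpre1
  db1 <- colSums(dpre1)
  C <- cfg$embed_dim
  dX <- dpre1 %*% t(dec$W1)
  dfin <- dX[, seq_len(C), drop = FALSE]
  du <- dX[, C + 1L]
  dprj <- colSums(dfin)
  dtok <- sweep(dfin, 2, cache$scl, "*")
  grads <- list(Wprj = matrix(0, C, C), Wscale = matrix(0, C, C),
                p_null = numeric(C),
                W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  dfp <- NULL
  if (is.null(cache$fp)) {
    grads$p_null <- dprj
  } else {
    dscl <- colSums(dfin * cache$tok)
    grads$Wprj <- outer(cache$fp, dprj)
    grads$Wscale <- outer(cache$fp, dscl)
    dfp <- as.vector(dec$Wprj %*% dprj) + as.vector(dec$Wscale %*% dscl) +
      as.vector(t(positional_encoding(cfg)) %*% du)
  }
  list(params = grads, dtok = dtok, dfp = dfp)
}

#' Decode an embedding grid (and optional prompt) into a probability map
#'
#' A prompt-conditioned per-token MLP expands each embedding token into a
#' 4x4 block of logits, giving a sigmoid probability map of side
#' `4 * grid_size` (256 at paper scale, 32 at tiny scale).  With `f_p =
#' NULL` the decoder runs prompt-free, substituting a learned null-prompt
#' embedding -- the promptable and prompt-free paths share all other
#' parameters.
#'
#' @param f A `grid_size` x `grid_size` x `embed_dim` embedding array.
#' @param model An `sf_model`.
#' @param f_p Optional prompt feature of length `embed_dim`.
#' @return A probability matrix with values in (0, 1).
#' @export
decode_mask <- function(f, model, f_p = NULL) {
  cfg <- model$config
  stopifnot(length(dim(f)) == 3L, dim(f)[1] == cfg$grid_size,
            dim(f)[2] == cfg$grid_size, dim(f)[3] == cfg$embed_dim)
  decoder_forward(grid_to_tokens(f), f_p, model$params$decoder, cfg)$prob
}

#' Threshold a probability map into a binary mask
#'
#' The fixed threshold is 0.5.  An Otsu histogram threshold is available
#' behind `method = "otsu"` for exploration, but the fixed threshold is the
#' documented behavior.
#'
#' @param prob Probability matrix in `[0, 1]`.
#' @param method `"fixed"` (default, threshold 0.5) or `"otsu"`.
#' @return An integer binary matrix.
#' @export
threshold_mask <- function(prob, method = c("fixed", "otsu")) {
  method <- match.arg(method)
  thr <- if (method == "fixed") 0.5 else EBImage::otsu(prob, range = c(0, 1))
  as_binary_mask((prob >= thr) * 1L)
}

# ---- freezing ---------------------------------------------------------------

#' Freeze parameter groups of a model
#'
#' Frozen groups receive no updates from any optimizer step; the training
#' functions assert this via [param_checksum()].
#'
#' @param model An `sf_model`.
#' @param groups Character vector of parameter-group names
#'   (subset of `names(model$params)`).
#' @return The model with the groups marked frozen.
#' @export
freeze <- function(model, groups = c("encoder", "prompt", "decoder")) {
  stopifnot(all(groups %in% names(model$params)))
  model$frozen <- union(model$frozen, groups)
  model
}

#' List the trainable (non-frozen) parameters of a model
#'
#' @param model An `sf_model`.
#' @return A named list (one entry per non-frozen group) of parameter lists.
#' @export
trainable_parameters <- function(model) {
  model$params[setdiff(names(model$params), model$frozen)]
}

#' Build backbone parameters from externally supplied arrays
#'
#' Adapter slot for pre-trained weights: takes a named list with `encoder`,
#' `prompt` and `decoder` entries whose arrays must match the shapes of the
#' stand-in backbone at the given config, validates them, and installs them
#' frozen.  Downstream modules behave identically with stand-in or external
#' weights.
#'
#' @param model An `sf_model` whose backbone is replaced.
#' @param arrays Named list of parameter arrays.
#' @return The model with the external backbone installed and frozen.
#' @export
backbone_from_arrays <- function(model, arrays) {
  stopifnot(all(c("encoder", "prompt", "decoder") %in% names(arrays)))
  for (grp in c("encoder", "prompt", "decoder")) {
    ref <- model$params[[grp]]
    stopifnot(setequal(names(arrays[[grp]]), names(ref)))
    for (nm in names(ref)) {
      a <- arrays[[grp]][[nm]]
      if (!identical(dim(a) %||% length(a), dim(ref[[nm]]) %||%
                     length(ref[[nm]]))) {
        stop("shape mismatch for ", grp, "$", nm, call. = FALSE)
      }
      model$params[[grp]][[nm]] <- a
    }
  }
  freeze(model, c("encoder", "prompt", "decoder"))
}

#' @export
print.sf_model <- function(x, ...) {
  np <- function(p) sum(lengths(lapply(unlist(p, recursive = FALSE),
                                       function(v) v)))
  cat("<sf_model> preset=", x$config$preset,
      " input=", x$config$input_size,
      " grid=", x$config$grid_size,
      " C=", x$config$embed_dim, "\n", sep = "")
  cat("  frozen groups: ",
      if (length(x$frozen)) paste(x$frozen, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}
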