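# Multi-modal fusion module (MFM): three multi-head cross-attention blocks
# (stacked-modality embedding as query, one single-modality embedding as
# key/value) followed by two-stage multi-scale modality attention (MSMA)
# producing per-channel significance scores for the three modalities.

init_mhca <- function(cfg) {
  C <- cfg$embed_dim
  list(Wq = kaiming_matrix(C, C), Wk = kaiming_matrix(C, C),
       Wv = kaiming_matrix(C, C), Wo = kaiming_matrix(C, C),
       bo = numeric(C))
}

init_msma <- function(cfg) {
  C <- cfg$embed_dim; Hb <- max(1L, C %/% 4L)
  list(W1 = kaiming_matrix(C, Hb), b1 = numeric(Hb),
       W2 = kaiming_matrix(Hb, 3L * C), b2 = numeric(3L * C))
}

init_mfm <- function(cfg) {
  list(t = init_mhca(cfg), d = init_mhca(cfg), a = init_mhca(cfg),
       s1 = init_msma(cfg), s2 = init_msma(cfg))
}

# ---- multi-head cross-attention ---------------------------------------------

mhca_forward <- function(Tq, Tkv, par, n_heads, want_cache = FALSE) {
  C <- ncol(Tq)
  stopifnot(identical(dim(Tq), dim(Tkv)))
  if (C %% n_heads != 0L) stop("head count must divide embed_dim",
                               call. = FALSE)
  dh <- C %/% n_heads
  lnq <- layernorm_rows(Tq)
  lnk <- layernorm_rows(Tkv)
  Q <- lnq$y %*% par$Wq
  K <- lnk$y %*% par$Wk
  V <- lnk$y %*% par$Wv
  O <- matrix(0, nrow(Tq), C)
  A <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmax_rows(S)
    O[, idx] <- A[[h]] %*% V[, idx, drop = FALSE]
  }
  out <- sweep(O %*% par$Wo, 2, par$bo, "+")
  res <- list(out = out, attn = A)
  if (want_cache) c(res, list(lnq = lnq, lnk = lnk, Q = Q, K = K, V = V,
                              O = O, n_heads = n_heads, dh = dh))
  else res
}

mhca_backward <- function(dout, cache, par) {
  dh <- cache$dh
  dWo <- t(cache$O) %*% dout
  dbo <- colSums(dout)
  dO <- dout %*% t(par$Wo)
  dQ <- dK <- dV <- matrix(0, nrow(dout), ncol(dout))
  for (h in seq_len(cache$n_heads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- cache$attn[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A))
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE] / sqrt(dh)
    dK[, idx] <- t(dS) %*% cache$Q[, idx, drop = FALSE] / sqrt(dh)
  }
  dlnq <- dQ %*% t(par$Wq)
  dlnk <- dK %*% t(par$Wk) + dV %*% t(par$Wv)
  list(params = list(Wq = t(cache$lnq$y) %*% dQ,
                     Wk = t(cache$lnk$y) %*% dK,
                     Wv = t(cache$lnk$y) %*% dV,
                     Wo = dWo, bo = dbo),
       dTq = layernorm_rows_bwd(dlnq, cache$lnq),
       dTkv = layernorm_rows_bwd(dlnk, cache$lnk))
}

#' Multi-head cross-attention between two embedding grids
#'
#' Query tokens come from the stacked-modality embedding, keys and values
#' from one single-modality embedding.  Query and key/value tokens are
#' layer-normalized, projected per head, combined by scaled-dot-product
#' softmax attention, and output-projected.  No residual or feed-forward
#' sublayer is applied; the block is plain cross-attention.
#'
#' @param query,key_value `g` x `g` x `C` embedding arrays of equal shape.
#' @param params An MHCA parameter set (`Wq`, `Wk`, `Wv`, `Wo`, `bo`).
#' @param n_heads Number of attention heads (must divide `C`).
#' @return A `g` x `g` x `C` array; per-head attention matrices (rows sum to
#'   1 over key tokens) are attached as attribute `"attention"`.
#' @export
mhca <- function(query, key_value, params, n_heads = 2L) {
  stopifnot(length(dim(query)) == 3L, identical(dim(query), dim(key_value)))
  g <- dim(query)[1]
  res <- mhca_forward(grid_to_tokens(query), grid_to_tokens(key_value),
                      params, n_heads)
  out <- tokens_to_grid(res$out, g)
  attr(out, "attention") <- res$attn
  out
}

# ---- multi-scale modality attention -----------------------------------------

# Adaptive pooling region id per token for an L x L local grid.
msma_regions <- function(g, L) {
  r <- rep(seq_len(g), each = g)
  cc <- rep(seq_len(g), times = g)
  rr <- floor((r - 1) * L / g) + 1L
  rc <- floor((cc - 1) * L / g) + 1L
  as.integer((rr - 1L) * L + rc)
}

msma_forward <- function(S, par, g, want_cache = FALSE) {
  if (!all(is.finite(S))) stop("non-finite input to modality attention",
                               call. = FALSE)
  C <- ncol(S); N <- nrow(S)
  L <- min(4L, g)
  reg <- msma_regions(g, L)
  counts <- tabulate(reg, nbins = L * L)
  Preg <- rowsum(S, reg) / counts
  P <- rbind(colMeans(S), Preg)            # global pool + local pools
  Zpre <- sweep(P %*% par$W1, 2, par$b1, "+")
  Z <- relu(Zpre)
  Lg <- sweep(Z %*% par$W2, 2, par$b2, "+")
  nreg <- nrow(Preg)
  logits <- Lg[1, ] + colMeans(Lg[-1, , drop = FALSE])
  Lmat <- matrix(logits, C, 3L)            # channel x (t, d, a)
  W <- softmax_rows(Lmat)
  res <- list(weights = W)
  if (want_cache) c(res, list(P = P, Zpre = Zpre, Z = Z, reg = reg,
                              counts = counts, nreg = nreg, N = N))
  else res
}

msma_backward <- function(dW, cache, par, weights) {
  C <- nrow(dW)
  dLmat <- weights * (dW - rowSums(dW * weights))
  dlogits <- as.vector(dLmat)
  dLg <- rbind(dlogits,
               matrix(rep(dlogits / cache$nreg, each = cache$nreg),
                      cache$nreg, length(dlogits)))
  dW2 <- t(cache$Z) %*% dLg
  db2 <- colSums(dLg)
  dZ <- dLg %*% t(par$W2)
  dZpre <- dZ * (cache$Zpre > 0)
  dW1 <- t(cache$P) %*% dZpre
  db1 <- colSums(dZpre)
  dP <- dZpre %*% t(par$W1)
  dS <- matrix(rep(dP[1, ] / cache$N, each = cache$N), cache$N, C)
  dS <- dS + (dP[-1, , drop = FALSE] / cache$counts)[cache$reg, , drop = FALSE]
  list(params = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dS = dS)
}

#' Per-channel modality significance scores
#'
#' Channel attention over global and local spatial scales: the summed
#' modality features are average-pooled globally (1x1) and locally (up to a
#' 4x4 grid of regions), each pooled vector passes through a shared
#' bottleneck MLP (reduction ratio 4) emitting `3 * C` logits, branch logits
#' are averaged within the local branch and summed across branches, and a
#' softmax across the modality axis yields per-channel scores
#' `(alpha, beta, gamma)` that are in `[0, 1]` and sum to one per channel.
#'
#' @param summed A `g` x `g` x `C` array: the elementwise sum of the three
#'   modality features entering the stage.
#' @param params An MSMA parameter set (`W1`, `b1`, `W2`, `b2`).
#' @return An object of class `fusion_weights`: list with `alpha`, `beta`,
#'   `gamma` (each length `C`, for the T2W-, DWI- and ADC-derived features).
#' @export
msma_scores <- function(summed, params) {
  stopifnot(length(dim(summed)) == 3L, dim(summed)[1] == dim(summed)[2])
  g <- dim(summed)[1]
  W <- msma_forward(grid_to_tokens(summed), params, g)$weights
  structure(list(alpha = W[, 1], beta = W[, 2], gamma = W[, 3]),
            class = "fusion_weights")
}

# ---- full MFM ---------------------------------------------------------------

# Column-broadcast multiply: each channel c of tokens scaled by w[c].
scale_channels <- function(tok, w) sweep(tok, 2, w, "*")

mfm_fwd <- function(Tall, Tt, Td, Ta, par, cfg, want_cache = FALSE) {
  g <- cfg$grid_size
  mt <- mhca_forward(Tall, Tt, par$t, cfg$n_heads, want_cache)
  md <- mhca_forward(Tall, Td, par$d, cfg$n_heads, want_cache)
  ma <- mhca_forward(Tall, Ta, par$a, cfg$n_heads, want_cache)
  s1in <- mt$out + md$out + ma$out
  m1 <- msma_forward(s1in, par$s1, g, want_cache)
  W1 <- m1$weights
  s1 <- scale_channels(mt$out, W1[, 1]) + scale_channels(md$out, W1[, 2]) +
    scale_channels(ma$out, W1[, 3])
  m2 <- msma_forward(s1, par$s2, g, want_cache)
  W2 <- m2$weights
  # stage 2 weights the ORIGINAL cross-attended features again
  out <- scale_channels(mt$out, W2[, 1]) + scale_channels(md$out, W2[, 2]) +
    scale_channels(ma$out, W2[, 3])
  res <- list(out = out, W1 = W1, W2 = W2)
  if (want_cache) c(res, list(mt = mt, md = md, ma = ma, m1 = m1, m2 = m2))
  else res
}

mfm_bwd <- function(dout, cache, par) {
  W1 <- cache$W1; W2 <- cache$W2
  ft <- cache$mt$out; fd <- cache$md$out; fa <- cache$ma$out
  # stage-2 weighting
  dft <- scale_channels(dout, W2[, 1])
  dfd <- scale_channels(dout, W2[, 2])
  dfa <- scale_channels(dout, W2[, 3])
  dW2 <- cbind(colSums(dout * ft), colSums(dout * fd), colSums(dout * fa))
  b2 <- msma_backward(dW2, cache$m2, par$s2, W2)
  ds1 <- b2$dS
  # stage-1 weighted sum feeding MSMA stage 2
  dft <- dft + scale_channels(ds1, W1[, 1])
  dfd <- dfd + scale_channels(ds1, W1[, 2])
  dfa <- dfa + scale_channels(ds1, W1[, 3])
  dW1 <- cbind(colSums(ds1 * ft), colSums(ds1 * fd), colSums(ds1 * fa))
  b1 <- msma_backward(dW1, cache$m1, par$s1, W1)
  dft <- dft + b1$dS
  dfd <- dfd + b1$dS
  dfa <- dfa + b1$dS
  bt <- mhca_backward(dft, cache$mt, par$t)
  bd <- mhca_backward(dfd, cache$md, par$d)
  ba <- mhca_backward(dfa, cache$ma, par$a)
  list(params = list(t = bt$params, d = bd$params, a = ba$params,
                     s1 = b1$params, s2 = b2$params),
       dTall = bt$dTq + bd$dTq + ba$dTq,
       dTt = bt$dTkv, dTd = bd$dTkv, dTa = ba$dTkv)
}

#' Fuse the four image embeddings through the multi-modal fusion module
#'
#' Implements the full fusion pipeline: `f_m' = MHCA_m(f_all; f_m)` for each
#' modality, stage-1 significance scores from `f_t' + f_d' + f_a'` weight
#' the `f_m'`, stage-2 scores computed from the stage-1 weighted sum weight
#' the original `f_m'` again, and the fused embedding is the sum of the
#' stage-2 weighted features.  Shape is preserved.
#'
#' @param f_all,f_t,f_d,f_a `g` x `g` x `C` embedding arrays (stacked input,
#'   T2W, DWI, ADC).
#' @param params An MFM parameter set from [model_init()] (`mfm_pf` or
#'   `mfm_g` entry).
#' @param config A [backbone_config()].
#' @return The fused `g` x `g` x `C` array, with stage-1/stage-2
#'   [msma_scores()]-style weights attached as attributes `"stage1"` and
#'   `"stage2"`.
#' @export
mfm_forward <- function(f_all, f_t, f_d, f_a, params, config) {
  stopifnot(identical(dim(f_all), dim(f_t)), identical(dim(f_all), dim(f_d)),
            identical(dim(f_all), dim(f_a)))
  g <- dim(f_all)[1]
  res <- mfm_fwd(grid_to_tokens(f_all), grid_to_tokens(f_t),
                 grid_to_tokens(f_d), grid_to_tokens(f_a), params, config)
  out <- tokens_to_grid(res$out, g)
  attr(out, "stage1") <- structure(list(alpha = res$W1[, 1],
                                        beta = res$W1[, 2],
                                        gamma = res$W1[, 3]),
                                   class = "fusion_weights")
  attr(out, "stage2") <- structure(list(alpha = res$W2[, 1],
                                        beta = res$W2[, 2],
                                        gamma = res$W2[, 3]),
                                   class = "fusion_weights")
  out
}
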