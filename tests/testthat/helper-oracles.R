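# Brute-force oracles written independently of the package internals: all
# computations are explicit elementwise loops over tokens, channels and
# heads, so they can serve as references for the vectorized implementation.

oracle_layernorm <- function(x, eps = 1e-6) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    v <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(v + eps)
  }
  out
}

oracle_linear <- function(x, W, b = NULL) {
  out <- matrix(0, nrow(x), ncol(W))
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(W))) {
      s <- 0
      for (k in seq_len(ncol(x))) s <- s + x[i, k] * W[k, j]
      out[i, j] <- s + if (is.null(b)) 0 else b[j]
    }
  }
  out
}

# Cross-attention: query tokens from Tq, keys/values from Tkv, pre-LN,
# per-head softmax(Q K' / sqrt(d)) V, concatenated and output-projected.
oracle_mhca <- function(Tq, Tkv, par, n_heads) {
  C <- ncol(Tq)
  dh <- C / n_heads
  Qn <- oracle_layernorm(Tq)
  Kn <- oracle_layernorm(Tkv)
  Q <- oracle_linear(Qn, par$Wq)
  K <- oracle_linear(Kn, par$Wk)
  V <- oracle_linear(Kn, par$Wv)
  O <- matrix(0, nrow(Tq), C)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    for (i in seq_len(nrow(Tq))) {
      scores <- numeric(nrow(Tkv))
      for (j in seq_len(nrow(Tkv))) {
        s <- 0
        for (d in idx) s <- s + Q[i, d] * K[j, d]
        scores[j] <- s / sqrt(dh)
      }
      a <- exp(scores - max(scores))
      a <- a / sum(a)
      for (d in idx) {
        acc <- 0
        for (j in seq_len(nrow(Tkv))) acc <- acc + a[j] * V[j, d]
        O[i, d] <- acc
      }
    }
  }
  oracle_linear(O, par$Wo, par$bo)
}

# Channel attention over global + local average pools with a shared
# bottleneck; softmax over the modality axis per channel.
oracle_msma <- function(S, par, g) {
  C <- ncol(S)
  L <- min(4, g)
  mlp <- function(p) {
    z <- numeric(length(par$b1))
    for (j in seq_along(z)) {
      s <- 0
      for (k in seq_len(C)) s <- s + p[k] * par$W1[k, j]
      z[j] <- max(s + par$b1[j], 0)
    }
    l <- numeric(3 * C)
    for (j in seq_along(l)) {
      s <- 0
      for (k in seq_along(z)) s <- s + z[k] * par$W2[k, j]
      l[j] <- s + par$b2[j]
    }
    l
  }
  pg <- numeric(C)
  for (k in seq_len(C)) pg[k] <- mean(S[, k])
  logits <- mlp(pg)
  loc <- matrix(0, L * L, 3 * C)
  cnt <- numeric(L * L)
  for (tok in seq_len(nrow(S))) {
    r <- (tok - 1) %/% g + 1
    cc <- (tok - 1) %% g + 1
    reg <- (floor((r - 1) * L / g)) * L + floor((cc - 1) * L / g) + 1
    cnt[reg] <- cnt[reg] + 1
  }
  pool <- matrix(0, L * L, C)
  for (tok in seq_len(nrow(S))) {
    r <- (tok - 1) %/% g + 1
    cc <- (tok - 1) %% g + 1
    reg <- (floor((r - 1) * L / g)) * L + floor((cc - 1) * L / g) + 1
    for (k in seq_len(C)) pool[reg, k] <- pool[reg, k] + S[tok, k] / cnt[reg]
  }
  for (reg in seq_len(L * L)) loc[reg, ] <- mlp(pool[reg, ])
  for (j in seq_len(3 * C)) logits[j] <- logits[j] + mean(loc[, j])
  W <- matrix(0, C, 3)
  for (k in seq_len(C)) {
    l3 <- c(logits[k], logits[C + k], logits[2 * C + k])
    e <- exp(l3 - max(l3))
    W[k, ] <- e / sum(e)
  }
  W
}

# Straight-line fusion oracle: three cross-attention blocks, stage-1 scores
# from the summed features weight them, stage-2 scores from the stage-1
# weighted sum weight the ORIGINAL cross-attended features again.
oracle_mfm <- function(Tall, Tt, Td, Ta, par, g, n_heads) {
  ft <- oracle_mhca(Tall, Tt, par$t, n_heads)
  fd <- oracle_mhca(Tall, Td, par$d, n_heads)
  fa <- oracle_mhca(Tall, Ta, par$a, n_heads)
  W1 <- oracle_msma(ft + fd + fa, par$s1, g)
  s1 <- ft
  for (k in seq_len(ncol(ft))) {
    s1[, k] <- W1[k, 1] * ft[, k] + W1[k, 2] * fd[, k] + W1[k, 3] * fa[, k]
  }
  W2 <- oracle_msma(s1, par$s2, g)
  out <- ft
  for (k in seq_len(ncol(ft))) {
    out[, k] <- W2[k, 1] * ft[, k] + W2[k, 2] * fd[, k] + W2[k, 3] * fa[, k]
  }
  out
}
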