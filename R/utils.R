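# Internal numeric helpers shared across modules.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(m) {
  e <- exp(m - apply(m, 1L, max))
  e / rowSums(e)
}

# Per-row (per-token) layer normalization without learnable affine.
layernorm_rows <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd_ <- sqrt(rowMeans(xc^2) + eps)
  list(y = xc / sd_, xc = xc, sd = sd_)
}

layernorm_rows_bwd <- function(dy, cache) {
  y <- cache$xc / cache$sd
  (dy - rowMeans(dy) - y * rowMeans(dy * y)) / cache$sd
}

# 2-D arrays are [row, col]; boxes are (x_min, y_min, x_max, y_max),
# 0-based half-open, x = column, y = row.

as_binary_mask <- function(m) {
  stopifnot(is.matrix(m))
  mode(m) <- "integer"
  m[m != 0L] <- 1L
  m
}

# Nearest-neighbour upsampling by an integer factor.
upsample_nearest <- function(m, factor) {
  m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor),
    drop = FALSE]
}

# Block-mean downsampling by an integer factor (used to bring masks to the
# decoder's output resolution); >= 0.5 block occupancy maps to foreground.
downsample_mask <- function(m, factor) {
  nr <- nrow(m) %/% factor
  nc <- ncol(m) %/% factor
  a <- array(m[seq_len(nr * factor), seq_len(nc * factor)],
             c(factor, nr, factor, nc))
  blk <- apply(a, c(2L, 4L), mean)
  as_binary_mask((blk >= 0.5) * 1L)
}

# Rotate a 2-D image about its centre, keeping size; outside pixels get 0.
rotate_image <- function(img, angle_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (angle_deg == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  ys <- rep(seq_len(n), times = m) - cy
  xs <- rep(seq_len(m), each = n) - cx
  # inverse mapping: source coordinates for each target pixel
  sy <- cos(th) * ys - sin(th) * xs + cy
  sx <- sin(th) * ys + cos(th) * xs + cx
  if (method == "nearest") {
    ri <- round(sy); ci <- round(sx)
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
    out <- numeric(n * m)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sy); c0 <- floor(sx)
    fr <- sy - r0; fc <- sx - c0
    val <- function(r, c) {
      ok <- r >= 1 & r <= n & c >= 1 & c <= m
      v <- numeric(length(r))
      v[ok] <- img[cbind(r[ok], c[ok])]
      v
    }
    out <- (1 - fr) * (1 - fc) * val(r0, c0) +
      (1 - fr) * fc * val(r0, c0 + 1) +
      fr * (1 - fc) * val(r0 + 1, c0) +
      fr * fc * val(r0 + 1, c0 + 1)
  }
  matrix(out, n, m)
}

# 8- or 4-connected component labelling (EBImage::bwlabel is 4-connected,
# lesion blobs are conventionally labelled with 8-connectivity).
label_components <- function(mask, connectivity = 8L) {
  mask <- as_binary_mask(mask)
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 0L, 0L, 1L)
    dc <- c(0L, -1L, 1L, 0L)
  }
  cur <- 0L
  fg <- which(mask == 1L)
  stack <- integer(n * m)
  for (s in fg) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- s
    lab[s] <- cur
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      pr <- ((p - 1L) %% n) + 1L
      pc <- ((p - 1L) %/% n) + 1L
      for (k in seq_along(dr)) {
        r2 <- pr + dr[k]; c2 <- pc + dc[k]
        if (r2 < 1L || r2 > n || c2 < 1L || c2 > m) next
        q <- r2 + (c2 - 1L) * n
        if (mask[q] == 1L && lab[q] == 0L) {
          lab[q] <- cur
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

# ---- parameter trees (nested named lists of numeric arrays) ----

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

param_zeros_like <- function(p) param_map(p, function(x) x * 0)

#' Checksum of a parameter tree
#'
#' A cheap deterministic fingerprint (sum of absolute values plus element
#' count) used to verify the freeze contract: frozen parameter groups must
#' have identical checksums before and after optimization.
#'
#' @param p A (possibly nested) named list of numeric arrays.
#' @return A single numeric value.
#' @export
param_checksum <- function(p) {
  v <- unlist(p, use.names = FALSE)
  sum(abs(v)) + length(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
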