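test_that("a single key token receives softmax weight exactly 1", {
  cfg <- backbone_config("tiny", input_size = 16, grid_size = 1,
                         embed_dim = 4, n_heads = 1)
  withr::with_seed(1, {
    par <- sf_ns$init_mhca(cfg)
    q <- rand_grid(1, 4)
    kv <- rand_grid(1, 4)
  })
  out <- mhca(q, kv, par, n_heads = 1)
  a <- attr(out, "attention")[[1]]
  expect_equal(as.numeric(a), 1)
  # output equals the output-projection of the (normalized) value
  v <- oracle_layernorm(matrix(kv[1, 1, ], 1)) %*% par$Wv
  expect_equal(as.numeric(out[1, 1, ]),
               as.numeric(v %*% par$Wo + par$bo), tolerance = 1e-12)
})

test_that("identical values across keys make the output query-independent", {
  cfg <- tiny3_config()
  withr::with_seed(2, {
    par <- sf_ns$init_mhca(cfg)
    kv_row <- rnorm(4)
    kv <- array(rep(kv_row, each = 9), c(3, 3, 4))
    q1 <- rand_grid(3, 4)
    q2 <- rand_grid(3, 4)
  })
  o1 <- mhca(q1, kv, par, 1)
  o2 <- mhca(q2, kv, par, 1)
  expect_equal(as.vector(o1), as.vector(o2), tolerance = 1e-10)
})

test_that("attention weights are a distribution over key tokens", {
  cfg <- tiny3_config(embed_dim = 8, n_heads = 2)
  withr::with_seed(3, {
    par <- sf_ns$init_mhca(cfg)
    out <- mhca(rand_grid(3, 8), rand_grid(3, 8), par, 2)
  })
  for (a in attr(out, "attention")) {
    expect_true(all(a >= 0))
    expect_equal(rowSums(a), rep(1, 9), tolerance = 1e-12)
  }
  expect_error(mhca(rand_grid(3, 8), rand_grid(3, 8), par, 3), "divide")
})

test_that("cross-attention matches the brute-force loop oracle", {
  cfg <- tiny3_config()
  for (seed in 1:5) {
    withr::with_seed(seed, {
      par <- sf_ns$init_mhca(cfg)
      q <- rand_tokens(9, 4)
      kv <- rand_tokens(9, 4)
    })
    got <- sf_ns$mhca_forward(q, kv, par, 1)$out
    expect_lt(max(abs(got - oracle_mhca(q, kv, par, 1))), 1e-5)
  }
})

test_that("a zeroed score head yields uniform 1/3 significance scores", {
  cfg <- backbone_config("tiny")
  par <- sf_ns$init_msma(cfg)
  par$W1[] <- 0; par$b1[] <- 0; par$W2[] <- 0; par$b2[] <- 0
  w <- msma_scores(array(0, c(8, 8, 32)), par)
  expect_equal(w$alpha, rep(1 / 3, 32))
  expect_equal(w$beta, rep(1 / 3, 32))
  expect_equal(w$gamma, rep(1 / 3, 32))
})

test_that("significance scores are in [0,1] and sum to one per channel", {
  cfg <- backbone_config("tiny")
  for (seed in 1:5) {
    withr::with_seed(seed, {
      par <- sf_ns$init_msma(cfg)
      s <- rand_grid(8, 32)
    })
    w <- msma_scores(s, par)
    sc <- cbind(w$alpha, w$beta, w$gamma)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(rowSums(sc), rep(1, 32), tolerance = 1e-12)
  }
  expect_error(msma_scores(array(NaN, c(8, 8, 32)), par), "finite")
})

test_that("scores of a constant input do not depend on the spatial size", {
  cfg <- backbone_config("tiny")
  withr::with_seed(4, par <- sf_ns$init_msma(cfg))
  v <- rnorm(32)
  s8 <- array(rep(v, each = 64), c(8, 8, 32))
  s16 <- array(rep(v, each = 256), c(16, 16, 32))
  w8 <- msma_scores(s8, par)
  w16 <- msma_scores(s16, par)
  expect_equal(w8$alpha, w16$alpha, tolerance = 1e-12)
  expect_equal(w8$gamma, w16$gamma, tolerance = 1e-12)
})

test_that("channel attention matches the loop oracle", {
  cfg <- tiny3_config()
  for (seed in 1:5) {
    withr::with_seed(seed, {
      par <- sf_ns$init_msma(cfg)
      s <- rand_tokens(9, 4)
    })
    got <- sf_ns$msma_forward(s, par, 3)$weights
    expect_lt(max(abs(got - oracle_msma(s, par, 3))), 1e-5)
  }
})

test_that("the fused embedding preserves shape and matches the oracle", {
  cfg <- tiny3_config()
  for (seed in 1:5) {
    withr::with_seed(seed, {
      par <- sf_ns$init_mfm(cfg)
      gs <- replicate(4, rand_grid(3, 4), simplify = FALSE)
    })
    out <- mfm_forward(gs[[1]], gs[[2]], gs[[3]], gs[[4]], par, cfg)
    expect_identical(dim(out), c(3L, 3L, 4L))
    ora <- oracle_mfm(sf_ns$grid_to_tokens(gs[[1]]),
                      sf_ns$grid_to_tokens(gs[[2]]),
                      sf_ns$grid_to_tokens(gs[[3]]),
                      sf_ns$grid_to_tokens(gs[[4]]),
                      par, 3, 1)
    expect_lt(max(abs(sf_ns$grid_to_tokens(out) - ora)), 1e-5)
  }
})

test_that("stage-2 scores forced to (1,0,0) reduce the fusion to f_t'", {
  cfg <- backbone_config("tiny")
  withr::with_seed(6, {
    par <- sf_ns$init_mfm(cfg)
    gs <- replicate(4, rand_grid(8, 32), simplify = FALSE)
  })
  par$s2$W1[] <- 0; par$s2$b1[] <- 0; par$s2$W2[] <- 0
  par$s2$b2 <- c(rep(60, 32), rep(0, 32), rep(0, 32))
  out <- mfm_forward(gs[[1]], gs[[2]], gs[[3]], gs[[4]], par, cfg)
  ft <- mhca(gs[[1]], gs[[2]], par$t, cfg$n_heads)
  expect_equal(as.vector(out), as.vector(ft), tolerance = 1e-8)
})

test_that("permuting modalities with their parameter blocks leaves f'
          unchanged", {
  cfg <- tiny3_config()
  withr::with_seed(7, {
    par <- sf_ns$init_mfm(cfg)
    gs <- replicate(4, rand_grid(3, 4), simplify = FALSE)
  })
  base <- mfm_forward(gs[[1]], gs[[2]], gs[[3]], gs[[4]], par, cfg)
  C <- 4
  blk <- function(i) ((i - 1) * C + 1):(i * C)
  perm_cols <- c(blk(2), blk(3), blk(1))      # (t,d,a) -> (d,a,t)
  par2 <- par
  par2$t <- par$d; par2$d <- par$a; par2$a <- par$t
  for (st in c("s1", "s2")) {
    par2[[st]]$W2 <- par[[st]]$W2[, perm_cols]
    par2[[st]]$b2 <- par[[st]]$b2[perm_cols]
  }
  permuted <- mfm_forward(gs[[1]], gs[[3]], gs[[4]], gs[[2]], par2, cfg)
  expect_equal(as.vector(permuted), as.vector(base), tolerance = 1e-10)
})

test_that("fusion stays finite for inputs in [-10, 10]", {
  cfg <- backbone_config("tiny")
  withr::with_seed(8, {
    par <- sf_ns$init_mfm(cfg)
    gs <- replicate(4, array(runif(8 * 8 * 32, -10, 10), c(8, 8, 32)),
                    simplify = FALSE)
  })
  out <- mfm_forward(gs[[1]], gs[[2]], gs[[3]], gs[[4]], par, cfg)
  expect_true(all(is.finite(out)))
})

test_that("the two fusion modules of a model hold distinct parameters", {
  m <- model_init(backbone_config("tiny"), seed = 9)
  expect_false(identical(m$params$mfm_pf, m$params$mfm_g))
})
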