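test_that("morphological post-processing removes isolated specks", {
  m <- matrix(0L, 9, 9)
  m[5, 5] <- 1L
  res <- postprocess(m, min_area = 0)
  expect_identical(sum(res$mask), 0L)
  expect_length(res$components, 0)
})

test_that("a 1-px gap between blobs is bridged by the merging closing", {
  m <- matrix(0L, 15, 15)
  m[4:8, 3:7] <- 1L
  m[4:8, 9:13] <- 1L            # 1-px gap at column 8
  res <- postprocess(m, merge_radius = 2, min_area = 0)
  expect_length(res$components, 1)
  expect_true(all(res$mask[4:8, 3:13] == 1L))
})

test_that("far-apart blobs stay separate single-lesion components", {
  m <- matrix(0L, 40, 40)
  m[3:7, 3:7] <- 1L
  m[30:34, 30:34] <- 1L
  res <- postprocess(m, min_area = 0)
  expect_length(res$components, 2)
  expect_identical(Reduce(`+`, res$components), unclass(res$mask))
  expect_identical(sum(res$components[[1]] * res$components[[2]]), 0L)
})

test_that("empty masks post-process to empty results", {
  res <- postprocess(matrix(0L, 10, 10))
  expect_identical(sum(res$mask), 0L)
  expect_length(res$components, 0)
})

test_that("post-processing is idempotent on phantom-like masks", {
  for (seed in 1:4) {
    tr <- generate_slice(phantom_spec(seed = seed))
    noisy <- tr$mask
    withr::with_seed(seed, {
      specks <- sample(length(noisy), 25)
      noisy[specks] <- 1L
    })
    once <- postprocess(noisy)
    twice <- postprocess(once$mask)
    expect_identical(unclass(twice$mask), unclass(once$mask))
  }
})

test_that("box expansion arithmetic matches the worked example", {
  m <- matrix(0L, 40, 40)
  m[11:20, 11:20] <- 1L          # tight box (10,10,20,20), w = h = 10
  b <- box_from_mask(m, 0.15)
  expect_identical(as.numeric(b), c(9, 9, 21, 21))
  expect_identical(as.numeric(box_from_mask(m, 0)), c(10, 10, 20, 20))
})

test_that("expanded boxes clamp to the image and contain the tight box", {
  m <- matrix(0L, 12, 12)
  m[1:5, 1:5] <- 1L              # touches (0, 0)
  b <- box_from_mask(m, 0.15)
  expect_identical(as.numeric(b[c("x_min", "y_min")]), c(0, 0))
  for (seed in 1:10) {
    tr <- withr::with_seed(seed, {
      n <- 30
      mm <- matrix(0L, n, n)
      r <- sort(sample(n, 2)); cc <- sort(sample(n, 2))
      mm[r[1]:r[2], cc[1]:cc[2]] <- 1L
      mm
    })
    tight <- box_from_mask(tr, 0)
    grown <- box_from_mask(tr, 0.15)
    expect_lte(grown[["x_min"]], tight[["x_min"]])
    expect_lte(grown[["y_min"]], tight[["y_min"]])
    expect_gte(grown[["x_max"]], tight[["x_max"]])
    expect_gte(grown[["y_max"]], tight[["y_max"]])
    expect_gte(grown[["x_min"]], 0)
    expect_lte(grown[["x_max"]], 30)
  }
  expect_error(box_from_mask(matrix(0L, 5, 5)), "empty")
})

test_that("refinement converges immediately when the decoder echoes m0", {
  m0 <- matrix(0L, 32, 32)
  m0[10:20, 10:20] <- 1L
  dec <- function(f, fp) m0 + 0           # probability 1 inside m0
  r <- refine_box(NULL, m0, function(b) b, dec)
  expect_true(r$trace$converged)
  expect_identical(r$trace$iterations, 1L)
  expect_identical(unclass(r$mask), unclass(segfuse:::as_binary_mask(m0)))
  expect_equal(r$trace$dsc_consecutive, 1)
})

test_that("a fixed decoder output different from m0 converges in two
          iterations", {
  m0 <- matrix(0L, 32, 32)
  m0[10:20, 10:20] <- 1L
  M <- matrix(0L, 32, 32)
  M[12:28, 12:28] <- 1L                   # DSC(m0, M) < 0.95
  stopifnot(dsc_pair(m0, M) < 0.95)
  r <- refine_box(NULL, m0, function(b) b, function(f, fp) M + 0)
  expect_true(r$trace$converged)
  expect_identical(r$trace$iterations, 2L)
  expect_identical(unclass(r$mask), unclass(segfuse:::as_binary_mask(M)))
  expect_equal(r$trace$dsc_consecutive[2], 1)
})

test_that("an oscillating decoder hits the iteration cap unconverged", {
  m0 <- matrix(0L, 32, 32); m0[2:6, 2:6] <- 1L
  A <- matrix(0L, 32, 32); A[10:15, 10:15] <- 1L
  B <- matrix(0L, 32, 32); B[20:25, 20:25] <- 1L
  i <- 0
  dec <- function(f, fp) { i <<- i + 1; if (i %% 2) A + 0 else B + 0 }
  r <- refine_box(NULL, m0, function(b) b, dec, max_iter = 10)
  expect_false(r$trace$converged)
  expect_identical(r$trace$iterations, 10L)
  expect_true(all(r$trace$dsc_consecutive < 0.95))
})

test_that("refinement always terminates, for arbitrary decoders", {
  withr::with_seed(77, {
    for (k in 1:100) {
      m0 <- matrix(0L, 16, 16)
      m0[sample(256, 20)] <- 1L
      dec <- local({
        masks <- replicate(3, matrix(runif(256), 16, 16) *
                             (runif(1) < 0.9), simplify = FALSE)
        j <- 0
        function(f, fp) { j <<- j + 1; masks[[(j %% 3) + 1]] }
      })
      r <- refine_box(NULL, m0, function(b) b, dec, max_iter = 10)
      expect_lte(r$trace$iterations, 10L)
      expect_true(sum(r$mask) >= 0)
    }
  })
})

test_that("a decoder collapsing to empty returns the previous mask", {
  m0 <- matrix(0L, 32, 32)
  m0[5:10, 5:10] <- 1L
  r <- refine_box(NULL, m0, function(b) b,
                  function(f, fp) matrix(0, 32, 32))
  expect_false(r$trace$converged)
  expect_identical(unclass(r$mask), unclass(segfuse:::as_binary_mask(m0)))
})

test_that("an untrained zero-bias prompt-free model emits a 0.5 map", {
  m <- frozen_toy_model(seed = 31)
  for (grp in c("encoder", "prompt", "decoder")) {
    m$params[[grp]] <- sf_ns$param_map(m$params[[grp]], function(x) x * 0)
  }
  for (blk in c("t", "d", "a", "s1", "s2")) {
    m$params$mfm_pf[[blk]] <- sf_ns$param_map(m$params$mfm_pf[[blk]],
                                              function(x) x * 0)
  }
  tr <- generate_slice(phantom_spec(n_lesions = 0, seed = 31))
  cs <- coarse_segment(tr, m)
  expect_true(all(abs(cs$prob - 0.5) < 1e-12))
  expect_true(all(cs$mask %in% c(0L, 1L)))
})

test_that("an empty coarse mask yields zero prompts and empty output", {
  m <- frozen_toy_model(seed = 32)
  m$params$decoder$b3 <- rep(-10, 16)     # coarse probabilities near 0
  tr <- generate_slice(phantom_spec(seed = 32))
  boxes <- generate_prompts(tr, m)
  expect_length(boxes, 0)
  seg <- segment_slice(m, tr, prompts = "auto")
  expect_identical(sum(seg$mask), 0L)
})

test_that("generated prompts stay within image bounds", {
  m <- frozen_toy_model(seed = 33)
  tr <- generate_slice(phantom_spec(seed = 33))
  boxes <- generate_prompts(tr, m, max_iter = 3)
  for (b in boxes) {
    expect_gte(b[["x_min"]], 0)
    expect_gte(b[["y_min"]], 0)
    expect_lte(b[["x_max"]], 128)
    expect_lte(b[["y_max"]], 128)
    expect_lt(b[["x_min"]], b[["x_max"]])
  }
})
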