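test_that("pairwise DSC matches hand counts and conventions", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_equal(dsc_pair(a, a), 1)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dsc_pair(a, b), 0)
  # |a| = 2, |b| = 1, overlap 1 -> 2/3
  a2 <- matrix(c(1, 1, 0, 0), 2, 2)
  b2 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(dsc_pair(a2, b2), 2 / 3)
  expect_equal(dsc_pair(a2, b2), dsc_pair(b2, a2))
  z <- matrix(0L, 2, 2)
  expect_equal(dsc_pair(z, z), 1)
  expect_equal(dsc_pair(z, z, both_empty = 0), 0)
  expect_error(dsc_pair(a, matrix(0, 3, 3)), "mismatch")
})

test_that("global DSC pools counts and disagrees with the per-image mean", {
  # img1: TP = 3, FP = 1, FN = 0; img2: TP = 0, FP = 0, FN = 2
  t1 <- matrix(0L, 3, 3); t1[1, 1:3] <- 1L
  p1 <- t1; p1[2, 1] <- 1L
  t2 <- matrix(0L, 3, 3); t2[3, 1:2] <- 1L
  p2 <- matrix(0L, 3, 3)
  rec <- dplyr::bind_rows(eval_record(p1, t1, "c1", 1),
                          eval_record(p2, t2, "c1", 2))
  expect_equal(dsc_global(rec), 6 / 9, tolerance = 1e-12)
  expect_equal(mean(rec$dsc), (6 / 7 + 0) / 2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dsc_global(rec), mean(rec$dsc))))
})

test_that("global DSC equals pairwise DSC on a single image and is
          additive over record splitting", {
  withr::with_seed(20, {
    truth <- matrix(rbinom(100, 1, 0.3), 10, 10)
    pred <- matrix(rbinom(100, 1, 0.3), 10, 10)
  })
  rec <- eval_record(pred, truth)
  expect_equal(dsc_global(rec), dsc_pair(pred, truth))
  split_rec <- dplyr::bind_rows(
    eval_record(pred[1:5, ], truth[1:5, ], slice_index = 1),
    eval_record(pred[6:10, ], truth[6:10, ], slice_index = 2))
  expect_equal(dsc_global(split_rec), dsc_global(rec))
  perfect <- eval_record(truth, truth)
  expect_equal(dsc_global(perfect), 1)
  expect_error(dsc_global(rec[0, ]), "empty")
})

test_that("the signed-rank test returns p = 1 for identical samples", {
  x <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  expect_equal(wilcoxon_signed_rank(x, x)$p_value, 1)
  expect_error(wilcoxon_signed_rank(1:3, 1:3))
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  adj <- bh_adjust(c(0.01, 0.04, 0.03, 0.005))
  expect_equal(adj$p_adjusted, c(0.02, 0.04, 0.04, 0.02))
  withr::with_seed(21, p <- runif(30))
  a <- bh_adjust(p)
  expect_true(all(a$p_adjusted >= a$p))
  expect_true(all(a$p_adjusted <= 1))
})

test_that("Bonferroni rejections are contained in BH rejections", {
  withr::with_seed(22, p <- runif(40)^2)
  q <- 0.05
  bh <- bh_adjust(p, q)$significant
  bonf <- stats::p.adjust(p, "bonferroni") <= q
  expect_true(all(!bonf | bh))
})

test_that("a uniform +0.1 DSC shift is flagged and identity is not", {
  withr::with_seed(23, base <- runif(50, 0.3, 0.8))
  rec <- dplyr::bind_rows(
    tibble::tibble(method = "A", case_id = "c", slice_index = 1:50,
                   dsc = base),
    tibble::tibble(method = "B", case_id = "c", slice_index = 1:50,
                   dsc = base + 0.1),
    tibble::tibble(method = "C", case_id = "c", slice_index = 1:50,
                   dsc = base)
  )
  cmp <- compare_methods(rec, q = 0.01)
  ab <- cmp[cmp$method_a == "A" & cmp$method_b == "B", ]
  expect_lt(ab$p_adjusted, 0.01)
  expect_true(ab$significant)
  ac <- cmp[cmp$method_a == "A" & cmp$method_b == "C", ]
  expect_false(ac$significant)
})

test_that("comparison flags are invariant to method ordering", {
  withr::with_seed(24, {
    base <- runif(30, 0.2, 0.7)
    rec <- dplyr::bind_rows(
      tibble::tibble(method = "m1", case_id = "c", slice_index = 1:30,
                     dsc = base),
      tibble::tibble(method = "m2", case_id = "c", slice_index = 1:30,
                     dsc = base + runif(30, 0, 0.2)))
  })
  c1 <- compare_methods(rec)
  c2 <- compare_methods(rec[sample(nrow(rec)), ])
  expect_equal(c1$p_value, c2$p_value)
  expect_equal(c1$significant, c2$significant)
})

test_that("mismatched image sets across methods are rejected", {
  rec <- dplyr::bind_rows(
    tibble::tibble(method = "A", case_id = "c", slice_index = 1:10,
                   dsc = runif(10)),
    tibble::tibble(method = "B", case_id = "c", slice_index = 3:12,
                   dsc = runif(10)))
  expect_error(compare_methods(rec), "identical image sets")
})
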