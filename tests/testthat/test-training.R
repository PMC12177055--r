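test_that("the combined loss reproduces its closed forms", {
  # perfect binary agreement
  y <- matrix(rbinom(400, 1, 0.3), 20, 20)
  expect_lt(loss_total(y + 0, y), 1e-3)
  # uniform 0.5 prediction, half the pixels positive
  n <- 10000
  y2 <- matrix(rep(c(1, 0), n / 2), 100, 100)
  expect_equal(loss_total(matrix(0.5, 100, 100), y2), log(2) + 0.5,
               tolerance = 1e-3)
  # inverted prediction: per-pixel BCE is -log(1e-7), Dice loss ~ 1
  li <- loss_total(1 - y2, y2)
  expect_equal(li, -log(1e-7) + 1, tolerance = 1e-3)
  expect_error(loss_total(matrix(0.5, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("loss is non-negative and a batch averages per-sample losses", {
  withr::with_seed(1, {
    preds <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
    ys <- replicate(3, matrix(rbinom(64, 1, 0.4), 8, 8), simplify = FALSE)
  })
  single <- vapply(1:3, function(i) loss_total(preds[[i]], ys[[i]]),
                   numeric(1))
  expect_true(all(single >= 0))
  expect_equal(loss_total(preds, ys), mean(single))
})

test_that("box perturbation respects its bounds and stays valid", {
  b <- bbox(40, 40, 70, 80)
  expect_identical(unclass(perturb_box(b, 128, 0)), unclass(b))
  withr::with_seed(2, {
    draws <- replicate(10000, unclass(perturb_box(b, 1024, 20)))
  })
  expect_true(all(abs(draws - as.numeric(b)) <= 20))
  # boxes touching every border stay non-degenerate
  edges <- list(bbox(0, 0, 10, 10), bbox(118, 0, 128, 10),
                bbox(0, 118, 10, 128), bbox(118, 118, 128, 128))
  withr::with_seed(3, {
    for (e in edges) {
      for (k in 1:200) {
        p <- perturb_box(e, 128, 20)
        expect_lt(p[["x_min"]], p[["x_max"]])
        expect_lt(p[["y_min"]], p[["y_max"]])
        expect_gte(p[["x_min"]], 0)
        expect_lte(p[["y_max"]], 128)
      }
    }
  })
})

test_that("an optimizer step with zero learning rate changes nothing", {
  withr::with_seed(4, {
    params <- list(a = matrix(rnorm(12), 3, 4), b = rnorm(5))
    grads <- list(a = matrix(rnorm(12), 3, 4), b = rnorm(5))
  })
  st <- sf_ns$adam_step(params, grads, sf_ns$adam_state(params), lr = 0,
                        weight_decay = 0.01)
  expect_identical(st$params, params)
})

test_that("Kaiming initialization has the fan-in variance", {
  withr::with_seed(5, W <- kaiming_matrix(256, 256))
  se <- sqrt(2 / 256) / sqrt(length(W))
  expect_lt(abs(mean(W)), 3 * se)
  expect_lt(abs(stats::var(as.vector(W)) - 2 / 256) / (2 / 256), 0.2)
  W2 <- withr::with_seed(6, kaiming_matrix(256, 256))
  expect_false(identical(W, W2))
})

test_that("training updates only the active fusion module", {
  ds <- toy_dataset(seed = 8, n_cases = 10, slices_per_case = 2)
  model <- frozen_toy_model(seed = 8)
  before <- lapply(model$params, param_checksum)
  cfgT <- train_config("tiny", epochs = 2L, seed = 8)   # >= 5 Adam steps
  fit <- train_promptfree(ds, model, cfgT)
  after <- lapply(fit$model$params, param_checksum)
  for (grp in c("encoder", "prompt", "decoder", "mfm_g")) {
    expect_identical(after[[grp]], before[[grp]])
  }
  expect_false(identical(after$mfm_pf, before$mfm_pf))
  # phase 2: prompt-free MFM is frozen, only the guided MFM moves
  fit2 <- train_guided(ds, fit, cfgT, warm_start = FALSE)
  after2 <- lapply(fit2$model$params, param_checksum)
  for (grp in c("encoder", "prompt", "decoder", "mfm_pf")) {
    expect_identical(after2[[grp]], after[[grp]])
  }
  expect_false(identical(after2$mfm_g, after$mfm_g))
  expect_true("mfm_pf" %in% fit2$model$frozen)
})

test_that("backbone pre-training leaves the fusion modules untouched and
          freezes the backbone", {
  ds <- toy_dataset(seed = 9, n_cases = 10, slices_per_case = 1)
  model <- model_init(backbone_config("tiny"), seed = 9)
  before <- lapply(model$params, param_checksum)
  pre <- pretrain_backbone(model, dataset_split(ds, "train"), epochs = 1,
                           seed = 9)
  after <- lapply(pre$params, param_checksum)
  expect_identical(after$mfm_pf, before$mfm_pf)
  expect_identical(after$mfm_g, before$mfm_g)
  expect_false(identical(after$encoder, before$encoder))
  expect_setequal(pre$frozen, c("encoder", "prompt", "decoder"))
})

test_that("training is reproducible from config + seed", {
  ds <- toy_dataset(seed = 10, n_cases = 10, slices_per_case = 2)
  model <- frozen_toy_model(seed = 10)
  cfgT <- train_config("tiny", epochs = 1L, seed = 10)
  f1 <- train_promptfree(ds, model, cfgT)
  f2 <- train_promptfree(ds, model, cfgT)
  expect_identical(f1$history, f2$history)
  expect_identical(param_checksum(f1$model$params$mfm_pf),
                   param_checksum(f2$model$params$mfm_pf))
})

test_that("an empty training split is an explicit error", {
  ds <- toy_dataset(seed = 11, n_cases = 10, slices_per_case = 1)
  ds$manifest$split[ds$manifest$split == "train"] <- "test"
  expect_error(train_promptfree(ds, frozen_toy_model(seed = 11),
                                train_config("tiny", epochs = 1L)),
               "empty training split")
})

test_that("fit objects expose tidy/glance history", {
  ds <- toy_dataset(seed = 12, n_cases = 10, slices_per_case = 1)
  fit <- train_promptfree(ds, frozen_toy_model(seed = 12),
                          train_config("tiny", epochs = 2L, seed = 12))
  h <- tidy(fit)
  expect_identical(names(h), c("epoch", "train_loss", "val_dsc"))
  expect_identical(nrow(h), 2L)
  g <- glance(fit)
  expect_identical(g$phase, "prompt_free")
  expect_identical(g$best_epoch, fit$best_epoch)
  expect_s3_class(autoplot(fit), "ggplot")
})
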