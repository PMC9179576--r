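test_that("the learning-rate schedule ramps, peaks at 0.1, and decays to 0", {
  cfg <- train_config(epochs = 100L, warmup_epochs = 5L, base_lr = 0.1,
                      backbone_lr_ratio = 0.1)
  expect_equal(lr_at(0, cfg, "projection"), 0)
  expect_equal(lr_at(5, cfg, "projection"), 0.1)
  expect_equal(lr_at(5, cfg, "backbone"), 0.01)
  expect_equal(lr_at(2.5, cfg, "projection"), 0.05)
  expect_lt(lr_at(99.999, cfg, "projection"), 1e-6)
  # cosine midpoint: half the base rate
  expect_equal(lr_at(5 + 95 / 2, cfg, "projection"), 0.05, tolerance = 1e-12)
  expect_error(lr_at(100, cfg), "epochs")
  expect_error(lr_at(-1, cfg), "epochs")
  # the two parameter groups keep the exact ratio everywhere
  for (e in c(0.5, 3, 5, 20, 80)) {
    expect_equal(lr_at(e, cfg, "backbone"),
                 0.1 * lr_at(e, cfg, "projection"), tolerance = 1e-15)
  }
  expect_error(train_config(epochs = 5L, warmup_epochs = 5L), "warmup")
})

test_that("weight transfer copies the backbone bitwise and reinitialises the head", {
  set.seed(40)
  bb <- small_cnn(16L, channels = c(2L, 2L, 3L, 3L))
  imgs <- lapply(1:6, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  rot <- build_rotation_dataset(imgs)
  cfg <- train_config(epochs = 3L, warmup_epochs = 1L, seed = 40,
                      batch_size = 8L)
  pre <- pretrain(model_spec(bb, "linear", 4L, init_seed = 40), rot, cfg)
  gspec <- model_spec(bb, "nonlinear_projection", 2L, init_seed = 41)
  g1 <- transfer_weights(pre, gspec)
  expect_identical(g1$backbone_params, pre$backbone_params)
  expect_identical(g1$spec$n_outputs, 2L)
  # fresh head: shapes differ from the pretext head and values are new
  expect_false(identical(names(g1$head_params), names(pre$head_params)))
  g2 <- transfer_weights(pre, gspec)
  expect_identical(g1$head_params, g2$head_params)  # deterministic init
  other <- small_cnn(16L, channels = c(3L, 3L, 3L, 3L))
  expect_error(transfer_weights(pre, model_spec(other, "nonlinear_projection",
                                                2L)), "match")
})

test_that("an untrained model is at chance on the rotation pretext", {
  set.seed(42)
  bb <- small_cnn(16L, channels = c(2L, 2L, 3L, 3L))
  m0 <- init_model(model_spec(bb, "linear", 4L, init_seed = 7))
  imgs <- lapply(1:50, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  rot <- build_rotation_dataset(imgs)
  x <- rccgrade:::stack_images(lapply(rot, `[[`, "pixels"))
  y <- vapply(rot, `[[`, numeric(1), "rotation_label") + 1
  acc <- pretext_accuracy(m0, x, y)
  expect_gt(acc, 0.10)
  expect_lt(acc, 0.40)
})

test_that("development trains with the configured schedule and both classes", {
  coh <- small_synth_cohort(seed = 43, n = 14L)
  bb <- small_cnn(16L, channels = c(2L, 3L, 4L, 4L))
  spec <- model_spec(bb, "nonlinear_projection", 2L, init_seed = 43)
  cfg <- train_config(epochs = 6L, warmup_epochs = 2L, seed = 43,
                      batch_size = 16L,
                      loss = loss_config(alpha = 0.4, lambda0 = 0.9,
                                         lambda1 = 1.1))
  m <- develop(init_model(spec), coh, cfg, target_edge = 16L)
  expect_identical(nrow(m$history), 6L)
  expect_true(all(is.finite(m$history$loss)))
  # logged learning rates conform to lr_at at every epoch, exact ratio
  for (e in 0:5) {
    expect_equal(m$history$lr_projection[e + 1], lr_at(e, cfg, "projection"))
    expect_equal(m$history$lr_backbone[e + 1], lr_at(e, cfg, "backbone"))
  }
  # determinism: same seeds, same final parameters
  m2 <- develop(init_model(spec), coh, cfg, target_edge = 16L)
  expect_identical(m$backbone_params, m2$backbone_params)
  expect_identical(m$head_params, m2$head_params)

  low_only <- cohort(Filter(function(p) p$binary_label == 0L, coh$patients),
                     "low")
  expect_error(develop(init_model(spec), low_only, cfg, target_edge = 16L),
               "both classes")
})

test_that("pretraining on an oriented cohort learns the rotation task", {
  # a fast, scaled-down sanity check: 16 patients, 16 px, 12 epochs
  coh <- small_synth_cohort(seed = 44, n = 16L)
  data <- rccgrade:::cohort_to_arrays(coh, 16L)
  imgs <- lapply(seq_len(dim(data$x)[4]), function(i) data$x[, , , i])
  rot <- build_rotation_dataset(imgs)
  bb <- small_cnn(16L, channels = c(4L, 6L, 8L, 8L))
  cfg <- train_config(epochs = 12L, warmup_epochs = 3L, seed = 44)
  pre <- pretrain(model_spec(bb, "linear", 4L, init_seed = 44), rot, cfg)
  expect_gt(pre$pretext_accuracy, 0.4)  # clearly above the 0.25 chance level
  # training reduced the loss overall
  expect_lt(tail(pre$history$loss, 1), pre$history$loss[2])
  expect_error(pretrain(model_spec(bb, "nonlinear_projection", 2L), rot, cfg),
               "linear")
})
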