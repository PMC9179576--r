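test_that("cross-entropy losses match hand arithmetic", {
  # perfect predictions -> zero loss
  perfect <- batch_prediction(rbind(c(1e-12, 1), c(1, 1e-12)), c(1, 0))
  expect_equal(ce_loss(perfect), 0, tolerance = 1e-10)
  # one sample, y = 1, p = (0.5, 0.5) -> ln 2
  b <- batch_prediction(matrix(c(0.5, 0.5), 1), 1)
  expect_equal(ce_loss(b), log(2), tolerance = 1e-12)
  # N = 2, one y = 0 sample with p0 = 0.5 -> (1/2) ln 2
  b2 <- batch_prediction(rbind(c(0.5, 0.5), c(0.1, 0.9)), c(0, 1))
  expect_equal(ce_class0_loss(b2), log(2) / 2, tolerance = 1e-12)
  # no class-0 samples -> class-0 term vanishes
  b3 <- batch_prediction(rbind(c(0.3, 0.7), c(0.2, 0.8)), c(1, 1))
  expect_equal(ce_class0_loss(b3), 0)
  # all-class-0 batch: the class-0 term IS the cross entropy
  b4 <- batch_prediction(rbind(c(0.6, 0.4), c(0.8, 0.2)), c(0, 0))
  expect_equal(ce_class0_loss(b4), ce_loss(b4), tolerance = 1e-12)
})

test_that("limit identities tie the loss family together exactly", {
  set.seed(20)
  for (r in 1:25) {
    b <- random_batch()
    cfg1 <- loss_config(alpha = 1)
    expect_equal(mixed_loss(b, cfg1), ce_loss(b), tolerance = 1e-12)
    cfg0 <- loss_config(alpha = 0)
    expect_equal(mixed_loss(b, cfg0), ce_class0_loss(b), tolerance = 1e-12)
    cfg_l1 <- loss_config(alpha = runif(1))
    expect_equal(total_weighted_loss(b, cfg_l1), mixed_loss(b, cfg_l1),
                 tolerance = 1e-12)
    cfg_a1 <- loss_config(alpha = 1, lambda0 = runif(1, 0.2, 2),
                          lambda1 = runif(1, 0.2, 2))
    expect_equal(total_weighted_loss(b, cfg_a1), weighted_ce_loss(b, cfg_a1),
                 tolerance = 1e-12)
    unit <- loss_config(alpha = runif(1), lambda0 = 1, lambda1 = 1)
    expect_equal(weighted_ce_loss(b, unit), ce_loss(b), tolerance = 1e-12)
  }
  expect_error(loss_config(alpha = 1.4), "alpha")
  expect_error(loss_config(lambda0 = -1), "positive")
})

test_that("vectorised losses match the scalar double-loop oracle to 1e-10", {
  set.seed(21)
  for (r in 1:1000) {
    b <- random_batch()
    alpha <- runif(1); lam0 <- runif(1, 0.2, 2); lam1 <- runif(1, 0.2, 2)
    cfg <- loss_config(alpha = alpha, lambda0 = lam0, lambda1 = lam1)
    expect_equal(ce_loss(b), oracle_ce(b$probs, b$labels),
                 tolerance = 1e-10)
    expect_equal(ce_class0_loss(b), oracle_ce_class0(b$probs, b$labels),
                 tolerance = 1e-10)
    expect_equal(mixed_loss(b, cfg), oracle_mixed(b$probs, b$labels, alpha),
                 tolerance = 1e-10)
    expect_equal(weighted_ce_loss(b, cfg),
                 oracle_weighted_ce(b$probs, b$labels, lam0, lam1),
                 tolerance = 1e-10)
    expect_equal(total_weighted_loss(b, cfg),
                 oracle_total_weighted(b$probs, b$labels, alpha, lam0, lam1),
                 tolerance = 1e-10)
  }
})

test_that("losses are permutation invariant and homogeneous in the weights", {
  set.seed(22)
  for (r in 1:20) {
    b <- random_batch()
    perm <- sample(nrow(b$probs))
    bp <- batch_prediction(b$probs[perm, , drop = FALSE], b$labels[perm])
    cfg <- loss_config(alpha = runif(1), lambda0 = runif(1, 0.2, 2),
                       lambda1 = runif(1, 0.2, 2))
    expect_equal(ce_loss(b), ce_loss(bp), tolerance = 1e-12)
    expect_equal(total_weighted_loss(b, cfg), total_weighted_loss(bp, cfg),
                 tolerance = 1e-12)
    cfg2 <- loss_config(alpha = cfg$alpha, lambda0 = 2 * cfg$lambda0,
                        lambda1 = 2 * cfg$lambda1)
    expect_equal(weighted_ce_loss(b, cfg2), 2 * weighted_ce_loss(b, cfg),
                 tolerance = 1e-12)
  }
})

test_that("the noise term never penalises high-labelled samples' p_i0", {
  # in the printed mixed objective, l_i0 log p_i0 vanishes for y_i = 1, so
  # altering a high-labelled sample's low-grade probability (holding its
  # counted probability fixed) cannot change the loss
  probs <- rbind(c(0.3, 0.7), c(0.6, 0.4))
  labels <- c(1, 0)
  cfg <- loss_config(alpha = 0.4)
  base <- mixed_loss(batch_prediction(probs, labels, validate = FALSE), cfg)
  probs2 <- probs; probs2[1, 1] <- 0.05  # y = 1 sample's p_i0 changed
  moved <- mixed_loss(batch_prediction(probs2, labels, validate = FALSE), cfg)
  expect_identical(base, moved)
  # whereas changing a low-labelled sample's p_i0 does change it
  probs3 <- probs; probs3[2, 1] <- 0.05
  expect_false(isTRUE(all.equal(
    base,
    mixed_loss(batch_prediction(probs3, labels, validate = FALSE), cfg))))
})

test_that("alternative mixing and noise-term readings behave as documented", {
  set.seed(23)
  b <- random_batch()
  a <- 0.3
  as_printed <- loss_config(alpha = a)
  complement <- loss_config(alpha = a, mixing = "complement")
  swapped <- loss_config(alpha = 1 - a)
  expect_equal(mixed_loss(b, complement), mixed_loss(b, swapped),
               tolerance = 1e-12)
  flip <- loss_config(alpha = a, noise_term = "flip_to_low")
  # flip-to-low applies -log p_i0 to every sample, so it upper-bounds the
  # class-0-restricted term
  expect_gte(mixed_loss(b, flip), mixed_loss(b, as_printed) - 1e-12)
})

test_that("class weights derive correctly from counts", {
  expect_equal(class_weights_from_counts(100, 100, "inverse_frequency"),
               c(lambda0 = 1, lambda1 = 1))
  w <- class_weights_from_counts(354, 238, "inverse_frequency")
  expect_equal(w[["lambda0"]], 592 / (2 * 354), tolerance = 1e-12)
  expect_equal(w[["lambda1"]], 592 / (2 * 238), tolerance = 1e-12)
  expect_equal(round(w[["lambda0"]], 3), 0.836)
  expect_equal(round(w[["lambda1"]], 3), 1.244)
  # noise_adjusted balances lambda0 * n_low = alpha * lambda1 * n_high,
  # normalised to lambda0 + lambda1 = 2
  for (alpha in c(0.4, 0.7, 1)) {
    na <- class_weights_from_counts(354, 238, "noise_adjusted", alpha = alpha)
    expect_equal(na[["lambda0"]] * 354, alpha * na[["lambda1"]] * 238,
                 tolerance = 1e-9)
    expect_equal(sum(na), 2, tolerance = 1e-12)
  }
  expect_error(class_weights_from_counts(0, 5), "positive")
})
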