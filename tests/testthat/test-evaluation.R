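test_that("patient aggregation is the max and is order invariant", {
  expect_equal(aggregate_patient(c(0.1, 0.9, 0.3)), 0.9)
  expect_equal(aggregate_patient(0.42), 0.42)
  set.seed(50)
  for (r in 1:20) {
    s <- runif(sample(1:10, 1))
    expect_equal(aggregate_patient(s), aggregate_patient(sample(s)))
    # adding a dominated score never changes the aggregate
    expect_equal(aggregate_patient(c(s, min(s))), aggregate_patient(s))
  }
  expect_error(aggregate_patient(numeric(0)), "no image scores")
  expect_error(aggregate_patient(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("classification metrics match confusion-table arithmetic", {
  pred <- patient_predictions(paste0("p", 1:4), c(0.9, 0.4, 0.2, 0.6),
                              c(1, 1, 0, 0))
  cm <- classification_metrics(pred, threshold = 0.5)
  expect_equal(cm$sen, 50.0)
  expect_equal(cm$spc, 50.0)
  expect_equal(cm$acc, 50.0)
  # threshold 0 calls everything positive
  cm0 <- classification_metrics(pred, threshold = 0)
  expect_equal(cm0$sen, 100.0)
  expect_equal(cm0$spc, 0.0)
  perfect <- patient_predictions(paste0("p", 1:4), c(0.9, 0.8, 0.1, 0.2),
                                 c(1, 1, 0, 0))
  cmp <- classification_metrics(perfect, 0.5)
  expect_equal(c(cmp$acc, cmp$sen, cmp$spc), c(100.0, 100.0, 100.0))
  one_class <- patient_predictions("p1", 0.5, 1)
  expect_error(classification_metrics(one_class), "both classes")
})

test_that("metrics agree with a brute-force confusion oracle on random instances", {
  set.seed(51)
  for (r in 1:1000) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both present
    scores <- round(runif(n), 2)
    thr <- runif(1)
    cm <- classification_metrics(patient_predictions(paste0("p", 1:n),
                                                     scores, labels), thr)
    called <- as.integer(scores >= thr)
    tp <- sum(called & labels); tn <- sum(!called & !labels)
    expect_equal(cm$acc, round_half_up(100 * (tp + tn) / n, 1))
    if (tp + cm$fn > 0)
      expect_equal(cm$sen, round_half_up(100 * tp / sum(labels == 1), 1))
    expect_equal(cm$spc, round_half_up(100 * tn / sum(labels == 0), 1))
  }
})

test_that("rank-based AUC equals brute-force pair counting", {
  pred <- patient_predictions(paste0("p", 1:4), c(0.9, 0.4, 0.2, 0.6),
                              c(1, 1, 0, 0))
  expect_equal(roc_auc(pred)$auc, 0.75)
  perfect <- patient_predictions(paste0("p", 1:4), c(0.9, 0.8, 0.1, 0.2),
                                 c(1, 1, 0, 0))
  expect_equal(roc_auc(perfect)$auc, 1.0)
  ties <- patient_predictions(paste0("p", 1:4), rep(0.5, 4), c(1, 1, 0, 0))
  expect_equal(roc_auc(ties)$auc, 0.5)
  set.seed(52)
  for (r in 1:1000) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)  # coarse grid to exercise ties
    pr <- patient_predictions(paste0("p", 1:n), scores, labels)
    expect_equal(roc_auc(pr)$auc, brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC matches an established implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(53)
  for (r in 1:20) {
    n <- 30
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)
    pr <- patient_predictions(paste0("p", 1:n), scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(pr)$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curve properties hold", {
  set.seed(54)
  for (r in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- runif(n)  # continuous: ties almost surely absent
    pr <- patient_predictions(paste0("p", 1:n), scores, labels)
    roc <- roc_auc(pr)
    expect_true(all(diff(roc$roc_points$fpr) >= 0))
    expect_true(all(diff(roc$roc_points$tpr) >= 0))
    expect_equal(unlist(roc$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(roc$roc_points[nrow(roc$roc_points), ]),
                 c(fpr = 1, tpr = 1))
    # complement property without ties
    prc <- patient_predictions(pr$patient_id, 1 - scores, labels)
    expect_equal(roc$auc + roc_auc(prc)$auc, 1, tolerance = 1e-12)
    # invariance under strictly monotone transforms
    prm <- patient_predictions(pr$patient_id, plogis(3 * scores - 1), labels)
    expect_equal(roc_auc(prm)$auc, roc$auc, tolerance = 1e-12)
  }
})

test_that("score_cohort returns one max-aggregated prediction per patient", {
  coh <- small_synth_cohort(seed = 55, n = 6L)
  bb <- small_cnn(16L, channels = c(2L, 2L, 3L, 3L))
  m <- init_model(model_spec(bb, "nonlinear_projection", 2L, init_seed = 55))
  pred <- score_cohort(m, coh, target_edge = 16L)
  expect_identical(nrow(pred), 6L)
  img_scores <- attr(pred, "image_scores")
  expect_identical(lengths(img_scores),
                   vapply(coh$patients, function(p) length(p$images),
                          integer(1)))
  expect_equal(pred$score, vapply(img_scores, max, numeric(1)))
  pred2 <- score_cohort(m, coh, target_edge = 16L)
  expect_identical(pred$score, pred2$score)  # deterministic under fixed state
})

test_that("youden threshold maximises tpr - fpr", {
  pred <- patient_predictions(paste0("p", 1:6),
                              c(0.9, 0.8, 0.55, 0.5, 0.3, 0.1),
                              c(1, 1, 1, 0, 0, 0))
  thr <- youden_threshold(pred)
  expect_equal(thr, 0.55)
  ev <- evaluate_predictions(pred, threshold = "youden")
  expect_equal(ev$sen, 100.0)
  expect_equal(ev$spc, 100.0)
})
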