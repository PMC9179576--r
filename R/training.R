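#' Training configuration
#'
#' Optimisation protocol shared by pretraining and grading development:
#' plain SGD with weight decay, a linear warm-up from 0 to `base_lr` over
#' `warmup_epochs`, then cosine decay to 0 over the remaining epochs,
#' evaluated per epoch. During grading development the backbone's learning
#' rate is `backbone_lr_ratio` times the projection head's at every step
#' (the pretrained backbone needs only gentle adjustment, while the fresh
#' head learns at full rate).
#'
#' The reference-scale protocol is 60 pretext / 100 development epochs at
#' 224 px; the shipped desk-scale profile (used throughout the tests and
#' the bundled experiment driver) is 20 / 25 epochs at 32 px.
#'
#' @param epochs total epochs (warm-up included).
#' @param warmup_epochs linear warm-up length (default 5).
#' @param base_lr peak learning rate (default 0.1).
#' @param backbone_lr_ratio backbone-to-projection LR ratio (default 0.1;
#'   applied during development only — pretraining trains everything at
#'   the full rate since nothing is pretrained yet).
#' @param weight_decay L2 penalty rate (default 1e-4).
#' @param batch_size minibatch size (default 32).
#' @param seed shuffling/augmentation seed.
#' @param loss an [loss_config()]; drives [total_weighted_loss()] during
#'   development.
#' @param augment apply random quarter-turn rotation + horizontal flip to
#'   every training image each epoch (development phase).
#' @return an object of class `rcc_train_config`.
#' @export
train_config <- function(epochs = 100L, warmup_epochs = 5L, base_lr = 0.1,
                         backbone_lr_ratio = 0.1, weight_decay = 1e-4,
                         batch_size = 32L, seed = 1L,
                         loss = loss_config(), augment = TRUE) {
  if (warmup_epochs >= epochs)
    stop_rcc("warmup_epochs must be smaller than epochs")
  if (base_lr <= 0 || backbone_lr_ratio <= 0)
    stop_rcc("learning rates must be positive")
  if (weight_decay < 0) stop_rcc("weight_decay must be non-negative")
  structure(list(epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 base_lr = base_lr, backbone_lr_ratio = backbone_lr_ratio,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), loss = loss, augment = augment),
            class = "rcc_train_config")
}

#' Learning rate at a given epoch
#'
#' Linear ramp from 0 to `base_lr` over the warm-up epochs, then
#' `base_lr * 0.5 * (1 + cos(pi * t))` with
#' `t = (epoch - warmup) / (epochs - warmup)`; the backbone's value is the
#' projection's multiplied by `backbone_lr_ratio`.
#'
#' @param epoch real-valued epoch in `[0, epochs)`.
#' @param config an [train_config()].
#' @param part `"projection"` or `"backbone"`.
#' @return positive learning rate.
#' @export
lr_at <- function(epoch, config, part = c("projection", "backbone")) {
  part <- match.arg(part)
  if (epoch < 0 || epoch >= config$epochs)
    stop_rcc("epoch must lie in [0, epochs)")
  lr <- if (epoch < config$warmup_epochs) {
    config$base_lr * epoch / config$warmup_epochs
  } else {
    t <- (epoch - config$warmup_epochs) /
      (config$epochs - config$warmup_epochs)
    config$base_lr * 0.5 * (1 + cos(pi * t))
  }
  if (part == "backbone") lr * config$backbone_lr_ratio else lr
}

# in-place-style SGD update over a nested list of parameter arrays
sgd_update <- function(params, grads, lr, wd) {
  for (nm in names(params)) {
    if (is.list(params[[nm]])) {
      params[[nm]] <- sgd_update(params[[nm]], grads[[nm]], lr, wd)
    } else {
      params[[nm]] <- params[[nm]] - lr * (grads[[nm]] + wd * params[[nm]])
    }
  }
  params
}
sgd_update_layers <- function(params, grads, lr, wd) {
  for (l in seq_along(params)) params[[l]] <- sgd_update(params[[l]],
                                                         grads[[l]], lr, wd)
  params
}

# one optimisation step shared by both phases; grad_fn maps (probs) to the
# logit gradient
train_step <- function(model, xb, grad_fn, lr_backbone, lr_head, wd) {
  bb <- model$spec$backbone
  fw <- bb$forward(model$backbone_params, xb)
  hd <- model$spec$head$forward(model$head_params, fw$features)
  probs <- softmax_rows(hd$logits)
  glogits <- grad_fn(probs)
  hb <- model$spec$head$backward(model$head_params, hd$cache, glogits)
  bgrads <- bb$backward(model$backbone_params, fw$cache, hb$gfeat)
  model$head_params <- sgd_update(model$head_params, hb$grads, lr_head, wd)
  model$backbone_params <- sgd_update_layers(model$backbone_params, bgrads,
                                             lr_backbone, wd)
  list(model = model, probs = probs)
}

#' Rotation-pretext pretraining
#'
#' Trains a 4-output linear-head model to predict the number of clockwise
#' quarter turns applied to each image, with plain cross-entropy and SGD.
#' A fraction of source images (grouped, so all four rotations of an image
#' stay together) is held out and the final pretext accuracy on it is
#' recorded — a model that has learned nothing scores ~0.25.
#'
#' @param spec a 4-output, linear-head [model_spec()].
#' @param rotation_data list of rotation samples from
#'   [build_rotation_dataset()].
#' @param config an [train_config()].
#' @param holdout_fraction fraction of source images held out.
#' @return an `rcc_model` with `history` (per-epoch mean loss and LR) and
#'   `pretext_accuracy`.
#' @export
pretrain <- function(spec, rotation_data, config, holdout_fraction = 0.1) {
  if (spec$n_outputs != 4L || spec$head$type != "linear")
    stop_rcc("pretraining requires a 4-output linear head")
  edges <- vapply(rotation_data, function(s) dim(as_image_array(s$pixels))[1],
                  integer(1))
  widths <- vapply(rotation_data, function(s) dim(as_image_array(s$pixels))[2],
                   integer(1))
  if (any(edges != widths)) stop_rcc("rotation samples must be square")

  x <- stack_images(lapply(rotation_data, function(s)
    as_image_array(s$pixels)))
  y <- vapply(rotation_data, function(s) s$rotation_label, numeric(1)) + 1L
  src <- vapply(rotation_data, function(s) s$source_image_id, character(1))

  model <- init_model(spec)
  with_seed(config$seed, {
    sources <- unique(src)
    n_hold <- max(1L, round(holdout_fraction * length(sources)))
    hold_src <- sample(sources, n_hold)
    hold <- src %in% hold_src
    tr_idx <- which(!hold)

    history <- data.frame(epoch = seq_len(config$epochs) - 1L,
                          loss = NA_real_, lr = NA_real_)
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- lr_at(epoch, config, "projection")
      order <- sample(tr_idx)
      losses <- c()
      for (start in seq(1L, length(order), by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1L, length(order))]
        xb <- x[, , , idx, drop = FALSE]
        yb <- y[idx]
        st <- train_step(model, xb,
                         function(p) grad_ce_logits(p, yb),
                         lr_backbone = lr, lr_head = lr,
                         wd = config$weight_decay)
        model <- st$model
        losses <- c(losses,
                    -mean(log(pmax(st$probs[cbind(seq_along(yb), yb)],
                                   1e-12))))
      }
      history$loss[epoch + 1L] <- mean(losses)
      history$lr[epoch + 1L] <- lr
    }
    model$history <- history
    model$pretext_accuracy <- pretext_accuracy(model, x[, , , hold,
                                                        drop = FALSE],
                                               y[hold])
    model
  })
}

#' Pretext accuracy of a model on rotation-labelled images
#'
#' @param model an `rcc_model` with 4 outputs.
#' @param x image batch array (H, W, C, N).
#' @param labels_onebased rotation labels + 1 (1..4).
#' @return fraction of correct argmax predictions.
#' @export
pretext_accuracy <- function(model, x, labels_onebased) {
  probs <- model_probs(model, x)
  mean(max.col(probs, ties.method = "first") == labels_onebased)
}

#' Transfer pretrained backbone weights into a grading model
#'
#' Copies the backbone parameters bitwise from a pretrained model and
#' freshly initialises the projection head from `grading_spec$init_seed`
#' (the pretext head is discarded; the output dimension becomes 2).
#'
#' @param pretrained an `rcc_model` from [pretrain()].
#' @param grading_spec a 2-output [model_spec()] built on the same
#'   backbone architecture.
#' @return an initialised `rcc_model`.
#' @export
transfer_weights <- function(pretrained, grading_spec) {
  pb <- pretrained$spec$backbone
  gb <- grading_spec$backbone
  if (!identical(pb$name, gb$name) ||
      !identical(pb$channels, gb$channels) ||
      !identical(pb$input_edge, gb$input_edge))
    stop_rcc("backbone architectures do not match")
  structure(list(backbone_params = pretrained$backbone_params,
                 head_params = grading_spec$head$init_params(
                   grading_spec$init_seed + 10000L),
                 spec = grading_spec, history = NULL),
            class = "rcc_model")
}

#' Develop (train) the grading model on a cohort
#'
#' Trains the 2-output grading model on every image of the cohort with the
#' overall weighted objective ([total_weighted_loss()]), SGD, weight
#' decay, per-epoch warm-up + cosine learning rates with the backbone at
#' `backbone_lr_ratio` times the projection rate, and (optionally)
#' quarter-turn/flip augmentation. Labels are the per-image observed
#' binary grades.
#'
#' @param model an initialised `rcc_model` (fresh via [init_model()] or
#'   transferred via [transfer_weights()]).
#' @param cohort development `rcc_cohort` containing both classes.
#' @param config an [train_config()]; `config$loss` supplies alpha and the
#'   class weights (see [class_weights_from_counts()]).
#' @param target_edge uniform image size fed to the backbone; defaults to
#'   the backbone's `input_edge`.
#' @return the trained `rcc_model`; `history` holds per-epoch mean loss
#'   and both learning rates.
#' @export
develop <- function(model, cohort, config, target_edge = NULL) {
  if (model$spec$n_outputs != 2L)
    stop_rcc("grading development requires a 2-output model")
  target_edge <- target_edge %||% model$spec$backbone$input_edge
  data <- cohort_to_arrays(cohort, target_edge)
  if (length(unique(data$labels)) < 2L)
    stop_rcc("development cohort must contain both classes")
  n <- length(data$labels)

  with_seed(config$seed, {
    history <- data.frame(epoch = seq_len(config$epochs) - 1L,
                          loss = NA_real_, lr_projection = NA_real_,
                          lr_backbone = NA_real_)
    for (epoch in seq_len(config$epochs) - 1L) {
      lr_head <- lr_at(epoch, config, "projection")
      lr_bb <- lr_at(epoch, config, "backbone")
      order <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1L, n)]
        xb <- data$x[, , , idx, drop = FALSE]
        if (config$augment) {
          for (k in seq_along(idx)) xb[, , , k] <- augment(xb[, , , k])
        }
        yb <- data$labels[idx]
        st <- train_step(model, xb,
                         function(p) grad_total_weighted_logits(p, yb,
                                                                config$loss),
                         lr_backbone = lr_bb, lr_head = lr_head,
                         wd = config$weight_decay)
        model <- st$model
        batch <- batch_prediction(st$probs, yb, validate = FALSE)
        losses <- c(losses, total_weighted_loss(batch, config$loss))
      }
      history$loss[epoch + 1L] <- mean(losses)
      history$lr_projection[epoch + 1L] <- lr_head
      history$lr_backbone[epoch + 1L] <- lr_bb
    }
    model$history <- history
    model
  })
}
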