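#' Small convolutional backbone
#'
#' The default desk-scale feature extractor: four 3x3 conv + ReLU + 2x2
#' max-pool blocks followed by global average pooling. Any object obeying
#' the same contract (fields `feature_dim`, `input_edge`; functions
#' `init_params(seed)`, `forward(params, x)` returning
#' `list(features, cache)`, and `backward(params, cache, gfeat)` returning
#' `list(grads)`) can be plugged into the trainer in its place, which is
#' how larger published architectures would slot in.
#'
#' @param input_edge square input edge; must be divisible by 16
#'   (four pooling stages).
#' @param channels integer length-4 vector of conv output channels.
#' @return an object of class `rcc_backbone`.
#' @export
small_cnn <- function(input_edge = 32L, channels = c(8L, 16L, 32L, 32L)) {
  if (input_edge %% 16L != 0L)
    stop_rcc("input_edge must be divisible by 16")
  if (length(channels) != 4L) stop_rcc("channels must have length 4")
  in_ch <- c(3L, channels[-4])

  init_params <- function(seed) {
    with_seed(seed, {
      params <- vector("list", 4L)
      for (l in 1:4) {
        fan_in <- 9L * in_ch[l]
        params[[l]] <- list(
          W = matrix(rnorm(fan_in * channels[l], sd = sqrt(2 / fan_in)),
                     fan_in, channels[l]),
          b = rep(0, channels[l]))
      }
      params
    })
  }

  forward <- function(params, x) {
    cache <- vector("list", 4L)
    for (l in 1:4) {
      z <- conv3x3_forward(x, params[[l]]$W, params[[l]]$b)
      a <- pmax(z, 0)
      dim(a) <- dim(z)
      pooled <- maxpool2_forward(a)
      cache[[l]] <- list(x = x, relu_mask = z > 0, argmax = pooled$argmax,
                         adim = dim(z))
      x <- pooled$y
    }
    d <- dim(x)  # (h, w, C4, N)
    hw <- d[1] * d[2]
    fm <- matrix(x, nrow = hw)                       # hw x (C4*N)
    features <- t(matrix(colMeans(fm), d[3], d[4]))  # N x C4
    list(features = features, cache = c(cache, list(out_dim = d)))
  }

  backward <- function(params, cache, gfeat) {
    d <- cache$out_dim
    hw <- d[1] * d[2]
    # global average pool: gradient spread uniformly over the h*w cells
    g <- array(rep(t(gfeat) / hw, each = hw), dim = d)
    grads <- vector("list", 4L)
    for (l in 4:1) {
      cl <- cache[[l]]
      ga <- maxpool2_backward(cl$argmax, g, cl$adim)
      gz <- ga * cl$relu_mask
      dim(gz) <- cl$adim
      bw <- conv3x3_backward(cl$x, params[[l]]$W, gz)
      grads[[l]] <- list(W = bw$gW, b = as.numeric(bw$gb))
      g <- bw$gx
    }
    grads
  }

  structure(list(name = "small_cnn", input_edge = as.integer(input_edge),
                 channels = as.integer(channels),
                 feature_dim = as.integer(channels[4]),
                 init_params = init_params, forward = forward,
                 backward = backward),
            class = "rcc_backbone")
}

# classifier heads ------------------------------------------------------

make_head <- function(type = c("linear", "nonlinear_projection"),
                      in_dim, n_outputs, hidden = in_dim) {
  type <- match.arg(type)
  init_params <- function(seed) {
    with_seed(seed, {
      if (type == "linear") {
        list(W = matrix(rnorm(in_dim * n_outputs, sd = sqrt(2 / in_dim)),
                        in_dim, n_outputs),
             b = rep(0, n_outputs))
      } else {
        list(W1 = matrix(rnorm(in_dim * hidden, sd = sqrt(2 / in_dim)),
                         in_dim, hidden),
             b1 = rep(0, hidden),
             W2 = matrix(rnorm(hidden * n_outputs, sd = sqrt(2 / hidden)),
                         hidden, n_outputs),
             b2 = rep(0, n_outputs))
      }
    })
  }
  forward <- function(params, features) {
    if (type == "linear") {
      logits <- sweep(features %*% params$W, 2, params$b, `+`)
      list(logits = logits, cache = list(features = features))
    } else {
      h_pre <- sweep(features %*% params$W1, 2, params$b1, `+`)
      h <- pmax(h_pre, 0)
      logits <- sweep(h %*% params$W2, 2, params$b2, `+`)
      list(logits = logits,
           cache = list(features = features, h = h, mask = h_pre > 0))
    }
  }
  backward <- function(params, cache, glogits) {
    if (type == "linear") {
      list(grads = list(W = crossprod(cache$features, glogits),
                        b = colSums(glogits)),
           gfeat = glogits %*% t(params$W))
    } else {
      gW2 <- crossprod(cache$h, glogits)
      gh <- (glogits %*% t(params$W2)) * cache$mask
      list(grads = list(W1 = crossprod(cache$features, gh),
                        b1 = colSums(gh),
                        W2 = gW2, b2 = colSums(glogits)),
           gfeat = gh %*% t(params$W1))
    }
  }
  list(type = type, in_dim = in_dim, n_outputs = n_outputs, hidden = hidden,
       init_params = init_params, forward = forward, backward = backward)
}

#' Model specification
#'
#' Binds a backbone to a classifier head. The pretext model uses a linear
#' head with 4 outputs (rotation classes); the grading model uses a
#' nonlinear projection head (hidden layer of the feature width, ReLU)
#' with 2 outputs.
#'
#' @param backbone an `rcc_backbone` (see [small_cnn()]).
#' @param head `"linear"` or `"nonlinear_projection"`.
#' @param n_outputs 4 (pretext) or 2 (grading).
#' @param init_seed seed for parameter initialisation (fan-in-scaled
#'   Gaussian weights, zero biases).
#' @return an object of class `rcc_model_spec`.
#' @export
model_spec <- function(backbone, head = c("linear", "nonlinear_projection"),
                       n_outputs, init_seed = 1L) {
  head <- match.arg(head)
  if (!n_outputs %in% c(2L, 4L)) stop_rcc("n_outputs must be 2 or 4")
  structure(list(backbone = backbone,
                 head = make_head(head, backbone$feature_dim, n_outputs),
                 head_type = head,
                 n_outputs = as.integer(n_outputs),
                 init_seed = as.integer(init_seed)),
            class = "rcc_model_spec")
}

#' Initialise a model from its specification
#'
#' @param spec an [model_spec()].
#' @return an object of class `rcc_model` holding backbone and head
#'   parameters plus the spec.
#' @export
init_model <- function(spec) {
  structure(list(backbone_params = spec$backbone$init_params(spec$init_seed),
                 head_params = spec$head$init_params(spec$init_seed + 10000L),
                 spec = spec, history = NULL),
            class = "rcc_model")
}

# full forward pass to class probabilities, in chunks to bound memory
model_probs <- function(model, x, chunk = 256L) {
  n <- dim(x)[4]
  out <- matrix(0, n, model$spec$n_outputs)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- model$spec$backbone$forward(model$backbone_params,
                                      x[, , , idx, drop = FALSE])
    hd <- model$spec$head$forward(model$head_params, fw$features)
    out[idx, ] <- softmax_rows(hd$logits)
  }
  out
}
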