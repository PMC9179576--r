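#' Bring an image to a uniform square size
#'
#' Standardises a ROI crop to `target_edge x target_edge x 3` before it
#' enters the network (the reference configuration is 224; desk-scale work
#' uses 32). `pad` centres the image on a zero background and requires both
#' edges to fit; `resize` rescales bilinearly with the aspect ratio
#' preserved (long edge to `target_edge`) and zero-pads the short edge.
#' Single-channel input is replicated to three channels.
#'
#' @param image matrix or (H, W, C) array, C in `{1, 3}`.
#' @param target_edge output edge length (>= 8).
#' @param mode `"resize"` (default) or `"pad"`.
#' @return a `(target_edge, target_edge, 3)` array.
#' @export
resize_or_pad <- function(image, target_edge = 224L,
                          mode = c("resize", "pad")) {
  mode <- match.arg(mode)
  if (target_edge < 8L) stop_rcc("target_edge must be at least 8")
  image <- as_image_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]; ch <- dim(image)[3]

  if (mode == "pad") {
    if (h > target_edge || w > target_edge)
      stop_rcc("image (", h, "x", w, ") exceeds target ", target_edge,
               "; use mode = 'resize'")
  } else if (h != target_edge || w != target_edge) {
    if (h >= w) {
      nh <- target_edge
      nw <- max(1L, as.integer(round(w * target_edge / h)))
    } else {
      nw <- target_edge
      nh <- max(1L, as.integer(round(h * target_edge / w)))
    }
    image <- vapply(seq_len(ch),
                    function(c) EBImage::resize(image[, , c], w = nh, h = nw),
                    matrix(0, nh, nw))
    h <- nh; w <- nw
  }

  out <- array(0, c(target_edge, target_edge, ch))
  top <- floor((target_edge - h) / 2)
  left <- floor((target_edge - w) / 2)
  out[top + seq_len(h), left + seq_len(w), ] <- image
  if (ch == 1L) out <- array(rep(out, 3L), c(target_edge, target_edge, 3L))
  out
}

#' Rotate a square image by quarter turns
#'
#' Exact clockwise rotation by `k` quarter turns — a pure index
#' permutation, so repeated rotations compose as the cyclic group C4 and
#' `k = 0` is the identity.
#'
#' @param image square matrix or (H, H, C) array.
#' @param k integer number of clockwise quarter turns (0--3; reduced mod 4).
#' @return rotated image of the same shape.
#' @export
rotate_quarter <- function(image, k) {
  was_matrix <- is.matrix(image)
  image <- as_image_array(image)
  if (dim(image)[1] != dim(image)[2])
    stop_rcc("rotate_quarter requires a square image")
  k <- as.integer(k) %% 4L
  n <- dim(image)[1]
  rot1 <- function(m) t(m[n:1, , drop = FALSE])
  for (c in seq_len(dim(image)[3])) {
    m <- image[, , c]
    if (k > 0) for (r in seq_len(k)) m <- rot1(m)
    image[, , c] <- m
  }
  if (was_matrix) image[, , 1] else image
}

#' Build the rotation-pretext dataset
#'
#' Expands every image into four rotated copies labelled by the number of
#' clockwise quarter turns (0, 1, 2, 3). Grade labels are deliberately not
#' carried over: the pretext task must not reveal the grading semantics.
#'
#' @param images list of square image arrays (post [resize_or_pad()]).
#' @param ids optional character vector of source image ids.
#' @return list of rotation samples, each a list with `pixels`,
#'   `rotation_label` (0--3) and `source_image_id`; length `4 * length(images)`.
#' @export
build_rotation_dataset <- function(images, ids = NULL) {
  ids <- ids %||% sprintf("img%05d", seq_along(images))
  out <- vector("list", 4L * length(images))
  pos <- 0L
  for (i in seq_along(images)) {
    for (k in 0:3) {
      pos <- pos + 1L
      out[[pos]] <- list(pixels = rotate_quarter(images[[i]], k),
                         rotation_label = k,
                         source_image_id = ids[i])
    }
  }
  out
}

#' Training-time augmentation
#'
#' Applies an independent uniform quarter-turn rotation and a
#' probability-0.5 horizontal flip. Both are index permutations, so the
#' pixel multiset is conserved. Quarter turns (rather than arbitrary-angle
#' interpolation) keep the augmentation lossless and consistent with the
#' pretext vocabulary; set `arbitrary_angle = TRUE` for bilinear rotation
#' by a uniform angle instead.
#'
#' Draws from the session RNG: seed the caller (`set.seed`) for
#' reproducibility.
#'
#' @param image square image array.
#' @param arbitrary_angle rotate by a uniform angle in `[0, 2*pi)` with
#'   bilinear interpolation instead of quarter turns.
#' @return augmented image, same shape.
#' @export
augment <- function(image, arbitrary_angle = FALSE) {
  image <- as_image_array(image)
  if (arbitrary_angle) {
    ang <- runif(1, 0, 360)
    for (c in seq_len(dim(image)[3]))
      image[, , c] <- EBImage::rotate(image[, , c], ang,
                                      output.dim = dim(image)[1:2])
  } else {
    image <- rotate_quarter(image, sample(0:3, 1))
  }
  if (runif(1) < 0.5) image <- image[, dim(image)[2]:1, , drop = FALSE]
  image
}

# stack a list of (E, E, C) arrays into the (E, E, C, N) batch layout the
# compiled primitives expect
stack_images <- function(images) {
  d <- dim(images[[1]])
  out <- array(0, c(d, length(images)))
  for (i in seq_along(images)) out[, , , i] <- images[[i]]
  out
}

# preprocess every image of a cohort once; returns the stacked array plus
# per-image observed labels and the owning patient index
cohort_to_arrays <- function(cohort, target_edge, mode = "resize") {
  imgs <- list(); labels <- integer(0); pindex <- integer(0)
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    for (im in p$images) {
      imgs[[length(imgs) + 1L]] <-
        resize_or_pad(load_pixels(im), target_edge, mode)
      labels <- c(labels, im$observed_label)
      pindex <- c(pindex, i)
    }
  }
  list(x = stack_images(imgs), labels = labels, patient_index = pindex)
}
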