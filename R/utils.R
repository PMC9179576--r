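#' Round half away from zero
#'
#' Decimal rounding with the "half-up" tie rule used for reported
#' percentages (e.g. 374/592 -> 63.2), as opposed to base R's banker's
#' rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_rcc <- function(...) stop(..., call. = FALSE)

# restore the caller's RNG state on exit; used by every seeded generator so
# that package functions do not clobber the session RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# coerce an image to an (H, W, C) array with C in {1, 3}
as_image_array <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop_rcc("image must be a matrix or an (H, W, C) array")
  if (!dim(image)[3] %in% c(1L, 3L))
    stop_rcc("image must have 1 or 3 channels")
  image
}
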