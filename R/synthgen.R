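#' Configuration for the synthetic cohort generator
#'
#' The defaults emulate the composition of the study cohort the pipeline is
#' designed for: 706 patients with a ~60/40 low/high grade imbalance, a
#' temporal development/validation structure (years 2010--2017 vs
#' 2018--2019, roughly 84%/16%), 10--25 ROI images per patient (~17 on
#' average) of varying raw sizes, and one-directional label noise in which
#' a fraction of high-labelled patients have lesions drawn from the
#' low-grade appearance distribution.
#'
#' @param n_patients number of patients.
#' @param high_fraction target fraction of high-grade patients.
#' @param images_per_patient_range integer (min, max); each patient gets a
#'   uniform draw of images in this range.
#' @param image_size_range integer (min, max) raw edge lengths in px,
#'   deliberately variable so the resize/pad path is exercised.
#' @param noise_rate_true probability that a high-labelled patient's
#'   appearance is drawn from the low-grade distribution (`true_label = 0`
#'   while `observed_label = 1`). Low-labelled patients are never corrupted.
#' @param year_range integer (min, max) acquisition years.
#' @param year_cutoff first validation year (patients with
#'   `year >= year_cutoff` are the temporal hold-out).
#' @param validation_fraction fraction of patients assigned years
#'   `>= year_cutoff`.
#' @param p_male probability of covariate `sex == "male"`.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param appearance_params per-grade lesion appearance: list with numeric
#'   length-4 vectors `radius_frac` (lesion semi-axis as a fraction of the
#'   image edge) and `heterogeneity` (amplitude of intra-lesion speckle),
#'   both increasing with grade, plus scalars `background_level`,
#'   `background_sd`, `lesion_level`, and `orientation_gradient` — the
#'   amplitude of a fixed head-to-foot background intensity trend shared
#'   by all grades, emulating the consistent patient orientation of real
#'   CT crops (it is what makes the rotation pretext task well-posed).
#' @return an object of class `rcc_synth_config`.
#' @export
synth_config <- function(n_patients = 706L,
                         high_fraction = 0.4,
                         images_per_patient_range = c(10L, 25L),
                         image_size_range = c(24L, 96L),
                         noise_rate_true = 0.4,
                         year_range = c(2010L, 2019L),
                         year_cutoff = 2018L,
                         validation_fraction = 114 / 706,
                         p_male = 0.632,
                         seed = 1L,
                         appearance_params = default_appearance()) {
  stopifnot(high_fraction >= 0, high_fraction <= 1,
            noise_rate_true >= 0, noise_rate_true <= 1,
            validation_fraction >= 0, validation_fraction <= 1)
  if (images_per_patient_range[1] < 1L ||
      diff(images_per_patient_range) < 0)
    stop_rcc("images_per_patient_range must be a non-degenerate range >= 1")
  if (image_size_range[1] < 8L || diff(image_size_range) < 0)
    stop_rcc("image_size_range must be a non-degenerate range >= 8")
  if (year_cutoff <= year_range[1] || year_cutoff > year_range[2])
    stop_rcc("year_cutoff must fall inside year_range")
  structure(
    list(n_patients = as.integer(n_patients),
         high_fraction = high_fraction,
         images_per_patient_range = as.integer(images_per_patient_range),
         image_size_range = as.integer(image_size_range),
         noise_rate_true = noise_rate_true,
         year_range = as.integer(year_range),
         year_cutoff = as.integer(year_cutoff),
         validation_fraction = validation_fraction,
         p_male = p_male,
         seed = as.integer(seed),
         appearance_params = appearance_params),
    class = "rcc_synth_config")
}

#' @rdname synth_config
#' @export
default_appearance <- function() {
  list(radius_frac = c(0.16, 0.22, 0.30, 0.38),
       heterogeneity = c(0.04, 0.08, 0.16, 0.24),
       background_level = 0.25,
       background_sd = 0.06,
       lesion_level = 0.65,
       orientation_gradient = 0.12)
}

# sample() treats a scalar first argument as 1:x; guard degenerate ranges
sample_one <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# one lesion phantom: Gaussian-textured background plus a rotated ellipse
# whose area and internal speckle grow with the generating grade
gen_lesion_image <- function(edge, grade, ap) {
  img <- matrix(rnorm(edge * edge, ap$background_level, ap$background_sd),
                edge, edge)
  # gentle head-to-foot intensity trend: real ROI crops share one patient
  # orientation, which is what makes rotation prediction well-posed; the
  # trend is identical across grades so it carries no grading signal
  og <- ap$orientation_gradient %||% 0
  if (og != 0)
    img <- img + og * (seq_len(edge) - (edge + 1) / 2) / edge
  cx <- edge / 2 + runif(1, -0.08, 0.08) * edge
  cy <- edge / 2 + runif(1, -0.08, 0.08) * edge
  a <- ap$radius_frac[grade] * edge * (1 + runif(1, -0.15, 0.15))
  b <- ap$radius_frac[grade] * edge * (1 + runif(1, -0.15, 0.15))
  theta <- runif(1, 0, pi)
  xs <- matrix(seq_len(edge), edge, edge) - cx          # row coordinate
  ys <- matrix(seq_len(edge), edge, edge, byrow = TRUE) - cy
  u <- xs * cos(theta) + ys * sin(theta)
  v <- -xs * sin(theta) + ys * cos(theta)
  mask <- (u / a)^2 + (v / b)^2 <= 1

  het <- ap$heterogeneity[grade]
  coarse_n <- max(2L, ceiling(edge / 4))
  coarse <- kronecker(matrix(rnorm(coarse_n^2), coarse_n, coarse_n),
                      matrix(1, 4, 4))[seq_len(edge), seq_len(edge)]
  speckle <- het * (0.6 * coarse + 0.4 * matrix(rnorm(edge * edge), edge, edge))
  img[mask] <- ap$lesion_level + speckle[mask]
  pmin(pmax(img, 0), 1)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`. Each patient receives a grade (1--2
#' for low, 3--4 for high), an acquisition year consistent with the
#' temporal split structure, a `sex` covariate, and M ~ uniform images of
#' varying raw size whose lesion appearance follows the patient's
#' *appearance grade*. A `noise_rate_true` fraction of high-labelled
#' patients (Bernoulli per patient) are corrupted: their appearance grade
#' is drawn from {1, 2} and every image carries `true_label = 0` while the
#' observed label stays 1. Low-labelled patients are never corrupted.
#'
#' @param config an [synth_config()].
#' @param dir optional directory; when given, images are written as PNG
#'   files and a `manifest.csv` compatible with [read_manifest()] is
#'   produced there. Otherwise the cohort is held in memory.
#' @return an `rcc_cohort`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "rcc_synth_config"))
  if (config$n_patients < 1L) stop_rcc("n_patients must be at least 1")
  ap <- config$appearance_params
  with_seed(config$seed, {
    n <- config$n_patients
    n_high <- round(n * config$high_fraction)
    is_high <- sample(rep(c(TRUE, FALSE), c(n_high, n - n_high)))
    n_val <- round(n * config$validation_fraction)
    is_val <- sample(rep(c(TRUE, FALSE), c(n_val, n - n_val)))

    patients <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- sprintf("P%04d", i)
      grade <- if (is_high[i]) sample_one(3:4) else sample_one(1:2)
      corrupted <- is_high[i] && rbinom(1, 1, config$noise_rate_true) == 1L
      appearance_grade <- if (corrupted) sample_one(1:2) else grade
      year <- if (is_val[i]) {
        sample_one(config$year_cutoff:config$year_range[2])
      } else {
        sample_one(config$year_range[1]:(config$year_cutoff - 1L))
      }
      m <- sample_one(config$images_per_patient_range[1]:
                        config$images_per_patient_range[2])
      obs <- as.integer(grade >= 3)
      true_lab <- if (corrupted) 0L else obs
      images <- lapply(seq_len(m), function(k) {
        edge <- sample_one(config$image_size_range[1]:config$image_size_range[2])
        image_sample(patient_id = pid, observed_label = obs,
                     pixels = gen_lesion_image(edge, appearance_grade, ap),
                     true_label = true_lab,
                     image_id = sprintf("%s_%03d", pid, k))
      })
      sex <- if (runif(1) < config$p_male) "male" else "female"
      patients[[i]] <- patient(pid, grade, year, images,
                               covariates = list(sex = sex))
    }
    coh <- cohort(patients, name = sprintf("synthetic_seed%d", config$seed))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      write_manifest(coh, file.path(dir, "manifest.csv"),
                     image_dir = file.path(dir, "images"))
      coh <- read_manifest(file.path(dir, "manifest.csv"))
    }
    coh
  })
}

#' Realized label-noise report for a synthetic cohort
#'
#' Computes the realized corruption rate among high-labelled patients
#' (fraction whose hidden true label is low grade) and verifies that no
#' low-labelled patient is corrupted — the noise is one-directional by
#' construction.
#'
#' @param cohort an `rcc_cohort` whose images carry true labels.
#' @return list with `n_high`, `n_corrupted`, `realized_rate` (NA when the
#'   cohort has no high-labelled patients), and `low_grade_clean` (TRUE).
#' @export
corruption_report <- function(cohort) {
  pt_true <- vapply(cohort$patients, function(p) {
    tl <- vapply(p$images, function(im) im$true_label, integer(1))
    if (anyNA(tl)) NA_integer_ else max(tl)
  }, integer(1))
  if (anyNA(pt_true))
    stop_rcc("cohort has images without true labels; not a synthetic cohort?")
  obs <- cohort_labels(cohort)
  high <- obs == 1L
  n_corrupted <- sum(high & pt_true == 0L)
  low_clean <- all(pt_true[!high] == obs[!high])
  if (!low_clean)
    stop_rcc("low-labelled patients must never be corrupted")
  list(n_high = sum(high),
       n_corrupted = n_corrupted,
       realized_rate = if (any(high)) n_corrupted / sum(high) else NA_real_,
       low_grade_clean = low_clean)
}

#' Mean thresholded lesion-area statistic per patient group
#'
#' A deliberately simple pixel statistic — the fraction of pixels brighter
#' than `threshold` — used to verify that the generator produces a
#' learnable signal: lesion area grows with the generating grade, so the
#' statistic separates true-label groups.
#'
#' @param cohort an `rcc_cohort` with in-memory or loadable pixels.
#' @param threshold intensity cut separating lesion from background.
#' @return data.frame with one row per patient: `patient_id`,
#'   `true_label` (observed label when hidden truth is absent),
#'   `fuhrman_grade`, `mean_area`.
#' @export
lesion_area_stats <- function(cohort, threshold = 0.45) {
  rows <- lapply(cohort$patients, function(p) {
    areas <- vapply(p$images, function(im) {
      px <- load_pixels(im)
      mean(px > threshold)
    }, numeric(1))
    tl <- vapply(p$images, function(im) im$true_label, integer(1))
    data.frame(patient_id = p$patient_id,
               true_label = if (anyNA(tl)) p$binary_label else max(tl),
               fuhrman_grade = p$fuhrman_grade,
               mean_area = mean(areas), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
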