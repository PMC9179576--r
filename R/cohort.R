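#' Construct a single image sample
#'
#' One 2-D ROI-cropped image belonging to a patient. Pixels may be held in
#' memory (`pixels`) or referenced by file (`path`) and loaded lazily with
#' [load_pixels()]. The observed label is the per-patient binary grade the
#' image inherits; synthetic cohorts may additionally carry a hidden true
#' label, which can only disagree in one direction: an image labelled
#' high grade may truly be low grade, never the reverse.
#'
#' @param patient_id string linking the image to its patient.
#' @param observed_label 0 (low grade) or 1 (high grade).
#' @param pixels optional numeric matrix or (H, W, C) array, values in
#'   `[0, 1]`, C in `{1, 3}`, both edges >= 8.
#' @param path optional path to a PNG or TIFF file.
#' @param true_label optional hidden true label (synthetic cohorts only);
#'   must satisfy `true_label <= observed_label`.
#' @param image_id identifier; defaults to the path or a generated id.
#' @return an object of class `rcc_image`.
#' @export
image_sample <- function(patient_id, observed_label, pixels = NULL,
                         path = NULL, true_label = NA_integer_,
                         image_id = NULL) {
  if (is.null(pixels) && is.null(path))
    stop_rcc("an image sample needs either pixels or a path")
  if (!observed_label %in% c(0, 1)) stop_rcc("observed_label must be 0 or 1")
  if (!is.na(true_label)) {
    if (!true_label %in% c(0, 1)) stop_rcc("true_label must be 0, 1 or NA")
    if (true_label > observed_label)
      stop_rcc("label noise is one-directional: true_label <= observed_label")
  }
  if (!is.null(pixels)) {
    pixels <- as_image_array(pixels)
    if (any(dim(pixels)[1:2] < 8L))
      stop_rcc("image edges must be at least 8 px")
  }
  structure(
    list(image_id = image_id %||% path %||%
           paste0(patient_id, "_img", sample.int(.Machine$integer.max, 1)),
         patient_id = patient_id,
         pixels = pixels, path = path,
         observed_label = as.integer(observed_label),
         true_label = as.integer(true_label)),
    class = "rcc_image")
}

#' Load the pixel data of an image sample
#'
#' Returns the in-memory pixels if present, otherwise reads the referenced
#' PNG/TIFF file. Values are scaled to `[0, 1]`.
#'
#' @param sample an `rcc_image`.
#' @return an (H, W, C) array.
#' @export
load_pixels <- function(sample) {
  if (!is.null(sample$pixels)) return(sample$pixels)
  path <- sample$path
  if (is.null(path) || !file.exists(path))
    stop_rcc("image file not found: ", path %||% "<missing path>")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_rcc("unsupported image format: .", ext))
  as_image_array(img)
}

#' Construct a patient record
#'
#' The binary label is derived from the Fuhrman grade: grades I and II are
#' low grade (0), grades III and IV are high grade (1).
#'
#' @param patient_id unique string.
#' @param fuhrman_grade integer 1--4.
#' @param acquisition_year calendar year of the CT acquisition.
#' @param images list of [image_sample()] objects (at least one), all
#'   carrying this `patient_id`.
#' @param covariates optional named list of categorical covariates
#'   (e.g. `sex = "male"`), surfaced by [cohort_stats()].
#' @return an object of class `rcc_patient`.
#' @export
patient <- function(patient_id, fuhrman_grade, acquisition_year, images,
                    covariates = list()) {
  if (!fuhrman_grade %in% 1:4)
    stop_rcc("fuhrman_grade must be in 1..4, got ", fuhrman_grade,
             " for patient ", patient_id)
  if (length(images) < 1L) stop_rcc("patient ", patient_id, " has no images")
  for (img in images) {
    if (!inherits(img, "rcc_image")) stop_rcc("images must be rcc_image objects")
    if (!identical(img$patient_id, patient_id))
      stop_rcc("image ", img$image_id, " does not belong to patient ", patient_id)
  }
  structure(
    list(patient_id = patient_id,
         fuhrman_grade = as.integer(fuhrman_grade),
         binary_label = as.integer(fuhrman_grade >= 3),
         acquisition_year = as.integer(acquisition_year),
         images = images,
         covariates = covariates),
    class = "rcc_patient")
}

#' Construct a cohort
#'
#' @param patients list of [patient()] objects with unique ids.
#' @param name cohort name.
#' @return an object of class `rcc_cohort`.
#' @export
cohort <- function(patients, name = "cohort") {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop_rcc("patient ids must be unique")
  structure(list(name = name, patients = patients), class = "rcc_cohort")
}

#' @export
print.rcc_cohort <- function(x, ...) {
  cat(sprintf("<rcc_cohort '%s': %d patients, %d images>\n",
              x$name, n_patients(x), n_images(x)))
  invisible(x)
}

#' Number of patients / images in a cohort
#' @param cohort an `rcc_cohort`.
#' @return integer count.
#' @export
n_patients <- function(cohort) length(cohort$patients)

#' @rdname n_patients
#' @export
n_images <- function(cohort)
  sum(vapply(cohort$patients, function(p) length(p$images), integer(1)))

patient_field <- function(cohort, field)
  vapply(cohort$patients, function(p) p[[field]], vector(typeof(0L), 1))

cohort_labels <- function(cohort)
  vapply(cohort$patients, function(p) p$binary_label, integer(1))

#' Read a cohort manifest
#'
#' Reads a CSV (default) or JSON manifest with one record per image and
#' fields `patient_id`, `fuhrman_grade`, `acquisition_year`, `image_path`,
#' optional `true_label`, plus any categorical covariate columns. Rows
#' sharing a `patient_id` are grouped into one patient in first-appearance
#' order; image paths are resolved relative to the manifest's directory and
#' loaded lazily.
#'
#' @param path manifest file (`.csv` or `.json`).
#' @return an `rcc_cohort`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_rcc("manifest not found: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  required <- c("patient_id", "fuhrman_grade", "acquisition_year", "image_path")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_rcc("manifest lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    return(cohort(list(), name = tools::file_path_sans_ext(basename(path))))

  bad <- which(!df$fuhrman_grade %in% 1:4)
  if (length(bad))
    stop_rcc("row ", bad[1], ": fuhrman_grade must be in 1..4, got ",
             df$fuhrman_grade[bad[1]])
  has_true <- "true_label" %in% names(df)
  covar_cols <- setdiff(names(df), c(required, "true_label", "observed_label",
                                     "image_id"))
  base_dir <- dirname(normalizePath(path))

  ids <- unique(df$patient_id)
  patients <- lapply(ids, function(id) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    grade <- rows$fuhrman_grade[1]
    obs <- as.integer(grade >= 3)
    imgs <- lapply(seq_len(nrow(rows)), function(r) {
      ipath <- rows$image_path[r]
      if (!file.exists(ipath)) ipath <- file.path(base_dir, rows$image_path[r])
      image_sample(
        patient_id = id, observed_label = obs, path = ipath,
        true_label = if (has_true && !is.na(rows$true_label[r]))
          rows$true_label[r] else NA_integer_,
        image_id = if ("image_id" %in% names(rows)) rows$image_id[r] else ipath)
    })
    covs <- as.list(rows[1, covar_cols, drop = FALSE])
    patient(id, grade, rows$acquisition_year[1], imgs, covariates = covs)
  })
  cohort(patients, name = tools::file_path_sans_ext(basename(path)))
}

#' Write a cohort manifest
#'
#' Writes one CSV (or JSON) row per image. Images held only in memory are
#' first written as PNG files under `image_dir`; paths are stored relative
#' to the manifest's directory so the pair travels as a unit.
#'
#' @param cohort an `rcc_cohort`.
#' @param path output manifest path (`.csv` or `.json`).
#' @param image_dir where to place PNGs for in-memory images; defaults to
#'   an `images/` directory next to the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path, image_dir = NULL) {
  base_dir <- dirname(path)
  dir.create(base_dir, recursive = TRUE, showWarnings = FALSE)
  image_dir <- image_dir %||% file.path(base_dir, "images")

  rows <- list()
  for (p in cohort$patients) {
    for (k in seq_along(p$images)) {
      img <- p$images[[k]]
      ipath <- img$path
      if (is.null(ipath)) {
        dir.create(image_dir, recursive = TRUE, showWarnings = FALSE)
        ipath <- file.path(image_dir,
                           sprintf("%s_%03d.png", p$patient_id, k))
        px <- img$pixels
        if (dim(px)[3] == 1L) px <- px[, , 1]
        png::writePNG(pmin(pmax(px, 0), 1), target = ipath)
      }
      row <- data.frame(patient_id = p$patient_id,
                        fuhrman_grade = p$fuhrman_grade,
                        acquisition_year = p$acquisition_year,
                        image_path = ipath,
                        true_label = img$true_label,
                        stringsAsFactors = FALSE)
      for (nm in names(p$covariates)) row[[nm]] <- p$covariates[[nm]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), fuhrman_grade = integer(),
               acquisition_year = integer(), image_path = character(),
               true_label = integer())
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(df, path, dataframe = "columns", na = "null")
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Split a cohort by acquisition year
#'
#' Patients acquired before `cutoff_year` form the development cohort;
#' patients acquired in or after `cutoff_year` form the validation cohort
#' (the "after 2018, including 2018" convention). The partition is
#' exhaustive and disjoint and preserves patient order within each part.
#'
#' @param cohort an `rcc_cohort`.
#' @param cutoff_year integer calendar year.
#' @return list with elements `development` and `validation`.
#' @export
temporal_split <- function(cohort, cutoff_year) {
  years <- patient_field(cohort, "acquisition_year")
  dev <- cohort$patients[years < cutoff_year]
  val <- cohort$patients[years >= cutoff_year]
  list(development = cohort(dev, name = paste0(cohort$name, "_development")),
       validation = cohort(val, name = paste0(cohort$name, "_validation")))
}

#' Descriptive cohort statistics
#'
#' Patient and image counts plus counts and percentages (half-up, one
#' decimal; base = number of patients) for the binary label and for every
#' categorical covariate present.
#'
#' @param cohort a non-empty `rcc_cohort`.
#' @return an object of class `rcc_cohort_stats`: a list with `n_patients`,
#'   `n_images`, and for each factor a table of counts and percentages.
#' @export
cohort_stats <- function(cohort) {
  n <- n_patients(cohort)
  if (n == 0L) stop_rcc("cohort is empty")
  pct_table <- function(x, levels_order = sort(unique(x))) {
    counts <- vapply(levels_order, function(l) sum(x == l), integer(1))
    data.frame(level = as.character(levels_order), count = counts,
               percent = round_half_up(100 * counts / n, 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  labels <- cohort_labels(cohort)
  out <- list(
    name = cohort$name,
    n_patients = n,
    n_images = n_images(cohort),
    binary_label = pct_table(ifelse(labels == 1, "high-grade", "low-grade"),
                             c("low-grade", "high-grade")),
    fuhrman_grade = pct_table(patient_field(cohort, "fuhrman_grade"), 1:4))
  covar_names <- unique(unlist(lapply(cohort$patients,
                                      function(p) names(p$covariates))))
  for (nm in covar_names) {
    vals <- vapply(cohort$patients,
                   function(p) as.character(p$covariates[[nm]] %||% NA),
                   character(1))
    out[[nm]] <- pct_table(vals[!is.na(vals)])
  }
  structure(out, class = "rcc_cohort_stats")
}

#' @export
print.rcc_cohort_stats <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d patients, %d images\n",
              x$name, x$n_patients, x$n_images))
  for (nm in setdiff(names(x), c("name", "n_patients", "n_images"))) {
    cat(nm, ":\n", sep = "")
    tab <- x[[nm]]
    for (r in seq_len(nrow(tab)))
      cat(sprintf("  %-12s %5d (%.1f%%)\n",
                  tab$level[r], tab$count[r], tab$percent[r]))
  }
  invisible(x)
}
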