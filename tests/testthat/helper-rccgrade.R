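# shared fixtures and independent oracles

# a flat 8x8 single-channel image, enough to satisfy the size invariant
tiny_pixels <- function(value = 0.5) matrix(value, 8, 8)

# build a patient with k trivial images
make_patient <- function(id, grade, year, k = 1L, covariates = list()) {
  imgs <- lapply(seq_len(k), function(j)
    image_sample(patient_id = id, observed_label = as.integer(grade >= 3),
                 pixels = tiny_pixels(), image_id = paste0(id, "_", j)))
  patient(id, grade, year, imgs, covariates = covariates)
}

# a cohort with prescribed class/covariate composition, one image each
make_counts_cohort <- function(n_low, n_high, n_male = 0L, year = 2015L) {
  n <- n_low + n_high
  patients <- lapply(seq_len(n), function(i) {
    grade <- if (i <= n_low) 1L else 3L
    covs <- if (n_male > 0L)
      list(sex = if (i <= n_male) "male" else "female")
    else list()
    make_patient(sprintf("p%04d", i), grade, year, covariates = covs)
  })
  cohort(patients, name = "counts")
}

# a small in-memory synthetic cohort for pipeline tests
small_synth_cohort <- function(seed = 1L, n = 20L, ...) {
  generate_cohort(synth_config(n_patients = n, seed = seed,
                               images_per_patient_range = c(2L, 4L),
                               image_size_range = c(16L, 40L), ...))
}

# scalar double-loop loss oracles, written independently of the package's
# vectorised implementations
oracle_ce <- function(probs, labels, eps = 1e-12) {
  n <- nrow(probs); total <- 0
  for (i in seq_len(n)) {
    for (j in 0:1) {
      l_ij <- if (labels[i] == j) 1 else 0
      total <- total + l_ij * log(max(probs[i, j + 1], eps))
    }
  }
  -total / n
}
oracle_ce_class0 <- function(probs, labels, eps = 1e-12) {
  n <- nrow(probs); total <- 0
  for (i in seq_len(n)) {
    l_i0 <- if (labels[i] == 0) 1 else 0
    total <- total + l_i0 * log(max(probs[i, 1], eps))
  }
  -total / n
}
oracle_mixed <- function(probs, labels, alpha, eps = 1e-12) {
  alpha * oracle_ce(probs, labels, eps) +
    (1 - alpha) * oracle_ce_class0(probs, labels, eps)
}
oracle_weighted_ce <- function(probs, labels, lam0, lam1, eps = 1e-12) {
  n <- nrow(probs); total <- 0
  for (i in seq_len(n)) {
    for (j in 0:1) {
      l_ij <- if (labels[i] == j) 1 else 0
      lam <- if (j == 0) lam0 else lam1
      total <- total + lam * l_ij * log(max(probs[i, j + 1], eps))
    }
  }
  -total / n
}
oracle_total_weighted <- function(probs, labels, alpha, lam0, lam1,
                                  eps = 1e-12) {
  n <- nrow(probs); t1 <- 0; t2 <- 0
  for (i in seq_len(n)) {
    for (j in 0:1) {
      l_ij <- if (labels[i] == j) 1 else 0
      lam <- if (j == 0) lam0 else lam1
      t1 <- t1 + lam * l_ij * log(max(probs[i, j + 1], eps))
    }
    l_i0 <- if (labels[i] == 0) 1 else 0
    t2 <- t2 + lam0 * l_i0 * log(max(probs[i, 1], eps))
  }
  -alpha * t1 / n - (1 - alpha) * t2 / n
}

random_batch <- function(n_max = 16L) {
  n <- sample(2:n_max, 1)
  p1 <- runif(n, 0.01, 0.99)
  batch_prediction(cbind(p1, 1 - p1), sample(0:1, n, replace = TRUE))
}

# brute-force AUC: average pairwise win probability with half credit for ties
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (if (p > q) 1 else if (p == q) 0.5 else 0)
  total / (length(pos) * length(neg))
}
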