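#' Experiment configuration
#'
#' One structure drives the whole pipeline: generate -> split -> pretrain
#' -> develop -> evaluate -> ensemble -> ablate. The defaults are the
#' desk-scale profile used throughout the package's tests: an 80-patient
#' synthetic cohort, 32 px images, the small CNN backbone, 20 pretext +
#' 25 development epochs. The reference-scale protocol (224 px, 60 + 100
#' epochs, four large published backbones) uses the same machinery with
#' different numbers.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @param synth list of [synth_config()] overrides (the generator seed
#'   defaults to `seed`).
#' @param input_edge square image size fed to the backbone.
#' @param channels conv channels of the [small_cnn()] backbone.
#' @param pretext_epochs,develop_epochs epochs for the two phases.
#' @param base_lr,backbone_lr_ratio,weight_decay,batch_size,warmup_epochs
#'   optimisation protocol (see [train_config()]).
#' @param alpha assumed label-noise rate for the mixed loss.
#' @param class_weight_scheme scheme for [class_weights_from_counts()].
#' @param threshold decision threshold for acc/sen/spc.
#' @param n_models number of models trained for the `full` cell; with
#'   more than one, their validation predictions are combined with
#'   decile-stripped AUC weights (AUCs measured on the development side).
#' @param cells which ablation cells to run, a subset of
#'   `c("base", "ssl", "loss", "full")`: `base` = neither pretext
#'   initialisation nor the noise/imbalance objective; `ssl` = pretext
#'   only; `loss` = mixed loss + reweighting only; `full` = everything.
#' @return an object of class `rcc_experiment_config`.
#' @export
experiment_config <- function(seed,
                              synth = list(),
                              input_edge = 32L,
                              channels = c(8L, 16L, 32L, 32L),
                              pretext_epochs = 20L,
                              develop_epochs = 25L,
                              base_lr = 0.1,
                              backbone_lr_ratio = 0.1,
                              weight_decay = 1e-4,
                              batch_size = 32L,
                              warmup_epochs = 5L,
                              alpha = 0.4,
                              class_weight_scheme = "inverse_frequency",
                              threshold = 0.5,
                              n_models = 1L,
                              cells = c("base", "ssl", "loss", "full")) {
  if (missing(seed) || is.null(seed)) stop_rcc("a seed is required")
  cells <- match.arg(cells, several.ok = TRUE)
  synth_defaults <- list(n_patients = 80L, image_size_range = c(24L, 96L),
                         high_fraction = 0.4, noise_rate_true = 0.4,
                         seed = as.integer(seed))
  synth <- utils::modifyList(synth_defaults, synth)
  structure(list(seed = as.integer(seed), synth = synth,
                 input_edge = as.integer(input_edge),
                 channels = as.integer(channels),
                 pretext_epochs = as.integer(pretext_epochs),
                 develop_epochs = as.integer(develop_epochs),
                 base_lr = base_lr, backbone_lr_ratio = backbone_lr_ratio,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 warmup_epochs = as.integer(warmup_epochs),
                 alpha = alpha, class_weight_scheme = class_weight_scheme,
                 threshold = threshold, n_models = as.integer(n_models),
                 cells = cells),
            class = "rcc_experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path configuration file; keys mirror [experiment_config()]
#'   arguments (`seed` is required).
#' @return an `rcc_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_rcc("config file not found: ", path)
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path) else yaml::read_yaml(path)
  if (is.null(raw$seed)) stop_rcc("config must contain a seed")
  do.call(experiment_config, raw)
}

cell_flags <- function(cell) {
  switch(cell,
         base = list(use_pretext = FALSE, use_mixed_loss = FALSE,
                     use_reweighting = FALSE),
         ssl = list(use_pretext = TRUE, use_mixed_loss = FALSE,
                    use_reweighting = FALSE),
         loss = list(use_pretext = FALSE, use_mixed_loss = TRUE,
                     use_reweighting = TRUE),
         full = list(use_pretext = TRUE, use_mixed_loss = TRUE,
                     use_reweighting = TRUE),
         stop_rcc("unknown ablation cell: ", cell))
}

cell_loss_config <- function(flags, config, dev_cohort) {
  alpha <- if (flags$use_mixed_loss) config$alpha else 1
  if (flags$use_reweighting) {
    n_img_low <- sum(vapply(dev_cohort$patients, function(p)
      if (p$binary_label == 0L) length(p$images) else 0L, integer(1)))
    n_img_high <- n_images(dev_cohort) - n_img_low
    lam <- class_weights_from_counts(n_img_low, n_img_high,
                                     config$class_weight_scheme,
                                     alpha = config$alpha)
  } else {
    lam <- c(lambda0 = 1, lambda1 = 1)
  }
  loss_config(alpha = alpha, lambda0 = lam[["lambda0"]],
              lambda1 = lam[["lambda1"]])
}

#' Run a full experiment
#'
#' Generates the synthetic cohort, splits it temporally, pretrains the
#' backbone on the rotation pretext where a cell requires it, develops a
#' grading model per ablation cell, evaluates every model on the
#' validation cohort, and (for `n_models > 1`) ensembles the `full`-cell
#' models with decile-stripped development-side AUC weights. Fully
#' reproducible from the config.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory; when given, the manifest, per-cell
#'   prediction CSVs, evaluation JSONs, ROC point TSVs and the summary
#'   CSV are written there.
#' @param quiet suppress progress messages.
#' @return an `rcc_experiment` bundle: list with `config`, `cohorts`
#'   (development/validation), `predictions` (per cell), `evals`,
#'   `models`, and `summary` (one row per cell, plus an ensemble row when
#'   applicable).
#' @export
run_experiment <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "rcc_experiment_config"))
  say <- function(...) if (!quiet) message("[rccgrade] ", ...)

  say("generating synthetic cohort (n = ", config$synth$n_patients, ")")
  coh <- generate_cohort(do.call(synth_config, config$synth))
  split <- temporal_split(coh, do.call(synth_config, config$synth)$year_cutoff)
  dev <- split$development; val <- split$validation
  say("split: ", n_patients(dev), " development / ", n_patients(val),
      " validation patients")

  backbone <- small_cnn(config$input_edge, config$channels)
  dev_data <- cohort_to_arrays(dev, config$input_edge)
  dev_images <- lapply(seq_len(dim(dev_data$x)[4]),
                       function(i) dev_data$x[, , , i])

  needs_ssl <- any(vapply(config$cells,
                          function(cl) cell_flags(cl)$use_pretext,
                          logical(1)))
  pretrained <- NULL
  if (needs_ssl) {
    say("pretraining on the rotation pretext (",
        4 * length(dev_images), " samples)")
    rot <- build_rotation_dataset(dev_images)
    pre_cfg <- train_config(epochs = config$pretext_epochs,
                            warmup_epochs = config$warmup_epochs,
                            base_lr = config$base_lr,
                            weight_decay = config$weight_decay,
                            batch_size = config$batch_size,
                            seed = config$seed)
    pretrained <- pretrain(model_spec(backbone, "linear", 4L,
                                      init_seed = config$seed),
                           rot, pre_cfg)
    say("held-out pretext accuracy: ",
        sprintf("%.3f", pretrained$pretext_accuracy))
  }

  train_one <- function(cell, model_seed) {
    flags <- cell_flags(cell)
    spec <- model_spec(backbone, "nonlinear_projection", 2L,
                       init_seed = model_seed)
    model <- if (flags$use_pretext) transfer_weights(pretrained, spec)
             else init_model(spec)
    cfg <- train_config(epochs = config$develop_epochs,
                        warmup_epochs = config$warmup_epochs,
                        base_lr = config$base_lr,
                        backbone_lr_ratio = config$backbone_lr_ratio,
                        weight_decay = config$weight_decay,
                        batch_size = config$batch_size,
                        seed = model_seed,
                        loss = cell_loss_config(flags, config, dev))
    develop(model, dev, cfg)
  }

  predictions <- list(); evals <- list(); models <- list()
  rows <- list()
  for (cell in config$cells) {
    say("developing cell '", cell, "'")
    model <- train_one(cell, config$seed)
    pred <- score_cohort(model, val)
    ev <- evaluate_predictions(pred, config$threshold)
    predictions[[cell]] <- pred; evals[[cell]] <- ev
    models[[cell]] <- model
    rows[[cell]] <- data.frame(cell = cell, model = "m1", acc = ev$acc,
                               sen = ev$sen, spc = ev$spc, auc = ev$auc)
  }

  if (config$n_models > 1L && "full" %in% config$cells) {
    say("training ", config$n_models - 1L, " additional full-cell models ",
        "for the ensemble")
    full_models <- c(list(models[["full"]]),
                     lapply(seq_len(config$n_models - 1L), function(m)
                       train_one("full", config$seed + 100L * m)))
    val_preds <- lapply(full_models, score_cohort, cohort = val)
    dev_aucs <- vapply(full_models, function(m)
      roc_auc(score_cohort(m, dev))$auc, numeric(1))
    weights <- tryCatch(decile_stripped_weights(dev_aucs),
                        error = function(e) dev_aucs)
    ens <- ensemble_cohort(val_preds, weights)
    ev <- evaluate_predictions(ens, config$threshold)
    predictions[["ensemble"]] <- ens; evals[["ensemble"]] <- ev
    for (k in seq_along(val_preds)) {
      evk <- evaluate_predictions(val_preds[[k]], config$threshold)
      rows[[paste0("full_m", k)]] <-
        data.frame(cell = "full", model = paste0("m", k), acc = evk$acc,
                   sen = evk$sen, spc = evk$spc, auc = evk$auc)
    }
    rows[["ensemble"]] <- data.frame(cell = "ensemble", model = "ensemble",
                                     acc = ev$acc, sen = ev$sen,
                                     spc = ev$spc, auc = ev$auc)
    rows[["full"]] <- NULL
    models[["full_models"]] <- full_models
    models[["ensemble_weights"]] <- weights
  }

  summary <- do.call(rbind, unname(rows))
  rownames(summary) <- NULL
  bundle <- structure(list(config = config,
                           cohorts = list(development = dev, validation = val),
                           pretrained = pretrained,
                           predictions = predictions, evals = evals,
                           models = models, summary = summary),
                      class = "rcc_experiment")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$summary, file.path(out_dir, "summary.csv"),
            row.names = FALSE)
  for (nm in names(bundle$predictions)) {
    write.csv(as.data.frame(bundle$predictions[[nm]]),
              file.path(out_dir, paste0("predictions_", nm, ".csv")),
              row.names = FALSE)
    ev <- bundle$evals[[nm]]
    jsonlite::write_json(ev[c("acc", "sen", "spc", "auc", "threshold")],
                         file.path(out_dir, paste0("eval_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write.table(ev$roc_points,
                file.path(out_dir, paste0("roc_", nm, ".tsv")),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Summarise an experiment for reading
#'
#' Produces the per-Fuhrman-grade prediction matrix (the fraction of
#' validation patients of each generating grade called low / high at the
#' configured threshold; rows sum to 100) for the chosen predictions, and
#' returns it with the run's summary table.
#'
#' @param bundle an `rcc_experiment` from [run_experiment()].
#' @param which which predictions to use for the grade matrix
#'   (default the ensemble when present, else the `full` cell, else the
#'   last cell run).
#' @param out_dir optional directory for `grade_matrix.csv`.
#' @return list with `summary` and `grade_matrix` (percentages, half-up,
#'   one decimal).
#' @export
report_experiment <- function(bundle, which = NULL, out_dir = NULL) {
  stopifnot(inherits(bundle, "rcc_experiment"))
  if (is.null(bundle$predictions) || !length(bundle$predictions))
    stop_rcc("bundle has no predictions; run_experiment() first")
  which <- which %||%
    if ("ensemble" %in% names(bundle$predictions)) "ensemble" else
      utils::tail(names(bundle$predictions), 1)
  pred <- bundle$predictions[[which]]
  val <- bundle$cohorts$validation
  grades <- patient_field(val, "fuhrman_grade")
  stopifnot(identical(vapply(val$patients, function(p) p$patient_id,
                             character(1)), pred$patient_id))
  thr <- bundle$config$threshold
  called_high <- pred$score >= thr
  rows <- lapply(sort(unique(grades)), function(g) {
    sel <- grades == g
    data.frame(fuhrman_grade = g, n = sum(sel),
               pct_low = round_half_up(100 * mean(!called_high[sel]), 1),
               pct_high = round_half_up(100 * mean(called_high[sel]), 1))
  })
  gm <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(gm, file.path(out_dir, "grade_matrix.csv"), row.names = FALSE)
  }
  list(summary = bundle$summary, grade_matrix = gm, predictions_used = which)
}
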