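#' Cross-validated evaluation of one configuration
#'
#' Trains the spec's model once per fold rotation (training folds balanced
#' per the spec's `balancing` policy, validation fold driving early
#' stopping) and evaluates on the rotation's test fold. The configuration's
#' performance is the average of the per-fold overall accuracy and average
#' recall per class. Training divergence (non-finite loss) marks the
#' rotation as failed instead of crashing; a configuration with any failed
#' rotation is flagged.
#'
#' @param spec A [model_spec()].
#' @param dataset A [feature_dataset()] already prepared on the spec's track.
#' @param folds A [make_folds()] plan for `dataset`.
#' @param config A [train_config()].
#' @param rotations Which rotations to run (default all `k`).
#' @return A `cv_result`: list with `spec`, per-rotation metrics data frame,
#'   `mean_accuracy`, `mean_recall`, `failed`.
#' @export
cv_evaluate <- function(spec, dataset, folds, config = train_config(),
                        rotations = seq_len(folds$k)) {
  stopifnot(inherits(spec, "model_spec"), inherits(folds, "fold_plan"))
  per <- lapply(rotations, function(r) {
    rot <- folds$rotations[[r]]
    fit <- fit_rotation(spec, dataset, rot, config)
    if (fit$failed) {
      return(data.frame(rotation = r, accuracy = NA_real_,
                        recall = NA_real_, failed = TRUE))
    }
    rep_ <- fit$report
    data.frame(rotation = r, accuracy = rep_$overall_accuracy,
               recall = rep_$average_recall, failed = FALSE)
  })
  per <- do.call(rbind, per)
  structure(list(spec = spec, metrics = per,
                 mean_accuracy = mean(per$accuracy),
                 mean_recall = mean(per$recall),
                 failed = any(per$failed)),
            class = "cv_result")
}

# Train on one rotation and evaluate its test fold.
fit_rotation <- function(spec, dataset, rot, config) {
  train <- subset_dataset(dataset, rot$train)
  val <- subset_dataset(dataset, rot$validation)
  test <- subset_dataset(dataset, rot$test)
  bal <- apply_balancing(train, spec$balancing %||% "none",
                         seed = config$seed)
  inp_shape <- model_input(train, spec$family)$input_shape
  model <- build_model(spec, inp_shape, length(dataset$class_set),
                       class_set = dataset$class_set, seed = config$seed)
  model <- tryCatch(
    train_model(model, bal$data, validation = val, config = config,
                class_weights = bal$class_weights),
    error = function(e) e)
  if (inherits(model, "error") ||
      isTRUE(model$history$diverged)) {
    return(list(failed = TRUE))
  }
  p <- predict_proba(model, test)
  pred <- predict_emotion(p, dataset$class_set)
  cm <- confusion_matrix(test$y, pred, dataset$class_set)
  list(failed = FALSE, model = model,
       report = eval_report(cm, zero_support = "mask"))
}

#' Run a grid search with cross-validation
#'
#' Evaluates every configuration of a grid (or a supplied spec list) with
#' [cv_evaluate()] and collects one row per configuration per rotation plus
#' the fold-averaged means.
#'
#' @param specs List of [model_spec()]s (e.g. from [enumerate_grid()]).
#' @param dataset,folds,config As in [cv_evaluate()].
#' @param rotations Rotations to run per configuration.
#' @return A `grid_result`: list with `results` (list of `cv_result`) and
#'   `table` (data frame: config id, hyperparameters, mean metrics).
#' @export
grid_search <- function(specs, dataset, folds, config = train_config(),
                        rotations = seq_len(folds$k)) {
  results <- lapply(seq_along(specs), function(i) {
    cv_evaluate(specs[[i]], dataset, folds, config, rotations)
  })
  tab <- do.call(rbind, lapply(seq_along(results), function(i) {
    sp <- specs[[i]]
    hp <- sp[setdiff(names(sp), "family")]
    hp <- vapply(hp, function(v) paste(format(v), collapse = ","),
                 character(1))
    data.frame(config = i, family = sp$family,
               params = paste(names(hp), hp, sep = "=", collapse = ";"),
               mean_accuracy = results[[i]]$mean_accuracy,
               mean_recall = results[[i]]$mean_recall,
               failed = results[[i]]$failed,
               stringsAsFactors = FALSE)
  }))
  structure(list(results = results, table = tab), class = "grid_result")
}

#' Select the best configuration and run the final training
#'
#' Picks the best non-failed configuration (highest fold-averaged overall
#' accuracy by default, configurable to average recall; ties break toward
#' the earliest configuration in enumeration order), retrains it with the
#' final epoch cap (1000 by default) on the first rotation's training and
#' validation folds, and reports test-fold metrics.
#'
#' @param grid_result A [grid_search()] result.
#' @param dataset,folds As used for the search.
#' @param final_config A [train_config()] with the final epoch cap.
#' @param score `"accuracy"` (default) or `"recall"`.
#' @param rotation Rotation whose split is used for the final training.
#' @return List with `spec`, `model` (trained), `report` (an
#'   [eval_report()]), `score`.
#' @export
select_and_train_final <- function(grid_result, dataset, folds,
                                   final_config = train_config(max_epochs = 1000),
                                   score = c("accuracy", "recall"),
                                   rotation = 1L) {
  score <- match.arg(score)
  results <- grid_result$results
  if (length(results) == 0L) stop("empty grid-search results")
  vals <- vapply(results, function(r) {
    if (r$failed) -Inf else if (score == "accuracy") r$mean_accuracy else r$mean_recall
  }, numeric(1))
  if (all(!is.finite(vals))) stop("every configuration failed")
  best <- which.max(vals)                  # first maximum: earliest config
  spec <- results[[best]]$spec
  fit <- fit_rotation(spec, dataset, folds$rotations[[rotation]],
                      final_config)
  if (fit$failed) stop("final training diverged")
  list(spec = spec, model = fit$model, report = fit$report,
       score = vals[best], config_index = best)
}
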