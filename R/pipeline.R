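# End-to-end orchestration: simulate -> split -> train -> predict ->
# evaluate -> shelf-life -> report, as a single seeded, reproducible run.

#' Experiment configuration
#'
#' @param cohort a [cohort_config()].
#' @param datasets data frame with columns `group` (one of `"general"`,
#'   `"T10"`, `"T20"`, `"Tamb"`) and `index` (5 or 10). The study design
#'   duplicates four datasets over the two index systems, eight in total.
#' @param fractions train/validation/test fractions.
#' @param render a [render_config()].
#' @param training a [training_config()] (its `num_classes` and `seed` are
#'   set per dataset).
#' @param augment an [augmentation_config()].
#' @param out_dir run directory for all artifacts.
#' @param seed master seed of the run (cohort, splits).
#' @param train_seed seed for classifier training only; two runs sharing
#'   `seed` but differing in `train_seed` train different models on
#'   identical test sets, enabling [compare_models()].
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              datasets = expand.grid(
                                group = c("general", "T10", "T20", "Tamb"),
                                index = c(5L, 10L), stringsAsFactors = FALSE),
                              fractions = c(0.70, 0.15, 0.15),
                              render = render_config(),
                              training = training_config(),
                              augment = augmentation_config(),
                              out_dir = tempfile("ripen_run_"), seed = 1L,
                              train_seed = seed) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(datasets$group %in% c("general", storage_groups())),
            all(datasets$index %in% c(5L, 10L)))
  structure(list(cohort = cohort, datasets = datasets, fractions = fractions,
                 render = render, training = training, augment = augment,
                 out_dir = out_dir, seed = as.integer(seed),
                 train_seed = as.integer(train_seed)),
            class = "experiment_config")
}

.ds_name <- function(group, index) sprintf("%s_ri%d", group, index)

#' Run the full ripening / shelf-life experiment
#'
#' Simulates the cohort, then for every configured dataset (storage group x
#' index system): builds a leakage-free grouped split, oversamples the
#' training set, trains the stage classifier, predicts the test set and
#' scores it (margin-of-error accuracy per picture and per sample, per-stage
#' accuracy, confusion matrix); fits the per-group forced-endpoint
#' shelf-life regressions on the attributed classifications, converts both
#' attributed and predicted stages into shelf-life losses, and smooths the
#' losses with a 1-day-bandwidth KDE. All stage outputs are written under
#' the run directory and indexed by a JSON manifest. Fully seeded: equal
#' configurations and seeds reproduce the run.
#'
#' @param config an [experiment_config()].
#' @return object of class `ripen_experiment`: the `manifest` (also written
#'   as `manifest.json`), per-dataset `predictions`, fitted shelf-life
#'   `models` and the trained classifiers.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort, seed = config$seed))
  provider <- cohort_image_provider(cohort, config$render)
  rec_all <- cohort$records
  utils::write.csv(rec_all, file.path(out, "database.csv"), row.names = FALSE)

  # forced-endpoint regressions per storage group x index system
  sl_models <- list()
  reg_rows <- list()
  for (g in intersect(storage_groups(), unique(rec_all$group))) {
    for (index in c(5L, 10L)) {
      d <- rec_all[rec_all$group == g & !rec_all$censored, , drop = FALSE]
      fit <- stage("shelflife", if (index == 10L)
        shelf_life_fit(days_left9 ~ ri10, d, endpoint = 9) else
          shelf_life_fit(days_left5 ~ ri5, d, endpoint = 5))
      sl_models[[sprintf("%s_ri%d", g, index)]] <- fit
      reg_rows[[length(reg_rows) + 1L]] <-
        data.frame(group = g, index = index, alpha = coef(fit)[["alpha"]],
                   se = fit$se, ci95 = fit$ci95, r_squared = fit$r.squared,
                   n = fit$n)
    }
  }
  regression <- do.call(rbind, reg_rows)
  utils::write.csv(regression, file.path(out, "regression.csv"), row.names = FALSE)

  datasets <- config$datasets
  ds_manifest <- list()
  predictions <- list()
  classifiers <- list()
  metric_rows <- list()
  loss_rows <- list()
  for (i in seq_len(nrow(datasets))) {
    g <- datasets$group[i]; index <- as.integer(datasets$index[i])
    nm <- .ds_name(g, index)
    recs <- if (g == "general") rec_all else
      rec_all[rec_all$group == g, , drop = FALSE]
    split <- stage("split", grouped_stratified_split(
      recs, config$fractions, seed = derive_seed(config$seed, "split", nm)))
    tcfg <- config$training
    tcfg$num_classes <- index
    tcfg$seed <- derive_seed(config$train_seed, "train", nm)
    model <- stage("train", train_ripening_classifier(
      recs, split, provider, tcfg, config$augment))
    classifiers[[nm]] <- model

    test_rec <- split_records(recs, split, "test")
    preds <- stage("predict", predict(model, test_rec, provider))
    dl_col <- if (index == 10L) "days_left9" else "days_left5"
    preds[[dl_col]] <- test_rec[[dl_col]][match(
      paste(preds$sample_id, preds$side, preds$day),
      paste(test_rec$sample_id, test_rec$side, test_rec$day))]
    predictions[[nm]] <- preds

    for (mode in c("picture", "sample")) for (margin in 0:2)
      metric_rows[[length(metric_rows) + 1L]] <-
        data.frame(dataset = nm, mode = mode, margin = margin,
                   accuracy = stage_accuracy(preds, mode, margin))
    cm <- confusion_matrix(preds, classes = seq_len(index))

    groups_here <- if (g == "general") intersect(storage_groups(),
                                                 unique(preds$group)) else g
    models_here <- stats::setNames(
      lapply(groups_here, function(gg) sl_models[[sprintf("%s_ri%d", gg, index)]]),
      groups_here)
    stage_col_true <- if (index == 10L) "ri10" else "ri5"
    attributed <- test_rec
    for (mode in c("picture", "sample")) {
      lt_pred <- stage("loss", loss_table(preds, models_here,
                                          stage_col = "pred_stage",
                                          actual_col = dl_col, by = mode))
      lt_attr <- stage("loss", loss_table(attributed, models_here,
                                          stage_col = stage_col_true,
                                          actual_col = dl_col, by = mode))
      loss_rows[[length(loss_rows) + 1L]] <-
        data.frame(dataset = nm, source = c("predicted", "attributed"),
                   mode = mode,
                   mean_abs_loss = c(lt_pred$overall, lt_attr$overall))
      if (mode == "picture") {
        kde <- rbind(cbind(source = "predicted", kde_loss(lt_pred$records$loss)),
                     cbind(source = "attributed", kde_loss(lt_attr$records$loss)))
        utils::write.csv(kde, file.path(out, sprintf("kde_%s.csv", nm)),
                         row.names = FALSE)
      }
    }

    utils::write.csv(model$history, file.path(out, sprintf("history_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(data.frame(sample_id = c(split$train_ids, split$val_ids,
                                              split$test_ids),
                                subset = rep(c("train", "validation", "test"),
                                             c(length(split$train_ids),
                                               length(split$val_ids),
                                               length(split$test_ids)))),
                     file.path(out, sprintf("split_%s.csv", nm)), row.names = FALSE)
    utils::write.csv(preds, file.path(out, sprintf("predictions_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cm), file.path(out, sprintf("confusion_%s.csv", nm)),
                     row.names = FALSE)

    ds_manifest[[nm]] <- list(
      group = g, index = index,
      n_samples = length(unique(recs$sample_id)),
      n_train = length(split$train_ids), n_val = length(split$val_ids),
      n_test = length(split$test_ids),
      best_val_accuracy = model$best_val_accuracy,
      best_iteration = model$best_iteration,
      test_accuracy_margin0 = stage_accuracy(preds, "picture", 0),
      artifacts = sprintf("%s_%s.csv", c("history", "split", "predictions",
                                         "confusion", "kde"), nm))
  }
  metrics <- do.call(rbind, metric_rows)
  losses <- do.call(rbind, loss_rows)
  utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  utils::write.csv(losses, file.path(out, "loss_summary.csv"), row.names = FALSE)

  manifest <- list(
    created_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    train_seed = config$train_seed,
    cohort = list(n_t10 = config$cohort$n_t10, n_t20 = config$cohort$n_t20,
                  n_tamb = config$cohort$n_tamb,
                  n_fruits = length(cohort$trajectories),
                  n_records = nrow(rec_all),
                  index_target = config$cohort$index_target),
    regression = regression,
    datasets = ds_manifest,
    metrics = metrics,
    losses = losses,
    artifacts = c("database.csv", "regression.csv", "metrics.csv",
                  "loss_summary.csv",
                  unlist(lapply(ds_manifest, `[[`, "artifacts"), use.names = FALSE)))
  missing_art <- manifest$artifacts[!file.exists(file.path(out, manifest$artifacts))]
  if (length(missing_art))
    stop("stage 'report' failed: missing artifacts ",
         paste(missing_art, collapse = ", "), call. = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(manifest = manifest, predictions = predictions,
                 shelf_life_models = sl_models, classifiers = classifiers,
                 out_dir = out),
            class = "ripen_experiment")
}

#' @export
print.ripen_experiment <- function(x, ...) {
  cat(sprintf("ripening experiment run: %d datasets, artifacts in %s\n",
              length(x$manifest$datasets), x$out_dir))
  for (nm in names(x$manifest$datasets)) {
    d <- x$manifest$datasets[[nm]]
    cat(sprintf("  %-12s val acc %.3f, test acc (margin 0) %.3f\n",
                nm, d$best_val_accuracy, d$test_accuracy_margin0))
  }
  invisible(x)
}

#' Compare two experiment runs on their shared test sets
#'
#' For every dataset present in both runs (and covering identical test
#' records), reports the two-model error overlap and side-by-side
#' margin-of-error accuracies.
#'
#' @param runA,runB [run_experiment()] objects.
#' @return object of class `model_comparison`: per-dataset `overlap`
#'   summaries and an `accuracy` data frame.
#' @export
compare_models <- function(runA, runB) {
  stopifnot(inherits(runA, "ripen_experiment"), inherits(runB, "ripen_experiment"))
  shared <- intersect(names(runA$predictions), names(runB$predictions))
  if (!length(shared)) stop("no shared datasets to compare", call. = FALSE)
  overlap <- list()
  acc <- list()
  for (nm in shared) {
    pa <- runA$predictions[[nm]]; pb <- runB$predictions[[nm]]
    overlap[[nm]] <- error_overlap(pa, pb)
    for (margin in 0:1)
      acc[[length(acc) + 1L]] <- data.frame(
        dataset = nm, margin = margin,
        accuracy_A = stage_accuracy(pa, "picture", margin),
        accuracy_B = stage_accuracy(pb, "picture", margin))
  }
  structure(list(overlap = overlap, accuracy = do.call(rbind, acc)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  for (nm in names(x$overlap)) {
    cat(nm, ": ", sep = "")
    print(x$overlap[[nm]])
  }
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}
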