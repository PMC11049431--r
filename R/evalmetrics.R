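# Accuracy metrics with a margin of error, per-picture and per-sample
# (best side) modes, confusion matrices, and two-model error overlap.

.check_preds <- function(preds) {
  stopifnot(is.data.frame(preds),
            all(c("true_stage", "pred_stage") %in% names(preds)))
  if (!nrow(preds)) stop("empty prediction set", call. = FALSE)
  invisible(preds)
}

.sample_day_hit <- function(preds, margin) {
  hit <- abs(preds$pred_stage - preds$true_stage) <= margin
  key <- paste(preds$sample_id, preds$day)
  sides <- table(key)
  if (any(sides < 2L))
    warning("unpaired sides for some sample-days; counted on available sides",
            call. = FALSE)
  tapply(hit, key, any)
}

#' Margin-of-error accuracy, per picture or per sample
#'
#' Picture mode: fraction of photographs whose predicted stage is within
#' `margin` stages of the truth. Sample mode: fraction of (sample, day)
#' pairs where at least one of the two photographed sides meets the margin
#' criterion (the model's "best side" potential).
#'
#' @param preds prediction records, see [predict.ripening_classifier()].
#' @param mode `"picture"` or `"sample"`.
#' @param margin non-negative integer margin in stages.
#' @return accuracy fraction in [0, 1].
#' @export
stage_accuracy <- function(preds, mode = c("picture", "sample"), margin = 0L) {
  .check_preds(preds)
  mode <- match.arg(mode)
  stopifnot(margin >= 0)
  if (mode == "picture")
    return(mean(abs(preds$pred_stage - preds$true_stage) <= margin))
  mean(.sample_day_hit(preds, margin))
}

#' Accuracy by true stage
#'
#' @inheritParams stage_accuracy
#' @param stages stages to report, default all stages of the model's index
#'   system present in the truth range.
#' @return data frame (stage, n, accuracy); stages with no records get
#'   `n = 0` and `NA` accuracy (undefined, never 0 or 1).
#' @export
per_stage_accuracy <- function(preds, mode = c("picture", "sample"), margin = 0L,
                               stages = NULL) {
  .check_preds(preds)
  mode <- match.arg(mode)
  if (is.null(stages))
    stages <- seq_len(if (max(preds$true_stage) > 5L) 10L else 5L)
  out <- data.frame(stage = stages, n = 0L, accuracy = NA_real_)
  for (i in seq_along(stages)) {
    sel <- preds$true_stage == stages[i]
    if (!any(sel)) next
    sub <- preds[sel, , drop = FALSE]
    out$n[i] <- if (mode == "picture") nrow(sub) else
      length(unique(paste(sub$sample_id, sub$day)))
    out$accuracy[i] <- stage_accuracy(sub, mode, margin)
  }
  out
}

#' Confusion matrix of stage predictions
#'
#' @param preds prediction records.
#' @param classes stage labels spanning the index system; default inferred.
#' @return K x K integer matrix, rows = true stage, columns = predicted
#'   stage; the trace over the total equals margin-0 picture accuracy.
#' @export
confusion_matrix <- function(preds, classes = NULL) {
  .check_preds(preds)
  if (is.null(classes))
    classes <- seq_len(if (max(c(preds$true_stage, preds$pred_stage)) > 5L) 10L else 5L)
  m <- table(factor(preds$true_stage, levels = classes),
             factor(preds$pred_stage, levels = classes))
  m <- matrix(as.integer(m), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Error overlap between two models on the same test set
#'
#' Partitions the common record set by the margin-0 correctness of each
#' model: errors unique to each model, shared errors, and records both
#' models classify correctly.
#'
#' @param predsA,predsB prediction records covering the identical
#'   (sample_id, side, day) records.
#' @return object of class `overlap_summary`: counts `errors_only_A`,
#'   `errors_only_B`, `errors_shared`, `correct_both`, and `n`.
#' @export
error_overlap <- function(predsA, predsB) {
  .check_preds(predsA); .check_preds(predsB)
  key <- function(p) paste(p$sample_id, p$side, p$day)
  ka <- key(predsA); kb <- key(predsB)
  if (nrow(predsA) != nrow(predsB) || !setequal(ka, kb) || anyDuplicated(ka))
    stop("prediction sets must cover the identical records", call. = FALSE)
  b <- predsB[match(ka, kb), , drop = FALSE]
  errA <- predsA$pred_stage != predsA$true_stage
  errB <- b$pred_stage != b$true_stage
  structure(list(errors_only_A = sum(errA & !errB),
                 errors_only_B = sum(errB & !errA),
                 errors_shared = sum(errA & errB),
                 correct_both = sum(!errA & !errB),
                 n = length(errA)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf(paste0("error overlap on %d records: %d only A, %d only B, ",
                     "%d shared, %d correct in both\n"),
              x$n, x$errors_only_A, x$errors_only_B, x$errors_shared,
              x$correct_both))
  invisible(x)
}
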