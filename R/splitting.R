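# Sample-grouped 70/15/15 partition and random oversampling.
#
# Every photograph of a fruit goes to exactly one subset (no leakage); a
# greedy randomized assignment keeps per-stage record proportions close to
# the subset fractions. Oversampling duplicates randomly chosen training
# records per stage until all stages match the largest stage count; the
# validation and test sets are never touched.

#' Leakage-free grouped, approximately stratified split
#'
#' Samples (all sides, all days of one fruit) are assigned whole to the
#' training, validation or test subset. Assignment is greedy in a seeded
#' random sample order: each sample goes to the subset where it most reduces
#' the deviation of per-stage record counts (plus total record counts) from
#' the subset's target share. Deterministic given the seed.
#'
#' @param db records, cohort or db object.
#' @param fractions length-3 positive vector (train, validation, test)
#'   summing to 1.
#' @param seed integer seed.
#' @param stage_col stage column driving the stratification (default the
#'   10-stage index).
#' @return object of class `dataset_split`: `train_ids`, `val_ids`,
#'   `test_ids` (disjoint sample ids covering all samples), `fractions`,
#'   `seed`.
#' @export
grouped_stratified_split <- function(db, fractions = c(0.70, 0.15, 0.15),
                                     seed = 1L, stage_col = "ri10") {
  rec <- db_records(db)
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  ids <- unique(rec$sample_id)
  if (length(ids) < 3L) stop("fewer samples than subsets", call. = FALSE)
  stages <- sort(unique(rec[[stage_col]]))
  # per-sample stage profile: record counts per stage
  pm <- vapply(ids, function(id) {
    tabulate(match(rec[[stage_col]][rec$sample_id == id], stages),
             nbins = length(stages))
  }, integer(length(stages)))
  prof <- if (length(stages) == 1L) matrix(pm, ncol = 1L) else t(pm)
  total_by_stage <- colSums(prof)
  n_total <- sum(total_by_stage)

  subsets <- c("train", "validation", "test")
  target <- outer(fractions, c(total_by_stage, n_total))  # 3 x (stages+1)
  current <- matrix(0, 3L, length(stages) + 1L)
  assign_to <- integer(length(ids))

  order_ids <- withr::with_seed(derive_seed(seed, "split"), sample(seq_along(ids)))
  for (k in seq_along(order_ids)) {
    i <- order_ids[k]
    add <- c(prof[i, ], sum(prof[i, ]))
    if (k <= 3L) {
      s <- k   # every subset gets at least one sample
    } else {
      cost <- vapply(1:3, function(s) {
        trial <- current
        trial[s, ] <- trial[s, ] + add
        sum((trial - target)^2 / pmax(target, 1))
      }, numeric(1))
      s <- which.min(cost)
    }
    assign_to[i] <- s
    current[s, ] <- current[s, ] + add
  }
  structure(list(train_ids = sort(ids[assign_to == 1L]),
                 val_ids = sort(ids[assign_to == 2L]),
                 test_ids = sort(ids[assign_to == 3L]),
                 fractions = fractions, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split: %d train / %d validation / %d test samples\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids)))
  invisible(x)
}

# subset label ("train"/"validation"/"test") for each sample id
split_subset_of <- function(split, sample_id) {
  stopifnot(inherits(split, "dataset_split"))
  out <- rep(NA_character_, length(sample_id))
  out[sample_id %in% split$train_ids] <- "train"
  out[sample_id %in% split$val_ids] <- "validation"
  out[sample_id %in% split$test_ids] <- "test"
  if (anyNA(out)) stop("split does not cover all samples", call. = FALSE)
  out
}

#' Records of one subset of a split
#'
#' @param db records, cohort or db object.
#' @param split a [grouped_stratified_split()].
#' @param subset `"train"`, `"validation"` or `"test"`.
#' @return records data frame restricted to the subset's samples.
#' @export
split_records <- function(db, split, subset = c("train", "validation", "test")) {
  subset <- match.arg(subset)
  rec <- db_records(db)
  ids <- switch(subset, train = split$train_ids, validation = split$val_ids,
                test = split$test_ids)
  out <- rec[rec$sample_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Random oversampling of the training records
#'
#' Duplicates randomly chosen training records of each understated stage
#' until every stage's count equals the largest stage count in training
#' (classes already at the maximum are untouched; a stage entirely absent
#' from training stays at zero and is reported). Only training data is ever
#' oversampled.
#'
#' @param train_records training-subset records (see [split_records()]).
#' @param label stage column to balance on: `"ri10"` or `"ri5"`.
#' @param seed integer seed.
#' @return records data frame: the original training records plus duplicates,
#'   balanced per stage.
#' @export
oversample_training <- function(train_records, label = c("ri10", "ri5"), seed = 1L) {
  label <- match.arg(label)
  rec <- db_records(train_records)
  if (!nrow(rec)) stop("empty training set", call. = FALSE)
  counts <- table(rec[[label]])
  n_max <- max(counts)
  n_stages <- if (label == "ri10") 10L else 5L
  absent <- setdiff(seq_len(n_stages), as.integer(names(counts)))
  if (length(absent))
    warning("stage(s) absent from training, left at zero: ",
            paste(absent, collapse = ", "), call. = FALSE)
  extra <- withr::with_seed(derive_seed(seed, "oversample"), {
    idx <- unlist(lapply(names(counts), function(st) {
      need <- n_max - counts[[st]]
      if (need == 0L) return(integer())
      pool <- which(rec[[label]] == as.integer(st))
      sample(pool, need, replace = TRUE)
    }))
    idx
  })
  out <- rbind(rec, rec[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}
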