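# Labelled image database: index semantics, Days Left annotation,
# descriptive statistics, CSV/PNG persistence, dry-matter utility.

.DB_COLUMNS <- c("sample_id", "side", "group", "day", "date_stamp",
                 "ri5", "ri10", "days_left5", "days_left9", "censored")

db_records <- function(x) {
  if (inherits(x, "fruit_cohort") || inherits(x, "fruit_db")) return(x$records)
  if (is.data.frame(x)) return(x)
  stop("expected a fruit_cohort, fruit_db or records data frame", call. = FALSE)
}

#' Map the 10-stage Ripening Index to the 5-stage index
#'
#' Each original 5-stage index was divided in half to form the 10-stage
#' index, so stages 2k-1 and 2k map back to stage k: `ri5 = ceiling(ri10/2)`.
#'
#' @param ri10 integer vector in 1..10.
#' @return integer vector in 1..5.
#' @examples
#' stage5_from_stage10(1:10)  # 1 1 2 2 3 3 4 4 5 5
#' @export
stage5_from_stage10 <- function(ri10) {
  if (any(is.na(ri10)) || any(ri10 < 1 | ri10 > 10 | ri10 != floor(ri10)))
    stop("ri10 must be integers in 1..10", call. = FALSE)
  as.integer(ceiling(ri10 / 2))
}

#' Annotate Days Left to the shelf-life endpoints
#'
#' For every sample, Days Left is the number of days from the photograph to
#' the first day the sample was classified at the endpoint stage (stage 5 of
#' the 5-stage index, stage 9 of the 10-stage index); it is 0 on the endpoint
#' day and undefined (NA) for photographs taken after it. Samples never
#' reaching the endpoint are flagged censored with undefined Days Left.
#' Idempotent: re-annotating changes nothing.
#'
#' @param db records data frame, [simulate_cohort()] or [read_fruit_db()]
#'   object (needs per-day stages per sample).
#' @return records data frame with `days_left5`, `days_left9`, `censored`
#'   recomputed.
#' @export
annotate_days_left <- function(db) {
  rec <- db_records(db)
  stopifnot(all(c("sample_id", "day", "ri10") %in% names(rec)))
  first_day_at <- function(day, ri, threshold) {
    hit <- day[ri >= threshold]
    if (length(hit)) min(hit) else NA_integer_
  }
  ep9 <- tapply(seq_len(nrow(rec)), rec$sample_id, function(i)
    first_day_at(rec$day[i], rec$ri10[i], 9L))
  ep <- ep9[as.character(rec$sample_id)]
  rec$censored <- is.na(ep)
  dl <- as.numeric(ep - rec$day)
  dl[!is.na(dl) & dl < 0] <- NA_real_
  rec$days_left9 <- dl
  rec$days_left5 <- dl   # first stage-5(5) day is the first stage-9(10) day
  rec
}

#' Per-stage record counts by subset
#'
#' Descriptive tally of the database in the style of the study's database
#' summary: photographs per Ripening Index stage in each of the train /
#' validation / test subsets, with row and column totals.
#'
#' @param db records or cohort/db object.
#' @param split a [grouped_stratified_split()] object, or `NULL` to count
#'   the whole database in one column.
#' @param index 10 or 5: which Ripening Index to tally.
#' @return integer matrix, stages (+ `Total`) x subsets (+ `Total`).
#' @export
summarize_counts <- function(db, split = NULL, index = 10L) {
  rec <- db_records(db)
  stage_col <- if (index == 10L) "ri10" else "ri5"
  stages <- seq_len(if (index == 10L) 10L else 5L)
  subset_of <- if (is.null(split)) rep("all", nrow(rec)) else
    split_subset_of(split, rec$sample_id)
  subsets <- if (is.null(split)) "all" else c("train", "validation", "test")
  m <- matrix(0L, length(stages), length(subsets),
              dimnames = list(stages, subsets))
  if (nrow(rec)) {
    t0 <- table(factor(rec[[stage_col]], levels = stages),
                factor(subset_of, levels = subsets))
    m[] <- as.integer(t0)
  }
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  storage.mode(m) <- "integer"
  m
}

#' Dry matter content
#'
#' Standard dry-matter definition: dehydrated flesh mass as a percentage of
#' raw flesh mass, the harvest-maturity proxy for avocado. Per-fruit values
#' are the mean over that fruit's flesh samples (vectorized: pass the three
#' sample masses and average).
#'
#' @param raw_flesh_mass raw flesh mass in grams (> 0).
#' @param dehydrated_flesh_mass dehydrated flesh mass in grams, in
#'   `[0, raw_flesh_mass]`.
#' @return dry matter percentage(s) in [0, 100].
#' @examples
#' dry_matter(10, 3.4)  # 34
#' @export
dry_matter <- function(raw_flesh_mass, dehydrated_flesh_mass) {
  if (any(raw_flesh_mass <= 0)) stop("raw flesh mass must be positive", call. = FALSE)
  if (any(dehydrated_flesh_mass < 0) || any(dehydrated_flesh_mass > raw_flesh_mass))
    stop("dehydrated mass must lie in [0, raw mass]", call. = FALSE)
  100 * dehydrated_flesh_mass / raw_flesh_mass
}

validate_records <- function(rec) {
  missing_cols <- setdiff(c("sample_id", "side", "group", "day", "ri5", "ri10"),
                          names(rec))
  if (length(missing_cols))
    stop("missing metadata columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad_group <- setdiff(unique(rec$group), storage_groups())
  if (length(bad_group))
    stop("unknown storage group label: ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  key <- paste(rec$sample_id, rec$side, rec$day)
  dup <- key[duplicated(key)]
  if (length(dup))
    stop("duplicate (sample_id, side, day) key: ", dup[1], call. = FALSE)
  if (any(rec$ri5 != stage5_from_stage10(rec$ri10)))
    stop("ri5 inconsistent with ceiling(ri10/2)", call. = FALSE)
  invisible(rec)
}

#' Write / read a labelled image database directory
#'
#' Layout: `metadata.csv` with one row per photograph plus, optionally, an
#' `images/` directory of PNG renders referenced by relative path in an
#' `image` column. Reading validates the metadata (known storage groups, no
#' duplicate (sample_id, side, day) keys, 5-/10-stage consistency, existing
#' image files) and the round trip is lossless for all metadata fields.
#'
#' @param db cohort, db object or records data frame.
#' @param directory target/source directory.
#' @param images `FALSE` (metadata only) or an image-provider function (see
#'   [cohort_image_provider()]) used to render and save one PNG per record.
#' @return `write_fruit_db()` returns the directory invisibly;
#'   `read_fruit_db()` returns an object of class `fruit_db` with `records`
#'   and `dir`.
#' @export
write_fruit_db <- function(db, directory, images = FALSE) {
  rec <- db_records(db)
  validate_records(rec)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (is.function(images)) {
    dir.create(file.path(directory, "images"), showWarnings = FALSE)
    rec$image <- sprintf("images/s%04d_%s_d%02d.png",
                         rec$sample_id, rec$side, rec$day)
    for (i in seq_len(nrow(rec)))
      png::writePNG(images(rec[i, ]), file.path(directory, rec$image[i]))
  }
  utils::write.csv(rec, file.path(directory, "metadata.csv"), row.names = FALSE)
  invisible(directory)
}

#' @rdname write_fruit_db
#' @export
read_fruit_db <- function(directory) {
  path <- file.path(directory, "metadata.csv")
  if (!file.exists(path)) stop("no metadata.csv in ", directory, call. = FALSE)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_records(rec)
  if (!is.null(rec$image)) {
    missing_img <- !file.exists(file.path(directory, rec$image))
    if (any(missing_img))
      stop("missing image file (metadata row ", which(missing_img)[1], "): ",
           rec$image[which(missing_img)[1]], call. = FALSE)
  }
  structure(list(records = rec, dir = directory), class = "fruit_db")
}

#' @export
print.fruit_db <- function(x, ...) {
  cat(sprintf("fruit image database: %d records, %d samples (%s)\n",
              nrow(x$records), length(unique(x$records$sample_id)), x$dir))
  invisible(x)
}
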