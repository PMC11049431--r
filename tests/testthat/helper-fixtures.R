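# Shared fixtures, built in code and memoised for the test session.

.fix <- new.env(parent = emptyenv())

# small mixed-group cohort with renderable images (26 fruits, 48 px)
small_cohort <- function() {
  if (is.null(.fix$cohort)) {
    .fix$cohort <- simulate_cohort(
      cohort_config(n_t10 = 10L, n_t20 = 8L, n_tamb = 8L, seed = 9L))
    .fix$render <- render_config(image_size = 48L)
    .fix$provider <- cohort_image_provider(.fix$cohort, .fix$render)
  }
  .fix$cohort
}
small_provider <- function() { small_cohort(); .fix$provider }
small_render_cfg <- function() { small_cohort(); .fix$render }

# augmentation with translation scaled to the 48-px renders
scaled_augment <- function() augmentation_config(translate_px = c(-2, 2))

# deterministic synthetic prediction records for the metric oracles
random_preds <- function(n, k = 5L, seed = 1L, sides = c("front", "back")) {
  withr::with_seed(seed, {
    sample_day <- data.frame(sample_id = sample(1:20, ceiling(n / 2), TRUE),
                             day = sample(0:6, ceiling(n / 2), TRUE))
    sample_day <- unique(sample_day)
    out <- do.call(rbind, lapply(seq_len(nrow(sample_day)), function(i)
      data.frame(sample_id = sample_day$sample_id[i], side = sides,
                 day = sample_day$day[i])))
    out <- out[seq_len(min(n, nrow(out))), ]
    out$group <- sample(c("T10", "T20", "Tamb"), nrow(out), TRUE)
    out$true_stage <- sample(seq_len(k), nrow(out), TRUE)
    out$pred_stage <- sample(seq_len(k), nrow(out), TRUE)
    rownames(out) <- NULL
    out
  })
}

# brute-force margin accuracy by explicit loops (enumeration oracle)
oracle_accuracy <- function(preds, mode, margin) {
  hits <- 0; total <- 0
  if (mode == "picture") {
    for (i in seq_len(nrow(preds))) {
      total <- total + 1
      if (abs(preds$pred_stage[i] - preds$true_stage[i]) <= margin)
        hits <- hits + 1
    }
  } else {
    for (id in unique(preds$sample_id)) {
      for (d in unique(preds$day[preds$sample_id == id])) {
        rows <- which(preds$sample_id == id & preds$day == d)
        total <- total + 1
        ok <- FALSE
        for (i in rows)
          if (abs(preds$pred_stage[i] - preds$true_stage[i]) <= margin)
            ok <- TRUE
        if (ok) hits <- hits + 1
      }
    }
  }
  hits / total
}
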