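# Ripening-stage classifier: geometric augmentation, compact backbone,
# minibatch SGD training with a step learning-rate schedule, periodic
# validation with patience-based early stopping and best-checkpoint
# selection, and deterministic prediction.

#' Geometric augmentation configuration
#'
#' One randomly augmented version of each training image is used during each
#' epoch. Defaults are the study's deliberately subtle ranges: random
#' reflection, rotation in [-10, 10] degrees, rescaling in [0.95, 1.05] and
#' translations in [-10, 10] pixels on each axis.
#'
#' @param reflect enable random horizontal reflection.
#' @param rotation_deg length-2 rotation range, degrees.
#' @param scale length-2 rescaling range.
#' @param translate_px length-2 translation range, pixels (both axes).
#' @return list of class `augmentation_config`. Zero-width ranges with
#'   `reflect = FALSE` give the identity transform.
#' @export
augmentation_config <- function(reflect = TRUE, rotation_deg = c(-10, 10),
                                scale = c(0.95, 1.05), translate_px = c(-10, 10)) {
  stopifnot(length(rotation_deg) == 2L, length(scale) == 2L,
            length(translate_px) == 2L, diff(rotation_deg) >= 0,
            diff(scale) >= 0, diff(translate_px) >= 0, all(scale > 0))
  structure(list(reflect = isTRUE(reflect), rotation_deg = rotation_deg,
                 scale = scale, translate_px = translate_px),
            class = "augmentation_config")
}

#' Randomly augment an image
#'
#' Draws one reflection/rotation/rescale/translation from the configured
#' ranges (one draw per call, from the current RNG state or a given seed) and
#' applies it by inverse nearest-neighbour mapping. Output dimensions equal
#' input dimensions; pixels mapped from outside the frame take the border
#' median (the backdrop).
#'
#' @param image H x W x 3 array.
#' @param cfg an [augmentation_config()].
#' @param seed optional integer seed for a reproducible single draw.
#' @return augmented image, same dimensions.
#' @export
augment_image <- function(image, cfg = augmentation_config(), seed = NULL) {
  stopifnot_image(image)
  draw <- function() {
    list(reflect = cfg$reflect && stats::runif(1) < 0.5,
         theta = stats::runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2]) * pi / 180,
         s = stats::runif(1, cfg$scale[1], cfg$scale[2]),
         tx = stats::runif(1, cfg$translate_px[1], cfg$translate_px[2]),
         ty = stats::runif(1, cfg$translate_px[1], cfg$translate_px[2]))
  }
  par <- if (is.null(seed)) draw() else withr::with_seed(derive_seed(seed, "augment"), draw())
  .apply_affine(image, par)
}

.apply_affine <- function(image, par) {
  h <- dim(image)[1]; w <- dim(image)[2]
  rc <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  yc <- rc - (h + 1) / 2 - par$ty
  xc <- cc - (w + 1) / 2 - par$tx
  ct <- cos(par$theta); st <- sin(par$theta)
  xs <- (ct * xc + st * yc) / par$s
  ys <- (-st * xc + ct * yc) / par$s
  if (par$reflect) xs <- -xs
  src_r <- round(ys + (h + 1) / 2)
  src_c <- round(xs + (w + 1) / 2)
  inside <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  border <- c(image[1, , ], image[h, , ], image[, 1, ], image[, w, ])
  pad <- stats::median(border)
  out <- array(pad, dim = dim(image))
  idx_in <- cbind(src_r[inside], src_c[inside])
  for (ch in 1:3) {
    plane <- matrix(pad, h, w)
    plane[cbind(rc[inside], cc[inside])] <- image[, , ch][idx_in]
    out[, , ch] <- plane
  }
  out
}

#' Compact pooled-CIELAB backbone
#'
#' The default feature extractor: the image is average-pooled to a
#' `grid x grid` mosaic, each cell converted to CIELAB and scaled, yielding a
#' `3 * grid^2` feature vector. Deliberately small so the full pipeline
#' trains on one CPU in seconds-to-minutes; pretrained deep backbones can be
#' plugged in behind the same interface (a list with `name`, `dim` and
#' `featurize`).
#'
#' @param grid pooling grid side length.
#' @return backbone list with fields `name`, `grid`, `dim`, `featurize`.
#' @export
backbone_pooled_lab <- function(grid = 4L) {
  stopifnot(is_count(grid))
  featurize <- function(image) {
    h <- dim(image)[1]; w <- dim(image)[2]
    gr <- ceiling(seq_len(h) / h * grid)
    gc <- ceiling(seq_len(w) / w * grid)
    pooled <- vapply(1:3, function(ch) {
      m <- rowsum(image[, , ch], gr)
      m <- rowsum(t(m), gc)
      as.vector(t(m) / tcrossprod(tabulate(gr, grid), tabulate(gc, grid)))
    }, numeric(grid * grid))
    lab <- rgb_to_lab(pooled)
    as.numeric(cbind(lab[, 1] / 100, lab[, 2] / 128, lab[, 3] / 128))
  }
  list(name = "pooled_lab", grid = as.integer(grid), dim = 3L * grid^2,
       featurize = featurize)
}

#' Training configuration
#'
#' Defaults follow the study's protocol: 30 epochs, mini-batch 128, step
#' learning-rate schedule (initial 0.01 dropped by a factor 0.1 every 10
#' epochs; 0.001 initial for the shallow preset), validation every 10
#' iterations, patience of 150 iterations, best-validation checkpoint.
#'
#' @param epochs,minibatch training length and batch size.
#' @param lr_init,lr_drop_factor,lr_drop_period_epochs step LR schedule.
#' @param val_every_iters,patience_iters validation cadence and early stop.
#' @param num_classes 5 or 10 (the Ripening Index system).
#' @param hidden hidden units of the classifier head (0 for softmax only).
#' @param momentum,weight_decay SGD settings.
#' @param backbone a backbone list, see [backbone_pooled_lab()].
#' @param seed training seed (initialization, shuffling, augmentation).
#' @return list of class `training_config`.
#' @export
training_config <- function(epochs = 30L, minibatch = 128L, lr_init = 0.01,
                            lr_drop_factor = 0.1, lr_drop_period_epochs = 10L,
                            val_every_iters = 10L, patience_iters = 150L,
                            num_classes = 10L, hidden = 24L, momentum = 0.9,
                            weight_decay = 1e-4, backbone = backbone_pooled_lab(),
                            seed = 1L) {
  stopifnot(is_count(epochs), is_count(minibatch), lr_init > 0,
            lr_drop_factor > 0, is_count(lr_drop_period_epochs),
            is_count(val_every_iters), is_count(patience_iters),
            num_classes %in% c(5L, 10L), hidden >= 0)
  structure(list(epochs = as.integer(epochs), minibatch = as.integer(minibatch),
                 lr_init = lr_init, lr_drop_factor = lr_drop_factor,
                 lr_drop_period_epochs = as.integer(lr_drop_period_epochs),
                 val_every_iters = as.integer(val_every_iters),
                 patience_iters = as.integer(patience_iters),
                 num_classes = as.integer(num_classes), hidden = as.integer(hidden),
                 momentum = momentum, weight_decay = weight_decay,
                 backbone = backbone, seed = as.integer(seed)),
            class = "training_config")
}

# learning rate for a 0-based epoch index
lr_at_epoch <- function(tcfg, epoch) {
  tcfg$lr_init * tcfg$lr_drop_factor^(floor(epoch / tcfg$lr_drop_period_epochs))
}

# earliest index of the best validation accuracy; ties broken by lower
# validation loss, then by earliness
select_checkpoint <- function(val_acc, val_loss = NULL) {
  best <- which(val_acc == max(val_acc))
  if (!is.null(val_loss) && length(best) > 1L)
    best <- best[val_loss[best] == min(val_loss[best])]
  best[1]
}

.mlp_init <- function(p, hidden, k, seed) {
  withr::with_seed(derive_seed(seed, "init"), {
    if (hidden > 0L)
      list(W1 = matrix(stats::rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden),
           b1 = rep(0, hidden),
           W2 = matrix(stats::rnorm(hidden * k, 0, sqrt(2 / hidden)), hidden, k),
           b2 = rep(0, k))
    else
      list(W2 = matrix(stats::rnorm(p * k, 0, sqrt(2 / p)), p, k), b2 = rep(0, k))
  })
}

.mlp_forward <- function(par, X) {
  if (!is.null(par$W1)) {
    A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
    S <- sweep(A1 %*% par$W2, 2, par$b2, "+")
  } else {
    A1 <- NULL
    S <- sweep(X %*% par$W2, 2, par$b2, "+")
  }
  S <- S - apply(S, 1, max)
  P <- exp(S); P <- P / rowSums(P)
  list(P = P, A1 = A1)
}

.ce_loss <- function(P, y) -mean(log(pmax(P[cbind(seq_along(y), y)], 1e-12)))

.mlp_grad <- function(par, X, y, wd) {
  n <- nrow(X)
  fw <- .mlp_forward(par, X)
  dS <- fw$P
  dS[cbind(seq_len(n), y)] <- dS[cbind(seq_len(n), y)] - 1
  dS <- dS / n
  if (!is.null(par$W1)) {
    g <- list(W2 = t(fw$A1) %*% dS + wd * par$W2, b2 = colSums(dS))
    dA1 <- dS %*% t(par$W2)
    dZ1 <- dA1 * (1 - fw$A1^2)
    g$W1 <- t(X) %*% dZ1 + wd * par$W1
    g$b1 <- colSums(dZ1)
  } else {
    g <- list(W2 = t(X) %*% dS + wd * par$W2, b2 = colSums(dS))
  }
  list(grad = g, loss = .ce_loss(fw$P, y))
}

#' Train the ripening-stage classifier
#'
#' Minimizes cross-entropy over the stage labels by momentum SGD on the
#' backbone features, with the study's training protocol: random
#' oversampling of the training records (validation and test untouched), one
#' random augmentation of each training image per epoch, a step LR schedule,
#' validation every `val_every_iters` iterations, early stopping after
#' `patience_iters` iterations without validation improvement, and selection
#' of the best-validation checkpoint (accuracy, loss as tie-break, earliest
#' on remaining ties).
#'
#' @param db records, cohort or db object.
#' @param split a [grouped_stratified_split()].
#' @param provider image provider function, see [cohort_image_provider()].
#' @param tcfg a [training_config()].
#' @param acfg an [augmentation_config()].
#' @param oversample balance training classes by random oversampling.
#' @return object of class `ripening_classifier`: learned parameters,
#'   feature standardization, class labels, full training history
#'   (iteration, epoch, lr, train_loss, val_accuracy, val_loss), and the
#'   selected checkpoint's iteration.
#' @export
train_ripening_classifier <- function(db, split, provider,
                                      tcfg = training_config(),
                                      acfg = augmentation_config(),
                                      oversample = TRUE) {
  rec <- db_records(db)
  label_col <- if (tcfg$num_classes == 10L) "ri10" else "ri5"
  train_rec <- split_records(rec, split, "train")
  val_rec <- split_records(rec, split, "validation")
  if (!nrow(train_rec) || !nrow(val_rec))
    stop("training and validation subsets must be non-empty", call. = FALSE)
  if (max(rec[[label_col]]) > tcfg$num_classes)
    stop("labels exceed num_classes; check the index system", call. = FALSE)
  if (oversample)
    train_rec <- oversample_training(train_rec, label = label_col,
                                     seed = tcfg$seed)

  bk <- tcfg$backbone
  # cache rendered images when they fit comfortably in memory; augmentation
  # is applied per epoch to the stored pixels
  cache_for <- function(records) {
    probe <- provider(records[1, ])
    bytes <- as.numeric(nrow(records)) * length(probe) * 8
    if (bytes > 6e8) return(NULL)
    c(list(probe), lapply(seq_len(nrow(records))[-1],
                          function(i) provider(records[i, ])))
  }
  train_cache <- cache_for(train_rec)
  feat_of <- function(records, augment_rng = FALSE, cache = NULL) {
    t(vapply(seq_len(nrow(records)), function(i) {
      img <- if (is.null(cache)) provider(records[i, ]) else cache[[i]]
      if (augment_rng) img <- augment_image(img, acfg)
      bk$featurize(img)
    }, numeric(bk$dim)))
  }
  X0 <- feat_of(train_rec, cache = train_cache)
  mu <- colMeans(X0)
  sdv <- pmax(apply(X0, 2, stats::sd), 1e-6)
  std <- function(X) sweep(sweep(X, 2, mu), 2, sdv, "/")
  Xval <- std(feat_of(val_rec))
  yval <- val_rec[[label_col]]
  ytr_all <- train_rec[[label_col]]

  par <- .mlp_init(bk$dim, tcfg$hidden, tcfg$num_classes, tcfg$seed)
  vel <- lapply(par, function(m) m * 0)
  history <- list()
  best <- list(acc = -Inf, loss = Inf, iter = 0L, par = par)
  iter <- 0L
  stopped <- FALSE

  for (epoch in seq_len(tcfg$epochs)) {
    lr <- lr_at_epoch(tcfg, epoch - 1L)
    ep <- withr::with_seed(derive_seed(tcfg$seed, "epoch", epoch), {
      Xe <- std(feat_of(train_rec, augment_rng = TRUE, cache = train_cache))
      ord <- sample(nrow(Xe))
      list(X = Xe[ord, , drop = FALSE], y = ytr_all[ord])
    })
    starts <- seq(1L, nrow(ep$X), by = tcfg$minibatch)
    for (s in starts) {
      idx <- s:min(s + tcfg$minibatch - 1L, nrow(ep$X))
      gl <- .mlp_grad(par, ep$X[idx, , drop = FALSE], ep$y[idx], tcfg$weight_decay)
      for (nm in names(par)) {
        vel[[nm]] <- tcfg$momentum * vel[[nm]] - lr * gl$grad[[nm]]
        par[[nm]] <- par[[nm]] + vel[[nm]]
      }
      iter <- iter + 1L
      if (iter %% tcfg$val_every_iters == 0L) {
        fw <- .mlp_forward(par, Xval)
        vacc <- mean(max.col(fw$P, ties.method = "first") == yval)
        vloss <- .ce_loss(fw$P, yval)
        history[[length(history) + 1L]] <-
          data.frame(iteration = iter, epoch = epoch, lr = lr,
                     train_loss = gl$loss, val_accuracy = vacc, val_loss = vloss)
        if (vacc > best$acc || (vacc == best$acc && vloss < best$loss)) {
          best <- list(acc = vacc, loss = vloss, iter = iter, par = par)
        } else if (iter - best$iter >= tcfg$patience_iters) {
          stopped <- TRUE
          break
        }
      }
    }
    if (stopped) break
  }
  # final validation if the last iteration fell between checks
  if (!stopped && (length(history) == 0L ||
                   history[[length(history)]]$iteration < iter)) {
    fw <- .mlp_forward(par, Xval)
    vacc <- mean(max.col(fw$P, ties.method = "first") == yval)
    vloss <- .ce_loss(fw$P, yval)
    history[[length(history) + 1L]] <-
      data.frame(iteration = iter, epoch = epoch, lr = lr,
                 train_loss = NA_real_, val_accuracy = vacc, val_loss = vloss)
    if (vacc > best$acc || (vacc == best$acc && vloss < best$loss))
      best <- list(acc = vacc, loss = vloss, iter = iter, par = par)
  }
  history <- if (length(history)) do.call(rbind, history) else
    data.frame(iteration = integer(), epoch = integer(), lr = numeric(),
               train_loss = numeric(), val_accuracy = numeric(), val_loss = numeric())
  structure(list(par = best$par, feat_mean = mu, feat_sd = sdv,
                 classes = seq_len(tcfg$num_classes), label_col = label_col,
                 backbone = bk, history = history,
                 best_iteration = best$iter, best_val_accuracy = best$acc,
                 early_stopped = stopped, tcfg = tcfg, acfg = acfg),
            class = "ripening_classifier")
}

#' @export
print.ripening_classifier <- function(x, ...) {
  cat(sprintf("ripening-stage classifier (%d classes, backbone %s, hidden %d)\n",
              length(x$classes), x$backbone$name, x$tcfg$hidden))
  cat(sprintf("  best validation accuracy %.3f at iteration %d%s\n",
              x$best_val_accuracy, x$best_iteration,
              if (x$early_stopped) " (early stop)" else ""))
  invisible(x)
}

#' Predict ripening stages for image records
#'
#' @param object a trained [train_ripening_classifier()] model.
#' @param records metadata records to score (must carry sample_id, side,
#'   day, group and the truth column of the model's index system).
#' @param provider image provider function.
#' @param ... unused.
#' @return prediction records: one row per image with `true_stage`,
#'   `pred_stage` (the score argmax) and normalized class scores
#'   `score_1..K` summing to 1. Deterministic for fixed parameters.
#' @export
predict.ripening_classifier <- function(object, records, provider, ...) {
  rec <- db_records(records)
  X <- t(vapply(seq_len(nrow(rec)), function(i)
    object$backbone$featurize(provider(rec[i, ])), numeric(object$backbone$dim)))
  X <- sweep(sweep(X, 2, object$feat_mean), 2, object$feat_sd, "/")
  P <- .mlp_forward(object$par, X)$P
  out <- data.frame(sample_id = rec$sample_id, side = rec$side, day = rec$day,
                    group = rec$group, true_stage = rec[[object$label_col]],
                    pred_stage = object$classes[max.col(P, ties.method = "first")],
                    stringsAsFactors = FALSE)
  colnames(P) <- paste0("score_", object$classes)
  cbind(out, as.data.frame(P))
}
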