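#' Training configuration
#'
#' Defaults follow the published regimen: Adam with learning rate 0.01 and
#' weight decay 1e-4, negative log-likelihood loss, 10 epochs,
#' validation every 1000 batches (and at each epoch end), and a
#' reduce-on-plateau schedule maximizing validation mAP with factor 0.1 and
#' patience 5.
#'
#' @param learning_rate,weight_decay Adam settings.
#' @param epochs number of passes; one epoch draws `ceiling(n_train /
#'   batch_size)` class-balanced batches with replacement.
#' @param batch_size samples per batch.
#' @param eval_interval validate every this many batches.
#' @param scheduler_factor,scheduler_patience plateau schedule (mode = max on
#'   validation mAP).
#' @param seed integer seed for sampling, dropout and any other RNG in the
#'   loop.
#' @return a `training_config` list.
#' @export
training_config <- function(learning_rate = 0.01, weight_decay = 1e-4,
                            epochs = 10L, batch_size = 256L,
                            eval_interval = 1000L, scheduler_factor = 0.1,
                            scheduler_patience = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 1,
            batch_size >= 1, eval_interval >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 eval_interval = as.integer(eval_interval),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Inverse-frequency sampling weights for class balance
#'
#' Weight of sample `i` is `1 / count(class(i))`, so drawing with replacement
#' proportional to these weights yields equal expected class frequencies.
#'
#' @param labels integer class labels (0-based).
#' @return numeric weights, one per sample.
#' @export
class_balance_weights <- function(labels) {
  if (length(labels) == 0) stopf("labels must be non-empty")
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}

#' Non-interpolated average precision
#'
#' Samples are ranked by decreasing score (stable in input order on ties) and
#' AP is the mean of the precision values at each positive's rank.
#'
#' @param scores numeric scores, higher = more confident positive.
#' @param positives logical, same length as scores.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(scores, positives) {
  if (length(scores) != length(positives)) stopf("length mismatch")
  if (!any(positives)) stopf("average precision needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  pos <- positives[ord]
  prec <- cumsum(pos) / seq_along(pos)
  mean(prec[pos])
}

#' Mean average precision over one-vs-rest classes
#'
#' The unweighted mean of per-class APs over classes with at least one
#' positive; empty classes are excluded from the mean.
#'
#' @param probs matrix `samples x classes` of predicted probabilities.
#' @param labels integer true labels (0-based, indexing the columns).
#' @return mAP in `[0, 1]`.
#' @export
mean_average_precision <- function(probs, labels) {
  k <- ncol(probs)
  aps <- vapply(seq_len(k) - 1L, function(cls) {
    pos <- labels == cls
    if (!any(pos)) return(NA_real_)
    average_precision(probs[, cls + 1], pos)
  }, numeric(1))
  if (all(is.na(aps))) stopf("no class has any positive sample")
  mean(aps, na.rm = TRUE)
}

# Reduce-on-plateau schedule (mode = max): after more than `patience`
# consecutive evaluations without improvement, multiply the rate by `factor`.
plateau_scheduler <- function(lr, factor, patience) {
  env <- new.env(parent = emptyenv())
  env$lr <- lr; env$best <- -Inf; env$bad <- 0L
  env$step <- function(metric) {
    if (metric > env$best) {
      env$best <- metric
      env$bad <- 0L
    } else {
      env$bad <- env$bad + 1L
      if (env$bad > patience) {
        env$lr <- env$lr * factor
        env$bad <- 0L
      }
    }
    env$lr
  }
  env
}

nll_loss <- function(logp, y) {
  n <- nrow(logp)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(logp[idx])
  dlogp <- matrix(0, n, ncol(logp))
  dlogp[idx] <- -1 / n
  list(loss = loss, grad = dlogp)
}

#' Train a classifier with class-balanced sampling and best-model selection
#'
#' Each epoch draws `ceiling(n_train / batch_size)` batches with replacement,
#' with per-sample probabilities from [class_balance_weights()]. The model is
#' evaluated on the validation split every `cfg$eval_interval` batches and at
#' every epoch end; the checkpoint with the highest validation mAP is kept
#' and restored into the returned model, and the plateau scheduler steps on
#' every validation mAP. The whole loop is deterministic given `cfg$seed`.
#'
#' @param model a `crescan_model` (freshly built or pre-trained).
#' @param ds a split `labeled_dataset` with non-empty train and val splits.
#' @param cfg a [training_config()].
#' @return list with `model` (best checkpoint), `history` (one row per
#'   validation event: epoch, batch, val_map, lr, is_best) and `best_map`.
#' @export
train_model <- function(model, ds, cfg = training_config()) {
  tr <- split_index(ds, "train")
  va <- split_index(ds, "val")
  if (length(tr) == 0 || length(va) == 0)
    stopf("train and val splits must be non-empty")
  if (n_classes(ds) != model$spec$n_classes)
    stopf("dataset has %d classes but the model expects %d",
          n_classes(ds), model$spec$n_classes)
  x_train <- ds$tensor$values[tr, , , drop = FALSE]
  y_train <- ds$labels[tr]
  x_val <- ds$tensor$values[va, , , drop = FALSE]
  y_val <- ds$labels[va]
  w <- class_balance_weights(y_train)
  n_batches <- ceiling(length(tr) / cfg$batch_size)
  sched <- plateau_scheduler(cfg$learning_rate, cfg$scheduler_factor,
                             cfg$scheduler_patience)
  opt <- adam_state(model$layers)
  history <- list()
  best <- list(map = -Inf, snap = snapshot_model(model))
  batch_counter <- 0L

  validate <- function(epoch) {
    m <- mean_average_precision(predict_proba(model, x_val), y_val)
    lr_now <- sched$step(m)
    is_best <- m > best$map
    if (is_best) best <<- list(map = m, snap = snapshot_model(model))
    history[[length(history) + 1L]] <<- data.frame(
      epoch = epoch, batch = batch_counter, val_map = m,
      lr = lr_now, is_best = is_best)
    invisible(m)
  }

  withr::with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      for (b in seq_len(n_batches)) {
        idx <- sample.int(length(tr), cfg$batch_size, replace = TRUE, prob = w)
        xb <- x_train[idx, , , drop = FALSE]
        yb <- y_train[idx]
        logp <- model_forward(model, xb, training = TRUE)
        ls <- nll_loss(logp, yb)
        if (!is.finite(ls$loss))
          stopf("non-finite loss at epoch %d batch %d; inspect inputs/learning rate",
                epoch, b)
        net_backward(model$layers, ls$grad)
        opt <- adam_step(model$layers, opt, lr = sched$lr,
                         weight_decay = cfg$weight_decay)
        batch_counter <- batch_counter + 1L
        if (batch_counter %% cfg$eval_interval == 0L) validate(epoch)
      }
      validate(epoch)
    }
  })
  restore_model(model, best$snap)
  list(model = model, history = do.call(rbind, history), best_map = best$map)
}

#' Evaluate a model on a dataset split
#'
#' Produces per-class precision-recall curves, ROC curves (via
#' [pROC::roc()]), a confusion matrix (rows = true class, columns = argmax
#' prediction, ties to the lower class index), per-class average precision
#' and the macro mAP.
#'
#' @param model a `crescan_model`.
#' @param ds a split `labeled_dataset`.
#' @param split `"test"` or `"val"`.
#' @return an `evaluation_report` list.
#' @export
evaluate_model <- function(model, ds, split = c("test", "val")) {
  split <- match.arg(split)
  idx <- split_index(ds, split)
  if (length(idx) == 0) stopf("split '%s' is empty", split)
  x <- ds$tensor$values[idx, , , drop = FALSE]
  y <- ds$labels[idx]
  probs <- predict_proba(model, x)
  k <- ncol(probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  lev <- seq_len(k) - 1L
  confusion <- table(true = factor(y, levels = lev),
                     predicted = factor(pred, levels = lev))
  dimnames(confusion) <- list(true = ds$class_names,
                              predicted = ds$class_names)
  pr_curves <- list(); roc_curves <- list(); aps <- rep(NA_real_, k)
  for (cls in lev) {
    pos <- y == cls
    nm <- ds$class_names[cls + 1]
    if (!any(pos) || all(pos)) next
    sc <- probs[, cls + 1]
    ord <- order(sc, decreasing = TRUE)
    tp <- cumsum(pos[ord])
    pr_curves[[nm]] <- data.frame(
      threshold = sc[ord],
      precision = tp / seq_along(tp),
      recall = tp / sum(pos))
    r <- pROC::roc(response = pos, predictor = sc, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
    roc_curves[[nm]] <- data.frame(fpr = 1 - r$specificities,
                                   tpr = r$sensitivities,
                                   auc = as.numeric(r$auc))
    aps[cls + 1] <- average_precision(sc, pos)
  }
  names(aps) <- ds$class_names
  structure(list(confusion = confusion, pr_curves = pr_curves,
                 roc_curves = roc_curves, average_precision = aps,
                 map = mean(aps, na.rm = TRUE), n = length(idx),
                 split = split),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s split, %d samples, mAP = %.4f\n",
              x$split, x$n, x$map))
  cat("per-class AP:\n")
  print(round(x$average_precision, 4))
  cat("confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report bundle to disk
#'
#' Emits CSV files of the PR and ROC curves, PNG plots of both curve
#' families, the confusion matrix, and a plain-text summary.
#'
#' @param report an `evaluation_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  plot_curves <- function(curves, xcol, ycol, xlab, ylab, path) {
    grDevices::png(path, width = 720, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::plot(NULL, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = xlab, ylab = ylab)
    cols <- seq_along(curves) + 1
    for (i in seq_along(curves))
      graphics::lines(curves[[i]][[xcol]], curves[[i]][[ycol]],
                      col = cols[i], lwd = 2)
    graphics::legend("bottomleft", legend = names(curves), col = cols, lwd = 2)
  }
  if (length(report$pr_curves))
    plot_curves(report$pr_curves, "recall", "precision", "Recall",
                "Precision", file.path(dir, "pr_curves.png"))
  if (length(report$roc_curves))
    plot_curves(report$roc_curves, "fpr", "tpr", "False positive rate",
                "True positive rate", file.path(dir, "roc_curves.png"))
  for (nm in names(report$pr_curves))
    utils::write.csv(report$pr_curves[[nm]],
                     file.path(dir, sprintf("pr_%s.csv", nm)),
                     row.names = FALSE)
  for (nm in names(report$roc_curves))
    utils::write.csv(report$roc_curves[[nm]],
                     file.path(dir, sprintf("roc_%s.csv", nm)),
                     row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(report$confusion),
                   file.path(dir, "confusion.csv"))
  summary_lines <- c(
    sprintf("split: %s", report$split),
    sprintf("samples: %d", report$n),
    sprintf("mAP: %.6f", report$map),
    sprintf("AP[%s]: %.6f", names(report$average_precision),
            report$average_precision))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}
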