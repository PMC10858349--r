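#' Model specification for the coverage classifiers
#'
#' Describes either the five-layer CNN or the conv+LSTM RNN operating on
#' `n_marks x n_bins` coverage windows. The CNN stack is
#' conv(7) / conv(3)+pool / conv(3) / conv(3)+pool (each with batch norm and
#' ReLU) followed by global average pooling and a 1x1 convolutional
#' classifier with softmax output. The RNN is a 7-wide convolution feeding
#' two stacked LSTMs of hidden size 32, classified from the final position.
#'
#' @param arch `"cnn"` or `"rnn"`.
#' @param n_marks number of histone marks (input channels).
#' @param n_bins bins per window (>= 7 so the first kernel fits; the CNN
#'   additionally needs `n_bins` divisible by 4 for its two poolings).
#' @param n_classes 2, 3 or 5.
#' @param mark_names optional mark names, used by [weight_profiles()].
#' @param cnn_channels,cnn_kernels channel/kernel plan of the four feature
#'   convolutions.
#' @param rnn_conv_filters,rnn_hidden,rnn_layers,dropout RNN front-end
#'   filters, LSTM hidden size and depth, inter-layer dropout rate.
#' @return a `model_spec` list.
#' @export
model_spec <- function(arch = c("cnn", "rnn"), n_marks, n_bins = 20L,
                       n_classes = 5L, mark_names = NULL,
                       cnn_channels = c(32L, 32L, 64L, 64L),
                       cnn_kernels = c(7L, 3L, 3L, 3L),
                       rnn_conv_filters = 32L, rnn_hidden = 32L,
                       rnn_layers = 2L, dropout = 0.5) {
  arch <- match.arg(arch)
  if (n_bins < 7) stopf("n_bins must be >= 7 so the first 7-wide kernel fits")
  if (!n_classes %in% c(2L, 3L, 5L)) stopf("n_classes must be 2, 3 or 5")
  if (!is.null(mark_names) && length(mark_names) != n_marks)
    stopf("mark_names must have length n_marks")
  structure(list(arch = arch, n_marks = as.integer(n_marks),
                 n_bins = as.integer(n_bins),
                 n_classes = as.integer(n_classes),
                 mark_names = mark_names,
                 cnn_channels = as.integer(cnn_channels),
                 cnn_kernels = as.integer(cnn_kernels),
                 rnn_conv_filters = as.integer(rnn_conv_filters),
                 rnn_hidden = as.integer(rnn_hidden),
                 rnn_layers = as.integer(rnn_layers),
                 dropout = dropout),
            class = "model_spec")
}

#' Build a classifier from a specification
#'
#' Parameters are initialized from the current RNG stream; wrap the call in
#' [withr::with_seed()] for reproducible builds. The forward map outputs
#' per-class probabilities (softmax); internally the network computes
#' log-probabilities for pairing with the negative log-likelihood loss.
#'
#' @param spec a [model_spec()].
#' @return a `crescan_model`.
#' @export
build_model <- function(spec) {
  if (spec$arch == "cnn") build_cnn(spec) else build_rnn(spec)
}

#' @rdname build_model
#' @export
build_cnn <- function(spec) {
  if (spec$arch != "cnn") stopf("spec$arch must be 'cnn'")
  if (spec$n_bins %% 4 != 0)
    stopf("CNN needs n_bins divisible by 4 for its two max-poolings")
  ch <- spec$cnn_channels
  k <- spec$cnn_kernels
  layers <- list(
    nn_conv1d(spec$n_marks, ch[1], k[1]), nn_bn1d(ch[1]), nn_relu(),
    nn_conv1d(ch[1], ch[2], k[2]), nn_bn1d(ch[2]), nn_relu(), nn_maxpool2(),
    nn_conv1d(ch[2], ch[3], k[3]), nn_bn1d(ch[3]), nn_relu(),
    nn_conv1d(ch[3], ch[4], k[4]), nn_bn1d(ch[4]), nn_relu(), nn_maxpool2(),
    nn_gap(),
    nn_linear(ch[4], spec$n_classes),  # 1x1 convolution on pooled features
    nn_logsoftmax())
  new_model(spec, layers)
}

#' @rdname build_model
#' @export
build_rnn <- function(spec) {
  if (spec$arch != "rnn") stopf("spec$arch must be 'rnn'")
  layers <- list(
    nn_conv1d(spec$n_marks, spec$rnn_conv_filters, 7L), nn_relu(),
    nn_flatten_conv())
  in_f <- spec$rnn_conv_filters
  for (i in seq_len(spec$rnn_layers)) {
    layers <- c(layers, list(nn_lstm(in_f, spec$rnn_hidden)))
    if (i < spec$rnn_layers)
      layers <- c(layers, list(nn_dropout(spec$dropout)))
    in_f <- spec$rnn_hidden
  }
  layers <- c(layers, list(nn_take_last(),
                           nn_linear(spec$rnn_hidden, spec$n_classes),
                           nn_logsoftmax()))
  new_model(spec, layers)
}

new_model <- function(spec, layers) {
  structure(list(spec = spec, layers = layers), class = "crescan_model")
}

#' @export
print.crescan_model <- function(x, ...) {
  cat(sprintf("<crescan_model> %s: %d marks x %d bins -> %d classes (%d parameters)\n",
              toupper(x$spec$arch), x$spec$n_marks, x$spec$n_bins,
              x$spec$n_classes, count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Counts every trainable scalar (convolution/linear weights and biases,
#' batch-norm scale and shift, LSTM gate matrices). Batch-norm running
#' statistics are not trainable and are not counted.
#'
#' @param model a `crescan_model`.
#' @return integer.
#' @export
count_parameters <- function(model) {
  sum(vapply(net_parameters(model$layers), length, integer(1)))
}

check_input <- function(model, x) {
  if (inherits(x, "signal_tensor")) x <- x$values
  d <- dim(x)
  if (length(d) != 3 || d[2] != model$spec$n_marks || d[3] != model$spec$n_bins)
    stopf("input must be batch x %d marks x %d bins",
          model$spec$n_marks, model$spec$n_bins)
  x
}

model_forward <- function(model, x, training = FALSE) {
  net_forward(model$layers, check_input(model, x), training)
}

#' Per-class probabilities for a batch of coverage windows
#'
#' Runs the network in evaluation mode (dropout off, batch norm using running
#' statistics); rows are valid probability vectors summing to 1.
#'
#' @param model a `crescan_model`.
#' @param x a [signal_tensor()] or array `batch x marks x bins`.
#' @return matrix `batch x n_classes`.
#' @export
predict_proba <- function(model, x) {
  p <- exp(model_forward(model, x, training = FALSE))
  colnames(p) <- NULL
  p
}

#' Save or load a model checkpoint
#'
#' A checkpoint directory holds the serialized parameters plus a JSON sidecar
#' of the model specification; loading verifies that the stored parameters
#' match the sidecar spec.
#'
#' @param model a `crescan_model`.
#' @param dir checkpoint directory.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pars <- net_parameters(model$layers)
  extra <- bn_running_stats(model$layers)
  saveRDS(list(pars = pars, bn = extra,
               spec_json = spec_canonical_json(model$spec)),
          file.path(dir, "params.rds"))
  writeLines(spec_canonical_json(model$spec), file.path(dir, "spec.json"))
  invisible(dir)
}

#' @rdname save_model
#' @return `load_model` returns the rebuilt `crescan_model`.
#' @export
load_model <- function(dir) {
  blob <- readRDS(file.path(dir, "params.rds"))
  spec_json <- paste(readLines(file.path(dir, "spec.json")), collapse = "\n")
  if (!identical(blob$spec_json, spec_json))
    stopf("checkpoint spec mismatch between params.rds and spec.json")
  spec <- spec_from_json(spec_json)
  model <- build_model(spec)
  net_restore(model$layers, blob$pars)
  restore_bn_running_stats(model$layers, blob$bn)
  model
}

spec_canonical_json <- function(spec) {
  as.character(jsonlite::toJSON(unclass(spec), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

spec_from_json <- function(json) {
  s <- jsonlite::fromJSON(json)
  model_spec(arch = s$arch, n_marks = s$n_marks, n_bins = s$n_bins,
             n_classes = s$n_classes, mark_names = s$mark_names,
             cnn_channels = s$cnn_channels, cnn_kernels = s$cnn_kernels,
             rnn_conv_filters = s$rnn_conv_filters, rnn_hidden = s$rnn_hidden,
             rnn_layers = s$rnn_layers, dropout = s$dropout)
}

bn_running_stats <- function(layers) {
  out <- list()
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "bn")
      out[[sprintf("L%02d", i)]] <- list(mean = layers[[i]]$running_mean,
                                         var = layers[[i]]$running_var)
  }
  out
}

restore_bn_running_stats <- function(layers, st) {
  for (nm in names(st)) {
    i <- as.integer(sub("L", "", nm))
    layers[[i]]$running_mean <- st[[nm]]$mean
    layers[[i]]$running_var <- st[[nm]]$var
  }
  invisible(layers)
}

snapshot_model <- function(model) {
  list(pars = net_parameters(model$layers),
       bn = bn_running_stats(model$layers))
}

restore_model <- function(model, snap) {
  net_restore(model$layers, snap$pars)
  restore_bn_running_stats(model$layers, snap$bn)
  invisible(model)
}
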