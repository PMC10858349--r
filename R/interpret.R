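#' Select the top-scoring regions per true class
#'
#' For each class, picks the `k_per_class` regions of that true class with
#' the highest predicted probability for the class, breaking ties by genomic
#' coordinate (then input order). Output indices are grouped by class.
#'
#' @param probs matrix `samples x classes` of predicted probabilities.
#' @param labels integer true labels (0-based).
#' @param k_per_class regions to keep per class (default 100).
#' @param intervals optional `GRanges` aligned with rows, used for the
#'   coordinate tie-break.
#' @return integer vector of row indices, length `k_per_class * n_classes`.
#' @export
select_top_regions <- function(probs, labels, k_per_class = 100L,
                               intervals = NULL) {
  k <- ncol(probs)
  if (!is.null(intervals) && length(intervals) != nrow(probs))
    stopf("intervals must align with probs rows")
  out <- integer(0)
  for (cls in seq_len(k) - 1L) {
    idx <- which(labels == cls)
    if (length(idx) < k_per_class)
      stopf("class %d has only %d samples in the pool but k_per_class = %d",
            cls, length(idx), k_per_class)
    p <- probs[idx, cls + 1]
    if (!is.null(intervals)) {
      iv <- intervals[idx]
      ord <- order(-p, as.character(GenomeInfoDb::seqnames(iv)),
                   GenomicRanges::start(iv))
    } else {
      ord <- order(-p)
    }
    out <- c(out, idx[ord[seq_len(k_per_class)]])
  }
  out
}

#' Raw first-layer convolutional activations
#'
#' Applies only the first convolutional layer (pre batch-norm, pre ReLU) of a
#' CNN to the selected regions, with zero padding preserving length. For the
#' RNN the convolutional front end can be inspected with
#' `allow_rnn = TRUE`.
#'
#' @param model a `crescan_model` (CNN, or RNN with `allow_rnn`).
#' @param regions a [signal_tensor()] (or array) of the selected regions.
#' @param allow_rnn permit the RNN's front convolution.
#' @return an `activation_tensor`: array `bins x filters x regions` with
#'   attributes `class` carried via `region_class` argument of downstream
#'   helpers.
#' @export
first_layer_activations <- function(model, regions, allow_rnn = FALSE) {
  if (model$spec$arch != "cnn" && !allow_rnn)
    stopf("first-layer activations are defined for CNN models (set allow_rnn = TRUE to inspect the RNN front convolution)")
  x <- check_input(model, regions)
  conv <- model$layers[[1]]
  stopifnot(conv$type == "conv")
  act <- conv_forward(conv, x)        # regions x filters x bins
  aperm(act, c(3, 2, 1))              # bins x filters x regions
}

#' Reduce per-filter activation matrices to one vector per filter by SVD
#'
#' For each filter, takes the first right-singular vector (length = regions)
#' of its `bins x regions` activation matrix; the sign is fixed so the entry
#' of largest magnitude is positive. Rows are unit-norm by construction.
#' All-zero filter matrices yield a zero row with a warning.
#'
#' @param act array `bins x filters x regions` from
#'   [first_layer_activations()].
#' @return matrix `filters x regions`.
#' @export
svd_reduce <- function(act) {
  d <- dim(act)
  out <- matrix(0, d[2], d[3])
  for (f in seq_len(d[2])) {
    M <- matrix(act[, f, ], d[1], d[3])
    if (all(M == 0)) {
      warnf("filter %d has all-zero activations; emitting a zero row", f)
      next
    }
    v <- svd(M, nu = 0, nv = 1)$v[, 1]
    if (v[which.max(abs(v))] < 0) v <- -v
    out[f, ] <- v
  }
  out
}

#' Hierarchically cluster filters by their reduced activation profiles
#'
#' Agglomerative clustering with correlation distance (`1 - cor` across
#' regions) and average linkage. Rows with undefined correlation (constant
#' profiles) are assigned the maximum distance of 2.
#'
#' @param reduced matrix `filters x regions` from [svd_reduce()].
#' @return list with `order` (leaf permutation of filter indices) and `tree`
#'   (the [stats::hclust] object).
#' @export
cluster_filters <- function(reduced) {
  if (nrow(reduced) < 2) stopf("need at least 2 filters to cluster")
  cr <- suppressWarnings(stats::cor(t(reduced)))
  d <- 1 - cr
  d[!is.finite(d)] <- 2
  diag(d) <- 0
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = tree$order, tree = tree)
}

#' First-layer filter weights for selected marks
#'
#' Returns, for each requested filter, its kernel-length weight vector per
#' requested mark channel, in input units (no normalization applied).
#'
#' @param model a `crescan_model` whose spec carries `mark_names`.
#' @param filter_ids integer filter indices (1-based).
#' @param marks character vector of mark names to extract.
#' @return named list of `kernel x marks` matrices, one per filter.
#' @export
weight_profiles <- function(model, filter_ids, marks) {
  conv <- model$layers[[1]]
  stopifnot(conv$type == "conv")
  mark_names <- model$spec$mark_names
  if (is.null(mark_names))
    stopf("model spec has no mark_names; rebuild with model_spec(mark_names = ...)")
  mi <- match(marks, mark_names)
  if (anyNA(mi))
    stopf("unknown mark(s): %s", paste(marks[is.na(mi)], collapse = ", "))
  if (any(filter_ids < 1 | filter_ids > conv$out_ch))
    stopf("filter ids must be in 1..%d", conv$out_ch)
  out <- lapply(filter_ids, function(f) {
    w <- t(matrix(conv$W[f, mi, ], length(mi), conv$k))  # kernel x marks
    colnames(w) <- marks
    w
  })
  names(out) <- sprintf("filter%02d", filter_ids)
  out
}

#' Full first-layer interpretation workflow
#'
#' Selects the top regions per class from a test split, extracts first-layer
#' activations, SVD-reduces them, clusters the filters, and optionally writes
#' TSV outputs.
#'
#' @param model a CNN `crescan_model`.
#' @param ds a split `labeled_dataset`.
#' @param split split to draw regions from.
#' @param k_per_class regions per class.
#' @param out_dir optional output directory for TSVs (reduced matrix with
#'   region classes, leaf order, per-filter weights).
#' @param marks marks for [weight_profiles()] (default: all marks).
#' @return list with `region_idx`, `region_class`, `activations`, `reduced`,
#'   `clustering`.
#' @export
interpret_filters <- function(model, ds, split = "test", k_per_class = 100L,
                              out_dir = NULL, marks = NULL) {
  idx <- split_index(ds, split)
  probs <- predict_proba(model, ds$tensor$values[idx, , , drop = FALSE])
  sel <- select_top_regions(probs, ds$labels[idx], k_per_class,
                            intervals = ds$intervals[idx])
  region_idx <- idx[sel]
  region_class <- ds$labels[region_idx]
  act <- first_layer_activations(
    model, ds$tensor$values[region_idx, , , drop = FALSE])
  reduced <- svd_reduce(act)
  clustering <- cluster_filters(reduced)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    red_df <- as.data.frame(reduced)
    colnames(red_df) <- sprintf("%s_%d", ds$class_names[region_class + 1],
                                seq_along(region_class))
    utils::write.table(red_df, file.path(out_dir, "reduced_activations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(as.character(clustering$order),
               file.path(out_dir, "filter_leaf_order.txt"))
    wp <- weight_profiles(model, seq_len(nrow(reduced)),
                          marks %||% model$spec$mark_names)
    for (nm in names(wp))
      utils::write.table(wp[[nm]],
                         file.path(out_dir, sprintf("weights_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(region_idx = region_idx, region_class = region_class,
       activations = act, reduced = reduced, clustering = clustering)
}
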