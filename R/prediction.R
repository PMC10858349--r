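#' Tile a genome with fixed-width sliding windows
#'
#' Per chromosome, windows start at 0 and advance by `step_bp`; the last
#' window ends at or before the chromosome end. Chromosomes shorter than
#' `window_bp` produce no windows. Output is ordered by chromosome (in
#' `sizes` order) then start.
#'
#' @param sizes named vector of chromosome lengths.
#' @param window_bp window width in bp.
#' @param step_bp step between window starts; `window_bp >= step_bp >= 1`.
#' @return a `GRanges` of windows.
#' @export
tile_genome <- function(sizes, window_bp = 2000L, step_bp = 200L) {
  if (step_bp < 1 || window_bp < step_bp)
    stopf("require window_bp >= step_bp >= 1")
  validate_chrom_sizes(sizes)
  per_chrom <- lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    if (len < window_bp) return(NULL)
    data.frame(chrom = ch, start0 = seq.int(0L, len - window_bp, by = step_bp))
  })
  df <- do.call(rbind, Filter(Negate(is.null), per_chrom))
  if (is.null(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start0 + 1, df$start0 + window_bp))
}

#' Score windows and keep confident non-background predictions
#'
#' Windows are kept when their maximum non-background class probability
#' exceeds `cutoff`, and are labeled with that class.
#'
#' @param model a `crescan_model`.
#' @param windows `GRanges` of windows.
#' @param signal a [signal_tensor()] aligned with `windows` (e.g. from
#'   [window_signal()] or [count_and_normalize()]).
#' @param cutoff probability cutoff (default 0.5).
#' @param batch_size forward-pass chunk size.
#' @param probs optional precomputed `windows x classes` probability matrix;
#'   when supplied, `model` and `signal` are not consulted for scoring.
#' @return `GRanges` of the retained windows with metadata columns
#'   `predicted_class` (integer, > 0), `score` (that class's probability) and
#'   `probs` (full probability matrix).
#' @export
predict_and_filter <- function(model, windows, signal, cutoff = 0.5,
                               batch_size = 1024L, probs = NULL) {
  n <- length(windows)
  if (is.null(probs)) {
    if (dim(signal)[1] != n)
      stopf("signal rows (%d) do not match windows (%d)", dim(signal)[1], n)
    probs <- matrix(0, n, model$spec$n_classes)
    for (i0 in seq(1, n, by = batch_size)) {
      i1 <- min(i0 + batch_size - 1, n)
      probs[i0:i1, ] <- predict_proba(
        model, signal$values[i0:i1, , , drop = FALSE])
    }
  } else if (nrow(probs) != n) {
    stopf("probs rows (%d) do not match windows (%d)", nrow(probs), n)
  }
  nb <- probs[, -1, drop = FALSE]
  best <- max.col(nb, ties.method = "first")
  best_p <- nb[cbind(seq_len(n), best)]
  keep <- best_p > cutoff
  out <- windows[keep]
  out$predicted_class <- best[keep]
  out$score <- best_p[keep]
  out$probs <- probs[keep, , drop = FALSE]
  out
}

#' Consolidate adjacent same-class window predictions into blocks
#'
#' Windows of the same predicted class whose spans overlap or abut are merged
#' into one block covering their union. Blocks carry the maximum member
#' probability as score and the number of member windows.
#'
#' @param preds output of [predict_and_filter()], sorted by (chromosome,
#'   start).
#' @return `GRanges` of blocks with metadata `class`, `score`, `n_windows`,
#'   sorted by position.
#' @export
consolidate_blocks <- function(preds) {
  if (length(preds) == 0) {
    out <- GenomicRanges::GRanges()
    out$class <- integer(0); out$score <- numeric(0)
    out$n_windows <- integer(0)
    return(out)
  }
  if (is.null(preds$predicted_class) || is.null(preds$score))
    stopf("preds must carry predicted_class and score (see predict_and_filter)")
  srt <- GenomicRanges::sort(GenomicRanges::granges(preds),
                             ignore.strand = TRUE)
  if (!identical(as.character(srt), as.character(GenomicRanges::granges(preds))))
    stopf("preds must be sorted by chromosome and start")
  pieces <- lapply(sort(unique(preds$predicted_class)), function(cls) {
    sub <- preds[preds$predicted_class == cls]
    blocks <- GenomicRanges::reduce(GenomicRanges::granges(sub),
                                    ignore.strand = TRUE)
    hit <- GenomicRanges::findOverlaps(sub, blocks, ignore.strand = TRUE)
    stopifnot(length(hit) == length(sub))
    blk <- factor(S4Vectors::subjectHits(hit), levels = seq_along(blocks))
    blocks$class <- cls
    blocks$score <- as.numeric(tapply(sub$score, blk, max))
    blocks$n_windows <- as.integer(tabulate(blk, nbins = length(blocks)))
    blocks
  })
  out <- do.call(c, pieces)
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Fraction of predicted blocks supported by positive markers
#'
#' For each predicted class, the rate is the fraction of that class's blocks
#' overlapping (>= 1 bp) at least one marker interval of the matching type.
#' Classes with no blocks are omitted with a warning; empty marker sets give
#' rate 0 with a warning.
#'
#' @param blocks output of [consolidate_blocks()].
#' @param markers named list, class name or id -> `GRanges` of positive
#'   markers; names must match `class_names[class + 1]` or the class id.
#' @param class_names optional class names used to label the result.
#' @return named numeric vector of per-class validation rates in `[0, 1]`.
#' @export
validation_rate <- function(blocks, markers, class_names = NULL) {
  classes <- sort(unique(blocks$class))
  if (!is.null(class_names)) {
    absent <- setdiff(seq_along(class_names) - 1L, c(0L, classes))
    for (a in absent)
      warnf("class %s has zero blocks; omitted from validation rates",
            class_names[a + 1])
  }
  rates <- vapply(classes, function(cls) {
    nm <- if (!is.null(class_names)) class_names[cls + 1] else as.character(cls)
    mk <- markers[[nm]] %||% markers[[as.character(cls)]]
    sub <- blocks[blocks$class == cls]
    if (is.null(mk) || length(mk) == 0) {
      warnf("no positive markers for class %s; rate reported as 0", nm)
      return(0)
    }
    mean(GenomicRanges::countOverlaps(sub, mk, ignore.strand = TRUE) > 0)
  }, numeric(1))
  names(rates) <- if (!is.null(class_names)) class_names[classes + 1]
                  else as.character(classes)
  rates
}

#' Default positive-marker sets from the training annotations
#'
#' An approximation used when no curated marker set is available: promoter
#' markers are window-slopped TSSs plus H3K4me3 peaks; enhancer markers are
#' TF peaks plus accessibility peaks minus the promoter markers.
#'
#' @inheritParams define_enhancers
#' @return list with elements `Prom` and `Enh` (`GRanges`).
#' @export
default_positive_markers <- function(tss, tf_peaks, accessibility_peaks,
                                     h3k4me3_peaks, cfg, sizes) {
  prom <- c(GenomicRanges::granges(slop_to_width(tss, cfg$window_bp, sizes)),
            GenomicRanges::granges(h3k4me3_peaks))
  enh_cand <- c(GenomicRanges::granges(tf_peaks),
                GenomicRanges::granges(accessibility_peaks))
  enh <- overlap_filter(enh_cand, prom, "remove")
  list(Prom = prom, Enh = enh)
}

#' Genome-wide prediction driver
#'
#' Tiles the genome, slices window coverage out of a genome-wide binned
#' signal grid (so normalization is bit-identical with preprocessing), scores
#' and filters the windows, and consolidates blocks.
#'
#' @param model a `crescan_model`.
#' @param bams named list mark -> replicate BAM paths.
#' @param sizes named vector of chromosome lengths.
#' @param cfg a [preprocess_config()].
#' @param cutoff probability cutoff.
#' @param step_bp window step.
#' @return list with `windows` (filtered `GRanges`) and `blocks`.
#' @export
predict_genome <- function(model, bams, sizes, cfg = preprocess_config(),
                           cutoff = 0.5, step_bp = 200L) {
  windows <- tile_genome(sizes, cfg$window_bp, step_bp)
  gsig <- genome_bin_signal(bams, sizes, cfg)
  sig <- window_signal(gsig, windows)
  preds <- predict_and_filter(model, windows, sig, cutoff = cutoff)
  list(windows = preds, blocks = consolidate_blocks(preds))
}

#' Write consolidated blocks as one BED6 file per class
#'
#' The BED name field carries the class label and the score field
#' `round(1000 * block score)`.
#'
#' @param blocks output of [consolidate_blocks()].
#' @param class_names class names (index = class id + 1); background is never
#'   emitted.
#' @param dir output directory.
#' @export
write_prediction_beds <- function(blocks, class_names, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cls in sort(unique(blocks$class))) {
    sub <- blocks[blocks$class == cls]
    nm <- class_names[cls + 1]
    out <- GenomicRanges::granges(sub)
    out$name <- nm
    out$score <- round(1000 * sub$score)
    write_bed(out, file.path(dir, sprintf("predictions_%s.bed", nm)))
  }
  invisible(dir)
}
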