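#' Binned signal tensors
#'
#' A `signal_tensor` is a 3-D numeric array of dimension
#' `samples x marks x bins` holding RPM-normalized, replicate-averaged read
#' coverage. `bins` must equal `window_bp / bin_bp` and all values must be
#' finite and non-negative.
#'
#' @param values numeric array `samples x marks x bins`.
#' @param mark_names character vector, one per mark.
#' @param window_bp,bin_bp window and bin width in bp.
#' @return an object of class `signal_tensor`.
#' @export
signal_tensor <- function(values, mark_names, window_bp, bin_bp) {
  if (length(dim(values)) != 3) stopf("values must be a 3-D array")
  if (dim(values)[2] != length(mark_names))
    stopf("mark dimension (%d) does not match mark_names (%d)",
          dim(values)[2], length(mark_names))
  if (window_bp %% bin_bp != 0) stopf("window_bp must be divisible by bin_bp")
  if (dim(values)[3] != window_bp %/% bin_bp)
    stopf("bin dimension (%d) != window_bp / bin_bp (%d)",
          dim(values)[3], window_bp %/% bin_bp)
  if (any(!is.finite(values)) || any(values < 0))
    stopf("signal values must be finite and >= 0")
  dimnames(values) <- list(NULL, mark_names, NULL)
  structure(list(values = values, mark_names = mark_names,
                 window_bp = as.integer(window_bp),
                 bin_bp = as.integer(bin_bp)),
            class = "signal_tensor")
}

#' @export
dim.signal_tensor <- function(x) dim(x$values)

#' @export
print.signal_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<signal_tensor> %d samples x %d marks x %d bins (%d bp bins)\n",
              d[1], d[2], d[3], x$bin_bp))
  invisible(x)
}

subset_tensor <- function(st, idx) {
  signal_tensor(st$values[idx, , , drop = FALSE], st$mark_names,
                st$window_bp, st$bin_bp)
}

#' Total mapped reads in a BAM file
#'
#' @param bam path to an indexed BAM file.
#' @return integer count of mapped reads (the RPM library size).
#' @export
library_size <- function(bam) {
  stats <- Rsamtools::idxstatsBam(bam)
  sum(stats$mapped)
}

# Per-region binned counts of read 5'-most aligned bases for one BAM.
# Each mapped read contributes to exactly the bin containing its leftmost
# aligned base; reads starting outside the region are not counted.
bam_bin_counts <- function(bam, regions, bin_bp) {
  n_bins <- unique(GenomicRanges::width(regions)) %/% bin_bp
  if (length(n_bins) != 1) stopf("all regions must have identical width")
  param <- Rsamtools::ScanBamParam(
    what = "pos",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    which = regions)
  res <- Rsamtools::scanBam(bam, param = param)
  # scanBam returns results grouped by chromosome (seqlevels order, original
  # order within a chromosome); map them back onto the input region order
  sq <- as.character(GenomeInfoDb::seqnames(regions))
  perm <- order(match(sq, GenomeInfoDb::seqlevels(regions)))
  stopifnot(length(res) == length(regions))
  expected <- sprintf("%s:%d-%d", sq[perm],
                      GenomicRanges::start(regions)[perm],
                      GenomicRanges::end(regions)[perm])
  if (!is.null(names(res)) && !all(names(res) == expected))
    stopf("unexpected scanBam result ordering; cannot align regions")
  s0 <- GenomicRanges::start(regions) - 1
  e0 <- GenomicRanges::end(regions)
  counts <- matrix(0, length(regions), n_bins)
  for (i in seq_along(regions)) {
    j <- perm[i]
    pos0 <- res[[i]]$pos - 1
    pos0 <- pos0[pos0 >= s0[j] & pos0 < e0[j]]
    if (length(pos0))
      counts[j, ] <- tabulate((pos0 - s0[j]) %/% bin_bp + 1, nbins = n_bins)
  }
  counts
}

#' Compute an RPM-normalized, replicate-averaged coverage tensor
#'
#' For every region and histone mark, counts the reads whose leftmost aligned
#' base falls in each bin, normalizes each replicate to Reads Per Million
#' mapped reads (count x 1e6 / library size), and averages the replicate
#' tensors elementwise per mark.
#'
#' @param bams named list, one element per mark, each a character vector of
#'   indexed BAM paths (replicates).
#' @param regions `GRanges`, all of width `cfg$window_bp`.
#' @param cfg a [preprocess_config()].
#' @return a [signal_tensor()] of dimension
#'   `length(regions) x length(bams) x (window_bp / bin_bp)`.
#' @export
count_and_normalize <- function(bams, regions, cfg) {
  if (is.null(names(bams)) || any(names(bams) == ""))
    stopf("bams must be a named list (one name per mark)")
  if (!all(GenomicRanges::width(regions) == cfg$window_bp))
    stopf("all regions must have width %d", cfg$window_bp)
  check_regions_in_bam(bams[[1]][1], regions)
  n_bins <- cfg$window_bp %/% cfg$bin_bp
  marks <- names(bams)
  vals <- array(0, c(length(regions), length(marks), n_bins))
  for (m in seq_along(marks)) {
    reps <- bams[[m]]
    acc <- matrix(0, length(regions), n_bins)
    for (bam in reps) {
      lib <- library_size(bam)
      if (lib == 0) stopf("BAM has zero mapped reads: %s", bam)
      acc <- acc + bam_bin_counts(bam, regions, cfg$bin_bp) * 1e6 / lib
    }
    vals[, m, ] <- acc / length(reps)
  }
  signal_tensor(vals, marks, cfg$window_bp, cfg$bin_bp)
}

check_regions_in_bam <- function(bam, regions) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  validate_against_sizes(as.character(GenomeInfoDb::seqnames(regions)),
                         GenomicRanges::end(regions), hdr)
}

#' Genome-wide binned RPM coverage on a fixed grid
#'
#' Computes, for every chromosome, the per-bin RPM coverage (replicate
#' averaged per mark) over the regular `bin_bp` grid starting at position 0.
#' Sliding windows whose starts are multiples of `bin_bp` can then be sliced
#' out of this grid with [window_signal()], reusing bit-identical
#' normalization with [count_and_normalize()].
#'
#' @inheritParams count_and_normalize
#' @param sizes named vector of chromosome lengths.
#' @return a list with elements `grid` (per-chromosome `marks x n_bins`
#'   matrices), `mark_names`, `bin_bp`.
#' @export
genome_bin_signal <- function(bams, sizes, cfg) {
  marks <- names(bams)
  bin_bp <- cfg$bin_bp
  grid <- lapply(names(sizes), function(ch) {
    n_bins <- sizes[[ch]] %/% bin_bp
    matrix(0, length(marks), n_bins,
           dimnames = list(marks, NULL))
  })
  names(grid) <- names(sizes)
  for (m in seq_along(marks)) {
    for (bam in bams[[m]]) {
      lib <- library_size(bam)
      if (lib == 0) stopf("BAM has zero mapped reads: %s", bam)
      for (ch in names(sizes)) {
        n_bins <- sizes[[ch]] %/% bin_bp
        which <- GenomicRanges::GRanges(ch, IRanges::IRanges(1, sizes[[ch]]))
        param <- Rsamtools::ScanBamParam(
          what = "pos",
          flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
          which = which)
        pos0 <- Rsamtools::scanBam(bam, param = param)[[1]]$pos - 1
        pos0 <- pos0[pos0 %/% bin_bp < n_bins]
        cnt <- tabulate(pos0 %/% bin_bp + 1, nbins = n_bins)
        grid[[ch]][m, ] <- grid[[ch]][m, ] +
          cnt * 1e6 / lib / length(bams[[m]])
      }
    }
  }
  list(grid = grid, mark_names = marks, bin_bp = bin_bp)
}

#' Slice window tensors out of a genome-wide coverage grid
#'
#' @param gsig result of [genome_bin_signal()].
#' @param windows `GRanges` of equal-width windows whose starts are multiples
#'   of the grid bin size.
#' @return a [signal_tensor()] aligned with `windows`.
#' @export
window_signal <- function(gsig, windows) {
  bin_bp <- gsig$bin_bp
  w <- unique(GenomicRanges::width(windows))
  if (length(w) != 1) stopf("windows must share one width")
  if (w %% bin_bp != 0) stopf("window width must be a multiple of the bin size")
  n_bins <- w %/% bin_bp
  s0 <- GenomicRanges::start(windows) - 1
  if (any(s0 %% bin_bp != 0))
    stopf("window starts must be multiples of the bin size (%d)", bin_bp)
  chrom <- as.character(GenomeInfoDb::seqnames(windows))
  n_marks <- length(gsig$mark_names)
  vals <- array(0, c(length(windows), n_marks, n_bins))
  for (i in seq_along(windows)) {
    g <- gsig$grid[[chrom[i]]]
    if (is.null(g)) stopf("no coverage for chromosome %s", chrom[i])
    first <- s0[i] %/% bin_bp + 1
    if (first + n_bins - 1 > ncol(g))
      stopf("window %s:%d-%d has no coverage (off grid end)",
            chrom[i], s0[i], s0[i] + w)
    vals[i, , ] <- g[, first:(first + n_bins - 1)]
  }
  signal_tensor(vals, gsig$mark_names, w, bin_bp)
}
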