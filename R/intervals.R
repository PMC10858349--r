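#' Construct genomic intervals from 0-based half-open coordinates
#'
#' All user-facing coordinates in this package follow the BED convention:
#' 0-based starts, half-open `[start, end)` spans. Internally intervals are
#' held as [GenomicRanges::GRanges] (1-based, closed), and this constructor
#' performs the conversion and validation.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; requires
#'   `0 <= start < end`.
#' @param name,score,strand optional per-interval annotation; `strand` must be
#'   one of `+`, `-`, `.` (stored as `*`).
#' @param sizes optional named vector of chromosome lengths (see
#'   [read_chrom_sizes()]); when supplied, chromosome names and `end` bounds
#'   are checked against it.
#' @return a `GRanges` object.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, score = NULL,
                              strand = NULL, sizes = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != length(start) || length(start) != length(end))
    stopf("chrom, start and end must have equal length")
  if (any(start < 0) || any(start >= end))
    stopf("invalid interval: require 0 <= start < end")
  if (!is.null(sizes)) validate_against_sizes(chrom, end, sizes)
  str <- if (is.null(strand)) "*" else {
    s <- as.character(strand)
    s[s == "."] <- "*"
    if (!all(s %in% c("+", "-", "*"))) stopf("strand must be one of +, -, .")
    s
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               strand = str)
  if (!is.null(name)) gr$name <- as.character(name)
  if (!is.null(score)) gr$score <- as.numeric(score)
  gr
}

validate_against_sizes <- function(chrom, end, sizes) {
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown))
    stopf("unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  bad <- end > unname(sizes[chrom])
  if (any(bad))
    stopf("%d interval(s) extend past the end of their chromosome", sum(bad))
  invisible(TRUE)
}

#' Read and write chromosome-sizes tables
#'
#' A chrom.sizes file is a two-column, tab-separated table of chromosome name
#' and length in bp, with no header.
#'
#' @param path file path.
#' @return `read_chrom_sizes` returns a named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  sizes <- as.integer(df$length)
  names(sizes) <- df$chrom
  validate_chrom_sizes(sizes)
  sizes
}

#' @rdname read_chrom_sizes
#' @param sizes named vector of chromosome lengths.
#' @export
write_chrom_sizes <- function(sizes, path) {
  validate_chrom_sizes(sizes)
  utils::write.table(data.frame(names(sizes), as.integer(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_chrom_sizes <- function(sizes) {
  if (is.null(names(sizes)) || anyDuplicated(names(sizes)))
    stopf("chromosome names must be present and unique")
  if (any(!is.finite(sizes)) || any(sizes < 1))
    stopf("chromosome lengths must be >= 1")
  invisible(TRUE)
}

#' Slop intervals to a fixed width about their midpoints
#'
#' Each interval is replaced by a window of `width` bp centred on its midpoint
#' `m = floor((start + end) / 2)` (0-based coordinates), spanning
#' `[m - floor(width/2), m - floor(width/2) + width)`. Windows are clamped to
#' `[0, chromosome length)`; clamping at one edge does not re-extend the other
#' side, so only boundary windows may come out narrower than `width`.
#'
#' @param x a `GRanges` of input intervals.
#' @param width target width in bp (>= 1).
#' @param sizes named vector of chromosome lengths.
#' @return a `GRanges` of the same length, metadata columns preserved.
#' @export
slop_to_width <- function(x, width, sizes) {
  if (!is_count(width)) stopf("width must be a positive integer")
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  unknown <- setdiff(unique(chrom), names(sizes))
  if (length(unknown))
    stopf("unknown chromosome(s): %s", paste(unknown, collapse = ", "))
  s0 <- GenomicRanges::start(x) - 1
  e0 <- GenomicRanges::end(x)
  m <- (s0 + e0) %/% 2
  ns0 <- m - width %/% 2
  ne0 <- ns0 + width
  len <- unname(sizes[chrom])
  ns0 <- pmax(ns0, 0)
  ne0 <- pmin(ne0, len)
  out <- x
  IRanges::ranges(out) <- IRanges::IRanges(ns0 + 1, ne0)
  out
}

#' Keep or remove intervals by overlap with a second set
#'
#' Overlap means at least one shared base under half-open semantics; abutting
#' intervals do not overlap. Input order is preserved and `a` is not mutated.
#'
#' @param a,b `GRanges` objects.
#' @param mode `"keep"` returns the members of `a` overlapping at least one
#'   member of `b`; `"remove"` returns those overlapping none.
#' @return a subset of `a`.
#' @export
overlap_filter <- function(a, b, mode = c("keep", "remove")) {
  mode <- match.arg(mode)
  hit <- GenomicRanges::countOverlaps(a, b, ignore.strand = TRUE) > 0
  if (mode == "keep") a[hit] else a[!hit]
}

#' Randomly sample background windows avoiding excluded regions
#'
#' Draws `n` distinct windows of `width` bp whose starts lie on a `grid_bp`
#' grid and that overlap none of the exclusion intervals. By default the
#' sampled windows are also pairwise disjoint; if the eligible candidate pool
#' is smaller than `2 * n`, mutual overlap among background windows is
#' permitted so that `n` windows can still be returned.
#'
#' @param sizes named vector of chromosome lengths.
#' @param exclusions `GRanges` of regions that background must not overlap.
#' @param n number of windows to draw.
#' @param width window width in bp.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param grid_bp spacing of the candidate start grid (default 100 bp).
#' @return a `GRanges` of `n` windows, sorted by chromosome and start.
#' @export
sample_background <- function(sizes, exclusions, n, width = 2000L, seed = 1L,
                              grid_bp = 100L) {
  if (!is_count(n)) stopf("n must be a positive integer")
  validate_chrom_sizes(sizes)
  cand <- candidate_grid(sizes, width, grid_bp)
  if (length(cand) == 0) stopf("no candidate windows: genome shorter than width")
  keep <- GenomicRanges::countOverlaps(cand, exclusions,
                                       ignore.strand = TRUE) == 0
  cand <- cand[keep]
  if (length(cand) < n)
    stopf("requested %d background windows but only %d candidates are free of exclusions",
          n, length(cand))
  allow_overlap <- length(cand) < 2 * n
  ord <- withr::with_seed(seed, sample.int(length(cand)))
  if (allow_overlap) {
    picked <- ord[seq_len(n)]
  } else {
    picked <- greedy_disjoint(cand, ord, n, width, grid_bp)
    if (length(picked) < n) {
      # disjoint packing exhausted; top up with remaining eligible candidates
      rest <- setdiff(ord, picked)
      picked <- c(picked, rest[seq_len(n - length(picked))])
    }
  }
  GenomicRanges::sort(cand[picked], ignore.strand = TRUE)
}

candidate_grid <- function(sizes, width, grid_bp) {
  per_chrom <- lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    if (len < width) return(NULL)
    data.frame(chrom = ch, start0 = seq.int(0L, len - width, by = grid_bp))
  })
  df <- do.call(rbind, Filter(Negate(is.null), per_chrom))
  if (is.null(df)) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start0 + 1, df$start0 + width))
}

# Greedy disjoint selection over a random candidate order. Candidates sit on a
# regular grid, so conflicts are tracked with one logical vector per
# chromosome indexed by grid cell.
greedy_disjoint <- function(cand, ord, n, width, grid_bp) {
  chrom <- as.character(GenomeInfoDb::seqnames(cand))
  cell <- (GenomicRanges::start(cand) - 1) %/% grid_bp + 1
  span <- ceiling(width / grid_bp) - 1  # cells blocked on each side
  blocked <- new.env(parent = emptyenv())
  for (ch in unique(chrom)) assign(ch, logical(max(cell[chrom == ch]) + span),
                                   envir = blocked)
  picked <- integer(0)
  for (i in ord) {
    ch <- chrom[i]
    bl <- get(ch, envir = blocked)
    if (bl[cell[i]]) next
    lo <- max(1L, cell[i] - span)
    hi <- cell[i] + span
    bl[lo:hi] <- TRUE
    assign(ch, bl, envir = blocked)
    picked <- c(picked, i)
    if (length(picked) == n) break
  }
  picked
}

#' Read and write BED files
#'
#' Thin wrappers around `rtracklayer::import()`/`rtracklayer::export()` for
#' BED3/BED6 (tab-separated, no header). On write, scores are clamped to the
#' BED-legal 0-1000 range.
#'
#' @param path file path.
#' @return `read_bed` returns a `GRanges`.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' @rdname read_bed
#' @param x a `GRanges` to write.
#' @export
write_bed <- function(x, path) {
  if (!is.null(x$score)) {
    x$score[is.na(x$score)] <- 0
    x$score <- pmin(pmax(x$score, 0), 1000)
  }
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
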