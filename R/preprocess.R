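#' Preprocessing configuration
#'
#' Defaults follow the standard pipeline setup: 2 kb windows split into 20
#' bins of 100 bp, 30 000 random background regions, and either a
#' chromosome-wise split (chr1-7 train, chr8-16 validation, chr17-22 + X + Y
#' test) or a random 60:20:20 split.
#'
#' @param window_bp window width in bp.
#' @param bin_bp bin width in bp; must divide `window_bp`.
#' @param n_background number of random background regions.
#' @param split_mode `"chromosome"` or `"random"`.
#' @param random_split_ratio train/validation/test fractions summing to 1.
#' @param train_chroms,val_chroms,test_chroms chromosome lists for the
#'   chromosome-wise split.
#' @param seed integer seed driving background sampling and the random split.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(window_bp = 2000L,
                              bin_bp = 100L,
                              n_background = 30000L,
                              split_mode = c("chromosome", "random"),
                              random_split_ratio = c(0.6, 0.2, 0.2),
                              train_chroms = paste0("chr", 1:7),
                              val_chroms = paste0("chr", 8:16),
                              test_chroms = c(paste0("chr", 17:22), "chrX", "chrY"),
                              seed = 1L) {
  split_mode <- match.arg(split_mode)
  if (window_bp %% bin_bp != 0) stopf("window_bp must be divisible by bin_bp")
  if (abs(sum(random_split_ratio) - 1) > 1e-8)
    stopf("random_split_ratio must sum to 1")
  structure(list(window_bp = as.integer(window_bp),
                 bin_bp = as.integer(bin_bp),
                 n_background = as.integer(n_background),
                 n_state_clusters = 2L,
                 split_mode = split_mode,
                 random_split_ratio = random_split_ratio,
                 train_chroms = train_chroms,
                 val_chroms = val_chroms,
                 test_chroms = test_chroms,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Define promoter regions from TSS annotation and accessibility peaks
#'
#' Each TSS is slopped to `cfg$window_bp` about its midpoint and retained if
#' the window overlaps at least one accessibility (DHS/ATAC) peak. Windows
#' with identical spans are collapsed to one.
#'
#' @param tss `GRanges` of TSS annotations (typically 1 bp points).
#' @param accessibility_peaks `GRanges` of open-chromatin peaks.
#' @param cfg a [preprocess_config()].
#' @param sizes named vector of chromosome lengths.
#' @return `GRanges` of promoter windows.
#' @export
define_promoters <- function(tss, accessibility_peaks, cfg, sizes) {
  if (length(tss) == 0) stopf("tss must be non-empty")
  if (length(accessibility_peaks) == 0)
    stopf("accessibility peaks are required for promoter definition")
  slopped <- slop_to_width(tss, cfg$window_bp, sizes)
  kept <- overlap_filter(slopped, accessibility_peaks, "keep")
  unique(kept)
}

#' Define enhancer regions from TF peaks
#'
#' Keeps TF (e.g. p300/CBP) peaks that overlap an accessibility peak, removes
#' any that overlap an H3K4me3 peak or a window-slopped TSS (to avoid
#' promoters), and slops the survivors to `cfg$window_bp` about the peak
#' midpoint. Identical spans are collapsed.
#'
#' @param tf_peaks `GRanges` of enhancer-associated TF peaks.
#' @param h3k4me3_peaks `GRanges` of H3K4me3 peaks.
#' @param tss `GRanges` of TSS annotations.
#' @inheritParams define_promoters
#' @return `GRanges` of enhancer windows.
#' @export
define_enhancers <- function(tf_peaks, accessibility_peaks, h3k4me3_peaks,
                             tss, cfg, sizes) {
  if (length(tf_peaks) == 0) stopf("tf_peaks must be non-empty")
  kept <- overlap_filter(tf_peaks, accessibility_peaks, "keep")
  tss_windows <- slop_to_width(tss, cfg$window_bp, sizes)
  kept <- overlap_filter(kept, h3k4me3_peaks, "remove")
  kept <- overlap_filter(kept, tss_windows, "remove")
  unique(slop_to_width(kept, cfg$window_bp, sizes))
}

#' Call active/poised states from GRO-seq coverage by K-means
#'
#' Per-site coverage is the unstranded total RPM of reads starting within the
#' site, averaged over the supplied alignment files. K-means with k = 2 is
#' run on `log2(coverage + 1)` using Lloyd iterations initialized
#' deterministically at the minimum and maximum values; the cluster with the
#' larger centroid is labeled `active`. Enhancers and promoters are expected
#' to be clustered separately by the caller.
#'
#' @param sites `GRanges` of >= 2 element sites.
#' @param groseq_bams character vector of indexed GRO-seq BAM paths.
#' @param cfg a [preprocess_config()].
#' @return a `state_assignment` list with `state` (factor, levels
#'   poised/active), `centroids` (log2 scale, poised < active), and the raw
#'   per-site `coverage`.
#' @export
groseq_state_kmeans <- function(sites, groseq_bams, cfg) {
  if (length(sites) < 2) stopf("need at least 2 sites to separate states")
  cov <- rep(0, length(sites))
  for (bam in groseq_bams) {
    lib <- library_size(bam)
    if (lib == 0) stopf("GRO-seq BAM has zero mapped reads: %s", bam)
    cnt <- rowSums(bam_bin_counts(bam, sites,
                                  bin_bp = unique(GenomicRanges::width(sites))))
    cov <- cov + cnt * 1e6 / lib
  }
  cov <- cov / length(groseq_bams)
  x <- log2(cov + 1)
  if (max(x) - min(x) < 1e-12)
    stopf("degenerate coverage, cannot separate states")
  centers <- matrix(c(min(x), max(x)), ncol = 1)
  km <- suppressWarnings(
    stats::kmeans(x, centers = centers, iter.max = 300, algorithm = "Lloyd"))
  active_cluster <- which.max(km$centers[, 1])
  state <- factor(ifelse(km$cluster == active_cluster, "active", "poised"),
                  levels = c("poised", "active"))
  centroids <- sort(km$centers[, 1])
  names(centroids) <- c("poised", "active")
  structure(list(state = state, centroids = centroids, coverage = cov),
            class = "state_assignment")
}

#' Assemble a labeled dataset from regions, states and a coverage tensor
#'
#' Sample order is background, then enhancers, then promoters; the tensor
#' rows must follow the same order. Class labels per mode:
#' \describe{
#'   \item{2-class}{enhancer = 1; background and promoter = 0.}
#'   \item{3-class}{background = 0, enhancer = 1, promoter = 2.}
#'   \item{5-class}{Bgd = 0, poised enhancer = 1, active enhancer = 2,
#'     poised promoter = 3, active promoter = 4 (requires `states`).}
#' }
#'
#' @param promoters,enhancers,background `GRanges` of the final regions.
#' @param states `NULL`, or a list with elements `enhancer` and `promoter`,
#'   each a [groseq_state_kmeans()] result (5-class mode only).
#' @param tensor a [signal_tensor()] whose rows follow
#'   `c(background, enhancers, promoters)`.
#' @param mode 2, 3 or 5.
#' @param cfg a [preprocess_config()].
#' @return a `labeled_dataset` list with `tensor`, integer `labels`,
#'   `intervals`, `mode`, `class_names` and a `split` slot (NULL until
#'   [split_dataset()] is applied).
#' @export
assemble_dataset <- function(promoters, enhancers, background, states = NULL,
                             tensor, mode = 3, cfg = preprocess_config()) {
  mode <- as.integer(mode)
  if (!mode %in% c(2L, 3L, 5L)) stopf("mode must be 2, 3 or 5")
  n <- length(background) + length(enhancers) + length(promoters)
  if (dim(tensor)[1] != n)
    stopf("tensor has %d rows but %d regions were supplied", dim(tensor)[1], n)
  if (mode == 5L) {
    if (is.null(states$enhancer) || is.null(states$promoter))
      stopf("5-class mode requires enhancer and promoter state assignments")
    if (length(states$enhancer$state) != length(enhancers) ||
        length(states$promoter$state) != length(promoters))
      stopf("state assignments do not match region counts")
  }
  labels <- switch(as.character(mode),
    "2" = c(rep(0L, length(background)), rep(1L, length(enhancers)),
            rep(0L, length(promoters))),
    "3" = c(rep(0L, length(background)), rep(1L, length(enhancers)),
            rep(2L, length(promoters))),
    "5" = c(rep(0L, length(background)),
            ifelse(states$enhancer$state == "active", 2L, 1L),
            ifelse(states$promoter$state == "active", 4L, 3L)))
  class_names <- switch(as.character(mode),
    "2" = c("Bgd", "Enh"),
    "3" = c("Bgd", "Enh", "Prom"),
    "5" = c("Bgd", "PE", "AE", "PT", "AT"))
  # combining sets whose seqlevels differ (e.g. one empty) is expected here
  intervals <- suppressWarnings(c(background, enhancers, promoters))
  structure(list(tensor = tensor, labels = labels, intervals = intervals,
                 mode = mode, class_names = class_names, split = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d samples, %d-class (%s)\n",
              length(x$labels), x$mode, paste(x$class_names, collapse = "/")))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

n_classes <- function(ds) length(ds$class_names)

#' Assign train/validation/test splits
#'
#' Chromosome mode assigns each sample by membership of its chromosome in the
#' configured train/validation/test lists and errors on chromosomes in none
#' of them. Random mode shuffles samples with the config seed and assigns the
#' first `floor(0.6 n)` to train, the next `floor(0.2 n)` to validation, and
#' the remainder to test.
#'
#' @param ds a `labeled_dataset`.
#' @param cfg a [preprocess_config()].
#' @return the dataset with a `split` factor (levels train/val/test).
#' @export
split_dataset <- function(ds, cfg) {
  n <- length(ds$labels)
  if (cfg$split_mode == "chromosome") {
    chrom <- as.character(GenomeInfoDb::seqnames(ds$intervals))
    split <- rep(NA_character_, n)
    split[chrom %in% cfg$train_chroms] <- "train"
    split[chrom %in% cfg$val_chroms] <- "val"
    split[chrom %in% cfg$test_chroms] <- "test"
    multi <- intersect(intersect(cfg$train_chroms, cfg$val_chroms),
                       cfg$test_chroms)
    dup <- c(intersect(cfg$train_chroms, cfg$val_chroms),
             intersect(cfg$train_chroms, cfg$test_chroms),
             intersect(cfg$val_chroms, cfg$test_chroms))
    if (length(dup))
      stopf("chromosome(s) in more than one split list: %s",
            paste(unique(dup), collapse = ", "))
    if (anyNA(split)) {
      missing <- unique(chrom[is.na(split)])
      stopf("chromosome(s) not in any split list: %s",
            paste(missing, collapse = ", "))
    }
  } else {
    r <- cfg$random_split_ratio
    perm <- withr::with_seed(cfg$seed, sample.int(n))
    n_train <- floor(r[1] * n)
    n_val <- floor(r[2] * n)
    split <- rep("test", n)
    split[perm[seq_len(n_train)]] <- "train"
    split[perm[n_train + seq_len(n_val)]] <- "val"
  }
  ds$split <- factor(split, levels = c("train", "val", "test"))
  ds
}

split_index <- function(ds, split) {
  if (is.null(ds$split)) stopf("dataset has no split; run split_dataset() first")
  which(ds$split == split)
}

#' Save or load a labeled dataset archive
#'
#' The archive is a directory holding the coverage array in a binary
#' container (`tensor.rds`) plus a JSON sidecar with mark names, intervals,
#' labels, splits and the configuration, and BED files of the final regions
#' with the class name in the BED name field.
#'
#' @param ds a `labeled_dataset`.
#' @param dir output directory (created if needed).
#' @export
save_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(ds$tensor$values, file.path(dir, "tensor.rds"))
  iv <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(ds$intervals)),
                   start = GenomicRanges::start(ds$intervals) - 1,
                   end = GenomicRanges::end(ds$intervals))
  side <- list(mark_names = ds$tensor$mark_names,
               window_bp = ds$tensor$window_bp,
               bin_bp = ds$tensor$bin_bp,
               mode = ds$mode,
               class_names = ds$class_names,
               labels = ds$labels,
               split = if (is.null(ds$split)) NULL else as.character(ds$split),
               intervals = iv)
  jsonlite::write_json(side, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  regions <- GenomicRanges::granges(ds$intervals)
  regions$name <- ds$class_names[ds$labels + 1]
  write_bed(regions, file.path(dir, "regions.bed"))
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "dataset.json"),
                              simplifyVector = TRUE)
  values <- readRDS(file.path(dir, "tensor.rds"))
  tensor <- signal_tensor(values, side$mark_names, side$window_bp, side$bin_bp)
  intervals <- genomic_intervals(side$intervals$chrom, side$intervals$start,
                                 side$intervals$end)
  ds <- structure(list(tensor = tensor,
                       labels = as.integer(side$labels),
                       intervals = intervals,
                       mode = as.integer(side$mode),
                       class_names = side$class_names,
                       split = NULL),
                  class = "labeled_dataset")
  if (!is.null(side$split))
    ds$split <- factor(side$split, levels = c("train", "val", "test"))
  ds
}

#' Run the full preprocessing pipeline
#'
#' Defines promoters, enhancers and background from annotation files, counts
#' and normalizes histone-mark coverage, optionally calls active/poised
#' states from GRO-seq (5-class mode), and returns a split
#' [assemble_dataset()] result.
#'
#' @param tss,accessibility_peaks,tf_peaks,h3k4me3_peaks `GRanges`
#'   annotations (see [define_promoters()], [define_enhancers()]).
#' @param bams named list mark -> character vector of replicate BAM paths.
#' @param sizes named vector of chromosome lengths.
#' @param cfg a [preprocess_config()].
#' @param mode 2, 3 or 5.
#' @param groseq_bams character vector of GRO-seq BAMs (required for mode 5).
#' @return a split `labeled_dataset`.
#' @export
run_preprocess <- function(tss, accessibility_peaks, tf_peaks, h3k4me3_peaks,
                           bams, sizes, cfg = preprocess_config(), mode = 3,
                           groseq_bams = NULL) {
  promoters <- define_promoters(tss, accessibility_peaks, cfg, sizes)
  enhancers <- define_enhancers(tf_peaks, accessibility_peaks, h3k4me3_peaks,
                                tss, cfg, sizes)
  exclusions <- suppressWarnings(
    c(GenomicRanges::granges(promoters),
      GenomicRanges::granges(enhancers),
      GenomicRanges::granges(accessibility_peaks),
      GenomicRanges::granges(tf_peaks)))
  background <- sample_background(sizes, exclusions, cfg$n_background,
                                  width = cfg$window_bp, seed = cfg$seed,
                                  grid_bp = cfg$bin_bp)
  regions <- suppressWarnings(
    c(GenomicRanges::granges(background),
      GenomicRanges::granges(enhancers),
      GenomicRanges::granges(promoters)))
  tensor <- count_and_normalize(bams, regions, cfg)
  states <- NULL
  if (as.integer(mode) == 5L) {
    if (is.null(groseq_bams))
      stopf("5-class mode requires GRO-seq alignment files")
    states <- list(
      enhancer = groseq_state_kmeans(enhancers, groseq_bams, cfg),
      promoter = groseq_state_kmeans(promoters, groseq_bams, cfg))
  }
  ds <- assemble_dataset(promoters, enhancers, background, states,
                         tensor, mode, cfg)
  split_dataset(ds, cfg)
}
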