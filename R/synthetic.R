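#' Configuration for the synthetic ChIP-seq bundle generator
#'
#' Generates a toy genome with planted promoter/enhancer/background sites
#' whose per-mark read coverage follows class-specific signatures: a
#' triangular peak of expected reads (scaled by the signature amplitude) on
#' top of a uniform background, with Poisson (optionally negative-binomial)
#' count noise. GRO-seq coverage is bimodal: active sites draw from a
#' high-mean process and poised sites from a low-mean one.
#'
#' Default signatures follow the qualitative chromatin-biology expectations:
#' active promoters are high in H3K4me3, H3K27ac, H3K9ac and H3K4me2; active
#' enhancers in H3K4me1, H3K27ac and H3K4me2 with no H3K4me3; poised
#' enhancers in H3K4me1 and H3K27me3 with low H3K27ac; poised promoters in
#' H3K4me3 and H3K27me3; background is flat.
#'
#' @param chrom_lengths named vector; default 24 chromosomes (chr1-chr22,
#'   chrX, chrY) of 200 kb.
#' @param n_per_class named integer vector for Bgd/PE/AE/PT/AT.
#' @param marks histone-mark names (default 12 marks).
#' @param signatures class x mark amplitude matrix (expected reads in the
#'   peak bin at replicate scale 1); `NULL` for the defaults.
#' @param background_rate expected background reads per 100 bp bin per
#'   library at replicate scale 1.
#' @param window_bp,bin_bp site width and bin width.
#' @param read_length emitted read length in bp.
#' @param replicate_scales per-replicate library scale factors (two
#'   replicates with different library sizes by default).
#' @param reads_per_library if set, every emitted ChIP library totals exactly
#'   this many reads (background takes up the remainder after planting);
#'   `NULL` auto-sizes each library.
#' @param noise `"poisson"` or `"nbinom"`.
#' @param nb_size negative-binomial size parameter when `noise = "nbinom"`.
#' @param groseq_high_mean,groseq_low_mean expected GRO-seq reads per active
#'   (resp. poised) site; the default separation ratio is 10.
#' @param groseq_background_rate expected GRO-seq background reads per bin.
#' @param seed integer master seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(chrom_lengths = NULL,
                             n_per_class = c(Bgd = 200L, PE = 200L, AE = 200L,
                                             PT = 200L, AT = 200L),
                             marks = c("H3K27ac", "H3K27me3", "H3K4me1",
                                       "H3K4me2", "H3K4me3", "H3K9ac",
                                       "H3K4ac", "H3K9me3", "H3K36me3",
                                       "H3K79me2", "H4K20me1", "H2AFZ"),
                             signatures = NULL,
                             background_rate = 1.0,
                             window_bp = 2000L, bin_bp = 100L,
                             read_length = 50L,
                             replicate_scales = c(1, 1.5),
                             reads_per_library = NULL,
                             noise = c("poisson", "nbinom"),
                             nb_size = 10,
                             groseq_high_mean = 200,
                             groseq_low_mean = 20,
                             groseq_background_rate = 0.2,
                             seed = 1L) {
  noise <- match.arg(noise)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(rep(200000L, 24),
                                     c(paste0("chr", 1:22), "chrX", "chrY"))
  }
  validate_chrom_sizes(chrom_lengths)
  classes <- c("Bgd", "PE", "AE", "PT", "AT")
  if (!all(classes %in% names(n_per_class)))
    stopf("n_per_class must name all of %s", paste(classes, collapse = ", "))
  if (is.null(signatures)) {
    signatures <- matrix(0, 5, length(marks),
                         dimnames = list(classes, marks))
    hi <- 20; lo <- 4
    set_amp <- function(cls, mks, amp) {
      mks <- intersect(mks, marks)
      signatures[cls, mks] <<- amp
    }
    set_amp("AT", c("H3K4me3", "H3K27ac", "H3K9ac", "H3K4me2"), hi)
    set_amp("AE", c("H3K4me1", "H3K27ac", "H3K4me2"), hi)
    set_amp("PE", c("H3K4me1", "H3K27me3"), hi)
    set_amp("PE", "H3K27ac", lo)
    set_amp("PT", c("H3K4me3", "H3K27me3"), hi)
  }
  if (!identical(rownames(signatures), classes))
    stopf("signatures rows must be %s", paste(classes, collapse = ", "))
  if (any(signatures < 0)) stopf("signature amplitudes must be >= 0")
  if (window_bp %% bin_bp != 0) stopf("window_bp must be divisible by bin_bp")
  structure(list(chrom_lengths = chrom_lengths,
                 n_per_class = n_per_class[classes],
                 marks = marks, signatures = signatures,
                 background_rate = background_rate,
                 window_bp = as.integer(window_bp),
                 bin_bp = as.integer(bin_bp),
                 read_length = as.integer(read_length),
                 replicate_scales = replicate_scales,
                 reads_per_library = reads_per_library,
                 noise = noise, nb_size = nb_size,
                 groseq_high_mean = groseq_high_mean,
                 groseq_low_mean = groseq_low_mean,
                 groseq_background_rate = groseq_background_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Triangular per-bin peak profile over the site, normalized to max 1.
triangle_profile <- function(n_bins) {
  centers <- seq_len(n_bins) - 0.5
  w <- 1 - abs(centers - n_bins / 2) / (n_bins / 2)
  w / max(w)
}

#' Plant class-labeled sites on the toy genome
#'
#' Sites are `window_bp` wide, pairwise separated by at least `window_bp`,
#' and spread across all chromosomes in an interleaved deterministic-random
#' order so that any chromosome-wise split retains sites of every class.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_truth` list with `sites` (`GRanges` with `class` and
#'   `state` metadata, position-sorted) and the `cfg`.
#' @export
plant_sites <- function(cfg) {
  w <- cfg$window_bp
  pitch <- 2L * w   # site + >= window_bp gap
  slots <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    if (len < 3L * w) return(NULL)
    starts0 <- seq.int(w, len - 2L * w, by = pitch)
    data.frame(chrom = ch, start0 = starts0)
  })
  slots <- do.call(rbind, Filter(Negate(is.null), slots))
  n_total <- sum(cfg$n_per_class)
  if (is.null(slots) || nrow(slots) < n_total)
    stopf("genome too small: %d site slots available for %d requested sites",
          if (is.null(slots)) 0L else nrow(slots), n_total)
  withr::with_seed(cfg$seed, {
    # stream slots one chromosome at a time in rounds so classes spread out
    rank_in_chrom <- stats::ave(seq_len(nrow(slots)), slots$chrom,
                                FUN = function(i) sample(seq_along(i)))
    tie <- stats::runif(nrow(slots))
    stream <- order(rank_in_chrom, tie)
  })
  counts <- cfg$n_per_class[cfg$n_per_class > 0]
  inst <- unlist(lapply(names(counts), function(cl)
    rep(cl, counts[[cl]])), use.names = FALSE)
  key <- unlist(lapply(counts, function(n) (seq_len(n) - 0.5) / n),
                use.names = FALSE)
  cls_seq <- inst[order(key, inst)]   # evenly interleaved class sequence
  chosen <- slots[stream[seq_len(n_total)], ]
  gr <- genomic_intervals(chosen$chrom, chosen$start0, chosen$start0 + w,
                          sizes = cfg$chrom_lengths)
  gr$class <- cls_seq
  gr$state <- ifelse(gr$class %in% c("AE", "AT"), "active",
                     ifelse(gr$class %in% c("PE", "PT"), "poised", NA))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  structure(list(sites = gr, cfg = cfg), class = "synthetic_truth")
}

# Write a set of aligned single-end reads (leftmost base pos0, 0-based) as a
# sorted, indexed BAM via an intermediate SAM.
write_toy_bam <- function(chrom, pos0, sizes, prefix, read_length) {
  len <- unname(sizes[chrom])
  pos0 <- pmin(pmax(pos0, 0), len - read_length)
  ord <- order(chrom, pos0)
  chrom <- chrom[ord]; pos0 <- pos0[ord]
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), unname(sizes)))
  lines <- sprintf("r%d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                   seq_along(chrom), chrom, pos0 + 1L, read_length)
  sam <- paste0(prefix, ".sam")
  writeLines(c(header, lines), sam)
  bam <- suppressMessages(
    Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE))
  unlink(sam)
  bam
}

count_noise <- function(n, lambda, cfg) {
  if (cfg$noise == "poisson") stats::rpois(n, lambda)
  else stats::rnbinom(n, size = cfg$nb_size, mu = lambda)
}

#' Emit the full synthetic ChIP-seq input bundle
#'
#' Writes, per mark and replicate, a sorted indexed BAM of reads drawn from a
#' uniform background process plus triangular site peaks scaled by the class
#' signature; plus the chrom.sizes table and the annotation BED files
#' consumed by preprocessing (TSS = promoter-site midpoints, TF peaks =
#' enhancer-site midpoints +- 250 bp, accessibility = all non-background
#' site spans, H3K4me3 peaks = promoter-site spans).
#'
#' @param truth a [plant_sites()] result.
#' @param cfg the matching [synthetic_config()].
#' @param dir output directory.
#' @return a manifest list: `bams` (mark -> replicate BAM paths),
#'   `chrom_sizes`, `sizes`, and the four annotation BED paths.
#' @export
emit_reads <- function(truth, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- cfg$chrom_lengths
  sites <- truth$sites
  n_bins <- cfg$window_bp %/% cfg$bin_bp
  tri <- triangle_profile(n_bins)
  genome_bins <- sum(sizes %/% cfg$bin_bp)
  s0 <- GenomicRanges::start(sites) - 1
  site_chrom <- as.character(GenomeInfoDb::seqnames(sites))
  amp_site <- function(mark) cfg$signatures[sites$class, mark]

  bams <- list()
  for (mark in cfg$marks) {
    paths <- character(0)
    for (r in seq_along(cfg$replicate_scales)) {
      scale <- cfg$replicate_scales[r]
      withr::with_seed(
        cfg$seed + 101L * match(mark, cfg$marks) + 7L * r, {
        amps <- amp_site(mark) * scale
        lam <- outer(amps, tri)                    # sites x bins
        k <- count_noise(length(lam), as.vector(lam), cfg)
        # expand one read per count; as.vector(lam) is column-major
        # (site fastest within bin), mirrored below
        read_site <- rep(rep(seq_along(sites), n_bins), k)
        read_bin <- rep(rep(seq_len(n_bins), each = length(sites)), k)
        planted_chrom <- site_chrom[read_site]
        planted_pos0 <- s0[read_site] + (read_bin - 1L) * cfg$bin_bp +
          floor(stats::runif(length(read_site), 0, cfg$bin_bp))
        expected_planted <- sum(amps) * sum(tri)
        target <- cfg$reads_per_library %||%
          round(cfg$background_rate * scale * genome_bins + expected_planted)
        bg_n <- target - length(read_site)
        if (bg_n < 0)
          stopf("reads_per_library = %d is smaller than the %d planted reads",
                target, length(read_site))
        bg_chrom <- sample(names(sizes), bg_n, replace = TRUE,
                           prob = as.numeric(sizes))
        bg_pos0 <- floor(stats::runif(bg_n) *
                           (unname(sizes[bg_chrom]) - cfg$read_length + 1))
        prefix <- file.path(dir, sprintf("%s_rep%d", mark, r))
        paths <- c(paths, write_toy_bam(c(planted_chrom, bg_chrom),
                                        c(planted_pos0, bg_pos0),
                                        sizes, prefix, cfg$read_length))
      })
    }
    bams[[mark]] <- paths
  }

  prom <- sites[sites$class %in% c("PT", "AT")]
  enh <- sites[sites$class %in% c("PE", "AE")]
  mid <- function(gr) (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) %/% 2
  tss <- genomic_intervals(as.character(GenomeInfoDb::seqnames(prom)),
                           mid(prom), mid(prom) + 1)
  tf <- genomic_intervals(as.character(GenomeInfoDb::seqnames(enh)),
                          mid(enh) - 250, mid(enh) + 250)
  acc <- GenomicRanges::granges(sites[sites$class != "Bgd"])
  h3k4me3 <- GenomicRanges::granges(prom)

  paths <- list(
    chrom_sizes = write_chrom_sizes(sizes, file.path(dir, "chrom.sizes")),
    tss = write_bed(tss, file.path(dir, "tss.bed")),
    tf_peaks = write_bed(tf, file.path(dir, "tf_peaks.bed")),
    accessibility = write_bed(acc, file.path(dir, "accessibility.bed")),
    h3k4me3_peaks = write_bed(h3k4me3, file.path(dir, "h3k4me3_peaks.bed")))
  c(list(bams = bams, sizes = sizes), paths)
}

#' Emit a synthetic GRO-seq alignment file
#'
#' Active sites draw read counts from the high-mean process and poised sites
#' from the low-mean one (default separation ratio 10); a light uniform
#' background covers the rest of the genome.
#'
#' @param truth a [plant_sites()] result.
#' @param cfg the matching [synthetic_config()].
#' @param dir output directory.
#' @return path to the sorted indexed BAM.
#' @export
emit_groseq <- function(truth, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- cfg$chrom_lengths
  sites <- truth$sites
  stated <- !is.na(sites$state)
  withr::with_seed(cfg$seed + 99991L, {
    mu <- ifelse(sites$state[stated] == "active",
                 cfg$groseq_high_mean, cfg$groseq_low_mean)
    k <- count_noise(sum(stated), mu, cfg)
    read_site <- rep(which(stated), k)
    chrom <- as.character(GenomeInfoDb::seqnames(sites))[read_site]
    off <- floor(stats::runif(length(read_site), 0, cfg$window_bp))
    pos0 <- GenomicRanges::start(sites)[read_site] - 1 + off
    genome_bins <- sum(sizes %/% cfg$bin_bp)
    bg_n <- stats::rpois(1, cfg$groseq_background_rate * genome_bins)
    bg_chrom <- sample(names(sizes), bg_n, replace = TRUE,
                       prob = as.numeric(sizes))
    bg_pos0 <- floor(stats::runif(bg_n) *
                       (unname(sizes[bg_chrom]) - cfg$read_length + 1))
    write_toy_bam(c(chrom, bg_chrom), c(pos0, bg_pos0), sizes,
                  file.path(dir, "groseq"), cfg$read_length)
  })
}

#' Generate the complete synthetic input bundle
#'
#' Convenience wrapper: [plant_sites()] + [emit_reads()] + [emit_groseq()].
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory.
#' @return list with `truth`, `files` (the [emit_reads()] manifest) and
#'   `groseq_bam`.
#' @export
simulate_bundle <- function(cfg, dir) {
  truth <- plant_sites(cfg)
  files <- emit_reads(truth, cfg, dir)
  groseq_bam <- emit_groseq(truth, cfg, dir)
  list(truth = truth, files = files, groseq_bam = groseq_bam)
}
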