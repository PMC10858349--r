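test_that("genome tiling arithmetic is exact", {
  expect_length(tile_genome(c(chr1 = 4000L), 2000, 200), 11)
  expect_equal(GenomicRanges::start(tile_genome(c(chr1 = 4000L), 2000, 200)) - 1,
               seq(0, 2000, by = 200))
  expect_length(tile_genome(c(chr1 = 1999L), 2000, 200), 0)
  tw <- tile_genome(c(chr1 = 2000L), 2000, 200)
  expect_length(tw, 1)
  expect_equal(GenomicRanges::start(tw) - 1, 0)
  expect_equal(GenomicRanges::end(tw), 2000)

  # (L - window)/step + 1 windows per chromosome; consecutive overlap = 1800
  sizes <- c(chr1 = 10000L, chr2 = 7300L)
  tiles <- tile_genome(sizes, 2000, 200)
  expect_length(tiles, (10000 - 2000) %/% 200 + 1 + (7300 - 2000) %/% 200 + 1)
  s <- GenomicRanges::start(tiles[as.character(GenomeInfoDb::seqnames(tiles)) == "chr1"])
  expect_true(all(diff(s) == 200))
})

fake_windows <- function(starts, chrom = "chr1") {
  gi(chrom, starts, starts + 2000)
}

test_that("probability filtering keeps confident non-background windows", {
  w <- fake_windows(c(0, 200, 400))
  probs <- rbind(c(0.9, 0.07, 0.03),
                 c(0.2, 0.6, 0.2),
                 c(0.1, 0.45, 0.45))
  kept <- predict_and_filter(NULL, w, NULL, cutoff = 0.5, probs = probs)
  expect_length(kept, 1)
  expect_equal(GenomicRanges::start(kept) - 1, 200)
  expect_equal(kept$predicted_class, 1L)
  expect_equal(kept$score, 0.6)

  # cutoff monotonicity and extremes
  withr::with_seed(12, {
    n <- 50
    p <- matrix(rexp(n * 3), n, 3)
    p <- p / rowSums(p)
  })
  w2 <- fake_windows(seq(0, by = 200, length.out = n))
  sizes_prev <- -1
  for (cut in c(0, 0.25, 0.5, 0.75, 1)) {
    kept_n <- length(predict_and_filter(NULL, w2, NULL, cutoff = cut, probs = p))
    if (sizes_prev >= 0) expect_lte(kept_n, sizes_prev)
    sizes_prev <- kept_n
  }
  expect_length(predict_and_filter(NULL, w2, NULL, cutoff = 1, probs = p), 0)
  k0 <- predict_and_filter(NULL, w2, NULL, cutoff = 0, probs = p)
  expect_equal(length(k0), sum(apply(p[, -1], 1, max) > 0))
})

test_that("consolidation merges overlapping/abutting same-class windows only", {
  mk <- function(starts, cls, score = 0.8, chrom = "chr1") {
    w <- fake_windows(starts, chrom)
    w$predicted_class <- cls
    w$score <- score
    w
  }
  one <- consolidate_blocks(mk(c(0, 200), c(1L, 1L), c(0.7, 0.9)))
  expect_length(one, 1)
  expect_equal(GenomicRanges::start(one) - 1, 0)
  expect_equal(GenomicRanges::end(one), 2200)
  expect_equal(one$n_windows, 2L)
  expect_equal(one$score, 0.9)

  two_cls <- consolidate_blocks(mk(c(0, 200), c(1L, 2L)))
  expect_length(two_cls, 2)

  gap <- consolidate_blocks(mk(c(0, 4000), c(1L, 1L)))
  expect_length(gap, 2)

  # abutting windows merge
  abut <- consolidate_blocks(mk(c(0, 2000), c(1L, 1L)))
  expect_length(abut, 1)

  expect_error(consolidate_blocks(mk(c(400, 0), c(1L, 1L))), "sorted")
})

test_that("consolidation is idempotent and conserves window counts", {
  withr::with_seed(77, {
    for (trial in 1:5) {
      starts <- sort(sample(seq(0, 40000, by = 200), 40))
      cls <- sample(1:2, 40, TRUE)
      w <- fake_windows(starts)
      w$predicted_class <- cls
      w$score <- runif(40, 0.5, 1)
      blocks <- consolidate_blocks(w)
      expect_equal(sum(blocks$n_windows), 40)
      # every window falls in exactly one block of its own class
      for (k in 1:2) {
        sub <- w[w$predicted_class == k]
        bl <- blocks[blocks$class == k]
        expect_true(all(GenomicRanges::countOverlaps(sub, bl) >= 1))
      }
      # feeding blocks back in changes nothing
      again <- blocks
      again$predicted_class <- again$class
      again$n_windows <- NULL
      res2 <- consolidate_blocks(again)
      expect_equal(GenomicRanges::granges(res2), GenomicRanges::granges(blocks))
      expect_equal(res2$score, blocks$score)
    }
  })
})

test_that("validation rates are per-class marker-overlap fractions", {
  blocks <- fake_windows(c(0, 4000, 8000, 12000))
  blocks$class <- rep(1L, 4)
  blocks$score <- rep(0.9, 4)
  blocks$n_windows <- rep(1L, 4)
  markers <- list(Enh = gi("chr1", c(100, 4100, 8100), c(300, 4300, 8300)))
  r <- validation_rate(blocks, markers, class_names = c("Bgd", "Enh"))
  expect_equal(unname(r["Enh"]), 0.75)

  all_hit <- validation_rate(blocks[1:3], markers, c("Bgd", "Enh"))
  expect_equal(unname(all_hit["Enh"]), 1.0)

  expect_warning(
    none <- validation_rate(blocks, list(Enh = gi("chr1", 0, 1)[0]),
                            c("Bgd", "Enh")),
    "no positive markers")
  expect_equal(unname(none["Enh"]), 0)
})

test_that("genome-wide prediction recovers planted elements end to end", {
  bundle <- shared_bundle()
  scfg <- bundle$truth$cfg
  sizes <- scfg$chrom_lengths
  cfgp <- preprocess_config(split_mode = "random", n_background = 40, seed = 6)
  ds <- run_preprocess(tss = read_bed(bundle$files$tss),
                       accessibility_peaks = read_bed(bundle$files$accessibility),
                       tf_peaks = read_bed(bundle$files$tf_peaks),
                       h3k4me3_peaks = read_bed(bundle$files$h3k4me3_peaks),
                       bams = bundle$files$bams, sizes = sizes,
                       cfg = cfgp, mode = 3)
  spec <- model_spec("cnn", n_marks = length(scfg$marks), n_bins = 20,
                     n_classes = 3, mark_names = scfg$marks)
  model <- withr::with_seed(24, build_cnn(spec))
  res <- train_model(model, ds, training_config(epochs = 10, batch_size = 16,
                                                seed = 24))
  out <- predict_genome(res$model, bundle$files$bams, sizes, cfgp,
                        cutoff = 0.5)
  expect_true(length(out$blocks) >= 1)
  expect_true(all(out$blocks$class != 0))
  expect_true(all(out$blocks$score > 0.5))
  expect_equal(sum(out$blocks$n_windows), length(out$windows))

  # most planted elements should be hit by a block of the right class
  sites <- bundle$truth$sites
  enh_sites <- sites[sites$class %in% c("PE", "AE")]
  prom_sites <- sites[sites$class %in% c("PT", "AT")]
  enh_blocks <- out$blocks[out$blocks$class == 1]
  prom_blocks <- out$blocks[out$blocks$class == 2]
  expect_gte(mean(GenomicRanges::countOverlaps(enh_sites, enh_blocks) > 0), 0.8)
  expect_gte(mean(GenomicRanges::countOverlaps(prom_sites, prom_blocks) > 0), 0.8)

  # validation rates against the default positive-marker stand-ins
  markers <- default_positive_markers(
    tss = read_bed(bundle$files$tss),
    tf_peaks = read_bed(bundle$files$tf_peaks),
    accessibility_peaks = read_bed(bundle$files$accessibility),
    h3k4me3_peaks = read_bed(bundle$files$h3k4me3_peaks),
    cfg = cfgp, sizes = sizes)
  rates <- validation_rate(out$blocks, markers,
                           class_names = c("Bgd", "Enh", "Prom"))
  expect_true(all(rates >= 0 & rates <= 1))

  d <- tempfile()
  write_prediction_beds(out$blocks, c("Bgd", "Enh", "Prom"), d)
  expect_true(length(list.files(d, pattern = "^predictions_")) >= 1)
})
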