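cfg <- preprocess_config()
sizes <- c(chr1 = 1000000L, chr2 = 1000000L)

test_that("promoter definition slops TSSs and requires accessibility overlap", {
  tss <- gi("chr1", c(5000, 5000, 200000), c(5001, 5001, 200001))
  dhs <- gi("chr1", 4900, 5100)
  prom <- define_promoters(tss, dhs, cfg, sizes)
  expect_length(prom, 1)  # identical spans collapsed
  expect_equal(GenomicRanges::start(prom) - 1, 4000)
  expect_equal(GenomicRanges::end(prom), 6000)

  # TSS far from any accessible site is dropped
  far <- define_promoters(gi("chr1", 5000, 5001), gi("chr1", 50000, 50200),
                          cfg, sizes)
  expect_length(far, 0)

  # two nearby TSSs sharing a DHS stay distinct unless spans are identical
  two <- define_promoters(gi("chr1", c(5000, 5010), c(5001, 5011)), dhs,
                          cfg, sizes)
  expect_length(two, 2)

  expect_error(define_promoters(tss, dhs[0], cfg, sizes), "accessibility")
})

test_that("enhancer definition intersects DHS and subtracts promoter evidence", {
  dhs <- gi("chr1", c(99900, 300000), c(100300, 300400))
  tss <- gi("chr1", 5000, 5001)
  k4 <- gi("chr1", 299000, 301000)

  # TF peak in a DHS, far from TSS/H3K4me3: kept as a 2 kb window
  enh <- define_enhancers(gi("chr1", 100000, 100200), dhs, k4, tss, cfg, sizes)
  expect_length(enh, 1)
  expect_equal(GenomicRanges::width(enh), 2000)
  expect_equal(GenomicRanges::start(enh) - 1, 99100)  # centred on peak midpoint

  # TF peak overlapping H3K4me3 is dropped
  expect_length(define_enhancers(gi("chr1", 300000, 300200), dhs, k4, tss,
                                 cfg, sizes), 0)
  # TF peak with no DHS overlap is dropped
  expect_length(define_enhancers(gi("chr1", 500000, 500200), dhs, k4, tss,
                                 cfg, sizes), 0)
  # TF peak overlapping a slopped TSS is dropped
  expect_length(define_enhancers(gi("chr1", 5500, 5700),
                                 gi("chr1", 5400, 5800), k4, tss, cfg, sizes), 0)
})

test_that("promoter and enhancer sets are disjoint by construction", {
  withr::with_seed(8, {
    tss_pos <- sort(sample(seq(5000, 900000, by = 1000), 40))
    tf_pos <- sort(sample(seq(5000, 900000, by = 1000), 40))
  })
  tss <- gi("chr1", tss_pos, tss_pos + 1)
  tf <- gi("chr1", tf_pos - 100, tf_pos + 100)
  dhs <- gi("chr1", c(tss_pos - 50, tf_pos - 50), c(tss_pos + 50, tf_pos + 50))
  k4 <- gi("chr1", tss_pos - 500, tss_pos + 500)
  prom <- define_promoters(tss, dhs, cfg, sizes)
  enh <- define_enhancers(tf, dhs, k4, tss, cfg, sizes)
  expect_true(length(prom) > 0 && length(enh) > 0)
  expect_equal(sum(GenomicRanges::countOverlaps(enh, prom)), 0)
})

make_coverage_bam <- function(site_starts, reads_per_site, sizes,
                              n_filler = 1000) {
  # reads_per_site reads at each 2 kb site + filler reads on chr2
  chrom <- c(rep("chr1", sum(reads_per_site)),
             rep("chr2", n_filler))
  pos0 <- c(rep(site_starts + 500, reads_per_site),
            seq(1000, by = 50, length.out = n_filler))
  fixture_bam(chrom, pos0, sizes)
}

test_that("GRO-seq K-means matches the exhaustive two-partition oracle", {
  site_starts <- seq(10000, by = 4000, length.out = 100)
  sites <- gi("chr1", site_starts, site_starts + 2000)
  withr::with_seed(4, {
    reads <- c(rpois(50, 2), rpois(50, 180))  # low vs high coverage sites
  })
  bam <- make_coverage_bam(site_starts, reads, sizes)
  st <- groseq_state_kmeans(sites, bam, cfg)
  expect_s3_class(st, "state_assignment")
  expect_lt(st$centroids["poised"], st$centroids["active"])

  # oracle: the optimal 2-partition of sorted 1-D data is a threshold split;
  # enumerate all thresholds and minimize within-cluster sum of squares
  x <- log2(st$coverage + 1)
  ord <- order(x)
  best <- NULL; best_wss <- Inf
  for (cut in 1:(length(x) - 1)) {
    lo <- x[ord[1:cut]]; hi <- x[ord[(cut + 1):length(x)]]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < best_wss) { best_wss <- wss; best <- cut }
  }
  oracle_active <- logical(length(x))
  oracle_active[ord[(best + 1):length(x)]] <- TRUE
  expect_equal(st$state == "active", oracle_active, ignore_attr = TRUE)
  expect_equal(unname(which(st$state == "active")), 51:100)
})

test_that("GRO-seq K-means handles forced and degenerate cases", {
  two_starts <- c(10000, 20000)
  sites2 <- gi("chr1", two_starts, two_starts + 2000)
  bam <- make_coverage_bam(two_starts, c(1, 8), sizes)
  st <- groseq_state_kmeans(sites2, bam, cfg)
  expect_equal(as.character(st$state), c("poised", "active"))

  same <- make_coverage_bam(two_starts, c(3, 3), sizes)
  expect_error(groseq_state_kmeans(sites2, same, cfg), "degenerate coverage")
  expect_error(groseq_state_kmeans(sites2[1], bam, cfg), "at least 2")
})

test_that("label assembly follows the class schemes of each mode", {
  n_b <- 10; n_e <- 5; n_p <- 5
  starts <- seq(0, by = 4000, length.out = n_b + n_e + n_p)
  iv <- gi("chr1", starts, starts + 2000)
  bgd <- iv[1:n_b]; enh <- iv[n_b + 1:n_e]; prom <- iv[n_b + n_e + 1:n_p]
  st <- signal_tensor(array(0, c(20, 3, 20)), paste0("M", 1:3), 2000, 100)

  ds3 <- assemble_dataset(prom, enh, bgd, NULL, st, mode = 3)
  expect_equal(ds3$labels, c(rep(0, 10), rep(1, 5), rep(2, 5)))

  ds2 <- assemble_dataset(prom, enh, bgd, NULL, st, mode = 2)
  expect_equal(ds2$labels, c(rep(0, 10), rep(1, 5), rep(0, 5)))

  states <- list(
    enhancer = list(state = factor(rep("poised", 5), c("poised", "active"))),
    promoter = list(state = factor(rep("active", 5), c("poised", "active"))))
  ds5 <- assemble_dataset(prom, enh, bgd, states, st, mode = 5)
  expect_equal(sort(unique(ds5$labels)), c(0, 1, 4))
  expect_equal(ds5$labels[n_b + 1:n_e], rep(1, 5))      # PE
  expect_equal(ds5$labels[n_b + n_e + 1:n_p], rep(4, 5)) # AT

  expect_error(assemble_dataset(prom, enh, bgd[1:3], NULL, st, mode = 3),
               "regions")
  expect_error(assemble_dataset(prom, enh, bgd, NULL, st, mode = 5),
               "state")
})

test_that("chromosome split maps samples by configured lists", {
  iv <- gi(c("chr5", "chr10", "chrX"), c(0, 0, 0), c(2000, 2000, 2000))
  st <- signal_tensor(array(0, c(3, 1, 20)), "M1", 2000, 100)
  ds <- assemble_dataset(iv[0], iv[0], iv, NULL, st, mode = 3)
  split <- split_dataset(ds, cfg)$split
  expect_equal(as.character(split), c("train", "val", "test"))

  st1 <- signal_tensor(array(0, c(1, 1, 20)), "M1", 2000, 100)
  odd <- assemble_dataset(iv[0], iv[0],
                          gi("chrUn_scaffold1", 0, 2000), NULL, st1, mode = 3)
  expect_error(split_dataset(odd, cfg), "chrUn_scaffold1")
})

test_that("random split is exact to integer rounding and partitions samples", {
  ds <- toy_dataset(n_per_class = 200, n_classes = 5, n_marks = 2, seed = 2,
                    split_mode = "random")
  expect_equal(as.numeric(table(ds$split)), c(600, 200, 200))
  expect_equal(length(ds$split), 1000)
  expect_false(anyNA(ds$split))
  # deterministic under the config seed
  ds2 <- split_dataset(ds, preprocess_config(split_mode = "random", seed = 2))
  ds3 <- split_dataset(ds, preprocess_config(split_mode = "random", seed = 2))
  expect_identical(ds2$split, ds3$split)
})

test_that("dataset archives round-trip through save/load", {
  ds <- toy_dataset(n_per_class = 10, n_classes = 3, n_marks = 2, seed = 9)
  dir <- tempfile()
  save_dataset(ds, dir)
  back <- load_dataset(dir)
  expect_equal(back$labels, ds$labels)
  expect_equal(back$tensor$values, ds$tensor$values, ignore_attr = TRUE)
  expect_identical(as.character(back$split), as.character(ds$split))
  expect_equal(GenomicRanges::start(back$intervals),
               GenomicRanges::start(ds$intervals))
  expect_true(file.exists(file.path(dir, "regions.bed")))
})
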