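# Shared fixture builders. Everything is generated in code at test time;
# no binary files ship with the package.

toy_sizes <- function(n = 2, len = 20000L, names = paste0("chr", seq_len(n))) {
  stats::setNames(rep(as.integer(len), n), names)
}

gi <- function(chrom, start, end, ...) genomic_intervals(chrom, start, end, ...)

# A BAM with reads at given 0-based leftmost positions.
fixture_bam <- function(chrom, pos0, sizes, read_length = 50L,
                        prefix = tempfile()) {
  crescan:::write_toy_bam(chrom, pos0, sizes, prefix, read_length)
}

# Easy, linearly separable labeled dataset built directly in memory (no BAM
# round trip): class-specific triangular bumps on distinct marks + Poisson
# noise. Used by training/interpretation tests.
toy_dataset <- function(n_per_class = 60, n_classes = 5, n_marks = 12,
                        n_bins = 20, amp = 8, seed = 7,
                        split_mode = "random") {
  withr::with_seed(seed, {
    marks <- paste0("M", seq_len(n_marks))
    tri <- 1 - abs(seq_len(n_bins) - 0.5 - n_bins / 2) / (n_bins / 2)
    sig <- matrix(0, n_classes, n_marks)
    for (k in seq_len(n_classes - 1)) {
      mk <- ((c(k, k + 2) - 1) %% n_marks) + 1  # distinct mark pair per class
      sig[k + 1, mk] <- amp
    }
    n <- n_per_class * n_classes
    vals <- array(stats::rpois(n * n_marks * n_bins, 1), c(n, n_marks, n_bins)) * 0.5
    labels <- rep(seq_len(n_classes) - 1L, each = n_per_class)
    for (i in seq_len(n)) {
      s <- sig[labels[i] + 1, ]
      for (m in which(s > 0))
        vals[i, m, ] <- vals[i, m, ] + stats::rpois(n_bins, s[m] * tri) * 0.5
    }
    st <- signal_tensor(vals, marks, n_bins * 100L, 100L)
    chroms <- rep(rep(c(paste0("chr", 1:22), "chrX", "chrY"), length.out = n))
    starts <- seq(0, by = 4000, length.out = n)
    iv <- genomic_intervals(chroms, starts, starts + n_bins * 100L)
    ds <- structure(list(tensor = st, labels = labels, intervals = iv,
                         mode = if (n_classes == 5) 5L else 3L,
                         class_names = switch(as.character(n_classes),
                                              "2" = c("Bgd", "Enh"),
                                              "3" = c("Bgd", "Enh", "Prom"),
                                              "5" = c("Bgd", "PE", "AE", "PT", "AT")),
                         split = NULL),
                    class = "labeled_dataset")
    split_dataset(ds, preprocess_config(split_mode = split_mode, seed = seed))
  })
}

small_cnn_spec <- function(n_marks = 12, n_classes = 5,
                           mark_names = paste0("M", seq_len(n_marks))) {
  model_spec("cnn", n_marks = n_marks, n_bins = 20, n_classes = n_classes,
             mark_names = mark_names)
}

# Small synthetic bundle for preprocessing tests: 4 chromosomes, 6 core marks.
small_synth_cfg <- function(n_per = 15L, seed = 5L) {
  synthetic_config(
    chrom_lengths = stats::setNames(rep(100000L, 4), paste0("chr", 1:4)),
    n_per_class = c(Bgd = n_per, PE = n_per, AE = n_per, PT = n_per, AT = n_per),
    marks = c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac"),
    seed = seed)
}

# One shared small bundle per test run (simulated lazily, reused across files).
.shared <- new.env(parent = emptyenv())
shared_bundle <- function() {
  if (is.null(.shared$bundle)) {
    dir <- file.path(tempdir(), "crescan-shared-bundle")
    .shared$bundle <- simulate_bundle(small_synth_cfg(), dir)
  }
  .shared$bundle
}
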