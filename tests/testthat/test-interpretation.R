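test_that("top-region selection is stratified by true class", {
  withr::with_seed(31, {
    n <- 60
    labels <- rep(0:2, each = 20)
    probs <- matrix(runif(n * 3), n, 3)
  })
  idx <- select_top_regions(probs, labels, k_per_class = 5)
  expect_length(idx, 15)
  expect_equal(anyDuplicated(idx), 0)
  # each class's picks come from its own stratum and are its top-k
  for (cls in 0:2) {
    pick <- idx[cls * 5 + 1:5]
    expect_true(all(labels[pick] == cls))
    stratum <- which(labels == cls)
    expect_setequal(pick, stratum[order(-probs[stratum, cls + 1])][1:5])
  }
  # k = 1 returns the single argmax region per class
  one <- select_top_regions(probs, labels, k_per_class = 1)
  expect_equal(one[1], which(labels == 0)[which.max(probs[labels == 0, 1])])
  expect_error(select_top_regions(probs, labels, k_per_class = 40),
               "only 20")
})

test_that("first-layer activations reproduce direct convolution", {
  spec <- small_cnn_spec(4, 3, paste0("M", 1:4))
  m <- withr::with_seed(32, build_cnn(spec))
  x <- withr::with_seed(33, array(rexp(5 * 4 * 20), c(5, 4, 20)))
  act <- first_layer_activations(m, x)
  expect_equal(dim(act), c(20, 32, 5))

  # all-zero input: every position equals the filter bias
  z <- first_layer_activations(m, array(0, c(2, 4, 20)))
  conv <- m$layers[[1]]
  for (f in c(1, 10, 32))
    expect_equal(unique(as.vector(z[, f, ])), conv$b[f], tolerance = 1e-12)

  # delta kernel on one mark reproduces that mark's profile plus bias
  conv$W[] <- 0
  conv$W[1, 2, 4] <- 1  # centre tap of the 7-wide kernel, mark 2
  act2 <- first_layer_activations(m, x)
  expect_equal(act2[, 1, 3], x[3, 2, ] + conv$b[1], ignore_attr = TRUE)

  # direct convolution oracle for an arbitrary filter
  W <- withr::with_seed(34, array(rnorm(32 * 4 * 7), c(32, 4, 7)))
  conv$W <- W
  act3 <- first_layer_activations(m, x)
  xp <- array(0, c(4, 26)); xp[, 4:23] <- x[2, , ]
  manual <- sapply(1:20, function(t) sum(W[5, , ] * xp[, t:(t + 6)]) + conv$b[5])
  expect_equal(act3[, 5, 2], manual, ignore_attr = TRUE, tolerance = 1e-12)

  rnn <- withr::with_seed(35, build_rnn(model_spec("rnn", 4, 20, 3)))
  expect_error(first_layer_activations(rnn, x), "CNN")
  expect_equal(dim(first_layer_activations(rnn, x, allow_rnn = TRUE)),
               c(20, 32, 5))
})

power_iteration_v1 <- function(M, iters = 5000, tol = 1e-14) {
  A <- crossprod(M)  # regions x regions
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  for (i in seq_len(iters)) {
    v2 <- A %*% v
    v2 <- v2 / sqrt(sum(v2^2))
    if (sum(abs(v2 - v)) < tol) { v <- v2; break }
    v <- as.vector(v2)
  }
  as.vector(v)
}

test_that("SVD reduction matches a power-iteration oracle and the sign rule", {
  # exact rank-1 recovery
  u <- c(1:20) / sqrt(sum((1:20)^2))
  v <- sin(seq_len(50))
  act <- array(0, c(20, 2, 50))
  act[, 1, ] <- u %*% t(v)
  act[, 2, ] <- withr::with_seed(36, matrix(rnorm(20 * 50), 20, 50))
  red <- svd_reduce(act)
  vn <- v / sqrt(sum(v^2))
  if (vn[which.max(abs(vn))] < 0) vn <- -vn
  expect_equal(red[1, ], vn, tolerance = 1e-12)
  expect_equal(sqrt(rowSums(red^2)), c(1, 1), tolerance = 1e-12)

  # random matrices vs power iteration on M'M
  withr::with_seed(37, {
    act2 <- array(rnorm(20 * 4 * 100), c(20, 4, 100))
  })
  red2 <- svd_reduce(act2)
  for (f in 1:4) {
    o <- power_iteration_v1(matrix(act2[, f, ], 20, 100))
    cosim <- abs(sum(red2[f, ] * o))
    expect_gt(cosim, 1 - 1e-8)
    # sign convention: largest-magnitude entry is positive
    expect_gt(red2[f, which.max(abs(red2[f, ]))], 0)
  }

  # positive rescaling of one filter's activations leaves its row unchanged
  act3 <- act2
  act3[, 2, ] <- act3[, 2, ] * 7.5
  expect_equal(svd_reduce(act3)[2, ], red2[2, ], tolerance = 1e-10)

  # all-zero filter yields a zero row with a warning
  act4 <- act2
  act4[, 3, ] <- 0
  expect_warning(red4 <- svd_reduce(act4), "all-zero")
  expect_equal(red4[3, ], rep(0, 100))
})

test_that("filter clustering orders filters and merges duplicates first", {
  withr::with_seed(38, {
    base <- matrix(rnorm(32 * 500), 32, 500)
  })
  base[2, ] <- base[1, ] + 1e-9 * rnorm(500)  # near-duplicate pair
  cl <- cluster_filters(base)
  expect_setequal(cl$order, 1:32)
  first_merge <- cl$tree$merge[1, ]
  expect_setequal(-first_merge, c(1, 2))

  # brute-force nearest-pair agglomeration agrees on the first two merges
  withr::with_seed(39, {
    m4 <- matrix(rnorm(4 * 30), 4, 30)
  })
  m4[2, ] <- m4[1, ] + 1e-6 * rnorm(30)
  m4[4, ] <- m4[3, ] + 1e-6 * rnorm(30)
  cl4 <- cluster_filters(m4)
  d <- 1 - cor(t(m4))
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  dist_of <- sapply(pairs, function(p) d[p[1], p[2]])
  expect_setequal(-cl4$tree$merge[1, ], pairs[[which.min(dist_of)]])
  merged2 <- cl4$tree$merge[2, ]
  expect_setequal(-merged2[merged2 < 0], setdiff(1:4, pairs[[which.min(dist_of)]]))

  # constant rows are tolerated via the max-distance rule
  m4[1, ] <- 5
  expect_silent(cluster_filters(m4))
})

test_that("weight profiles slice the first-layer kernels by mark", {
  spec <- small_cnn_spec(12, 5, c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me2",
                                  "H3K4me3", "H3K9ac", paste0("X", 1:6)))
  m <- withr::with_seed(40, build_cnn(spec))
  six <- c("H3K27ac", "H3K27me3", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac")
  wp <- weight_profiles(m, c(15, 12, 20, 8), six)
  expect_length(wp, 4)
  expect_equal(dim(wp$filter15), c(7, 6))
  all12 <- weight_profiles(m, 1, spec$mark_names)[[1]]
  expect_equal(dim(all12), c(7, 12))
  conv <- m$layers[[1]]
  expect_equal(unname(all12[, 3]), conv$W[1, 3, ])

  # profiles survive a checkpoint round trip
  dir <- tempfile()
  save_model(m, dir)
  expect_equal(weight_profiles(load_model(dir), 8, six), wp["filter08"],
               ignore_attr = TRUE)

  expect_error(weight_profiles(m, 1, "H3K999"), "unknown mark")
  expect_error(weight_profiles(m, 99, six), "filter ids")
})

test_that("the interpretation workflow yields the documented shapes", {
  ds <- toy_dataset(n_per_class = 40, n_classes = 5, n_marks = 6, seed = 41)
  m <- withr::with_seed(42, build_cnn(small_cnn_spec(6, 5, paste0("M", 1:6))))
  res <- train_model(m, ds, training_config(epochs = 2, batch_size = 32, seed = 42))
  out_dir <- tempfile()
  out <- interpret_filters(res$model, ds, split = "test", k_per_class = 4,
                           out_dir = out_dir)
  expect_length(out$region_idx, 20)
  expect_equal(dim(out$activations), c(20, 32, 20))
  expect_equal(dim(out$reduced), c(32, 20))
  expect_setequal(out$clustering$order, 1:32)
  expect_true(file.exists(file.path(out_dir, "reduced_activations.tsv")))
  expect_true(file.exists(file.path(out_dir, "filter_leaf_order.txt")))
})
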