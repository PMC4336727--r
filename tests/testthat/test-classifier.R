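test_that("chi-square kernel matches direct arithmetic", {
  x <- c(0.5, 0.5)
  expect_equal(chi2_kernel(x, x), 1)
  expect_equal(chi2_kernel(c(1, 0), c(0, 1)), 0)
  expect_equal(chi2_kernel(c(0.5, 0.5), c(0.25, 0.75)),
               2 * 0.125 / 0.75 + 2 * 0.375 / 1.25)
  expect_error(chi2_kernel(c(-1, 1), c(1, 1)), "nonnegative")
  expect_error(chi2_kernel(c(1, 1), c(1, 1, 1)), "equal length")
  # symmetry and the (|x|_1 + |y|_1)/2 bound on random histograms
  set.seed(1)
  for (i in 1:20) {
    a <- runif(15); b <- runif(15)
    expect_equal(chi2_kernel(a, b), chi2_kernel(b, a))
    expect_lte(chi2_kernel(a, b), (sum(a) + sum(b)) / 2 + 1e-12)
  }
})

test_that("the homogeneous kernel map approximates the chi-square kernel", {
  expect_equal(kernel_map(numeric(600), n = 2, L = 0.5), numeric(3000))
  expect_length(kernel_map(runif(600), n = 2, L = 0.5), 3000)
  # histograms shaped like the pipeline's own window encodings: ~300
  # quantized descriptors spread over 600 visual words, L1-normalized
  rand_hist <- function() {
    w <- sample.int(600, 300, replace = TRUE)
    tabulate(w, 600) / 300
  }
  errs <- sapply(1:3, function(n) {
    set.seed(99)
    max(replicate(100, {
      x <- rand_hist(); y <- rand_hist()
      abs(sum(kernel_map(x, n, 0.5) * kernel_map(y, n, 0.5)) -
            chi2_kernel(x, y))
    }))
  })
  expect_lte(errs[2], 0.01)
  expect_true(all(diff(errs) < 0))
})

test_that("a linearly separable toy problem is learned perfectly", {
  set.seed(5)
  k <- 12
  mk <- function(bins) t(replicate(15, {
    h <- numeric(k); h[bins] <- runif(length(bins)); h / sum(h)
  }))
  H <- rbind(mk(1:4), mk(7:10))
  labels <- rep(c(1L, -1L), each = 15)
  model <- anthesis:::fit_mapped_svm(H, labels, C = 10, n = 2, L = 0.5, k = k,
                                     window_px = 140, grid = grid_spec(),
                                     seed = 1)
  pred <- predict_flowering(H, model)
  expect_equal(pred$label, labels)
  # determinism
  model2 <- anthesis:::fit_mapped_svm(H, labels, C = 10, n = 2, L = 0.5,
                                      k = k, window_px = 140,
                                      grid = grid_spec(), seed = 1)
  expect_identical(model$weights, model2$weights)
  expect_identical(model$bias, model2$bias)
})

test_that("training rejects degenerate inputs", {
  pipe <- tiny_pipeline()
  one_class <- pipe$db[pipe$db$label == 1, ]
  expect_error(train_flower_model(one_class, pipe$codebook),
               "both flowering")
  expect_error(train_flower_model(pipe$db[0, ], pipe$codebook), "no training")
  expect_error(train_flower_model(pipe$db, pipe$codebook, C = -1), "C")
})

test_that("prediction is the sign of the mapped linear score", {
  m <- stub_model(k = 8, bias = 0.5)
  p <- predict_flowering(numeric(8), m)
  expect_equal(p$score, 0.5) # zero histogram maps to zero: score = bias
  expect_equal(p$label, 1L)
  # score exactly 0 is classified background
  m0 <- stub_model(k = 8, bias = 0)
  expect_equal(predict_flowering(numeric(8), m0)$label, -1L)
  expect_error(predict_flowering(numeric(9), m), "does not match")
})

test_that("confusion-matrix metrics match their definitions", {
  m <- evaluate_metrics(tp = 59, fp = 1, tn = 99, fn = 41)
  expect_equal(m$tp_rate, 0.59)
  expect_equal(m$tn_rate, 0.99)
  expect_equal(m$accuracy, 0.79)
  perfect <- evaluate_metrics(tp = 10, fp = 0, tn = 20, fn = 0)
  expect_equal(unlist(perfect), c(accuracy = 1, tp_rate = 1, tn_rate = 1))
  # undefined rates are NA, not 0, and accuracy is still computed
  deg <- evaluate_metrics(tp = 0, fp = 2, tn = 8, fn = 0)
  expect_true(is.na(deg$tp_rate))
  expect_equal(deg$accuracy, 0.8)
  expect_error(evaluate_metrics(0, 0, 0, 0), "empty")
  expect_error(evaluate_metrics(-1, 0, 1, 0), "nonnegative")
})

test_that("models persist to disk and load consistently", {
  pipe <- tiny_pipeline()
  f <- withr::local_tempfile(fileext = ".txt")
  write_model(pipe$model, f)
  back <- read_model(f)
  expect_equal(back$weights, pipe$model$weights, tolerance = 1e-15)
  expect_equal(back$bias, pipe$model$bias, tolerance = 1e-15)
  expect_equal(back$k, pipe$model$k)
  expect_equal(back$window_px, pipe$model$window_px)
  # tampered weight dimension is caught on load
  lines <- readLines(f)
  writeLines(lines[-2], f)
  expect_error(read_model(f), "inconsistent")
})
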