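test_that("k-means recovers analytic optima", {
  set.seed(10)
  X <- matrix(runif(40 * 128), 40, 128)
  # k = 1: the arithmetic mean
  cb1 <- train_codebook(X, k = 1, n_restarts = 3, seed = 1)
  expect_equal(as.numeric(cb1$centers), colMeans(X), tolerance = 1e-12)
  # k = n distinct points: zero inertia, centers a permutation of inputs
  Xs <- X[1:8, ]
  cbn <- train_codebook(Xs, k = 8, n_restarts = 3, seed = 2)
  expect_equal(cbn$inertia, 0)
  perm <- apply(cbn$centers, 1, function(ctr)
    which(apply(Xs, 1, function(x) isTRUE(all.equal(x, ctr, tolerance = 1e-12)))))
  expect_setequal(perm, 1:8)
})

test_that("two well-separated clouds yield the cloud means (Lloyd oracle)", {
  set.seed(11)
  a <- matrix(runif(30 * 128, 0, 0.1), 30, 128)
  b <- matrix(runif(25 * 128, 0, 0.1), 25, 128)
  b[, 1] <- b[, 1] + 50 # gap >> spread
  X <- rbind(a, b)
  cb <- train_codebook(X, k = 2, n_restarts = 5, seed = 3)
  means <- rbind(colMeans(a), colMeans(b))
  ord <- order(cb$centers[, 1])
  expect_equal(cb$centers[ord, ], means, tolerance = 1e-10, ignore_attr = TRUE)
  # and cross-check against stats::kmeans from the same initial centers
  init <- withr::with_seed(3, sample.int(nrow(X), 2))
  km <- stats::kmeans(X, centers = X[init, ], iter.max = 100,
                      algorithm = "Lloyd")
  expect_equal(sort(unname(km$centers[, 1])), sort(cb$centers[, 1]),
               tolerance = 1e-8)
})

test_that("codebook training is reproducible and picks the best restart", {
  set.seed(12)
  X <- matrix(runif(300 * 128), 300, 128)
  cb1 <- train_codebook(X, k = 15, n_restarts = 4, seed = 7)
  cb2 <- train_codebook(X, k = 15, n_restarts = 4, seed = 7)
  expect_identical(cb1$centers, cb2$centers)
  # the first restart of the multi-restart run equals a 1-restart run, so
  # the returned inertia can only be better
  cb_first <- train_codebook(X, k = 15, n_restarts = 1, seed = 7)
  expect_lte(cb1$inertia, cb_first$inertia)
  expect_error(train_codebook(X[1:5, ], k = 10, seed = 1), "at least")
})

test_that("word assignment matches exhaustive nearest-neighbor search", {
  cb <- stub_codebook(10, seed = 21)
  # exact center -> its own index
  expect_equal(assign_word(cb$centers[3, ], cb), 3L)
  # equidistant descriptor between centers 1 and 4 -> lowest index
  cb2 <- cb
  cb2$centers <- matrix(100, 10, 128)
  cb2$centers[1, ] <- 0
  cb2$centers[4, ] <- 2 # constant rows; midpoint is exactly equidistant
  expect_equal(assign_word(rep(1, 128), cb2), 1L)
  # 50 random descriptors vs brute-force oracle
  set.seed(22)
  D <- matrix(runif(50 * 128), 50, 128)
  oracle <- apply(D, 1, function(x)
    which.min(colSums((t(cb$centers) - x)^2)))
  expect_equal(assign_word(D, cb), as.integer(oracle))
  expect_error(assign_word(runif(64), cb), "dimension")
})

test_that("BoVW histograms count every non-flat descriptor once", {
  cb <- stub_codebook(12, seed = 31)
  set.seed(32)
  D <- matrix(runif(80 * 128), 80, 128)
  h <- bovw_histogram(D, cb, normalize = FALSE)
  expect_equal(sum(h), 80)
  expect_true(all(h >= 0))
  # flat (zero) descriptors are skipped
  Dz <- rbind(D, matrix(0, 5, 128))
  expect_equal(sum(bovw_histogram(Dz, cb, normalize = FALSE)), 80)
  # all descriptors identical to one center -> one-hot
  Dj <- matrix(rep(cb$centers[7, ], 10), 10, 128, byrow = TRUE)
  hj <- bovw_histogram(Dj, cb, normalize = FALSE)
  expect_equal(which(hj > 0), 7L)
  expect_equal(hj[7], 10)
  # normalization contract
  hn <- bovw_histogram(D, cb, normalize = TRUE)
  expect_equal(sum(hn), 1, tolerance = 1e-9)
  expect_equal(sum(bovw_histogram(matrix(0, 0, 128), cb)), 0)
})

test_that("histograms are equivariant under codebook relabeling", {
  cb <- stub_codebook(9, seed = 41)
  set.seed(42)
  D <- matrix(runif(60 * 128), 60, 128)
  h <- bovw_histogram(D, cb, normalize = FALSE)
  perm <- withr::with_seed(43, sample(9))
  cbp <- cb
  cbp$centers <- cb$centers[perm, ]
  hp <- bovw_histogram(D, cbp, normalize = FALSE)
  expect_equal(hp, h[perm], ignore_attr = TRUE)
})

test_that("codebooks persist to CSV and back", {
  cb <- stub_codebook(6, seed = 51)
  cb$inertia <- 12.5
  f <- withr::local_tempfile(fileext = ".csv")
  write_codebook(cb, f)
  back <- read_codebook(f)
  expect_equal(back$centers, cb$centers, tolerance = 1e-15)
  expect_equal(back$k, 6L)
  expect_equal(back$inertia, 12.5)
})
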