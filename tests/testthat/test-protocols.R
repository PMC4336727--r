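# a short evaluation series with contrast in FPN: frames around the peak
# plus quiet frames, rendered at the down-scaled test canopy
eval_series <- function(seed = 17) {
  ser <- simulate_series(days = 1, peak_time = 12, amplitude = 8,
                         spec = tiny_spec(), seed = seed)
  keep <- ser[c(1, 20, 44, 46, 48, 50, 52, 75, 97), ]
  stopifnot(inherits(keep, "canopy_series"))
  keep
}

test_that("the training-size experiment reports seeded, flagged replicates", {
  pipe <- tiny_pipeline()
  ser <- eval_series()
  rep1 <- training_size_experiment(pipe$db, sizes = c(3, 6), replicates = 2,
                                   eval_series = ser, seed = 5,
                                   codebook = pipe$codebook,
                                   window_px = 140)
  rep2 <- training_size_experiment(pipe$db, sizes = c(3, 6), replicates = 2,
                                   eval_series = ser, seed = 5,
                                   codebook = pipe$codebook,
                                   window_px = 140)
  expect_identical(rep1$rows, rep2$rows)
  expect_equal(nrow(rep1$rows), 4)
  metrics <- rep1$rows[, c("accuracy", "tp_rate", "tn_rate")]
  expect_true(all(as.matrix(metrics) >= 0 & as.matrix(metrics) <= 1,
                  na.rm = TRUE))
  expect_true(all(abs(rep1$rows$r_fpn_fcbn) <= 1, na.rm = TRUE))
  # one best replicate per size (none when every correlation is undefined),
  # attaining the max correlation
  by_size <- split(rep1$rows, rep1$rows$condition)
  for (grp in by_size) {
    if (all(is.na(grp$r_fpn_fcbn))) {
      expect_equal(sum(grp$best), 0)
    } else {
      expect_equal(sum(grp$best), 1)
      expect_equal(grp$r_fpn_fcbn[grp$best],
                   max(grp$r_fpn_fcbn, na.rm = TRUE))
    }
  }
  expect_error(
    training_size_experiment(pipe$db, sizes = 999, replicates = 1,
                             seed = 1, codebook = pipe$codebook),
    "exceeds"
  )
  # summary has one row per condition
  expect_equal(sort(rep1$summary$condition), c(3, 6))
})

test_that("held-out and in-sample patch evaluation are both available", {
  pipe <- tiny_pipeline()
  ins <- training_size_experiment(pipe$db, sizes = 6, replicates = 3,
                                  eval_series = NULL, seed = 5,
                                  codebook = pipe$codebook, in_sample = TRUE)
  held <- training_size_experiment(pipe$db, sizes = 6, replicates = 3,
                                   eval_series = NULL, seed = 5,
                                   codebook = pipe$codebook)
  expect_true(all(held$rows$accuracy >= 0 & held$rows$accuracy <= 1))
  # fitting and scoring the same patches cannot do worse on average than
  # scoring the held-out remainder
  expect_gte(mean(ins$rows$accuracy), mean(held$rows$accuracy))
})

test_that("the resolution experiment scans each factor with a fixed window", {
  pipe <- tiny_pipeline()
  ser <- eval_series(seed = 19)
  rep <- resolution_experiment(ser, pipe$model, pipe$codebook,
                               factors = c(1, 0.75, 0.5))
  expect_equal(nrow(rep$rows), 3)
  expect_true(all(rep$rows$feasible))
  # factor 1 reproduces the plain detection baseline exactly
  base <- detect_series(ser, pipe$model, pipe$codebook)
  cors <- correlate_counts(base)
  expect_equal(rep$rows$r_fpn_fcbn[rep$rows$condition == 1],
               cors$r[cors$metric_pair == "fpn_fcbn"])
  # a factor that shrinks the image below one window is infeasible, not fatal
  rep2 <- resolution_experiment(ser, pipe$model, pipe$codebook,
                                factors = c(1, 0.4))
  expect_false(rep2$rows$feasible[rep2$rows$condition == 0.4])
  expect_true(is.na(rep2$rows$r_fpn_fcbn[rep2$rows$condition == 0.4]))
})

test_that("experiment reports expose tidy rows, summaries and CSV output", {
  pipe <- tiny_pipeline()
  rep <- training_size_experiment(pipe$db, sizes = c(3, 6), replicates = 2,
                                  eval_series = NULL, seed = 5,
                                  codebook = pipe$codebook)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(glance(rep)), 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep, f, config = list(), seed = 5)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.csv$", "_summary.csv", f)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
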