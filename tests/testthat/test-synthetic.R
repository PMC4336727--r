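test_that("rendering is seed-deterministic with ground truth by construction", {
  spec <- tiny_spec(seed = 7, n_flowering = 5)
  rc1 <- render_canopy(spec)
  expect_equal(rc1$ground_truth$fpn, 5)
  expect_equal(nrow(rc1$ground_truth$flowering_regions), 5)
  rg <- rc1$ground_truth$flowering_regions
  expect_true(all(rg$x_min >= 0 & rg$x_max <= spec$width &
                    rg$y_min >= 0 & rg$y_max <= spec$height))
  rc2 <- render_canopy(spec)
  expect_identical(rc1$image$pixels, rc2$image$pixels)
  # placement-only replay gives the same ground truth without painting
  expect_equal(plan_canopy(spec)$flowering_regions, rg)
  # unplaceable flowering regions are an error
  expect_error(render_canopy(canopy_spec(width = 60, height = 60,
                                         n_flowering = 1, seed = 1)),
               "placed")
})

test_that("flowering regions carry more local texture variance than background", {
  rc <- render_canopy(canopy_spec(seed = 7))
  lum <- rc$image$luminance
  rg <- rc$ground_truth$flowering_regions
  local_var <- function(cx, cy) {
    var(as.numeric(lum[(cy - 7):(cy + 7), (cx - 7):(cx + 7)]))
  }
  inside <- vapply(seq_len(nrow(rg)), function(i)
    local_var(round((rg$x_min[i] + rg$x_max[i]) / 2),
              round((rg$y_min[i] + rg$y_max[i]) / 2)), numeric(1))
  # background probes away from every flowering region
  set.seed(1)
  outside <- c()
  while (length(outside) < 40) {
    cx <- sample(30:(ncol(lum) - 30), 1)
    cy <- sample(30:(nrow(lum) - 30), 1)
    clear <- all(cx < rg$x_min - 15 | cx > rg$x_max + 15 |
                   cy < rg$y_min - 15 | cy > rg$y_max + 15)
    if (clear) outside <- c(outside, local_var(cx, cy))
  }
  expect_gt(mean(inside), mean(outside))
})

test_that("patch sampling honors counts, labels and overlap constraints", {
  rc <- render_canopy(tiny_spec(seed = 11, n_flowering = 5))
  db <- sample_patches(rc$image, rc$ground_truth, 12, 9, seed = 3)
  expect_equal(sum(db$label == 1), 12)
  expect_equal(sum(db$label == -1), 9)
  rg <- rc$ground_truth$flowering_regions
  overlap <- function(p) {
    ox <- pmax(0, pmin(rg$x_max, p$x_max) - pmax(rg$x_min, p$x_min))
    oy <- pmax(0, pmin(rg$y_max, p$y_max) - pmax(rg$y_min, p$y_min))
    ox * oy
  }
  area <- (rg$x_max - rg$x_min) * (rg$y_max - rg$y_min)
  for (i in which(db$label == 1))
    expect_true(any(overlap(db[i, ]) >= 0.3 * area))
  for (i in which(db$label == -1))
    expect_true(all(overlap(db[i, ]) == 0))
  # patch images match their recorded rectangles
  expect_equal(dim(db$patch[[1]]$pixels)[2], db$x_max[1] - db$x_min[1])
  # positives without ground truth are impossible
  empty_gt <- structure(list(flowering_regions =
                               rc$ground_truth$flowering_regions[0, ],
                             fpn = 0L), class = "ground_truth")
  expect_error(sample_patches(rc$image, empty_gt, 1, 1, seed = 1),
               "no flowering regions")
  db2 <- sample_patches(rc$image, rc$ground_truth, 12, 9, seed = 3)
  expect_identical(db$x_min, db2$x_min)
})

test_that("simulated series follow the diurnal Poisson-Gaussian model", {
  spec <- tiny_spec(seed = 1)
  ser <- simulate_series(days = 1, peak_time = 12, amplitude = 12,
                         spec = spec, seed = 5)
  expect_equal(nrow(ser), 97) # 8 h at 5-min cadence, inclusive
  expect_equal(format(min(ser$timestamp), "%H:%M"), "08:00")
  expect_equal(format(max(ser$timestamp), "%H:%M"), "16:00")
  expect_equal(max(ser$rate), 12)
  # fpn equals the planned flowering count of the deferred image
  i <- which.max(ser$fpn)
  expect_equal(ser$image_spec[[i]]$n_flowering, ser$fpn[i])
  expect_equal(plan_canopy(ser$image_spec[[i]])$fpn, ser$fpn[i])
  ser2 <- simulate_series(days = 1, peak_time = 12, amplitude = 12,
                          spec = spec, seed = 5)
  expect_identical(ser$fpn, ser2$fpn)
  # multi-day with per-day peaks
  ser3 <- simulate_series(days = 3, peak_time = c(12, 12, 15),
                          spec = spec, seed = 6)
  expect_equal(nrow(ser3), 291)
  expect_equal(length(unique(ser3$date)), 3)
})

test_that("the mean simulated curve peaks at the configured time", {
  spec <- tiny_spec(seed = 1)
  curves <- sapply(1:20, function(s) {
    simulate_series(days = 1, peak_time = 12, amplitude = 12,
                    spec = spec, seed = 100 + s)$fpn
  })
  mean_curve <- rowMeans(curves)
  tod <- seq(8 * 60, 16 * 60, by = 5)
  peak_minute <- tod[which.max(mean_curve)]
  expect_lte(abs(peak_minute - 12 * 60), 15)
  # mean count at the peak instant approximates the amplitude
  expect_lt(abs(mean(curves[which(tod == 720), ]) - 12), 2.5)
})

test_that("series fixtures are written in the shared file dialects", {
  spec <- canopy_spec(width = 200, height = 180, n_flowering = 1,
                      flowering_size_range = c(40, 50), seed = 2)
  ser <- simulate_series(days = 1, peak_time = 12, amplitude = 2,
                         width_minutes = 240, spec = spec, seed = 7)
  ser <- ser[1:4, ]
  class(ser) <- c("canopy_series", class(tibble::tibble()))
  dir <- withr::local_tempdir()
  write_series_fixtures(ser, dir)
  pngs <- list.files(dir, pattern = "^canopy_.*\\.png$")
  expect_length(pngs, 4)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  expect_equal(ann$fpn, ser$fpn)
  expect_equal(ann$timestamp, ser$timestamp)
  img <- load_image(file.path(dir, pngs[1]))
  expect_equal(img$timestamp, ser$timestamp[1])
})
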