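test_that("sliding windows tile the image without overlap, partial tiles dropped", {
  w <- slide_windows(5184, 3456, 140)
  expect_equal(nrow(w), 37 * 24)
  expect_equal(max(w$col) + 1, 37)
  expect_equal(max(w$row) + 1, 24)
  expect_equal(nrow(slide_windows(2001, 1301, 140)), 14 * 9)
  expect_equal(nrow(slide_windows(150, 150, 200)), 0)
  # a 50%-resized default canopy leaves a 5 x 4 block grid
  expect_equal(nrow(slide_windows(700, 560, 140)), 20)
  # half-open pixel bounds
  expect_equal(w$x_max[1] - w$x_min[1], 140)
})

test_that("degenerate models give all-true / all-false block maps", {
  cb <- stub_codebook(8, seed = 1)
  img <- canopy_image(array(runif(560 * 420 * 3, 0, 255), dim = c(420, 560, 3)))
  bm_on <- classify_blocks(img, stub_model(8, bias = 1), cb)
  expect_equal(dim(bm_on$verdicts), c(3, 4))
  expect_true(all(bm_on$verdicts))
  expect_equal(summarize_detection(bm_on)$fbn, 12)
  bm_off <- classify_blocks(img, stub_model(8, bias = -1), cb)
  expect_false(any(bm_off$verdicts))
  # image smaller than one window -> empty map, not an error
  tiny <- canopy_image(array(0, dim = c(100, 100, 3)))
  expect_equal(dim(classify_blocks(tiny, stub_model(8, 1), cb)$verdicts),
               c(0, 0))
})

test_that("block verdicts equal an independent per-window recomputation", {
  pipe <- tiny_pipeline()
  rc <- render_canopy(tiny_spec(seed = 7))
  bm <- classify_blocks(rc$image, pipe$model, pipe$codebook)
  # oracle: global dense features, then an explicit histogram + prediction
  # per window over the window's own grid points
  dset <- dense_multiscale_sift(rc$image$luminance, pipe$model$grid)
  nr <- length(dset$radii)
  px <- rep(dset$points$x, each = nr)
  py <- rep(dset$points$y, each = nr)
  wpx <- pipe$model$window_px
  for (row in seq_len(bm$n_rows) - 1) {
    for (col in seq_len(bm$n_cols) - 1) {
      sel <- px >= col * wpx & px < (col + 1) * wpx &
        py >= row * wpx & py < (row + 1) * wpx
      D <- dset$descriptors[sel, , drop = FALSE]
      h <- bovw_histogram(D, pipe$codebook, normalize = TRUE)
      verdict <- if (sum(h) == 0) FALSE else
        predict_flowering(h, pipe$model)$label == 1L
      expect_identical(bm$verdicts[row + 1, col + 1], verdict)
    }
  }
})

test_that("connected regions match brute-force flood fill on all 3x3 maps", {
  for (code in 0:511) {
    v <- matrix(as.logical(bitwAnd(code, 2^(0:8))), 3, 3)
    for (conn in c(4, 8)) {
      got <- connected_regions(v, conn)
      want <- flood_fill_oracle(v, conn)
      # compare as unordered sets of block-index sets
      canon <- function(l) sort(vapply(l, function(m)
        paste(m[, 1], m[, 2], sep = ",", collapse = ";"), character(1)))
      expect_identical(canon(got), canon(want))
    }
  }
  # diagonal adjacency differs between the two connectivities
  v <- matrix(FALSE, 2, 2); v[1, 1] <- v[2, 2] <- TRUE
  expect_length(connected_regions(v, 8), 1)
  expect_length(connected_regions(v, 4), 2)
  expect_error(connected_regions(v, 6), "connectivity")
})

test_that("detection summaries expose FBN, FCBN and pixel bounding boxes", {
  v <- matrix(FALSE, 5, 6)
  expect_equal(summarize_detection(block_map(v))$fcbn, 0)
  v[3, 4] <- TRUE # block row 2, col 3 (0-based)
  d1 <- summarize_detection(block_map(v, window_px = 140))
  expect_equal(d1$fbn, 1)
  expect_equal(unlist(d1$regions[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 420, y_min = 280, x_max = 560, y_max = 420))
  # L-shaped triple: one region spanning a 2 x 2 block box
  v2 <- matrix(FALSE, 4, 4)
  v2[2, 2] <- v2[3, 2] <- v2[3, 3] <- TRUE
  d2 <- summarize_detection(block_map(v2, window_px = 100))
  expect_equal(d2$fbn, 3)
  expect_equal(d2$fcbn, 1)
  expect_equal(unlist(d2$regions[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 100, y_min = 100, x_max = 300, y_max = 300))
})

test_that("fcbn <= fbn, with equality iff no two true blocks are adjacent", {
  set.seed(8)
  for (i in 1:25) {
    v <- matrix(runif(48) < 0.3, 6, 8)
    d <- summarize_detection(block_map(v))
    expect_lte(d$fcbn, d$fbn)
    comps <- connected_regions(v, 8)
    any_adjacent <- any(vapply(comps, nrow, integer(1)) > 1)
    expect_identical(d$fcbn == d$fbn, !any_adjacent)
  }
})

test_that("flipping a block false->true merges exactly its adjacent components", {
  set.seed(9)
  for (i in 1:20) {
    v <- matrix(runif(30) < 0.35, 5, 6)
    off <- which(!v, arr.ind = TRUE)
    if (nrow(off) == 0) next
    cell <- off[sample(nrow(off), 1), ]
    comps <- connected_regions(v, 8)
    adjacent <- sum(vapply(comps, function(m) {
      any(abs(m[, "row"] - (cell[1] - 1)) <= 1 &
            abs(m[, "col"] - (cell[2] - 1)) <= 1)
    }, logical(1)))
    v2 <- v
    v2[cell[1], cell[2]] <- TRUE
    d <- summarize_detection(block_map(v))
    d2 <- summarize_detection(block_map(v2))
    expect_equal(d2$fbn, d$fbn + 1)
    expect_equal(d2$fcbn, d$fcbn + 1 - adjacent)
  }
})

test_that("overlay PNGs are written with tinted blocks and outlined regions", {
  pipe <- tiny_pipeline()
  rc <- render_canopy(tiny_spec(seed = 13))
  det <- detect_image(rc$image, pipe$model, pipe$codebook)
  f <- withr::local_tempfile(fileext = ".png")
  write_overlay(rc$image, det, f)
  expect_true(file.exists(f))
  overlay <- png::readPNG(f)
  expect_equal(dim(overlay)[1:2], dim(rc$image$pixels)[1:2])
})
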