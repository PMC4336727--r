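#' Synthetic canopy specification
#'
#' Parameters of the seeded canopy renderer. The renderer emulates the
#' statistical structure the detector exploits: a green/brown field of
#' randomly oriented elongated strokes (leaves), dull curvilinear arcs
#' (non-flowering panicles), and flowering panicles drawn as arcs overlaid
#' with dense bright 1-3 px speckles (extruded anthers). The flowering cue
#' is deliberately textural, not purely chromatic, since the detector is
#' texture-based.
#'
#' @param width,height Canvas size in pixels. Default 1400 x 1120 = 10 x 8
#'   sliding-window blocks of 140 px.
#' @param n_flowering Number of flowering panicles to place.
#' @param n_nonflowering_panicles Number of non-flowering panicle arcs.
#' @param background_stroke_density Background strokes per 1000 px
#'   (default 2).
#' @param anther_speckle_density Speckles per 1000 px^2 of flowering-region
#'   area (default 20, the dense anther cover of an actively flowering
#'   panicle).
#' @param flowering_size_range Side range (px) of a flowering panicle's
#'   bounding region, drawn uniformly.
#' @param illumination_gain Global multiplicative gain (default 1).
#' @param seed Integer seed; output is bitwise-reproducible per seed.
#' @return A `canopy_spec` list.
#' @export
canopy_spec <- function(width = 1400, height = 1120, n_flowering = 8,
                        n_nonflowering_panicles = 40,
                        background_stroke_density = 2,
                        anther_speckle_density = 20,
                        flowering_size_range = c(50, 90),
                        illumination_gain = 1, seed = 1) {
  stopifnot(width >= 1, height >= 1, n_flowering >= 0,
            n_nonflowering_panicles >= 0, background_stroke_density > 0,
            anther_speckle_density > 0, illumination_gain > 0,
            length(flowering_size_range) == 2,
            flowering_size_range[1] <= flowering_size_range[2])
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_flowering = as.integer(n_flowering),
         n_nonflowering_panicles = as.integer(n_nonflowering_panicles),
         background_stroke_density = background_stroke_density,
         anther_speckle_density = anther_speckle_density,
         flowering_size_range = as.integer(flowering_size_range),
         illumination_gain = illumination_gain, seed = as.integer(seed)),
    class = "canopy_spec"
  )
}

# Placement phase: drawn FIRST under the spec seed, so ground truth can be
# computed without painting (deferred rendering of large series).
draw_placements <- function(spec) {
  lo <- spec$flowering_size_range[1]
  hi <- spec$flowering_size_range[2]
  if (spec$n_flowering > 0 && (hi >= spec$width || hi >= spec$height))
    abort("flowering regions cannot be placed within the image bounds")
  n <- spec$n_flowering
  if (n == 0) {
    return(tibble::tibble(region_id = integer(), x_min = integer(),
                          y_min = integer(), x_max = integer(),
                          y_max = integer()))
  }
  rw <- as.integer(round(runif(n, lo, hi)))
  rh <- as.integer(round(runif(n, lo, hi)))
  x0 <- y0 <- integer(n)
  placed <- matrix(0L, 0, 4)
  for (i in seq_len(n)) {
    for (try in 1:50) {
      xi <- as.integer(floor(runif(1, 0, spec$width - rw[i])))
      yi <- as.integer(floor(runif(1, 0, spec$height - rh[i])))
      if (nrow(placed) == 0) break
      ox <- pmax(0, pmin(placed[, 3], xi + rw[i]) - pmax(placed[, 1], xi))
      oy <- pmax(0, pmin(placed[, 4], yi + rh[i]) - pmax(placed[, 2], yi))
      if (all(ox * oy <= 0.3 * rw[i] * rh[i])) break
    }
    x0[i] <- xi; y0[i] <- yi
    placed <- rbind(placed, c(xi, yi, xi + rw[i], yi + rh[i]))
  }
  tibble::tibble(
    region_id = seq_len(n),
    x_min = x0, y_min = y0,
    x_max = x0 + rw, y_max = y0 + rh
  )
}

#' Ground truth of a canopy spec without painting pixels
#'
#' Replays only the placement phase of [render_canopy()] (which draws its
#' placement randomness first), so the flowering-region rectangles and FPN
#' of a spec can be obtained cheaply and exactly.
#'
#' @param spec A [canopy_spec()].
#' @return A `ground_truth` list: `flowering_regions` tibble and `fpn`.
#' @export
plan_canopy <- function(spec) {
  stopifnot(inherits(spec, "canopy_spec"))
  regions <- run_seeded(spec$seed, draw_placements(spec))
  structure(list(flowering_regions = regions, fpn = nrow(regions)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> fpn = %d flowering panicles\n", x$fpn))
  invisible(x)
}

# A paint layer: point coordinates (0-based) with per-point RGB. Layers are
# accumulated and painted once, in order (later layers overwrite earlier).
paint_layer <- function(x, y, r, g, b) {
  m <- max(length(x), length(y))
  list(x = x, y = y, r = rep_len(r, m), g = rep_len(g, m), b = rep_len(b, m))
}

apply_layers <- function(arr, layers) {
  x <- round(unlist(lapply(layers, `[[`, "x")))
  y <- round(unlist(lapply(layers, `[[`, "y")))
  r <- unlist(lapply(layers, `[[`, "r"))
  g <- unlist(lapply(layers, `[[`, "g"))
  b <- unlist(lapply(layers, `[[`, "b"))
  H <- dim(arr)[1]; W <- dim(arr)[2]
  ok <- x >= 0 & x < W & y >= 0 & y < H
  if (!any(ok)) return(arr)
  xi <- x[ok] + 1; yi <- y[ok] + 1
  # with duplicated indices R keeps the last assignment, preserving order
  arr[cbind(yi, xi, 1)] <- r[ok]
  arr[cbind(yi, xi, 2)] <- g[ok]
  arr[cbind(yi, xi, 3)] <- b[ok]
  arr
}

# quadratic Bezier arc sampled at ~1 px steps; returns x, y, t vectors
bezier_points <- function(p0, p1, p2) {
  chord <- sqrt(sum((p2 - p0)^2))
  m <- max(8L, as.integer(ceiling(chord * 1.5)))
  t <- seq(0, 1, length.out = m)
  list(
    x = (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
    y = (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2],
    t = t
  )
}

#' Render a synthetic canopy image with ground truth
#'
#' Deterministic per seed: the same spec always yields bitwise-identical
#' pixels and ground truth. Placement randomness is consumed before painting
#' randomness, so [plan_canopy()] reproduces the ground truth exactly.
#'
#' @param spec A [canopy_spec()].
#' @return List with `image` (a [canopy_image()]) and `ground_truth`.
#' @export
render_canopy <- function(spec) {
  stopifnot(inherits(spec, "canopy_spec"))
  run_seeded(spec$seed, {
    regions <- draw_placements(spec)
    H <- spec$height; W <- spec$width
    npx <- H * W
    layers <- list()

    # base green field with pixel noise
    arr <- array(0, dim = c(H, W, 3))
    arr[, , 1] <- 55 + runif(npx, -6, 6)
    arr[, , 2] <- 95 + runif(npx, -7, 7)
    arr[, , 3] <- 45 + runif(npx, -5, 5)

    # background: randomly oriented green-brown elongated strokes
    n_bg <- max(1L, as.integer(round(spec$background_stroke_density * npx / 1000)))
    cx <- runif(n_bg, 0, W - 1); cy <- runif(n_bg, 0, H - 1)
    ang <- runif(n_bg, 0, pi)
    len <- runif(n_bg, 15, 45)
    colr <- runif(n_bg, 40, 120)
    colg <- runif(n_bg, 70, 150)
    colb <- runif(n_bg, 20, 70)
    steps <- as.integer(ceiling(len))
    idx <- rep.int(seq_len(n_bg), steps)
    tpos <- sequence(steps) - 1
    px <- cx[idx] + (tpos - len[idx] / 2) * cos(ang[idx])
    py <- cy[idx] + (tpos - len[idx] / 2) * sin(ang[idx])
    layers[[1]] <- paint_layer(px, py, colr[idx], colg[idx], colb[idx])
    # second offset row gives strokes ~2 px thickness
    layers[[2]] <- paint_layer(px - sin(ang[idx]), py + cos(ang[idx]),
                               colr[idx], colg[idx], colb[idx])

    # non-flowering panicles: dull curvilinear arcs
    for (i in seq_len(spec$n_nonflowering_panicles)) {
      p0 <- c(runif(1, 0, W - 1), runif(1, 0, H - 1))
      dir <- runif(1, 0, 2 * pi)
      l <- runif(1, 60, 110)
      p2 <- p0 + l * c(cos(dir), sin(dir))
      p1 <- (p0 + p2) / 2 + runif(1, 15, 35) * c(-sin(dir), cos(dir))
      bz <- bezier_points(p0, p1, p2)
      cr <- runif(1, 130, 165); cg <- runif(1, 140, 170); cb <- runif(1, 80, 110)
      layers[[length(layers) + 1]] <-
        paint_layer(c(bz$x, bz$x + 1), c(bz$y, bz$y), cr, cg, cb)
    }

    # flowering panicles: arc + bright anther speckles inside each region
    for (i in seq_len(nrow(regions))) {
      rg <- regions[i, ]
      w <- rg$x_max - rg$x_min; h <- rg$y_max - rg$y_min
      p0 <- c(rg$x_min + 0.1 * w, rg$y_min + runif(1, 0.2, 0.8) * h)
      p2 <- c(rg$x_max - 0.1 * w, rg$y_min + runif(1, 0.2, 0.8) * h)
      p1 <- c((p0[1] + p2[1]) / 2,
              max(rg$y_min, min(rg$y_max - 1, (p0[2] + p2[2]) / 2 +
                                  runif(1, -0.4, 0.4) * h)))
      bz <- bezier_points(p0, p1, p2)
      layers[[length(layers) + 1]] <- paint_layer(bz$x, bz$y, 170, 170, 120)
      n_spk <- max(4L, as.integer(round(spec$anther_speckle_density * w * h / 1000)))
      at <- runif(n_spk)
      sx <- (1 - at)^2 * p0[1] + 2 * (1 - at) * at * p1[1] + at^2 * p2[1] +
        stats::rnorm(n_spk, 0, w / 10)
      sy <- (1 - at)^2 * p0[2] + 2 * (1 - at) * at * p1[2] + at^2 * p2[2] +
        stats::rnorm(n_spk, 0, h / 10)
      sx <- pmin(pmax(sx, rg$x_min), rg$x_max - 1)
      sy <- pmin(pmax(sy, rg$y_min), rg$y_max - 1)
      bright <- runif(n_spk, 225, 255)
      sz <- sample(1:3, n_spk, replace = TRUE)
      # speckles of 1-3 px: extra pixels right of / below the larger ones
      spx <- c(sx, sx[sz >= 2] + 1, sx[sz >= 3])
      spy <- c(sy, sy[sz >= 2], sy[sz >= 3] + 1)
      spr <- c(bright, bright[sz >= 2], bright[sz >= 3])
      layers[[length(layers) + 1]] <- paint_layer(
        spx, spy, spr,
        spr - runif(length(spr), 0, 15), spr - runif(length(spr), 0, 25))
    }

    arr <- apply_layers(arr, layers)
    arr <- pmin(pmax(arr * spec$illumination_gain, 0), 255)
    list(
      image = canopy_image(round(arr)),
      ground_truth = structure(
        list(flowering_regions = regions, fpn = nrow(regions)),
        class = "ground_truth"
      )
    )
  })
}

#' Sample labeled training patches from a rendered canopy
#'
#' Positive patches are rectangles whose intersection with some flowering
#' region covers at least 30% of that region's area; negative patches
#' intersect no flowering region. Patch sides are drawn uniformly from
#' `patch_px_range` (training patches "are not necessarily the same" size).
#'
#' @param img A rendered [canopy_image()].
#' @param gt The matching `ground_truth`.
#' @param n_pos,n_neg Numbers of positive / negative patches.
#' @param patch_px_range Side range in pixels, default `c(60, 140)`.
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per patch (default 200).
#' @return Tibble with `label` (+1/-1), patch bounds, `source`, and `patch`
#'   (list of [canopy_image()]).
#' @export
sample_patches <- function(img, gt, n_pos, n_neg, patch_px_range = c(60, 140),
                           seed, max_tries = 200) {
  stopifnot(inherits(img, "canopy_image"))
  if (missing(seed)) abort("`seed` is required")
  regions <- gt$flowering_regions
  if (n_pos > 0 && nrow(regions) == 0)
    abort("cannot sample positive patches: ground truth has no flowering regions")
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  lo <- patch_px_range[1]; hi <- min(patch_px_range[2], W, H)

  run_seeded(seed, {
    draw_patch <- function(label) {
      for (try in seq_len(max_tries)) {
        s <- as.integer(round(runif(1, lo, hi)))
        if (label > 0) {
          # uniform over all placements that can meet the overlap floor, so
          # weak positives (a window catching only part of a panicle) are
          # represented in the training database
          j <- sample.int(nrow(regions), 1)
          rg <- regions[j, ]
          x0 <- as.integer(round(runif(1, rg$x_min - s + 1, rg$x_max - 1)))
          y0 <- as.integer(round(runif(1, rg$y_min - s + 1, rg$y_max - 1)))
        } else {
          x0 <- as.integer(floor(runif(1, 0, W - s)))
          y0 <- as.integer(floor(runif(1, 0, H - s)))
        }
        if (x0 < 0 || y0 < 0 || x0 + s > W || y0 + s > H) next
        if (nrow(regions) > 0) {
          ox <- pmax(0, pmin(regions$x_max, x0 + s) - pmax(regions$x_min, x0))
          oy <- pmax(0, pmin(regions$y_max, y0 + s) - pmax(regions$y_min, y0))
          ov <- ox * oy
          area <- (regions$x_max - regions$x_min) * (regions$y_max - regions$y_min)
          if (label > 0 && !any(ov >= 0.3 * area)) next
          if (label < 0 && any(ov > 0)) next
        }
        return(c(x0, y0, s))
      }
      abort(sprintf("could not place a %s patch after %d tries",
                    if (label > 0) "positive" else "negative", max_tries))
    }
    specs <- c(
      lapply(seq_len(n_pos), function(i) c(1L, draw_patch(1L))),
      lapply(seq_len(n_neg), function(i) c(-1L, draw_patch(-1L)))
    )
    purrr::map_dfr(specs, function(v) {
      lab <- v[1]; x0 <- v[2]; y0 <- v[3]; s <- v[4]
      patch <- canopy_image(img$pixels[(y0 + 1):(y0 + s),
                                       (x0 + 1):(x0 + s), , drop = FALSE])
      tibble::tibble(
        label = lab, x_min = x0, y_min = y0, x_max = x0 + s, y_max = y0 + s,
        source = sprintf("%s[%d,%d,%d,%d]",
                         img$source_path %||% "synthetic", x0, y0, x0 + s, y0 + s),
        patch = list(patch)
      )
    })
  })
}

#' Simulate a diurnal flowering image series
#'
#' Timestamps every 5 minutes from 08:00 to 16:00 (inclusive; 97 per day).
#' The per-image flowering-panicle count is drawn Poisson with a
#' Gaussian-shaped diurnal rate
#' `amplitude * exp(-(t - peak)^2 / (2 * width^2))`, the typical
#' noon-peaked pattern; shifting a day's peak (e.g. to 15:00) emulates the
#' flowering delay after morning rain. Images are rendered on demand via the
#' per-row `image_spec` (see [render_canopy()]); ground truth is computed at
#' simulation time and is identical to the deferred render's.
#'
#' @param days Number of consecutive days (>= 1).
#' @param peak_time Peak hour(s): a single number or one per day
#'   (e.g. `c(12, 12, 15)`).
#' @param amplitude Poisson rate at the peak (default 12).
#' @param width_minutes Gaussian sigma of the diurnal rate, minutes (default
#'   30: active flowering lasts roughly 1-2 h).
#' @param spec Base [canopy_spec()]; `n_flowering` and `seed` are overridden
#'   per image.
#' @param seed Integer master seed.
#' @param start_date First calendar date (default `"2013-08-24"`).
#' @return A `canopy_series` tibble: `timestamp`, `date`, `fpn`, `rate`,
#'   `image_spec` (list of [canopy_spec()]), `ground_truth` (list).
#' @export
simulate_series <- function(days, peak_time, amplitude = 12,
                            width_minutes = 30, spec = canopy_spec(),
                            seed, start_date = as.Date("2013-08-24")) {
  stopifnot(days >= 1)
  if (missing(seed)) abort("`seed` is required")
  peaks <- rep_len(peak_time, days)
  tod <- seq(8 * 60, 16 * 60, by = 5) # minutes since midnight
  rows <- purrr::map_dfr(seq_len(days), function(d) {
    tibble::tibble(
      date = start_date + (d - 1),
      minute = tod,
      rate = amplitude * exp(-(tod - peaks[d] * 60)^2 / (2 * width_minutes^2))
    )
  })
  rows$timestamp <- as.POSIXct(paste(rows$date, sprintf("%02d:%02d:00",
                                                        rows$minute %/% 60,
                                                        rows$minute %% 60)),
                               tz = "UTC")
  n <- nrow(rows)
  counts <- run_seeded(seed, rpois(n, rows$rate))
  specs <- vector("list", n)
  gts <- vector("list", n)
  for (i in seq_len(n)) {
    si <- spec
    si$n_flowering <- counts[i]
    si$seed <- derive_seed(seed, i)
    specs[[i]] <- si
    gts[[i]] <- plan_canopy(si)
  }
  out <- tibble::tibble(
    timestamp = rows$timestamp, date = rows$date,
    fpn = as.integer(counts), rate = rows$rate,
    image_spec = specs, ground_truth = gts
  )
  tibble::new_tibble(out, class = "canopy_series")
}

#' Write a simulated series to disk as fixtures
#'
#' PNG images named by timestamp (`canopy_%Y%m%d_%H%M.png`), an FPN
#' annotation CSV (`timestamp,fpn`) and a regions CSV
#' (`image,region_id,x_min,y_min,x_max,y_max`).
#'
#' @param series A [simulate_series()] result.
#' @param dir Output directory (created if needed).
#' @export
write_series_fixtures <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- list()
  for (i in seq_len(nrow(series))) {
    fname <- format(series$timestamp[i], "canopy_%Y%m%d_%H%M.png")
    rc <- render_canopy(series$image_spec[[i]])
    save_image(rc$image, file.path(dir, fname))
    fr <- rc$ground_truth$flowering_regions
    if (nrow(fr) > 0) regions[[length(regions) + 1]] <-
        dplyr::mutate(fr, image = fname, .before = 1)
  }
  write_annotations(tibble::tibble(timestamp = series$timestamp,
                                   fpn = series$fpn),
                    file.path(dir, "annotations.csv"))
  reg <- if (length(regions)) dplyr::bind_rows(regions) else
    tibble::tibble(image = character(), region_id = integer(),
                   x_min = integer(), y_min = integer(),
                   x_max = integer(), y_max = integer())
  readr::write_csv(reg, file.path(dir, "regions.csv"))
  invisible(dir)
}

#' Build a training patch database from several synthetic canopies
#'
#' Renders `n_canopies` flowering canopies under derived seeds and samples
#' an equal share of positive and negative patches from each, mirroring the
#' field protocol of drawing training patches from multiple acquisition
#' images so that both classes cover scene-to-scene variation. Shares are
#' rounded so exactly `n_pos` + `n_neg` patches are returned.
#'
#' @param n_pos,n_neg Total positive / negative patch counts.
#' @param seed Integer master seed.
#' @param n_canopies Number of source canopies (default 3).
#' @param spec Base [canopy_spec()]; `seed` is overridden per canopy and
#'   `n_flowering` is kept as given (default 12 flowering panicles so that
#'   positives are plentiful).
#' @param patch_px_range Patch side range, see [sample_patches()].
#' @return A patch tibble as from [sample_patches()].
#' @export
build_training_db <- function(n_pos, n_neg, seed, n_canopies = 3,
                              spec = canopy_spec(n_flowering = 12),
                              patch_px_range = c(60, 140)) {
  if (missing(seed)) abort("`seed` is required")
  share <- function(total, i) {
    # split `total` as evenly as possible over canopies
    base <- total %/% n_canopies
    base + as.integer(i <= total %% n_canopies)
  }
  purrr::map_dfr(seq_len(n_canopies), function(i) {
    si <- spec
    si$seed <- derive_seed(seed, 500 + i)
    rc <- render_canopy(si)
    sample_patches(rc$image, rc$ground_truth,
                   n_pos = share(n_pos, i), n_neg = share(n_neg, i),
                   patch_px_range = patch_px_range,
                   seed = derive_seed(seed, 600 + i))
  })
}
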