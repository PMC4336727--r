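#' Non-overlapping sliding windows over an image
#'
#' `window_px x window_px` tiles anchored at `(col * window_px,
#' row * window_px)` (0-based), row-major; partial tiles at the right and
#' bottom edges are discarded rather than padded.
#'
#' @param width,height Image dimensions in pixels.
#' @param window_px Window side in pixels (>= 1).
#' @return Tibble with `row`, `col` (0-based block indices) and half-open
#'   pixel bounds `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
slide_windows <- function(width, height, window_px) {
  stopifnot(window_px >= 1)
  n_cols <- floor(width / window_px)
  n_rows <- floor(height / window_px)
  if (n_cols < 1 || n_rows < 1) {
    return(tibble::tibble(row = integer(), col = integer(),
                          x_min = integer(), y_min = integer(),
                          x_max = integer(), y_max = integer()))
  }
  g <- expand.grid(col = seq_len(n_cols) - 1L, row = seq_len(n_rows) - 1L)
  tibble::tibble(
    row = as.integer(g$row), col = as.integer(g$col),
    x_min = as.integer(g$col * window_px), y_min = as.integer(g$row * window_px),
    x_max = as.integer((g$col + 1) * window_px),
    y_max = as.integer((g$row + 1) * window_px)
  )
}

#' Classify every sliding window of an image
#'
#' Dense multi-scale SIFT is computed once over the full image; each grid
#' point is assigned to the window containing it (descriptor support may
#' extend past the window edge, zero-padded only at image borders); each
#' window's normalized BoVW histogram is scored by the model. Windows whose
#' grid is empty get verdict `FALSE`. Per-window recomputation equals this
#' global computation restricted to the window's points.
#'
#' @param img A [canopy_image()] (or luminance matrix).
#' @param model A [train_flower_model()] model (provides `window_px`, grid
#'   and kernel-map parameters).
#' @param codebook The codebook the model was trained against.
#' @return A `block_map`: list with logical `verdicts` matrix
#'   (`n_rows x n_cols`), `scores` matrix, `window_px`, `image_ref`.
#' @export
classify_blocks <- function(img, model, codebook) {
  stopifnot(inherits(model, "flower_model"), inherits(codebook, "codebook"))
  if (codebook$k != model$k) abort("codebook does not match the model")
  lum <- if (inherits(img, "canopy_image")) img$luminance else img
  ref <- if (inherits(img, "canopy_image")) img$source_path else NA_character_
  wpx <- model$window_px
  n_cols <- floor(ncol(lum) / wpx)
  n_rows <- floor(nrow(lum) / wpx)
  if (n_cols < 1 || n_rows < 1) {
    return(new_block_map(matrix(FALSE, 0, 0), matrix(numeric(0), 0, 0), wpx, ref))
  }
  dset <- dense_multiscale_sift(lum, model$grid)
  verdicts <- matrix(FALSE, n_rows, n_cols)
  scores <- matrix(model$bias, n_rows, n_cols) # empty windows: zero histogram
  if (nrow(dset$points) > 0) {
    nr <- length(dset$radii)
    px <- rep(dset$points$x, each = nr)
    py <- rep(dset$points$y, each = nr)
    keep <- rowSums(dset$descriptors != 0) > 0
    wcol <- px %/% wpx
    wrow <- py %/% wpx
    inside <- keep & wcol < n_cols & wrow < n_rows
    if (any(inside)) {
      words <- assign_word(dset$descriptors[inside, , drop = FALSE], codebook)
      widx <- (wrow[inside] * n_cols + wcol[inside]) + 1L # row-major window id
      nwin <- n_rows * n_cols
      counts <- matrix(
        tabulate((words - 1L) * nwin + widx, nbins = nwin * codebook$k),
        nwin, codebook$k
      )
      sums <- rowSums(counts)
      nz <- sums > 0
      counts[nz, ] <- counts[nz, , drop = FALSE] / sums[nz]
      pred <- predict_flowering(counts, model)
      sc <- pred$score
      sc[!nz] <- model$bias
      # window id is row-major: fill matrices accordingly
      scores <- matrix(sc, n_rows, n_cols, byrow = TRUE)
      verdicts <- matrix(pred$label == 1L & nz, n_rows, n_cols, byrow = TRUE)
    }
  }
  new_block_map(verdicts, scores, wpx, ref)
}

new_block_map <- function(verdicts, scores, window_px, image_ref) {
  structure(
    list(verdicts = verdicts, scores = scores,
         n_rows = nrow(verdicts), n_cols = ncol(verdicts),
         window_px = as.integer(window_px), image_ref = image_ref),
    class = "block_map"
  )
}

#' Build a block map directly from a verdict matrix
#'
#' Mainly for testing and for degenerate (always-on / always-off) models.
#'
#' @param verdicts Logical matrix (`n_rows x n_cols`).
#' @param window_px Window side in pixels.
#' @param image_ref Optional source identifier.
#' @export
block_map <- function(verdicts, window_px = 140, image_ref = NA_character_) {
  stopifnot(is.matrix(verdicts), is.logical(verdicts))
  new_block_map(verdicts, matrix(NA_real_, nrow(verdicts), ncol(verdicts)),
                window_px, image_ref)
}

#' @export
print.block_map <- function(x, ...) {
  cat(sprintf("<block_map> %d x %d blocks of %d px, %d flowering\n",
              x$n_rows, x$n_cols, x$window_px, sum(x$verdicts)))
  invisible(x)
}

#' Connected components of flowering blocks
#'
#' Maximal connected components of `TRUE` blocks under 8- (default) or
#' 4-adjacency, ordered by their top-left block in row-major order.
#'
#' @param bm A `block_map` (or logical matrix).
#' @param connectivity 4 or 8 (default 8: a panicle crossing a window corner
#'   should not split a region).
#' @return List of integer matrices, each with columns `row`, `col` (0-based
#'   block indices) for one component.
#' @export
connected_regions <- function(bm, connectivity = 8) {
  v <- if (inherits(bm, "block_map")) bm$verdicts else bm
  stopifnot(is.matrix(v), is.logical(v))
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8")
  nr <- nrow(v); nc <- ncol(v)
  if (nr == 0 || nc == 0 || !any(v)) return(list())
  labels <- matrix(0L, nr, nc)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), times = 3); dc <- rep(c(-1L, 0L, 1L), each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  comps <- list()
  nextl <- 0L
  # scan row-major over (row, col) so components are ordered by their
  # top-left (first-encountered) block
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!v[r, cc] || labels[r, cc] != 0L) next
      nextl <- nextl + 1L
      queue <- matrix(c(r, cc), 1, 2)
      labels[r, cc] <- nextl
      members <- queue
      while (nrow(queue) > 0) {
        cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
        for (dd in seq_along(dr)) {
          rr <- cur[1] + dr[dd]; c2 <- cur[2] + dc[dd]
          if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc &&
              v[rr, c2] && labels[rr, c2] == 0L) {
            labels[rr, c2] <- nextl
            queue <- rbind(queue, c(rr, c2))
            members <- rbind(members, c(rr, c2))
          }
        }
      }
      comp <- cbind(row = members[, 1] - 1L, col = members[, 2] - 1L)
      comps[[nextl]] <- comp[order(comp[, 1], comp[, 2]), , drop = FALSE]
    }
  }
  comps
}

#' Summarize a block map into FBN, FCBN and region boxes
#'
#' FBN is the number of blocks judged to contain flowering parts; FCBN the
#' number of connected-block regions (a proxy for the number of flowering
#' panicles); each region rectangle is the pixel-space bounding box of its
#' blocks (0-based, half-open).
#'
#' @param bm A `block_map`.
#' @param connectivity 4 or 8 (default 8).
#' @return A `detection_result`: list with `fbn`, `fcbn`, `regions` tibble
#'   (`region_id`, `x_min`, `y_min`, `x_max`, `y_max`, `n_blocks`) and the
#'   `block_map`.
#' @export
summarize_detection <- function(bm, connectivity = 8) {
  stopifnot(inherits(bm, "block_map"))
  comps <- connected_regions(bm, connectivity)
  wpx <- bm$window_px
  regions <- purrr::map_dfr(seq_along(comps), function(i) {
    m <- comps[[i]]
    tibble::tibble(
      region_id = i,
      x_min = as.integer(min(m[, "col"]) * wpx),
      y_min = as.integer(min(m[, "row"]) * wpx),
      x_max = as.integer((max(m[, "col"]) + 1) * wpx),
      y_max = as.integer((max(m[, "row"]) + 1) * wpx),
      n_blocks = nrow(m)
    )
  })
  if (length(comps) == 0) {
    regions <- tibble::tibble(region_id = integer(), x_min = integer(),
                              y_min = integer(), x_max = integer(),
                              y_max = integer(), n_blocks = integer())
  }
  structure(
    list(fbn = sum(bm$verdicts), fcbn = length(comps),
         regions = regions, block_map = bm, connectivity = connectivity),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> FBN = %d flowering blocks, FCBN = %d regions\n",
              x$fbn, x$fcbn))
  invisible(x)
}

#' @export
tidy.detection_result <- function(x, ...) x$regions

#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(fbn = x$fbn, fcbn = x$fcbn,
                 n_blocks = x$block_map$n_rows * x$block_map$n_cols,
                 window_px = x$block_map$window_px,
                 connectivity = x$connectivity)
}

#' Detect flowering in a single image
#'
#' Convenience wrapper: [classify_blocks()] then [summarize_detection()].
#'
#' @inheritParams classify_blocks
#' @param connectivity 4 or 8.
#' @export
detect_image <- function(img, model, codebook, connectivity = 8) {
  summarize_detection(classify_blocks(img, model, codebook), connectivity)
}

#' Write a detection overlay PNG
#'
#' Flowering blocks are alpha-tinted violet and region bounding boxes
#' outlined in red, over the original image.
#'
#' @param img The [canopy_image()] that was scanned.
#' @param det A `detection_result` for that image.
#' @param path Output PNG path.
#' @param alpha Tint opacity in `[0, 1]`.
#' @export
write_overlay <- function(img, det, path, alpha = 0.45) {
  stopifnot(inherits(img, "canopy_image"), inherits(det, "detection_result"))
  arr <- img$pixels / 255
  bm <- det$block_map
  wpx <- bm$window_px
  tint <- c(199, 21, 133) / 255 # violet red
  for (r in seq_len(bm$n_rows)) {
    for (cc in seq_len(bm$n_cols)) {
      if (!bm$verdicts[r, cc]) next
      ys <- ((r - 1) * wpx + 1):(r * wpx)
      xs <- ((cc - 1) * wpx + 1):(cc * wpx)
      for (ch in 1:3)
        arr[ys, xs, ch] <- (1 - alpha) * arr[ys, xs, ch] + alpha * tint[ch]
    }
  }
  if (nrow(det$regions) > 0) {
    for (i in seq_len(nrow(det$regions))) {
      rg <- det$regions[i, ]
      ys <- (rg$y_min + 1):rg$y_max
      xs <- (rg$x_min + 1):rg$x_max
      edge_y <- c(head(ys, 2), utils::tail(ys, 2))
      edge_x <- c(head(xs, 2), utils::tail(xs, 2))
      arr[edge_y, xs, 1] <- 1; arr[edge_y, xs, 2] <- 0; arr[edge_y, xs, 3] <- 0
      arr[ys, edge_x, 1] <- 1; arr[ys, edge_x, 2] <- 0; arr[ys, edge_x, 3] <- 0
    }
  }
  png::writePNG(pmin(pmax(arr, 0), 1), target = path)
  invisible(path)
}
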