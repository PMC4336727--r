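# Shared fixtures, built in code. Heavy objects (a down-scaled trained
# pipeline) are cached for the duration of the test run.

fixture_cache <- new.env(parent = emptyenv())

tiny_spec <- function(seed = 7, n_flowering = 4) {
  canopy_spec(width = 420, height = 336, n_flowering = n_flowering,
              flowering_size_range = c(50, 80), seed = seed)
}

# A small trained pipeline: 12+12 patches from two 420x336 canopies,
# k = 40 vocabulary. Enough signal to detect synthetic panicles, cheap
# enough to share across test files.
tiny_pipeline <- function() {
  if (!is.null(fixture_cache$pipe)) return(fixture_cache$pipe)
  db <- build_training_db(12, 12, seed = 91, n_canopies = 2,
                          spec = tiny_spec(n_flowering = 5),
                          patch_px_range = c(60, 120))
  desc <- do.call(rbind, lapply(db$patch, function(p)
    dense_multiscale_sift(p$luminance)$descriptors))
  cb <- train_codebook(desc, k = 40, n_restarts = 2, seed = 92)
  model <- train_flower_model(db, cb, seed = 93)
  fixture_cache$pipe <- list(db = db, codebook = cb, model = model)
  fixture_cache$pipe
}

# degenerate linear model with fixed bias (always-on / always-off verdicts)
stub_model <- function(k, bias, window_px = 140, n = 2, L = 0.5) {
  structure(
    list(weights = rep(0, (2 * n + 1) * k), bias = bias,
         map_order_n = as.integer(n), map_period_L = L, C = 1,
         k = as.integer(k), window_px = as.integer(window_px),
         grid = grid_spec(), seed = 0L, n_support = 0L,
         codebook_ref = "stub"),
    class = "flower_model"
  )
}

stub_codebook <- function(k, seed = 5) {
  centers <- withr::with_seed(seed, matrix(runif(k * 128), k, 128))
  structure(list(centers = centers, k = as.integer(k), inertia = 0,
                 seed = as.integer(seed), n_restarts = 1L,
                 iterations = 1L, converged = TRUE),
            class = "codebook")
}

# luminance ramps (H x W matrices, [y, x] indexing)
ramp_x <- function(h = 41, w = 41) matrix(rep(seq_len(w), each = h), h, w)
ramp_y <- function(h = 41, w = 41) matrix(rep(seq_len(h), times = w), h, w)

# smooth random texture (sum of a few sinusoids), deterministic
smooth_texture <- function(n = 81, seed = 3) {
  withr::with_seed(seed, {
    xs <- seq_len(n)
    m <- matrix(0, n, n)
    for (i in 1:6) {
      fx <- runif(1, 0.05, 0.3); fy <- runif(1, 0.05, 0.3)
      ph <- runif(2, 0, 2 * pi); amp <- runif(1, 10, 40)
      m <- m + amp * outer(sin(fy * xs + ph[1]), sin(fx * xs + ph[2]))
    }
    m - min(m)
  })
}

# independent connected-component oracle via igraph
flood_fill_oracle <- function(v, connectivity) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  idx <- which(v, arr.ind = TRUE)
  if (nrow(idx) == 0) return(list())
  n <- nrow(idx)
  edges <- c()
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a >= b) next
      dr <- abs(idx[a, 1] - idx[b, 1]); dc <- abs(idx[a, 2] - idx[b, 2])
      adj <- if (connectivity == 4) dr + dc == 1 else max(dr, dc) == 1
      if (adj) edges <- c(edges, a, b)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lapply(sort(unique(comp)), function(ci) {
    m <- cbind(row = idx[comp == ci, 1] - 1L, col = idx[comp == ci, 2] - 1L)
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
}

# minimal JPEG byte stream carrying only an EXIF DateTimeOriginal
write_exif_jpeg <- function(path, datetime = "2013:08:23 09:41:00") {
  u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
  u32le <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, x %/% 16777216))
  ascii <- charToRaw(paste0(datetime))
  ascii <- c(ascii, as.raw(0))
  stopifnot(length(ascii) == 20)
  tiff <- c(
    charToRaw("II"), u16le(42), u32le(8),
    # IFD0: one entry pointing at the Exif sub-IFD (offset 26)
    u16le(1),
    u16le(0x8769), u16le(4), u32le(1), u32le(26),
    u32le(0),
    # Exif IFD at 26: DateTimeOriginal, ASCII x20 at offset 44
    u16le(1),
    u16le(0x9003), u16le(2), u32le(20), u32le(44),
    u32le(0),
    ascii
  )
  app1 <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  seglen <- length(app1) + 2
  bytes <- c(as.raw(c(0xff, 0xd8, 0xff, 0xe1)),
             as.raw(c(seglen %/% 256, seglen %% 256)), app1,
             as.raw(c(0xff, 0xd9)))
  writeBin(bytes, path)
  path
}
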