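#' Train a visual-word codebook by restarted k-means
#'
#' Lloyd's algorithm with initial centers drawn uniformly (without
#' replacement) from the data points, run `n_restarts` times from seeded
#' initializations; the restart with the minimum within-cluster sum of
#' squares (inertia) wins, ties going to the earliest restart. Iteration
#' stops when assignments no longer change or after `max_iter` sweeps.
#' Zero descriptors (flat image patches) are excluded before clustering.
#'
#' @param descriptors Numeric matrix `n x 128` (or a `descriptor_set`).
#' @param k Number of visual words (default 600).
#' @param n_restarts Number of seeded restarts (default 8).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param max_iter Iteration cap per restart (default 300).
#' @return A `codebook`: list with `centers` (`k x 128`), `k`, `inertia`,
#'   `seed`, `n_restarts`, `iterations`, `converged`.
#' @export
train_codebook <- function(descriptors, k = 600, n_restarts = 8, seed,
                           max_iter = 300) {
  if (inherits(descriptors, "descriptor_set")) descriptors <- descriptors$descriptors
  stopifnot(is.matrix(descriptors))
  if (missing(seed)) abort("`seed` is required")
  k <- as.integer(k)
  if (k < 1) abort("`k` must be >= 1")
  keep <- rowSums(descriptors != 0) > 0
  X <- descriptors[keep, , drop = FALSE]
  if (nrow(X) < k)
    abort(sprintf("need at least k = %d non-zero descriptors, have %d", k, nrow(X)))
  best <- NULL
  run_seeded(seed, {
    for (r in seq_len(n_restarts)) {
      init <- sample.int(nrow(X), k)
      fit <- .kmeans_lloyd_cpp(X, init, as.integer(max_iter))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  structure(
    list(centers = best$centers, k = k, inertia = best$inertia,
         seed = as.integer(seed), n_restarts = as.integer(n_restarts),
         iterations = best$iterations, converged = best$converged),
    class = "codebook"
  )
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> k = %d visual words, inertia = %.4g (seed %d, %d restarts)\n",
              x$k, x$inertia, x$seed, x$n_restarts))
  invisible(x)
}

#' Assign descriptors to visual words
#'
#' Index (1-based) of the nearest codebook center by Euclidean distance;
#' exact ties break toward the lowest index.
#'
#' @param descriptors One 128-dim vector or an `n x 128` matrix.
#' @param codebook A [train_codebook()] result.
#' @return Integer vector of word indices in `1..k`.
#' @export
assign_word <- function(descriptors, codebook) {
  stopifnot(inherits(codebook, "codebook"))
  if (is.vector(descriptors)) descriptors <- matrix(descriptors, nrow = 1)
  if (ncol(descriptors) != ncol(codebook$centers))
    abort("descriptor dimension does not match the codebook")
  .assign_words_cpp(descriptors, codebook$centers)
}

#' Bag-of-visual-words histogram of a descriptor set
#'
#' Every descriptor (each grid point, each scale) increments its assigned
#' word's count. Zero-vector descriptors (flat supports) carry no texture
#' evidence and are skipped. With `normalize = TRUE` counts are divided by
#' their sum (L1), so window histograms of different sizes are comparable
#' under the chi-square kernel.
#'
#' @param dset A `descriptor_set` or a descriptor matrix.
#' @param codebook A [train_codebook()] result.
#' @param normalize L1-normalize the counts (default `TRUE`).
#' @return Numeric vector of length `k` with attribute `normalized`.
#' @export
bovw_histogram <- function(dset, codebook, normalize = TRUE) {
  stopifnot(inherits(codebook, "codebook"))
  X <- if (inherits(dset, "descriptor_set")) dset$descriptors else dset
  if (is.null(X) || nrow(X) == 0) {
    h <- numeric(codebook$k)
    attr(h, "normalized") <- normalize
    return(h)
  }
  keep <- rowSums(X != 0) > 0
  X <- X[keep, , drop = FALSE]
  counts <- tabulate(if (nrow(X)) assign_word(X, codebook) else integer(0),
                     nbins = codebook$k)
  h <- as.numeric(counts)
  if (normalize) {
    s <- sum(h)
    if (s > 0) h <- h / s
  }
  attr(h, "normalized") <- normalize
  h
}

# luminance plane -> normalized BoVW histogram (the per-patch / per-window
# encoding used by training and detection)
image_bovw <- function(lum, codebook, grid = grid_spec(), normalize = TRUE) {
  if (inherits(lum, "canopy_image")) lum <- lum$luminance
  dset <- dense_multiscale_sift(lum, grid)
  bovw_histogram(dset, codebook, normalize = normalize)
}

#' Persist / load a codebook as CSV
#'
#' Flat text format: a `#`-prefixed metadata header (k, inertia, seed,
#' restarts) followed by `k` rows of 128 center coordinates.
#'
#' @param codebook A codebook.
#' @param path CSV path.
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "codebook"))
  meta <- sprintf("# anthesis codebook k=%d inertia=%.17g seed=%d n_restarts=%d",
                  codebook$k, codebook$inertia, codebook$seed, codebook$n_restarts)
  writeLines(meta, path)
  df <- tibble::as_tibble(codebook$centers, .name_repair = ~ sprintf("d%03d", seq_along(.x)))
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  meta <- readLines(path, n = 1)
  kv <- regmatches(meta, gregexpr("[a-z_]+=[-0-9.e+]+", meta))[[1]]
  vals <- setNames(
    as.numeric(sub(".*=", "", kv)),
    sub("=.*", "", kv)
  )
  centers <- as.matrix(readr::read_csv(path, comment = "#",
                                       col_types = readr::cols(.default = readr::col_double())))
  dimnames(centers) <- NULL
  structure(
    list(centers = centers, k = as.integer(vals[["k"]]),
         inertia = vals[["inertia"]], seed = as.integer(vals[["seed"]]),
         n_restarts = as.integer(vals[["n_restarts"]]),
         iterations = NA_integer_, converged = NA),
    class = "codebook"
  )
}
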