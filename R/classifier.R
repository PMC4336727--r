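#' Exact chi-square kernel between histograms
#'
#' `K(x, y) = sum_i 2 x_i y_i / (x_i + y_i)`, with zero-denominator terms
#' contributing 0. For identical L1-normalized histograms `K = 1`.
#'
#' @param h1,h2 Nonnegative numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
chi2_kernel <- function(h1, h2) {
  if (length(h1) != length(h2)) abort("histograms must have equal length")
  if (any(h1 < 0) || any(h2 < 0)) abort("histogram entries must be nonnegative")
  s <- h1 + h2
  ok <- s > 0
  sum(2 * h1[ok] * h2[ok] / s[ok])
}

# spectral weights of the closed-form chi-square feature map:
# kappa(lambda) = sech(pi * lambda)
chi2_kappa <- function(lambda) 1 / cosh(pi * lambda)

#' Homogeneous kernel map for the chi-square kernel
#'
#' Closed-form finite-dimensional feature expansion whose inner product
#' approximates the chi-square kernel, enabling a fast linear SVM. Per bin
#' value `x > 0`, `2n + 1` coordinates are emitted:
#' `sqrt(x L)`, and for `j = 1..n` the pair
#' `sqrt(2 x L sech(pi j L)) * cos(j L log x)` and the matching `sin` term;
#' `x = 0` maps to zeros. Output ordering is bin-major: the `2n + 1`
#' coordinates of bin 1, then bin 2, and so on.
#'
#' @param h Nonnegative histogram (vector) or matrix of row histograms.
#' @param n Approximation order (default 2).
#' @param L Sampling period of the spectral representation (default 0.5).
#' @return Vector of length `(2n + 1) * k`, or a matrix with such rows.
#' @export
kernel_map <- function(h, n = 2, L = 0.5) {
  vec <- is.null(dim(h))
  X <- if (vec) matrix(h, nrow = 1) else as.matrix(h)
  if (any(X < 0)) abort("histogram entries must be nonnegative")
  if (n < 1 || L <= 0) abort("need n >= 1 and L > 0")
  k <- ncol(X)
  m <- 2 * n + 1
  out <- matrix(0, nrow(X), k * m)
  pos <- X > 0
  logx <- matrix(0, nrow(X), k)
  logx[pos] <- log(X[pos])
  # column layout: bin i occupies columns (i-1)*m + 1..m
  base <- (seq_len(k) - 1) * m
  out[, base + 1] <- sqrt(X * L) # j = 0, kappa(0) = 1
  for (j in seq_len(n)) {
    amp <- sqrt(2 * X * L * chi2_kappa(j * L))
    phase <- j * L * logx
    cosj <- amp * cos(phase)
    sinj <- amp * sin(phase)
    cosj[!pos] <- 0
    sinj[!pos] <- 0
    out[, base + 2 * j] <- cosj
    out[, base + 2 * j + 1] <- sinj
  }
  if (vec) out[1, ] else out
}

#' Train the flowering-detection SVM
#'
#' Each training patch is encoded as a normalized BoVW histogram over the
#' codebook, expanded with [kernel_map()], and a linear soft-margin SVM
#' (hinge loss, regularization `C`) is fitted on the mapped vectors via
#' libsvm. The result is reduced to an explicit weight vector and bias so
#' prediction is a dot product.
#'
#' @param samples Patch samples: a tibble from [sample_patches()] (columns
#'   `patch` — list of [canopy_image()] — and `label` in `{-1, 1}`), or any
#'   data frame with those columns.
#' @param codebook A [train_codebook()] codebook.
#' @param C Soft-margin regularization (> 0), default 1.
#' @param n,L Kernel-map order and period (defaults 2, 0.5).
#' @param grid Dense-sampling [grid_spec()].
#' @param window_px Sliding-window size the model is intended for.
#' @param seed Integer seed (kept for provenance; the fit is deterministic).
#' @return A `flower_model` with fields `weights`, `bias`, `map_order_n`,
#'   `map_period_L`, `C`, `k`, `window_px`, `grid`, `codebook_ref`.
#' @export
train_flower_model <- function(samples, codebook, C = 1, n = 2, L = 0.5,
                               grid = grid_spec(), window_px = 140, seed = 0) {
  stopifnot(inherits(codebook, "codebook"))
  if (NROW(samples) == 0) abort("no training samples")
  labels <- as.integer(samples$label)
  if (!all(labels %in% c(-1L, 1L))) abort("labels must be +1 / -1")
  if (length(unique(labels)) < 2)
    abort("training needs both flowering (+1) and background (-1) samples")
  if (C <= 0) abort("`C` must be > 0")
  H <- t(vapply(samples$patch, function(p) {
    image_bovw(p, codebook, grid = grid, normalize = TRUE)
  }, numeric(codebook$k)))
  fit_mapped_svm(H, labels, C = C, n = n, L = L, k = codebook$k,
                 window_px = window_px, grid = grid, seed = seed)
}

# Fit the linear SVM on already-encoded histograms (rows of H, length k).
fit_mapped_svm <- function(H, labels, C, n, L, k, window_px, grid, seed) {
  Phi <- kernel_map(H, n = n, L = L)
  y <- factor(labels, levels = c(-1L, 1L))
  sv <- e1071::svm(x = Phi, y = y, kernel = "linear", cost = C,
                   scale = FALSE, type = "C-classification")
  w <- as.numeric(t(sv$coefs) %*% sv$SV)
  b <- -sv$rho
  # orient so that score > 0 <=> flowering (+1), independent of libsvm's
  # internal label order
  dec <- attr(stats::predict(sv, Phi[1, , drop = FALSE], decision.values = TRUE),
              "decision.values")
  pos_first <- identical(colnames(dec)[1], "1/-1") ||
    grepl("^1/", colnames(dec)[1])
  if (!pos_first) {
    w <- -w
    b <- -b
  }
  structure(
    list(weights = w, bias = b, map_order_n = as.integer(n),
         map_period_L = L, C = C, k = as.integer(k),
         window_px = as.integer(window_px), grid = grid,
         seed = as.integer(seed), n_support = nrow(sv$SV),
         codebook_ref = sprintf("k%d", k)),
    class = "flower_model"
  )
}

#' @export
print.flower_model <- function(x, ...) {
  cat(sprintf(
    "<flower_model> linear SVM on chi2 kernel map (n = %d, L = %g), C = %g\n  k = %d words -> %d features; window %d px; %d support vectors\n",
    x$map_order_n, x$map_period_L, x$C, x$k, length(x$weights), x$window_px,
    x$n_support
  ))
  invisible(x)
}

#' Score and classify a BoVW histogram
#'
#' `score = <weights, kernel_map(h)> + bias`; label +1 (flowering) iff
#' `score > 0` — a score of exactly 0 is classified background.
#'
#' @param h Histogram of length `k`, or a matrix of row histograms.
#' @param model A [train_flower_model()] model.
#' @return Tibble with `score` and `label` columns.
#' @export
predict_flowering <- function(h, model) {
  stopifnot(inherits(model, "flower_model"))
  X <- if (is.null(dim(h))) matrix(h, nrow = 1) else as.matrix(h)
  if (ncol(X) != model$k) abort("histogram length does not match the model's k")
  Phi <- kernel_map(X, n = model$map_order_n, L = model$map_period_L)
  score <- as.numeric(Phi %*% model$weights) + model$bias
  tibble::tibble(score = score, label = ifelse(score > 0, 1L, -1L))
}

#' Detection performance metrics from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + FP + TN + FN)`; `tp_rate = TP / (TP + FN)`
#' (sensitivity over the flowering class); `tn_rate = TN / (FP + TN)`
#' (specificity over the background class). A rate whose denominator is zero
#' is reported as `NA` (undefined), never 0.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return Tibble with `accuracy`, `tp_rate`, `tn_rate`.
#' @export
evaluate_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) abort("confusion counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) abort("confusion matrix is empty")
  tibble::tibble(
    accuracy = (tp + tn) / total,
    tp_rate = if ((tp + fn) > 0) tp / (tp + fn) else NA_real_,
    tn_rate = if ((fp + tn) > 0) tn / (fp + tn) else NA_real_
  )
}

#' @export
tidy.flower_model <- function(x, ...) {
  tibble::tibble(
    term = c("(bias)", sprintf("phi%04d", seq_along(x$weights))),
    estimate = c(x$bias, x$weights)
  )
}

#' @export
glance.flower_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, n_features = length(x$weights), map_order_n = x$map_order_n,
    map_period_L = x$map_period_L, C = x$C, window_px = x$window_px,
    n_support = x$n_support
  )
}

#' Persist / load a flowering model
#'
#' Flat text bundle: `#`-prefixed metadata (map parameters, C, window size,
#' k, bias, codebook reference) followed by one weight per line. Loading
#' verifies that the weight dimension equals `(2n + 1) * k`.
#'
#' @param model A `flower_model`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "flower_model"))
  meta <- sprintf(
    "# anthesis model n=%d L=%.17g C=%.17g k=%d window_px=%d spacing=%d radii=%s bias=%.17g codebook=%s",
    model$map_order_n, model$map_period_L, model$C, model$k, model$window_px,
    model$grid$spacing, paste(model$grid$radii, collapse = ";"),
    model$bias, model$codebook_ref
  )
  writeLines(c(meta, sprintf("%.17g", model$weights)), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[1]
  kvs <- regmatches(meta, gregexpr("[A-Za-z_]+=[^ ]+", meta))[[1]]
  vals <- setNames(sub(".*=", "", kvs), sub("=.*", "", kvs))
  w <- as.numeric(lines[-1])
  n <- as.integer(vals[["n"]])
  k <- as.integer(vals[["k"]])
  if (length(w) != (2 * n + 1) * k)
    abort("model file is inconsistent: weight dimension != (2n + 1) * k")
  structure(
    list(weights = w, bias = as.numeric(vals[["bias"]]),
         map_order_n = n, map_period_L = as.numeric(vals[["L"]]),
         C = as.numeric(vals[["C"]]), k = k,
         window_px = as.integer(vals[["window_px"]]),
         grid = grid_spec(as.integer(vals[["spacing"]]),
                          as.integer(strsplit(vals[["radii"]], ";")[[1]])),
         seed = NA_integer_, n_support = NA_integer_,
         codebook_ref = vals[["codebook"]]),
    class = "flower_model"
  )
}
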