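#' Training-set-size selection experiment
#'
#' For each training size and replicate, draws that many positive and
#' negative patches (seeded, without replacement) from the patch database,
#' trains an SVM, and evaluates (i) patch-classification accuracy, TP rate
#' and TN rate, and (ii) the Pearson correlation between ground-truth FPN
#' and detected FBN/FCBN on an evaluation series. By default the patch
#' metrics are computed on held-out patches (those not drawn for training);
#' `in_sample = TRUE` evaluates on the training patches instead. The
#' replicate with the highest `r_fpn_fcbn` within each size is flagged
#' `best`.
#'
#' The k = 600 visual vocabulary is trained once on the full patch database
#' and shared across replicates.
#'
#' @param patch_db Patch tibble from [sample_patches()] (both labels).
#' @param sizes Integer vector of per-class training sizes.
#' @param replicates Replicates per size.
#' @param eval_series A [simulate_series()] series for the correlation part;
#'   `NULL` skips it (correlations reported as NA).
#' @param seed Integer master seed.
#' @param codebook Optional pre-trained codebook (trained from `patch_db`
#'   when omitted).
#' @param k,n_restarts Codebook parameters when training here.
#' @param C,n,L,window_px,grid Model parameters, see [train_flower_model()].
#' @param in_sample Evaluate patch metrics on the training patches
#'   (the historical convention) instead of held-out ones.
#' @return An `experiment_report`: list with `rows` (condition, replicate,
#'   accuracy, tp_rate, tn_rate, r_fpn_fbn, r_fpn_fcbn, best) and `summary`
#'   (per-condition mean and sd).
#' @export
training_size_experiment <- function(patch_db, sizes, replicates,
                                     eval_series = NULL, seed,
                                     codebook = NULL, k = 600, n_restarts = 8,
                                     C = 1, n = 2, L = 0.5, window_px = 140,
                                     grid = grid_spec(), in_sample = FALSE) {
  if (missing(seed)) abort("`seed` is required")
  pos <- which(patch_db$label == 1)
  neg <- which(patch_db$label == -1)
  if (max(sizes) > length(pos) || max(sizes) > length(neg))
    abort("a requested size exceeds the available per-class patches")
  if (is.null(codebook)) {
    all_desc <- do.call(rbind, lapply(patch_db$patch, function(p)
      dense_multiscale_sift(p$luminance, grid)$descriptors))
    codebook <- train_codebook(all_desc, k = k, n_restarts = n_restarts,
                               seed = derive_seed(seed, 0))
  }
  # encode every patch once; SVM training then only re-fits per draw
  H <- t(vapply(patch_db$patch, function(p)
    image_bovw(p$luminance, codebook, grid = grid), numeric(codebook$k)))
  labels <- as.integer(patch_db$label)

  rows <- purrr::map_dfr(seq_along(sizes), function(si) {
    purrr::map_dfr(seq_len(replicates), function(rep_i) {
      s <- sizes[si]
      rs <- derive_seed(seed, si * 1000 + rep_i)
      sel <- run_seeded(rs, c(sample(pos, s), sample(neg, s)))
      model <- fit_mapped_svm(H[sel, , drop = FALSE], labels[sel],
                              C = C, n = n, L = L, k = codebook$k,
                              window_px = window_px, grid = grid, seed = rs)
      eval_idx <- if (in_sample) sel else setdiff(seq_len(nrow(H)), sel)
      pred <- predict_flowering(H[eval_idx, , drop = FALSE], model)
      truth <- labels[eval_idx]
      m <- evaluate_metrics(
        tp = sum(pred$label == 1 & truth == 1),
        fp = sum(pred$label == 1 & truth == -1),
        tn = sum(pred$label == -1 & truth == -1),
        fn = sum(pred$label == -1 & truth == 1)
      )
      r_fbn <- r_fcbn <- NA_real_
      if (!is.null(eval_series)) {
        fs <- detect_series(eval_series, model, codebook)
        cors <- safe_correlations(fs)
        r_fbn <- cors$r[cors$metric_pair == "fpn_fbn"]
        r_fcbn <- cors$r[cors$metric_pair == "fpn_fcbn"]
      }
      tibble::tibble(condition = s, replicate = rep_i,
                     accuracy = m$accuracy, tp_rate = m$tp_rate,
                     tn_rate = m$tn_rate, r_fpn_fbn = r_fbn,
                     r_fpn_fcbn = r_fcbn)
    })
  })
  rows <- rows |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(best = if (all(is.na(.data$r_fpn_fcbn))) FALSE else
      !is.na(.data$r_fpn_fcbn) &
        .data$r_fpn_fcbn == max(.data$r_fpn_fcbn, na.rm = TRUE)) |>
    dplyr::mutate(best = .data$best & cumsum(.data$best) == 1) |>
    dplyr::ungroup()
  new_experiment_report(rows, condition_label = "training_size")
}

#' Image-resolution reduction experiment
#'
#' Every image of the series is resized by each factor and detection is run
#' with the unchanged model and window size; reports the correlation between
#' ground-truth FPN and detected FBN/FCBN per factor. A factor under which
#' the resized image is smaller than one window is reported as infeasible
#' (NA correlations), not an error.
#'
#' @param series A [simulate_series()] series.
#' @param model,codebook Trained model and matching codebook.
#' @param factors Resolution factors in `(0, 1]`, e.g. `c(1, 0.75, 0.5)`.
#' @param connectivity 4 or 8.
#' @return An `experiment_report` with one row per factor.
#' @export
resolution_experiment <- function(series, model, codebook,
                                  factors = c(1, 0.75, 0.5),
                                  connectivity = 8) {
  stopifnot(all(factors > 0), all(factors <= 1))
  spec0 <- series$image_spec[[1]]
  feasible <- vapply(factors, function(f) {
    floor(spec0$width * f) >= model$window_px &&
      floor(spec0$height * f) >= model$window_px
  }, logical(1))
  live <- factors[feasible]
  # render each frame once and scan it at every feasible factor
  counts <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
    rc <- render_canopy(series$image_spec[[i]])
    purrr::map_dfr(live, function(f) {
      img <- if (f < 1) resize_image(rc$image, f) else rc$image
      res <- detect_image(img, model, codebook, connectivity)
      tibble::tibble(factor = f, timestamp = series$timestamp[i],
                     fbn = res$fbn, fcbn = res$fcbn)
    })
  })
  ann <- tibble::tibble(timestamp = series$timestamp, fpn = series$fpn)
  rows <- purrr::map_dfr(factors, function(f) {
    if (!feasible[match(f, factors)]) {
      return(tibble::tibble(condition = f, replicate = 1L,
                            accuracy = NA_real_, tp_rate = NA_real_,
                            tn_rate = NA_real_, r_fpn_fbn = NA_real_,
                            r_fpn_fcbn = NA_real_, feasible = FALSE))
    }
    fs <- build_series(counts[counts$factor == f,
                              c("timestamp", "fbn", "fcbn")], ann)
    cors <- safe_correlations(fs)
    tibble::tibble(condition = f, replicate = 1L,
                   accuracy = NA_real_, tp_rate = NA_real_, tn_rate = NA_real_,
                   r_fpn_fbn = cors$r[cors$metric_pair == "fpn_fbn"],
                   r_fpn_fcbn = cors$r[cors$metric_pair == "fpn_fcbn"],
                   feasible = TRUE)
  })
  new_experiment_report(rows, condition_label = "resolution_factor")
}

# a replicate whose detections are constant has no defined correlation;
# report NA for it instead of aborting the whole experiment
safe_correlations <- function(fs) {
  tryCatch(correlate_counts(fs), error = function(e) {
    tibble::tibble(metric_pair = c("fpn_fbn", "fpn_fcbn"),
                   n = NA_integer_, r = NA_real_)
  })
}

new_experiment_report <- function(rows, condition_label) {
  metrics <- intersect(c("accuracy", "tp_rate", "tn_rate",
                         "r_fpn_fbn", "r_fpn_fcbn"), names(rows))
  summary <- rows |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(metrics),
      list(mean = ~mean(.x, na.rm = TRUE), sd = ~sd(.x, na.rm = TRUE))
    ), .groups = "drop")
  structure(list(rows = rows, summary = summary,
                 condition_label = condition_label),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s, %d conditions x rows:\n",
              x$condition_label, length(unique(x$rows$condition))))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.experiment_report <- function(x, ...) x$rows

#' @export
glance.experiment_report <- function(x, ...) x$summary

#' Plot an experiment report
#'
#' Per-condition mean with replicate scatter for each available metric.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @export
autoplot.experiment_report <- function(object, ...) {
  metrics <- intersect(c("accuracy", "tp_rate", "tn_rate",
                         "r_fpn_fbn", "r_fpn_fcbn"), names(object$rows))
  long <- object$rows |>
    tidyr::pivot_longer(dplyr::all_of(metrics),
                        names_to = "metric", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$condition), .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$condition_label, y = NULL) +
    ggplot2::theme_minimal()
}

#' Write an experiment report to CSV
#'
#' @param report An `experiment_report`.
#' @param path Rows CSV path; the per-condition summary goes to
#'   `<path base>_summary.csv`.
#' @param config,seed Optional audit stamp fields.
#' @export
write_report_csv <- function(report, path, config = NULL, seed = NULL) {
  write_stamped_csv(report$rows, path, config, seed)
  spath <- paste0(tools::file_path_sans_ext(path), "_summary.",
                  tools::file_ext(path))
  write_stamped_csv(report$summary, spath, config, seed)
  invisible(path)
}
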