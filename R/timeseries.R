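#' Assemble per-image detections into a flowering series
#'
#' Sorts detections by timestamp, joins optional manual panicle counts (FPN)
#' by exact timestamp match — nearest-neighbor joining is deliberately
#' rejected so a 5-minute acquisition cadence can never be silently
#' mispaired — and reports unmatched annotations in a join log attribute.
#' Missing acquisitions are simply absent rows, never imputed.
#'
#' @param detections Tibble with `timestamp` (POSIXct) and counts `fbn`,
#'   `fcbn` (e.g. from [detect_series()]), or a list of
#'   `(timestamp, detection_result)` pairs.
#' @param annotations Optional tibble with `timestamp`, `fpn`
#'   (see [read_annotations()]).
#' @return A `flowering_series` tibble with columns `timestamp`, `date`,
#'   `fbn`, `fcbn`, `fpn` (NA where unannotated); attribute `join_log` lists
#'   annotation timestamps that matched no detection.
#' @export
build_series <- function(detections, annotations = NULL) {
  if (is.list(detections) && !is.data.frame(detections)) {
    detections <- purrr::map_dfr(detections, function(d) {
      tibble::tibble(timestamp = d$timestamp, fbn = d$result$fbn,
                     fcbn = d$result$fcbn)
    })
  }
  stopifnot(all(c("timestamp", "fbn", "fcbn") %in% names(detections)))
  if (anyNA(detections$timestamp)) abort("all detections need a timestamp")
  dup <- detections$timestamp[duplicated(detections$timestamp)]
  if (length(dup) > 0) {
    abort(paste0("duplicate detection timestamps: ",
                 paste(format(unique(dup), "%Y-%m-%d %H:%M"), collapse = ", ")))
  }
  out <- detections |>
    dplyr::arrange(.data$timestamp) |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC"), .after = "timestamp")
  unmatched <- character(0)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    ann <- tibble::tibble(timestamp = annotations$timestamp,
                          fpn = as.integer(annotations$fpn))
    out <- dplyr::left_join(out, ann, by = "timestamp")
    miss <- !ann$timestamp %in% out$timestamp
    unmatched <- format(ann$timestamp[miss], "%Y-%m-%d %H:%M")
  } else if (!"fpn" %in% names(out)) {
    out$fpn <- NA_integer_
  }
  out <- tibble::new_tibble(out, class = "flowering_series")
  attr(out, "join_log") <- unmatched
  out
}

#' Time of the daily flowering peak
#'
#' Timestamp of the maximum of the chosen metric on the given date, on the
#' raw (unsmoothed) series; ties break to the earliest time. A day whose
#' metric is all zero has no flowering, reported as `NA` (the "no flowering"
#' sentinel); a date with no entries at all is an error.
#'
#' @param series A [build_series()] result.
#' @param date A `Date` (or coercible).
#' @param metric `"fcbn"` (default), `"fbn"` or `"fpn"`.
#' @return A single POSIXct, or `NA` for a no-flowering day.
#' @export
daily_peak <- function(series, date, metric = c("fcbn", "fbn", "fpn")) {
  metric <- match.arg(metric)
  date <- as.Date(date)
  day <- series[series$date == date, ]
  if (nrow(day) == 0)
    abort(paste0("no entries for date ", format(date)))
  v <- day[[metric]]
  if (all(is.na(v)) || all(v == 0, na.rm = TRUE))
    return(as.POSIXct(NA, tz = "UTC"))
  day$timestamp[which.max(v)]
}

#' @rdname daily_peak
#' @description `daily_peaks()` applies [daily_peak()] to every date present.
#' @export
daily_peaks <- function(series, metric = c("fcbn", "fbn", "fpn")) {
  metric <- match.arg(metric)
  dates <- sort(unique(series$date))
  peaks <- vapply(dates, function(d)
    as.numeric(daily_peak(series, d, metric)), numeric(1))
  tibble::tibble(
    date = dates,
    metric = metric,
    peak_time = as.POSIXct(peaks, origin = "1970-01-01", tz = "UTC")
  )
}

#' Pearson correlation over pairwise-complete pairs
#'
#' Sample product-moment correlation, computed on rows where both values are
#' present, so missing acquisitions shrink n rather than abort. Constant
#' input (zero variance) is an error: the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) abort("need at least 3 pairwise-complete observations")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0)
    abort("correlation undefined for a constant sequence")
  cor(x[ok], y[ok], method = "pearson")
}

#' Correlate automated counts with manual FPN
#'
#' Pearson r between `fpn` and each of `fbn` and `fcbn` over
#' pairwise-complete rows of the series.
#'
#' @param series A [build_series()] result carrying `fpn`.
#' @return Tibble `metric_pair`, `n`, `r`.
#' @export
correlate_counts <- function(series) {
  purrr::map_dfr(c("fbn", "fcbn"), function(m) {
    ok <- !is.na(series$fpn) & !is.na(series[[m]])
    tibble::tibble(
      metric_pair = paste0("fpn_", m),
      n = sum(ok),
      r = pearson_r(series$fpn, series[[m]])
    )
  })
}

#' Write a flowering series, its daily peaks and count correlations as CSV
#'
#' Series CSV: `timestamp,fbn,fcbn,fpn` (fpn blank when absent); peaks CSV:
#' `date,metric,peak_time`; correlation CSV: `metric_pair,n,r`.
#'
#' @param series A `flowering_series`.
#' @param path Series CSV path.
#' @param config,seed Optional audit stamp fields.
#' @export
write_series_csv <- function(series, path, config = NULL, seed = NULL) {
  out <- tibble::tibble(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    fbn = series$fbn, fcbn = series$fcbn, fpn = series$fpn
  )
  write_stamped_csv(out, path, config, seed)
}

#' @export
glance.flowering_series <- function(x, ...) {
  tibble::tibble(
    n = nrow(x), n_days = length(unique(x$date)),
    n_annotated = sum(!is.na(x$fpn)),
    first = min(x$timestamp), last = max(x$timestamp)
  )
}

#' Plot a flowering series
#'
#' Diurnal FBN/FCBN (and FPN where annotated) curves, faceted by date.
#'
#' @param object A `flowering_series`.
#' @param ... Unused.
#' @export
autoplot.flowering_series <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::any_of(c("fbn", "fcbn", "fpn")),
                        names_to = "metric", values_to = "count") |>
    dplyr::filter(!is.na(.data$count)) |>
    dplyr::mutate(tod = as.numeric(difftime(
      .data$timestamp, as.POSIXct(paste(.data$date, "00:00:00"), tz = "UTC"),
      units = "hours"
    )))
  ggplot2::ggplot(long, ggplot2::aes(.data$tod, .data$count,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~date) +
    ggplot2::labs(x = "time of day (h)", y = "count", colour = NULL) +
    ggplot2::theme_minimal()
}
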