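#' Run detection over a simulated or on-disk image series
#'
#' For a [simulate_series()] object, each image is rendered on demand from
#' its stored spec (optionally resized), scanned, and discarded, so series of
#' hundreds of large frames stay memory-safe. For a directory of images,
#' every PNG/JPEG is loaded and scanned.
#'
#' @param series A `canopy_series` from [simulate_series()], or a directory
#'   path containing images.
#' @param model A [train_flower_model()] model.
#' @param codebook The matching codebook.
#' @param factor Optional resolution-reduction factor in `(0, 1]` applied to
#'   every image before detection (window size unchanged).
#' @param connectivity 4 or 8.
#' @param annotations Optional FPN annotations to join; for a simulated
#'   series the ground-truth FPN is joined automatically.
#' @param timestamp_pattern Filename timestamp pattern for directory input.
#' @return A `flowering_series` tibble (see [build_series()]).
#' @export
detect_series <- function(series, model, codebook, factor = 1,
                          connectivity = 8, annotations = NULL,
                          timestamp_pattern = "%Y%m%d_%H%M") {
  if (inherits(series, "canopy_series")) {
    det <- purrr::map_dfr(seq_len(nrow(series)), function(i) {
      rc <- render_canopy(series$image_spec[[i]])
      img <- if (factor < 1) resize_image(rc$image, factor) else rc$image
      res <- detect_image(img, model, codebook, connectivity)
      tibble::tibble(timestamp = series$timestamp[i],
                     fbn = res$fbn, fcbn = res$fcbn)
    })
    if (is.null(annotations))
      annotations <- tibble::tibble(timestamp = series$timestamp,
                                    fpn = series$fpn)
  } else {
    paths <- sort(list.files(series, pattern = "\\.(png|jpe?g)$",
                             full.names = TRUE, ignore.case = TRUE))
    if (length(paths) == 0) abort(paste0("no images found under ", series))
    det <- purrr::map_dfr(paths, function(p) {
      img <- load_image(p, timestamp_pattern)
      if (is.null(img$timestamp))
        abort(paste0("image has no parseable timestamp: ", p))
      if (factor < 1) img <- resize_image(img, factor)
      res <- detect_image(img, model, codebook, connectivity)
      tibble::tibble(timestamp = img$timestamp, fbn = res$fbn, fcbn = res$fcbn)
    })
  }
  build_series(det, annotations)
}
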