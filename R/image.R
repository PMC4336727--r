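#' Canopy image objects
#'
#' A `canopy_image` bundles an 8-bit RGB raster (stored as an `H x W x 3`
#' double array with values in `[0, 255]`), the derived real-valued luminance
#' plane, an optional acquisition timestamp and the source path. Luminance is
#' computed once with [to_luminance()] and kept unquantized, because all
#' feature extraction operates on the intensity plane.
#'
#' @param pixels `H x W x 3` numeric array of RGB intensities in `[0, 255]`.
#' @param timestamp Optional `POSIXct` acquisition instant (or `NA`/`NULL`).
#' @param source_path Optional path the raster came from.
#'
#' @return A `canopy_image` object with fields `pixels`, `luminance`,
#'   `timestamp` and `source_path`.
#' @export
canopy_image <- function(pixels, timestamp = NULL, source_path = NA_character_) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    abort("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    abort("image must have at least one row and one column")
  storage.mode(pixels) <- "double"
  ts <- timestamp
  if (!is.null(ts)) {
    ts <- as.POSIXct(ts, tz = "UTC")
    if (length(ts) != 1) abort("`timestamp` must be a single instant")
    if (is.na(ts)) ts <- NULL
  }
  structure(
    list(
      pixels = pixels,
      luminance = to_luminance(pixels),
      timestamp = ts,
      source_path = source_path
    ),
    class = "canopy_image"
  )
}

#' @export
print.canopy_image <- function(x, ...) {
  d <- dim(x$pixels)
  ts <- if (is.null(x$timestamp)) "none" else format(x$timestamp, "%Y-%m-%d %H:%M")
  cat(sprintf("<canopy_image> %d x %d px, timestamp: %s\n", d[2], d[1], ts))
  invisible(x)
}

#' @export
dim.canopy_image <- function(x) dim(x$pixels)

#' Convert an RGB raster to luminance
#'
#' Rec.601 luma weights: `0.299 R + 0.587 G + 0.114 B`. The result is kept as
#' real values (not re-quantized to 8 bits).
#'
#' @param pixels `H x W x 3` numeric array.
#' @return `H x W` numeric matrix in `[0, 255]` (for 8-bit input).
#' @export
to_luminance <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    abort("`pixels` must have exactly 3 channels (H x W x 3)")
  l <- 0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
  dim(l) <- dim(pixels)[1:2] # keep matrix shape even for 1-pixel rasters
  l
}

#' Load a canopy image from PNG or JPEG
#'
#' Reads the raster, converts it to the internal 8-bit RGB representation
#' (grayscale is replicated across channels, alpha is dropped), computes the
#' luminance plane and resolves the acquisition timestamp: EXIF
#' `DateTimeOriginal` takes precedence (JPEG only), then a filename pattern,
#' otherwise the timestamp is absent.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @param timestamp_pattern `strftime`-style pattern searched for in the file
#'   name (see [parse_timestamp()]).
#' @return A [canopy_image()].
#' @export
load_image <- function(path, timestamp_pattern = "%Y%m%d_%H%M") {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    abort(paste0("cannot read image: file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    {
      if (ext == "png") {
        a <- png::readPNG(path) # H x W x C in [0,1]
        if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
        if (dim(a)[3] == 2) a <- array(rep(a[, , 1], 3), dim = c(dim(a)[1:2], 3))
        if (dim(a)[3] >= 4) a <- a[, , 1:3, drop = FALSE]
        a * 255
      } else if (ext %in% c("jpg", "jpeg", "tif", "tiff")) {
        a <- EBImage::imageData(EBImage::readImage(path)) # W x H x C
        if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
        if (dim(a)[3] >= 4) a <- a[, , 1:3, drop = FALSE]
        aperm(a, c(2, 1, 3)) * 255
      } else {
        abort(paste0("unsupported image format '", ext, "': ", path))
      }
    },
    error = function(e) {
      abort(paste0("cannot read image ", path, ": ", conditionMessage(e)))
    }
  )
  ts <- parse_timestamp(path, timestamp_pattern)
  canopy_image(arr, timestamp = if (is.na(ts)) NULL else ts, source_path = path)
}

#' Write a canopy image to PNG
#'
#' @param img A [canopy_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "canopy_image"))
  arr <- pmin(pmax(img$pixels, 0), 255)
  # quantize to 8-bit so a PNG round trip is exact for 8-bit content
  png::writePNG(round(arr) / 255, target = path)
  invisible(path)
}

#' Resize an image by a factor in (0, 1]
#'
#' Output dimensions are `floor(H * factor) x floor(W * factor)`; bilinear
#' interpolation; the timestamp is preserved. `factor = 1` returns the input
#' unchanged.
#'
#' @param img A [canopy_image()].
#' @param factor Scale factor in `(0, 1]`.
#' @return A resized [canopy_image()].
#' @export
resize_image <- function(img, factor) {
  stopifnot(inherits(img, "canopy_image"))
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    abort("`factor` must be a single value in (0, 1]")
  if (factor == 1) return(img)
  d <- dim(img$pixels)
  nh <- floor(d[1] * factor)
  nw <- floor(d[2] * factor)
  if (nh < 1 || nw < 1) abort("resized image would be empty")
  out <- array(0, dim = c(nh, nw, 3))
  for (ch in 1:3) out[, , ch] <- .resize_bilinear_cpp(img$pixels[, , ch], nh, nw)
  canopy_image(out, timestamp = img$timestamp, source_path = img$source_path)
}

#' Parse an acquisition timestamp from EXIF or the file name
#'
#' For JPEG files the EXIF `DateTimeOriginal` (falling back to `DateTime`)
#' takes precedence; otherwise the base name is searched for `pattern`
#' (supported tokens: `%Y`, `%m`, `%d`, `%H`, `%M`, `%S`). Returns `NA` when
#' neither source parses; never raises.
#'
#' @param path File path (need not exist for filename-only parsing).
#' @param pattern `strftime`-style pattern, default `"%Y%m%d_%H%M"`.
#' @return A single `POSIXct` (UTC) or `NA`.
#' @export
parse_timestamp <- function(path, pattern = "%Y%m%d_%H%M") {
  ts <- NA
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg") && file.exists(path)) {
    ts <- read_exif_datetime(path)
  }
  if (is.na(ts)) {
    # token-by-token translation of the strftime pattern into a regex
    chars <- strsplit(pattern, "")[[1]]
    parts <- character(0)
    i <- 1
    while (i <= length(chars)) {
      if (chars[i] == "%" && i < length(chars) &&
          chars[i + 1] %in% c("Y", "m", "d", "H", "M", "S")) {
        parts <- c(parts, if (chars[i + 1] == "Y") "\\d{4}" else "\\d{2}")
        i <- i + 2
      } else {
        parts <- c(parts, if (grepl("[A-Za-z0-9_]", chars[i])) chars[i]
                   else paste0("\\", chars[i]))
        i <- i + 1
      }
    }
    rex <- paste(parts, collapse = "")
    base <- basename(path)
    m <- regmatches(base, regexpr(rex, base))
    if (length(m) == 1) {
      parsed <- as.POSIXct(strptime(m, pattern, tz = "UTC"))
      if (!is.na(parsed)) ts <- parsed
    }
  }
  if (inherits(ts, "POSIXct")) ts else as.POSIXct(NA, tz = "UTC")
}

# Minimal EXIF DateTimeOriginal reader (JPEG APP1 / TIFF IFD walk); no R
# package in scope reads EXIF. Returns POSIXct (UTC) or NA on any failure.
read_exif_datetime <- function(path) {
  out <- tryCatch(
    {
      raw <- readBin(path, "raw", n = 262144L)
      b <- as.integer(raw)
      n <- length(b)
      if (n < 4 || b[1] != 0xff || b[2] != 0xd8) return(as.POSIXct(NA, tz = "UTC"))
      pos <- 3L # 1-based index of next marker 0xff
      tiff0 <- NA_integer_
      while (pos + 3 <= n) {
        if (b[pos] != 0xff) break
        marker <- b[pos + 1]
        if (marker == 0xd9 || marker == 0xda) break
        seglen <- b[pos + 2] * 256L + b[pos + 3]
        if (marker == 0xe1 && pos + 9 <= n &&
            all(b[(pos + 4):(pos + 9)] == c(0x45, 0x78, 0x69, 0x66, 0x00, 0x00))) {
          tiff0 <- pos + 10L # 1-based offset of TIFF header
          break
        }
        pos <- pos + 2L + seglen
      }
      if (is.na(tiff0) || tiff0 + 7 > n) return(as.POSIXct(NA, tz = "UTC"))
      little <- (b[tiff0] == 0x49 && b[tiff0 + 1] == 0x49)
      u16 <- function(off) { # off: 0-based from TIFF header
        i <- tiff0 + off
        if (little) b[i] + b[i + 1] * 256 else b[i] * 256 + b[i + 1]
      }
      u32 <- function(off) {
        i <- tiff0 + off
        if (little) b[i] + b[i + 1] * 256 + b[i + 2] * 65536 + b[i + 3] * 16777216
        else b[i] * 16777216 + b[i + 1] * 65536 + b[i + 2] * 256 + b[i + 3]
      }
      read_ascii <- function(off, cnt) {
        i <- tiff0 + off
        rawToChar(raw[i:(i + cnt - 2)]) # drop trailing NUL
      }
      find_tag <- function(ifd_off, want) {
        cnt <- u16(ifd_off)
        for (e in seq_len(cnt) - 1L) {
          eoff <- ifd_off + 2L + 12L * e
          if (u16(eoff) == want) return(eoff)
        }
        NA_integer_
      }
      get_datetime <- function(eoff) {
        cnt <- u32(eoff + 4L)
        val <- read_ascii(u32(eoff + 8L), cnt)
        as.POSIXct(strptime(val, "%Y:%m:%d %H:%M:%S", tz = "UTC"))
      }
      ifd0 <- u32(4L)
      e <- find_tag(ifd0, 0x8769) # Exif sub-IFD pointer
      if (!is.na(e)) {
        sub <- u32(e + 8L)
        d <- find_tag(sub, 0x9003) # DateTimeOriginal
        if (!is.na(d)) return(get_datetime(d))
      }
      d <- find_tag(ifd0, 0x0132) # DateTime
      if (!is.na(d)) return(get_datetime(d))
      as.POSIXct(NA, tz = "UTC")
    },
    error = function(e) as.POSIXct(NA, tz = "UTC")
  )
  if (inherits(out, "POSIXct") && length(out) == 1) out else as.POSIXct(NA, tz = "UTC")
}

#' Read manual flowering-panicle counts (FPN annotations)
#'
#' CSV dialect: header `timestamp,fpn`, ISO-8601 timestamps (UTC), one row per
#' annotated image. Timestamps must be unique and counts nonnegative.
#'
#' @param path CSV path.
#' @return Tibble with `timestamp` (POSIXct) and `fpn` (integer).
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_character(), fpn = readr::col_integer()
  ), comment = "#")
  ts <- as.POSIXct(strptime(df$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  plain <- is.na(ts)
  ts[plain] <- as.POSIXct(strptime(df$timestamp[plain], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
  if (anyNA(ts)) abort("unparseable timestamps in annotation file")
  if (anyDuplicated(ts)) abort("duplicate timestamps in annotation file")
  if (any(df$fpn < 0)) abort("fpn counts must be nonnegative")
  tibble::tibble(timestamp = ts, fpn = df$fpn)
}

#' @rdname read_annotations
#' @param annotations Tibble with `timestamp` and `fpn` columns.
#' @export
write_annotations <- function(annotations, path) {
  out <- tibble::tibble(
    timestamp = format(annotations$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    fpn = as.integer(annotations$fpn)
  )
  readr::write_csv(out, path)
  invisible(path)
}

# Write a data frame as CSV with a leading audit comment line.
write_stamped_csv <- function(df, path, config = NULL, seed = NULL) {
  stamp <- sprintf("# anthesis config_hash=%s seed=%s",
                   fnv1a_hash(paste(deparse(config %||% list()), collapse = "")),
                   as.character(seed %||% NA))
  writeLines(stamp, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
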