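#' Pipeline configuration
#'
#' One flat set of keys drives every stage; all defaults are overridable and
#' unknown keys are rejected. `seed` has no default: every run must be
#' explicitly seeded.
#'
#' @param grid_spacing Dense-grid spacing M in px (default 15).
#' @param radii Integer support radii (default `c(4, 6, 8, 10)`).
#' @param k Visual-vocabulary size (default 600).
#' @param kmeans_restarts k-means restarts (default 8).
#' @param svm_C SVM regularization (default 1).
#' @param map_order Kernel-map order n (default 2).
#' @param map_period Kernel-map period L (default 0.5).
#' @param window_px Sliding-window side (default 140; 170 suits coarser
#'   canopies with larger panicle images).
#' @param connectivity Block adjacency, 4 or 8 (default 8).
#' @param normalize_histograms L1-normalize window histograms (default TRUE).
#' @param seed Integer seed (required).
#' @param timestamp_pattern Filename timestamp pattern.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(grid_spacing = 15, radii = c(4, 6, 8, 10),
                            k = 600, kmeans_restarts = 8, svm_C = 1,
                            map_order = 2, map_period = 0.5, window_px = 140,
                            connectivity = 8, normalize_histograms = TRUE,
                            seed, timestamp_pattern = "%Y%m%d_%H%M") {
  if (missing(seed)) abort("`seed` is required in the pipeline configuration")
  cfg <- list(
    grid_spacing = as.integer(grid_spacing), radii = as.integer(radii),
    k = as.integer(k), kmeans_restarts = as.integer(kmeans_restarts),
    svm_C = as.numeric(svm_C), map_order = as.integer(map_order),
    map_period = as.numeric(map_period), window_px = as.integer(window_px),
    connectivity = as.integer(connectivity),
    normalize_histograms = isTRUE(normalize_histograms),
    seed = as.integer(seed), timestamp_pattern = timestamp_pattern
  )
  if (!cfg$connectivity %in% c(4L, 8L)) abort("connectivity must be 4 or 8")
  structure(cfg, class = "pipeline_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` (comments with `#`); `radii` as a
#' comma-separated list. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file (flags win).
#' @return A [pipeline_config()].
#' @export
read_config <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "\\s*=\\s*")[[1]]
      if (length(parts) != 2) abort(paste0("malformed config line: ", ln))
      kv[[parts[1]]] <- parts[2]
    }
  }
  kv <- modifyList(kv, overrides)
  known <- setdiff(names(formals(pipeline_config)), "")
  bad <- setdiff(names(kv), known)
  if (length(bad) > 0)
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  parse_val <- function(key, val) {
    if (key == "radii") return(as.integer(strsplit(as.character(val), ",")[[1]]))
    if (key == "timestamp_pattern") return(as.character(val))
    if (key == "normalize_histograms")
      return(tolower(as.character(val)) %in% c("true", "1", "yes"))
    as.numeric(val)
  }
  args <- lapply(seq_along(kv), function(i) parse_val(names(kv)[i], kv[[i]]))
  names(args) <- names(kv)
  do.call(pipeline_config, args)
}

config_hash <- function(cfg) {
  fnv1a_hash(paste(names(cfg), sapply(cfg, paste, collapse = ";"),
                   sep = "=", collapse = " "))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> hash", config_hash(x), "\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}
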