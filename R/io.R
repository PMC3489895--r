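#' Write / read a FLIM image as multi-page TIFF + JSON sidecar
#'
#' The on-disk format is a multi-page 16-bit unsigned TIFF — page k holds
#' the photon counts of time bin k — plus a JSON sidecar (same path,
#' `.json` extension) with `repetition_rate_MHz`, `n_bins` and
#' `excitation_nm`. The round trip is bit-exact for integer counts.
#' Counts above 65535 raise an explicit range error rather than clipping;
#' non-integer (noise-free) counts must be rounded by the caller first.
#'
#' @param img A [flim_image()] with integer counts in `[0, 65535]`.
#' @param path Path to the `.tif` file; the sidecar is written next to it.
#' @return `write_flim()` returns `path` invisibly; `read_flim()` returns
#'   a [flim_image()].
#' @export
write_flim <- function(img, path) {
  stopifnot(inherits(img, "flim_image"))
  if (any(img$counts > 65535)) {
    stop("photon counts exceed the 16-bit range (65535); no silent clipping",
         call. = FALSE)
  }
  if (any(img$counts != round(img$counts))) {
    stop("photon counts must be integers for 16-bit storage", call. = FALSE)
  }
  pages <- lapply(seq_len(img$n_bins), function(k) img$counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(repetition_rate_MHz = img$rep_rate_MHz,
         n_bins = img$n_bins,
         excitation_nm = img$excitation_nm),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_flim
#' @export
read_flim <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop(sprintf("format error: missing sidecar '%s'", sc_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  for (fld in c("repetition_rate_MHz", "n_bins")) {
    if (is.null(meta[[fld]])) {
      stop(sprintf("format error: sidecar lacks field '%s'", fld), call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != meta$n_bins) {
    stop(sprintf(
      "format error: sidecar n_bins = %d but TIFF has %d pages",
      meta$n_bins, length(pages)
    ), call. = FALSE)
  }
  counts <- array(0, dim = c(dim(pages[[1L]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * 65535)
  flim_image(counts, rep_rate_MHz = meta$repetition_rate_MHz,
             excitation_nm = meta$excitation_nm %||% 740)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a phasor field as a 32-bit TIFF + JSON sidecar
#'
#' Three 32-bit planes: g, s, and a validity mask (1 = defined). Undefined
#' pixels store 0 in the g/s planes and 0 in the mask; readers restore
#' `NA`. The sidecar records the harmonic, period and encoding.
#'
#' @param field A `phasor_field`.
#' @param path Path to the `.tif` file.
#' @return `write_phasor_field()` returns `path` invisibly;
#'   `read_phasor_field()` returns a `phasor_field` (with intensity `NA`,
#'   which is not stored).
#' @export
write_phasor_field <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  mask <- !is.na(field$g)
  g <- ifelse(mask, field$g, 0)
  s <- ifelse(mask, field$s, 0)
  if (any(g < 0 | g > 1 | s < 0 | s > 1)) {
    stop("phasor coordinates outside [0, 1] cannot be stored", call. = FALSE)
  }
  tiff::writeTIFF(list(g, s, mask * 1), path, bits.per.sample = 32L,
                  reduce = FALSE)
  jsonlite::write_json(
    list(planes = c("g", "s", "valid"), harmonic = field$harmonic,
         period_ns = field$period, n_bins = field$n_bins,
         calibrated = isTRUE(field$calibrated)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(path) {
  sc_path <- sidecar_path(path)
  if (!file.exists(sc_path)) {
    stop(sprintf("format error: missing sidecar '%s'", sc_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 3L) {
    stop("format error: phasor-field TIFF must have 3 planes (g, s, valid)",
         call. = FALSE)
  }
  mask <- planes[[3L]] > 0.5
  g <- ifelse(mask, planes[[1L]], NA_real_)
  s <- ifelse(mask, planes[[2L]], NA_real_)
  structure(
    list(g = g, s = s, intensity = matrix(NA_real_, nrow(g), ncol(g)),
         harmonic = as.integer(meta$harmonic),
         omega = 2 * pi * meta$harmonic / meta$period_ns,
         period = meta$period_ns, n_bins = meta$n_bins,
         calibrated = isTRUE(meta$calibrated)),
    class = "phasor_field"
  )
}

#' Write / read an ROI label image
#'
#' 16-bit TIFF (or PNG) of integer labels; bit-exact for labels up to
#' 65535.
#'
#' @param rois An [roi_set()] or label matrix.
#' @param path Path ending in `.tif`/`.tiff` or `.png`. Group tags, when
#'   present, go to a JSON sidecar.
#' @return `write_roi()` returns `path` invisibly; `read_roi()` an
#'   [roi_set()].
#' @export
write_roi <- function(rois, path) {
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    # writePNG stores 8-bit samples
    if (any(rois$labels > 255)) {
      stop("labels exceed the 8-bit PNG range; use TIFF", call. = FALSE)
    }
    png::writePNG(rois$labels / 255, path)
  } else {
    if (any(rois$labels > 65535)) {
      stop("labels exceed 16-bit range", call. = FALSE)
    }
    tiff::writeTIFF(rois$labels / 65535, path, bits.per.sample = 16L,
                    reduce = FALSE)
  }
  if (!all(is.na(rois$groups$group))) {
    jsonlite::write_json(rois$groups, sidecar_path(path), digits = NA)
  }
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  labels <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    round(png::readPNG(path) * 255)
  } else {
    round(tiff::readTIFF(path) * 65535)
  }
  sc <- sidecar_path(path)
  groups <- if (file.exists(sc)) {
    jsonlite::read_json(sc, simplifyVector = TRUE)
  } else {
    NULL
  }
  roi_set(labels, groups)
}

#' Write / read cell-phasor records as CSV
#'
#' Standard header: `roi_label, group, g_mean, s_mean, n_pixels,
#' total_counts, free_fraction`.
#'
#' @param records A cell-phasor record tibble.
#' @param path CSV path.
#' @return `write_records()` returns `path` invisibly; `read_records()` a
#'   tibble.
#' @export
write_records <- function(records, path) {
  cols <- c("roi_label", "group", "g_mean", "s_mean", "n_pixels",
            "total_counts", "free_fraction")
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop(sprintf("records lack column(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run configuration
#'
#' A validated bundle of the acquisition and analysis parameters shared
#' across pipeline stages; round-trips losslessly through YAML or JSON.
#'
#' @param rep_rate_MHz Laser repetition rate in MHz (default 80).
#' @param n_bins Time bins per period (default 256).
#' @param harmonic Analysis harmonic (default 1).
#' @param free_tau,bound_tau Cursor endpoint lifetimes in ns.
#' @param min_counts Background cut in photons (default 30).
#' @param smooth Median-smooth rendered maps (default `FALSE`).
#' @param seed Default RNG seed (default 1).
#' @return A list of class `run_config`.
#' @export
run_config <- function(rep_rate_MHz = 80, n_bins = 256L, harmonic = 1L,
                       free_tau = 0.4, bound_tau = 3.2, min_counts = 30,
                       smooth = FALSE, seed = 1L) {
  for (v in c(rep_rate_MHz, n_bins, harmonic, free_tau, bound_tau, min_counts)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stop("all physical configuration quantities must be positive scalars",
           call. = FALSE)
    }
  }
  structure(
    list(rep_rate_MHz = as.numeric(rep_rate_MHz), n_bins = as.integer(n_bins),
         harmonic = as.integer(harmonic), free_tau = as.numeric(free_tau),
         bound_tau = as.numeric(bound_tau), min_counts = as.numeric(min_counts),
         smooth = isTRUE(smooth), seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path `.yaml`/`.yml` or `.json` path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, x)
}
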