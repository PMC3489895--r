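#' Region-of-interest set for a FLIM image
#'
#' Regions are supplied as a label image: one positive integer per ROI,
#' 0 for background, mirroring manual cell segmentation. Each label may
#' carry a group tag (cell type or condition) used by the population
#' statistics.
#'
#' @param labels Integer matrix of per-pixel labels (0 = background).
#' @param groups Optional named character vector or tibble mapping labels
#'   to group tags; unnamed labels get group `NA`.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(labels, groups = NULL) {
  labels <- as.matrix(labels)
  if (anyNA(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("ROI labels must be non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  if (is.null(groups)) {
    group_tbl <- tibble::tibble(roi_label = ids, group = NA_character_)
  } else if (is.data.frame(groups)) {
    group_tbl <- tibble::tibble(roi_label = as.integer(groups$roi_label),
                                group = as.character(groups$group))
  } else {
    group_tbl <- tibble::tibble(
      roi_label = as.integer(names(groups)),
      group = as.character(unname(groups))
    )
  }
  structure(list(labels = labels, groups = group_tbl), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d x %d pixels, %d ROIs\n",
              nrow(x$labels), ncol(x$labels), nrow(x$groups)))
  invisible(x)
}

#' Per-cell average phasor ("cell phasor")
#'
#' Averages the per-pixel phasor over the defined pixels of one ROI. The
#' average is intensity-weighted, which makes it algebraically identical
#' to the phasor of the pooled (summed) decay of the ROI — the cell-phasor
#' definition under which photon-poor pixels do not inflate the variance.
#' An unweighted pixel mean is available for sensitivity checks.
#'
#' @param field A `phasor_field`.
#' @param rois An [roi_set()] (or a bare label matrix) with the field's
#'   dimensions.
#' @param cursor Optional [species_cursor()]; when given, each record also
#'   carries the free fraction of the cell phasor.
#' @param weighted Intensity-weighted average (default `TRUE`).
#' @return A tibble of cell-phasor records: `roi_label`, `group`,
#'   `g_mean`, `s_mean`, `n_pixels`, `total_counts`, `free_fraction`.
#' @seealso [summarize_groups()], [compare_groups()]
#' @export
cell_phasors <- function(field, rois, cursor = NULL, weighted = TRUE) {
  stopifnot(inherits(field, "phasor_field"))
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois)
  if (!all(dim(rois$labels) == dim(field$g))) {
    stop("ROI label image and phasor field dimensions differ", call. = FALSE)
  }
  lab <- as.vector(rois$labels)
  g <- as.vector(field$g)
  s <- as.vector(field$s)
  w <- as.vector(field$intensity)
  defined <- !is.na(g) & lab > 0L
  if (!any(defined)) stop("no ROI contains a defined pixel", call. = FALSE)
  df <- tibble::tibble(
    roi_label = lab[defined], g = g[defined], s = s[defined], w = w[defined]
  )
  recs <- df |>
    dplyr::group_by(.data$roi_label) |>
    dplyr::summarise(
      g_mean = if (weighted) sum(.data$w * .data$g) / sum(.data$w) else mean(.data$g),
      s_mean = if (weighted) sum(.data$w * .data$s) / sum(.data$w) else mean(.data$s),
      n_pixels = dplyr::n(),
      total_counts = sum(.data$w),
      .groups = "drop"
    )
  empty <- setdiff(rois$groups$roi_label, recs$roi_label)
  if (length(empty)) {
    stop(sprintf("ROI(s) without defined pixels: %s",
                 paste(empty, collapse = ", ")), call. = FALSE)
  }
  recs <- dplyr::left_join(recs, rois$groups, by = "roi_label") |>
    dplyr::relocate("group", .after = "roi_label")
  recs$free_fraction <- if (!is.null(cursor)) {
    free_bound_fraction(recs$g_mean, cursor, s = recs$s_mean)
  } else {
    NA_real_
  }
  recs
}

#' Cell phasor of a single ROI
#'
#' @inheritParams cell_phasors
#' @param roi_label The label to summarise.
#' @return A one-row tibble (see [cell_phasors()]).
#' @export
cell_phasor <- function(field, rois, roi_label, cursor = NULL, weighted = TRUE) {
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois)
  recs <- cell_phasors(field, rois, cursor = cursor, weighted = weighted)
  rec <- recs[recs$roi_label == roi_label, ]
  if (nrow(rec) == 0L) {
    stop(sprintf("ROI %s has no defined pixels", roi_label), call. = FALSE)
  }
  rec
}

#' Back-project a phasor-plot region to an image mask
#'
#' Cluster identification in reverse: selects the image pixels whose
#' phasor falls inside a region of the phasor plot (a circle or polygon),
#' boundary inclusive. Undefined pixels are never selected.
#'
#' @param field A `phasor_field`.
#' @param region Either `list(center = c(g, s), radius = r)` or
#'   `list(vertices = <N x 2 matrix or data frame>)` (a simple polygon).
#' @return A logical matrix mask with the field's dimensions.
#' @examples
#' sim <- simulate_cell_image(frame = c(32, 32), n_bins = 64, seed = 1)
#' field <- image_phasor_field(sim$image)
#' mask <- phasor_cursor_select(field, list(center = c(0.5, 0.4), radius = 0.3))
#' @export
phasor_cursor_select <- function(field, region) {
  stopifnot(inherits(field, "phasor_field"), is.list(region))
  g <- as.vector(field$g)
  s <- as.vector(field$s)
  inside <- rep(FALSE, length(g))
  ok <- !is.na(g)
  if (!is.null(region$center)) {
    if (is.null(region$radius) || region$radius <= 0) {
      stop("circle region needs a positive `radius`", call. = FALSE)
    }
    d2 <- (g[ok] - region$center[1L])^2 + (s[ok] - region$center[2L])^2
    inside[ok] <- d2 <= region$radius^2
  } else if (!is.null(region$vertices)) {
    v <- as_gs_matrix(region$vertices)
    if (nrow(v) < 3L) stop("polygon region needs >= 3 vertices", call. = FALSE)
    inside[ok] <- point_in_polygon(g[ok], s[ok], v)
  } else {
    stop("region must have `center`/`radius` or `vertices`", call. = FALSE)
  }
  matrix(inside, nrow(field$g), ncol(field$g))
}

# even-odd ray casting, boundary inclusive within a small tolerance
point_in_polygon <- function(x, y, v, tol = 1e-12) {
  n <- nrow(v)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    # boundary test: point within tol of segment i-j
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) pmin(pmax(((x - xi) * dx + (y - yi) * dy) / len2, 0), 1) else 0
    d2 <- (x - (xi + t * dx))^2 + (y - (yi + t * dy))^2
    on_edge <- on_edge | d2 <= tol
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

#' Frame-to-frame stability of cell phasors
#'
#' Repeated scanning of the same field of view should leave the phasor
#' signature unchanged if the sample is not photobleaching or photodamaged.
#' Frames are pooled in fixed consecutive blocks (default 10 frames, the
#' usual acquisition block), a cell phasor is computed per block and per
#' ROI, and each ROI gets (i) the standard deviation of g across blocks
#' (delta g) and (ii) a linear trend of g over block index with a 95%
#' confidence interval — a drift detector.
#'
#' @param frames A list of [flim_image()]s with identical geometry.
#' @param rois An [roi_set()] (or label matrix).
#' @param frame_group_size Frames pooled per block (default 10).
#' @param harmonic,cal,min_counts Passed to [image_phasor_field()].
#' @param cursor Optional [species_cursor()] for per-block free fractions.
#' @return An object of class `frame_stability`: `records` (tibble with
#'   one row per ROI x block) and `summary` (tibble with `roi_label`,
#'   `delta_g`, `slope`, `slope_lo`, `slope_hi`, `drift_detected`).
#' @export
frame_stability <- function(frames, rois, frame_group_size = 10L,
                            harmonic = 1L, cal = NULL, min_counts = 30,
                            cursor = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  if (!inherits(rois, "roi_set")) rois <- roi_set(rois)
  dims <- lapply(frames, function(f) {
    stopifnot(inherits(f, "flim_image"))
    dim(f$counts)
  })
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all frames must have identical dimensions", call. = FALSE)
  }
  n_groups <- length(frames) %/% frame_group_size
  if (n_groups < 2L) {
    stop("need at least 2 full frame groups for a stability analysis",
         call. = FALSE)
  }
  records <- purrr::map_dfr(seq_len(n_groups), function(gi) {
    idx <- ((gi - 1L) * frame_group_size + 1L):(gi * frame_group_size)
    pooled <- Reduce(`+`, lapply(frames[idx], `[[`, "counts"))
    img <- flim_image(pooled, period = frames[[1L]]$period,
                      rep_rate_MHz = frames[[1L]]$rep_rate_MHz,
                      excitation_nm = frames[[1L]]$excitation_nm)
    field <- image_phasor_field(img, harmonic = harmonic, cal = cal,
                                min_counts = min_counts)
    dplyr::mutate(cell_phasors(field, rois, cursor = cursor),
                  frame_group = gi, .before = 1L)
  })
  summary <- records |>
    dplyr::group_by(.data$roi_label) |>
    dplyr::group_modify(function(d, key) {
      fit <- stats::lm(g_mean ~ frame_group, data = d)
      if (stats::df.residual(fit) < 1L) {
        # two blocks fix the line exactly; no trend inference possible
        ci <- c(NA_real_, NA_real_)
      } else {
        # identical frames give a zero-residual fit; the CI is then [0, 0]
        ci <- withCallingHandlers(
          stats::confint(fit, "frame_group", level = 0.95),
          warning = function(w) {
            if (grepl("essentially perfect fit", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          }
        )
      }
      tibble::tibble(
        delta_g = stats::sd(d$g_mean),
        slope = stats::coef(fit)[["frame_group"]],
        slope_lo = ci[1L], slope_hi = ci[2L],
        drift_detected = if (anyNA(ci)) NA else ci[1L] > 0 || ci[2L] < 0
      )
    }) |>
    dplyr::ungroup()
  structure(list(records = records, summary = summary,
                 frame_group_size = frame_group_size),
            class = "frame_stability")
}

#' @export
print.frame_stability <- function(x, ...) {
  cat(sprintf("<frame_stability> %d ROIs x %d frame groups (%d frames each)\n",
              nrow(x$summary), max(x$records$frame_group), x$frame_group_size))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.frame_stability <- function(x, ...) x$records

#' @export
glance.frame_stability <- function(x, ...) x$summary
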