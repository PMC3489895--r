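#' Per-group summaries of cell-phasor records
#'
#' Summarises cell phasors by group: number of cells, mean g and s, the
#' heterogeneity measure delta g (sample standard deviation of the cell
#' g coordinates, n - 1 denominator), and the mean free-NADH fraction.
#'
#' @param records A tibble of cell-phasor records (see [cell_phasors()]),
#'   with columns `group`, `g_mean`, `s_mean` and optionally
#'   `free_fraction`.
#' @return A tibble with one row per group: `group`, `n_cells`, `mean_g`,
#'   `mean_s`, `delta_g`, `mean_free_fraction`. Errors if any group has
#'   fewer than 2 records.
#' @examples
#' recs <- tibble::tibble(group = rep(c("E12", "neuron"), each = 3),
#'                        g_mean = c(0.4, 0.45, 0.5, 0.6, 0.65, 0.7),
#'                        s_mean = 0.4, free_fraction = NA)
#' summarize_groups(recs)
#' @export
summarize_groups <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 2L) {
    stop("insufficient data: need >= 2 records", call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_g = mean(.data$g_mean),
      mean_s = mean(.data$s_mean),
      delta_g = stats::sd(.data$g_mean),
      mean_free_fraction = if ("free_fraction" %in% names(records)) {
        mean(.data$free_fraction)
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::rename(group = "group")
  if (any(out$n_cells < 2L)) {
    stop("insufficient data: every group needs >= 2 records for a std",
         call. = FALSE)
  }
  out
}

#' Two-group comparison of cell phasors
#'
#' Welch two-sample t-test (unequal variances, two-sided by default) on a
#' chosen coordinate of the cell-phasor records — by default the g
#' coordinate, the axis along which metabolic shifts between free- and
#' bound-NADH-dominated populations express themselves. Under a fixed
#' cursor the free fraction is monotonically related to g and can be
#' tested instead.
#'
#' Two groups with identical means and zero pooled variance return
#' `statistic = 0`, `p.value = 1` (no evidence of a difference) rather
#' than erroring on constant data.
#'
#' @param records A tibble of cell-phasor records containing exactly two
#'   groups, or the first of two tibbles.
#' @param records_b Optional second tibble; then `records` is group A.
#' @param coordinate Column tested: `"g_mean"` (default) or
#'   `"free_fraction"` (or `"s_mean"`).
#' @param var_equal Pooled-variance Student test instead of Welch
#'   (default `FALSE`).
#' @param alternative Passed to [stats::t.test()] (default two-sided).
#' @return An object of class `phasor_group_test` wrapping the `htest`,
#'   with [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' a <- tibble::tibble(group = "A", g_mean = c(1, 2, 3))
#' b <- tibble::tibble(group = "B", g_mean = c(4, 5, 6))
#' compare_groups(a, b) # Welch t = -3.674
#' @export
compare_groups <- function(records, records_b = NULL, coordinate = "g_mean",
                           var_equal = FALSE, alternative = "two.sided") {
  if (!is.null(records_b)) {
    ga <- if (!is.null(records$group)) as.character(records$group[1L]) else "A"
    gb <- if (!is.null(records_b$group)) as.character(records_b$group[1L]) else "B"
    if (identical(ga, gb)) {
      gb <- paste0(gb, ".2")
    }
    x <- records[[coordinate]]
    y <- records_b[[coordinate]]
  } else {
    stopifnot(is.data.frame(records), "group" %in% names(records))
    groups <- unique(as.character(records$group))
    if (length(groups) != 2L) {
      stop("`records` must contain exactly two groups", call. = FALSE)
    }
    ga <- groups[1L]
    gb <- groups[2L]
    x <- records[[coordinate]][records$group == ga]
    y <- records[[coordinate]][records$group == gb]
  }
  if (is.null(x) || is.null(y)) {
    stop(sprintf("records lack the `%s` column", coordinate), call. = FALSE)
  }
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: each group needs >= 2 records", call. = FALSE)
  }
  ht <- tryCatch(
    stats::t.test(x, y, var.equal = var_equal, alternative = alternative),
    error = function(e) {
      if (grepl("constant", conditionMessage(e)) && isTRUE(all.equal(mean(x), mean(y)))) {
        structure(
          list(statistic = c(t = 0), parameter = c(df = length(x) + length(y) - 2),
               p.value = 1, estimate = c(`mean of x` = mean(x), `mean of y` = mean(y)),
               conf.int = c(0, 0), method = "Two Sample t-test (degenerate: constant data)",
               alternative = alternative, data.name = "x and y"),
          class = "htest"
        )
      } else {
        stop(e)
      }
    }
  )
  structure(
    list(htest = ht, group_a = ga, group_b = gb, coordinate = coordinate,
         n_a = length(x), n_b = length(y),
         welch = !var_equal),
    class = "phasor_group_test"
  )
}

#' @export
print.phasor_group_test <- function(x, ...) {
  cat(sprintf(
    "<phasor_group_test> %s: %s (n=%d) vs %s (n=%d)\n  t = %.4g, df = %.4g, p = %.4g (%s)\n",
    x$coordinate, x$group_a, x$n_a, x$group_b, x$n_b,
    unname(x$htest$statistic), unname(x$htest$parameter), x$htest$p.value,
    if (x$welch) "Welch" else "pooled variance"
  ))
  invisible(x)
}

#' @export
tidy.phasor_group_test <- function(x, ...) {
  ht <- x$htest
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b, coordinate = x$coordinate,
    estimate = unname(ht$estimate[1L] - ht$estimate[2L]),
    mean_a = unname(ht$estimate[1L]), mean_b = unname(ht$estimate[2L]),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value,
    conf.low = ht$conf.int[1L], conf.high = ht$conf.int[2L],
    method = ht$method, alternative = ht$alternative
  )
}

#' @export
glance.phasor_group_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$htest$statistic), df = unname(x$htest$parameter),
    p.value = x$htest$p.value, n_a = x$n_a, n_b = x$n_b
  )
}

#' Metabolic-trajectory ordering of group summaries
#'
#' Along the metabolic trajectory from a glycolytic phenotype (high
#' free/bound NADH) to an oxidative-phosphorylation phenotype (low
#' free/bound NADH), progenitor populations precede differentiated
#' neurons. Checks whether the group mean free fractions strictly
#' decrease along a stated order (equivalently, whether g decreases along
#' the configured cursor direction).
#'
#' @param summaries A tibble from [summarize_groups()].
#' @param order Character vector of group tags in the expected order,
#'   e.g. `c("E12", "E16", "neuron")`.
#' @param by Column to order on: `"mean_free_fraction"` (default) or
#'   `"mean_g"`.
#' @return A list of class `trajectory_order` with `ordered` (logical
#'   verdict), `by`, `order` and the values along it.
#' @examples
#' s <- tibble::tibble(group = c("E12", "E16", "neuron"),
#'                     mean_free_fraction = c(0.7, 0.6, 0.4))
#' trajectory_order(s)$ordered # TRUE
#' @export
trajectory_order <- function(summaries, order = c("E12", "E16", "neuron"),
                             by = "mean_free_fraction") {
  stopifnot(is.data.frame(summaries), by %in% names(summaries))
  missing <- setdiff(order, summaries$group)
  if (length(missing)) {
    stop(sprintf("summaries lack group(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  vals <- summaries[[by]][match(order, summaries$group)]
  structure(
    list(ordered = all(diff(vals) < 0), by = by, order = order, values = vals),
    class = "trajectory_order"
  )
}

#' @export
print.trajectory_order <- function(x, ...) {
  cat(sprintf(
    "<trajectory_order> %s: %s -> %s\n",
    if (x$ordered) "strictly decreasing" else "NOT monotone",
    paste(x$order, collapse = " > "),
    paste(sprintf("%.4g", x$values), collapse = ", ")
  ))
  invisible(x)
}
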