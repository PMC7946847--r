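# Scoring: pair-correct accuracy aggregation, the ascending 75 %-criterion
# threshold per meridian, and attention-window (AW) reconstruction.

#' Aggregate trial records into accuracy cells
#'
#' Pools the two diagonal meridians into one `"diagonal"` class (the
#' meridian factor of the analysis has three levels) and computes the exact
#' pair-correct accuracy `n_correct / n_trials` per grouping cell. Under the
#' default design this gives 9 trials per separation for the horizontal and
#' vertical classes and 18 for the pooled diagonal class.
#'
#' @param records Trial-record tibble with at least `meridian`,
#'   `separation_deg` and `correct` columns (see [simulate_responses()]).
#' @param by Extra grouping columns (e.g. `"subject"`, `"version"`,
#'   `"cue_validity"`). Defaults to `"subject"` when present.
#' @param pool_diagonals Pool `diagonal1`/`diagonal2` into `"diagonal"`
#'   (default `TRUE`). When `FALSE` the raw meridian is kept.
#' @return A tibble of accuracy cells: grouping columns, `meridian_class`,
#'   `separation_deg`, `n_trials`, `n_correct`, `accuracy`.
#' @export
score_records <- function(records, by = NULL, pool_diagonals = TRUE) {
  stopifnot(all(c("meridian", "separation_deg", "correct") %in% names(records)))
  if (is.null(by)) by <- intersect("subject", names(records))
  records$meridian_class <-
    if (pool_diagonals) meridian_class(records$meridian) else records$meridian
  out <- records |>
    group_by(across(all_of(c(by, "meridian_class", "separation_deg")))) |>
    summarise(
      n_trials = dplyr::n(),
      n_correct = sum(.data$correct),
      accuracy = sum(.data$correct) / dplyr::n(),
      .groups = "drop"
    ) |>
    arrange(across(all_of(c(by, "meridian_class", "separation_deg"))))
  out
}

#' Ascending threshold on one accuracy profile
#'
#' The sequential measurement rule: starting from the smallest separation
#' and ascending the grid, the threshold is the separation immediately below
#' the first separation whose accuracy falls below the criterion
#' ("at least 75 %" is inclusive, so accuracy exactly at criterion passes).
#' If no separation fails, the threshold is the largest tested separation
#' (ceiling-censored); if the smallest separation already fails, the
#' threshold is 0 (floor-censored). Later recoveries above criterion are
#' ignored: the scan stops at the first failure.
#'
#' @param accuracy Accuracies ordered by ascending separation; must cover
#'   the full grid (no `NA`).
#' @param separations The ascending separation grid (degrees), same length.
#' @param criterion Pass criterion, default 0.75 (inclusive).
#' @return A one-row tibble: `threshold_deg`, `censoring` (`"none"`,
#'   `"floor"`, `"ceiling"`).
#' @examples
#' # accuracy first drops below criterion at 30 deg -> threshold 25 deg
#' estimate_threshold(c(1, .9, .85, .8, .6, .9, .5, .4), seq(10, 45, 5))
#' @export
estimate_threshold <- function(accuracy, separations, criterion = 0.75) {
  if (length(accuracy) != length(separations) || anyNA(accuracy)) {
    abort("`accuracy` must cover the full separation grid with no gaps.")
  }
  if (is.unsorted(separations, strictly = TRUE)) {
    abort("`separations` must be strictly increasing.")
  }
  res <- threshold_scan(accuracy, separations, criterion)
  tibble(threshold_deg = res$threshold_deg, censoring = res$censoring)
}

# bare-vector core of the ascending scan (no validation, no tibble)
threshold_scan <- function(accuracy, separations, criterion) {
  first_fail <- which(accuracy < criterion)[1]
  if (is.na(first_fail)) {
    list(threshold_deg = separations[length(separations)],
         censoring = "ceiling")
  } else if (first_fail == 1L) {
    list(threshold_deg = 0, censoring = "floor")
  } else {
    list(threshold_deg = separations[first_fail - 1L], censoring = "none")
  }
}

#' Thresholds for every accuracy-cell group
#'
#' Applies [estimate_threshold()] to each (grouping x meridian class)
#' profile of a [score_records()] table. Every group must cover the full
#' separation grid: the sequential rule is gap-intolerant.
#'
#' @param cells Accuracy-cell tibble from [score_records()].
#' @param criterion Pass criterion, default 0.75.
#' @param separations The full separation grid the cells must cover;
#'   defaults to the sorted unique separations present in `cells`.
#' @param on_missing `"error"` (default) aborts when a profile misses a grid
#'   point; `"drop"` scans only the separations observed for that profile —
#'   intended for sparse condition splits (e.g. the 20 % invalid-cue subset)
#'   where some cells can be empty by chance.
#' @return A tibble with the grouping columns, `meridian_class`,
#'   `threshold_deg` and `censoring`.
#' @export
estimate_thresholds <- function(cells, criterion = 0.75, separations = NULL,
                                on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  separations <- separations %||% sort(unique(cells$separation_deg))
  keys <- setdiff(names(cells),
                  c("separation_deg", "n_trials", "n_correct", "accuracy"))
  cells |>
    group_by(across(all_of(keys))) |>
    group_modify(function(d, g) {
      d <- arrange(d, .data$separation_deg)
      complete <- identical(as.numeric(d$separation_deg),
                            as.numeric(separations))
      if (!complete && on_missing == "error") {
        abort(paste0(
          "Accuracy profile does not cover the full separation grid for ",
          "group: ", paste(unlist(g), collapse = "/"), "."
        ))
      }
      estimate_threshold(d$accuracy, d$separation_deg, criterion)
    }) |>
    ungroup()
}

aw_angle_meridian <- function() {
  # half-meridian angles of the octagon and the meridian each belongs to
  tibble(
    angle_deg = seq(0, 315, by = 45),
    meridian = c("horizontal", "diagonal1", "vertical", "diagonal2",
                 "horizontal", "diagonal1", "vertical", "diagonal2")
  )
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Reconstruct the attention window from meridian thresholds
#'
#' Draws the attention window the way the task defines it: each threshold
#' separation places two endpoints at radius `threshold / 2` on the two
#' halves of its meridian, and the window is the octagon connecting the
#' eight endpoints in angular order (0, 45, ..., 315 degrees). The polygon
#' area follows from the shoelace formula; a fitted-ellipse area using the
#' convention `pi * (H/2)/2 * (V/2)/2` and the horizontal-to-vertical aspect
#' ratio are attached as secondary descriptors.
#'
#' @param thresholds Named numeric vector of threshold separations in
#'   degrees. Names must include `horizontal` and `vertical` plus either
#'   both `diagonal1` and `diagonal2` or a single pooled `diagonal` value
#'   applied to both.
#' @return An object of class `awt_window`: thresholds, the eight polar
#'   vertices, `polygon_area_deg2`, `ellipse_area_deg2` and `aspect_ratio`.
#' @examples
#' aw <- build_attention_window(
#'   c(horizontal = 40, vertical = 20, diagonal = 30))
#' aw$polygon_area_deg2
#' @export
build_attention_window <- function(thresholds) {
  thr <- as.list(thresholds)
  if (!is.null(thr$diagonal) && is.null(thr$diagonal1)) {
    thr$diagonal1 <- thr$diagonal
    thr$diagonal2 <- thr$diagonal
  }
  need <- c("horizontal", "vertical", "diagonal1", "diagonal2")
  if (!all(need %in% names(thr))) {
    abort("`thresholds` must name horizontal, vertical and diagonal values.")
  }
  thr <- unlist(thr[need])
  if (any(thr < 0)) abort("Thresholds must be non-negative.")
  vertices <- aw_angle_meridian()
  vertices$radius_deg <- unname(thr[vertices$meridian] / 2)
  theta <- vertices$angle_deg * pi / 180
  vertices$x <- vertices$radius_deg * cos(theta)
  vertices$y <- vertices$radius_deg * sin(theta)
  structure(
    list(
      thresholds = thr,
      vertices = vertices,
      polygon_area_deg2 = shoelace_area(vertices$x, vertices$y),
      ellipse_area_deg2 = pi * (thr[["horizontal"]] / 4) * (thr[["vertical"]] / 4),
      aspect_ratio = if (thr[["vertical"]] > 0) {
        thr[["horizontal"]] / thr[["vertical"]]
      } else {
        NA_real_
      }
    ),
    class = "awt_window"
  )
}

#' @export
print.awt_window <- function(x, ...) {
  cat("<awt_window>\n")
  cat("  thresholds (deg):",
      paste(sprintf("%s=%g", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  cat(sprintf("  polygon area: %.1f deg^2   ellipse area: %.1f deg^2   H/V: %s\n",
              x$polygon_area_deg2, x$ellipse_area_deg2,
              ifelse(is.na(x$aspect_ratio), "NA",
                     sprintf("%.2f", x$aspect_ratio))))
  invisible(x)
}

#' @describeIn build_attention_window Tidy the window into one vertex per row.
#' @param x An `awt_window` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.awt_window <- function(x, ...) {
  as_tibble(x$vertices)
}

#' @describeIn build_attention_window One-row summary of window geometry.
#' @exportS3Method generics::glance
glance.awt_window <- function(x, ...) {
  tibble(
    polygon_area_deg2 = x$polygon_area_deg2,
    ellipse_area_deg2 = x$ellipse_area_deg2,
    aspect_ratio = x$aspect_ratio,
    horizontal_deg = x$thresholds[["horizontal"]],
    vertical_deg = x$thresholds[["vertical"]]
  )
}

#' Plot an attention window
#'
#' Draws the endpoint octagon around fixation, with the meridian endpoints
#' marked. Axes are degrees of visual angle from fixation.
#'
#' @param object An `awt_window`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.awt_window <- function(object, ...) {
  v <- object$vertices
  ggplot2::ggplot(v, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_polygon(fill = "steelblue", alpha = 0.3, colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$meridian), size = 2) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "horizontal eccentricity (deg)",
      y = "vertical eccentricity (deg)",
      title = sprintf("Attention window, %.0f deg²",
                      object$polygon_area_deg2)
    ) +
    ggplot2::theme_minimal()
}
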