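# Branching of CAF cohorts, quantified through convexity defects: regions
# where the contour bends away from its convex hull. Each sufficiently
# deep defect is counted as one cellular extension (branch).

#' Convex hull of a contour
#'
#' Smallest convex polygon containing all contour points, returned
#' counter-clockwise in the x-right / y-down image coordinate frame.
#'
#' @param contour n x 2 matrix of (x, y) points, n >= 3, not all collinear.
#' @return integer vector of row indices into `contour`, in hull order.
#' @export
convex_hull <- function(contour) {
  if (nrow(contour) < 3) stopf("need >= 3 contour points")
  idx <- chull(contour[, 1], contour[, 2])
  if (length(idx) < 3)
    stopf("contour points are collinear; hull is degenerate")
  # grDevices::chull returns clockwise order for y-up axes, which is
  # counter-clockwise in image coordinates (y grows downward)
  idx
}

# signed perpendicular distance of points P to the line through a and b
chord_distance <- function(p, a, b) {
  v <- b - a
  L <- sqrt(sum(v^2))
  if (L == 0) return(sqrt((p[, 1] - a[1])^2 + (p[, 2] - a[2])^2))
  abs((p[, 1] - a[1]) * v[2] - (p[, 2] - a[2]) * v[1]) / L
}

#' Convexity defects of a closed contour
#'
#' One defect per hull gap: for each pair of hull vertices consecutive
#' along the contour, the contour run between them is examined and the
#' point farthest from the hull chord is recorded together with its
#' distance (defect depth).
#'
#' @param contour n x 2 matrix of ordered (x, y) contour vertices.
#' @param hull hull indices from [convex_hull()] on this contour.
#' @return list of `ConvexityDefect` objects (`start_vertex`,
#'   `end_vertex`, `farthest_point` -- 1-based contour indices -- and
#'   `depth` in pixels); empty for a convex contour.
#' @export
convexity_defects <- function(contour, hull) {
  n <- nrow(contour)
  hs <- sort(unique(hull))
  defects <- list()
  for (g in seq_along(hs)) {
    i0 <- hs[g]
    i1 <- if (g < length(hs)) hs[g + 1] else hs[1]
    run <- if (i1 > i0) {
      if (i1 - i0 < 2) integer(0) else (i0 + 1):(i1 - 1)
    } else {
      c(if (i0 < n) (i0 + 1):n else integer(0),
        if (i1 > 1) 1:(i1 - 1) else integer(0))
    }
    if (length(run) == 0) next
    d <- chord_distance(contour[run, , drop = FALSE],
                        contour[i0, ], contour[i1, ])
    k <- which.max(d)
    if (d[k] <= 0) next
    defects[[length(defects) + 1]] <-
      structure(list(start_vertex = i0, end_vertex = i1,
                     farthest_point = run[k], depth = unname(d[k])),
                class = "ConvexityDefect")
  }
  defects
}

#' Branch metrics of one cohort contour
#'
#' Convexity defects deeper than `depth_threshold` are counted as reliable
#' extensions; shallower ones are treated as rasterization noise.
#'
#' @param contour n x 2 matrix of ordered (x, y) contour vertices.
#' @param depth_threshold minimum defect depth in pixels (default 5).
#' @return list of class `BranchMetrics`: `n_extensions`,
#'   `extension_sizes` (depths, px) and `mean_extension_size` (0 when
#'   there are no extensions).
#' @export
branch_metrics <- function(contour, depth_threshold = 5) {
  empty <- structure(list(n_extensions = 0L, extension_sizes = numeric(0),
                          mean_extension_size = 0), class = "BranchMetrics")
  if (nrow(contour) < 3) return(empty)
  hull <- tryCatch(convex_hull(contour), error = function(e) NULL)
  if (is.null(hull)) return(empty)
  defects <- convexity_defects(contour, hull)
  depths <- vapply(defects, `[[`, 0, "depth")
  depths <- depths[depths > depth_threshold]
  structure(list(n_extensions = length(depths), extension_sizes = depths,
                 mean_extension_size = if (length(depths))
                   mean(depths) else 0),
            class = "BranchMetrics")
}

#' Per-frame branching summary of a mask sequence
#'
#' For every frame, branch metrics are computed per cohort (components
#' below `min_area` are excluded) and averaged across cohorts.
#'
#' @param masks cleaned [mask_sequence()].
#' @param depth_threshold minimum defect depth (px).
#' @param min_area smallest cohort included (px).
#' @return data frame with `frame`, `n_cohorts`, `mean_extensions`,
#'   `mean_extension_size` (`NaN` for frames without cohorts).
#' @export
branching_series <- function(masks, depth_threshold = 5, min_area = 50) {
  rows <- lapply(seq_along(masks$frames), function(t) {
    cohorts <- extract_cohorts(clean_mask(masks$frames[[t]], min_area))
    if (length(cohorts) == 0)
      return(data.frame(frame = t, n_cohorts = 0L,
                        mean_extensions = NaN, mean_extension_size = NaN))
    bm <- lapply(cohorts, function(co)
      branch_metrics(co$contour, depth_threshold))
    data.frame(frame = t, n_cohorts = length(cohorts),
               mean_extensions = mean(vapply(bm, `[[`, 0L,
                                             "n_extensions")),
               mean_extension_size = mean(vapply(bm, `[[`, 0,
                                                 "mean_extension_size")))
  })
  do.call(rbind, rows)
}
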