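# End-point morphometrics of segmented tumor organoids and the group
# statistics of a multi-parametric screen. Parameter definitions follow
# the conventions of high-content 3D organoid analysis: Area in pixels,
# Roundness = 4*pi*Area/Perimeter^2 (1 for a perfect disc), appendages
# are thin protrusions beyond the morphologically opened "body".

# chain-code perimeter of a traced contour with Kulpa's corner correction
# (a raw Freeman chain overestimates smooth boundaries by ~5%)
contour_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2) return(0)
  nxt <- c(2:n, 1)
  dx <- abs(contour[nxt, 1] - contour[, 1])
  dy <- abs(contour[nxt, 2] - contour[, 2])
  straight <- sum(pmax(dx, dy) == 1 & pmin(dx, dy) == 0)
  diag_ <- sum(dx == 1 & dy == 1)
  0.9481 * (straight + sqrt(2) * diag_)
}

mask_roundness <- function(mask) {
  area <- sum(mask != 0)
  if (area == 0) return(NA_real_)
  lab <- cpp_label(mask != 0, 8L)
  contour <- cpp_trace_contour(lab, 1L)
  p <- contour_perimeter(cbind(contour[, 2], contour[, 1]))
  if (p <= 0) return(1)
  min(1, 4 * pi * area / p^2)
}

#' Morphometric parameters of one organoid
#'
#' * `Area`: object pixel count.
#' * `Roundness`: `4*pi*Area/Perimeter^2` in (0, 1], 1 = perfect disc;
#'   loss of roundness marks loss of the epithelial organoid phenotype.
#' * `FiltRound`: Roundness of the object after morphological opening
#'   removes its appendages.
#' * `Density`: mean segmented-structure intensity (red channel).
#' * `AppNumber`, `MaxApp`, `MedApp`: count, maximum and median length of
#'   appendages (invasive protrusions): connected parts of the object
#'   outside the opened body, measured as the farthest Euclidean distance
#'   from the body.
#' * `CellNumber`: calibrated estimate `Area / mean_cell_area`.
#'
#' @param object_mask binary matrix containing a single connected object.
#' @param intensity_img matched intensity image.
#' @param mean_cell_area calibration constant (px^2/cell, default 250).
#' @param body_open_radius opening disc radius separating body from
#'   appendages (px, default 4).
#' @param min_app_area smallest pixel count counted as an appendage.
#' @return one-row data frame (class `OrganoidRecord`).
#' @export
measure_organoid <- function(object_mask, intensity_img,
                             mean_cell_area = 250, body_open_radius = 4,
                             min_app_area = 5) {
  m <- (object_mask != 0) * 1L
  area <- sum(m)
  if (area == 0) stopf("empty object mask")
  if (!identical(dim(m), dim(intensity_img)))
    stopf("mask and intensity image shapes differ")
  roundness <- mask_roundness(m)
  density <- mean(intensity_img[m == 1])
  brush <- EBImage::makeBrush(2 * body_open_radius + 1, shape = "disc")
  body <- EBImage::opening(m, brush)
  if (sum(body) == 0) body <- m
  filt_round <- mask_roundness(body)
  grown <- EBImage::dilate(body, EBImage::makeBrush(3, shape = "disc"))
  app <- m
  app[grown != 0] <- 0L
  lab <- cpp_label(app != 0, 8L)
  lens <- numeric(0)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    dist_body <- EBImage::distmap(1 - body)
    for (l in which(sizes >= min_app_area))
      lens <- c(lens, max(dist_body[lab == l]))
  }
  rec <- data.frame(
    Area = area,
    Roundness = roundness,
    FiltRound = filt_round,
    Density = density,
    AppNumber = length(lens),
    MaxApp = if (length(lens)) max(lens) else 0,
    MedApp = if (length(lens)) median(lens) else 0,
    CellNumber = area / mean_cell_area
  )
  class(rec) <- c("OrganoidRecord", class(rec))
  rec
}

#' Measure every object of a labeled organoid field
#'
#' @param labels integer object-label matrix (0 = background).
#' @param intensity_img matched intensity image.
#' @param ... passed to [measure_organoid()].
#' @return data frame of per-object records with an `id` column.
#' @export
measure_field <- function(labels, intensity_img, ...) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  if (length(ids) == 0)
    return(data.frame(id = integer(0)))
  rows <- lapply(ids, function(l) {
    rec <- measure_organoid((labels == l) * 1L, intensity_img, ...)
    cbind(data.frame(id = l), as.data.frame(rec))
  })
  do.call(rbind, rows)
}

#' Compare treatment groups against a control
#'
#' For each morphometric parameter and each non-control group, a
#' two-sided Mann-Whitney U test (or Welch t-test) against the control is
#' run; p-values are Bonferroni-corrected across all comparisons made in
#' the call. The effect direction comes from the median (U test) or mean
#' (t-test) ratio to control.
#'
#' @param records_by_group named list of per-object data frames.
#' @param control_name name of the control group.
#' @param test `"mannwhitney"` or `"ttest"`.
#' @param params parameter columns to compare (default: all shared
#'   numeric columns except `id`).
#' @return data frame with `parameter`, `group`, `direction`, `p_raw`,
#'   `p_adj`, `test`.
#' @export
compare_groups <- function(records_by_group, control_name,
                           test = c("mannwhitney", "ttest"),
                           params = NULL) {
  test <- match.arg(test)
  if (!control_name %in% names(records_by_group))
    stopf("control group '%s' not found", control_name)
  for (g in names(records_by_group))
    if (nrow(records_by_group[[g]]) < 3)
      stopf("group '%s' has fewer than 3 records", g)
  ctrl <- records_by_group[[control_name]]
  if (is.null(params)) {
    params <- Reduce(intersect, lapply(records_by_group, function(d)
      names(d)[vapply(d, is.numeric, TRUE)]))
    params <- setdiff(params, "id")
  }
  groups <- setdiff(names(records_by_group), control_name)
  rows <- list()
  for (g in groups) {
    for (p in params) {
      x <- records_by_group[[g]][[p]]
      y <- ctrl[[p]]
      if (test == "mannwhitney") {
        pv <- suppressWarnings(wilcox.test(x, y, exact = TRUE)$p.value)
        cx <- median(x); cy <- median(y)
      } else {
        pv <- if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) 1
        else t.test(x, y)$p.value
        cx <- mean(x); cy <- mean(y)
      }
      dir <- if (cx > cy) "increased" else if (cx < cy) "decreased"
      else "none"
      rows[[length(rows) + 1]] <-
        data.frame(parameter = p, group = g, direction = dir,
                   p_raw = pv, test = test)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out[, c("parameter", "group", "direction", "p_raw", "p_adj", "test")]
}

#' Fold-change heatmap matrix of a multi-group screen
#'
#' Log2 fold change of each group's parameter median over the control
#' median, with the aligned matrix of adjusted p-values.
#'
#' @param comparisons output of [compare_groups()].
#' @param records_by_group named list of per-object data frames.
#' @param control_name name of the control group.
#' @return list with `log2fc` and `p` matrices (parameter x group).
#' @export
heatmap_matrix <- function(comparisons, records_by_group, control_name) {
  params <- unique(comparisons$parameter)
  groups <- unique(comparisons$group)
  ctrl <- records_by_group[[control_name]]
  fc <- p <- matrix(NA_real_, length(params), length(groups),
                    dimnames = list(params, groups))
  for (pp in params) {
    m0 <- median(ctrl[[pp]])
    for (g in groups) {
      mg <- median(records_by_group[[g]][[pp]])
      if (m0 == 0) {
        warning("zero control median for '", pp,
                "'; fold change flagged NaN", call. = FALSE)
        fc[pp, g] <- NaN
      } else {
        fc[pp, g] <- log2(mg / m0)
      }
      sel <- comparisons$parameter == pp & comparisons$group == g
      p[pp, g] <- comparisons$p_adj[sel][1]
    }
  }
  list(log2fc = fc, p = p)
}

#' Render a fold-change heatmap to a PNG file
#'
#' @param hm output of [heatmap_matrix()].
#' @param path output PNG path.
#' @export
render_heatmap <- function(hm, path) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stopf("rendering requires the 'pheatmap' package")
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  pheatmap::pheatmap(hm$log2fc, cluster_rows = FALSE,
                     cluster_cols = FALSE)
  invisible(path)
}

#' Normalize growth curves to a vehicle control
#'
#' Each treated curve is divided pointwise by the control curve and
#' expressed in percent, so the control sits at a flat 100% and its final
#' time point is 100% by construction. The inhibition at the final time
#' point is `100 * (1 - treated/control)`.
#'
#' @param treated_curves named list of numeric curves sharing the control
#'   time base.
#' @param control_curve numeric control (e.g. DMSO) curve; final value
#'   must be positive.
#' @return list with `curves` (named list of normalized percent curves,
#'   control included) and `inhibition_pct` (named vector, final time
#'   point).
#' @export
normalize_growth_to_control <- function(treated_curves, control_curve) {
  nT <- length(control_curve)
  if (nT < 1 || control_curve[nT] <= 0)
    stopf("control curve must end at a positive value")
  if (!is.list(treated_curves)) treated_curves <- list(treated_curves)
  if (is.null(names(treated_curves)) || any(names(treated_curves) == ""))
    names(treated_curves) <- paste0("treated_",
                                    seq_along(treated_curves))
  curves <- list(control = rep(100, nT))
  inhib <- numeric(0)
  for (nm in names(treated_curves)) {
    tc <- treated_curves[[nm]]
    if (length(tc) != nT)
      stopf("curve '%s' does not share the control time base", nm)
    if (any(control_curve == 0))
      warning("control curve touches zero; normalized points flagged",
              call. = FALSE)
    curves[[nm]] <- 100 * tc / control_curve
    inhib[nm] <- 100 * (1 - tc[nT] / control_curve[nT])
  }
  list(curves = curves, inhibition_pct = inhib)
}

#' Centered moving-average smoothing of a measurement curve
#'
#' Used for display of time-series measurements to suppress frame-level
#' noise; the raw curve should always be retained alongside.
#'
#' @param x numeric vector.
#' @param window odd window length (default 5); edges use the available
#'   partial window.
#' @return smoothed numeric vector of the same length.
#' @export
smooth_curve <- function(x, window = 5) {
  if (!is_odd(window) || window < 1) stopf("`window` must be odd >= 1")
  k <- window %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - k):min(n, i + k)]), 0)
}
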