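# Fibroblast (CAF) cohort segmentation from the green fluorescence channel.
# Cohorts are low-contrast and intensity-variant over time, so a per-pixel
# local adaptive threshold is used instead of a global (Otsu-style) cut.

#' Adaptive threshold parameters
#'
#' The threshold for pixel (x, y) is the Gaussian-weighted mean of its
#' (2k+1) x (2k+1) block offset by a constant kappa: a pixel is
#' foreground only if it exceeds its neighborhood mean by more than
#' kappa, so a positive kappa suppresses flat background and increasing
#' kappa never adds foreground. The Gaussian width defaults to (2k+1)/6
#' so the kernel tapers smoothly inside the block.
#'
#' @param block_halfwidth k >= 1; block is (2k+1) x (2k+1) (default 25).
#' @param sigma Gaussian width; `NA` uses (2k+1)/6.
#' @param kappa background-suppression constant (any real, default 2).
#' @return list of class `AdaptiveThresholdParams`.
#' @export
adaptive_threshold_params <- function(block_halfwidth = 25, sigma = NA,
                                      kappa = 2) {
  if (block_halfwidth < 1) stopf("`block_halfwidth` must be >= 1")
  if (is.na(sigma)) sigma <- (2 * block_halfwidth + 1) / 6
  if (sigma <= 0) stopf("`sigma` must be > 0")
  structure(list(block_halfwidth = as.integer(block_halfwidth),
                 sigma = sigma, kappa = kappa),
            class = "AdaptiveThresholdParams")
}

# normalized Gaussian block kernel; exported to keep the R-level test
# oracle and the C++ path numerically identical weight-for-weight
gaussian_block_kernel <- function(k, sigma) {
  d <- (-k):k
  w <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  w / sum(w)
}

#' Local adaptive thresholding
#'
#' Pixel `p(x, y)` is foreground iff `p(x, y) > T(x, y)` where `T(x, y)`
#' is the Gaussian-weighted mean of the surrounding block offset by
#' `kappa` (ties go to background). Borders are mirror-reflected.
#'
#' @param img single-channel numeric matrix.
#' @param params an [adaptive_threshold_params()] object.
#' @return binary integer mask (1 = foreground).
#' @export
adaptive_threshold <- function(img, params = adaptive_threshold_params()) {
  ker <- gaussian_block_kernel(params$block_halfwidth, params$sigma)
  thr <- cpp_weighted_local_mean(img, ker) + params$kappa
  mask <- (img > thr) * 1L
  storage.mode(mask) <- "integer"
  mask
}

#' Remove small noisy regions from a binary mask
#'
#' Deletes 8-connected components with fewer than `min_area` pixels;
#' larger components are untouched.
#'
#' @param mask binary matrix.
#' @param min_area smallest surviving component size (px, default 50).
#' @return cleaned binary integer mask.
#' @export
clean_mask <- function(mask, min_area = 50) {
  m <- mask != 0
  lab <- cpp_label(m, 8L)
  if (max(lab) == 0) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab %in% keep] <- 1L
  out
}

#' Fill enclosed holes of a binary mask
#'
#' Background components (4-connected, the dual of the 8-connected
#' foreground) that do not touch the image border are converted to
#' foreground. Used after adaptive thresholding, which hollows out the
#' interior of objects larger than the threshold block.
#'
#' @param mask binary matrix.
#' @return binary integer mask with holes filled.
#' @export
fill_holes <- function(mask) {
  bg <- cpp_label(mask == 0, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border_labs <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  out <- (mask != 0) | (bg > 0 & !(bg %in% border_labs))
  out <- out * 1L
  storage.mode(out) <- "integer"
  out
}

#' Extract cohort regions from a cleaned mask
#'
#' One region per 8-connected component, with the outer boundary traced as
#' a closed contour (Moore neighborhood tracing; contours of components
#' touching the image border are clipped at the border and stay closed).
#'
#' @param mask cleaned binary matrix.
#' @return list of `CohortRegion` objects: `label`, `contour` (n x 2
#'   matrix of 0-based x = column, y = row vertices), `area` (component
#'   pixel count) and `bbox` (`x0, x1, y0, y1`, 0-based inclusive).
#' @export
extract_cohorts <- function(mask) {
  lab <- cpp_label(mask != 0, 8L)
  nlab <- max(lab)
  if (nlab == 0) return(list())
  lapply(seq_len(nlab), function(l) {
    rc <- cpp_trace_contour(lab, l)
    contour <- cbind(x = rc[, 2], y = rc[, 1])
    px <- which(lab == l, arr.ind = TRUE)
    structure(list(label = l, contour = contour, area = nrow(px),
                   bbox = c(x0 = min(px[, 2]) - 1, x1 = max(px[, 2]) - 1,
                            y0 = min(px[, 1]) - 1, y1 = max(px[, 1]) - 1)),
              class = "CohortRegion")
  })
}

#' Segment the fibroblast channel of a sequence
#'
#' Per frame: median filter, non-local means denoising, local adaptive
#' threshold, hole filling, small-region removal.
#'
#' @param seq fluorescence [image_sequence()].
#' @param config [default_config()]-style list.
#' @param denoise apply the median + NLM cascade before thresholding.
#' @return a [mask_sequence()].
#' @export
segment_fibroblasts <- function(seq, config = default_config(),
                                denoise = TRUE) {
  p <- config$preprocess
  fp <- config$fibro
  atp <- adaptive_threshold_params(fp$block_halfwidth,
                                   fp$sigma %||% NA, fp$kappa)
  masks <- lapply(seq$frames, function(f) {
    if (denoise) {
      f <- median_filter(f, p$median_window)
      f <- nlm_denoise(f, nlm_params(p$nlm_patch, p$nlm_search, p$nlm_h))
    }
    clean_mask(fill_holes(adaptive_threshold(f, atp)), fp$min_area)
  })
  mask_sequence(masks, source_channel = seq$channel)
}

#' Per-frame total fibroblast area
#'
#' Growth proxy: the total number of mask-foreground pixels per frame.
#'
#' @param masks a [mask_sequence()].
#' @return numeric vector, one value per frame.
#' @export
fibroblast_area_series <- function(masks) {
  vapply(masks$frames, sum, 0)
}

#' Growth-rate series normalized to the initial area
#'
#' Element i is `area_i / area_1`, so the series starts at exactly 1;
#' normalization standardizes comparisons across wells whose field of view
#' and seeding density differ.
#'
#' @param area_series numeric vector of per-frame areas; the first element
#'   must be positive.
#' @return normalized numeric vector.
#' @export
growth_rate_series <- function(area_series) {
  if (length(area_series) < 1 || area_series[1] <= 0)
    stopf("initial area must be > 0 to normalize a growth series")
  area_series / area_series[1]
}
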