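# Denoising and feature filters. All windowed filters use mirror-reflection
# borders, fixed package-wide so that the exhaustive per-pixel oracles in
# the test suite are well defined.

#' Median filter
#'
#' Replaces each pixel by the median of its square window; preferred for
#' impulsive ("salt-and-pepper") noise in the fluorescence channel.
#'
#' @param img numeric matrix.
#' @param window odd window width >= 3 (default 5).
#' @return filtered matrix.
#' @export
median_filter <- function(img, window = 5) {
  if (window < 3 || !is_odd(window))
    stopf("`window` must be an odd integer >= 3, got %s", format(window))
  cpp_median_filter(img, as.integer(window))
}

#' Non-local means parameters
#'
#' @param patch_size odd patch width (default 7).
#' @param search_window odd search window width (default 31).
#' @param h weight-decay control parameter (default 15).
#' @return list of class `NLMParams`.
#' @export
nlm_params <- function(patch_size = 7, search_window = 31, h = 15) {
  if (!is_odd(patch_size) || !is_odd(search_window))
    stopf("patch_size and search_window must be odd")
  if (patch_size > search_window)
    stopf("patch_size (%d) must be <= search_window (%d)",
          patch_size, search_window)
  if (h <= 0) stopf("`h` must be > 0")
  structure(list(patch_size = patch_size, search_window = search_window,
                 h = h), class = "NLMParams")
}

#' Non-local means denoising
#'
#' Self-similarity based patch averaging: each pixel is replaced by a
#' weighted mean of search-window pixels, weighted by
#' `exp(-(mean squared patch difference) / h^2)`.
#'
#' @param img numeric matrix larger than the search window.
#' @param params an [nlm_params()] object.
#' @return denoised matrix (within the input intensity range).
#' @export
nlm_denoise <- function(img, params = nlm_params()) {
  if (min(dim(img)) <= params$search_window)
    stopf("image (%dx%d) must be larger than the search window (%d)",
          nrow(img), ncol(img), params$search_window)
  cpp_nlm(img, as.integer(params$patch_size),
          as.integer(params$search_window), params$h)
}

#' Intensive tumor-channel denoising
#'
#' Two cascaded non-local means passes followed by joint spatial/range
#' mean-shift filtering, which flattens homogeneous regions while keeping
#' edges; used before thresholding the low-SNR phase-contrast channel.
#'
#' @inheritParams nlm_denoise
#' @param spatial_radius mean-shift spatial radius (px).
#' @param range_radius mean-shift range radius (intensity units).
#' @param max_iter mode-seeking iteration cap per pixel.
#' @return denoised matrix.
#' @export
tumor_denoise <- function(img, params = nlm_params(), spatial_radius = 10,
                          range_radius = 10, max_iter = 8) {
  out <- nlm_denoise(img, params)
  out <- nlm_denoise(out, params)
  cpp_meanshift(out, as.integer(spatial_radius), range_radius,
                as.integer(max_iter))
}

#' Local entropy filter
#'
#' Each output pixel is the Shannon entropy (bits) of the 8-bit intensity
#' histogram in the disc neighborhood of the given radius. Input must
#' already be in 8-bit representation (see [scale_to_8bit()]).
#'
#' @param img_8bit integer-valued matrix in \[0, 255\].
#' @param neighborhood_radius disc radius >= 1.
#' @return entropy matrix (bits).
#' @export
entropy_filter <- function(img_8bit, neighborhood_radius = 5) {
  if (neighborhood_radius < 1)
    stopf("`neighborhood_radius` must be >= 1")
  m <- round(img_8bit)
  storage.mode(m) <- "integer"
  cpp_entropy_filter(m, as.integer(neighborhood_radius))
}

#' Scale an image to 8-bit representation
#'
#' Affine map of the intensity range to \[0, 255\], rounded half-up.
#'
#' @param img numeric matrix with `max > min`.
#' @return integer-valued matrix in \[0, 255\].
#' @export
scale_to_8bit <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stopf("image contains non-finite intensities")
  if (diff(rng) == 0)
    stopf("constant image cannot be contrast-scaled to 8-bit")
  floor((img - rng[1]) / diff(rng) * 255 + 0.5)
}
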