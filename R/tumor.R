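# Tumor organoid segmentation from the phase-contrast channel. The channel
# has low SNR and high background clutter, so intensive denoising (two
# cascaded NLM passes + mean-shift) precedes adaptive thresholding; the
# result also picks up fibroblast cohorts, which are removed by masking
# with the fibroblast segmentation from the registered fluorescence frame.

#' Segment tumor organoids in one frame
#'
#' Pipeline: [tumor_denoise()], [adaptive_threshold()], morphological
#' smoothing (closing then opening with a disc), small-region removal,
#' then subtraction of the fibroblast mask. Pixels claimed by both
#' compartments are assigned to the fibroblasts.
#'
#' @param phase_img phase-contrast frame (registered, post-stabilization).
#' @param fibro_mask binary fibroblast mask from the matched fluorescence
#'   frame.
#' @param config [default_config()]-style list.
#' @param denoise apply the denoising cascade (disable for clean
#'   phantoms).
#' @return list of class `TumorMaskFrame` with `mask` (binary) and
#'   `excluded_fibro_pixels` (count removed by masking).
#' @export
segment_tumor_frame <- function(phase_img, fibro_mask,
                                config = default_config(),
                                denoise = TRUE) {
  if (!identical(dim(phase_img), dim(fibro_mask)))
    stopf("phase frame and fibroblast mask shapes differ")
  p <- config$preprocess
  tp <- config$tumor
  img <- phase_img
  if (denoise)
    img <- tumor_denoise(img, nlm_params(p$nlm_patch, p$nlm_search,
                                         p$nlm_h),
                         spatial_radius = p$ms_spatial_radius,
                         range_radius = p$ms_range_radius)
  atp <- adaptive_threshold_params(tp$block_halfwidth, tp$sigma %||% NA,
                                   tp$kappa)
  mask <- fill_holes(adaptive_threshold(img, atp))
  brush <- EBImage::makeBrush(2 * tp$smooth_radius + 1, shape = "disc")
  mask <- EBImage::opening(EBImage::closing(mask, brush), brush)
  mask <- clean_mask(mask, tp$min_area)
  overlap <- sum(mask == 1 & fibro_mask != 0)
  mask[fibro_mask != 0] <- 0L
  structure(list(mask = mask, excluded_fibro_pixels = overlap),
            class = "TumorMaskFrame")
}

#' Per-frame organoid area curve
#'
#' Applies [segment_tumor_frame()] with identical fixed parameters to
#' every frame of a stabilized sequence and sums the organoid mask pixels.
#'
#' @param seq stabilized phase-contrast [image_sequence()].
#' @param fibro_masks [mask_sequence()] from [segment_fibroblasts()].
#' @param config [default_config()]-style list.
#' @param denoise apply the denoising cascade per frame.
#' @return list with `area` (numeric per-frame curve) and `masks`
#'   (a [mask_sequence()] of organoid masks).
#' @export
tumor_area_series <- function(seq, fibro_masks, config = default_config(),
                              denoise = TRUE) {
  n <- length(seq$frames)
  if (length(fibro_masks$frames) != n)
    stopf("fibroblast mask sequence length mismatch")
  res <- lapply(seq_len(n), function(t)
    segment_tumor_frame(seq$frames[[t]], fibro_masks$frames[[t]],
                        config, denoise = denoise))
  list(area = vapply(res, function(r) sum(r$mask), 0),
       masks = mask_sequence(lapply(res, `[[`, "mask"),
                             source_channel = "phase"))
}
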