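# CAF motility from dense optical flow. Each pixel neighborhood is
# approximated by a quadric polynomial f(x) = x'Ax + b'x + c; a pure
# translation d of the quadric gives A2 = A1, b2 = b1 - 2 A1 d, hence
# d = -(1/2) A1^{-1} (b2 - b1). The per-pixel solution is averaged over a
# window and refined iteratively across an image pyramid (Farneback).

#' Farneback dense optical flow between two frames
#'
#' @param frame_a,frame_b numeric matrices of equal size (ideally
#'   stabilized first).
#' @param levels pyramid levels (default 3).
#' @param window averaging window width for the flow solve (default 15).
#' @param iterations refinement iterations per level (default 3).
#' @param poly_n polynomial expansion neighborhood half-width (default 5).
#' @param poly_sigma Gaussian applicability width (default 1.1).
#' @return list of class `FlowField` with per-pixel `dx`, `dy`
#'   (pixels/frame) and a `valid` mask.
#' @export
farneback_flow <- function(frame_a, frame_b, levels = 3, window = 15,
                           iterations = 3, poly_n = 5, poly_sigma = 1.1) {
  if (!identical(dim(frame_a), dim(frame_b)))
    stopf("frames must have identical dimensions")
  fl <- cpp_farneback(frame_a, frame_b, as.integer(levels),
                      as.integer(window), as.integer(iterations),
                      as.integer(poly_n), poly_sigma)
  structure(list(dx = fl$dx, dy = fl$dy,
                 valid = matrix(TRUE, nrow(frame_a), ncol(frame_a))),
            class = "FlowField")
}

#' Mean motion of one frame pair under a mask
#'
#' Mean displacement magnitude `sqrt(dx^2 + dy^2)` over mask-foreground
#' pixels; the mask suppresses background regions. Returns 0 for an empty
#' mask.
#'
#' @param flow a [farneback_flow()] result.
#' @param mask binary matrix of the same shape.
#' @return scalar mean displacement (pixels/frame).
#' @export
mean_motion_per_frame <- function(flow, mask) {
  if (!identical(dim(flow$dx), dim(mask)))
    stopf("mask shape does not match the flow field")
  sel <- mask != 0
  if (!any(sel)) return(0)
  mean(sqrt(flow$dx[sel]^2 + flow$dy[sel]^2))
}

#' Mean displacement vector of one frame pair under a mask
#'
#' Component-wise mean of the flow over mask-foreground pixels. For a
#' cohort that both translates and grows, the isotropic growth expansion
#' cancels in the vector mean, so this estimates the net translation,
#' while [mean_motion_per_frame()] reports total motility including
#' expansion.
#'
#' @inheritParams mean_motion_per_frame
#' @return numeric `c(dx, dy)` (pixels/frame); zeros for an empty mask.
#' @export
mean_velocity_per_frame <- function(flow, mask) {
  if (!identical(dim(flow$dx), dim(mask)))
    stopf("mask shape does not match the flow field")
  sel <- mask != 0
  if (!any(sel)) return(c(dx = 0, dy = 0))
  c(dx = mean(flow$dx[sel]), dy = mean(flow$dy[sel]))
}

#' Per-frame motility curve of a sequence
#'
#' Element i is the masked mean displacement magnitude between frames i
#' and i+1 (mask of frame i).
#'
#' @param seq [image_sequence()] with >= 2 frames.
#' @param masks aligned [mask_sequence()].
#' @param config [default_config()]-style list (flow parameters).
#' @return numeric vector of length `n_frames - 1`.
#' @export
motion_series <- function(seq, masks, config = default_config()) {
  n <- length(seq$frames)
  if (n < 2) stopf("need >= 2 frames for a motility curve")
  if (length(masks$frames) != n)
    stopf("mask sequence length does not match the image sequence")
  fp <- config$flow
  vapply(seq_len(n - 1), function(i) {
    fl <- farneback_flow(seq$frames[[i]], seq$frames[[i + 1]],
                         levels = fp$levels, window = fp$window,
                         iterations = fp$iterations, poly_n = fp$poly_n,
                         poly_sigma = fp$poly_sigma)
    mean_motion_per_frame(fl, masks$frames[[i]])
  }, 0)
}
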