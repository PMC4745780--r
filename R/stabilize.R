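# Video stabilization: global translation between consecutive frames is
# estimated from the peak of the inverse-transformed normalized cross-power
# spectrum (phase correlation), then compensated cumulatively against the
# first frame, and the sequence is cropped to the common field of view.

#' Estimate the global translation between two frames
#'
#' Computes the normalized cross-power spectrum
#' `T(u) = F(u) G*(u) / (|F(u)| |G(u)|)` of the two frames; the argmax of
#' its inverse transform is the translation relating them. The spectral
#' normalization is floored at machine epsilon, and an optional Hann window
#' suppresses wrap-around edge energy. `method = "blur_robust"` runs the
#' same correlation on gradient-magnitude images, which is less sensitive
#' to defocus blur.
#'
#' @param frame_a,frame_b numeric matrices of equal size (non-constant).
#' @param method `"standard"` or `"blur_robust"`.
#' @param subpixel refine the peak location by quadratic interpolation.
#' @param window `"hann"` or `"none"`; `"none"` makes recovery of integer
#'   circular shifts exact.
#' @return list of class `ShiftEstimate` with `dx`, `dy` (pixels; the
#'   content of `frame_b` equals the content of `frame_a` moved by
#'   `(dx, dy)`), `peak_response` in \[0, 1\] and `method`.
#' @export
estimate_shift <- function(frame_a, frame_b,
                           method = c("standard", "blur_robust"),
                           subpixel = TRUE, window = c("hann", "none")) {
  method <- match.arg(method)
  window <- match.arg(window)
  if (!identical(dim(frame_a), dim(frame_b)))
    stopf("frames must have identical dimensions")
  if (sd(frame_a) == 0 || sd(frame_b) == 0)
    stopf("constant image: phase correlation spectrum is undefined")
  a <- frame_a; b <- frame_b
  if (method == "blur_robust") {
    a <- gradient_magnitude(a)
    b <- gradient_magnitude(b)
  }
  if (window == "hann") {
    w <- hann2d(nrow(a), ncol(a))
    a <- (a - mean(a)) * w
    b <- (b - mean(b)) * w
  }
  Fa <- fft(a); Fb <- fft(b)
  denom <- pmax(Mod(Fa) * Mod(Fb), .Machine$double.eps)
  r <- Re(fft(Fa * Conj(Fb) / denom, inverse = TRUE)) / length(a)
  pk <- arrayInd(which.max(r), dim(r))
  peak <- r[pk[1], pk[2]]
  nr <- nrow(r); nc <- ncol(r)
  # 0-based peak index; wrap to signed shift. r peaks at index (-dy, -dx)
  # for b = a shifted by (dx, dy) since F G* has phase +2*pi*u*delta.
  iy <- pk[1] - 1; ix <- pk[2] - 1
  refine <- function(vals, i0, n) {
    if (!subpixel) return(0)
    ym <- vals[((i0 - 1) %% n) + 1]
    y0 <- vals[(i0 %% n) + 1]
    yp <- vals[((i0 + 1) %% n) + 1]
    den <- ym - 2 * y0 + yp
    if (abs(den) < .Machine$double.eps) return(0)
    d <- 0.5 * (ym - yp) / den
    max(min(d, 0.5), -0.5)
  }
  dyf <- refine(r[, pk[2]], iy, nr)
  dxf <- refine(r[pk[1], ], ix, nc)
  sy <- iy + dyf; sx <- ix + dxf
  if (sy > nr / 2) sy <- sy - nr
  if (sx > nc / 2) sx <- sx - nc
  structure(list(dx = -sx, dy = -sy,
                 peak_response = min(max(peak, 0), 1), method = method),
            class = "ShiftEstimate")
}

hann2d <- function(nr, nc) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(nr - 1)) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(nc - 1)) / (nc - 1))
  outer(wy, wx)
}

gradient_magnitude <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gx <- img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]
  gy <- img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]
  sqrt(gx^2 + gy^2)
}

#' Stabilize a time-lapse sequence
#'
#' Estimates the translation between each consecutive frame pair, applies
#' the cumulative compensation against frame 1, and crops every frame to
#' the maximal rectangle covered by all compensated frames (out-of-field
#' pixels are never padded). The motion model is translation only.
#'
#' @param seq an [image_sequence()] with at least 2 frames.
#' @inheritParams estimate_shift
#' @return list with `sequence` (stabilized, cropped [image_sequence()]),
#'   `crop_rect` (0-based inclusive `x0, x1, y0, y1` in original frame
#'   coordinates) and `shifts` (data frame of per-consecutive-pair
#'   estimates).
#' @export
stabilize_sequence <- function(seq, method = c("standard", "blur_robust"),
                               subpixel = TRUE,
                               window = c("hann", "none")) {
  method <- match.arg(method); window <- match.arg(window)
  frames <- seq$frames
  n <- length(frames)
  if (n < 2) stopf("need >= 2 frames to stabilize")
  nr <- nrow(frames[[1]]); nc <- ncol(frames[[1]])
  est <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    est[[i]] <- estimate_shift(frames[[i]], frames[[i + 1]],
                               method = method, subpixel = subpixel,
                               window = window)
  }
  dx <- vapply(est, `[[`, 0, "dx")
  dy <- vapply(est, `[[`, 0, "dy")
  cumx <- c(0, cumsum(dx))
  cumy <- c(0, cumsum(dy))
  if (max(abs(cumx)) > nc / 2 || max(abs(cumy)) > nr / 2)
    stopf("cumulative shift exceeds half the frame; field of view lost")
  comp <- vector("list", n)
  for (t in seq_len(n))
    comp[[t]] <- translate_image(frames[[t]], -cumx[t], -cumy[t])
  # common field of view: x valid when 0 <= x + cumx <= nc-1 (0-based)
  x0 <- max(0, ceiling(max(-cumx)))
  x1 <- min(nc - 1, floor(nc - 1 - max(cumx)))
  y0 <- max(0, ceiling(max(-cumy)))
  y1 <- min(nr - 1, floor(nr - 1 - max(cumy)))
  if (x1 < x0 || y1 < y0) stopf("no common field of view after shifts")
  cropped <- lapply(comp, function(f) f[(y0:y1) + 1, (x0:x1) + 1,
                                        drop = FALSE])
  stab <- image_sequence(cropped, channel = seq$channel,
                         frame_interval = seq$frame_interval,
                         pixel_size = seq$pixel_size)
  shifts <- data.frame(frame = 2:n, dx = dx, dy = dy,
                       peak = vapply(est, `[[`, 0, "peak_response"))
  list(sequence = stab,
       crop_rect = c(x0 = x0, x1 = x1, y0 = y0, y1 = y1),
       shifts = shifts)
}

#' Apply the crop and compensation of one stabilization to another channel
#'
#' Both live-cell channels are captured registered, so the translation
#' estimated on one channel is applied verbatim to the other.
#'
#' @param seq [image_sequence()] to compensate.
#' @param stab result of [stabilize_sequence()] from the matched channel.
#' @return stabilized, cropped [image_sequence()].
#' @export
apply_stabilization <- function(seq, stab) {
  frames <- seq$frames
  cumx <- c(0, cumsum(stab$shifts$dx))
  cumy <- c(0, cumsum(stab$shifts$dy))
  if (length(frames) != length(cumx))
    stopf("sequence length does not match the stabilization result")
  cr <- stab$crop_rect
  out <- lapply(seq_along(frames), function(t) {
    f <- translate_image(frames[[t]], -cumx[t], -cumy[t])
    f[(cr["y0"]:cr["y1"]) + 1, (cr["x0"]:cr["x1"]) + 1, drop = FALSE]
  })
  image_sequence(out, channel = seq$channel,
                 frame_interval = seq$frame_interval,
                 pixel_size = seq$pixel_size)
}
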