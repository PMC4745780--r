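`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_odd <- function(x) x %% 2 == 1

#' Circularly shift an image
#'
#' Content moves by `dx` columns and `dy` rows with wrap-around; pixels
#' leaving one edge re-enter at the opposite edge.
#'
#' @param img numeric matrix.
#' @param dx,dy integer shift along x (columns) and y (rows).
#' @return shifted matrix of identical dimensions.
#' @export
circshift <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  ci <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  img[ri, ci, drop = FALSE]
}

# Translate image content by (dx, dy) (may be fractional); out-of-field
# pixels become `fill`. out(y, x) = img(y - dy, x - dx), bilinear for
# fractional shifts.
translate_image <- function(img, dx, dy, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  if (dx == round(dx) && dy == round(dy)) {
    dx <- as.integer(round(dx)); dy <- as.integer(round(dy))
    out <- matrix(fill, nr, nc)
    src_r <- seq_len(nr) - dy
    src_c <- seq_len(nc) - dx
    vr <- src_r >= 1 & src_r <= nr
    vc <- src_c >= 1 & src_c <= nc
    out[vr, vc] <- img[src_r[vr], src_c[vc], drop = FALSE]
    return(out)
  }
  yy <- matrix(seq_len(nr), nr, nc) - dy
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - dx
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  y1 <- y0 + 1; x1 <- x0 + 1
  valid <- y0 >= 1 & y1 <= nr & x0 >= 1 & x1 <= nc
  out <- matrix(fill, nr, nc)
  idx <- which(valid)
  g <- function(r, c) img[cbind(r[idx], c[idx])]
  out[idx] <- (1 - fy[idx]) * ((1 - fx[idx]) * g(y0, x0) + fx[idx] * g(y0, x1)) +
    fy[idx] * ((1 - fx[idx]) * g(y1, x0) + fx[idx] * g(y1, x1))
  out
}

# gaussian blur via separable kernel, reflect borders (used by phantoms)
gauss_blur <- function(img, sigma) {
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-(-k:k)^2 / (2 * sigma^2))
  w <- w / sum(w)
  ker <- outer(w, w)
  cpp_weighted_local_mean(img, ker)
}
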