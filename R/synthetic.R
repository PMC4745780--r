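# Phantom generators. These emulate the statistical structure the analysis
# assumes -- bright branched fibroblast cohorts and round protrusive
# organoids on a granular ECM-like background with frame jitter -- with
# exact, code-level ground truth. They make every stage testable without
# real microscope data; they do not attempt to simulate biology.

#' Star polygon contour with analytic notch depth
#'
#' Builds a 2n-vertex star polygon (alternating outer and inner radius).
#' The convex hull is the outer n-gon, and each notch has analytic
#' convexity-defect depth `outer_r * cos(pi/n) - inner_r` (the hull chord
#' between adjacent outer vertices lies at distance `outer_r * cos(pi/n)`
#' from the center and the inner vertex sits on the chord's bisector).
#'
#' @param n_points number of star points (>= 3).
#' @param outer_r,inner_r outer and inner vertex radii, `outer_r > inner_r`.
#' @param center numeric (x, y) center.
#' @param phase rotation of the first outer vertex (radians).
#' @return list with `contour` (2n x 2 matrix of x,y vertices, closed
#'   implicitly), `notch_depth`, and `n_points`.
#' @export
generate_star_contour <- function(n_points, outer_r, inner_r,
                                  center = c(0, 0), phase = 0) {
  if (n_points < 3) stopf("`n_points` must be >= 3")
  if (!(outer_r > inner_r && inner_r > 0))
    stopf("need outer_r > inner_r > 0")
  ang_out <- phase + 2 * pi * (0:(n_points - 1)) / n_points
  ang_in <- ang_out + pi / n_points
  xs <- as.vector(rbind(center[1] + outer_r * cos(ang_out),
                        center[1] + inner_r * cos(ang_in)))
  ys <- as.vector(rbind(center[2] + outer_r * sin(ang_out),
                        center[2] + inner_r * sin(ang_in)))
  list(contour = cbind(x = xs, y = ys),
       notch_depth = outer_r * cos(pi / n_points) - inner_r,
       n_points = n_points)
}

# even-odd scanline polygon rasterization; vertices in 0-based pixel
# coordinates (x = column index, y = row index); returns integer mask.
rasterize_polygon <- function(vx, vy, nr, nc) {
  mask <- matrix(0L, nr, nc)
  n <- length(vx)
  nxt <- c(2:n, 1)
  for (r in seq_len(nr)) {
    yc <- r - 1
    x1 <- vx; y1 <- vy; x2 <- vx[nxt]; y2 <- vy[nxt]
    crosses <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(crosses)) next
    xi <- x1[crosses] + (yc - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xi <- sort(xi)
    for (p in seq(1, length(xi) - 1, by = 2)) {
      a <- ceiling(xi[p]); b <- floor(xi[p + 1])
      a <- max(a, 0); b <- min(b, nc - 1)
      if (b >= a) mask[r, (a:b) + 1] <- 1L
    }
  }
  mask
}

draw_disc <- function(nr, nc, cx, cy, r) {
  xx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yy <- matrix(0:(nr - 1), nr, nc)
  ((xx - cx)^2 + (yy - cy)^2 <= r^2) * 1L
}

draw_star_mask <- function(nr, nc, cx, cy, n_branches, r_outer, r_inner,
                           phase = 0) {
  if (n_branches == 0) return(draw_disc(nr, nc, cx, cy, r_outer))
  st <- generate_star_contour(n_branches, r_outer, r_inner,
                              center = c(cx, cy), phase = phase)
  rasterize_polygon(st$contour[, 1], st$contour[, 2], nr, nc)
}

# low-frequency multiplicative field emulating ECM granularity: coarse
# uniform grid, bilinearly upsampled, mapped to [1 - amp, 1 + amp]
granular_field <- function(nr, nc, amp = 0.15, cells = 8) {
  g <- matrix(runif((cells + 1)^2), cells + 1, cells + 1)
  ry <- seq(0, cells, length.out = nr)
  rx <- seq(0, cells, length.out = nc)
  i0 <- pmin(floor(ry), cells - 1); fy <- ry - i0
  j0 <- pmin(floor(rx), cells - 1); fx <- rx - j0
  up <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    a <- g[i0[r] + 1, j0 + 1] * (1 - fx) + g[i0[r] + 1, j0 + 2] * fx
    b <- g[i0[r] + 2, j0 + 1] * (1 - fx) + g[i0[r] + 2, j0 + 2] * fx
    up[r, ] <- a * (1 - fy[r]) + b * fy[r]
  }
  1 + amp * (2 * up - 1)
}

#' Synthetic fibroblast-cohort time-lapse with known ground truth
#'
#' Generates a two-channel phantom: a green-fluorescence channel holding a
#' bright star-shaped "CAF cohort" whose area grows geometrically by
#' `(1 + growth_per_frame)` per frame and which translates by a fixed
#' per-frame velocity, plus a phase-contrast channel holding round
#' "organoid" discs. Each frame is shifted circularly by a known random
#' jitter (camera shake) and corrupted by additive Gaussian noise on a
#' granular multiplicative background. All ground truth (jitter, per-frame
#' drawn areas, centroids, per-frame object masks) is returned.
#'
#' @param n_frames number of frames (>= 2 unless jitter and growth are 0).
#' @param jitter_amplitude maximum absolute per-frame jitter (px).
#' @param growth_per_frame fractional area growth per frame (>= 0).
#' @param n_branches number of star branches of the cohort (0 = disc).
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param seed RNG seed; output is bit-identical for equal seeds.
#' @param width,height frame size in pixels.
#' @param velocity numeric (vx, vy) cohort translation per frame (px).
#' @param n_organoids number of organoid discs in the phase channel.
#' @param integer_jitter draw jitter on the integer grid (exact
#'   stabilization ground truth); `FALSE` adds a sub-pixel component.
#' @return list with `fluor` and `phase` [image_sequence()]s and `truth`
#'   (jitter data frame, per-frame `area`, `centroid`, masks, seed).
#' @export
generate_cohort_sequence <- function(n_frames, jitter_amplitude = 0,
                                     growth_per_frame = 0, n_branches = 5,
                                     noise_sigma = 0, seed = 1,
                                     width = 128, height = 128,
                                     velocity = c(0, 0), n_organoids = 0,
                                     integer_jitter = TRUE) {
  if (n_frames < 1) stopf("`n_frames` must be >= 1")
  if (growth_per_frame < 0) stopf("`growth_per_frame` must be >= 0")
  if (n_branches < 0) stopf("`n_branches` must be >= 0")
  set.seed(seed)
  nr <- height; nc <- width
  drift <- sqrt(sum(velocity^2)) * (n_frames - 1)
  growth_factor <- (1 + growth_per_frame)^((n_frames - 1) / 2)
  fit_bound <- (min(nr, nc) / 2 - drift / 2 - jitter_amplitude - 3) /
    growth_factor
  r0 <- min(min(nr, nc) / 6.5, fit_bound)
  if (r0 < 4)
    stopf(paste("cohort would exit the frame (final radius %.1f + drift",
                "%.1f + jitter %.1f); use a larger canvas"),
          4 * growth_factor, drift, jitter_amplitude)
  cx0 <- (nc - 1) / 2 - velocity[1] * (n_frames - 1) / 2
  cy0 <- (nr - 1) / 2 - velocity[2] * (n_frames - 1) / 2

  jx <- jy <- numeric(n_frames)
  if (jitter_amplitude > 0 && n_frames > 1) {
    jx[-1] <- sample(-jitter_amplitude:jitter_amplitude, n_frames - 1,
                     replace = TRUE)
    jy[-1] <- sample(-jitter_amplitude:jitter_amplitude, n_frames - 1,
                     replace = TRUE)
    if (!integer_jitter) {
      jx[-1] <- jx[-1] + runif(n_frames - 1, -0.45, 0.45)
      jy[-1] <- jy[-1] + runif(n_frames - 1, -0.45, 0.45)
    }
  }

  field <- granular_field(nr, nc, amp = 0.15)
  # cohort-internal granularity (cellular substructure) travels with the
  # object, unlike the static ECM background field
  objfield <- granular_field(nr, nc, amp = 0.2, cells = 24)
  org_masks0 <- matrix(0L, nr, nc)
  org_r <- min(nr, nc) / 10
  if (n_organoids > 0) {
    # organoids parked in corners, away from the cohort track
    spots <- list(c(0.18, 0.18), c(0.82, 0.18), c(0.18, 0.82),
                  c(0.82, 0.82))
    for (k in seq_len(min(n_organoids, 4))) {
      org_masks0 <- pmax(org_masks0,
                         draw_disc(nr, nc, spots[[k]][1] * (nc - 1),
                                   spots[[k]][2] * (nr - 1), org_r))
    }
  }

  fl <- ph <- vector("list", n_frames)
  fmask <- omask <- vector("list", n_frames)
  area <- numeric(n_frames)
  cent <- matrix(0, n_frames, 2, dimnames = list(NULL, c("x", "y")))
  phase0 <- runif(1, 0, 2 * pi)
  for (t in seq_len(n_frames)) {
    rt <- r0 * (1 + growth_per_frame)^((t - 1) / 2)
    cx <- cx0 + velocity[1] * (t - 1)
    cy <- cy0 + velocity[2] * (t - 1)
    m <- draw_star_mask(nr, nc, cx, cy, n_branches, rt, 0.45 * rt, phase0)
    area[t] <- sum(m)
    cent[t, ] <- c(cx, cy)
    of_t <- translate_image(objfield, velocity[1] * (t - 1),
                            velocity[2] * (t - 1), fill = 1)
    fluor <- 20 * field + 180 * m * of_t
    phase <- 100 * field + 60 * org_masks0 + 40 * m * of_t
    fluor <- circshift(fluor, jx[t], jy[t])
    phase <- circshift(phase, jx[t], jy[t])
    fmask[[t]] <- circshift(m, jx[t], jy[t])
    omask[[t]] <- circshift(org_masks0, jx[t], jy[t])
    if (noise_sigma > 0) {
      fluor <- fluor + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
      phase <- phase + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
    }
    fl[[t]] <- pmax(fluor, 0)
    ph[[t]] <- pmax(phase, 0)
  }
  list(
    fluor = image_sequence(fl, channel = "fluor_green"),
    phase = image_sequence(ph, channel = "phase"),
    truth = list(jitter = data.frame(frame = seq_len(n_frames),
                                     dx = jx, dy = jy),
                 area = area, centroid = cent, n_branches = n_branches,
                 velocity = velocity, fibro_masks = fmask,
                 organoid_masks = omask, seed = seed)
  )
}

#' Synthetic three-label image for MRF segmentation tests
#'
#' Pixel intensities are drawn from the Gaussian of their true label
#' (background, cell shadow, in-focus cells). The default label map is a
#' disc (in-focus) inside a halo ring (shadow) on background.
#'
#' @param shape integer (rows, cols).
#' @param label_map optional integer matrix in \{1, 2, 3\}; 1 = background.
#' @param means,sigmas per-label Gaussian parameters (length 3).
#' @param seed RNG seed.
#' @return list with `image` and `labels`.
#' @export
generate_mrf_image <- function(shape = c(64, 64), label_map = NULL,
                               means = c(10, 100, 200),
                               sigmas = c(5, 5, 5), seed = 1) {
  if (length(means) != 3 || length(sigmas) != 3)
    stopf("`means` and `sigmas` must have length 3")
  if (any(duplicated(means))) stopf("`means` must be distinct")
  if (any(sigmas <= 0)) stopf("`sigmas` must be > 0")
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  if (is.null(label_map)) {
    r_in <- min(nr, nc) / 5
    disc <- draw_disc(nr, nc, (nc - 1) / 2, (nr - 1) / 2, r_in)
    halo <- draw_disc(nr, nc, (nc - 1) / 2, (nr - 1) / 2, 1.6 * r_in)
    label_map <- matrix(1L, nr, nc)
    label_map[halo == 1] <- 2L
    label_map[disc == 1] <- 3L
  }
  img <- matrix(rnorm(nr * nc, means[label_map], sigmas[label_map]), nr, nc)
  list(image = img, labels = label_map)
}

#' Synthetic organoid field with known morphometric truth
#'
#' Places non-overlapping fluorescent discs, each optionally decorated with
#' thin radial appendages of known count and length, on a dim background.
#'
#' @param n_organoids number of organoids (0 allowed).
#' @param radius_range numeric (min, max) disc radius in px.
#' @param appendage_spec list of `list(count =, length =)` recycled across
#'   organoids; empty list means no appendages. Lengths must be smaller
#'   than a quarter of the frame.
#' @param seed RNG seed.
#' @param shape integer (rows, cols).
#' @param intensity,background object and background intensities.
#' @param noise_sigma additive Gaussian noise sd.
#' @return list with `image`, `labels` (integer object map) and `truth`
#'   data frame (id, area, centroid, radius, app_count, max/median
#'   appendage length) plus `app_lengths` list.
#' @export
generate_organoid_field <- function(n_organoids = 5,
                                    radius_range = c(12, 20),
                                    appendage_spec = list(), seed = 1,
                                    shape = c(256, 256), intensity = 180,
                                    background = 20, noise_sigma = 0) {
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  labels <- matrix(0L, nr, nc)
  rows <- list(); lens <- list()
  app_w <- 1.5  # half-width of appendage strokes (px)
  if (n_organoids > 0) {
    for (k in seq_len(n_organoids)) {
      spec <- if (length(appendage_spec))
        appendage_spec[[(k - 1) %% length(appendage_spec) + 1]]
      else list(count = 0, length = 0)
      if (spec$length >= min(nr, nc) / 4)
        stopf("appendage length %s too large for a %dx%d frame",
              spec$length, nr, nc)
      reach <- max(radius_range) + spec$length + 2
      placed <- FALSE
      for (try in 1:300) {
        r <- runif(1, radius_range[1], radius_range[2])
        cx <- runif(1, reach, nc - 1 - reach)
        cy <- runif(1, reach, nr - 1 - reach)
        clear <- TRUE
        for (p in rows) {
          if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) <
              r + p$reach + spec$length + 4) { clear <- FALSE; break }
        }
        if (!clear) next
        m <- draw_disc(nr, nc, cx, cy, r)
        alens <- numeric(0)
        if (spec$count > 0) {
          angs <- runif(1, 0, 2 * pi) +
            2 * pi * (0:(spec$count - 1)) / spec$count
          for (a in angs) {
            # stroke from the disc edge outward, length `spec$length`
            x0 <- cx + (r - 1) * cos(a); y0 <- cy + (r - 1) * sin(a)
            x1 <- cx + (r - 1 + spec$length) * cos(a)
            y1 <- cy + (r - 1 + spec$length) * sin(a)
            m <- pmax(m, draw_stroke(nr, nc, x0, y0, x1, y1, app_w))
            alens <- c(alens, spec$length)
          }
        }
        labels[m == 1] <- k
        rows[[k]] <- list(id = k, cx = cx, cy = cy, r = r,
                          reach = r + spec$length,
                          area = sum(labels == k),
                          app_count = spec$count)
        lens[[k]] <- alens
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place organoid %d without overlap", k)
    }
  }
  img <- matrix(background, nr, nc) + intensity * (labels > 0)
  if (noise_sigma > 0)
    img <- img + matrix(rnorm(nr * nc, 0, noise_sigma), nr, nc)
  truth <- if (length(rows)) {
    data.frame(id = vapply(rows, `[[`, 0, "id"),
               area = vapply(rows, `[[`, 0, "area"),
               cx = vapply(rows, `[[`, 0, "cx"),
               cy = vapply(rows, `[[`, 0, "cy"),
               radius = vapply(rows, `[[`, 0, "r"),
               app_count = vapply(rows, `[[`, 0, "app_count"),
               max_app = vapply(lens, function(v)
                 if (length(v)) max(v) else 0, 0),
               med_app = vapply(lens, function(v)
                 if (length(v)) median(v) else 0, 0))
  } else {
    data.frame(id = integer(0), area = numeric(0), cx = numeric(0),
               cy = numeric(0), radius = numeric(0),
               app_count = numeric(0), max_app = numeric(0),
               med_app = numeric(0))
  }
  list(image = img, labels = labels, truth = truth, app_lengths = lens)
}

# thick line segment (capsule) rasterization
draw_stroke <- function(nr, nc, x0, y0, x1, y1, halfwidth) {
  xx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  yy <- matrix(0:(nr - 1), nr, nc)
  vx <- x1 - x0; vy <- y1 - y0
  L2 <- vx^2 + vy^2
  tt <- pmin(pmax(((xx - x0) * vx + (yy - y0) * vy) / L2, 0), 1)
  d2 <- (xx - (x0 + tt * vx))^2 + (yy - (y0 + tt * vy))^2
  (d2 <= halfwidth^2) * 1L
}
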