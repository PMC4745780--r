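# Confocal segmentation as a 3-label Markov random field. Pixel labels
# ('background' < 'cell_shadow' < 'in_focus_cells', ordered by mixture
# mean) minimize
#   E(x) = sum_i theta_{i;l} + sum_(i,j) theta_{ij;lk}
# with unaries theta_{i;l} = -log f_l(z_i) from a 3-component Gaussian
# mixture and contrast-sensitive Potts pairwise terms
#   theta_{ij;lk} = lambda0 + lambda1 exp(-beta ||z_i - z_j||^2 / 2)
# for l != k (0 otherwise), minimized by alpha-expansion graph cuts.

MRF_LABELS <- c("background", "cell_shadow", "in_focus_cells")

#' Fit a three-component Gaussian mixture to pixel values
#'
#' EM with k-means++ initialization and multiple restarts (best
#' log-likelihood kept). Components are sorted by mean and mapped to the
#' labels background < cell shadow < in-focus cells.
#'
#' @param values numeric vector of pixel values (>= 300, non-constant).
#' @param seed RNG seed; same seed gives an identical fit.
#' @param restarts number of k-means++ restarts (default 5).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return list of class `MixtureModel3` with `weight`, `mean`, `sigma`
#'   (each length 3, sorted by mean), `labels`, and `loglik`.
#' @export
fit_mixture3 <- function(values, seed = 1, restarts = 5, max_iter = 200,
                         tol = 1e-8) {
  values <- as.numeric(values)
  if (length(values) < 300)
    stopf("need >= 300 samples to fit the mixture, got %d", length(values))
  if (sd(values) == 0) stopf("constant sample: mixture fit is degenerate")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + (r - 1) * 7919)
    mu0 <- kmeanspp_centers(values, 3)
    fit <- em_gauss3(values, mu0, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (best$degenerate)
    warning("degenerate mixture component: sigma floored at 1e-3",
            call. = FALSE)
  o <- order(best$mean)
  structure(list(weight = best$weight[o], mean = best$mean[o],
                 sigma = best$sigma[o], labels = MRF_LABELS,
                 loglik = best$loglik),
            class = "MixtureModel3")
}

# k-means++ seeding on a 1-D sample (D^2-weighted center choice)
kmeanspp_centers <- function(x, k) {
  centers <- x[sample.int(length(x), 1)]
  while (length(centers) < k) {
    d2 <- vapply(x, function(v) min((v - centers)^2), 0)
    if (sum(d2) == 0) {
      centers <- c(centers, x[sample.int(length(x), 1)])
    } else {
      centers <- c(centers, x[sample.int(length(x), 1, prob = d2)])
    }
  }
  centers
}

em_gauss3 <- function(x, mu, max_iter, tol) {
  n <- length(x)
  w <- rep(1 / 3, 3)
  sg <- rep(max(sd(x) / 3, 1e-3), 3)
  ll_old <- -Inf
  floor_sigma <- 1e-3
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(k) w[k] * dnorm(x, mu[k], sg[k]),
                   numeric(n))
    rowsum_ <- pmax(rowSums(dens), 1e-300)
    resp <- dens / rowsum_
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / pmax(nk, 1e-12)
    sg <- sqrt(colSums(resp * (x - rep(mu, each = n))^2) /
                 pmax(nk, 1e-12))
    if (any(sg < floor_sigma)) {
      degenerate <- TRUE
      sg <- pmax(sg, floor_sigma)
    }
    ll <- sum(log(rowsum_))
    if (is.finite(ll) && ll - ll_old < tol && it > 1) break
    ll_old <- ll
  }
  list(weight = w, mean = mu, sigma = sg, loglik = ll_old,
       degenerate = degenerate)
}

#' Per-component density of a fitted mixture
#'
#' `f_l` is the component density itself (integrates to 1 per label).
#'
#' @param mixture a [fit_mixture3()] object.
#' @param z numeric values.
#' @return length(z) x 3 matrix of densities.
#' @export
mixture_density <- function(mixture, z) {
  vapply(1:3, function(k) dnorm(as.numeric(z), mixture$mean[k],
                                mixture$sigma[k]),
         numeric(length(z)))
}

#' Build the MRF energy model for an image
#'
#' Unaries are `-log f_l(z_i)` (density floored at 1e-12 before the log)
#' evaluated on `feature_img` (by default the entropy-filtered image);
#' pairwise contrast uses `contrast_img` (by default the 8-bit raw
#' intensities) on a 4-neighbor grid.
#'
#' @param feature_img matrix of values the mixture was fitted to.
#' @param mixture a [fit_mixture3()] object.
#' @param lambda0,lambda1 non-negative pairwise strength parameters.
#' @param beta contrast sensitivity (>= 0; on the `contrast_img` scale).
#' @param contrast_img matrix used in the pairwise exponential (defaults
#'   to `feature_img`).
#' @return list of class `MRFModel`: `unary` (rows x cols x 3), edge
#'   weights `wh` (horizontal) and `wv` (vertical), and `labels`.
#' @export
build_energy <- function(feature_img, mixture, lambda0 = 0.5,
                         lambda1 = 2.0, beta = 0.05,
                         contrast_img = feature_img) {
  if (lambda0 < 0 || lambda1 < 0)
    stopf("lambda0 and lambda1 must be >= 0 (metric pairwise term)")
  if (beta < 0) stopf("beta must be >= 0")
  if (!identical(dim(feature_img), dim(contrast_img)))
    stopf("feature and contrast images must share dimensions")
  nr <- nrow(feature_img); nc <- ncol(feature_img)
  dens <- mixture_density(mixture, feature_img)
  unary <- array(-log(pmax(dens, 1e-12)), c(nr, nc, 3))
  z <- contrast_img
  wh <- if (nc > 1)
    lambda0 + lambda1 * exp(-0.5 * beta *
                              (z[, -nc, drop = FALSE] -
                                 z[, -1, drop = FALSE])^2)
  else matrix(0, nr, 0)
  wv <- if (nr > 1)
    lambda0 + lambda1 * exp(-0.5 * beta *
                              (z[-nr, , drop = FALSE] -
                                 z[-1, , drop = FALSE])^2)
  else matrix(0, 0, nc)
  structure(list(dims = c(nr, nc), unary = unary, wh = wh, wv = wv,
                 labels = MRF_LABELS),
            class = "MRFModel")
}

#' Total MRF energy of a labeling
#'
#' @param model a [build_energy()] object.
#' @param labeling integer matrix in \{1, 2, 3\}.
#' @return scalar energy.
#' @export
mrf_energy <- function(model, labeling) {
  nr <- model$dims[1]; nc <- model$dims[2]
  idx <- cbind(as.vector(row(labeling)), as.vector(col(labeling)),
               as.vector(labeling))
  e <- sum(model$unary[idx])
  if (nc > 1)
    e <- e + sum(model$wh * (labeling[, -nc, drop = FALSE] !=
                               labeling[, -1, drop = FALSE]))
  if (nr > 1)
    e <- e + sum(model$wv * (labeling[-nr, , drop = FALSE] !=
                               labeling[-1, , drop = FALSE]))
  e
}

#' Per-pixel maximum-likelihood labeling (no pairwise coupling)
#'
#' @param model a [build_energy()] object.
#' @return integer label matrix.
#' @export
ml_labeling <- function(model) {
  nr <- model$dims[1]; nc <- model$dims[2]
  u <- matrix(model$unary, nr * nc, 3)
  matrix(max.col(-u, ties.method = "first"), nr, nc)
}

# one alpha-expansion move solved as an s-t min cut (igraph max-flow).
# Binary variable y_i = 1 (source side) means pixel i switches to alpha.
expand_move <- function(model, labeling, alpha) {
  nr <- model$dims[1]; nc <- model$dims[2]
  n <- nr * nc
  u <- matrix(model$unary, n, 3)
  idx <- cbind(seq_len(n), as.vector(labeling))
  cap_src <- u[idx]                      # theta_i(l_i) paid when y_i = 0
  cap_snk <- u[, alpha]                  # theta_i(alpha) paid when y_i = 1
  efrom <- integer(0); eto <- integer(0); ecap <- numeric(0)
  add_pairs <- function(ii, jj, w, cap_src, cap_snk) {
    li <- labeling[ii]; lj <- labeling[jj]
    A <- w * (li != lj)
    B <- w * (li != alpha)
    C <- w * (lj != alpha)
    # E(yi,yj) = A + (C-A) yi + (-C) yj + (B+C-A) (1-yi) yj
    ci <- C - A
    pos <- ci > 0
    cap_snk[ii[pos]] <- cap_snk[ii[pos]] + ci[pos]
    cap_src[ii[!pos]] <- cap_src[ii[!pos]] - ci[!pos]
    cap_src[jj] <- cap_src[jj] + C
    cross <- B + C - A
    keep <- cross > 0
    list(from = jj[keep], to = ii[keep], cap = cross[keep],
         cap_src = cap_src, cap_snk = cap_snk)
  }
  if (nc > 1) {
    ii <- as.vector(outer(seq_len(nr), (seq_len(nc - 1) - 1) * nr, "+"))
    jj <- ii + nr
    pr <- add_pairs(ii, jj, as.vector(model$wh), cap_src, cap_snk)
    cap_src <- pr$cap_src; cap_snk <- pr$cap_snk
    efrom <- c(efrom, pr$from); eto <- c(eto, pr$to)
    ecap <- c(ecap, pr$cap)
  }
  if (nr > 1) {
    ii <- as.vector(outer(seq_len(nr - 1), (seq_len(nc) - 1) * nr, "+"))
    jj <- ii + 1L
    pr <- add_pairs(ii, jj, as.vector(model$wv), cap_src, cap_snk)
    cap_src <- pr$cap_src; cap_snk <- pr$cap_snk
    efrom <- c(efrom, pr$from); eto <- c(eto, pr$to)
    ecap <- c(ecap, pr$cap)
  }
  src <- n + 1L; snk <- n + 2L
  s_keep <- cap_src > 0
  k_keep <- cap_snk > 0
  from <- c(rep(src, sum(s_keep)), which(k_keep), efrom)
  to <- c(which(s_keep), rep(snk, sum(k_keep)), eto)
  caps <- c(cap_src[s_keep], cap_snk[k_keep], ecap)
  g <- igraph::make_graph(rbind(from, to), n = n + 2L, directed = TRUE)
  mf <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  take <- mf$partition1[mf$partition1 <= n]
  out <- labeling
  out[as.integer(take)] <- alpha
  out
}

#' Minimize the MRF energy by alpha-expansion
#'
#' Iterates expansion moves over the three labels, each solved exactly as
#' a min cut, until a full sweep yields no energy decrease. The pairwise
#' term is a weighted Potts metric, so every move is optimal and the
#' energy is non-increasing across moves (asserted). Expansion converges
#' to a move-optimal labeling that can still be a local optimum, so by
#' default the solver restarts from the maximum-likelihood labeling and
#' from each constant labeling and keeps the lowest-energy result.
#'
#' @param model a [build_energy()] object.
#' @param init_labeling starting labeling; `NULL` (default) uses the
#'   multi-start strategy above, a matrix runs a single descent from it.
#' @param max_sweeps sweep cap per start (default 10).
#' @return list with `labeling`, `energy`, `sweeps`, and the per-move
#'   `energy_trace` of the winning start.
#' @export
alpha_expansion <- function(model, init_labeling = NULL, max_sweeps = 10) {
  inits <- if (is.null(init_labeling)) {
    nr <- model$dims[1]; nc <- model$dims[2]
    c(list(ml_labeling(model)),
      lapply(seq_along(model$labels), function(k) matrix(k, nr, nc)))
  } else {
    list(init_labeling)
  }
  best <- NULL
  for (init in inits) {
    run <- expansion_descent(model, init, max_sweeps)
    if (is.null(best) || run$energy < best$energy) best <- run
  }
  best
}

expansion_descent <- function(model, lab, max_sweeps) {
  e <- mrf_energy(model, lab)
  trace <- e
  sweep <- 0
  for (sweep in seq_len(max_sweeps)) {
    improved <- FALSE
    for (alpha in seq_along(model$labels)) {
      cand <- expand_move(model, lab, alpha)
      ec <- mrf_energy(model, cand)
      if (ec > e + 1e-6 * max(1, abs(e)))
        stopf("internal error: expansion move increased the energy")
      if (ec < e - 1e-9) {
        lab <- cand; e <- ec; improved <- TRUE
      }
      trace <- c(trace, e)
    }
    if (!improved) break
  }
  list(labeling = lab, energy = e, sweeps = sweep, energy_trace = trace)
}

#' Quantiles of the unary potentials
#'
#' The pairwise strengths are chosen manually relative to the unary
#' distribution; this helper prints the quantiles that guide that choice.
#'
#' @param model a [build_energy()] object.
#' @param probs quantile probabilities.
#' @return matrix of quantiles (rows = probs, cols = labels).
#' @export
unary_quantiles <- function(model, probs = c(0.05, 0.25, 0.5, 0.75,
                                             0.95)) {
  sapply(1:3, function(l) quantile(model$unary[, , l], probs))
}

#' Segment confocal channels and overlay the results
#'
#' Per channel: maximum-intensity projection (for z-stacks), 8-bit
#' scaling, local entropy filtering, mixture fit, energy construction and
#' alpha-expansion. The per-channel 'in focus cells' labels are overlaid
#' to display co-localization.
#'
#' @param stack named list of channels; each a matrix or 3-D array
#'   (rows x cols x z).
#' @param channels names of the channels to segment (default: all).
#' @param config [default_config()]-style list.
#' @param seed RNG seed for the mixture fits.
#' @return list with per-channel `labels` (integer matrices), `mixtures`,
#'   and `overlay` (0 none, 1 first channel, 2 second, 3 both).
#' @export
segment_stack <- function(stack, channels = names(stack),
                          config = default_config(), seed = 1) {
  if (is.null(channels) || length(channels) == 0)
    stopf("no channels requested")
  missing <- setdiff(channels, names(stack))
  if (length(missing))
    stopf("channel '%s' missing from the stack", missing[1])
  mp <- config$mrf
  res <- list(); mixtures <- list()
  for (ch in channels) {
    img <- stack[[ch]]
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), max)
    img8 <- scale_to_8bit(img)
    feat <- entropy_filter(img8, mp$entropy_radius)
    fit_on <- if (mp$unary_on == "entropy") feat else img8
    mix <- fit_mixture3(as.vector(fit_on), seed = seed,
                        restarts = mp$restarts)
    model <- build_energy(fit_on, mix, mp$lambda0, mp$lambda1, mp$beta,
                          contrast_img = img8)
    sol <- alpha_expansion(model, max_sweeps = mp$max_sweeps)
    res[[ch]] <- sol$labeling
    mixtures[[ch]] <- mix
  }
  overlay <- NULL
  if (length(channels) >= 1) {
    infocus <- lapply(res, function(l) l == 3L)
    overlay <- matrix(0L, nrow(infocus[[1]]), ncol(infocus[[1]]))
    if (length(channels) >= 1) overlay <- overlay + infocus[[1]]
    if (length(channels) >= 2) overlay <- overlay + 2L * infocus[[2]]
  }
  list(labels = res, mixtures = mixtures, overlay = overlay)
}
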