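toy_mixture <- function(means = c(50, 120, 200), sigmas = c(20, 25, 30)) {
  structure(list(weight = rep(1 / 3, 3), mean = means, sigma = sigmas,
                 labels = organotrack:::MRF_LABELS, loglik = 0),
            class = "MixtureModel3")
}

test_that("the three-component mixture fit recovers simulated parameters", {
  set.seed(13)
  vals <- c(rnorm(1000, 10, 5), rnorm(1000, 100, 5), rnorm(1000, 200, 5))
  fit <- fit_mixture3(vals, seed = 2)
  expect_true(all(abs(fit$mean - c(10, 100, 200)) < 2))
  expect_true(all(diff(fit$mean) > 0))
  expect_equal(sum(fit$weight), 1, tolerance = 1e-9)
  expect_true(all(abs(fit$weight - 1 / 3) < 0.05))

  fit2 <- fit_mixture3(vals, seed = 2)
  expect_identical(fit, fit2)

  # independent EM implementation agrees on the component means
  # (Mclust resolves mclustBIC in the caller's scope, hence the alias)
  mclustBIC <- mclust::mclustBIC
  mc <- mclust::Mclust(vals, G = 3, modelNames = "V", verbose = FALSE)
  expect_true(all(abs(sort(as.numeric(mc$parameters$mean)) - fit$mean)
                  < 1))

  # two-value data: degenerate component handled with a floored sigma
  twov <- rep(c(0, 100), each = 400)
  expect_warning(fitd <- fit_mixture3(twov, seed = 1), "degenerate")
  expect_true(all(fitd$sigma >= 1e-3))
  expect_error(fit_mixture3(rnorm(50), seed = 1), ">= 300")
  expect_error(fit_mixture3(rep(1, 500), seed = 1), "constant")
})

test_that("energy construction follows the unary and pairwise formulas", {
  img <- matrix(c(10, 200, 100, 10), 2, 2)
  mix <- toy_mixture()
  lam0 <- 0.7; lam1 <- 1.3; beta <- 0.01
  model <- build_energy(img, mix, lam0, lam1, beta)
  # hand-computed energy of a fixed labeling on the 2x2 grid
  lab <- matrix(c(1L, 3L, 2L, 1L), 2, 2)
  unary <- sum(-log(pmax(dnorm(img[1, 1], 50, 20), 1e-12)),
               -log(pmax(dnorm(img[2, 1], 200, 30), 1e-12)),
               -log(pmax(dnorm(img[1, 2], 120, 25), 1e-12)),
               -log(pmax(dnorm(img[2, 2], 50, 20), 1e-12)))
  w <- function(a, b) lam0 + lam1 * exp(-0.5 * beta * (a - b)^2)
  pair <- w(10, 200) +      # vertical left pair, labels 1 vs 3
    w(100, 10) +            # vertical right pair, labels 2 vs 1
    w(10, 100) +            # horizontal top pair, labels 1 vs 2
    w(200, 10)              # horizontal bottom pair, labels 3 vs 1
  expect_equal(mrf_energy(model, lab), unary + pair, tolerance = 1e-12)

  # lambda0 = lambda1 = 0: pairwise term vanishes
  m0 <- build_energy(img, mix, 0, 0, beta)
  expect_equal(mrf_energy(m0, lab),
               unary, tolerance = 1e-12)
  # beta = 0 reduces to a plain Potts penalty
  mp <- build_energy(img, mix, lam0, lam1, 0)
  expect_equal(mrf_energy(mp, lab), unary + 4 * (lam0 + lam1),
               tolerance = 1e-12)
  expect_error(build_energy(img, mix, -1, 0, 0.1), "lambda")
})

test_that("alpha-expansion attains the exhaustive minimum on tiny instances", {
  mix <- toy_mixture()
  for (s in 1:15) {
    set.seed(s)
    img <- matrix(runif(9, 0, 255), 3, 3)
    model <- build_energy(img, mix, runif(1, 0, 2), runif(1, 0, 3),
                          runif(1, 0, 0.02))
    sol <- alpha_expansion(model)
    expect_equal(sol$energy, oracle_mrf_minimum(model), tolerance = 1e-9)
    # energy trace never increases
    expect_true(all(diff(sol$energy_trace) <= 1e-9))
  }
})

test_that("the decoupled limit equals per-pixel maximum likelihood", {
  img <- rmat(12, 12, 3)
  model <- build_energy(img, toy_mixture(), 0, 0, 0.05)
  sol <- alpha_expansion(model)
  expect_identical(sol$labeling, ml_labeling(model))
})

test_that("noisy three-region phantoms are segmented accurately", {
  ph <- generate_mrf_image(c(96, 96), means = c(10, 100, 200),
                           sigmas = c(15, 15, 15), seed = 5)
  mix <- fit_mixture3(as.vector(ph$image), seed = 2)
  model <- build_energy(ph$image, mix, 0.5, 2, 0.01)
  sol <- alpha_expansion(model)
  expect_gte(mean(sol$labeling == ph$labels), 0.98)
  # smoothing should not do worse than the pointwise ML labeling
  expect_gte(mean(sol$labeling == ph$labels),
             mean(ml_labeling(model) == ph$labels))
})

test_that("stack segmentation overlays channels and is deterministic", {
  set.seed(99)
  nr <- 72
  disc1 <- organotrack:::draw_disc(nr, nr, 18, 36, 11)
  disc2 <- organotrack:::draw_disc(nr, nr, 54, 36, 11)
  mk <- function(disc) {
    img <- 20 + 160 * disc + matrix(rnorm(nr * nr, 0, 6), nr, nr)
    organotrack:::gauss_blur(img, 1)
  }
  stack <- list(tumor = mk(disc1), caf = mk(disc2))
  cfg <- default_config()
  cfg$mrf$entropy_radius <- 3
  res <- segment_stack(stack, config = cfg, seed = 4)
  # disjoint, well-separated objects: no "both" pixels
  expect_equal(sum(res$overlay == 3), 0)
  expect_gt(sum(res$overlay == 1), 0)
  expect_gt(sum(res$overlay == 2), 0)

  res2 <- segment_stack(stack, config = cfg, seed = 4)
  expect_identical(res$labels, res2$labels)
  expect_error(segment_stack(stack, channels = c("tumor", "nuclei"),
                             config = cfg),
               "nuclei")

  # a z-stack input is reduced by maximum projection
  zstack <- array(0, c(nr, nr, 3))
  zstack[, , 2] <- stack$tumor
  res4 <- segment_stack(list(tumor = zstack, caf = stack$caf),
                        config = cfg, seed = 4)
  expect_identical(res4$labels$tumor, res$labels$tumor)
})

test_that("channel overlays report co-localized area faithfully", {
  # raw-intensity unaries localize boundaries sharply, so the overlap of
  # two partially co-localized objects is recovered to within 10%
  set.seed(7)
  nr <- 96
  disc1 <- organotrack:::draw_disc(nr, nr, 38, 48, 22)
  disc3 <- organotrack:::draw_disc(nr, nr, 56, 48, 22)
  halo1 <- organotrack:::draw_disc(nr, nr, 38, 48, 28) - disc1
  halo3 <- organotrack:::draw_disc(nr, nr, 56, 48, 28) - disc3
  mk <- function(disc, halo)
    20 + 80 * halo + 160 * disc + matrix(rnorm(nr * nr, 0, 6), nr, nr)
  cfg <- default_config()
  cfg$mrf$unary_on <- "raw"
  res <- segment_stack(list(tumor = mk(disc1, halo1),
                            caf = mk(disc3, halo3)),
                       config = cfg, seed = 4)
  true_overlap <- sum(disc1 * disc3)
  expect_lt(abs(sum(res$overlay == 3) - true_overlap) / true_overlap,
            0.1)
})
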