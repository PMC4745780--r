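test_that("adaptive threshold equals the direct formula oracle", {
  for (s in 1:5) {
    img <- rmat(24, 24, 100 + s)
    p <- adaptive_threshold_params(block_halfwidth = 5, kappa = 2)
    expect_identical(adaptive_threshold(img, p),
                     oracle_adaptive_mask(img, 5, p$sigma, 2))
  }
})

test_that("adaptive threshold behaves correctly in its limits", {
  flat <- matrix(77, 32, 32)
  p <- adaptive_threshold_params(5, kappa = 2)
  expect_equal(sum(adaptive_threshold(flat, p)), 0)

  img <- matrix(10, 41, 41)
  img[16:26, 16:26] <- 200
  m <- adaptive_threshold(img, adaptive_threshold_params(10, kappa = 2))
  expect_true(all(m[18:24, 18:24] == 1))  # bright block interior on
  expect_true(all(m[1:5, 1:5] == 0))      # far background off

  # kappa below the intensity range: everything passes
  p_low <- adaptive_threshold_params(5, kappa = -300)
  expect_true(all(adaptive_threshold(img, p_low) == 1))

  # monotonicity: larger kappa never adds foreground
  img2 <- rmat(32, 32, 9)
  kappas <- c(-5, 0, 2, 10)
  masks <- lapply(kappas, function(k)
    adaptive_threshold(img2, adaptive_threshold_params(5, kappa = k)))
  for (i in 2:length(masks))
    expect_true(all(masks[[i]] <= masks[[i - 1]]))
})

test_that("small-region cleaning keeps exactly the large components", {
  m <- matrix(0L, 30, 60)
  m[2:8, 2:8] <- 1L          # 49 px
  m[10:26, 40:42] <- 1L      # 51 px
  cl <- clean_mask(m, 50)
  expect_equal(sum(cl), 51)
  expect_true(all(cl[10:26, 40:42] == 1))

  expect_equal(sum(clean_mask(matrix(0L, 10, 10), 50)), 0)

  set.seed(8)
  rm_ <- matrix(rbinom(400, 1, 0.35), 20, 20)
  lab <- oracle_label8(rm_)
  keep <- which(tabulate(lab[lab > 0]) >= 5)
  expected <- (lab %in% keep) * 1L
  dim(expected) <- dim(rm_)
  expect_equal(clean_mask(rm_, 5), expected)
})

test_that("hole filling restores enclosed interiors only", {
  m <- matrix(0L, 20, 20)
  m[5:15, 5:15] <- 1L
  m[8:12, 8:12] <- 0L              # enclosed hole
  f <- fill_holes(m)
  expect_true(all(f[8:12, 8:12] == 1))
  expect_equal(sum(f), 11 * 11)
  # open bay touching the border is not filled
  m2 <- matrix(0L, 10, 10)
  m2[1:10, 4:6] <- 1L
  m2[1:5, 5] <- 0L
  expect_equal(fill_holes(m2), m2)
})

test_that("cohort extraction yields correct areas and closed contours", {
  m <- matrix(0L, 40, 40)
  m[5:24, 5:24] <- 1L
  co <- extract_cohorts(m)
  expect_equal(length(co), 1)
  expect_equal(co[[1]]$area, 400)
  expect_equal(unname(co[[1]]$bbox), c(4, 23, 4, 23))
  # contour vertices lie on the square's border ring
  expect_true(all(co[[1]]$contour[, 1] %in% c(4:23)))
  expect_true(all(co[[1]]$contour[, 1] == 4 | co[[1]]$contour[, 1] == 23 |
                    co[[1]]$contour[, 2] == 4 | co[[1]]$contour[, 2] == 23))

  m2 <- matrix(0L, 50, 50)
  m2 <- m2 + organotrack:::draw_disc(50, 50, 12, 12, 7) +
    organotrack:::draw_disc(50, 50, 36, 36, 9)
  co2 <- extract_cohorts(m2)
  expect_equal(length(co2), 2)
  expect_equal(sort(vapply(co2, `[[`, 0, "area")),
               sort(c(sum(organotrack:::draw_disc(50, 50, 12, 12, 7)),
                      sum(organotrack:::draw_disc(50, 50, 36, 36, 9)))))

  # component touching the border still produces a closed, in-range contour
  m3 <- matrix(0L, 20, 20)
  m3[1:6, 1:6] <- 1L
  co3 <- extract_cohorts(m3)
  expect_equal(co3[[1]]$area, 36)
  expect_true(all(co3[[1]]$contour >= 0 & co3[[1]]$contour <= 19))
})

test_that("area and growth-rate series follow the phantom ground truth", {
  empty <- mask_sequence(list(matrix(0L, 8, 8), matrix(0L, 8, 8)))
  expect_equal(fibroblast_area_series(empty), c(0, 0))

  sim <- generate_cohort_sequence(6, 0, 0.1, 5, 0, seed = 14,
                                  width = 192, height = 192)
  masks <- mask_sequence(lapply(sim$fluor$frames, function(f)
    (f > 100) * 1L))
  a <- fibroblast_area_series(masks)
  expect_true(all(abs(a / sim$truth$area - 1) < 0.05))

  g <- growth_rate_series(a)
  expect_equal(g[1], 1)
  expect_true(all(abs(g / 1.1^(0:5) - 1) < 0.05))

  expect_equal(growth_rate_series(c(100, 150, 200)), c(1, 1.5, 2))
  expect_equal(growth_rate_series(rep(42, 4)), rep(1, 4))
  expect_error(growth_rate_series(c(0, 10)), "initial area")
})

test_that("segmented phantom growth correlates with truth (r > 0.99)", {
  sim <- generate_cohort_sequence(8, 0, 0.12, 5, 4, seed = 23,
                                  width = 160, height = 160)
  masks <- segment_fibroblasts(sim$fluor, default_config())
  a <- fibroblast_area_series(masks)
  expect_gt(cor(a, sim$truth$area), 0.99)
})
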