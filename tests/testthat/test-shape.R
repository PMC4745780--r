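test_that("convex hull agrees with the brute-force side test", {
  sq <- cbind(x = c(0, 5, 10, 10, 10, 5, 0, 0),
              y = c(0, 0, 0, 5, 10, 10, 10, 5))
  h <- convex_hull(sq)
  expect_setequal(sq[h, 1] + 1i * sq[h, 2], c(0, 10, 10 + 10i, 10i))

  for (s in 1:5) {
    set.seed(s)
    pts <- cbind(runif(100, 0, 50), runif(100, 0, 50))
    h <- convex_hull(pts)
    expect_true(oracle_is_hull(pts, h))
  }
  # convex polygon is its own hull
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  poly <- cbind(10 * cos(ang), 10 * sin(ang))
  expect_setequal(convex_hull(poly), 1:12)
  expect_error(convex_hull(cbind(1:5, 1:5)), "collinear")
})

test_that("convexity defects locate notches with analytic depth", {
  ang <- seq(0, 2 * pi, length.out = 21)[-21]
  disc <- cbind(20 * cos(ang), 20 * sin(ang))
  expect_equal(length(convexity_defects(disc, convex_hull(disc))), 0)

  st <- generate_star_contour(5, 30, 13)
  d <- convexity_defects(st$contour, convex_hull(st$contour))
  expect_equal(length(d), 5)
  for (def in d)
    expect_equal(def$depth, st$notch_depth, tolerance = 1e-9)

  # square with one 10-px-deep notch along its top edge
  notched <- cbind(x = c(0, 12, 14, 16, 18, 30, 30, 0),
                   y = c(0, 0, 10, 10, 0, 0, 30, 30))
  d2 <- convexity_defects(notched, convex_hull(notched))
  expect_equal(length(d2), 1)
  expect_equal(d2[[1]]$depth, 10, tolerance = 0.5)
})

test_that("branch metrics count only defects beyond the depth threshold", {
  ang <- seq(0, 2 * pi, length.out = 41)[-41]
  disc <- cbind(15 * cos(ang), 15 * sin(ang))
  expect_equal(branch_metrics(disc, 5)$n_extensions, 0)
  expect_equal(branch_metrics(disc, 5)$mean_extension_size, 0)

  st <- generate_star_contour(5, 40, 40 * cos(pi / 5) - 20)
  bm <- branch_metrics(st$contour, 5)
  expect_equal(bm$n_extensions, 5)
  expect_equal(bm$mean_extension_size, 20, tolerance = 1e-9)
  expect_equal(branch_metrics(st$contour, 25)$n_extensions, 0)

  # non-increasing in the threshold
  counts <- vapply(c(0, 5, 10, 19, 21),
                   function(th) branch_metrics(st$contour, th)$n_extensions,
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("defect depths survive rasterization, rotation and translation", {
  base <- organotrack:::draw_star_mask(120, 120, 59, 59, 5, 40, 18)
  co <- extract_cohorts(base)[[1]]
  bm <- branch_metrics(co$contour, 5)
  true_depth <- 40 * cos(pi / 5) - 18
  expect_equal(bm$n_extensions, 5)
  expect_true(all(abs(bm$extension_sizes - true_depth) <= 1))

  rot <- organotrack:::draw_star_mask(120, 120, 59, 59, 5, 40, 18,
                                      phase = 0.7)
  shifted <- circshift(organotrack:::draw_star_mask(120, 120, 45, 52, 5,
                                                    40, 18), 6, 9)
  for (m in list(rot, shifted)) {
    b <- branch_metrics(extract_cohorts(m)[[1]]$contour, 5)
    expect_equal(b$n_extensions, 5)
    expect_true(all(abs(b$extension_sizes - true_depth) <= 1))
  }
})

test_that("per-frame branching series averages across cohorts", {
  blank <- organotrack:::draw_disc(80, 80, 40, 40, 15)
  ms <- mask_sequence(list(blank, blank))
  bs <- branching_series(ms, 5, min_area = 50)
  expect_equal(bs$mean_extensions, c(0, 0))

  # two cohorts with 3 and 5 branches -> mean 4
  two <- organotrack:::draw_star_mask(160, 160, 42, 42, 3, 30, 7) +
    organotrack:::draw_star_mask(160, 160, 115, 115, 5, 30, 12)
  bs2 <- branching_series(mask_sequence(list(two)), 5, min_area = 50)
  expect_equal(bs2$n_cohorts, 2)
  expect_equal(bs2$mean_extensions, 4)

  # constant 5-branch phantom: flat series at exactly 5 on clean masks
  st <- organotrack:::draw_star_mask(120, 120, 59, 59, 5, 40, 18)
  bs3 <- branching_series(mask_sequence(list(st, st, st)), 5)
  expect_equal(bs3$mean_extensions, c(5, 5, 5))

  # no cohorts at all -> NaN-flagged frame
  bs4 <- branching_series(mask_sequence(list(matrix(0L, 20, 20))), 5)
  expect_true(is.nan(bs4$mean_extensions))
})
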