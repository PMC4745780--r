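test_that("organoid parameters match geometric expectations", {
  d <- organotrack:::draw_disc(64, 64, 31, 31, 20)
  rec <- measure_organoid(d, d * 100)
  expect_equal(rec$Area, sum(d))
  expect_gt(rec$Roundness, 0.95)       # isoperimetric identity
  expect_lte(rec$Roundness, 1)
  expect_equal(rec$AppNumber, 0)
  expect_equal(rec$MaxApp, 0)
  expect_equal(rec$MedApp, 0)
  expect_equal(rec$Density, 100)       # uniform intensity
  expect_equal(rec$CellNumber, sum(d) / 250)
  expect_error(measure_organoid(matrix(0L, 8, 8), matrix(0, 8, 8)),
               "empty")
})

test_that("roundness is invariant to rotation and translation", {
  st1 <- organotrack:::draw_star_mask(100, 100, 49, 49, 5, 30, 14)
  st2 <- organotrack:::draw_star_mask(100, 100, 49, 49, 5, 30, 14,
                                      phase = 1.1)
  st3 <- circshift(st1, 9, -7)
  r <- vapply(list(st1, st2, st3), function(m)
    measure_organoid(m, m)$Roundness, 0)
  expect_lt(max(abs(r / r[1] - 1)), 0.05)
  expect_lt(r[1], 0.6)  # a star is far from a disc
})

test_that("appendage metrics follow the drawn ground truth", {
  f <- generate_organoid_field(3, c(14, 18),
                               appendage_spec = list(list(count = 1,
                                                          length = 30)),
                               seed = 4, shape = c(200, 200))
  rec <- measure_field(f$labels, f$image)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$Area, f$truth$area)
  expect_true(all(rec$AppNumber == 1))
  expect_true(all(abs(rec$MaxApp - 30) <= 2))
  expect_true(all(rec$MaxApp >= rec$MedApp))
  # FiltRound: the opened body is the disc, nearly round again
  expect_true(all(rec$FiltRound > rec$Roundness))

  multi <- generate_organoid_field(2, c(16, 18),
                                   appendage_spec = list(
                                     list(count = 3, length = 20)),
                                   seed = 8, shape = c(220, 220))
  rec2 <- measure_field(multi$labels, multi$image)
  expect_true(all(rec2$AppNumber == 3))
  expect_true(all(abs(rec2$MaxApp - 20) <= 2))
})

test_that("Mann-Whitney comparisons match the exact permutation oracle", {
  grp <- list(ctrl = data.frame(Area = c(6, 7, 8, 9, 10)),
              drug = data.frame(Area = c(1, 2, 3, 4, 5)))
  cmp <- compare_groups(grp, "ctrl", test = "mannwhitney")
  expect_equal(cmp$p_raw, 0.007937, tolerance = 1e-4)
  expect_equal(cmp$p_raw, oracle_mw_pvalue(grp$drug$Area, grp$ctrl$Area),
               tolerance = 1e-9)
  expect_equal(cmp$direction, "decreased")
  # single comparison: Bonferroni leaves p unchanged
  expect_equal(cmp$p_adj, cmp$p_raw)

  # permutation-oracle agreement across group sizes up to 6
  set.seed(10)
  for (n in 3:6) {
    pool <- sample(seq_len(1000), 2 * n)  # tie-free pooled sample
    x <- pool[1:n]; y <- pool[(n + 1):(2 * n)]
    g <- list(a = data.frame(v = x), b = data.frame(v = y))
    got <- compare_groups(g, "a", test = "mannwhitney")$p_raw
    expect_equal(got, oracle_mw_pvalue(y, x), tolerance = 1e-9)
  }
})

test_that("group comparisons handle identical groups and multiplicity", {
  set.seed(2)
  base <- data.frame(Area = rnorm(20, 100, 10), Roundness = runif(20))
  grp <- list(ctrl = base, same = base,
              big = transform(base, Area = Area * 3))
  cmp <- compare_groups(grp, "ctrl", test = "mannwhitney")
  same_area <- cmp[cmp$group == "same" & cmp$parameter == "Area", ]
  expect_equal(same_area$p_adj, 1)
  expect_equal(same_area$direction, "none")
  big_area <- cmp[cmp$group == "big" & cmp$parameter == "Area", ]
  expect_equal(big_area$direction, "increased")
  # Bonferroni: adjusted >= raw, scaled by the number of comparisons
  expect_true(all(cmp$p_adj >= cmp$p_raw))
  expect_equal(cmp$p_adj, pmin(1, cmp$p_raw * nrow(cmp)))

  cmp_t <- compare_groups(grp, "ctrl", test = "ttest")
  expect_true(all(cmp_t$test == "ttest"))
  expect_error(compare_groups(grp, "nope"), "not found")
  expect_error(compare_groups(list(a = base, b = base[1:2, ]), "a"),
               "fewer than 3")
})

test_that("two-sided tests reject reliably under a 2-sigma shift", {
  set.seed(123)
  hits <- 0
  for (r in 1:200) {
    x <- rnorm(50, 0, 1); y <- rnorm(50, 2, 1)
    g <- list(a = data.frame(v = x), b = data.frame(v = y))
    p <- compare_groups(g, "a", test = "mannwhitney")$p_raw
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / 200, 0.99)
})

test_that("heatmap matrices are the log2 median fold changes", {
  set.seed(3)
  ctrl <- data.frame(Area = rnorm(12, 100, 5), Density = rnorm(12, 50, 2))
  dbl <- transform(ctrl, Area = Area * 2)
  grp <- list(ctrl = ctrl, ctrl2 = ctrl, dbl = dbl)
  cmp <- compare_groups(grp, "ctrl")
  hm <- heatmap_matrix(cmp, grp, "ctrl")
  expect_equal(hm$log2fc["Area", "ctrl2"], 0)
  expect_equal(hm$log2fc["Density", "ctrl2"], 0)
  expect_equal(hm$log2fc["Area", "dbl"], 1)
  expect_equal(dim(hm$p), dim(hm$log2fc))
  # hand-computed median ratio
  expect_equal(hm$log2fc["Density", "dbl"],
               log2(median(dbl$Density) / median(ctrl$Density)))
  # zero control median is flagged, not an error
  grp0 <- list(ctrl = data.frame(v = c(0, 0, 0, 0)),
               g = data.frame(v = c(1, 2, 3, 4)))
  cmp0 <- compare_groups(grp0, "ctrl")
  expect_warning(hm0 <- heatmap_matrix(cmp0, grp0, "ctrl"), "zero control")
  expect_true(is.nan(hm0$log2fc["v", "g"]))
})

test_that("growth normalization reproduces the inhibition arithmetic", {
  ctrl <- c(1, 2, 4, 8, 10)
  same <- normalize_growth_to_control(list(t = ctrl), ctrl)
  expect_equal(same$curves$t, rep(100, 5))
  expect_equal(unname(same$inhibition_pct["t"]), 0)

  res <- normalize_growth_to_control(list(drug = 0.37 * ctrl), ctrl)
  expect_equal(unname(res$inhibition_pct["drug"]), 63)

  res0 <- normalize_growth_to_control(list(dead = ctrl * 0), ctrl)
  expect_equal(unname(res0$inhibition_pct["dead"]), 100)

  expect_error(normalize_growth_to_control(list(x = 1:3), 1:4),
               "time base")
  expect_error(normalize_growth_to_control(list(x = 1:3), c(1, 2, 0)),
               "positive")
})

test_that("curve smoothing is a centered moving average with edge windows", {
  x <- c(1, 2, 3, 4, 5, 6)
  s <- smooth_curve(x, 3)
  expect_equal(s, c(mean(x[1:2]), 2, 3, 4, 5, mean(x[5:6])))
  expect_equal(smooth_curve(rep(7, 10), 5), rep(7, 10))
  expect_error(smooth_curve(x, 4), "odd")
})
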