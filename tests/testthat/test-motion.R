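test_that("flow of identical frames is identically zero", {
  a <- rmat(64, 64, 17)
  fl <- farneback_flow(a, a)
  expect_true(all(fl$dx == 0) && all(fl$dy == 0))
})

test_that("global translations are recovered against a block-matching oracle", {
  tex <- organotrack:::gauss_blur(rmat(128, 128, 7), 2)
  sub <- 20:108
  for (d in list(c(3, 0), c(0, 2), c(2, -2))) {
    b <- circshift(tex, d[1], d[2])
    fl <- farneback_flow(tex, b)
    expect_lt(abs(median(fl$dx[sub, sub]) - d[1]), 0.2)
    expect_lt(abs(median(fl$dy[sub, sub]) - d[2]), 0.2)
    expect_equal(oracle_best_shift(tex, b, 6), d)
    # flow agrees with the brute-force oracle within 0.5 px
    expect_lt(abs(median(fl$dx[sub, sub]) - oracle_best_shift(tex, b, 6)[1]),
              0.5)
  }
})

test_that("flow is anti-symmetric on smooth translations", {
  tex <- organotrack:::gauss_blur(rmat(96, 96, 29), 2)
  b <- circshift(tex, 3, 1)
  f <- farneback_flow(tex, b)
  r <- farneback_flow(b, tex)
  sub <- 15:80
  expect_lt(median(abs(f$dx[sub, sub] + r$dx[sub, sub])), 0.3)
  expect_lt(median(abs(f$dy[sub, sub] + r$dy[sub, sub])), 0.3)
})

test_that("two objects with different motions are both recovered", {
  bg <- matrix(10, 128, 128)
  set.seed(41)
  obj <- organotrack:::granular_field(128, 128, amp = 0.3, cells = 20)
  d1 <- organotrack:::draw_disc(128, 128, 35, 60, 18)
  d2 <- organotrack:::draw_disc(128, 128, 92, 60, 18)
  frame_at <- function(s1, s2) {
    o1 <- circshift(150 * obj * d1, s1[1], s1[2])
    o2 <- circshift(150 * obj * d2, s2[1], s2[2])
    bg + o1 + o2
  }
  a <- frame_at(c(0, 0), c(0, 0))
  b <- frame_at(c(2, 0), c(0, 2))
  fl <- farneback_flow(a, b)
  core1 <- organotrack:::draw_disc(128, 128, 35, 60, 10) != 0
  core2 <- organotrack:::draw_disc(128, 128, 92, 60, 10) != 0
  expect_lt(abs(median(fl$dx[core1]) - 2), 0.5)
  expect_lt(abs(median(fl$dy[core1]) - 0), 0.5)
  expect_lt(abs(median(fl$dx[core2]) - 0), 0.5)
  expect_lt(abs(median(fl$dy[core2]) - 2), 0.5)
})

test_that("masked mean motion reduces to the arithmetic definition", {
  zero <- structure(list(dx = matrix(0, 8, 8), dy = matrix(0, 8, 8),
                         valid = matrix(TRUE, 8, 8)), class = "FlowField")
  mask <- matrix(1L, 8, 8)
  expect_equal(mean_motion_per_frame(zero, mask), 0)
  expect_equal(mean_motion_per_frame(zero, matrix(0L, 8, 8)), 0)

  f34 <- structure(list(dx = matrix(3, 8, 8), dy = matrix(4, 8, 8),
                        valid = matrix(TRUE, 8, 8)), class = "FlowField")
  m <- matrix(0L, 8, 8); m[3:5, 2:7] <- 1L
  expect_equal(mean_motion_per_frame(f34, m), 5)
  expect_equal(unname(mean_velocity_per_frame(f34, m)), c(3, 4))

  set.seed(6)
  rf <- structure(list(dx = matrix(rnorm(64), 8, 8),
                       dy = matrix(rnorm(64), 8, 8),
                       valid = matrix(TRUE, 8, 8)), class = "FlowField")
  rm_ <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(mean_motion_per_frame(rf, rm_),
               mean(sqrt(rf$dx[rm_ == 1]^2 + rf$dy[rm_ == 1]^2)))
  expect_error(mean_motion_per_frame(rf, matrix(1L, 4, 4)), "shape")
})

test_that("motility curves track phantom velocity and stabilization helps", {
  static <- generate_cohort_sequence(3, 0, 0, 5, 0, seed = 31,
                                     width = 128, height = 128)
  masks_s <- mask_sequence(lapply(static$fluor$frames,
                                  function(f) (f > 100) * 1L))
  mot_s <- motion_series(static$fluor, masks_s, default_config())
  expect_true(all(mot_s < 0.05))

  moving <- generate_cohort_sequence(5, 0, 0, 5, 2, seed = 32,
                                     width = 160, height = 160,
                                     velocity = c(2, 0))
  masks_m <- mask_sequence(lapply(moving$fluor$frames,
                                  function(f) (f > 100) * 1L))
  mot_m <- motion_series(moving$fluor, masks_m, default_config())
  expect_true(all(abs(mot_m / 2 - 1) < 0.15))

  # jittery input inflates apparent motion; stabilization removes it
  jit <- generate_cohort_sequence(5, 5, 0, 5, 2, seed = 33,
                                  width = 160, height = 160)
  masks_j <- mask_sequence(lapply(jit$fluor$frames,
                                  function(f) (f > 100) * 1L))
  mot_raw <- motion_series(jit$fluor, masks_j, default_config())
  st <- stabilize_sequence(jit$phase, subpixel = FALSE, window = "none")
  stab_fl <- apply_stabilization(jit$fluor, st)
  masks_st <- mask_sequence(lapply(stab_fl$frames,
                                   function(f) (f > 100) * 1L))
  mot_st <- motion_series(stab_fl, masks_st, default_config())
  expect_lt(mean(mot_st), mean(mot_raw))
})
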