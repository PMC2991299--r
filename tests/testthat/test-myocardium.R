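mph <- make_myo_phantom(phantom_config("myo"), seed = 5)
myo_roi <- phantom_myo_roi()

test_that("cluster_profiles is deterministic under a fixed seed", {
  pr <- pixel_velocity_profiles(mph$series, myo_roi)
  dims <- dim(mph$series$velocity)[2:3]
  cl1 <- cluster_profiles(pr$profiles, pr$pixels, dims, k = 7, seed = 3)
  cl2 <- cluster_profiles(pr$profiles, pr$pixels, dims, k = 7, seed = 3)
  expect_identical(cl1$label_map, cl2$label_map)
  expect_equal(sort(unique(as.integer(cl1$label_map[cl1$label_map >= 0]))),
               0:6)
  expect_equal(sum(cl1$label_map >= 0), nrow(pr$profiles))
  expect_true(all(cl1$label_map[cl1$label_map < 0] == -1L))
})

test_that("myocardial_cluster picks the largest spatially connected region", {
  lab <- matrix(-1L, 8, 8)   # -1 = outside the ROI
  lab[2:5, 2:5] <- 1L     # 16-px block, label 1
  lab[7:8, 7:8] <- 2L     # 4-px block, label 2
  lab[1, 8] <- 1L         # far-away speck of label 1: not connected
  m <- myocardial_cluster(lab)
  expect_equal(sum(m), 16)
  expect_true(all(m[2:5, 2:5]))
  expect_false(m[1, 8])
})

test_that("myocardial pipeline recovers the ring and E' on the phantom", {
  mp <- analyze_myocardium(mph$series, myo_roi, seed = 3)
  expect_equal(overlap_percentage(mp$myocardial_mask, mph$truth$ring_mask),
               100)
  expect_lt(abs(mp$E_prime - mph$truth$E_prime) / mph$truth$E_prime, 0.10)
  expect_equal(mp$t_E_prime, mph$truth$t_E_prime, tolerance = 1e-8)
  expect_equal(mp$direction, -1)   # diastolic annular motion is negative here
  expect_true(is.na(mp$E_over_Eprime))

  mp2 <- analyze_myocardium(mph$series, myo_roi, seed = 3, E_velocity = 80)
  expect_equal(mp2$E_over_Eprime, 80 / mp2$E_prime)
})

test_that("detect_e_prime respects an explicit filling window", {
  tt <- seq(0, 880, by = 20)
  pk <- function(t, tp, amp, half = 60)
    amp * pmax(0, 1 - abs(t - tp) / half)
  v <- -(pk(tt, 200, 8.5) + pk(tt, 560, 11.3) + pk(tt, 800, 6))
  cv <- time_curve(tt, v)
  ep <- detect_e_prime(cv, filling_window = c(440, 900))
  expect_equal(ep$E_prime, 11.3)
  expect_equal(ep$t_E_prime, 560)
  expect_equal(ep$direction, -1)
  # auto-derived window finds the same early-diastolic peak
  ep2 <- detect_e_prime(cv)
  expect_equal(ep2$E_prime, 11.3)
  expect_equal(ep2$t_E_prime, 560)
})

test_that("analyze_myocardium rejects an ROI smaller than k", {
  tiny <- roi(0, list(centre = c(32, 32), semi_axes = c(2.4, 2.4)), "ellipse")
  expect_error(analyze_myocardium(mph$series, tiny, k = 25, seed = 1),
               "fewer pixels")
})
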