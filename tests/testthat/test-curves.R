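# toy piecewise-linear curves on a 10-ms grid, cycle 1000 ms
.tri_at <- function(t, t0, tp, t1, peak) {
  ifelse(t > t0 & t <= tp, peak * (t - t0) / (tp - t0),
         ifelse(t > tp & t < t1, peak * (t1 - t) / (t1 - tp), 0))
}
tt10 <- seq(0, 990, by = 10)
aortic_q <- time_curve(tt10, .tri_at(tt10, 60, 200, 420, 350), "ml/s")
mitral_q <- time_curve(tt10, .tri_at(tt10, 500, 600, 780, 400) +
                             .tri_at(tt10, 800, 860, 940, 200), "ml/s")
toy_mitral <- structure(
  list(v_max = mitral_q, v_mean = mitral_q, q = mitral_q,
       areas_cm2 = rep(1, length(tt10)), flow_sign = 1),
  class = "flow_curves")

test_that("flow_curves keeps the q = v_mean x area identity", {
  ph <- make_flow_phantom(phantom_config("flow"), seed = 2)
  seg <- segment_flow(ph$series, phantom_flow_rois()$mitral, "mitral")
  fc <- flow_curves(ph$series, seg)
  expect_equal(fc$q$values, fc$v_mean$values * fc$areas_cm2)
  expect_true(all(fc$v_max$values >= fc$v_mean$values - 1e-12))
  px_cm2 <- prod(ph$series$pixel_spacing / 10)
  expect_equal(fc$areas_cm2, seg$areas * px_cm2)
})

test_that("limb_zero_crossing recovers triangle vertices exactly", {
  # rising limb 0 -> 400 ml/s over t = 500 -> 600 ms
  i_peak <- which(tt10 == 600)
  expect_equal(limb_zero_crossing(mitral_q, i_peak, "ascending"), 500)
  expect_equal(limb_zero_crossing(mitral_q, i_peak, "descending"), 780)
  i_ap <- which(tt10 == 200)
  expect_equal(limb_zero_crossing(aortic_q, i_ap, "descending"), 420)
  expect_equal(end_of_ejection(aortic_q), 420)

  # truncated limb: never descends below 70% within the window
  flat <- time_curve(tt10, pmax(.tri_at(tt10, 500, 600, 780, 400), 300))
  expect_error(limb_zero_crossing(flat, i_peak, "descending"),
               "limb truncated")
})

test_that("detect_two_peaks orders the best pair by time", {
  pk <- detect_two_peaks(mitral_q, window = c(420, 1000), min_sep = 1000 / 6)
  expect_equal(unname(pk$first), c(600, 400))
  expect_equal(unname(pk$second), c(860, 200))
  expect_false(pk$single)

  # a larger late peak still lands second
  swapped <- time_curve(tt10, .tri_at(tt10, 500, 600, 780, 200) +
                               .tri_at(tt10, 800, 860, 940, 400))
  pk2 <- detect_two_peaks(swapped, c(420, 1000), 1000 / 6)
  expect_equal(pk2$first[["t"]], 600)
  expect_equal(pk2$second[["t"]], 860)

  # separation constraint rejects a close bump, leaving a single peak
  bump <- time_curve(tt10, .tri_at(tt10, 500, 600, 780, 400) +
                            .tri_at(tt10, 600, 640, 700, 50))
  pk3 <- detect_two_peaks(bump, c(420, 1000), 1000 / 6)
  expect_true(pk3$single)
  expect_equal(pk3$first[["t"]], 600)

  none <- detect_two_peaks(time_curve(tt10, rep(0, length(tt10))),
                           c(420, 1000), 1000 / 6)
  expect_true(none$none)
})

test_that("single-peak curves yield E with NA atrial parameters", {
  eonly <- structure(
    list(v_max = time_curve(tt10, .tri_at(tt10, 500, 600, 780, 80), "cm/s"),
         v_mean = time_curve(tt10, .tri_at(tt10, 500, 600, 780, 40), "cm/s"),
         q = time_curve(tt10, .tri_at(tt10, 500, 600, 780, 400), "ml/s"),
         areas_cm2 = rep(1, length(tt10)), flow_sign = 1),
    class = "flow_curves")
  expect_warning(fp <- compute_flow_parameters(eonly, aortic_q, 1000),
                 "only one admissible")
  expect_equal(fp$E, 80)
  expect_true(is.na(fp$A))
  expect_true(is.na(fp$EA_ratio))
  expect_true(is.na(fp$EfAf_ratio))
  expect_true(fp$single_peak)
  # FV integrates the E wave alone: triangle area 0.5 * 400 * 0.28 s
  expect_equal(fp$FV, 56)
})

test_that("IVRT is clamped to zero with a warning when filling starts early", {
  early <- structure(
    list(v_max = time_curve(tt10, .tri_at(tt10, 380, 480, 660, 80) +
                                   .tri_at(tt10, 800, 860, 940, 60), "cm/s"),
         v_mean = mitral_q, q = time_curve(
           tt10, .tri_at(tt10, 380, 480, 660, 400) +
                 .tri_at(tt10, 800, 860, 940, 200), "ml/s"),
         areas_cm2 = rep(1, length(tt10)), flow_sign = 1),
    class = "flow_curves")
  expect_warning(fp <- compute_flow_parameters(early, aortic_q, 1000),
                 "IVRT reported as 0")
  expect_equal(fp$IVRT, 0)
})
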