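test_that("phantom_config carries defaults and rejects unknown fields", {
  cfg <- phantom_config("flow")
  expect_equal(cfg$grid, c(128L, 128L))
  expect_equal(cfg$n_phases, 60L)
  expect_equal(cfg$cycle_length, 900)
  expect_equal(cfg$E_true, 80)
  cfg2 <- phantom_config("flow", noise_sd = 0, E_true = 90)
  expect_equal(cfg2$noise_sd, 0)
  expect_equal(cfg2$E_true, 90)
  expect_error(phantom_config("flow", not_a_field = 1), "unknown config")
  cfgm <- phantom_config("myo")
  expect_equal(cfgm$venc, 20)
  expect_equal(cfgm$E_prime_true, 11.3)
})

test_that("flow phantom truth reports the grid-snapped generated values", {
  ph <- make_flow_phantom(phantom_config("flow"), seed = 1)
  tr <- ph$truth
  expect_equal(tr$E, 80)
  expect_equal(tr$A, 60)
  expect_equal(tr$EA_ratio, 80 / 60)
  # requested DT=185 ms and IVRT=78 ms snap to the 15-ms phase grid
  expect_equal(tr$DT, 180)
  expect_equal(tr$IVRT, 75)
  expect_equal(tr$DT %% 15, 0)
  expect_equal(tr$IVRT %% 15, 0)
  expect_equal(tr$EfAf_ratio, tr$Ef / tr$Af)
  expect_equal(tr$Ef, 80 * tr$profile_sum_cm2)
  expect_gt(tr$FV, 0)

  # truth masks flag exactly the noise-free jet support
  expect_equal(dim(tr$mitral_masks), dim(ph$series$velocity))
  active <- apply(tr$mitral_masks, 1, sum)
  expect_true(any(active > 0))
  expect_true(all(active[active > 0] == max(active)))  # rigid jet support

  # velocities stay within venc despite additive noise
  expect_lte(max(abs(ph$series$velocity)), ph$series$venc)
})

test_that("phantoms are reproducible in their seed and vary across seeds", {
  a <- make_flow_phantom(phantom_config("flow"), seed = 3)
  b <- make_flow_phantom(phantom_config("flow"), seed = 3)
  c3 <- make_flow_phantom(phantom_config("flow"), seed = 4)
  expect_identical(a$series$velocity, b$series$velocity)
  expect_false(identical(a$series$velocity, c3$series$velocity))
})

test_that("transmitral waveform peaks at the configured values and times", {
  cfg <- phantom_config("flow")
  w <- transmitral_waveform(seq(0, 885, by = 15), cfg)
  expect_equal(max(w), 80)
  expect_equal(seq(0, 885, by = 15)[which.max(w)], 585)  # snapped t_E
  expect_equal(w[seq(0, 885, by = 15) == 810], 60)       # A peak
  expect_true(all(w[seq(0, 885, by = 15) <= 420] == 0))  # systole is silent
})

test_that("myo phantom truth and geometry are consistent", {
  mp <- make_myo_phantom(phantom_config("myo"), seed = 2)
  tr <- mp$truth
  expect_equal(tr$E_prime, 11.3)
  expect_equal(tr$t_E_prime, 560)
  expect_equal(mp$series$series_kind, "myocardial")
  # the ring mask is an annulus: contains neither centre nor corner
  expect_false(tr$ring_mask[33, 33])
  expect_false(tr$ring_mask[1, 1])
  expect_gt(sum(tr$ring_mask), 100)
  # annulus radii in pixels (1.9 mm spacing)
  w <- which(tr$ring_mask, arr.ind = TRUE)
  rad <- sqrt((w[, 1] - 33)^2 + (w[, 2] - 33)^2) * 1.9
  expect_gte(min(rad), 17 - 1.9)
  expect_lte(max(rad), 27 + 1.9)
})

test_that("perturb_roi jitters vertices within the bound, reproducibly", {
  r <- roi(30, rbind(c(69.5, 53.5), c(69.5, 74.5),
                     c(90.5, 74.5), c(90.5, 53.5)))
  p1 <- perturb_roi(r, 2, seed = 9)
  p2 <- perturb_roi(r, 2, seed = 9)
  expect_identical(p1$coords, p2$coords)
  expect_true(all(abs(p1$coords - r$coords) <= 2))
  expect_false(identical(perturb_roi(r, 2, seed = 10)$coords, p1$coords))

  e <- phantom_myo_roi()
  pe <- perturb_roi(e, 2, seed = 9)
  expect_true(all(abs(pe$coords$centre - e$coords$centre) <= 2))
  expect_equal(pe$coords$semi_axes, e$coords$semi_axes)
})
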