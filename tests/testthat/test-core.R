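test_that("pc_series enforces its invariants and counts aliased samples", {
  P <- 10; H <- 8; W <- 8
  mod <- array(1, c(P, H, W))
  vel <- array(0, c(P, H, W))
  s <- pc_series(mod, vel, 15, 180, c(1.9, 1.9), "flow")
  expect_s3_class(s, "pc_series")
  expect_equal(s$n_phases, P)
  expect_equal(s$cycle_length, P * 15)
  expect_equal(phase_times(s), (0:9) * 15)
  expect_equal(s$n_aliased, 0)

  vel2 <- vel; vel2[3, 2, 2] <- 180; vel2[5, 4, 4] <- -180
  s2 <- pc_series(mod, vel2, 15, 180, 1.9, "flow")
  expect_equal(s2$n_aliased, 2)

  vel3 <- vel; vel3[3, 2, 2] <- 181
  expect_error(pc_series(mod, vel3, 15, 180, 1.9, "flow"),
               "exceeds venc")
  expect_error(pc_series(mod, vel, 15, 180, 1.9, "flow", cycle_length = 200),
               "cycle_length")
  expect_error(pc_series(array(1, c(4, H, W)), array(0, c(4, H, W)),
                         15, 180, 1.9, "flow"),
               "at least 8")
})

test_that("decode_velocity is linear, sign-preserving and range-checked", {
  expect_equal(decode_velocity(2048, 180, 4096), 90)
  expect_equal(decode_velocity(-4096, 180, 4096), -180)
  expect_equal(decode_velocity(0, 180, 4096), 0)
  raw <- array(0, c(6, 4, 4)); raw[4, 1, 1] <- 5000
  expect_error(decode_velocity(raw, 180, 4096), "phase 4")
})

test_that("roi_mask rasterizes polygons and ellipses by pixel centre", {
  # 4x4-centre square with half-integer vertices: rows 2..6, cols 3..7
  r <- roi(0, rbind(c(1.5, 2.5), c(1.5, 7.5), c(6.5, 7.5), c(6.5, 2.5)))
  m <- roi_mask(r, c(10, 12))
  expect_equal(sum(m), 5 * 5)
  expect_true(m[3, 4])      # pixel (row0=2, col0=3)
  expect_false(m[2, 4])     # row0=1 is outside
  expect_equal(r$phase_index, 0L)

  e <- roi(2, list(centre = c(5, 5), semi_axes = c(3.2, 3.2)), "ellipse")
  me <- roi_mask(e, c(11, 11))
  # a centred disc is symmetric and contains its centre
  expect_true(me[6, 6])
  expect_equal(me, me[11:1, ])
  expect_equal(me, me[, 11:1])

  expect_error(roi_mask(roi(0, rbind(c(-2, 0), c(-2, 3), c(2, 3), c(2, 0))),
                        c(10, 10)),
               "outside image bounds")
  expect_error(roi_mask(roi(0, rbind(c(0.6, 0.6), c(0.6, 2.4),
                                     c(2.4, 2.4), c(2.4, 0.6))),
                        c(10, 10)),
               "fewer than 16")
})

test_that("dilate_mask and erode_mask act by Chebyshev radius", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  d1 <- dilate_mask(m, 1L)
  expect_equal(sum(d1), 9)
  expect_true(all(d1[3:5, 3:5]))
  d2 <- dilate_mask(m, 2L)
  expect_equal(sum(d2), 25)
  expect_equal(erode_mask(d2, 2L), m)
  expect_equal(dilate_mask(m, 0L), m)
})

test_that("pc_series container round-trips exactly and refuses missing venc", {
  ph <- make_myo_phantom(phantom_config("myo"), seed = 7)
  d <- file.path(tempdir(), "series_rt")
  write_pc_series(ph$series, d, overwrite = TRUE)
  s2 <- read_pc_series(d)
  expect_identical(s2$velocity, ph$series$velocity)
  expect_identical(s2$modulus, ph$series$modulus)
  expect_equal(s2$venc, ph$series$venc)
  expect_equal(s2$frame_interval, ph$series$frame_interval)
  expect_equal(s2$pixel_spacing, ph$series$pixel_spacing)
  expect_equal(s2$series_kind, ph$series$series_kind)

  # remove venc from the sidecar: refusal, not a guess
  meta <- jsonlite::read_json(file.path(d, "series.json"))
  meta$venc_cm_s <- NULL
  jsonlite::write_json(meta, file.path(d, "series.json"), auto_unbox = TRUE)
  expect_error(read_pc_series(d), "venc")
  unlink(d, recursive = TRUE)
})

test_that("roi and mask_series round-trip through their file formats", {
  r <- roi(5, rbind(c(1.5, 2.5), c(1.5, 7.5), c(6.5, 7.5), c(6.5, 2.5)))
  f <- file.path(tempdir(), "roi.json")
  write_roi(r, f)
  r2 <- read_roi(f)
  expect_equal(r2$phase_index, r$phase_index)
  expect_equal(unname(as.matrix(r2$coords)), unname(as.matrix(r$coords)))

  e <- roi(0, list(centre = c(5, 6), semi_axes = c(3, 4), angle_deg = 30),
           "ellipse")
  write_roi(e, f)
  e2 <- read_roi(f)
  expect_equal(e2$coords$centre, c(5, 6))
  expect_equal(e2$coords$angle_deg, 30)
  unlink(f)
})

test_that("dicom ingestion fails with a pointer to the container route", {
  expect_error(load_pc_series(tempdir(), format = "dicom"), "container")
})
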