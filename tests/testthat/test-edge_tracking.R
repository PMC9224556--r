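test_that("median filter matches the brute-force sliding-window oracle", {
  # constant frame is a fixed point
  const <- matrix(0.4, 10, 12)
  expect_identical(denoise_frame(const, 3), const)
  # a lone salt pixel in a flat field is removed
  salt <- matrix(0.1, 9, 9)
  salt[5, 5] <- 1
  expect_identical(denoise_frame(salt, 3), matrix(0.1, 9, 9))
  # random frames against the oracle, kernels 3 and 5 (checkerboards
  # included via rounding)
  withr::with_seed(42, {
    for (k in c(3L, 5L)) {
      x <- matrix(round(runif(20 * 24), 1), 20, 24)
      expect_identical(denoise_frame(x, k), median_filter_oracle(x, k))
    }
  })
  expect_error(denoise_frame(const, 4), "odd")
})

test_that("reference tracking recovers rigid displacements", {
  init <- tracking_init(rbind(c(40, 60), c(80, 60)),
                        roi = c(30, 90, 10, 110), portion_mm = 20)
  withr::with_seed(3, {
    f1 <- blob_frame(rbind(c(40, 60), c(80, 60)))
    # static video: all displacements zero
    static <- ultrasound_sequence(rep(list(f1), 35), 0.2, 30)
    r <- track_references(static, init)
    expect_equal(max(abs(r$displacement)), 0)
    # rigid (3, 0) shift from frame 2 onward
    shift3 <- f1 * 0 + 0.2
    shift3[4:120, ] <- f1[1:117, ]
    shifted <- ultrasound_sequence(c(list(f1), rep(list(shift3), 34)), 0.2, 30)
    r2 <- track_references(shifted, init)
    expect_equal(r2$displacement[2, ], c(drow = 3, dcol = 0), tolerance = 0.5)
    # points moving by (2,0) and (4,0): average displacement (3,0)
    f2 <- blob_frame(rbind(c(42, 60), c(84, 60)))
    two <- ultrasound_sequence(list(f1, f2), 0.2, 30)
    r3 <- track_references(two, init)
    expect_equal(unname(r3$displacement[2, ]), c(3, 0))
  })
  # template outside the frame errors
  bad <- tracking_init(rbind(c(2, 2), c(80, 60)), roi = c(30, 90, 10, 110),
                       portion_mm = 20)
  f1 <- matrix(0.5, 120, 120)
  seq1 <- ultrasound_sequence(rep(list(f1), 30), 0.2, 30)
  expect_error(track_references(seq1, bad), "outside")
})

test_that("borders land on the band edges within half a pixel", {
  frame <- band_frame()
  tr <- delineate_borders(frame, band_init(), 0.5)
  # lumen rows 41..80: true edges at rows 40.5 and 80.5
  expect_true(all(abs(tr$upper_border[, 1] - 40.5) <= 0.5))
  expect_true(all(abs(tr$lower_border[, 1] - 80.5) <= 0.5))
  expect_true(all(tr$upper_border[, 1] < tr$lower_border[, 1]))
  expect_equal(tr$midline,
               (tr$upper_border + tr$lower_border) / 2, tolerance = 1e-9)
  # separation of the 40 px band at 0.5 mm/px is 20 mm
  dm <- compute_midline_diameters(tr, portion_mm = 50)
  expect_equal(dm$diameters_mm, rep(20, 5), tolerance = 0.25)
})

test_that("a dropout scan line is interpolated with confidence zero", {
  frame <- band_frame()
  cols <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
  frame[cols >= 78 & cols <= 84] <- 200 / 255  # fully bright stripe
  tr <- delineate_borders(frame, band_init(), 0.5)
  dropped <- which(tr$quality == 0)
  expect_true(length(dropped) >= 1)
  expect_true(all(abs(tr$upper_border[dropped, 1] - 40.5) <= 0.75))
  dm <- compute_midline_diameters(tr, portion_mm = 50)
  expect_equal(dm$diameters_mm, rep(20, 5), tolerance = 0.25)
})

test_that("diameters are orthogonal to the midline, not to the scan axis", {
  theta <- 30 * pi / 180
  frame <- tilted_band_frame(theta, width_mm = 15)
  # axis hint deliberately horizontal: the band runs 30 degrees off it
  init <- tracking_init(rbind(c(30, 100), c(170, 100)),
                        roi = c(40, 160, 40, 160), axis_hint = c(0, 1),
                        portion_mm = 30)
  dm <- compute_midline_diameters(delineate_borders(frame, init, 0.5),
                                  portion_mm = 30)
  expect_equal(dm$diameters_mm, rep(15, 5), tolerance = 0.3)
  # sanity: nowhere near the oblique separation 15 / cos(30)
  expect_true(all(dm$diameters_mm < 16))
})

test_that("straight 18 mm band yields 18 mm at all stations and correct station spacing", {
  frame <- band_frame(nr = 200, nc = 260, band_center = 100.5, width_px = 90,
                      lumen = 0.1, wall = 0.8)
  init <- tracking_init(rbind(c(30, 130), c(170, 130)),
                        roi = c(40, 161, 30, 230), portion_mm = 40)
  tr <- delineate_borders(frame, init, 0.2)
  dm <- compute_midline_diameters(tr, portion_mm = 40)
  expect_equal(dm$diameters_mm, rep(18, 5), tolerance = 0.25)
  # the 5 stations cover the central 15 mm: spacing 15/4 mm
  expect_equal(diff(dm$stations_mm), rep(3.75, 4))
  expect_error(compute_midline_diameters(tr, portion_mm = 12), "15 mm")
})

test_that("a known rigid shift leaves the diameter series unchanged", {
  cfg0 <- vessel_sim_config(pulsatility = 0.3, resp_drift_px = 0,
                            duration_s = 1, seed = 9)
  cfg1 <- vessel_sim_config(pulsatility = 0.3, resp_drift_px = 3,
                            duration_s = 1, seed = 9)
  sim0 <- simulate_vessel_video(cfg0)
  sim1 <- simulate_vessel_video(cfg1)
  d0 <- track_ivc(sim0$sequence, sim0$init)$series$diameters
  d1 <- track_ivc(sim1$sequence, sim1$init)$series$diameters
  expect_true(all(d0 > 0) && all(d1 > 0))
  expect_equal(d1, d0, tolerance = 0.5 * 0.2 / mean(d0))  # 0.5 px * mm/px
})
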