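test_that("noise-free bubbles advance flow_speed/frame_rate per frame", {
  # closed-form kinematics oracle on a straight segment
  ph <- manual_phantom(list(straight_segment(-4, 4, speed = 1)))
  acq <- small_acq(frame_rate = 100, duration = 2)
  tr <- simulate_tracks(ph, acq, n_bubbles = 1, localization_noise = 0,
                        seed = 4)
  df <- tr$tracks
  expect_gt(nrow(df), 2)
  steps <- sqrt(diff(df$x_mm)^2 + diff(df$y_mm)^2)
  expect_equal(steps, rep(1 / 100, length(steps)), tolerance = 1e-10)
  expect_equal(diff(df$frame), rep(1L, nrow(df) - 1L))
})

test_that("zero bubbles give an empty set with a finite motion series", {
  ph <- manual_phantom(list(straight_segment(-4, 4)))
  tr <- simulate_tracks(ph, small_acq(), n_bubbles = 0, motion_amplitude = 0.3,
                        seed = 1)
  expect_equal(nrow(tr$tracks), 0)
  expect_true(all(is.finite(tr$displacement_series)))
  expect_equal(max(tr$displacement_series), 0.3)
})

test_that("zero motion amplitude gives an identically-zero series", {
  ph <- manual_phantom(list(straight_segment(-4, 4)))
  tr <- simulate_tracks(ph, small_acq(), n_bubbles = 3, motion_amplitude = 0,
                        seed = 1)
  expect_identical(tr$displacement_series, numeric(small_acq()$n_frames))
})

test_that("an empty phantom with bubbles requested warns and returns empty", {
  ph <- manual_phantom(list())
  expect_warning(tr <- simulate_tracks(ph, small_acq(), n_bubbles = 5,
                                       seed = 1),
                 "no segments")
  expect_equal(nrow(tr$tracks), 0)
})

test_that("simulated track sets satisfy the structural invariants", {
  ph <- generate_phantom(phantom_config("metastatic", node_axes = c(4, 3),
                                        target_vd = 0.25, seed = 2))
  acq <- small_acq()
  tr <- simulate_tracks(ph, acq, n_bubbles = 100, seed = 9)
  df <- tr$tracks
  expect_true(all(df$frame >= 0 & df$frame < acq$n_frames))
  expect_true(all(df$intensity >= 0))
  expect_true(all(df$x_mm >= 0 & df$x_mm <= acq$field_of_view[1]))
  expect_true(all(df$y_mm >= 0 & df$y_mm <= acq$field_of_view[2]))
  gaps <- unlist(tapply(df$frame, df$track_id, diff))
  expect_true(all(gaps > 0))
  # deterministic under the same seed
  tr2 <- simulate_tracks(ph, acq, n_bubbles = 100, seed = 9)
  expect_identical(tr$tracks, tr2$tracks)
})

test_that("track container validates its invariants", {
  acq <- small_acq()
  bad_frame <- data.frame(track_id = 1L, frame = -1L, x_mm = 1, y_mm = 1,
                          intensity = 1)
  expect_error(bubble_tracks(bad_frame, acq), "frame indices")
  outside <- data.frame(track_id = 1L, frame = 0L, x_mm = 99, y_mm = 1,
                        intensity = 1)
  expect_error(bubble_tracks(outside, acq), "field of view")
  dup <- data.frame(track_id = 1L, frame = c(0L, 0L), x_mm = 1, y_mm = 1,
                    intensity = 1)
  expect_error(bubble_tracks(dup, acq), "strictly increasing")
})
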