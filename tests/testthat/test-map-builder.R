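test_that("nearest-neighbour linking matches exhaustive assignment", {
  # two well-separated detections per frame: exactly 2 tracks
  det <- data.frame(frame = rep(0:4, each = 2),
                    x_mm = rep(c(1, 8), 5) + rep(0:4, each = 2) * 0.05,
                    y_mm = rep(c(1, 8), 5), intensity = 1)
  out <- link_tracks(det, max_link_distance = 0.5)
  expect_equal(length(unique(out$track_id)), 2)
  expect_true(all(table(out$track_id) == 5))
  # single unambiguous chain
  chain <- data.frame(frame = 0:9, x_mm = 1 + 0.02 * (0:9), y_mm = 2,
                      intensity = 1)
  out <- link_tracks(chain, max_link_distance = 0.1)
  expect_equal(length(unique(out$track_id)), 1)
  expect_equal(nrow(out), 10)
  # everything farther apart than the gate: all singletons
  spread <- data.frame(frame = 0:4, x_mm = (0:4) * 2, y_mm = 1, intensity = 1)
  out <- link_tracks(spread, max_link_distance = 0.5)
  expect_equal(length(unique(out$track_id)), 5)
  expect_equal(nrow(link_tracks(det[0, ], 0.5)), 0)
})

test_that("a stationary bubble accumulates density with zero velocity", {
  df <- data.frame(track_id = 1L, frame = 0:9, x_mm = 3.33, y_mm = 4.21,
                   intensity = 2)
  maps <- build_maps(tracks_from_df(df), pixel_size = 100)
  expect_equal(sum(maps$density), 10)
  expect_equal(max(maps$density), 10)
  px <- which(maps$density == 10)
  expect_equal(maps$velocity[px], 0)
  expect_equal(maps$intensity[px], 20)
  expect_true(is.na(maps$direction[px]))  # no displacement, no direction
})

test_that("map velocity and direction match track kinematics", {
  # bubble moving +x at 1 mm/s, no noise
  acq <- small_acq(frame_rate = 100, duration = 2)
  df <- data.frame(track_id = 1L, frame = 0:199,
                   x_mm = 1 + (0:199) / 100, y_mm = 5, intensity = 1)
  maps <- build_maps(tracks_from_df(df, acq), pixel_size = 100)
  trav <- which(maps$coverage > 0)
  expect_true(all(abs(maps$velocity[trav] - 1) < 1e-9))
  expect_true(all(abs(maps$direction[maps$dir_coverage > 0]) < 1e-9))
})

test_that("density conserves the localization count", {
  ph <- generate_phantom(phantom_config("reactive", node_axes = c(4, 3),
                                        target_vd = 0.2, seed = 6))
  tr <- simulate_tracks(ph, small_acq(), n_bubbles = 60, seed = 3)
  maps <- build_maps(tr)
  expect_equal(sum(maps$density), nrow(tr$tracks))
  def <- maps$direction[!is.na(maps$direction)]
  expect_true(all(def >= -180 & def < 180))
  expect_true(all(maps$velocity[maps$coverage > 0] >= 0))
})

test_that("empty track sets give all-zero maps with no defined directions", {
  empty <- data.frame(track_id = integer(), frame = integer(),
                      x_mm = numeric(), y_mm = numeric(),
                      intensity = numeric())
  maps <- build_maps(tracks_from_df(empty))
  expect_equal(sum(maps$density), 0)
  expect_true(all(is.na(maps$direction)))
  expect_true(all(is.na(maps$velocity)))
})

test_that("mm to pixel-centre mapping round-trips within half a pixel", {
  px_mm <- 0.1
  x <- runif(200, 0, 10)
  i <- floor(x / px_mm) + 1
  centre <- (i - 0.5) * px_mm
  expect_true(all(abs(centre - x) <= px_mm / 2 + 1e-12))
})

test_that("segment maps partition the acquisition and conserve counts", {
  ph <- generate_phantom(phantom_config("reactive", node_axes = c(4, 3),
                                        target_vd = 0.2, seed = 8))
  acq <- acquisition_config(frame_rate = 500, duration = 6,
                            field_of_view = c(10, 10), pixel_size = 100)
  tr <- simulate_tracks(ph, acq, n_bubbles = 40, seed = 2)
  segs <- build_segment_maps(tr, segment_duration = 1)
  expect_length(segs, 6)
  full <- build_maps(tr)
  expect_equal(sum(vapply(segs, function(m) sum(m$density), numeric(1))),
               sum(full$density))
  # identity segmentation reproduces the full map
  one <- build_segment_maps(tr, segment_duration = 6)
  expect_length(one, 1)
  expect_equal(one[[1]]$density, full$density)
  expect_equal(one[[1]]$velocity, full$velocity)
  expect_error(build_segment_maps(tr, segment_duration = 0.7),
               "divide")
})

test_that("the motion gate applies the strict 0.5 mm rejection rule", {
  qc <- motion_qc(c(0.1, 0.6, 0.2))
  expect_false(qc$passed)
  expect_equal(qc$max_displacement, 0.6)
  expect_equal(qc$n_frames_checked, 3)
  expect_true(motion_qc(rep(0, 100))$passed)
  expect_true(motion_qc(c(0.2, 0.5))$passed)   # boundary: rule is strict >
  expect_false(motion_qc(c(0.2, 0.500001))$passed)
  expect_error(motion_qc(numeric(0)), "empty")
})
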