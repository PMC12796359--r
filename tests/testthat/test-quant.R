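test_that("vascular binarization and density follow the pixel rule", {
  roi <- matrix(TRUE, 10, 10)
  den <- matrix(0L, 10, 10)
  den[1:23] <- 1L
  vas <- binarize_vascular(den, roi)
  expect_equal(compute_vd(vas, roi), 0.23)
  expect_equal(compute_vd(roi, roi), 1)
  expect_equal(compute_vd(matrix(FALSE, 10, 10), roi), 0)
  # threshold 2 keeps only the densest pixels (elementwise oracle)
  den2 <- matrix(sample(0:3, 100, replace = TRUE), 10, 10)
  expect_identical(binarize_vascular(den2, roi, rule = 2), den2 >= 2 & roi)
  expect_error(binarize_vascular(den, matrix(FALSE, 10, 10)), "empty")
})

test_that("flow-weighted vascular density is the ROI-normalized sum", {
  roi <- matrix(TRUE, 2, 2)
  inten <- matrix(c(3, 5, 7, 9), 2, 2)
  vas <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(compute_fwvd(inten, vas, roi), 2)  # (3+5)/4
  expect_equal(compute_fwvd(matrix(2, 2, 2), roi, roi), 2)
  expect_equal(compute_fwvd(inten, matrix(FALSE, 2, 2), roi), 0)
})

test_that("diameter estimates match analytic strip widths", {
  # 5-pixel-wide strip at 25 um: true diameter 125 um
  strip <- matrix(FALSE, 20, 40)
  strip[8:12, 3:38] <- TRUE
  d <- compute_diameters(strip, 25)
  expect_lt(abs(d["Dmean"] - 125), 25)
  expect_lt(abs(d["Dmax"] - 125), 25 + 1e-9)
  # single isolated pixel: one-pixel vessel
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_equal(unname(compute_diameters(single, 25)["Dmean"]), 25)
  # two strips of width 3 and 7 with equal skeleton length
  two <- matrix(FALSE, 30, 40)
  two[5:7, 3:38] <- TRUE    # width 3
  two[15:21, 3:38] <- TRUE  # width 7
  d2 <- compute_diameters(two, 25)
  expect_lt(abs(d2["Dmax"] - 175), 25 + 1e-9)
  expect_lt(abs(d2["Dmean"] - 125), 25)
  expect_warning(d0 <- compute_diameters(matrix(FALSE, 5, 5), 25), "empty")
  expect_equal(unname(d0), c(0, 0, 0))
})

test_that("box-counting dimension recovers analytic fractal limits", {
  expect_lt(abs(compute_fd(matrix(TRUE, 256, 256)) - 2), 0.05)
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  expect_lt(abs(compute_fd(line) - 1), 0.05)
  sier <- sierpinski_mask(6)
  expect_lt(abs(compute_fd(sier) - log(3) / log(2)), 0.05)
})

test_that("fractal dimension orders curve < tree < plane", {
  line <- matrix(FALSE, 128, 128); line[64, ] <- TRUE
  tree <- sierpinski_mask(7)
  expect_lt(compute_fd(line), compute_fd(tree))
  expect_lt(compute_fd(tree), compute_fd(matrix(TRUE, 128, 128)))
})

test_that("velocity statistics match closed-form cases", {
  roi <- matrix(TRUE, 4, 4)
  vas <- roi
  const <- matrix(7, 4, 4)
  vs <- velocity_stats(const, vas, roi)
  expect_equal(unname(vs[c("Vmean", "Vmax", "Vmin")]), c(7, 7, 7))
  expect_equal(unname(vs["VelVar"]), 0)
  expect_equal(unname(vs["VelEntropy"]), 0)
  # two equal-mass values 1 and 3: hand-computed entropy ln2/lnK
  two <- matrix(c(1, 3), 4, 4)
  vs2 <- velocity_stats(two, vas, roi)
  expect_equal(unname(vs2["Vmean"]), 2)
  expect_equal(unname(vs2["VelVar"]), 1)
  expect_equal(unname(vs2["VelEntropy"]), log(2) / log(64))
  # values filling all K bins equally: maximum entropy
  K <- 64
  vals <- rep((seq_len(K) - 0.5) / K * 10, each = 4)
  grid <- matrix(vals, 16, 16)
  vs3 <- velocity_stats(grid, matrix(TRUE, 16, 16), matrix(TRUE, 16, 16))
  expect_equal(unname(vs3["VelEntropy"]), 1)
  # background (coverage-undefined) pixels are excluded from Vmin
  v <- matrix(NA_real_, 4, 4); v[1, 1] <- 2.5; v[2, 2] <- 4
  expect_equal(unname(velocity_stats(v, vas, roi)["Vmin"]), 2.5)
  expect_error(velocity_stats(matrix(NA_real_, 4, 4), vas, roi), "defined")
})

test_that("direction statistics use wrapped deviations about the circular mean", {
  roi <- matrix(TRUE, 4, 4); vas <- roi
  same <- matrix(45, 4, 4)
  ds <- direction_stats(same, vas, roi)
  expect_equal(unname(ds["DirVar"]), 0)
  expect_equal(unname(ds["DirEntropy"]), 0)
  # equal mass at +90 and -90: deviations +/-90 about the circular mean
  pm <- matrix(c(90, -90), 4, 4)
  expect_equal(unname(direction_stats(pm, vas, roi)["DirVar"]), 8100)
  # uniform angular histogram: maximum entropy
  K <- 64
  ang <- rep(-180 + (seq_len(K) - 0.5) * 360 / K, each = 4)
  du <- direction_stats(matrix(ang, 16, 16), matrix(TRUE, 16, 16),
                        matrix(TRUE, 16, 16))
  expect_equal(unname(du["DirEntropy"]), 1)
  # wrap-around flows (179 vs -179 degrees) stay nearly aligned
  wrap <- matrix(c(179, -179), 4, 4)
  expect_lt(unname(direction_stats(wrap, vas, roi)["DirVar"]), 5)
})

test_that("entropies are invariant under pixel permutation", {
  set.seed(3)
  v <- matrix(runif(64, 1, 30), 8, 8)
  roi <- matrix(TRUE, 8, 8)
  e1 <- velocity_stats(v, roi, roi)["VelEntropy"]
  perm <- matrix(sample(v), 8, 8)
  expect_equal(velocity_stats(perm, roi, roi)["VelEntropy"], e1)
})

test_that("perfusion index is the exact product of Vmean and VD", {
  expect_equal(compute_pi(25, 0.4), 10)
  expect_equal(compute_pi(25, 0), 0)
  expect_equal(compute_pi(0, 0.5), 0)
  expect_error(compute_pi(10, 1.5), "vd")
})

test_that("the assembled parameter vector matches a brute-force oracle", {
  set.seed(7)
  for (rep in 1:3) {
    ph <- generate_phantom(phantom_config("metastatic", node_axes = c(4, 3),
                                          target_vd = 0.3, seed = rep))
    acq <- small_acq(frame_rate = 100, duration = 2, pixel_size = 300)
    tr <- simulate_tracks(ph, acq, n_bubbles = 80, seed = rep)
    maps <- build_maps(tr)  # <= 34x34 grid at 300 um
    roi <- roi_ellipse(maps, semi_axes = ph$node_axes)
    pv <- compute_all(maps, roi)
    orc <- oracle_stats(maps$density, maps$intensity, maps$velocity,
                        maps$direction, roi)
    for (p in names(orc)) {
      expect_equal(unname(pv[p]), orc[[p]], tolerance = 1e-12, label = p)
    }
    expect_equal(unname(pv["PI"]), unname(pv["Vmean"] * pv["VD"]),
                 tolerance = 1e-15)
    expect_true(all(is.finite(pv)))
    expect_true(pv["VD"] >= 0 && pv["VD"] <= 1)
    expect_true(pv["Vmin"] <= pv["Vmean"] && pv["Vmean"] <= pv["Vmax"])
    expect_true(pv["FD"] >= 0 && pv["FD"] <= 2)
    expect_true(all(pv[c("VelEntropy", "DirEntropy")] >= 0) &&
                all(pv[c("VelEntropy", "DirEntropy")] <= 1))
  }
})

test_that("parameter statistics are invariant under map translation", {
  df <- data.frame(track_id = rep(1:5, each = 20),
                   frame = rep(0:19, 5),
                   x_mm = rep(1:5, each = 20) + rep(0:19, 5) * 0.03,
                   y_mm = rep(c(2, 3, 4, 5, 6), each = 20),
                   intensity = 1)
  acq <- small_acq(frame_rate = 100, duration = 2, field_of_view = c(20, 20))
  m1 <- build_maps(tracks_from_df(df, acq), pixel_size = 200)
  df2 <- df; df2$x_mm <- df$x_mm + 3; df2$y_mm <- df$y_mm + 3
  m2 <- build_maps(tracks_from_df(df2, acq), pixel_size = 200)
  roi1 <- m1$density >= 0  # full-grid ROI
  pv1 <- compute_all(m1, roi1)
  pv2 <- compute_all(m2, roi1)
  for (p in c("FWVD", "Vmean", "Vmax", "Vmin", "VelVar", "VelEntropy")) {
    expect_equal(pv1[p], pv2[p], tolerance = 1e-12)
  }
})
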