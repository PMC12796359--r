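# Shared fixtures, built in code.

# A hand-made phantom with explicit segments (node-centred coordinates).
manual_phantom <- function(segments, node_axes = c(5, 5)) {
  structure(list(segments = segments, node_axes = node_axes,
                 vascular_fraction = NA_real_, pixel_size = 25,
                 config = phantom_config("reactive", node_axes = node_axes)),
            class = "vascular_phantom")
}

straight_segment <- function(x0, x1, y = 0, speed = 1, radius = 30,
                             sign = 1L) {
  list(poly = cbind(seq(x0, x1, length.out = 50), rep(y, 50)),
       radius_um = radius, flow_speed = speed, flow_sign = sign)
}

# Small acquisition used throughout unit tests.
small_acq <- function(frame_rate = 100, duration = 2,
                      field_of_view = c(10, 10), pixel_size = 100) {
  acquisition_config(frame_rate = frame_rate, duration = duration,
                     pixel_size = pixel_size, field_of_view = field_of_view)
}

# Build a bubble_tracks object directly from a localization table.
tracks_from_df <- function(df, acq = small_acq()) {
  bubble_tracks(df, acq)
}

# Sierpinski-triangle raster of side 2^depth (exact self-similar set).
sierpinski_mask <- function(depth = 6) {
  n <- 2^depth
  outer(0:(n - 1), 0:(n - 1), function(i, j) bitwAnd(i, j) == 0)
}

# Independent direct-enumeration statistics used as a brute-force oracle
# for the map-level parameter estimators (kept deliberately naive).
oracle_stats <- function(density, intensity, velocity, direction, roi,
                         rule = 1, K = 64) {
  vas <- which(roi & density >= rule)
  n_roi <- length(which(roi))
  vd <- length(vas) / n_roi
  fwvd <- sum(intensity[vas]) / n_roi
  v <- velocity[vas]; v <- v[!is.na(v)]
  ent <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    -sum(p * log(p)) / log(K)
  }
  vbin <- pmin(pmax(ceiling(v / max(v) * K), 1), K)
  th <- direction[vas]; th <- th[!is.na(th)]
  mu <- atan2(mean(sin(th * pi / 180)), mean(cos(th * pi / 180))) * 180 / pi
  dev <- ((th - mu + 180) %% 360) - 180
  tbin <- pmin(pmax(floor((th + 180) / 360 * K) + 1, 1), K)
  list(VD = vd, FWVD = fwvd, Vmean = mean(v), Vmax = max(v), Vmin = min(v),
       VelVar = mean((v - mean(v))^2), VelEntropy = ent(tabulate(vbin, K)),
       DirVar = mean(dev^2), DirEntropy = ent(tabulate(tbin, K)))
}

# Cohort with one parameter column overridden by explicit group values.
make_cohort <- function(met, rea, param = "VD") {
  co <- generate_cohort(cohort_calibration(n_metastatic = length(met),
                                           n_reactive = length(rea)),
                        seed = 1)
  co[[param]][co$label == "metastatic"] <- met
  co[[param]][co$label == "reactive"] <- rea
  co
}

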