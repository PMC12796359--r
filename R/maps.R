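# SRUS map accumulation: localized bubble tracks -> co-registered density,
# intensity, velocity and direction grids.
#
# Grid convention (fixed for reproducible rasterization): image convention,
# x right / y down; pixel (row r, col c) covers
# [x0 + (c-1) px, x0 + c px) x [y0 + (r-1) px, y0 + r px) in mm with
# pixel-centre registration; R matrices are 1-based, the mm<->pixel helpers
# below are the single source of truth.

mm_to_px <- function(x_mm, origin, px_mm) {
  pmin(pmax(floor((x_mm - origin) / px_mm) + 1L, 1L), .Machine$integer.max)
}

px_centre_mm <- function(i, origin, px_mm) origin + (i - 0.5) * px_mm

#' Greedy nearest-neighbour track linking
#'
#' Links per-frame localizations into tracks: proceeding frame by frame,
#' candidate (previous-track, detection) pairs within `max_link_distance` are
#' assigned greedily by increasing distance (ties broken by lowest track id);
#' unlinked detections start new tracks. A deliberately minimal, pluggable
#' stand-in for scanner-internal trackers.
#'
#' @param per_frame_localizations `data.frame` with columns `frame`, `x_mm`,
#'   `y_mm`, `intensity`, sorted by frame (0-based frames).
#' @param max_link_distance Maximum frame-to-frame link distance, mm.
#' @return `data.frame` with columns `track_id`, `frame`, `x_mm`, `y_mm`,
#'   `intensity`.
#' @export
#' @examples
#' det <- data.frame(frame = c(0, 1, 1), x_mm = c(1, 1.05, 5),
#'                   y_mm = c(1, 1, 5), intensity = 1)
#' link_tracks(det, max_link_distance = 0.5)
link_tracks <- function(per_frame_localizations, max_link_distance) {
  df <- per_frame_localizations
  need <- c("frame", "x_mm", "y_mm", "intensity")
  if (!all(need %in% names(df))) {
    stop("localizations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(data.frame(track_id = integer(), frame = integer(),
                      x_mm = numeric(), y_mm = numeric(),
                      intensity = numeric()))
  }
  df <- df[order(df$frame), , drop = FALSE]
  df$track_id <- NA_integer_
  next_id <- 1L
  prev_idx <- integer(0)  # row indices of previous frame's detections
  for (f in sort(unique(df$frame))) {
    cur_idx <- which(df$frame == f)
    if (length(prev_idx) > 0 && length(cur_idx) > 0) {
      d <- outer(seq_along(prev_idx), seq_along(cur_idx),
                 Vectorize(function(i, j) {
                   sqrt((df$x_mm[prev_idx[i]] - df$x_mm[cur_idx[j]])^2 +
                        (df$y_mm[prev_idx[i]] - df$y_mm[cur_idx[j]])^2)
                 }))
      cand <- which(d <= max_link_distance, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], df$track_id[prev_idx[cand[, 1]]])
        cand <- cand[ord, , drop = FALSE]
        used_prev <- logical(length(prev_idx))
        used_cur <- logical(length(cur_idx))
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!used_prev[i] && !used_cur[j]) {
            df$track_id[cur_idx[j]] <- df$track_id[prev_idx[i]]
            used_prev[i] <- TRUE; used_cur[j] <- TRUE
          }
        }
      }
    }
    new <- cur_idx[is.na(df$track_id[cur_idx])]
    if (length(new) > 0) {
      df$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
    prev_idx <- cur_idx
  }
  rownames(df) <- NULL
  df[, c("track_id", "frame", "x_mm", "y_mm", "intensity")]
}

#' Build the SRUS map set from bubble tracks
#'
#' Each localization increments the density grid and adds its intensity at
#' its pixel. Per-track instantaneous speed (finite difference times frame
#' rate, handling frame gaps) and step direction (`atan2` of the step vector,
#' degrees in `[-180, 180)`, x right / y down) are accumulated at the pixel
#' of the step's starting localization; per-pixel velocity is the arithmetic
#' mean of contributing step speeds and per-pixel direction the circular mean
#' of step unit vectors. Pixels with no contributing step carry `NA`
#' velocity/direction; zero-length steps contribute speed 0 but no direction.
#'
#' @param tracks A [bubble_tracks()] object.
#' @param pixel_size Pixel pitch, micrometres (defaults to the acquisition's).
#' @param roi_extent Numeric length-4 `c(x0, y0, width, height)` in mm;
#'   defaults to the acquisition field of view anchored at the origin.
#' @return Object of class `srus_maps` with grids `density`, `intensity`,
#'   `velocity`, `direction`, `coverage` (velocity steps per pixel),
#'   `dir_coverage`, plus `pixel_size`, `origin` and `acquisition`.
#' @export
build_maps <- function(tracks, pixel_size = tracks$acquisition$pixel_size,
                       roi_extent = NULL) {
  stopifnot(inherits(tracks, "bubble_tracks"))
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (is.null(roi_extent)) {
    roi_extent <- c(0, 0, tracks$acquisition$field_of_view)
  }
  if (length(roi_extent) != 4 || any(roi_extent[3:4] <= 0)) {
    stop("roi_extent must be c(x0, y0, width > 0, height > 0)", call. = FALSE)
  }
  px_mm <- pixel_size / 1000
  nx <- ceiling(roi_extent[3] / px_mm)
  ny <- ceiling(roi_extent[4] / px_mm)
  zero <- matrix(0, ny, nx)
  maps <- list(density = zero, intensity = zero,
               vel_sum = zero, coverage = zero,
               dir_cos = zero, dir_sin = zero, dir_coverage = zero)
  df <- tracks$tracks
  if (nrow(df) > 0) {
    ci <- mm_to_px(df$x_mm, roi_extent[1], px_mm)
    ri <- mm_to_px(df$y_mm, roi_extent[2], px_mm)
    if (any(ci > nx | ri > ny | df$x_mm < roi_extent[1] |
            df$y_mm < roi_extent[2])) {
      stop("tracks fall outside roi_extent", call. = FALSE)
    }
    lin <- (ci - 1L) * ny + ri
    tab <- tabulate(lin, nbins = nx * ny)
    maps$density <- matrix(tab, ny, nx)
    maps$intensity <- matrix(
      unname(rowsum_vec(df$intensity, lin, nx * ny)), ny, nx)
    # track steps
    same <- c(df$track_id[-1] == df$track_id[-nrow(df)], FALSE)
    i0 <- which(same)
    if (length(i0) > 0) {
      i1 <- i0 + 1L
      dt <- (df$frame[i1] - df$frame[i0]) / tracks$acquisition$frame_rate
      dx <- df$x_mm[i1] - df$x_mm[i0]
      dy <- df$y_mm[i1] - df$y_mm[i0]
      step <- sqrt(dx^2 + dy^2)
      speed <- step / dt
      at <- lin[i0]
      maps$vel_sum <- matrix(unname(rowsum_vec(speed, at, nx * ny)), ny, nx)
      maps$coverage <- matrix(tabulate(at, nbins = nx * ny), ny, nx)
      moving <- step > 0
      if (any(moving)) {
        ux <- dx[moving] / step[moving]
        uy <- dy[moving] / step[moving]
        atm <- at[moving]
        maps$dir_cos <- matrix(unname(rowsum_vec(ux, atm, nx * ny)), ny, nx)
        maps$dir_sin <- matrix(unname(rowsum_vec(uy, atm, nx * ny)), ny, nx)
        maps$dir_coverage <- matrix(tabulate(atm, nbins = nx * ny), ny, nx)
      }
    }
  }
  velocity <- ifelse(maps$coverage > 0, maps$vel_sum / pmax(maps$coverage, 1),
                     NA_real_)
  direction <- matrix(NA_real_, ny, nx)
  defined <- maps$dir_coverage > 0
  direction[defined] <- wrap_degrees(
    atan2(maps$dir_sin[defined], maps$dir_cos[defined]) * 180 / pi)
  structure(list(density = maps$density, intensity = maps$intensity,
                 velocity = velocity, direction = direction,
                 coverage = maps$coverage, dir_coverage = maps$dir_coverage,
                 pixel_size = pixel_size,
                 origin = roi_extent[1:2], extent = roi_extent,
                 acquisition = tracks$acquisition),
            class = "srus_maps")
}

# Sum `values` by integer bin over 1..nbins (dense result).
rowsum_vec <- function(values, bins, nbins) {
  out <- numeric(nbins)
  s <- rowsum(values, bins)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' @export
print.srus_maps <- function(x, ...) {
  cat(sprintf("srus_maps: %d x %d grid at %g um, %d localizations\n",
              nrow(x$density), ncol(x$density), x$pixel_size,
              sum(x$density)))
  invisible(x)
}

#' Time-resolved segment maps
#'
#' Splits the acquisition into consecutive segments of `segment_duration`
#' seconds (default 1 s, i.e. 500 frames at the default frame rate) and
#' builds one map set per segment over the common extent. Localization
#' counts across segments sum to the full-map count.
#'
#' @inheritParams build_maps
#' @param segment_duration Segment length in seconds; must divide the
#'   acquisition duration.
#' @return List of `srus_maps`, one per segment.
#' @export
build_segment_maps <- function(tracks, segment_duration = 1,
                               pixel_size = tracks$acquisition$pixel_size,
                               roi_extent = NULL) {
  stopifnot(inherits(tracks, "bubble_tracks"))
  acq <- tracks$acquisition
  n_seg <- acq$duration / segment_duration
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    stop("segment_duration must divide the acquisition duration",
         call. = FALSE)
  }
  n_seg <- as.integer(round(n_seg))
  frames_per <- acq$n_frames / n_seg
  lapply(seq_len(n_seg), function(k) {
    lo <- (k - 1) * frames_per
    hi <- k * frames_per
    sub <- tracks$tracks[tracks$tracks$frame >= lo & tracks$tracks$frame < hi, ,
                         drop = FALSE]
    bt <- bubble_tracks(sub, acq, tracks$displacement_series)
    build_maps(bt, pixel_size = pixel_size, roi_extent = roi_extent)
  })
}

#' Motion quality-control gate
#'
#' Accepts an acquisition when the maximum per-frame tissue displacement does
#' not exceed the threshold; the rejection rule is strict (`> threshold`
#' fails), so a maximum of exactly 0.5 mm passes at the default threshold.
#'
#' @param displacement_series Per-frame displacement, mm (finite, non-empty).
#' @param threshold Rejection threshold, mm (default 0.5).
#' @return Object of class `qc_result` with `passed`, `max_displacement`,
#'   `threshold`, `n_frames_checked`.
#' @export
#' @examples
#' motion_qc(c(0.1, 0.6, 0.2))$passed  # FALSE
#' motion_qc(c(0.1, 0.5))$passed       # TRUE (strict rule)
motion_qc <- function(displacement_series, threshold = 0.5) {
  if (length(displacement_series) == 0) {
    stop("displacement_series is empty; nothing to check", call. = FALSE)
  }
  if (any(!is.finite(displacement_series))) {
    stop("displacement_series must be finite", call. = FALSE)
  }
  mx <- max(displacement_series)
  structure(list(passed = mx <= threshold, max_displacement = mx,
                 threshold = threshold,
                 n_frames_checked = length(displacement_series)),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("motion QC: %s (max displacement %.3f mm, threshold %.3f mm, %d frames)\n",
              if (x$passed) "PASS" else "FAIL", x$max_displacement,
              x$threshold, x$n_frames_checked))
  invisible(x)
}

#' Elliptical ROI mask congruent with a map set
#'
#' @param maps An `srus_maps` object.
#' @param center Ellipse centre in mm (defaults to the extent centre).
#' @param semi_axes Semi-axes in mm (defaults to 45% of the extent, a
#'   whole-parenchyma ROI).
#' @return Logical matrix, same shape as the maps.
#' @export
roi_ellipse <- function(maps, center = NULL, semi_axes = NULL) {
  stopifnot(inherits(maps, "srus_maps"))
  ext <- maps$extent
  if (is.null(center)) center <- ext[1:2] + ext[3:4] / 2
  if (is.null(semi_axes)) semi_axes <- 0.45 * ext[3:4]
  px_mm <- maps$pixel_size / 1000
  xs <- px_centre_mm(seq_len(ncol(maps$density)), ext[1], px_mm)
  ys <- px_centre_mm(seq_len(nrow(maps$density)), ext[2], px_mm)
  mask <- outer((ys - center[2])^2 / semi_axes[2]^2,
                (xs - center[1])^2 / semi_axes[1]^2, "+") <= 1
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  mask
}
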