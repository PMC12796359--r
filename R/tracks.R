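# Microbubble track simulation.

#' Construct a bubble track set
#'
#' Container for localized microbubble positions over frames: one row per
#' localization with 0-based frame index, position in mm (field-of-view
#' coordinates, x right / y down), and an arbitrary-unit signal intensity.
#' Validates the structural invariants (frames strictly increasing within a
#' track and in `[0, n_frames)`, intensities non-negative, positions inside
#' the field of view).
#'
#' @param tracks `data.frame` with columns `track_id`, `frame`, `x_mm`,
#'   `y_mm`, `intensity`.
#' @param acquisition An [acquisition_config()].
#' @param displacement_series Per-frame global tissue displacement (mm),
#'   length `n_frames`; used by [motion_qc()].
#' @return Object of class `bubble_tracks`.
#' @export
bubble_tracks <- function(tracks, acquisition,
                          displacement_series = numeric(acquisition$n_frames)) {
  stopifnot(inherits(acquisition, "acquisition_config"))
  need <- c("track_id", "frame", "x_mm", "y_mm", "intensity")
  if (!all(need %in% names(tracks))) {
    stop("tracks must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tracks) > 0) {
    if (any(tracks$frame < 0L) || any(tracks$frame >= acquisition$n_frames)) {
      stop("frame indices must lie in [0, n_frames)", call. = FALSE)
    }
    if (any(tracks$intensity < 0)) {
      stop("intensities must be non-negative", call. = FALSE)
    }
    fov <- acquisition$field_of_view
    if (any(tracks$x_mm < 0 | tracks$x_mm > fov[1] |
            tracks$y_mm < 0 | tracks$y_mm > fov[2])) {
      stop("track positions must lie inside the field of view", call. = FALSE)
    }
    ord <- order(tracks$track_id, tracks$frame)
    tracks <- tracks[ord, , drop = FALSE]
    rownames(tracks) <- NULL
    dup <- stats::ave(tracks$frame, tracks$track_id,
                      FUN = function(f) c(1, diff(f)))
    if (any(dup <= 0)) {
      stop("frame indices must be strictly increasing within a track",
           call. = FALSE)
    }
  }
  if (length(displacement_series) != acquisition$n_frames ||
      any(!is.finite(displacement_series))) {
    stop("displacement_series must be finite with length n_frames",
         call. = FALSE)
  }
  structure(list(tracks = tracks, acquisition = acquisition,
                 displacement_series = as.numeric(displacement_series)),
            class = "bubble_tracks")
}

#' @export
print.bubble_tracks <- function(x, ...) {
  cat(sprintf("bubble_tracks: %d localizations in %d tracks over %d frames\n",
              nrow(x$tracks), length(unique(x$tracks$track_id)),
              x$acquisition$n_frames))
  invisible(x)
}

# Arc-length parameterization of a polyline; returns interpolating function
# mm-along -> (x, y).
polyline_interp <- function(poly) {
  d <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  cs <- c(0, cumsum(d))
  list(length = cs[length(cs)],
       at = function(s) cbind(
         approx(cs, poly[, 1], xout = s, ties = "ordered")$y,
         approx(cs, poly[, 2], xout = s, ties = "ordered")$y))
}

#' Simulate microbubble tracks through a phantom
#'
#' Bubbles enter random vessel segments (probability proportional to segment
#' length) at random times and traverse the centerline at the segment's flow
#' speed, in the segment's flow direction. Localized positions get isotropic
#' Gaussian localization noise; a smooth per-frame tissue displacement series
#' (the residual after the scanner's motion correction) is generated for QC
#' with maximum exactly `motion_amplitude`.
#'
#' The phantom is node-centred; positions are shifted so the node sits at the
#' centre of the acquisition field of view. Localizations that would fall
#' outside the field of view terminate the track.
#'
#' @param phantom A `vascular_phantom` from [generate_phantom()].
#' @param acq An [acquisition_config()].
#' @param n_bubbles Number of bubbles to inject (>= 0).
#' @param localization_noise Localization error sd, micrometres (default 5,
#'   i.e. a ~10-12 micrometre FWHM localization spot, the super-resolution
#'   scale).
#' @param motion_amplitude Peak inter-frame tissue displacement, mm.
#' @param seed Integer seed.
#' @return A [bubble_tracks()] object.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config("reactive", node_axes = c(4, 3),
#'                                       target_vd = 0.15, seed = 1))
#' acq <- acquisition_config(field_of_view = c(10, 8))
#' tr <- simulate_tracks(ph, acq, n_bubbles = 50, seed = 2)
simulate_tracks <- function(phantom, acq, n_bubbles,
                            localization_noise = 5, motion_amplitude = 0,
                            seed = 1L) {
  stopifnot(inherits(phantom, "vascular_phantom"),
            inherits(acq, "acquisition_config"))
  if (n_bubbles < 0 || localization_noise < 0 || motion_amplitude < 0) {
    stop("n_bubbles, localization_noise and motion_amplitude must be >= 0",
         call. = FALSE)
  }
  fov <- acq$field_of_view
  off <- fov / 2
  empty_df <- data.frame(track_id = integer(), frame = integer(),
                         x_mm = numeric(), y_mm = numeric(),
                         intensity = numeric())
  if (length(phantom$segments) == 0L) {
    if (n_bubbles > 0) {
      warning("phantom has no segments; returning an empty track set",
              call. = FALSE)
    }
    disp <- with_seed(substream_seed(seed, "motion"),
                      motion_series(acq$n_frames, motion_amplitude))
    return(bubble_tracks(empty_df, acq, disp))
  }
  interps <- lapply(phantom$segments, function(s) polyline_interp(s$poly))
  lens <- vapply(interps, `[[`, numeric(1), "length")
  rows <- with_seed(substream_seed(seed, "tracks"), {
    if (n_bubbles == 0) list() else {
      seg_idx <- sample.int(length(lens), n_bubbles, replace = TRUE,
                            prob = lens)
      out <- vector("list", n_bubbles)
      for (i in seq_len(n_bubbles)) {
        k <- seg_idx[i]
        seg <- phantom$segments[[k]]
        ip <- interps[[k]]
        f0 <- sample.int(acq$n_frames, 1L) - 1L
        s0 <- runif(1, 0, ip$length)
        amp <- exp(rnorm(1, 0, 0.3))
        v <- seg$flow_speed / acq$frame_rate  # mm per frame
        if (seg$flow_sign >= 0) {
          n_steps <- floor((ip$length - s0) / max(v, 1e-12))
        } else {
          n_steps <- floor(s0 / max(v, 1e-12))
        }
        n_steps <- min(n_steps, acq$n_frames - 1L - f0)
        if (n_steps < 0) next
        fr <- f0 + 0:n_steps
        s <- s0 + seg$flow_sign * v * (0:n_steps)
        xy <- ip$at(s)
        x <- xy[, 1] + off[1]
        y <- xy[, 2] + off[2]
        if (localization_noise > 0) {
          x <- x + rnorm(length(x), 0, localization_noise / 1000)
          y <- y + rnorm(length(y), 0, localization_noise / 1000)
        }
        ok <- x >= 0 & x <= fov[1] & y >= 0 & y <= fov[2]
        first_bad <- which(!ok)[1]
        if (!is.na(first_bad)) ok[first_bad:length(ok)] <- FALSE
        if (!any(ok)) next
        out[[i]] <- data.frame(track_id = i, frame = fr[ok],
                               x_mm = x[ok], y_mm = y[ok], intensity = amp)
      }
      out
    }
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else empty_df
  disp <- with_seed(substream_seed(seed, "motion"),
                    motion_series(acq$n_frames, motion_amplitude))
  bubble_tracks(df, acq, disp)
}

# Smooth non-negative per-frame displacement series with max == amplitude.
motion_series <- function(n_frames, amplitude) {
  if (amplitude == 0) return(numeric(n_frames))
  raw <- stats::filter(rnorm(n_frames + 100), rep(1 / 25, 25), sides = 1)
  raw <- abs(raw[(length(raw) - n_frames + 1):length(raw)])
  raw * (amplitude / max(raw))
}
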