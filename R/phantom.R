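# Synthetic vascular phantoms.
#
# A phantom is a set of vessel segments (centerline polylines with a radius,
# a flow speed and a traversal sign) grown inside an elliptical lymph-node
# parenchyma. Two phenotype presets bracket the biology the package targets:
# reactive nodes keep hilum-centred, gently curved vessels with organized
# flow; metastatic nodes grow a denser, more tortuous network entered from
# all around the capsule with disordered flow, consistent with the published
# direction of effects (higher density, complexity and entropy).

#' Phantom configuration and phenotype presets
#'
#' @param phenotype `"reactive"` or `"metastatic"`; selects the preset that
#'   the remaining arguments override.
#' @param node_axes Semi-axes of the node ellipse in mm (long, short).
#'   Defaults give an 18 x 12 mm node, inside the published cohort's size
#'   interquartile ranges.
#' @param n_root_vessels Number of feeding vessels entering the capsule.
#' @param branching_prob Per-mm probability that a growing vessel spawns a
#'   child branch.
#' @param tortuosity Angular-noise amplitude (radians per sqrt(mm)) of the
#'   vessel random walk; higher values give more serpentine vessels.
#' @param radius_root Root vessel radius, micrometres.
#' @param radius_decay Child/parent radius ratio per branching generation.
#' @param target_vd Target rasterized vascular fraction of the node ellipse,
#'   in `[0, 1]`; growth stops once reached (must be `<= 0.95`).
#' @param velocity_mean Mean root flow speed, mm/s.
#' @param velocity_cv Coefficient of variation of segment flow speeds.
#' @param velocity_floor Lower clamp on branch flow speed, mm/s; lower in the
#'   metastatic preset (immature tumour vessels carry slower minimum flow).
#' @param direction_disorder In `[0, 1]`: 0 concentrates feeding vessels at a
#'   hilum with coherent branching; 1 spreads entry points around the whole
#'   capsule with wide branching angles and random traversal signs.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   config.
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config("metastatic", seed = 7)
#' cfg$target_vd
phantom_config <- function(phenotype = c("reactive", "metastatic"),
                           node_axes = NULL, n_root_vessels = NULL,
                           branching_prob = NULL, tortuosity = NULL,
                           radius_root = NULL, radius_decay = NULL,
                           target_vd = NULL, velocity_mean = NULL,
                           velocity_cv = NULL, velocity_floor = NULL,
                           direction_disorder = NULL, seed = 1L) {
  phenotype <- match.arg(phenotype)
  preset <- if (phenotype == "reactive") {
    list(node_axes = c(9, 6), n_root_vessels = 6, branching_prob = 0.45,
         tortuosity = 0.15, radius_root = 60, radius_decay = 0.85,
         target_vd = 0.40, velocity_mean = 25, velocity_cv = 0.15,
         velocity_floor = 4, direction_disorder = 0.15)
  } else {
    list(node_axes = c(9, 6), n_root_vessels = 12, branching_prob = 0.85,
         tortuosity = 0.50, radius_root = 60, radius_decay = 0.80,
         target_vd = 0.48, velocity_mean = 25, velocity_cv = 0.40,
         velocity_floor = 1, direction_disorder = 0.70)
  }
  user <- list(node_axes = node_axes, n_root_vessels = n_root_vessels,
               branching_prob = branching_prob, tortuosity = tortuosity,
               radius_root = radius_root, radius_decay = radius_decay,
               target_vd = target_vd, velocity_mean = velocity_mean,
               velocity_cv = velocity_cv, velocity_floor = velocity_floor,
               direction_disorder = direction_disorder)
  for (nm in names(user)) if (!is.null(user[[nm]])) preset[[nm]] <- user[[nm]]
  cfg <- c(list(phenotype = phenotype), preset, list(seed = as.integer(seed)))
  if (cfg$target_vd < 0 || cfg$target_vd > 1) {
    stop("`target_vd` must lie in [0, 1]", call. = FALSE)
  }
  for (nm in c("node_axes", "radius_root", "velocity_mean")) {
    if (any(cfg[[nm]] <= 0)) stop("`", nm, "` must be positive", call. = FALSE)
  }
  if (cfg$direction_disorder < 0 || cfg$direction_disorder > 1) {
    stop("`direction_disorder` must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "phantom_config")
}

# Stamp one segment into the occupancy raster. Returns updated count of
# occupied pixels inside the ellipse.
stamp_segment <- function(occ, inside, poly, radius_um, pixel_size, a, b) {
  px <- pixel_size / 1000
  ny <- nrow(occ); nx <- ncol(occ)
  # resample centerline at half-pixel steps
  d <- sqrt(diff(poly[, 1])^2 + diff(poly[, 2])^2)
  len <- sum(d)
  n_s <- max(2L, ceiling(len / (px / 2)))
  s <- seq(0, len, length.out = n_s)
  cs <- c(0, cumsum(d))
  xs <- approx(cs, poly[, 1], xout = s, ties = "ordered")$y
  ys <- approx(cs, poly[, 2], xout = s, ties = "ordered")$y
  ci <- floor((xs + a) / px) + 1L
  ri <- floor((ys + b) / px) + 1L
  rpx <- radius_um / pixel_size
  off <- expand.grid(dr = -ceiling(rpx):ceiling(rpx),
                     dc = -ceiling(rpx):ceiling(rpx))
  off <- off[off$dr^2 + off$dc^2 <= max(rpx, 0.501)^2, , drop = FALSE]
  rr <- outer(ri, off$dr, "+"); cc <- outer(ci, off$dc, "+")
  keep <- rr >= 1L & rr <= ny & cc >= 1L & cc <= nx
  idx <- unique((cc[keep] - 1L) * ny + rr[keep])
  idx <- idx[!occ[idx]]
  occ[idx] <- TRUE
  list(occ = occ, gained = sum(inside[idx]))
}

# Grow one vessel tree from a capsule entry point; returns a list of
# segments (poly, radius_um, flow_speed, flow_sign).
grow_tree <- function(cfg, root_angle) {
  a <- cfg$node_axes[1]; b <- cfg$node_axes[2]
  ds <- 0.15
  segs <- list()
  # queue of branches to grow: position, heading, radius, speed, depth
  start <- c(a * cos(root_angle) * 0.98, b * sin(root_angle) * 0.98)
  target <- c(runif(1, -0.4, 0.4) * a, runif(1, -0.4, 0.4) * b)
  heading <- atan2(target[2] - start[2], target[1] - start[1])
  # Per-branch flow speed: a bounded log-normal heterogeneity factor drawn
  # independently per branch (so every node carries the full within-node
  # speed distribution) times a per-generation slowdown whose range widens
  # with velocity_cv -- organized networks lose a little speed per
  # generation, chaotic immature networks both stall (towards
  # velocity_floor) and shunt (local speed-ups).
  decay_lo <- clamp(1 - 0.9 * cfg$velocity_cv, 0.5, 1)
  decay_hi <- 1 + 0.4 * cfg$velocity_cv
  speed_cap <- 2.2 * cfg$velocity_mean
  # fraction of branches with fully chaotic perfusion (speed uniform over
  # the physiological range instead of the organized bell around the mean)
  chaos <- clamp(1.8 * (cfg$velocity_cv - 0.1), 0, 1)
  branch_speed <- function(depth) {
    if (runif(1) < chaos) {
      runif(1, cfg$velocity_floor, speed_cap)
    } else {
      # generation slowdown saturates at the capillary plateau
      clamp(cfg$velocity_mean *
              clamp(exp(rnorm(1, 0, cfg$velocity_cv)), 0.2, 2.2) *
              runif(1, decay_lo, decay_hi)^min(depth, 3L),
            cfg$velocity_floor, speed_cap)
    }
  }
  queue <- list(list(pos = start, heading = heading,
                     radius = cfg$radius_root,
                     speed = branch_speed(0L), depth = 0L))
  sign_random <- runif(1) < cfg$direction_disorder
  while (length(queue) > 0L && length(segs) < 400L) {
    br <- queue[[1L]]; queue <- queue[-1L]
    pos <- br$pos; heading <- br$heading
    pts <- matrix(pos, ncol = 2)
    max_len <- runif(1, 3, 8)
    len <- 0
    while (len < max_len) {
      heading <- heading + rnorm(1, 0, cfg$tortuosity * sqrt(ds))
      nxt <- pos + ds * c(cos(heading), sin(heading))
      if ((nxt[1] / a)^2 + (nxt[2] / b)^2 > 0.97) break
      pos <- nxt; len <- len + ds
      pts <- rbind(pts, pos)
      if (br$depth < 8L && runif(1) < cfg$branching_prob * ds) {
        spread <- (30 + 60 * cfg$direction_disorder) * pi / 180
        child_heading <- heading + sample(c(-1, 1), 1) * runif(1, 0.4, 1) * spread
        queue <- c(queue, list(list(
          pos = pos, heading = child_heading,
          radius = max(br$radius * cfg$radius_decay, 12),
          speed = branch_speed(br$depth + 1L),
          depth = br$depth + 1L)))
      }
    }
    if (nrow(pts) >= 2L) {
      flow_sign <- if (sign_random && runif(1) < 0.5) -1L else 1L
      segs[[length(segs) + 1L]] <- list(poly = pts, radius_um = br$radius,
                                        flow_speed = br$speed,
                                        flow_sign = flow_sign)
    }
  }
  segs
}

#' Generate a synthetic vascular phantom
#'
#' Grows vessel trees inside the node ellipse until the rasterized vascular
#' fraction (at `pixel_size`) reaches `target_vd`; growth stops mid-tree as
#' soon as the target is met, so the realized fraction stays within a few
#' percent of the target. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @param pixel_size Raster pitch in micrometres used to monitor the vascular
#'   fraction (default 25, the map-building default).
#' @return An object of class `vascular_phantom` with elements `segments`
#'   (list of `poly` (n x 2 mm, node-centred coordinates), `radius_um`,
#'   `flow_speed` (mm/s), `flow_sign`), `node_axes`, `vascular_fraction`, and
#'   `config`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config("reactive", node_axes = c(4, 3),
#'                                       target_vd = 0.2, seed = 1))
#' ph$vascular_fraction
generate_phantom <- function(config, pixel_size = 25) {
  stopifnot(inherits(config, "phantom_config"))
  if (config$target_vd > 0.95) {
    stop("target_vd > 0.95 is unreachable for a vessel raster", call. = FALSE)
  }
  a <- config$node_axes[1]; b <- config$node_axes[2]
  empty <- structure(list(segments = list(), node_axes = config$node_axes,
                          vascular_fraction = 0, pixel_size = pixel_size,
                          config = config),
                     class = "vascular_phantom")
  if (config$target_vd == 0) return(empty)
  px <- pixel_size / 1000
  nx <- ceiling(2 * a / px); ny <- ceiling(2 * b / px)
  xs <- (seq_len(nx) - 0.5) * px - a
  ys <- (seq_len(ny) - 0.5) * px - b
  inside <- outer(ys^2 / b^2, xs^2 / a^2, "+") <= 1
  n_inside <- sum(inside)
  occ <- matrix(FALSE, ny, nx)
  n_vasc <- 0L
  segments <- list()
  with_seed(config$seed, {
    max_roots <- max(config$n_root_vessels * 50L, 500L)
    hilum <- 0
    halfwidth <- pi * clamp(0.08 + config$direction_disorder, 0, 1)
    done <- FALSE
    for (root in seq_len(max_roots)) {
      root_angle <- hilum + runif(1, -halfwidth, halfwidth)
      tree <- grow_tree(config, root_angle)
      for (seg in tree) {
        st <- stamp_segment(occ, inside, seg$poly, seg$radius_um,
                            pixel_size, a, b)
        occ <- st$occ
        n_vasc <- n_vasc + st$gained
        segments[[length(segments) + 1L]] <- seg
        if (n_vasc / n_inside >= config$target_vd) { done <- TRUE; break }
      }
      if (done) break
    }
    if (!done && n_vasc / n_inside < 0.8 * config$target_vd) {
      stop("phantom growth could not reach target_vd = ", config$target_vd,
           " (achieved ", signif(n_vasc / n_inside, 3), ")", call. = FALSE)
    }
  })
  structure(list(segments = segments, node_axes = config$node_axes,
                 vascular_fraction = n_vasc / n_inside,
                 pixel_size = pixel_size, config = config),
            class = "vascular_phantom")
}

#' Rasterize a phantom to a binary vessel mask
#'
#' Independent of the growth bookkeeping: stamps every segment at the given
#' pitch and returns the occupancy grid over the node bounding box, plus the
#' vascular fraction inside the ellipse.
#'
#' @param phantom A `vascular_phantom`.
#' @param pixel_size Pitch in micrometres.
#' @return List with `mask` (logical matrix, rows = y, cols = x), `inside`
#'   (ellipse membership), and `fraction`.
#' @export
rasterize_phantom <- function(phantom, pixel_size = 25) {
  a <- phantom$node_axes[1]; b <- phantom$node_axes[2]
  px <- pixel_size / 1000
  nx <- ceiling(2 * a / px); ny <- ceiling(2 * b / px)
  xs <- (seq_len(nx) - 0.5) * px - a
  ys <- (seq_len(ny) - 0.5) * px - b
  inside <- outer(ys^2 / b^2, xs^2 / a^2, "+") <= 1
  occ <- matrix(FALSE, ny, nx)
  n_vasc <- 0L
  for (seg in phantom$segments) {
    st <- stamp_segment(occ, inside, seg$poly, seg$radius_um, pixel_size, a, b)
    occ <- st$occ
    n_vasc <- n_vasc + st$gained
  }
  list(mask = occ, inside = inside, fraction = n_vasc / sum(inside))
}

#' @export
print.vascular_phantom <- function(x, ...) {
  cat(sprintf("vascular_phantom (%s): %d segments, vascular fraction %.3f in %g x %g mm ellipse\n",
              x$config$phenotype, length(x$segments), x$vascular_fraction,
              2 * x$node_axes[1], 2 * x$node_axes[2]))
  invisible(x)
}
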