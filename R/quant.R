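# The fourteen quantitative SRUS parameters of one node.

#' Quantification configuration
#'
#' Estimator settings for the parameter suite: the vascular-pixel rule
#' (minimum localization count, default 1 — a pixel visited by at least one
#' localized bubble counts as vascular), the histogram bin count used by
#' both normalized entropies (default 64), and the box-counting setup for
#' the fractal dimension (descending power-of-two box sizes; the smallest
#' and largest sizes are dropped from the log-log fit to avoid saturation
#' bias unless too few sizes remain).
#'
#' @param vascular_pixel_rule Minimum per-pixel localization count (>= 1).
#' @param entropy_bins Histogram bin count K (>= 2); entropies are divided
#'   by `log(K)` so they live in `[0, 1]`.
#' @param fd_box_sizes Optional integer vector of strictly decreasing box
#'   sizes; defaults to powers of two fitted to the mask at run time.
#' @return Object of class `quant_config`.
#' @export
quant_config <- function(vascular_pixel_rule = 1, entropy_bins = 64,
                         fd_box_sizes = NULL) {
  if (entropy_bins < 2) stop("entropy_bins must be >= 2", call. = FALSE)
  if (vascular_pixel_rule < 1) {
    stop("vascular_pixel_rule must be >= 1", call. = FALSE)
  }
  if (!is.null(fd_box_sizes)) {
    fd_box_sizes <- as.integer(fd_box_sizes)
    if (any(diff(fd_box_sizes) >= 0) || any(fd_box_sizes < 1)) {
      stop("fd_box_sizes must be strictly decreasing positive integers",
           call. = FALSE)
    }
  }
  structure(list(vascular_pixel_rule = vascular_pixel_rule,
                 entropy_bins = as.integer(entropy_bins),
                 fd_box_sizes = fd_box_sizes),
            class = "quant_config")
}

#' Binarize the density map into a vascular mask
#'
#' A pixel is vascular iff it lies inside the ROI and its localization count
#' meets the rule threshold.
#'
#' @param density Localization-count grid.
#' @param roi Logical ROI mask, congruent with `density`, non-empty.
#' @param rule Minimum localization count (default 1).
#' @return Logical matrix.
#' @export
binarize_vascular <- function(density, roi, rule = 1) {
  if (!all(dim(density) == dim(roi))) {
    stop("density and roi must be congruent", call. = FALSE)
  }
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  density >= rule & roi
}

#' Vascular density
#'
#' Fraction of ROI pixels classified as vascular (microvascular richness).
#'
#' @param vascular Logical vascular mask.
#' @param roi Logical ROI mask.
#' @return VD in `[0, 1]`.
#' @export
compute_vd <- function(vascular, roi) {
  n_roi <- sum(roi)
  if (n_roi == 0) stop("ROI is empty", call. = FALSE)
  sum(vascular & roi) / n_roi
}

#' Flow-weighted vascular density
#'
#' Sum of signal intensities over vascular ROI pixels divided by the total
#' ROI pixel count — a total-blood-volume proxy.
#'
#' @param intensity Intensity grid.
#' @param vascular,roi Logical masks congruent with `intensity`.
#' @return FWVD (intensity units per ROI pixel).
#' @export
compute_fwvd <- function(intensity, vascular, roi) {
  if (!all(dim(intensity) == dim(roi))) {
    stop("grids must be congruent", call. = FALSE)
  }
  n_roi <- sum(roi)
  if (n_roi == 0) stop("ROI is empty", call. = FALSE)
  sum(intensity[vascular & roi]) / n_roi
}

#' Vessel diameter statistics
#'
#' Skeletonizes the vascular mask and samples a local diameter at every
#' skeleton pixel as `(2 d - 1) * pixel_size`, where `d` is the Euclidean
#' distance (in pixels) from the skeleton pixel to the nearest background
#' pixel — the standard medial-axis morphometric estimator (a strip w pixels
#' wide has centerline distance `(w + 1) / 2`, hence diameter `w` pixels).
#'
#' @param vascular Logical vascular mask.
#' @param pixel_size Pixel pitch, micrometres.
#' @return Named numeric: `Dmax`, `Dmean`, `Dstd` (micrometres). An empty
#'   mask returns zeros with a warning.
#' @export
compute_diameters <- function(vascular, pixel_size) {
  stopifnot_scalar_pos(pixel_size, "pixel_size")
  if (!any(vascular)) {
    warning("empty vascular mask; diameters reported as 0", call. = FALSE)
    return(c(Dmax = 0, Dmean = 0, Dstd = 0))
  }
  m <- matrix(as.integer(vascular), nrow(vascular), ncol(vascular))
  dist <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
  skel <- skeletonize(vascular)
  d <- dist[skel]
  d <- d[d > 0]
  diam <- (2 * d - 1) * pixel_size
  c(Dmax = max(diam), Dmean = mean(diam),
    Dstd = if (length(diam) > 1) sd(diam) else 0)
}

# Count boxes of size s (pixels) containing at least one TRUE.
count_boxes <- function(mask, s) {
  ny <- nrow(mask); nx <- ncol(mask)
  ri <- (row(mask) - 1L) %/% s
  ci <- (col(mask) - 1L) %/% s
  length(unique((ci[mask]) * (((ny - 1L) %/% s) + 1L) + ri[mask]))
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes N(s) over descending power-of-two box sizes and
#' fits `log N(s)` against `log(1/s)` by least squares; the slope, clamped
#' to `[0, 2]`, quantifies branching complexity (1 = curve, 2 =
#' plane-filling). The smallest and largest box sizes are excluded from the
#' fit when at least four sizes are available, avoiding saturation bias at
#' the scale extremes.
#'
#' @param vascular Logical vascular mask (non-empty).
#' @param config A [quant_config()]; `fd_box_sizes` overrides the default
#'   size ladder.
#' @return FD in `[0, 2]`.
#' @export
#' @examples
#' compute_fd(matrix(TRUE, 64, 64))            # ~2
#' compute_fd(diag(64) > 0)                    # ~1
compute_fd <- function(vascular, config = quant_config()) {
  if (!any(vascular)) stop("vascular mask is empty", call. = FALSE)
  sizes <- config$fd_box_sizes
  if (is.null(sizes)) {
    kmax <- floor(log2(min(dim(vascular))))
    sizes <- 2^(seq(kmax - 1, 0))
  }
  sizes <- sizes[sizes <= min(dim(vascular))]
  if (length(sizes) < 2) {
    warning("mask smaller than box range; shrinking to 2 sizes",
            call. = FALSE)
    sizes <- c(2L, 1L)
  }
  n <- vapply(sizes, function(s) count_boxes(vascular, s), numeric(1))
  fit_idx <- if (length(sizes) >= 4) 2:(length(sizes) - 1) else
    seq_along(sizes)
  x <- log(1 / sizes[fit_idx])
  y <- log(n[fit_idx])
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  clamp(slope, 0, 2)
}

# Normalized Shannon entropy of counts over K bins (0 for degenerate, 1 for
# uniform), divided by log(K).
norm_entropy <- function(counts, K) {
  p <- counts[counts > 0] / sum(counts)
  h <- -sum(p * log(p))
  h / log(K)
}

#' Velocity statistics over the vascular ROI
#'
#' Statistics of per-pixel mean flow speed over vascular ROI pixels with at
#' least one contributing track step (pixels without flow signal are
#' excluded, so `Vmin` reflects the slowest observed flow, not background
#' zeros). `VelEntropy` is the Shannon entropy of the K-bin histogram over
#' `(0, max]`, normalized by `log(K)`.
#'
#' @param velocity Per-pixel speed grid (mm/s, `NA` where undefined).
#' @param vascular,roi Logical masks.
#' @param config A [quant_config()].
#' @return Named numeric: `Vmean`, `Vmax`, `Vmin` (mm/s), `VelVar`
#'   ((mm/s)^2, population variance), `VelEntropy` in `[0, 1]`.
#' @export
velocity_stats <- function(velocity, vascular, roi, config = quant_config()) {
  v <- velocity[vascular & roi]
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    stop("no vascular ROI pixels with defined velocity", call. = FALSE)
  }
  K <- config$entropy_bins
  vmax <- max(v)
  if (vmax <= 0) {
    counts <- c(length(v), rep(0, K - 1))
  } else {
    bin <- clamp(ceiling(v / vmax * K), 1, K)
    counts <- tabulate(bin, nbins = K)
  }
  c(Vmean = mean(v), Vmax = vmax, Vmin = min(v),
    VelVar = mean((v - mean(v))^2),
    VelEntropy = norm_entropy(counts, K))
}

#' Direction statistics over the vascular ROI
#'
#' `DirVar` is the variance of per-pixel flow directions about their
#' circular mean, with deviations wrapped to `[-180, 180)` and measured in
#' degrees squared (uniform directions give 10800 deg^2 in expectation).
#' `DirEntropy` is the normalized Shannon entropy of the K-bin angular
#' histogram over `[-180, 180)`.
#'
#' @param direction Per-pixel direction grid (degrees in `[-180, 180)`,
#'   `NA` where undefined).
#' @param vascular,roi Logical masks.
#' @param config A [quant_config()].
#' @return Named numeric: `DirVar` (deg^2), `DirEntropy` in `[0, 1]`.
#' @export
direction_stats <- function(direction, vascular, roi,
                            config = quant_config()) {
  th <- direction[vascular & roi]
  th <- th[!is.na(th)]
  if (length(th) == 0) {
    stop("no vascular ROI pixels with defined direction", call. = FALSE)
  }
  rad <- th * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  dev <- wrap_degrees(th - mu)
  K <- config$entropy_bins
  bin <- clamp(floor((th + 180) / 360 * K) + 1, 1, K)
  c(DirVar = mean(dev^2),
    DirEntropy = norm_entropy(tabulate(bin, nbins = K), K))
}

#' Perfusion index
#'
#' @param vmean Mean flow velocity, mm/s.
#' @param vd Vascular density in `[0, 1]`.
#' @return `PI = vmean * vd` (mm/s).
#' @export
compute_pi <- function(vmean, vd) {
  if (!is.finite(vmean) || !is.finite(vd) || vd < 0 || vd > 1) {
    stop("vmean must be finite and vd in [0, 1]", call. = FALSE)
  }
  vmean * vd
}

#' Compute all fourteen SRUS parameters of a node
#'
#' Assembles the full parameter vector from an SRUS map set restricted to an
#' ROI: vascular density, diameter statistics, fractal dimension,
#' flow-weighted vascular density, velocity statistics and entropies,
#' direction variance and entropy, and the perfusion index
#' (`PI = Vmean * VD`, exact by construction).
#'
#' @param maps An `srus_maps` object from [build_maps()].
#' @param roi Logical ROI mask congruent with the maps.
#' @param config A [quant_config()].
#' @return Named numeric vector of length 14 in [srus_parameters()] order.
#' @export
compute_all <- function(maps, roi, config = quant_config()) {
  stopifnot(inherits(maps, "srus_maps"))
  if (!all(dim(maps$density) == dim(roi))) {
    stop("maps and ROI must be congruent", call. = FALSE)
  }
  vascular <- binarize_vascular(maps$density, roi,
                                rule = config$vascular_pixel_rule)
  vd <- compute_vd(vascular, roi)
  diam <- if (any(vascular)) compute_diameters(vascular, maps$pixel_size) else
    c(Dmax = 0, Dmean = 0, Dstd = 0)
  fwvd <- compute_fwvd(maps$intensity, vascular, roi)
  fd <- if (any(vascular)) compute_fd(vascular, config) else 0
  vel <- velocity_stats(maps$velocity, vascular, roi, config)
  dir <- direction_stats(maps$direction, vascular, roi, config)
  out <- c(VD = vd, diam, FWVD = fwvd, FD = fd, vel, dir,
           PI = compute_pi(unname(vel["Vmean"]), vd))
  out[srus_parameters()]
}
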