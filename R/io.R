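# Plain-text / raster IO for every pipeline artifact.
#
# Schemas:
#   tracks CSV:  track_id,frame,x_mm,y_mm,intensity (0-based frames)
#   cohort CSV:  node_id,label,<14 parameter columns>[,covariates]
#   map TIFF:    32-bit float pages in fixed order (density, intensity,
#                velocity, direction, coverage, dir_coverage), each page
#                scaled to [0,1] with per-page offset/scale recorded in the
#                JSON sidecar; undefined velocity/direction pixels are
#                reconstructed from the coverage pages on read
#   ROI raster:  8-bit PNG, 0/255
#   model/report: JSON

#' Write / read a bubble-tracks CSV
#'
#' @param tracks A [bubble_tracks()] object.
#' @param path Output CSV path; the displacement series and acquisition are
#'   stored in a JSON sidecar `<path>.json`.
#' @return `write_tracks_csv`: the path, invisibly. `read_tracks_csv`: a
#'   `bubble_tracks` object.
#' @export
write_tracks_csv <- function(tracks, path) {
  stopifnot(inherits(tracks, "bubble_tracks"))
  write.csv(tracks$tracks, path, row.names = FALSE)
  acq <- tracks$acquisition
  jsonlite::write_json(
    list(acquisition = unclass(acq),
         displacement_series = tracks$displacement_series),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @param acquisition Acquisition to attach when no sidecar exists.
#' @export
read_tracks_csv <- function(path, acquisition = NULL) {
  df <- read.csv(path)
  need <- c("track_id", "frame", "x_mm", "y_mm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("tracks file ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(df$frame < 0 | df$frame != floor(df$frame))[1]
  if (!is.na(bad)) {
    stop("tracks file ", path, ": malformed frame index at row ", bad,
         call. = FALSE)
  }
  bad <- which(df$intensity < 0 | !is.finite(df$intensity))[1]
  if (!is.na(bad)) {
    stop("tracks file ", path, ": invalid intensity at row ", bad,
         call. = FALSE)
  }
  side <- paste0(path, ".json")
  disp <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    acquisition <- do.call(acquisition_config, meta$acquisition)
    disp <- meta$displacement_series
  }
  if (is.null(acquisition)) {
    stop("no acquisition sidecar found for ", path,
         "; pass `acquisition` explicitly", call. = FALSE)
  }
  if (is.null(disp)) disp <- numeric(acquisition$n_frames)
  bubble_tracks(df, acquisition, disp)
}

#' Write / read a cohort CSV
#'
#' @param cohort Cohort `data.frame` (`node_id`, `label`, 14 parameters,
#'   optional covariates).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  check_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_cohort(df)
  if (anyDuplicated(df$node_id)) {
    stop("cohort file ", path, ": duplicate node_id", call. = FALSE)
  }
  df
}

map_page_order <- c("density", "intensity", "velocity", "direction",
                    "coverage", "dir_coverage")

#' Write / read an SRUS map set as multi-page TIFF + JSON sidecar
#'
#' Pages are written in a fixed, documented order; each page is affinely
#' scaled to `[0, 1]` for 32-bit float TIFF storage and the offset/scale are
#' recorded in the sidecar together with pixel size, extent and acquisition
#' metadata. Undefined (`NA`) velocity/direction pixels are re-derived from
#' the coverage pages on read.
#'
#' @param maps An `srus_maps` object.
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @export
write_maps_tiff <- function(maps, path) {
  stopifnot(inherits(maps, "srus_maps"))
  pages <- list(); scales <- list()
  for (nm in map_page_order) {
    g <- maps[[nm]]
    g[is.na(g)] <- 0
    lo <- min(g); hi <- max(g)
    sc <- if (hi > lo) hi - lo else 1
    pages[[nm]] <- (g - lo) / sc
    scales[[nm]] <- list(offset = lo, scale = sc)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(pages = map_page_order, scaling = scales,
         pixel_size = maps$pixel_size, extent = maps$extent,
         acquisition = unclass(maps$acquisition)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_maps_tiff
#' @export
read_maps_tiff <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) {
    stop("missing sidecar ", side, call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("pixel_size", "extent", "pages", "scaling")) {
    if (is.null(meta[[field]])) {
      stop("sidecar ", side, " is missing `", field, "`", call. = FALSE)
    }
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- list()
  for (i in seq_along(meta$pages)) {
    nm <- meta$pages[i]
    sc <- meta$scaling[[nm]]
    out[[nm]] <- pages[[i]] * sc$scale + sc$offset
  }
  out$velocity[out$coverage == 0] <- NA_real_
  out$direction[out$dir_coverage == 0] <- NA_real_
  acq <- do.call(acquisition_config, as.list(meta$acquisition))
  structure(c(out, list(pixel_size = meta$pixel_size,
                        origin = meta$extent[1:2], extent = meta$extent,
                        acquisition = acq)),
            class = "srus_maps")
}

#' Write / read an ROI mask raster (8-bit PNG, 0/255)
#'
#' @param roi Logical matrix.
#' @param path PNG path.
#' @export
write_roi_png <- function(roi, path) {
  png::writePNG(matrix(as.numeric(roi), nrow(roi), ncol(roi)), path)
  invisible(path)
}

#' @rdname write_roi_png
#' @export
read_roi_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  mask <- img >= 0.5
  if (!any(mask)) stop("ROI raster ", path, " is empty", call. = FALSE)
  mask
}

#' Write / read a fitted logistic model as JSON
#'
#' Serializes coefficients, intercept, selection trace and the
#' preprocessing spec — everything needed to score new cohorts.
#'
#' @param model A `logistic_model`.
#' @param path JSON path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "logistic_model"))
  jsonlite::write_json(
    list(predictors = model$predictors, intercept = model$intercept,
         coefficients = model$coefficients, trace = model$trace,
         spec = model$spec),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @param design,labels Data used to rebuild the glm fit object on read.
#' @export
read_model_json <- function(path, design = NULL, labels = NULL) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- if (!is.null(m$spec)) {
    lapply(m$spec, function(s) s)
  }
  structure(list(predictors = as.character(unlist(m$predictors)),
                 coefficients = as.data.frame(m$coefficients),
                 intercept = m$intercept, trace = m$trace, fit = NULL,
                 spec = spec),
            class = "logistic_model")
}
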