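# End-to-end orchestration.

#' Pipeline configuration
#'
#' Bundles every stage configuration plus a single global seed that fans out
#' deterministically to stage substreams. Two entry modes exist: the
#' image-level path simulates phantoms and bubble tracks per node, builds
#' maps (with the motion-QC gate; a failing node is re-acquired with reduced
#' motion, mirroring a repeated scan) and quantifies them; the cohort-level
#' path samples calibrated parameter vectors directly and is the substrate
#' of the statistics stage.
#'
#' @param n_nodes_per_phenotype Nodes per phenotype on the image-level path
#'   (default 3, the 6-node demo).
#' @param n_bubbles Bubbles per node.
#' @param acquisition An [acquisition_config()].
#' @param reactive,metastatic [phantom_config()]s for the two phenotypes
#'   (seeds are reassigned per node from the global seed).
#' @param calibration A [cohort_calibration()] for the cohort-level path.
#' @param quant A [quant_config()].
#' @param stepwise A [stepwise_config()].
#' @param motion_amplitude Peak tissue displacement per acquisition, mm.
#' @param run_imaging,run_cohort Stage toggles.
#' @param seed Global seed.
#' @param out_dir Output directory (`NULL` = no artifacts written).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_nodes_per_phenotype = 3L, n_bubbles = 300L,
                            acquisition = acquisition_config(),
                            reactive = phantom_config("reactive"),
                            metastatic = phantom_config("metastatic"),
                            calibration = cohort_calibration(),
                            quant = quant_config(),
                            stepwise = stepwise_config(),
                            motion_amplitude = 0.2,
                            run_imaging = TRUE, run_cohort = TRUE,
                            seed = 1L, out_dir = NULL) {
  structure(list(n_nodes_per_phenotype = as.integer(n_nodes_per_phenotype),
                 n_bubbles = as.integer(n_bubbles),
                 acquisition = acquisition, reactive = reactive,
                 metastatic = metastatic, calibration = calibration,
                 quant = quant, stepwise = stepwise,
                 motion_amplitude = motion_amplitude,
                 run_imaging = run_imaging, run_cohort = run_cohort,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full SRUS pipeline
#'
#' Executes simulate -> maps (with motion QC; nodes failing the 0.5 mm gate
#' are re-acquired with halved motion until they pass) -> quant on the
#' image-level path, and cohort sampling -> group comparison -> univariate
#' ROC -> preprocessing -> forward-conditional stepwise logistic ->
#' combined-model ROC on the cohort-level path. Re-running with an identical
#' config reproduces identical numeric blocks.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: per-node parameter table and QC
#'   outcomes (`imaging`), comparison/ROC/model blocks (`stats`), and
#'   provenance (`seed`, timing, package version).
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_nodes_per_phenotype = 1L, n_bubbles = 80L,
#'                        acquisition = acquisition_config(
#'                          field_of_view = c(10, 8), pixel_size = 50),
#'                        reactive = phantom_config("reactive",
#'                          node_axes = c(4, 3)),
#'                        metastatic = phantom_config("metastatic",
#'                          node_axes = c(4, 3)))
#' rep <- run_pipeline(cfg)
#' }
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  report <- list(seed = config$seed,
                 package_version = as.character(utils::packageVersion("srusq")))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (config$run_imaging) {
    nodes <- list(); qc_log <- list()
    node_id <- 0L
    for (phen in c("reactive", "metastatic")) {
      base_cfg <- config[[phen]]
      for (k in seq_len(config$n_nodes_per_phenotype)) {
        node_id <- node_id + 1L
        ph_cfg <- base_cfg
        ph_cfg$seed <- substream_seed(config$seed, "phantom") + node_id
        phantom <- tryCatch(
          generate_phantom(ph_cfg, pixel_size = config$acquisition$pixel_size),
          error = function(e) stop("stage phantom_sim (node ", node_id, "): ",
                                   conditionMessage(e), call. = FALSE))
        amp <- config$motion_amplitude
        attempt <- 0L
        repeat {
          attempt <- attempt + 1L
          tr <- simulate_tracks(phantom, config$acquisition,
                                n_bubbles = config$n_bubbles,
                                motion_amplitude = amp,
                                seed = config$seed * 1000L + node_id * 10L +
                                  attempt)
          qc <- motion_qc(tr$displacement_series)
          qc_log[[length(qc_log) + 1]] <-
            list(node = node_id, attempt = attempt, passed = qc$passed,
                 max_displacement = qc$max_displacement)
          if (qc$passed) break
          if (attempt >= 5L) {
            stop("stage map_builder (node ", node_id,
                 "): motion QC kept failing", call. = FALSE)
          }
          amp <- amp / 2
        }
        maps <- build_maps(tr)
        roi <- roi_ellipse(maps,
                           semi_axes = phantom$node_axes)
        pv <- tryCatch(compute_all(maps, roi, config$quant),
                       error = function(e) stop("stage quant (node ", node_id,
                                                "): ", conditionMessage(e),
                                                call. = FALSE))
        nodes[[node_id]] <- data.frame(
          node_id = sprintf("%s%02d", toupper(substr(phen, 1, 1)), k),
          label = if (phen == "metastatic") "metastatic" else "reactive",
          t(pv))
        if (!is.null(out_dir)) {
          write_maps_tiff(maps, file.path(out_dir,
                                          sprintf("node%02d.tif", node_id)))
        }
      }
    }
    imaging_table <- do.call(rbind, nodes)
    rownames(imaging_table) <- NULL
    report$imaging <- list(parameters = imaging_table, qc = qc_log)
    if (!is.null(out_dir)) {
      write.csv(imaging_table, file.path(out_dir, "imaging_parameters.csv"),
                row.names = FALSE)
    }
  }
  if (config$run_cohort) {
    cohort <- generate_cohort(config$calibration, seed = config$seed)
    comparison <- compare_groups(cohort)
    roc_tab <- do.call(rbind, lapply(setdiff(srus_parameters(),
                                             c("Dmax", "Dmean", "Dstd")),
      function(p) {
        r <- univariate_roc(cohort, p)
        data.frame(parameter = p, auc = r$auc, ci_low = r$ci95[1],
                   ci_high = r$ci95[2], sensitivity = r$sensitivity,
                   specificity = r$specificity)
      }))
    pp <- preprocess_cohort(cohort)
    model <- tryCatch(
      stepwise_logistic(pp$design, pp$labels, config$stepwise),
      error = function(e) stop("stage stats: ", conditionMessage(e),
                               call. = FALSE))
    model$spec <- pp$spec
    combined <- evaluate_model(model, cohort)
    report$stats <- list(
      comparison = comparison, univariate_roc = roc_tab,
      model = list(predictors = model$predictors,
                   coefficients = model$coefficients,
                   intercept = model$intercept),
      combined_roc = list(auc = combined$auc, ci95 = combined$ci95,
                          sensitivity = combined$sensitivity,
                          specificity = combined$specificity))
    if (!is.null(out_dir)) {
      write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
      write.csv(comparison, file.path(out_dir, "comparison.csv"),
                row.names = FALSE)
      write.csv(roc_tab, file.path(out_dir, "univariate_roc.csv"),
                row.names = FALSE)
      write_model_json(model, file.path(out_dir, "model.json"))
    }
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (!is.null(out_dir)) {
    jsonlite::write_json(report_numeric_blocks(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(report, class = "run_report")
}

# Numeric blocks only (drops fit objects / timing) for serialization and
# determinism checks.
report_numeric_blocks <- function(report) {
  out <- list(seed = report$seed)
  if (!is.null(report$imaging)) {
    out$imaging <- list(parameters = report$imaging$parameters,
                        qc = report$imaging$qc)
  }
  if (!is.null(report$stats)) out$stats <- report$stats
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("SRUS pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$imaging)) {
    cat(sprintf("  imaging: %d nodes quantified, %d QC checks\n",
                nrow(x$imaging$parameters), length(x$imaging$qc)))
  }
  if (!is.null(x$stats)) {
    cat(sprintf("  model: %s; combined AUC %.3f\n",
                paste(x$stats$model$predictors, collapse = " + "),
                x$stats$combined_roc$auc))
  }
  invisible(x)
}
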