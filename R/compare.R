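# Group comparison with a normality gate.

#' Compare SRUS parameters between metastatic and reactive groups
#'
#' For each parameter: Shapiro-Wilk normality check at alpha = 0.05 in each
#' group; if both groups look normal a Welch two-sample t-test is used,
#' otherwise a Mann-Whitney U test (normal approximation with continuity and
#' tie correction). Summaries report mean +/- SD and median (IQR) for every
#' parameter so either presentation convention can be used downstream.
#'
#' @param cohort Cohort `data.frame` with a binary `label` column
#'   (`"metastatic"`/`"reactive"`) and the 14 parameter columns.
#' @param parameters Character vector of columns to compare (default all 14).
#' @param shapiro_alpha Normality-gate significance level (default 0.05).
#' @return `data.frame` with one row per parameter: group means/SDs,
#'   medians/IQRs, normality outcome, test used, statistic and p-value.
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' head(compare_groups(co))
compare_groups <- function(cohort, parameters = srus_parameters(),
                           shapiro_alpha = 0.05) {
  check_cohort(cohort, parameters)
  met <- cohort[cohort$label == "metastatic", , drop = FALSE]
  rea <- cohort[cohort$label == "reactive", , drop = FALSE]
  if (nrow(met) < 3 || nrow(rea) < 3) {
    stop("each group needs at least 3 nodes", call. = FALSE)
  }
  rows <- lapply(parameters, function(p) {
    x <- met[[p]]; y <- rea[[p]]
    normal <- shapiro_ok(x, shapiro_alpha) && shapiro_ok(y, shapiro_alpha)
    if (normal) {
      tt <- t.test(x, y, var.equal = FALSE)
      test <- "t"; statistic <- unname(tt$statistic); pval <- tt$p.value
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
      test <- "mann-whitney"; statistic <- unname(wt$statistic)
      pval <- wt$p.value
    }
    data.frame(parameter = p,
               mean_metastatic = mean(x), sd_metastatic = sd(x),
               mean_reactive = mean(y), sd_reactive = sd(y),
               median_metastatic = median(x),
               iqr_metastatic = unname(diff(quantile(x, c(0.25, 0.75)))),
               median_reactive = median(y),
               iqr_reactive = unname(diff(quantile(y, c(0.25, 0.75)))),
               normal = normal, test = test, statistic = statistic,
               p_value = pval)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

shapiro_ok <- function(x, alpha) {
  if (length(unique(x)) < 3) return(FALSE)
  x <- if (length(x) > 5000) sample(x, 5000) else x
  shapiro.test(x)$p.value > alpha
}

#' Compare a categorical covariate between groups (chi-square)
#'
#' @param cohort Cohort `data.frame` with a `label` column.
#' @param covariate Name of a categorical column.
#' @return List with the contingency `table`, `statistic` and `p_value`.
#' @export
compare_categorical <- function(cohort, covariate) {
  if (!covariate %in% names(cohort)) {
    stop("covariate `", covariate, "` not found", call. = FALSE)
  }
  tab <- table(cohort$label, cohort[[covariate]])
  ct <- suppressWarnings(chisq.test(tab))
  list(table = tab, statistic = unname(ct$statistic), p_value = ct$p.value)
}

check_cohort <- function(cohort, parameters = srus_parameters()) {
  if (!"label" %in% names(cohort)) {
    stop("cohort needs a `label` column", call. = FALSE)
  }
  if (!all(cohort$label %in% c("metastatic", "reactive"))) {
    stop("labels must be 'metastatic' or 'reactive'", call. = FALSE)
  }
  miss <- setdiff(parameters, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(as.matrix(cohort[parameters])))) {
    stop("cohort parameters contain missing or non-finite values",
         call. = FALSE)
  }
  invisible(cohort)
}
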