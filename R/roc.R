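# Empirical ROC analysis with DeLong variance.
#
# The AUC is the Mann-Whitney two-sample statistic (ties get half credit);
# its standard error and the covariance between two markers on the same
# nodes come from DeLong's structural components: V10_i = mean_j psi(x_i,
# y_j) over controls for each case i, V01_j the dual, with
# var(AUC) = var(V10)/m + var(V01)/n.

delong_components <- function(cases, controls) {
  psi <- outer(cases, controls,
               function(x, y) (x > y) + 0.5 * (x == y))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
}

#' Univariate ROC analysis of one parameter
#'
#' Empirical AUC for discriminating metastatic from reactive nodes, with
#' DeLong standard error and Wald 95% CI, plus the Youden-optimal operating
#' point (maximum sensitivity + specificity - 1; ties resolved towards the
#' higher-specificity threshold). By default the raw parameter is the score
#' with larger values indicating metastasis, so inverse markers can show
#' AUC < 0.5 (`direction = "auto"` flips such markers instead).
#'
#' @param cohort Cohort `data.frame` with `label` and the parameter column.
#' @param parameter Column name to evaluate.
#' @param direction `"larger"` (default: larger values called metastatic) or
#'   `"auto"` (flip the sign when the uncorrected AUC is below 0.5).
#' @param conf_level Confidence level for the CI (default 0.95).
#' @return Object of class `roc_result`: `auc`, `auc_se`, `ci95`,
#'   `youden_threshold`, `sensitivity`, `specificity`, `direction`,
#'   `parameter`, `n_cases`, `n_controls`, and the score components needed
#'   for paired comparisons.
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' univariate_roc(co, "VD")
univariate_roc <- function(cohort, parameter, direction = c("larger", "auto"),
                           conf_level = 0.95) {
  direction <- match.arg(direction)
  check_cohort(cohort, parameter)
  roc_from_scores(cohort[[parameter]][cohort$label == "metastatic"],
                  cohort[[parameter]][cohort$label == "reactive"],
                  direction = direction, conf_level = conf_level,
                  parameter = parameter)
}

roc_from_scores <- function(cases, controls, direction = "larger",
                            conf_level = 0.95, parameter = "score") {
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  flipped <- FALSE
  dc <- delong_components(cases, controls)
  if (direction == "auto" && dc$auc < 0.5) {
    flipped <- TRUE
    cases <- -cases; controls <- -controls
    dc <- delong_components(cases, controls)
  }
  m <- length(cases); n <- length(controls)
  degenerate <- length(unique(c(cases, controls))) < 2
  if (degenerate) {
    warning("constant scores: AUC 0.5 with degenerate CI", call. = FALSE)
    se <- 0
  } else {
    se <- sqrt(var(dc$v10) / m + var(dc$v01) / n)
  }
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- clamp(dc$auc + c(-1, 1) * z * se, 0, 1)
  # Youden point over all candidate thresholds (predict positive if
  # score >= threshold)
  thr <- sort(unique(c(cases, controls)))
  thr <- c(thr, Inf)
  sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(controls < t), numeric(1))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[which.max(spec[best])]
  structure(list(auc = dc$auc, auc_se = se, ci95 = ci,
                 youden_threshold = if (flipped) -thr[best] else thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 direction = if (flipped) "inverse" else "larger",
                 parameter = parameter, n_cases = m, n_controls = n,
                 v10 = dc$v10, v01 = dc$v01),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s%s): AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.4g -> sens %.3f / spec %.3f\n",
              x$parameter, if (x$direction == "inverse") ", inverted" else "",
              x$auc, x$ci95[1], x$ci95[2], x$youden_threshold,
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Paired DeLong test for two AUCs
#'
#' Two-sided test that two markers measured on the same nodes have equal
#' AUCs, using the covariance of the DeLong structural components.
#'
#' @param cohort Cohort `data.frame`.
#' @param parameter_a,parameter_b Column names of the two markers.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' delong_test(co, "VD", "FD")$p_value
delong_test <- function(cohort, parameter_a, parameter_b) {
  check_cohort(cohort, c(parameter_a, parameter_b))
  cases_a <- cohort[[parameter_a]][cohort$label == "metastatic"]
  ctrls_a <- cohort[[parameter_a]][cohort$label == "reactive"]
  cases_b <- cohort[[parameter_b]][cohort$label == "metastatic"]
  ctrls_b <- cohort[[parameter_b]][cohort$label == "reactive"]
  a <- delong_components(cases_a, ctrls_a)
  b <- delong_components(cases_b, ctrls_b)
  m <- length(cases_a); n <- length(ctrls_a)
  s10 <- cov(cbind(a$v10, b$v10))
  s01 <- cov(cbind(a$v01, b$v01))
  v <- s10[1, 1] / m + s01[1, 1] / n + s10[2, 2] / m + s01[2, 2] / n -
    2 * (s10[1, 2] / m + s01[1, 2] / n)
  if (v <= .Machine$double.eps) {
    return(list(auc_a = a$auc, auc_b = b$auc, z = 0, p_value = 1))
  }
  z <- (a$auc - b$auc) / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, z = z, p_value = 2 * pnorm(-abs(z)))
}
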