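# Preprocessing and forward-conditional stepwise logistic modelling.

#' Table-style preprocessing of cohort parameters
#'
#' Applies the published preprocessing before logistic modelling: vascular
#' density is analyzed as a percentage (x 100); FD, Vel Entropy, Dir
#' Entropy, Dir Var and FWVD are Z-standardized (cohort mean/SD stored so
#' new rows can be scored identically); the remaining parameters enter
#' untransformed.
#'
#' @param cohort Cohort `data.frame` with the 14 parameter columns.
#' @param spec Optional stored preprocessing spec from an earlier call, used
#'   to transform new data with the training means/SDs.
#' @return List with `design` (transformed `data.frame` of the 14
#'   parameters), `labels` (0/1, metastatic = 1, when a `label` column is
#'   present), and `spec` (transform type and stored constants per column).
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' pp <- preprocess_cohort(co)
#' round(mean(pp$design$FD), 10)  # 0 after standardization
preprocess_cohort <- function(cohort, spec = NULL) {
  params <- srus_parameters()
  miss <- setdiff(params, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  percent_cols <- "VD"
  z_cols <- c("FD", "VelEntropy", "DirEntropy", "DirVar", "FWVD")
  if (is.null(spec)) {
    spec <- list()
    for (p in params) {
      if (p %in% percent_cols) {
        spec[[p]] <- list(type = "percent")
      } else if (p %in% z_cols) {
        s <- sd(cohort[[p]])
        if (s == 0) {
          stop("cannot Z-standardize constant column `", p, "`",
               call. = FALSE)
        }
        spec[[p]] <- list(type = "zscore", mean = mean(cohort[[p]]), sd = s)
      } else {
        spec[[p]] <- list(type = "identity")
      }
    }
  }
  design <- cohort[params]
  for (p in params) {
    tr <- spec[[p]]
    design[[p]] <- switch(tr$type,
      percent = cohort[[p]] * 100,
      zscore = (cohort[[p]] - tr$mean) / tr$sd,
      identity = cohort[[p]],
      stop("unknown transform for `", p, "`", call. = FALSE))
  }
  labels <- NULL
  if ("label" %in% names(cohort)) {
    check_cohort(cohort)
    labels <- as.integer(cohort$label == "metastatic")
  }
  list(design = design, labels = labels, spec = spec)
}

#' Invert a preprocessing spec
#'
#' Maps a transformed design matrix back to the original parameter scale
#' (round-trip identity used in validation).
#'
#' @param design Transformed `data.frame` from [preprocess_cohort()].
#' @param spec Stored preprocessing spec.
#' @return `data.frame` on the original scale.
#' @export
unpreprocess <- function(design, spec) {
  out <- design
  for (p in names(spec)) {
    tr <- spec[[p]]
    out[[p]] <- switch(tr$type,
      percent = design[[p]] / 100,
      zscore = design[[p]] * tr$sd + tr$mean,
      identity = design[[p]])
  }
  out
}

#' Stepwise configuration
#'
#' @param entry_alpha Likelihood-ratio p-value required to enter (default
#'   0.05).
#' @param removal_alpha Removal threshold; an included variable whose
#'   removal p exceeds it is dropped (default 0.10).
#' @param max_steps Safety cap on selection iterations.
#' @return Object of class `stepwise_config`.
#' @export
stepwise_config <- function(entry_alpha = 0.05, removal_alpha = 0.10,
                            max_steps = 50L) {
  if (entry_alpha >= removal_alpha) {
    stop("entry_alpha must be < removal_alpha", call. = FALSE)
  }
  structure(list(entry_alpha = entry_alpha, removal_alpha = removal_alpha,
                 max_steps = as.integer(max_steps)),
            class = "stepwise_config")
}

fit_logistic <- function(design, labels, vars) {
  dat <- cbind(data.frame(.y = labels), design[vars])
  f <- if (length(vars) == 0) .y ~ 1 else
    stats::reformulate(sprintf("`%s`", vars), response = ".y")
  fit <- suppressWarnings(glm(f, data = dat, family = binomial()))
  if (length(vars) > 0 && fit$deviance < 1e-6) {
    co <- coef(fit)[-1]
    worst <- gsub("`", "", names(which.max(abs(co))))
    stop("perfect separation detected; offending variable: ", worst,
         call. = FALSE)
  }
  fit
}

lr_pvalue <- function(fit_small, fit_big) {
  stat <- as.numeric(2 * (logLik(fit_big) - logLik(fit_small)))
  df <- attr(logLik(fit_big), "df") - attr(logLik(fit_small), "df")
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Forward-conditional stepwise logistic regression
#'
#' Iterative forward selection with backward pruning: at each step the
#' candidate with the smallest likelihood-ratio entry p-value joins the
#' model if `p < entry_alpha` (ties broken by lexicographic name); after
#' every addition, included variables whose likelihood-ratio removal
#' p-value exceeds `removal_alpha` are dropped (largest first). Iteration
#' stops when no addition or removal changes the model. The final model is
#' refit by maximum likelihood with Wald confidence intervals for the odds
#' ratios.
#'
#' @param design `data.frame` of candidate predictors (already
#'   preprocessed).
#' @param labels 0/1 outcome (1 = metastatic).
#' @param config A [stepwise_config()].
#' @param candidates Columns eligible for selection (default all).
#' @return Object of class `logistic_model`: `predictors`, `coefficients`
#'   table (beta, se, Wald p, `OR = exp(beta)`, OR 95% CI), `intercept`,
#'   `trace` (selection history), `fit` (the glm), and `spec` slot to attach
#'   preprocessing for scoring.
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' pp <- preprocess_cohort(co)
#' m <- stepwise_logistic(pp$design, pp$labels)
#' m$predictors
stepwise_logistic <- function(design, labels, config = stepwise_config(),
                              candidates = names(design)) {
  if (length(candidates) < 2) {
    stop("need at least 2 candidate predictors", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  included <- character(0)
  trace <- list()
  current <- fit_logistic(design, labels, included)
  for (step in seq_len(config$max_steps)) {
    changed <- FALSE
    pool <- setdiff(candidates, included)
    if (length(pool) > 0) {
      entry_p <- vapply(sort(pool), function(v) {
        lr_pvalue(current, fit_logistic(design, labels, c(included, v)))
      }, numeric(1))
      best <- names(entry_p)[which.min(entry_p)]  # sorted names break ties
      if (entry_p[best] < config$entry_alpha) {
        included <- c(included, best)
        current <- fit_logistic(design, labels, included)
        trace[[length(trace) + 1]] <- list(step = step, action = "enter",
                                           variable = best,
                                           p = unname(entry_p[best]))
        changed <- TRUE
      }
    }
    repeat {
      if (length(included) == 0) break
      removal_p <- vapply(sort(included), function(v) {
        lr_pvalue(fit_logistic(design, labels, setdiff(included, v)), current)
      }, numeric(1))
      worst <- names(removal_p)[which.max(removal_p)]
      if (removal_p[worst] > config$removal_alpha) {
        included <- setdiff(included, worst)
        current <- fit_logistic(design, labels, included)
        trace[[length(trace) + 1]] <- list(step = step, action = "remove",
                                           variable = worst,
                                           p = unname(removal_p[worst]))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  logistic_model(design, labels, included, trace = trace)
}

#' Fit a logistic model with a fixed predictor set
#'
#' Maximum-likelihood fit with Wald CIs for the odds ratios; used both for
#' the stepwise final refit and to fit a pre-specified predictor panel.
#'
#' @inheritParams stepwise_logistic
#' @param predictors Character vector of predictor columns.
#' @param trace Optional selection trace to store.
#' @param spec Optional preprocessing spec to store for scoring.
#' @return Object of class `logistic_model`.
#' @export
logistic_model <- function(design, labels, predictors, trace = list(),
                           spec = NULL) {
  fit <- fit_logistic(design, labels, predictors)
  co <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- co / se
  p <- 2 * pnorm(-abs(z))
  idx <- setdiff(names(co), "(Intercept)")
  coefs <- data.frame(
    term = gsub("`", "", idx),
    beta = unname(co[idx]), se = unname(se[idx]),
    p_value = unname(p[idx]),
    OR = exp(unname(co[idx])),
    OR_low = exp(unname(co[idx] - 1.96 * se[idx])),
    OR_high = exp(unname(co[idx] + 1.96 * se[idx])))
  rownames(coefs) <- NULL
  structure(list(predictors = predictors, coefficients = coefs,
                 intercept = unname(co["(Intercept)"]), trace = trace,
                 fit = fit, spec = spec),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("logistic_model:",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ") else
        "(intercept only)", "\n")
  if (nrow(x$coefficients)) {
    print(format(x$coefficients, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' Score a model and evaluate its ROC
#'
#' Computes the linear-predictor score of every node (applying the model's
#' stored preprocessing spec when present) and returns the empirical ROC of
#' the scores with DeLong CI and the Youden operating point.
#'
#' @param model A `logistic_model`.
#' @param cohort Cohort `data.frame` containing the model predictors (raw
#'   scale if the model carries a preprocessing spec, otherwise already
#'   transformed).
#' @return An `roc_result` for the model scores.
#' @export
#' @examples
#' co <- generate_cohort(cohort_calibration(), seed = 1)
#' pp <- preprocess_cohort(co)
#' m <- logistic_model(pp$design, pp$labels,
#'                     c("VD", "Vmin", "VelVar", "VelEntropy", "PI"),
#'                     spec = pp$spec)
#' evaluate_model(m, co)
evaluate_model <- function(model, cohort) {
  stopifnot(inherits(model, "logistic_model"))
  miss <- setdiff(model$predictors, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing predictor columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  design <- if (!is.null(model$spec)) {
    preprocess_cohort(cohort, spec = model$spec)$design
  } else {
    cohort
  }
  beta <- model$coefficients$beta[match(model$predictors,
                                        model$coefficients$term)]
  scores <- model$intercept +
    if (length(model$predictors) > 0) {
      as.matrix(design[model$predictors]) %*% beta
    } else rep(0, nrow(cohort))
  scores <- as.numeric(scores)
  check_cohort(cohort, character(0))
  roc_from_scores(scores[cohort$label == "metastatic"],
                  scores[cohort$label == "reactive"],
                  parameter = "model score")
}
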