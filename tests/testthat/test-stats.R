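test_that("group comparison reproduces the closed-form Welch t-test", {
  # {1..5} vs {2..6}: t = -1, df = 8 (textbook formula oracle)
  co <- make_cohort(1:5, 2:6)
  res <- compare_groups(co, parameters = "VD")
  se <- sqrt(2.5 / 5 + 2.5 / 5)
  t_expected <- (3 - 4) / se
  p_expected <- 2 * pt(-abs(t_expected), df = 8)
  expect_equal(res$test, "t")
  expect_equal(res$statistic, t_expected, tolerance = 1e-12)
  expect_equal(res$p_value, p_expected, tolerance = 1e-12)
})

test_that("identical groups give a null comparison", {
  co <- make_cohort(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  res <- compare_groups(co, parameters = "VD")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the comparison detects the published VD difference with high power", {
  cal <- cohort_calibration()
  hits <- vapply(1:300, function(s) {
    co <- generate_cohort(cal, seed = 2000 + s)
    compare_groups(co, parameters = "VD")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.90)
})

test_that("empirical AUC equals exhaustive pair counting", {
  co <- make_cohort(c(3, 5, 7), c(1, 2, 4))
  r <- univariate_roc(co, "VD")
  expect_equal(r$auc, 8 / 9)
  # perfectly separated groups
  co2 <- make_cohort(c(10, 11, 12), c(1, 2, 3))
  r2 <- univariate_roc(co2, "VD")
  expect_equal(r2$auc, 1)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)
})

test_that("AUC agrees with trapezoidal area under the empirical ROC", {
  # exhaustive check on small random datasets, including ties
  set.seed(42)
  for (rep in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    cases <- sample(1:5, m, replace = TRUE)
    ctrls <- sample(1:5, n, replace = TRUE)
    co <- make_cohort(cases, ctrls)
    auc <- univariate_roc(co, "VD")$auc
    thr <- c(Inf, sort(unique(c(cases, ctrls)), decreasing = TRUE), -Inf)
    sens <- vapply(thr, function(t) mean(cases >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(ctrls >= t), numeric(1))
    trap <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
    expect_equal(auc, trap, tolerance = 1e-12)
  }
})

test_that("AUC and DeLong variance agree with an independent implementation", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_calibration(), seed = 3)
  for (p in c("VD", "Vmin", "DirEntropy")) {
    r <- univariate_roc(co, p)
    pr <- pROC::roc(co$label, co[[p]], levels = c("reactive", "metastatic"),
                    direction = "<", quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(r$auc_se^2, pROC::var(pr), tolerance = 1e-12)
  }
  dt <- delong_test(co, "VD", "FD")
  rt <- pROC::roc.test(
    pROC::roc(co$label, co$VD, levels = c("reactive", "metastatic"),
              direction = "<", quiet = TRUE),
    pROC::roc(co$label, co$FD, levels = c("reactive", "metastatic"),
              direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(dt$p_value, rt$p.value, tolerance = 1e-12)
})

test_that("permuted labels give a null AUC and self-comparison p = 1", {
  set.seed(9)
  co <- generate_cohort(cohort_calibration(n_metastatic = 400L,
                                           n_reactive = 400L), seed = 4)
  co$VD <- sample(co$VD)  # break the association
  r <- univariate_roc(co, "VD")
  expect_lt(abs(r$auc - 0.5), 3 * r$auc_se)
  expect_equal(delong_test(co, "VD", "VD")$p_value, 1)
})

test_that("constant markers yield a degenerate AUC of one half", {
  co <- generate_cohort(cohort_calibration(), seed = 5)
  co$VD <- 0.5
  expect_warning(r <- univariate_roc(co, "VD"), "constant")
  expect_equal(r$auc, 0.5)
})

test_that("preprocessing applies the published transforms and round-trips", {
  co <- generate_cohort(cohort_calibration(), seed = 6)
  pp <- preprocess_cohort(co)
  expect_equal(pp$design$VD, co$VD * 100)
  for (p in c("FD", "VelEntropy", "DirEntropy", "DirVar", "FWVD")) {
    expect_equal(mean(pp$design[[p]]), 0, tolerance = 1e-12)
    expect_equal(sd(pp$design[[p]]), 1, tolerance = 1e-12)
  }
  expect_identical(pp$design$Vmean, co$Vmean)
  back <- unpreprocess(pp$design, pp$spec)
  for (p in srus_parameters()) {
    expect_equal(back[[p]], co[[p]], tolerance = 1e-12, label = p)
  }
  co$FD <- 1.5
  expect_error(preprocess_cohort(co), "constant")
})

test_that("stepwise selection recovers a single informative predictor", {
  # one informative + four pure-noise candidates; the informative variable
  # also has the best single-variable likelihood by exhaustive search
  set.seed(11)
  n <- 166
  included <- 0; exact <- 0; reps <- 100
  for (r in seq_len(reps)) {
    y <- rep(c(1, 0), c(77, 89))
    design <- data.frame(signal = y * 1.2 + rnorm(n),
                         n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n),
                         n4 = rnorm(n))
    m <- stepwise_logistic(design, y)
    included <- included + ("signal" %in% m$predictors)
    exact <- exact + identical(m$predictors, "signal")
    if (r <= 10) {
      ll <- vapply(names(design), function(v) {
        as.numeric(logLik(glm(y ~ design[[v]], family = binomial())))
      }, numeric(1))
      expect_equal(names(which.max(ll)), "signal")
    }
  }
  expect_gte(included / reps, 0.95)
  # with entry alpha 0.05 and 4 noise candidates, about 1 - 0.95^4 of
  # replicates legitimately admit one spurious entry; exact recovery is
  # bounded below accordingly
  expect_gte(exact / reps, 0.70)
})

test_that("pure-noise candidates rarely enter and never flood the model", {
  set.seed(12)
  n <- 150; k <- 5
  n_selected <- vapply(1:60, function(r) {
    y <- rbinom(n, 1, 0.5)
    design <- as.data.frame(matrix(rnorm(n * k), n,
                                   dimnames = list(NULL, paste0("x", 1:k))))
    length(stepwise_logistic(design, y)$predictors)
  }, numeric(1))
  expect_gte(mean(n_selected == 0), 0.6)
  expect_true(all(n_selected <= k))
})

test_that("selection is invariant to candidate column order", {
  set.seed(13)
  y <- rep(c(1, 0), c(77, 89))
  design <- data.frame(a = y + rnorm(166), b = rnorm(166),
                       c = 0.8 * y + rnorm(166), d = rnorm(166))
  m1 <- stepwise_logistic(design, y)
  m2 <- stepwise_logistic(design[, c("d", "c", "b", "a")], y)
  expect_setequal(m1$predictors, m2$predictors)
})

test_that("the likelihood-ratio entry test holds its nominal size", {
  set.seed(14)
  n <- 100
  rejections <- vapply(1:2000, function(r) {
    y <- rbinom(n, 1, 0.5)
    x <- rnorm(n)
    null <- glm(y ~ 1, family = binomial())
    full <- glm(y ~ x, family = binomial())
    stat <- 2 * as.numeric(logLik(full) - logLik(null))
    pchisq(stat, 1, lower.tail = FALSE) < 0.05
  }, logical(1))
  rate <- mean(rejections)
  band <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(rate - 0.05), band + 0.005)
})

test_that("odds ratios are exactly exp(coefficients) with bracketing CIs", {
  co <- generate_cohort(cohort_calibration(), seed = 7)
  pp <- preprocess_cohort(co)
  m <- logistic_model(pp$design, pp$labels,
                      c("VD", "Vmin", "VelVar", "VelEntropy", "PI"))
  expect_equal(m$coefficients$OR, exp(m$coefficients$beta), tolerance = 1e-15)
  expect_true(all(m$coefficients$OR_low <= m$coefficients$OR))
  expect_true(all(m$coefficients$OR >= m$coefficients$OR_low &
                  m$coefficients$OR <= m$coefficients$OR_high))
})

test_that("perfect separation is flagged with the offending variable", {
  y <- rep(c(0, 1), each = 20)
  design <- data.frame(sep = y * 10 - 5 + 0.01 * seq_len(40), ok = rnorm(40))
  expect_error(logistic_model(design, y, c("sep", "ok")), "sep")
})

test_that("model scoring reproduces trivial ROC anchors", {
  co <- generate_cohort(cohort_calibration(), seed = 8)
  pp <- preprocess_cohort(co)
  # intercept-only model scores every node identically: AUC one half
  m0 <- logistic_model(pp$design, pp$labels, character(0), spec = pp$spec)
  expect_warning(r0 <- evaluate_model(m0, co), "constant")
  expect_equal(r0$auc, 0.5)
  # a model scored on perfectly separated data: AUC 1
  co2 <- co
  co2$VD <- ifelse(co2$label == "metastatic", 0.9, 0.1)
  r2 <- evaluate_model(
    structure(list(predictors = "VD",
                   coefficients = data.frame(term = "VD", beta = 1),
                   intercept = 0, spec = NULL), class = "logistic_model"),
    co2)
  expect_equal(r2$auc, 1)
  # a missing predictor column is reported by name
  m_bad <- structure(list(predictors = "NotAColumn",
                          coefficients = data.frame(term = "NotAColumn",
                                                    beta = 1),
                          intercept = 0, spec = NULL),
                     class = "logistic_model")
  expect_error(evaluate_model(m_bad, co), "NotAColumn")
})
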