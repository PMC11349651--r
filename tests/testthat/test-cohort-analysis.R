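test_that("confusion metrics reproduce the development-cohort values", {
  m <- confusion_metrics(confusion_table(tp = 25, fp = 4, tn = 16, fn = 3))
  expect_equal(m$sensitivity, 25 / 28)
  expect_equal(round(100 * m$specificity, 1), 80.0)
  expect_equal(round(100 * m$ppv, 1), 86.2)
  expect_equal(round(100 * m$npv, 1), 84.2)
  expect_equal(m$lr_positive, m$sensitivity / (1 - m$specificity))
  expect_equal(m$lr_negative, (1 - m$sensitivity) / m$specificity)
})

test_that("perfect classifiers and zero denominators are handled", {
  perfect <- confusion_metrics(confusion_table(tp = 10, fn = 0, tn = 10, fp = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  no_neg <- confusion_metrics(confusion_table(tp = 5, fn = 1, tn = 0, fp = 0))
  expect_true(is.na(no_neg$specificity))  # undefined, not zero
  expect_true(is.na(no_neg$lr_positive))
})

test_that("swapping class labels swaps sensitivity/specificity and PPV/NPV", {
  tab <- confusion_table(tp = 25, fp = 4, tn = 16, fn = 3)
  swapped <- confusion_table(tp = tab$tn, fp = tab$fn, tn = tab$tp, fn = tab$fp)
  m <- confusion_metrics(tab)
  ms <- confusion_metrics(swapped)
  expect_equal(ms$sensitivity, m$specificity)
  expect_equal(ms$specificity, m$sensitivity)
  expect_equal(ms$ppv, m$npv)
  expect_equal(ms$npv, m$ppv)
})

test_that("PPV rises and NPV falls with prevalence", {
  prev <- seq(0.05, 0.95, by = 0.05)
  pv <- predictive_values(25 / 28, 16 / 20, prev)
  expect_true(all(diff(pv$ppv) > 0))
  expect_true(all(diff(pv$npv) < 0))
})

test_that("ROC handles separation, ties and label swaps", {
  perfect <- roc_analysis(c(0, 1, 2, 3), c("negative", "negative", "positive", "positive"))
  expect_equal(perfect$auc, 1.0)
  expect_equal(perfect$tpr[1], 0)
  expect_equal(perfect$fpr[1], 0)
  expect_equal(perfect$tpr[length(perfect$tpr)], 1)
  expect_equal(perfect$fpr[length(perfect$fpr)], 1)

  ties <- roc_analysis(rep(2, 10), rep(c("positive", "negative"), 5))
  expect_equal(ties$auc, 0.5)

  set.seed(11)
  sc <- sample(0:5, 30, replace = TRUE)
  lab <- sample(c(0, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
  a <- roc_analysis(sc, lab)$auc
  a_swapped <- roc_analysis(sc, 1 - lab)$auc
  expect_equal(a_swapped, 1 - a)

  expect_error(roc_analysis(1:5, rep(1, 5)), "both classes")
})

test_that("AUC equals the pairwise Mann-Whitney statistic and the curve area", {
  set.seed(202)
  for (i in 1:40) {
    n1 <- sample(2:20, 1)
    n0 <- sample(2:20, 1)
    sc <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 2 == 0) sc <- round(sc)  # force ties half the time
    y <- rep(c(1, 0), c(n1, n0))
    r <- roc_analysis(sc, y)
    expect_equal(r$auc, auc_pairwise_oracle(sc, y), tolerance = 1e-12)
    trapezoid <- sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
    expect_equal(r$auc, trapezoid, tolerance = 1e-12)
    expect_true(r$auc_ci_95[1] <= r$auc && r$auc <= r$auc_ci_95[2])
  }
})

test_that("both CI methods bracket the point estimate", {
  set.seed(3)
  sc <- c(rnorm(15, 1.2), rnorm(12))
  y <- rep(c("positive", "negative"), c(15, 12))
  d <- roc_analysis(sc, y, ci_method = "delong")
  h <- roc_analysis(sc, y, ci_method = "hanley_mcneil")
  expect_equal(d$auc, h$auc)
  for (r in list(d, h)) {
    expect_true(r$auc_ci_95[1] <= r$auc && r$auc <= r$auc_ci_95[2])
    expect_true(all(r$auc_ci_95 >= 0 & r$auc_ci_95 <= 1))
  }
})

test_that("group comparison gates on normality and supports categoricals", {
  set.seed(9)
  df <- data.frame(group = rep(c("a", "b"), each = 40),
                   value = c(rnorm(40, 0, 1), rnorm(40, 1.5, 1)))
  cmp <- compare_groups(df, "value")
  expect_equal(cmp$test, "t")
  expect_lt(cmp$p_value, 0.01)

  skewed <- data.frame(group = rep(c("a", "b"), each = 60),
                       value = c(rexp(60), rexp(60)))
  expect_equal(compare_groups(skewed, "value")$test, "mann_whitney")

  cat_same <- data.frame(group = rep(c("a", "b"), each = 30),
                         value = rep(c("x", "y"), 30))
  expect_equal(compare_groups(cat_same, "value")$p_value, 1, tolerance = 0.05)

  const <- data.frame(group = rep(c("a", "b"), each = 10), value = rep(5, 20))
  expect_error(compare_groups(const, "value", type = "continuous"),
               class = "capscore_degenerate_variance")
})

test_that("MMSE-like group difference is detected in most draws", {
  # two-group draws shaped like the cohort's baseline MMSE comparison
  set.seed(401)
  hits <- 0L
  for (i in 1:20) {
    df <- data.frame(group = rep(c("pos", "neg"), c(30, 22)),
                     value = c(rnorm(30, 24.50, 2.52), rnorm(22, 26.85, 3.71)))
    if (compare_groups(df, "value")$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 12L)
})

test_that("logistic regression flags nulls, recovers the NPI-Q signal, detects separation", {
  set.seed(77)
  # null: outcome independent of the feature
  x <- matrix(rnorm(600), ncol = 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rbinom(300, 1, 0.5)
  f <- fit_logistic(x, y)
  expect_true(f$converged)
  expect_lt(abs(f$coefficients$estimate[f$coefficients$term == "f1"]), 0.35)

  # NPI-Q as the only true predictor, in a generated cohort
  params <- default_cohort_params()
  params$positive$n <- 150L
  params$negative$n <- 150L
  cohort <- generate_cohort(params, seed = 5)
  tab <- cohort_table(cohort)
  fit <- fit_logistic(tab[, c("npiq_total", "age", "hachinski")],
                      tab$amyloid_status_reference)
  p <- setNames(fit$coefficients$p_value, fit$coefficients$term)
  expect_lt(p[["npiq_total"]], 0.05)
  expect_gt(p[["age"]], 0.05)

  # perfect separation
  xs <- matrix(c(1:10), ncol = 1, dimnames = list(NULL, "x"))
  ys <- c(rep(0, 5), rep(1, 5))
  sep <- fit_logistic(xs, ys)
  expect_true(sep$separation_detected)
  expect_false(sep$converged)

  expect_error(fit_logistic(matrix(1, 10, 1), rbinom(10, 1, 0.5)), "constant")
})

test_that("IRLS log-likelihood beats a local coefficient grid", {
  set.seed(19)
  for (rep in 1:4) {
    X <- matrix(rnorm(100), ncol = 2, dimnames = list(NULL, c("a", "b")))
    y <- rbinom(50, 1, plogis(0.3 + 0.8 * X[, 1]))
    f <- fit_logistic(X, y)
    beta_hat <- f$coefficients$estimate
    offsets <- seq(-0.1, 0.1, by = 0.02)
    grid <- as.matrix(expand.grid(b0 = beta_hat[1] + offsets,
                                  b1 = beta_hat[2] + offsets,
                                  b2 = beta_hat[3] + offsets))
    ll <- apply(grid, 1, function(b) capscore:::logistic_loglik(b, X, y))
    expect_gte(f$log_likelihood, max(ll) - 1e-8)
  }
})

test_that("evaluate_score drops unscoreable subjects and counts cells correctly", {
  cohort <- c(fixture_cohort()[1:10], list(make_subject(
    id = "INC", npiq_total = 2, drop = 3, fazekas = 0, status = "positive")))
  cohort[[11]]$cognitive_scores <- cohort[[11]]$cognitive_scores[1L, ]
  expect_message(ev <- evaluate_score(cohort), "dropped 1")
  expect_equal(ev$n_scored, 10L)
  expect_equal(ev$n_dropped, 1L)
  with(ev$confusion, expect_equal(tp + fp + tn + fn, 10L))

  # conservation: tp + fn equals the number of reference positives
  full <- suppressMessages(evaluate_score(fixture_cohort()))
  n_pos <- sum(vapply(fixture_cohort(), function(s)
    s$amyloid_status_reference == "positive", logical(1)))
  expect_equal(full$confusion$tp + full$confusion$fn, n_pos)
})

test_that("single-class cohorts yield undefined specificity, not zero", {
  all_pos <- lapply(1:6, function(i) make_subject(
    id = paste0("P", i), npiq_total = 3, drop = 4, fazekas = 0,
    status = "positive"))
  ev <- evaluate_score(all_pos)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_true(is.na(ev$metrics$specificity))
  expect_null(ev$roc)
})
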