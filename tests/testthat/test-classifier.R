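# small protocol for fast unit tests; the full printed protocol is
# exercised in test-acceptance.R
small_protocol <- function(seed = 1)
  cv_protocol(outer_folds = 4, inner_folds = 2, estimators = c(10, 50),
              max_features = c(2, 4), seed = seed)

test_that("the printed hyperparameter grid enumerates 15 candidates in order", {
  p <- cv_protocol()
  expect_equal(nrow(p$grid), 15)
  expect_equal(unique(p$grid$estimators), c(10, 100, 500))
  expect_equal(p$grid$max_features[1:5], c(2, 4, 6, 10, 12))
  expect_equal(p$max_depth, 3)
  expect_error(cv_protocol(outer_folds = 1), "folds")
  expect_error(cv_protocol(estimators = numeric(0)), "nonempty")
})

test_that("nested CV is deterministic for a fixed seed", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 2)
  r1 <- nested_cv_train(co, small_protocol(7), "random_forest")
  r2 <- nested_cv_train(co, small_protocol(7), "random_forest")
  expect_identical(r1$report$folds, r2$report$folds)
  expect_identical(r1$model$params, r2$model$params)
  expect_identical(predict(r1$model, co), predict(r2$model, co))
})

test_that("stratified folds fail loudly when a class cannot be spread", {
  co <- make_cohort(class_counts = c(1, 20, 10, 10), seed = 3)
  expect_error(
    nested_cv_train(co, cv_protocol(outer_folds = 10, inner_folds = 3,
                                    seed = 1), "random_forest"),
    "protocol error|fold")
})

test_that("evaluation metrics follow their defining identities", {
  # one-vs-rest counts TP=9 FP=1 FN=1 TN=9 for class 0
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 9), 1, 0, rep(1, 9))
  rep_ <- evaluation_report(truth, pred, classes = 0:3)
  c0 <- rep_$per_class[rep_$per_class$class == 0, ]
  expect_equal(c(c0$tp, c0$fp, c0$fn, c0$tn), c(9, 1, 1, 9))
  expect_equal(c0$precision, 0.9)
  expect_equal(c0$recall, 0.9)
  expect_equal(c0$f1, 0.9)
  expect_equal(c0$ovr_accuracy, 0.9)

  # perfect prediction
  perf <- evaluation_report(0:3, 0:3)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$balanced_accuracy, 1)
  expect_true(all(diag(perf$confusion) == 1))

  # random labels against an independent tally
  set.seed(14)
  t2 <- sample(0:3, 200, replace = TRUE)
  p2 <- sample(0:3, 200, replace = TRUE)
  r2 <- evaluation_report(t2, p2)
  for (k in 0:3) {
    tp <- sum(t2 == k & p2 == k); fp <- sum(t2 != k & p2 == k)
    fn <- sum(t2 == k & p2 != k)
    row <- r2$per_class[r2$per_class$class == k, ]
    expect_equal(row$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(row$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
    expect_equal(row$f1, if (row$precision + row$recall > 0)
      2 * row$precision * row$recall / (row$precision + row$recall) else 0)
  }
  expect_equal(r2$accuracy, mean(t2 == p2))
  expect_equal(r2$accuracy,
               sum(diag(r2$confusion)) / sum(r2$confusion))
  # row sums are the per-class test counts
  expect_equal(unname(rowSums(r2$confusion)),
               as.integer(table(factor(t2, levels = 0:3))))
})

test_that("evaluate refuses train/test leakage and predicts held-out rows", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 4)
  test_idx <- seq(1, 48, by = 4)
  fit <- nested_cv_train(co[-test_idx, ], small_protocol(5),
                         "random_forest")
  ev <- evaluate(fit$model, co[test_idx, ])
  expect_s3_class(ev, "bindresp_eval")
  expect_equal(ev$n, length(test_idx))
  expect_error(evaluate(fit$model, co), "leakage")
})

test_that("stratified evaluation partitions the pooled confusion", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 6)
  test_idx <- seq(2, 48, by = 4)
  fit <- nested_cv_train(co[-test_idx, ], small_protocol(6),
                         "random_forest")
  test_rows <- co[test_idx, ]
  pooled <- evaluate(fit$model, test_rows)
  per <- stratified_evaluate(fit$model, test_rows, "sex_code")
  expect_equal(Reduce(`+`, lapply(per, function(e) e$confusion)),
               pooled$confusion)
  expect_equal(sum(vapply(per, function(e) e$n, numeric(1))), pooled$n)
  expect_error(stratified_evaluate(fit$model, test_rows, "nope"),
               "missing stratum")
  single <- stratified_evaluate(fit$model,
                                dplyr::mutate(test_rows, grp = 1), "grp")
  expect_length(single, 1)
  expect_equal(single[[1]]$confusion, pooled$confusion)
})

test_that("y-scrambling is reproducible and leaves training artifacts untouched", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 8)
  s1 <- y_scramble(co, small_protocol(9), "random_forest", iterations = 1)
  s2 <- y_scramble(co, small_protocol(9), "random_forest", iterations = 1)
  expect_identical(s1, s2)
  expect_error(y_scramble(co, small_protocol(9), iterations = 0),
               "iterations")
})

test_that("ablation reruns the protocol per feature-group union", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 10)
  ab <- ablation(co, small_protocol(11), "random_forest",
                 groups = list("geometric", "dci",
                               c("dci", "energy", "geometric")))
  expect_equal(nrow(ab), 3)
  expect_equal(ab$n_features, c(5, 3, 12))
  # labels ride on the geometric columns by construction
  expect_gte(ab$mean_accuracy[ab$groups == "geometric"],
             ab$mean_accuracy[ab$groups == "dci"])
  expect_error(ablation(co, small_protocol(1), groups = list("bogus")),
               "unknown feature group")
  expect_error(ablation(co, small_protocol(1),
                        groups = list(character(0))), "empty")
})

test_that("all model families train and predict under the protocol", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 12)
  for (fam in c("gradient_boosting", "random_forest", "knn", "svm",
                "neural_network")) {
    r <- nested_cv_train(co, small_protocol(13), fam)
    expect_true(is.finite(r$report$mean_accuracy), info = fam)
    expect_length(predict(r$model, co), nrow(co))
    expect_true(all(predict(r$model, co) %in% 0:3), info = fam)
  }
})

test_that("tidy and glance methods expose fold and summary tables", {
  co <- make_cohort(class_counts = c(8, 20, 10, 10), seed = 15)
  r <- nested_cv_train(co, small_protocol(16), "random_forest")
  td <- tidy(r$report)
  expect_equal(nrow(td), 4)
  expect_true(all(c("fold", "accuracy") %in% names(td)))
  gl <- glance(r$report)
  expect_equal(gl$mean_accuracy, mean(td$accuracy))
})
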