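#' Nested cross-validation protocol
#'
#' Captures the evaluation protocol: stratified outer folds for
#' generalization estimation, inner folds for grid-search hyperparameter
#' selection, and the hyperparameter grid for the tree-ensemble families
#' (number of estimators, maximum features, fixed maximum depth).  The
#' grid is enumerated estimators-major, max-features-minor; ties in inner
#' accuracy are broken by enumeration order, so runs are fully
#' deterministic for a fixed seed.
#'
#' @param outer_folds number of outer folds (default 10).
#' @param inner_folds number of inner folds (default 3).
#' @param estimators candidate ensemble sizes (default `c(10, 100, 500)`).
#' @param max_features candidate feature-subsampling sizes (default
#'   `c(2, 4, 6, 10, 12)`).
#' @param max_depth tree depth (default 3).
#' @param seed integer seed driving all randomness.
#' @param stratified stratify folds by class label (default TRUE).
#' @return object of class `bindresp_protocol`.
#' @export
cv_protocol <- function(outer_folds = 10, inner_folds = 3,
                        estimators = c(10, 100, 500),
                        max_features = c(2, 4, 6, 10, 12),
                        max_depth = 3, seed = 1, stratified = TRUE) {
  if (outer_folds < 2 || inner_folds < 2) abort("folds must be >= 2")
  if (length(estimators) == 0 || length(max_features) == 0)
    abort("grid must be nonempty")
  grid <- expand.grid(max_features = sort(max_features),
                      estimators = sort(estimators))[, c("estimators",
                                                         "max_features")]
  grid <- grid[order(grid$estimators, grid$max_features), ]
  rownames(grid) <- NULL
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 grid = as_tibble(grid), max_depth = as.integer(max_depth),
                 seed = as.integer(seed), stratified = stratified),
            class = "bindresp_protocol")
}

# stratified fold assignment; deterministic given seed
make_folds <- function(labels, k, seed, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  set.seed(seed)
  if (stratified) {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
  }
  tab <- table(factor(fold, levels = seq_len(k)), labels)
  if (any(rowSums(tab) == 0))
    abort(paste0("protocol error: a fold received no rows; ",
                 "use fewer folds"))
  fold
}

check_fold_classes <- function(labels, fold, k) {
  tab <- table(factor(fold, levels = seq_len(k)), labels)
  if (any(tab == 0)) {
    cls <- colnames(tab)[which(tab == 0, arr.ind = TRUE)[1, 2]]
    abort(paste0("protocol error: class ", cls, " is absent from some ",
                 "stratified fold; use fewer folds"))
  }
}

# one model fit; all families share this surface
fit_family <- function(family, X, y, params, max_depth, seed) {
  p <- ncol(X)
  if (family == "gradient_boosting") {
    d <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
    booster <- xgboost::xgb.train(
      params = list(objective = "multi:softmax", num_class = 4,
                    max_depth = max_depth,
                    colsample_bytree = min(1, params$max_features / p),
                    nthread = 1, seed = seed),
      data = d, nrounds = params$estimators, verbose = 0)
    list(kind = "xgb", booster = booster)
  } else if (family == "random_forest") {
    fit <- withCallingHandlers(
      ranger::ranger(
        x = as.data.frame(X), y = factor(y, levels = 0:3),
        num.trees = params$estimators, mtry = min(params$max_features, p),
        max.depth = max_depth, seed = seed, num.threads = 1),
      warning = function(w) {
        if (grepl("Dropped unused factor level", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    list(kind = "ranger", fit = fit)
  } else if (family == "knn") {
    list(kind = "knn", X = as.matrix(X), y = y, k = params$k)
  } else if (family == "neural_network") {
    set.seed(seed)
    fit <- nnet::nnet(x = as.matrix(X),
                      y = nnet::class.ind(factor(y, levels = 0:3)),
                      softmax = TRUE, size = params$size, decay = 1e-3,
                      maxit = 300, trace = FALSE, MaxNWts = 5000)
    list(kind = "nnet", fit = fit)
  } else if (family == "svm") {
    set.seed(seed)
    fit <- e1071::svm(x = as.matrix(X), y = factor(y, levels = 0:3),
                      cost = params$cost, kernel = "radial", scale = FALSE)
    list(kind = "svm", fit = fit)
  } else abort(paste0("unknown model family: ", family))
}

predict_family <- function(fit, X) {
  X <- as.matrix(X)
  if (fit$kind == "xgb") {
    as.integer(predict(fit$booster, xgboost::xgb.DMatrix(X)))
  } else if (fit$kind == "ranger") {
    set.seed(571)  # majority-vote ties consult the RNG
    as.integer(as.character(predict(fit$fit, data = as.data.frame(X),
                                    num.threads = 1)$predictions))
  } else if (fit$kind == "knn") {
    set.seed(571)  # neighbour-vote ties consult the RNG
    as.integer(as.character(class::knn(fit$X, X, factor(fit$y, levels = 0:3),
                                       k = fit$k)))
  } else if (fit$kind == "nnet") {
    p <- predict(fit$fit, X)
    as.integer(colnames(p)[max.col(p, ties.method = "first")])
  } else {
    as.integer(as.character(predict(fit$fit, X)))
  }
}

family_grid <- function(family, protocol) {
  if (family %in% c("gradient_boosting", "random_forest")) {
    protocol$grid
  } else if (family == "knn") {
    tibble(k = c(1, 3, 5, 7, 9))
  } else if (family == "neural_network") {
    tibble(size = c(4, 8, 16))
  } else {
    tibble(cost = c(0.1, 1, 10, 100))
  }
}

#' Train a four-class drug-response classifier under nested CV
#'
#' Outer folds (stratified by label) estimate generalization accuracy; in
#' each outer-training part an inner grid search selects hyperparameters
#' by mean inner-fold accuracy with deterministic enumeration-order
#' tie-breaking.  Features are z-scored with statistics fitted on the
#' training part of each split only.  The returned model is refit on all
#' rows with parameters chosen by a final inner-style grid search.
#'
#' @param table feature tibble with `patient_id`, `response_label` and the
#'   feature columns.
#' @param protocol a [cv_protocol()].
#' @param model_family one of `"gradient_boosting"`, `"random_forest"`,
#'   `"knn"`, `"svm"`, or `"neural_network"` (an optional single-hidden-
#'   layer softmax baseline).  The estimators/max-features grid applies to
#'   the tree ensembles; the other families use small conventional grids
#'   (neighbours, cost, hidden units).
#' @param feature_cols feature columns to use; default all raw
#'   feature-group columns present in `table`.
#' @param refit_final fit the final full-data model (default TRUE).
#' @return list with `model` (class `bindresp_model`) and `report` (class
#'   `bindresp_cv`: per-fold accuracies and chosen parameters, mean, sd).
#' @export
nested_cv_train <- function(table, protocol = cv_protocol(),
                            model_family = c("gradient_boosting",
                                             "random_forest", "knn", "svm",
                                             "neural_network"),
                            feature_cols = NULL, refit_final = TRUE) {
  model_family <- match.arg(model_family)
  stopifnot(inherits(protocol, "bindresp_protocol"))
  if (!"response_label" %in% names(table))
    abort("table must have a response_label column")
  if (is.null(feature_cols))
    feature_cols <- intersect(unlist(feature_groups()), names(table))
  if (length(feature_cols) == 0) abort("no feature columns found")
  y <- as.integer(table$response_label)
  if (length(unique(y)) < 2) abort("labels must cover at least 2 classes")
  if (nrow(table) < protocol$outer_folds)
    abort("fewer rows than outer folds")

  grid <- family_grid(model_family, protocol)
  fold <- make_folds(y, protocol$outer_folds, protocol$seed,
                     protocol$stratified)
  check_fold_classes(y, fold, protocol$outer_folds)

  fold_res <- purrr::map(seq_len(protocol$outer_folds), function(f) {
    tr <- which(fold != f); te <- which(fold == f)
    best <- grid_select(table[tr, ], y[tr], grid, protocol, model_family,
                        feature_cols, seed = protocol$seed + 1000L * f)
    nz <- fit_normalizer(table[tr, ], columns = feature_cols)
    Xtr <- apply_normalizer(nz, table[tr, feature_cols])
    Xte <- apply_normalizer(nz, table[te, feature_cols])
    fit <- fit_family(model_family, Xtr, y[tr], best,
                      protocol$max_depth, protocol$seed + 1000L * f)
    pred <- predict_family(fit, Xte)
    tibble(fold = f, n_test = length(te),
           accuracy = mean(pred == y[te])) %>%
      bind_cols(as_tibble(best))
  }) %>% bind_rows()

  report <- structure(
    list(folds = fold_res, mean_accuracy = mean(fold_res$accuracy),
         sd_accuracy = sd(fold_res$accuracy), grid = grid,
         model_family = model_family, protocol = protocol,
         feature_cols = feature_cols),
    class = "bindresp_cv")

  model <- NULL
  if (refit_final) {
    best <- grid_select(table, y, grid, protocol, model_family,
                        feature_cols, seed = protocol$seed + 999983L)
    nz <- fit_normalizer(table, columns = feature_cols)
    X <- apply_normalizer(nz, table[, feature_cols])
    fit <- fit_family(model_family, X, y, best, protocol$max_depth,
                      protocol$seed)
    model <- structure(
      list(family = model_family, params = best, fit = fit,
           feature_cols = feature_cols, normalizer = nz,
           train_ids = as.character(table$patient_id),
           max_depth = protocol$max_depth, seed = protocol$seed),
      class = "bindresp_model")
  }
  list(model = model, report = report)
}

# inner grid search: mean inner-fold accuracy, enumeration-order tie-break
grid_select <- function(table, y, grid, protocol, family, feature_cols,
                        seed) {
  fold <- make_folds(y, protocol$inner_folds, seed, protocol$stratified)
  scores <- vapply(seq_len(nrow(grid)), function(g) {
    params <- as.list(grid[g, ])
    accs <- vapply(seq_len(protocol$inner_folds), function(f) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(te) == 0 || length(unique(y[tr])) < 2) return(NA_real_)
      nz <- fit_normalizer(table[tr, ], columns = feature_cols)
      Xtr <- apply_normalizer(nz, table[tr, feature_cols])
      Xte <- apply_normalizer(nz, table[te, feature_cols])
      fit <- fit_family(family, Xtr, y[tr], params, protocol$max_depth,
                        seed + f)
      mean(predict_family(fit, Xte) == y[te])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  as.list(grid[which.max(scores), ])  # which.max takes the first maximum
}

#' Predict response labels
#'
#' @param object a `bindresp_model`.
#' @param newdata feature tibble.
#' @param ... unused.
#' @return integer labels in `0:3`.
#' @export
predict.bindresp_model <- function(object, newdata, ...) {
  X <- apply_normalizer(object$normalizer, newdata[, object$feature_cols])
  predict_family(object$fit, X)
}

#' Evaluate a classifier on held-out rows
#'
#' Builds the 4x4 confusion matrix (rows = true label) and the per-class
#' one-vs-rest precision, recall and F1, plus pooled accuracy
#' (trace/total) and balanced accuracy (macro recall).  Train/test overlap
#' on `patient_id` is refused.  Zero-denominator metrics are reported as 0
#' and flagged.
#'
#' @param model a `bindresp_model`.
#' @param test_rows feature tibble disjoint from the training rows.
#' @return object of class `bindresp_eval`.
#' @export
evaluate <- function(model, test_rows) {
  stopifnot(inherits(model, "bindresp_model"))
  if ("patient_id" %in% names(test_rows)) {
    overlap <- intersect(as.character(test_rows$patient_id),
                         model$train_ids)
    if (length(overlap) > 0)
      abort(paste0("leakage error: test rows share patient_id with ",
                   "training rows (e.g. ", overlap[1], ")"))
  }
  truth <- as.integer(test_rows$response_label)
  pred <- predict(model, test_rows)
  evaluation_report(truth, pred)
}

#' Build an evaluation report from true and predicted labels
#'
#' @param truth,pred integer labels in `0:3`.
#' @param classes label set (default `0:3`).
#' @return object of class `bindresp_eval`: `confusion` (rows = truth),
#'   `per_class` tibble (one-vs-rest TP/FP/FN/TN, precision, recall, f1,
#'   `zero_denominator` flag), `accuracy`, `balanced_accuracy`, macro
#'   averages.
#' @export
evaluation_report <- function(truth, pred, classes = 0:3) {
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  confusion <- matrix(as.integer(confusion), nrow = length(classes),
                      dimnames = list(truth = classes, pred = classes))
  per_class <- purrr::map(seq_along(classes), function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    tn <- sum(confusion[-i, -i])
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    tibble(class = classes[i], tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall, f1 = f1,
           ovr_accuracy = (tp + tn) / (tp + tn + fp + fn),
           zero_denominator = (tp + fp == 0) || (tp + fn == 0) ||
             (precision + recall == 0))
  }) %>% bind_rows()
  structure(list(
    confusion = confusion, per_class = per_class,
    accuracy = sum(diag(confusion)) / sum(confusion),
    balanced_accuracy = mean(per_class$recall),
    macro_precision = mean(per_class$precision),
    macro_recall = mean(per_class$recall),
    macro_f1 = mean(per_class$f1),
    n = sum(confusion)), class = "bindresp_eval")
}

#' y-scrambling (label permutation) control
#'
#' Reruns the full nested-CV protocol with labels randomly permuted, once
#' per iteration with iteration-indexed seeds, and reports the mean outer
#' accuracy across iterations.  On informative data this collapses to the
#' majority-class baseline, confirming that unscrambled performance is not
#' chance.
#'
#' @param table feature tibble.
#' @param protocol a [cv_protocol()].
#' @param model_family model family as in [nested_cv_train()].
#' @param iterations number of scrambles (default 50).
#' @param feature_cols feature columns (default as in [nested_cv_train()]).
#' @return list with `mean_accuracy` and `accuracies` (tibble iteration,
#'   accuracy).
#' @export
y_scramble <- function(table, protocol = cv_protocol(),
                       model_family = "gradient_boosting", iterations = 50,
                       feature_cols = NULL) {
  if (iterations < 1) abort("iterations must be >= 1")
  accs <- vapply(seq_len(iterations), function(it) {
    scram <- table
    set.seed(protocol$seed + 7919L * it)
    scram$response_label <- sample(scram$response_label)
    p <- protocol
    p$seed <- protocol$seed + it
    res <- nested_cv_train(scram, p, model_family,
                           feature_cols = feature_cols, refit_final = FALSE)
    res$report$mean_accuracy
  }, numeric(1))
  list(mean_accuracy = mean(accs),
       accuracies = tibble(iteration = seq_len(iterations), accuracy = accs))
}

#' Feature-group ablation
#'
#' Reruns nested CV restricted to each requested union of feature groups
#' and tabulates mean outer accuracy with its standard deviation.
#'
#' @param table feature tibble.
#' @param protocol a [cv_protocol()].
#' @param model_family model family.
#' @param groups list of character vectors naming feature groups from
#'   [feature_groups()] (`"dci"`, `"energy"`, `"geometric"`); default all
#'   singletons plus the full set.
#' @return tibble with `groups`, `n_features`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
ablation <- function(table, protocol = cv_protocol(),
                     model_family = "gradient_boosting",
                     groups = list("dci", "energy", "geometric",
                                   c("dci", "energy", "geometric"))) {
  gg <- feature_groups()
  purrr::map(groups, function(gr) {
    if (length(gr) == 0) abort("parameter error: empty feature-group set")
    unknown <- setdiff(gr, names(gg))
    if (length(unknown) > 0)
      abort(paste0("unknown feature group: ", unknown[1]))
    cols <- intersect(unlist(gg[gr]), names(table))
    res <- nested_cv_train(table, protocol, model_family,
                           feature_cols = cols, refit_final = FALSE)
    tibble(groups = paste(gr, collapse = "+"), n_features = length(cols),
           mean_accuracy = res$report$mean_accuracy,
           sd_accuracy = res$report$sd_accuracy)
  }) %>% bind_rows()
}

#' Stratified evaluation
#'
#' Evaluates the model separately within each level of a stratum column
#' (for example `sex_code`), returning one evaluation report per stratum.
#' Per-stratum confusion matrices sum elementwise to the pooled one.
#'
#' @param model a `bindresp_model`.
#' @param test_rows feature tibble.
#' @param stratum_column column name to stratify on.
#' @return named list of `bindresp_eval`, one per stratum level present.
#' @export
stratified_evaluate <- function(model, test_rows, stratum_column) {
  if (!stratum_column %in% names(test_rows))
    abort(paste0("missing stratum column: ", stratum_column))
  lv <- sort(unique(test_rows[[stratum_column]]))
  out <- lapply(lv, function(v)
    evaluate(model, test_rows[test_rows[[stratum_column]] == v, ]))
  names(out) <- as.character(lv)
  out
}

#' @export
tidy.bindresp_cv <- function(x, ...) x$folds

#' @export
glance.bindresp_cv <- function(x, ...) {
  tibble(model_family = x$model_family,
         outer_folds = x$protocol$outer_folds,
         inner_folds = x$protocol$inner_folds,
         mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy)
}

#' @export
tidy.bindresp_eval <- function(x, ...) x$per_class

#' @export
glance.bindresp_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, balanced_accuracy = x$balanced_accuracy,
         macro_precision = x$macro_precision, macro_recall = x$macro_recall,
         macro_f1 = x$macro_f1, n = x$n)
}

#' @export
print.bindresp_eval <- function(x, ...) {
  cat("4-class evaluation on", x$n, "rows\n")
  cat("accuracy:", round(x$accuracy, 4),
      " balanced accuracy (macro recall):", round(x$balanced_accuracy, 4),
      "\n")
  cat("macro precision/recall/F1:", round(x$macro_precision, 4),
      round(x$macro_recall, 4), round(x$macro_f1, 4), "\n")
  print(x$confusion)
  invisible(x)
}

#' @export
print.bindresp_cv <- function(x, ...) {
  cat("nested CV (", x$protocol$outer_folds, "outer /",
      x$protocol$inner_folds, "inner ),", x$model_family, "\n")
  cat("mean accuracy:", round(x$mean_accuracy, 4), "sd:",
      round(x$sd_accuracy, 4), "\n")
  invisible(x)
}
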