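classifier_families <- c("margin_kernel", "boosted_trees_hist",
                         "boosted_trees_exact", "logistic", "knn")

default_hyperparameters <- list(
  margin_kernel = list(cost = 1, gamma = NULL), # gamma NULL -> 1/(d * var)
  boosted_trees_hist = list(nrounds = 100, max_depth = 6, eta = 0.1),
  boosted_trees_exact = list(nrounds = 100, max_depth = 6, eta = 0.1),
  logistic = list(penalty = 1), # ridge; lambda = 1 / (n * penalty)
  knn = list(k = 5)
)

#' Specify a classifier
#'
#' The five families mirror the algorithms commonly benchmarked on
#' embedding features for enhancer identification: an RBF-kernel support
#' vector machine (`margin_kernel`), gradient-boosted trees with
#' histogram-based (`boosted_trees_hist`) and exact (`boosted_trees_exact`)
#' split finding, ridge-penalised logistic regression (`logistic`), and
#' k-nearest neighbours (`knn`). Defaults: SVM cost 1 with kernel width
#' 1/(d * total feature variance); both boosted families 100 trees, depth 6,
#' learning rate 0.1; logistic L2 penalty 1; knn k = 5.
#'
#' @param family one of `"margin_kernel"`, `"boosted_trees_hist"`,
#'   `"boosted_trees_exact"`, `"logistic"`, `"knn"`.
#' @param hyperparameters named list overriding the family defaults; unknown
#'   names are rejected.
#' @param seed integer seed making the fit deterministic.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(family, hyperparameters = list(), seed = 1L) {
  if (length(family) != 1L || !family %in% classifier_families)
    stop_emb("config", sprintf("unknown classifier family '%s' (expected one of %s)",
                               paste(family, collapse = ","),
                               paste(classifier_families, collapse = ", ")))
  defaults <- default_hyperparameters[[family]]
  unknown <- setdiff(names(hyperparameters), names(defaults))
  if (length(unknown))
    stop_emb("config", sprintf("unknown hyperparameter(s) for %s: %s",
                               family, paste(unknown, collapse = ", ")))
  hp <- utils::modifyList(defaults, hyperparameters)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters,
                     function(v) if (is.null(v)) "auto" else format(v),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("classifier_spec: %s (%s; seed %d)\n", x$family, hp, x$seed))
  invisible(x)
}

#' Fit a classifier and score an evaluation set
#'
#' Trains the specified family on the training snapshot and returns one
#' continuous score per evaluation sample (higher = more enhancer-like;
#' for the margin-kernel family the signed distance to the decision
#' boundary, for the tree and logistic families the predicted positive
#' probability, for knn the positive vote fraction) plus hard labels from
#' each family's native decision rule. Deterministic given `spec$seed`.
#'
#' @param spec a [classifier_spec()].
#' @param train an [embedding_set()] containing both classes.
#' @param eval a non-empty [embedding_set()] with the same dimension.
#' @return A list with `scores` (numeric) and `predicted` (0/1 integer),
#'   one entry per evaluation sample.
#' @export
fit_predict <- function(spec, train, eval) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(train, "embedding_set"),
            inherits(eval, "embedding_set"))
  if (length(unique(train$labels)) < 2L)
    stop_emb("input", "training set must contain both classes")
  if (ncol(train$features) != ncol(eval$features))
    stop_emb("input", sprintf("dimension mismatch: train d = %d, eval d = %d",
                              ncol(train$features), ncol(eval$features)))
  hp <- spec$hyperparameters
  x <- train$features
  y <- train$labels
  xe <- eval$features
  out <- with_seed(spec$seed, switch(
    spec$family,
    margin_kernel = {
      gamma <- hp$gamma
      if (is.null(gamma)) {
        v <- var(as.vector(x))
        gamma <- if (v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      }
      fit <- e1071::svm(x = x, y = factor(y, levels = c("0", "1")),
                        kernel = "radial", cost = hp$cost, gamma = gamma,
                        scale = FALSE)
      pred <- predict(fit, xe, decision.values = TRUE)
      dv <- drop(attr(pred, "decision.values"))
      # e1071 orients the margin towards the first class named in the column
      if (startsWith(colnames(attr(pred, "decision.values"))[1L], "0")) dv <- -dv
      list(scores = unname(dv), predicted = as.integer(as.character(pred)))
    },
    boosted_trees_hist = xgb_fit_predict(x, y, xe, hp, "hist", spec$seed),
    boosted_trees_exact = xgb_fit_predict(x, y, xe, hp, "exact", spec$seed),
    logistic = {
      # ridge logistic; glmnet needs >= 2 columns, pad a zero column at d = 1
      pad <- ncol(x) < 2L
      xtr <- if (pad) cbind(x, 0) else x
      xev <- if (pad) cbind(xe, 0) else xe
      lam <- 1 / (nrow(x) * hp$penalty)
      fit <- glmnet::glmnet(xtr, factor(y, levels = c("0", "1")),
                            family = "binomial", alpha = 0, lambda = lam)
      p <- drop(predict(fit, xev, type = "response"))
      list(scores = unname(p), predicted = as.integer(p > 0.5))
    },
    knn = {
      pred <- class::knn(train = x, test = xe,
                         cl = factor(y, levels = c("0", "1")),
                         k = hp$k, prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      p1 <- ifelse(pred == "1", win, 1 - win)
      list(scores = unname(p1), predicted = as.integer(as.character(pred)))
    }
  ))
  out
}

xgb_fit_predict <- function(x, y, xe, hp, tree_method, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, tree_method = tree_method, nthread = 1,
                  seed = seed),
    data = dtrain, nrounds = hp$nrounds, verbose = 0)
  p <- predict(fit, xgboost::xgb.DMatrix(xe, nthread = 1))
  list(scores = unname(p), predicted = as.integer(p > 0.5))
}

# label-stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, folds, seed) {
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  assignment
}

#' Stratified k-fold cross-validation with optional independent test
#'
#' Splits the training set into label-stratified folds, fits the classifier
#' on each complement and evaluates the held-out fold with the full
#' eight-metric report, then averages the metrics fieldwise. When an
#' independent `test` set is supplied the classifier is refit on the whole
#' training set and evaluated on it.
#'
#' @param spec a [classifier_spec()].
#' @param train an [embedding_set()]; every class count must be >= `folds`.
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed; keep it fixed across specs for paired
#'   comparisons.
#' @param test optional independent-test [embedding_set()].
#' @return An object of class `cv_result`: `fold_metrics` (list of
#'   [metrics_report()]s), `mean_metrics`, `test_metrics` (or `NULL`),
#'   `fold_assignment`, `spec`.
#' @export
cross_validate <- function(spec, train, folds = 5L, seed = 1L, test = NULL) {
  stopifnot(inherits(train, "embedding_set"))
  folds <- as.integer(folds)
  tab <- table(factor(train$labels, levels = c(0L, 1L)))
  if (any(tab < folds))
    stop_emb("stratification",
             sprintf("every class needs >= %d samples for %d-fold CV (have %s)",
                     folds, folds, paste(tab, collapse = "/")))
  assignment <- stratified_folds(train$labels, folds, seed)
  fold_metrics <- lapply(seq_len(folds), function(f) {
    tr <- subset_embedding_set(train, which(assignment != f))
    va <- subset_embedding_set(train, which(assignment == f))
    fp <- fit_predict(spec, tr, va)
    metrics_report(va$labels, fp$predicted, fp$scores)
  })
  mean_metrics <- setNames(lapply(metric_names, function(m) {
    mean(vapply(fold_metrics, function(r) r[[m]], numeric(1)))
  }), metric_names)
  class(mean_metrics) <- "metrics_report"
  test_metrics <- NULL
  if (!is.null(test)) {
    fp <- fit_predict(spec, train, test)
    test_metrics <- metrics_report(test$labels, fp$predicted, fp$scores)
  }
  structure(list(spec = spec, fold_metrics = fold_metrics,
                 mean_metrics = mean_metrics, test_metrics = test_metrics,
                 fold_assignment = assignment, folds = folds, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("%d-fold cross-validation, %s\n", x$folds, x$spec$family))
  cat("CV mean: ")
  print(round(vapply(metric_names, function(m) x$mean_metrics[[m]],
                     numeric(1)), digits))
  if (!is.null(x$test_metrics)) {
    cat("independent test: ")
    print(round(vapply(metric_names, function(m) x$test_metrics[[m]],
                       numeric(1)), digits))
  }
  invisible(x)
}

#' Compare a roster of classifiers under shared folds
#'
#' Runs [cross_validate()] for every spec with the same seed, so fold
#' assignments are identical and the comparison is paired.
#'
#' @param specs list of [classifier_spec()]s.
#' @inheritParams cross_validate
#' @return An object of class `classifier_comparison`: `results` (named list
#'   of `cv_result`s) and `table` (one row per (classifier, split) with the
#'   eight metric columns).
#' @export
compare_classifiers <- function(specs, train, test = NULL, folds = 5L,
                                seed = 1L) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop_emb("config", "empty classifier roster")
  results <- lapply(specs, cross_validate, train = train, folds = folds,
                    seed = seed, test = test)
  names(results) <- make.unique(vapply(specs, `[[`, character(1), "family"))
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    row_of <- function(mr, split) cbind(
      data.frame(classifier = nm, split = split),
      as.data.frame.metrics_report(mr))
    out <- row_of(r$mean_metrics, "cv_mean")
    if (!is.null(r$test_metrics)) out <- rbind(out, row_of(r$test_metrics, "test"))
    out
  }))
  structure(list(results = results, table = rows), class = "classifier_comparison")
}

#' @export
print.classifier_comparison <- function(x, digits = 4, ...) {
  tab <- x$table
  tab[metric_names] <- round(tab[metric_names], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.classifier_comparison <- function(x, ...) x$table
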