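#' Classifier specification
#'
#' Describes one of the five benchmark classifier families together with its
#' hyperparameters, validated against a per-family schema. Defaults mirror a
#' Weka-style benchmark setup: random forest with 100 trees and
#' floor(log2(p)) + 1 candidate features per split; an entropy-split decision
#' tree with minimum-leaf-size pruning (a C4.5/J48 approximation); Gaussian
#' naive Bayes; a linear-kernel SVM on standardized features; 1-nearest
#' neighbour (IBk default).
#'
#' @param family one of `"random_forest"`, `"c45_tree"`, `"naive_bayes"`,
#'   `"svm"`, `"knn"`
#' @param ... family-specific hyperparameters overriding the defaults:
#'   `ntree`, `mtry` (random_forest); `minbucket`, `cp` (c45_tree);
#'   `laplace` (naive_bayes); `kernel`, `cost`, `gamma` (svm); `k` (knn)
#' @param seed integer seed used for every fit under this spec
#' @return a `classifier_spec`
#' @examples
#' classifier_spec("random_forest", seed = 1)
#' classifier_spec("knn", k = 3, seed = 1)
#' @export
classifier_spec <- function(family = c("random_forest", "c45_tree",
                                       "naive_bayes", "svm", "knn"),
                            ..., seed = 1L) {
  family <- match.arg(family)
  defaults <- switch(family,
    random_forest = list(ntree = 100L, mtry = NULL),
    c45_tree = list(minbucket = 2L, cp = 0.01),
    naive_bayes = list(laplace = 0),
    svm = list(kernel = "linear", cost = 1, gamma = NULL),
    knn = list(k = 1L))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad))
    stop_validation("unknown hyperparameter(s) for %s: %s", family,
                    paste(bad, collapse = ", "))
  hp <- utils::modifyList(defaults, over)
  validate_hyperparameters(family, hp)
  structure(list(family = family, hyperparameters = hp,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

validate_hyperparameters <- function(family, hp) {
  chk <- function(cond, msg) if (!cond) stop_validation("%s: %s", family, msg)
  switch(family,
    random_forest = {
      chk(hp$ntree >= 1, "ntree must be >= 1")
      chk(is.null(hp$mtry) || hp$mtry >= 1, "mtry must be >= 1")
    },
    c45_tree = {
      chk(hp$minbucket >= 1, "minbucket must be >= 1")
      chk(hp$cp >= 0, "cp must be >= 0")
    },
    naive_bayes = chk(hp$laplace >= 0, "laplace must be >= 0"),
    svm = {
      chk(hp$kernel %in% c("linear", "radial", "polynomial", "sigmoid"),
          "unknown kernel")
      chk(hp$cost > 0, "cost must be > 0")
    },
    knn = chk(hp$k >= 1, "k must be >= 1"))
  invisible(hp)
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- x$hyperparameters[!vapply(x$hyperparameters, is.null, logical(1))]
  cat(sprintf("classifier_spec: %s (%s), seed %d\n", x$family,
              paste(sprintf("%s=%s", names(hp), unlist(hp)), collapse = ", "),
              x$seed))
  invisible(x)
}

#' Fit a classifier on a feature matrix
#'
#' @param x numeric matrix (or `feature_matrix`) of predictors
#' @param labels class labels (`"positive"` / `"negative"`); taken from the
#'   `feature_matrix` attribute when omitted
#' @param spec a [classifier_spec()]
#' @return an `abct_model` (fitted model plus metadata); for k-NN, a lazy
#'   model storing the training data
#' @export
fit_classifier <- function(x, labels = NULL, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  labels <- resolve_labels(x, labels)
  x <- strip_fm(x)
  if (length(unique(labels)) < 2L)
    stop_validation("training data must contain both classes")
  y <- factor(labels, levels = c("negative", "positive"))
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    random_forest = randomForest::randomForest(
      x = x, y = y, ntree = hp$ntree,
      mtry = hp$mtry %||% (floor(log2(ncol(x))) + 1L)),
    c45_tree = {
      df <- data.frame(y = y, x, check.names = FALSE)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = "information"),
                   control = rpart::rpart.control(minbucket = hp$minbucket,
                                                  cp = hp$cp))
    },
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y,
                                    laplace = hp$laplace),
    svm = e1071::svm(x = x, y = y, kernel = hp$kernel, cost = hp$cost,
                     gamma = hp$gamma %||% (1 / ncol(x)),
                     scale = TRUE, probability = TRUE),
    knn = list(train = x, y = y, k = hp$k))
  structure(list(family = spec$family, spec = spec, fit = fit,
                 features = colnames(x), n_train = nrow(x)),
            class = "abct_model")
}

#' @export
print.abct_model <- function(x, ...) {
  cat(sprintf("abct_model: %s fitted on %d samples x %d features\n",
              x$family, x$n_train, length(x$features)))
  invisible(x)
}

#' Predict from a fitted classifier
#'
#' @param object an `abct_model`
#' @param newdata numeric matrix with the same columns as the training data
#' @param type `"score"` for the positive-class score in \[0, 1\] (class
#'   probability, or vote fraction for k-NN), `"class"` for hard labels
#'   (score >= 0.5 -> `"positive"`)
#' @param ... unused
#' @return numeric vector of scores, or character vector of labels
#' @export
predict.abct_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- strip_fm(newdata)
  if (ncol(newdata) != length(object$features))
    stop_validation("feature count mismatch: model has %d, newdata has %d",
                    length(object$features), ncol(newdata))
  score <- switch(object$family,
    random_forest = stats::predict(object$fit, newdata, type = "prob")[, "positive"],
    c45_tree = stats::predict(object$fit,
                              data.frame(newdata, check.names = FALSE),
                              type = "prob")[, "positive"],
    naive_bayes = stats::predict(object$fit, as.data.frame(newdata),
                                 type = "raw")[, "positive"],
    svm = {
      pr <- stats::predict(object$fit, newdata, probability = TRUE)
      attr(pr, "probabilities")[, "positive"]
    },
    knn = {
      set.seed(object$spec$seed)  # knn breaks distance ties at random
      pred <- class::knn(object$fit$train, newdata, object$fit$y,
                         k = object$fit$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "positive", p, 1 - p)
    })
  score <- unname(score)
  if (type == "score") score else ifelse(score >= 0.5, "positive", "negative")
}

#' Stratified k-fold cross-validation of one classifier
#'
#' Assigns samples to `folds` stratified folds (class proportions per fold
#' within one sample of the global proportions), fits on folds-1 parts, scores
#' the held-out part, and pools confusion counts and scores over all folds.
#' ROC/AUC are computed from the pooled scores. Fully deterministic for a
#' fixed seed.
#'
#' @param x a `feature_matrix`, or numeric matrix with `labels` given
#' @param spec a [classifier_spec()]
#' @param folds number of folds (default 10); must not exceed the
#'   minority-class count
#' @param seed integer seed for fold assignment and per-fold fits
#' @param labels class labels when `x` is a bare matrix
#' @return an `evaluation_report` with `level = "split"`, per-fold counts in
#'   `$folds`, pooled scores in `$scores`
#' @export
cross_validate <- function(x, spec = classifier_spec(), folds = 10L, seed,
                           labels = NULL) {
  if (missing(seed)) stop_validation("seed is required")
  labels <- resolve_labels(x, labels)
  x <- strip_fm(x)
  y <- factor(labels, levels = c("negative", "positive"))
  if (any(is.na(y))) stop_validation("labels must be 'positive' or 'negative'")
  if (nlevels(droplevels(y)) < 2L)
    stop_validation("cross-validation requires both classes present")
  if (folds < 2L) stop_validation("folds must be >= 2")
  if (folds > min(table(y)))
    stop_validation("folds (%d) exceed minority-class count (%d)",
                    folds, min(table(y)))
  fold_id <- stratified_folds(y, folds, derive_seed(seed, 0L))
  score <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    fit_spec <- spec
    fit_spec$seed <- derive_seed(seed, f)
    model <- fit_classifier(x[!hold, , drop = FALSE], labels[!hold], fit_spec)
    score[hold] <- predict(model, x[hold, , drop = FALSE], type = "score")
    pred_pos <- score[hold] >= 0.5
    truth_pos <- y[hold] == "positive"
    per_fold[[f]] <- c(fold = f,
                       tp = sum(pred_pos & truth_pos),
                       tn = sum(!pred_pos & !truth_pos),
                       fp = sum(pred_pos & !truth_pos),
                       fn = sum(!pred_pos & truth_pos))
  }
  folds_df <- as.data.frame(do.call(rbind, per_fold))
  metrics <- compute_metrics(sum(folds_df$tp), sum(folds_df$tn),
                             sum(folds_df$fp), sum(folds_df$fn))
  ra <- compute_roc_auc(score, as.character(y), positive = "positive")
  new_evaluation_report(spec$family, "split", metrics, auc = ra$auc,
                        roc = ra$roc, folds = folds_df,
                        scores = data.frame(score = score,
                                            label = as.character(y)))
}

# per-class shuffled round-robin assignment; proportions per fold differ from
# global by at most one sample
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Evaluate a fitted classifier on a held-out set
#'
#' With the repeated-undersampling protocol the held-out sets contain only
#' negatives; accuracy on such a set equals specificity on unseen negatives,
#' and SN/MCC/AUC are undefined (flagged, reported as 0 / omitted). Mixed
#' test sets yield the full metric panel.
#'
#' @param model an `abct_model`
#' @param x test `feature_matrix` (or matrix plus `labels`)
#' @param labels test labels when `x` is a bare matrix
#' @return an `evaluation_report` with `level = "holdout"`
#' @export
evaluate_holdout <- function(model, x, labels = NULL) {
  stopifnot(inherits(model, "abct_model"))
  labels <- resolve_labels(x, labels)
  x <- strip_fm(x)
  if (nrow(x) == 0L) stop_validation("empty test set")
  score <- predict(model, x, type = "score")
  pred_pos <- score >= 0.5
  truth_pos <- labels == "positive"
  metrics <- compute_metrics(sum(pred_pos & truth_pos),
                             sum(!pred_pos & !truth_pos),
                             sum(pred_pos & !truth_pos),
                             sum(!pred_pos & truth_pos))
  both <- any(truth_pos) && any(!truth_pos)
  ra <- if (both) compute_roc_auc(score, labels, positive = "positive") else NULL
  new_evaluation_report(model$family, "holdout", metrics,
                        auc = if (both) ra$auc else NULL,
                        roc = if (both) ra$roc else NULL,
                        scores = data.frame(score = score, label = labels))
}

#' Grid-search hyperparameters by cross-validation
#'
#' Optional model selection: evaluates each candidate hyperparameter setting
#' with [cross_validate()] and returns the spec with the highest CV accuracy
#' (ties broken by grid order). Default grids are small and documented here:
#' random_forest ntree {50, 100, 200}; c45_tree minbucket {2, 5, 10};
#' naive_bayes laplace {0, 1}; svm cost {0.1, 1, 10}; knn k {1, 3, 5}.
#'
#' @param x a `feature_matrix` (or matrix plus `labels`)
#' @param family classifier family
#' @param grid named list of hyperparameter vectors; default per-family grid
#' @param folds CV folds
#' @param seed integer seed
#' @param labels labels when `x` is a bare matrix
#' @return list with `spec` (best [classifier_spec()]), `results` (data frame
#'   of candidate settings and their CV accuracy)
#' @export
tune_classifier <- function(x, family = "random_forest", grid = NULL,
                            folds = 10L, seed, labels = NULL) {
  if (missing(seed)) stop_validation("seed is required")
  if (is.null(grid))
    grid <- switch(family,
      random_forest = list(ntree = c(50L, 100L, 200L)),
      c45_tree = list(minbucket = c(2L, 5L, 10L)),
      naive_bayes = list(laplace = c(0, 1)),
      svm = list(cost = c(0.1, 1, 10)),
      knn = list(k = c(1L, 3L, 5L)))
  cand <- expand.grid(grid, stringsAsFactors = FALSE)
  acc <- vapply(seq_len(nrow(cand)), function(i) {
    spec <- do.call(classifier_spec,
                    c(list(family = family, seed = derive_seed(seed, 1000L + i)),
                      as.list(cand[i, , drop = FALSE])))
    cross_validate(x, spec, folds = folds, seed = seed, labels = labels)$acc
  }, numeric(1))
  best <- which.max(acc)
  spec <- do.call(classifier_spec,
                  c(list(family = family, seed = derive_seed(seed, 1000L + best)),
                    as.list(cand[best, , drop = FALSE])))
  list(spec = spec, results = cbind(cand, cv_accuracy = acc))
}

resolve_labels <- function(x, labels) {
  if (is.null(labels)) labels <- attr(x, "labels")
  if (is.null(labels)) stop_validation("labels are required")
  as.character(labels)
}

strip_fm <- function(x) {
  if (inherits(x, "feature_matrix")) {
    attr(x, "class") <- NULL
    attr(x, "labels") <- NULL
  }
  as.matrix(x)
}
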