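#' Fit, select and evaluate a classifier on one design matrix
#'
#' The evaluation protocol of the pipeline: features are Yeo-Johnson
#' transformed (parameters fitted on training rows only); every candidate
#' family — random forest, multilayer perceptron, ridge-logistic regression
#' and a radial support-vector machine — is compared by mean AUC under
#' stratified 10-fold cross-validation on the training set; the winning
#' family's hyperparameters are then chosen by a 5-fold grid search on AUC;
#' the selected model is refitted on the full training set and reported on
#' the held-out test set (precision, recall, F1, accuracy and AUC for the
#' positive class at a 0.5 threshold). Stochastic learners are averaged over
#' `n_runs` seeded fits for the reported test predictions.
#'
#' @param x_train,y_train training design matrix and labels.
#' @param x_test,y_test held-out design matrix and labels.
#' @param algorithms candidate families.
#' @param seed master seed for folds and stochastic fits.
#' @param cv_folds folds of the family-selection stage (reduced with a
#'   warning when a class is smaller).
#' @param grid_folds folds of the grid-search stage.
#' @param n_runs seeded runs averaged for stochastic learners.
#' @param transform apply the Yeo-Johnson transform (fitted on train).
#' @param positive positive-class label.
#' @return object of class `spv_eval`; see [tidy.spv_eval()] /
#'   [glance.spv_eval()].
#' @export
fit_select_evaluate <- function(x_train, y_train, x_test, y_test,
                                algorithms = c("rf", "mlp", "logistic", "svm"),
                                seed = 1, cv_folds = 10, grid_folds = 5,
                                n_runs = 3, transform = TRUE,
                                positive = "risk") {
  y_train <- droplevels(as.factor(y_train)); y_test <- droplevels(as.factor(y_test))
  if (nlevels(y_train) != 2) stop("training labels must have exactly two classes")
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  if (is.null(colnames(x_train))) {
    colnames(x_train) <- colnames(x_test) <- paste0("f", seq_len(ncol(x_train)))
  }
  pp <- NULL; pp_keep <- NULL
  if (transform) {
    tr <- transform_features(x_train, x_test)
    pp <- tr$pp
    pp_keep <- setdiff(colnames(x_train), tr$zero_variance)
    x_train <- tr$train; x_test <- tr[[4]]
  }
  # stage 1: family selection by 10-fold CV AUC at default parameters
  fold <- stratified_folds(y_train, cv_folds, seed = seed)
  stage1 <- dplyr::bind_rows(lapply(algorithms, function(alg) {
    aucs <- vapply(sort(unique(fold)), function(f) {
      fit <- fit_classifier(alg, x_train[fold != f, , drop = FALSE], y_train[fold != f],
                            default_params(alg, ncol(x_train)), positive,
                            seed = child_seed(seed, f))
      auc_rank(y_train[fold == f] == positive,
               predict_classifier(fit, x_train[fold == f, , drop = FALSE]),
               positive = "TRUE")
    }, 0)
    tibble(algorithm = alg, cv_auc = mean(aucs, na.rm = TRUE))
  }))
  best_alg <- stage1$algorithm[which.max(stage1$cv_auc)]
  # stage 2: grid search on the winning family by 5-fold CV AUC
  grid <- param_grid(best_alg, ncol(x_train))
  gfold <- stratified_folds(y_train, grid_folds, seed = child_seed(seed, 101))
  grid$cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(sort(unique(gfold)), function(f) {
      fit <- fit_classifier(best_alg, x_train[gfold != f, , drop = FALSE],
                            y_train[gfold != f], as.list(grid[g, , drop = FALSE]),
                            positive, seed = child_seed(seed, 200 + f))
      auc_rank(y_train[gfold == f] == positive,
               predict_classifier(fit, x_train[gfold == f, , drop = FALSE]),
               positive = "TRUE")
    }, 0), na.rm = TRUE)
  }, 0)
  best_params <- as.list(grid[which.max(grid$cv_auc), setdiff(names(grid), "cv_auc"), drop = FALSE])
  # final fit on the full training set; stochastic learners averaged
  runs <- if (best_alg %in% c("rf", "mlp")) n_runs else 1L
  fits <- lapply(seq_len(runs), function(r) {
    fit_classifier(best_alg, x_train, y_train, best_params, positive,
                   seed = child_seed(seed, 300 + r))
  })
  prob_test <- rowMeans(vapply(fits, predict_classifier, numeric(nrow(x_test)),
                               newx = x_test))
  metrics <- classification_metrics(y_test, prob_test, positive = positive)
  structure(list(
    metrics = metrics, classifier = best_alg, params = best_params,
    stage1 = stage1, grid = grid, fits = fits, pp = pp, pp_keep = pp_keep,
    columns = colnames(x_train), positive = positive, seed = seed,
    prob_test = prob_test, y_test = y_test, n_train = nrow(x_train)
  ), class = "spv_eval")
}

default_params <- function(alg, p) {
  switch(alg,
    rf = list(mtry = max(1L, floor(sqrt(p))), ntree = 300L),
    mlp = list(size = 5L, decay = 0.1),
    logistic = list(lambda = 0.01),
    svm = list(cost = 1, gamma = 1 / p),
    stop("unknown algorithm: ", alg)
  )
}

param_grid <- function(alg, p) {
  switch(alg,
    rf = tidyr::expand_grid(mtry = unique(c(max(1L, floor(sqrt(p))),
                                            max(1L, floor(p / 3)))),
                            ntree = 300L),
    mlp = tidyr::expand_grid(size = c(3L, 8L), decay = c(0.1, 0.01)),
    logistic = tibble(lambda = c(1, 0.1, 0.01, 0.001)),
    svm = tidyr::expand_grid(cost = c(1, 10), gamma = unique(c(1 / p, 3 / p)))
  )
}

fit_classifier <- function(alg, x, y, params, positive, seed = 1) {
  fit <- with_seed(seed, switch(alg,
    rf = randomForest::randomForest(x, y, ntree = params$ntree %||% 300L,
                                    mtry = min(params$mtry, ncol(x))),
    mlp = nnet::nnet(x, as.integer(y == positive), size = params$size,
                     decay = params$decay, maxit = 200, trace = FALSE,
                     entropy = TRUE, MaxNWts = 1e6),
    logistic = ridge_logistic_fit(x, y, positive, params$lambda),
    svm = e1071::svm(x, y, kernel = "radial", cost = params$cost,
                     gamma = params$gamma, probability = TRUE)
  ))
  structure(list(alg = alg, fit = fit, positive = positive), class = "spv_classifier")
}

predict_classifier <- function(object, newx) {
  fit <- object$fit
  switch(object$alg,
    rf = as.numeric(predict(fit, newx, type = "prob")[, object$positive]),
    mlp = as.numeric(predict(fit, newx)),
    logistic = ridge_logistic_prob(fit, newx),
    svm = {
      pr <- attr(predict(fit, newx, probability = TRUE), "probabilities")
      as.numeric(pr[, object$positive])
    }
  )
}

#' Predict with an evaluated model
#'
#' Applies the stored Yeo-Johnson transform and the final fitted model(s) to
#' new rows (stochastic fits are averaged), returning positive-class
#' probabilities.
#'
#' @param object an `spv_eval`.
#' @param newx matrix with the model's feature columns.
#' @param ... unused.
#' @export
predict.spv_eval <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  missing_cols <- setdiff(object$columns, colnames(newx))
  if (length(missing_cols) > 0) {
    stop("feature mismatch; missing columns: ", paste(missing_cols, collapse = ", "))
  }
  newx <- newx[, object$columns, drop = FALSE]
  if (!is.null(object$pp)) {
    out <- matrix(0, nrow(newx), length(object$columns),
                  dimnames = list(rownames(newx), object$columns))
    out[, object$pp_keep] <- as.matrix(
      predict(object$pp, as.data.frame(newx[, object$pp_keep, drop = FALSE]))
    )
    newx <- out
  }
  rowMeans(vapply(object$fits, predict_classifier, numeric(nrow(newx)), newx = newx))
}

#' @rdname fit_select_evaluate
#' @param x an `spv_eval`.
#' @param ... unused.
#' @export
tidy.spv_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname fit_select_evaluate
#' @export
glance.spv_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble(classifier = x$classifier, n_train = x$n_train,
                          n_test = length(x$y_test)))
}

#' @export
print.spv_eval <- function(x, ...) {
  cat("<spv_eval> classifier:", x$classifier, "\n")
  print(x$metrics)
  invisible(x)
}
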