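#' Classifier protocol specification
#'
#' @param model_kind `"elastic_net_logistic"` (glmnet, alpha 0.5),
#'   `"linear_svm"` (linear-kernel SVM) or `"gradient_boosting"` (xgboost).
#' @param train_fraction fraction of samples in the stratified training
#'   split (default 0.70; the rest is the held-out validation set).
#' @param cv_folds folds for cross-validated hyperparameter choice on the
#'   training split.
#' @param rfe_drop_fraction fraction of remaining features dropped per
#'   recursive-feature-elimination round.
#' @param seed RNG seed.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(model_kind = c("elastic_net_logistic", "linear_svm",
                                           "gradient_boosting"),
                            train_fraction = 0.70, cv_folds = 5L,
                            rfe_drop_fraction = 0.5, seed = 1L) {
  model_kind <- match.arg(model_kind)
  stopifnot(train_fraction > 0, train_fraction < 1, cv_folds >= 2L,
            rfe_drop_fraction > 0, rfe_drop_fraction < 1)
  structure(list(model_kind = model_kind, train_fraction = train_fraction,
                 cv_folds = as.integer(cv_folds),
                 rfe_drop_fraction = rfe_drop_fraction, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Stratified train/test split
#'
#' Samples `train_fraction` of each class (rounded per class) without
#' replacement; deterministic given the spec seed.
#'
#' @param labels two-class vector; names (or positions) identify samples.
#' @param spec a [classifier_spec()].
#' @return list with `train_ids` and `test_ids` (names when `labels` is
#'   named, integer positions otherwise); disjoint and exhaustive.
#' @export
split_train_test <- function(labels, spec = classifier_spec()) {
  ids <- if (!is.null(names(labels))) names(labels) else seq_along(labels)
  y <- as.factor(labels)
  if (length(y) < 10L) stop("need at least 10 labeled samples", call. = FALSE)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L) stop("each class needs at least 2 samples", call. = FALSE)
  # per-class counts: floors first, then hand the remaining slots (to reach
  # round(fraction * n) in total) to the classes with the largest fractional
  # parts, so the split stays within one sample of exact stratification
  n_c <- table(y)
  target <- round(spec$train_fraction * length(y))
  base <- floor(spec$train_fraction * n_c)
  frac <- spec$train_fraction * n_c - base
  extra <- target - sum(base)
  if (extra > 0) {
    bump <- order(-frac)[seq_len(extra)]
    base[bump] <- base[bump] + 1
  }
  with_seed(spec$seed, function() {
    train <- unlist(lapply(seq_along(levels(y)), function(i) {
      pool <- ids[y == levels(y)[i]]
      sample(pool, base[i])
    }), use.names = FALSE)
    list(train_ids = train, test_ids = setdiff(ids, train))
  })
}

# stratified fold assignment; every fold's complement must contain both
# classes, retried with a shifted seed up to 5 times
stratified_folds <- function(y, k, seed) {
  for (attempt in 0:4) {
    folds <- with_seed(seed + attempt, function() {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(i) nlevels(droplevels(y[folds != i])) == 2L,
                     logical(1L)))
    if (ok) return(folds)
  }
  stop("could not build folds with both classes in every training part", call. = FALSE)
}

# fit one model family and return decision scores for new data plus
# feature importances; hyper is a single scalar hyperparameter
fit_score <- function(kind, x_train, y_train, x_test, hyper, seed = 1L) {
  y01 <- as.numeric(y_train == levels(y_train)[2L])
  if (kind == "elastic_net_logistic") {
    xtr <- x_train; xte <- x_test
    if (ncol(xtr) == 1L) {  # glmnet needs >= 2 columns
      xtr <- cbind(xtr, .pad = 0); xte <- cbind(xte, .pad = 0)
    }
    if (all(apply(xtr, 2L, var) == 0)) {
      # intercept-only problem: constant score, no informative features
      return(list(score = rep(0, nrow(x_test)),
                  importance = setNames(numeric(ncol(x_train)), colnames(x_train))))
    }
    fit <- glmnet::glmnet(xtr, y01, family = "binomial", alpha = 0.5,
                          lambda = hyper)
    score <- as.vector(predict(fit, xte, s = hyper))
    w <- abs(as.vector(coef(fit, s = hyper))[-1L])
    names(w) <- colnames(xtr)
    w <- w[colnames(x_train)]
  } else if (kind == "linear_svm") {
    fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = hyper,
                      scale = FALSE)
    dv <- attr(predict(fit, x_test, decision.values = TRUE), "decision.values")
    score <- as.vector(dv)
    # positive decision values favour the class named before the "/";
    # orient the score toward the second factor level
    favoured <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
    if (favoured != levels(y_train)[2L]) score <- -score
    w <- abs(as.vector(t(fit$coefs) %*% fit$SV))
    names(w) <- colnames(x_train)
  } else {
    # exact splits place thresholds at gap midpoints, which matters at these
    # sample sizes; the histogram method cuts at training values instead
    fit <- xgboost::xgboost(x_train, factor(y01, levels = c(0, 1)),
                            objective = "binary:logistic", nrounds = hyper,
                            learning_rate = 0.1, max_depth = 2L,
                            tree_method = "exact",
                            nthreads = 1L, verbosity = 0, seed = seed)
    score <- predict(fit, x_test)
    if (is.matrix(score)) score <- score[, ncol(score)]
    imp <- tryCatch(xgboost::xgb.importance(model = fit), error = function(e) NULL)
    w <- setNames(numeric(ncol(x_train)), colnames(x_train))
    if (!is.null(imp) && nrow(imp)) w[imp$Feature] <- imp$Gain
  }
  list(score = score, importance = w)
}

hyper_grid <- function(kind) {
  switch(kind,
         elastic_net_logistic = 10^seq(-4, 0, length.out = 9L),
         linear_svm = c(0.01, 0.1, 1, 10),
         gradient_boosting = c(25L, 50L, 100L))
}

# mean/sd of fold AUROCs for each hyperparameter value
cv_auroc_by_hyper <- function(kind, x, y, folds, grid, seed) {
  res <- vapply(grid, function(h) {
    aucs <- vapply(sort(unique(folds)), function(i) {
      tr <- folds != i
      fs <- fit_score(kind, x[tr, , drop = FALSE], droplevels(y[tr]),
                      x[!tr, , drop = FALSE], h, seed = seed)
      if (nlevels(droplevels(y[!tr])) < 2L) return(NA_real_)
      auroc(fs$score, y[!tr] == levels(y)[2L])
    }, numeric(1L))
    c(mean = mean(aucs, na.rm = TRUE), sd = sd(aucs[!is.na(aucs)]))
  }, numeric(2L))
  colnames(res) <- as.character(grid)
  res
}

#' Fit a subset classifier and evaluate it on the held-out split
#'
#' Splits the cohort 70/30 with stratification, chooses the model family's
#' hyperparameter by stratified k-fold cross-validated AUROC on the training
#' split, refits on the full training split and reports AUROC on the
#' held-out validation samples.
#'
#' @param features samples x features numeric matrix or data frame with
#'   sample rownames.
#' @param labels two-class vector aligned to rows (named or positional).
#' @param spec a [classifier_spec()].
#' @return object of class `classifier_report`: `model_kind`,
#'   `validation_auroc`, `cv_auroc_mean`, `cv_auroc_sd`, `hyperparameter`,
#'   `importances` (tibble sorted by decreasing importance), `train_ids`,
#'   `test_ids`.
#' @export
fit_and_evaluate <- function(features, labels, spec = classifier_spec()) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("features must not contain missing values", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.factor(labels)
  names(y) <- rownames(x)

  split <- split_train_test(setNames(as.character(y), rownames(x)), spec)
  tr_ids <- as.character(split$train_ids); te_ids <- as.character(split$test_ids)
  x_tr <- x[tr_ids, , drop = FALSE]; y_tr <- droplevels(y[tr_ids])
  folds <- stratified_folds(y_tr, spec$cv_folds, spec$seed)

  grid <- hyper_grid(spec$model_kind)
  cv <- cv_auroc_by_hyper(spec$model_kind, x_tr, y_tr, folds, grid, spec$seed)
  best <- which.max(cv["mean", ])
  hyper <- grid[best]

  final <- fit_score(spec$model_kind, x_tr, y_tr, x[te_ids, , drop = FALSE],
                     hyper, seed = spec$seed)
  val_auroc <- auroc(final$score, y[te_ids] == levels(y)[2L])
  imp <- tibble::tibble(feature = names(final$importance),
                        importance = unname(final$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))

  structure(
    list(model_kind = spec$model_kind,
         validation_auroc = val_auroc,
         cv_auroc_mean = unname(cv["mean", best]),
         cv_auroc_sd = unname(cv["sd", best]),
         hyperparameter = unname(hyper),
         importances = imp,
         train_ids = tr_ids, test_ids = te_ids),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s: validation AUROC %.3f (CV %.3f +/- %.3f)\n",
              x$model_kind, x$validation_auroc, x$cv_auroc_mean, x$cv_auroc_sd))
  invisible(x)
}

#' @rdname ipfsubsets-tidiers
#' @method tidy classifier_report
#' @export
tidy.classifier_report <- function(x, ...) x$importances

#' @rdname ipfsubsets-tidiers
#' @method glance classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind,
                 validation_auroc = x$validation_auroc,
                 cv_auroc_mean = x$cv_auroc_mean,
                 cv_auroc_sd = x$cv_auroc_sd,
                 hyperparameter = x$hyperparameter,
                 n_train = length(x$train_ids), n_test = length(x$test_ids))
}

#' Recursive feature elimination
#'
#' Iteratively fits the model family on all samples, records the stratified
#' CV AUROC at the current feature-set size, then drops the
#' lowest-importance `rfe_drop_fraction` of remaining features, down to a
#' single feature. The final ranking is the elimination order reversed; the
#' minimal set is the smallest evaluated size whose CV AUROC is within
#' 0.005 of the best size.
#'
#' @param features samples x features matrix or data frame.
#' @param labels two-class vector aligned to rows.
#' @param spec a [classifier_spec()].
#' @return object of class `rfe_result`: `ranking` (tibble `feature`,
#'   `rank`), `path` (tibble `n_features`, `cv_auroc`, `cv_sd`),
#'   `minimal_set` (character vector).
#' @export
recursive_feature_elimination <- function(features, labels, spec = classifier_spec()) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.factor(labels)
  stopifnot(ncol(x) >= 1L, nlevels(y) == 2L)
  folds <- stratified_folds(y, spec$cv_folds, spec$seed)
  hyper <- switch(spec$model_kind, elastic_net_logistic = 0.01,
                  linear_svm = 1, gradient_boosting = 50L)

  remaining <- colnames(x)
  eliminated <- character(0)
  path <- list()
  sets <- list()
  while (TRUE) {
    xs <- x[, remaining, drop = FALSE]
    aucs <- vapply(sort(unique(folds)), function(i) {
      tr <- folds != i
      fs <- fit_score(spec$model_kind, xs[tr, , drop = FALSE], droplevels(y[tr]),
                      xs[!tr, , drop = FALSE], hyper, seed = spec$seed)
      auroc(fs$score, y[!tr] == levels(y)[2L])
    }, numeric(1L))
    path[[length(path) + 1L]] <- tibble::tibble(
      n_features = length(remaining), cv_auroc = mean(aucs), cv_sd = sd(aucs))
    sets[[length(sets) + 1L]] <- remaining
    if (length(remaining) == 1L) break
    full <- fit_score(spec$model_kind, xs, y, xs, hyper, seed = spec$seed)
    imp <- full$importance[remaining]
    n_drop <- max(1L, floor(spec$rfe_drop_fraction * length(remaining)))
    n_drop <- min(n_drop, length(remaining) - 1L)
    drop <- names(sort(imp))[seq_len(n_drop)]
    eliminated <- c(eliminated, drop[order(imp[drop])])  # least important first
    remaining <- setdiff(remaining, drop)
  }
  ranking <- rev(c(eliminated, remaining))
  path <- dplyr::bind_rows(path)
  best <- max(path$cv_auroc)
  eligible <- which(path$cv_auroc >= best - 0.005)
  minimal <- sets[[eligible[which.min(path$n_features[eligible])]]]

  structure(
    list(ranking = tibble::tibble(feature = ranking, rank = seq_along(ranking)),
         path = path, minimal_set = minimal),
    class = "rfe_result"
  )
}

#' @rdname ipfsubsets-tidiers
#' @method tidy rfe_result
#' @export
tidy.rfe_result <- function(x, ...) x$ranking

#' @rdname ipfsubsets-tidiers
#' @method glance rfe_result
#' @export
glance.rfe_result <- function(x, ...) {
  tibble::tibble(best_cv_auroc = max(x$path$cv_auroc),
                 minimal_set_size = length(x$minimal_set))
}
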