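# Model-family plumbing shared by cross-validation, backward selection and
# leave-one-out evaluation.  "lm" predicts continuous RAP and classifies by
# thresholding at 5/10 mmHg; "svm" classifies directly.

fit_family <- function(family, train, features, opts = list()) {
  if (family == "lm") {
    lm_fit(train, features, denominators = opts$denominators,
           cci_offset = if (is.null(opts$cci_offset)) 0.3 else opts$cci_offset)
  } else if (family == "svm") {
    svm_fit(train, features,
            cost = if (is.null(opts$cost)) 1 else opts$cost,
            gamma = opts$gamma)
  } else {
    stop("unknown model family: ", family)
  }
}

predict_family <- function(family, model, test) {
  if (family == "lm") {
    rap <- lm_predict(test, model)
    list(class = rap_to_class(pmax(rap, 0)), rap = rap)
  } else {
    list(class = svm_predict(test, model), rap = rep(NA_real_, nrow(test)))
  }
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# out cyclically so every fold sees every class when counts allow.
stratified_folds <- function(classes, k, seed) {
  folds <- integer(length(classes))
  with_seed(seed, {
    for (cl in sort(unique(classes))) {
      idx <- which(classes == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Cross-validated classification accuracy
#'
#' Rows are partitioned into k folds stratified by RAP class with a fixed
#' seed.  Each fold is predicted by a model fitted on the remaining folds;
#' in the default leakage-safe mode missing values in both the training
#' and held-out rows are imputed with training-fold medians.  Accuracy is
#' pooled correct / total, deterministic given the seed.
#'
#' @param family \code{"lm"} (continuous prediction thresholded at 5/10
#'   mmHg) or \code{"svm"}.
#' @param table Patient feature table with measured \code{RAP}.
#' @param features Feature names for the model.
#' @param k Number of folds, default 10.
#' @param seed Fold-assignment seed (logged in results), default 20220607.
#' @param impute_mode \code{"fold"} (leakage-safe, default) imputes with
#'   training-fold statistics; \code{"table"} imputes the whole table once
#'   before splitting.
#' @param opts Model-family options (e.g. \code{denominators}, \code{cost},
#'   \code{gamma}).
#' @return Accuracy fraction in \code{[0, 1]}.
#' @export
kfold_accuracy <- function(family, table, features, k = 10,
                           seed = 20220607,
                           impute_mode = c("fold", "table"),
                           opts = list()) {
  impute_mode <- match.arg(impute_mode)
  if (k < 2) stop("k must be at least 2")
  if (nrow(table) < k) stop("need at least k rows")
  truth <- rap_to_class(table$RAP)
  if (impute_mode == "table") table <- impute_missing(table, columns = features)
  folds <- stratified_folds(truth, k, seed)
  correct <- 0L
  total <- 0L
  for (f in sort(unique(folds))) {
    train <- table[folds != f, , drop = FALSE]
    test <- table[folds == f, , drop = FALSE]
    if (length(unique(rap_to_class(train$RAP))) < 3L) {
      stop("a RAP class is absent from a training split; reduce k or ",
           "rebalance the data")
    }
    if (impute_mode == "fold") {
      st <- imputation_stats(train, features)
      train <- impute_missing(train, stats = st, columns = features)
      test <- impute_missing(test, stats = st, columns = features)
    }
    model <- fit_family(family, train, features, opts)
    pred <- predict_family(family, model, test)$class
    correct <- correct + sum(pred == truth[folds == f])
    total <- total + nrow(test)
  }
  correct / total
}

canonical_feature_order <- function(features) {
  canon <- ivc_feature_columns()
  known <- features[order(match(features, canon))]
  c(known[!is.na(match(known, canon))], setdiff(features, canon))
}

#' Backward feature elimination by cross-validated accuracy
#'
#' Starting from all candidate features, every leave-one-feature-out
#' subset is scored by [kfold_accuracy()] and the feature whose removal
#' yields the highest accuracy (the least informative one) is eliminated;
#' the procedure iterates down to a single feature, ranking the candidates
#' in order of importance.  On ties the feature occurring later in the
#' canonical column order is removed, keeping clinically primary features
#' longer.
#'
#' @inheritParams kfold_accuracy
#' @param candidates Candidate feature names (at least two).
#' @return Object of class \code{selection_result}: \code{removal_order}
#'   (least important first, a permutation of the candidates),
#'   \code{accuracy_path} (CV accuracy per subset, from the full set down
#'   to one feature), \code{best_subset} (maximal accuracy, smallest
#'   subset on ties), \code{seed} and \code{family}.
#' @export
backward_select <- function(family, table, candidates, k = 10,
                            seed = 20220607,
                            impute_mode = c("fold", "table"),
                            opts = list()) {
  impute_mode <- match.arg(impute_mode)
  if (length(candidates) < 2L) stop("need at least two candidate features")
  current <- canonical_feature_order(candidates)
  removal_order <- character(0)
  subsets <- list(current)
  # a rank-deficient subset (e.g. duplicated columns) cannot be scored;
  # it gets NA accuracy and the elimination continues on the others
  safe_acc <- function(feats) {
    tryCatch(
      kfold_accuracy(family, table, feats, k, seed, impute_mode, opts),
      error = function(e) {
        if (grepl("collinear", conditionMessage(e))) NA_real_ else stop(e)
      })
  }
  accuracy_path <- safe_acc(current)
  while (length(current) > 1L) {
    accs <- vapply(seq_along(current), function(i) {
      safe_acc(current[-i])
    }, numeric(1))
    if (all(is.na(accs))) stop("no scorable feature subset at this step")
    best <- max(accs, na.rm = TRUE)
    drop_idx <- max(which(!is.na(accs) & accs == best))  # later on ties
    removal_order <- c(removal_order, current[drop_idx])
    current <- current[-drop_idx]
    subsets[[length(subsets) + 1L]] <- current
    accuracy_path <- c(accuracy_path, best)
  }
  removal_order <- c(removal_order, current)
  best_acc <- max(accuracy_path, na.rm = TRUE)
  # smallest subset on ties
  best_idx <- max(which(!is.na(accuracy_path) & accuracy_path == best_acc))
  structure(list(
    removal_order = removal_order,
    accuracy_path = accuracy_path,
    subsets = subsets,
    best_subset = subsets[[best_idx]],
    best_accuracy = best_acc,
    seed = seed, k = k, family = family
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result (%s, k = %d, seed = %s)>\n", x$family,
              x$k, format(x$seed)))
  cat("removal order:", paste(x$removal_order, collapse = " < "), "\n")
  cat(sprintf("best subset (%d features, accuracy %.3f): %s\n",
              length(x$best_subset), x$best_accuracy,
              paste(x$best_subset, collapse = ", ")))
  invisible(x)
}

#' Leave-one-out cross-validated predictions
#'
#' Each row is predicted by a model trained on all other rows (with
#' leakage-safe imputation in the default mode).  For the linear model the
#' continuous RAP estimate is returned alongside the class.
#'
#' @inheritParams kfold_accuracy
#' @return Data frame aligned with the input rows: \code{truth},
#'   \code{class} (predicted) and \code{rap} (continuous estimate, NA for
#'   the SVM).
#' @export
loocv_predictions <- function(family, table, features,
                              impute_mode = c("fold", "table"),
                              opts = list()) {
  impute_mode <- match.arg(impute_mode)
  n <- nrow(table)
  if (n < 3L) stop("need at least 3 rows for leave-one-out")
  truth <- rap_to_class(table$RAP)
  if (impute_mode == "table") table <- impute_missing(table, columns = features)
  cls <- integer(n)
  rap <- numeric(n)
  for (i in seq_len(n)) {
    train <- table[-i, , drop = FALSE]
    test <- table[i, , drop = FALSE]
    if (impute_mode == "fold") {
      st <- imputation_stats(train, features)
      train <- impute_missing(train, stats = st, columns = features)
      test <- impute_missing(test, stats = st, columns = features)
    }
    model <- fit_family(family, train, features, opts)
    pred <- predict_family(family, model, test)
    cls[i] <- pred$class
    rap[i] <- pred$rap
  }
  data.frame(truth = truth, class = cls, rap = rap)
}

#' Serialize a selection result as JSON
#'
#' @param result A \code{selection_result}.
#' @param path JSON path.
#' @return \code{path}, invisibly.
#' @export
save_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  jsonlite::write_json(
    list(family = result$family, k = result$k, seed = result$seed,
         removal_order = result$removal_order,
         accuracy_path = result$accuracy_path,
         best_subset = result$best_subset,
         best_accuracy = result$best_accuracy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
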