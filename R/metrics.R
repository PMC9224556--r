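#' Confusion matrix over the three RAP classes
#'
#' @param true_classes,predicted_classes Equal-length integer vectors with
#'   labels in \code{1:3}.
#' @return 3x3 integer matrix of counts, rows = true class, columns =
#'   predicted class, of class \code{confusion_matrix}.
#' @export
confusion <- function(true_classes, predicted_classes) {
  t_ <- as.integer(true_classes)
  p_ <- as.integer(predicted_classes)
  if (length(t_) != length(p_)) stop("class vectors differ in length")
  if (any(!t_ %in% 1:3) || any(!p_ %in% 1:3)) {
    stop("class labels must lie in {1, 2, 3}")
  }
  m <- table(factor(t_, levels = 1:3), factor(p_, levels = 1:3))
  m <- matrix(as.integer(m), nrow = 3,
              dimnames = list(true = 1:3, predicted = 1:3))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' One-vs-all classification metrics
#'
#' For each class k the other two classes are pooled into the negative
#' set, giving TP, TN, FP, FN and the standard indexes: sensitivity
#' TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), accuracy
#' (TP+TN)/n and F-score 2*precision*sensitivity/(precision+sensitivity).
#' Macro averages are unweighted means over the three classes; an index
#' undefined for a class (zero denominator) is recorded as NA and excluded
#' from its macro mean with a warning.  The overall (plain multi-class)
#' accuracy, trace/n, is reported separately from the macro one-vs-all
#' accuracy since the two differ.
#'
#' @param cm A [confusion()] matrix.
#' @return List with \code{per_class} (data frame of counts and indexes),
#'   \code{macro} (named vector of macro-averaged indexes) and
#'   \code{overall_accuracy}.
#' @export
one_vs_all_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  per <- data.frame(class = 1:3, TP = NA_real_, TN = NA_real_,
                    FP = NA_real_, FN = NA_real_, sensitivity = NA_real_,
                    specificity = NA_real_, precision = NA_real_,
                    accuracy = NA_real_, f_score = NA_real_)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  for (k in 1:3) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    prec <- ratio(tp, tp + fp)
    acc <- (tp + tn) / n
    f <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      NA_real_
    }
    per[k, -1] <- c(tp, tn, fp, fn, sens, spec, prec, acc, f)
  }
  idx_cols <- c("sensitivity", "specificity", "precision", "accuracy",
                "f_score")
  if (anyNA(per[idx_cols])) {
    warning("undefined per-class index (zero denominator) excluded from ",
            "macro averages")
  }
  macro <- vapply(idx_cols, function(nm) mean(per[[nm]], na.rm = TRUE),
                  numeric(1))
  list(per_class = per, macro = macro,
       overall_accuracy = sum(diag(cm)) / n)
}

#' Fisher ratio of two distributions
#'
#' Linear class-separability score: the squared difference of the group
#' means divided by the sum of the group variances.
#'
#' @param values_a,values_b Numeric vectors, each with at least two finite
#'   values.
#' @return Nonnegative scalar.
#' @export
fisher_ratio <- function(values_a, values_b) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least two finite values")
  }
  v <- var(a) + var(b)
  if (v == 0) stop("degenerate distributions: zero variance sum")
  (mean(a) - mean(b))^2 / v
}

#' Average Fisher ratio over the three class pairs
#'
#' Unweighted mean of the pairwise Fisher ratios between classes 1-2, 1-3
#' and 2-3, the per-feature separability summary used to rank features.
#'
#' @param values Numeric feature values.
#' @param classes Class labels in \code{1:3}, same length.
#' @return Nonnegative scalar.
#' @export
avg_fisher_ratio <- function(values, classes) {
  stopifnot(length(values) == length(classes))
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  mean(vapply(pairs, function(p) {
    fisher_ratio(values[classes == p[1]], values[classes == p[2]])
  }, numeric(1)))
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as \code{x - y} with \code{x} the operator (or
#' reference) measure and \code{y} the algorithm estimate; the bias is the
#' mean difference and the limits of agreement are bias +/- 1.96 times the
#' sample standard deviation (n - 1) of the differences.
#'
#' @param x,y Paired finite numeric vectors, n >= 3.
#' @return Object of class \code{bland_altman}: \code{bias},
#'   \code{loa_lower}, \code{loa_upper}, \code{sd_diff},
#'   \code{correlation} (Pearson r of the pairs) and \code{n}.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("values must be finite")
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_lower = bias - 1.96 * s,
                 loa_upper = bias + 1.96 * s, sd_diff = s,
                 correlation = if (sd(x) > 0 && sd(y) > 0) cor(x, y) else NA_real_,
                 n = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman: bias %.3f, LoA [%.3f, %.3f], r = %.3f, n = %d>\n",
              x$bias, x$loa_lower, x$loa_upper, x$correlation, x$n))
  invisible(x)
}

#' Mean absolute error
#'
#' @param true_rap,predicted_rap Paired finite numeric vectors (mmHg).
#' @return Mean of the absolute differences.
#' @export
mean_absolute_error <- function(true_rap, predicted_rap) {
  if (length(true_rap) != length(predicted_rap)) {
    stop("paired vectors differ in length")
  }
  if (any(!is.finite(true_rap)) || any(!is.finite(predicted_rap))) {
    stop("values must be finite")
  }
  mean(abs(true_rap - predicted_rap))
}

#' Distinguishable RAP levels at a given estimation error
#'
#' Treating the mean absolute error as the effective resolution of a
#' continuous estimator, the observed pressure range divides into
#' \code{round(range / mae)} distinguishable levels, a practical summary
#' of how finely a patient can be followed over time.
#'
#' @param rap_range_mmHg Width of the observed RAP range (default 24 mmHg).
#' @param mae_mmHg Mean absolute error of the estimator.
#' @return Integer number of distinguishable levels.
#' @export
rap_resolution_levels <- function(rap_range_mmHg = 24, mae_mmHg) {
  if (mae_mmHg <= 0) stop("mae_mmHg must be positive")
  as.integer(round(rap_range_mmHg / mae_mmHg))
}
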