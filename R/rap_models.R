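#' Guidelines estimate of right atrial pressure from IVC size and collapse
#'
#' The echocardiographic guidelines rule: an IVC with diameter < 2.1 cm
#' that collapses > 50% with a sniff suggests normal RAP (0--5 mmHg); a
#' diameter > 2.1 cm with collapse < 50% suggests high RAP (10--20 mmHg);
#' intermediate values (5--10 mmHg) are assumed in all other cases,
#' including the exact boundaries (both class-1 and class-3 inequalities
#' are strict).
#'
#' @param ivc_diameter_cm IVC diameter in cm (vectorized).
#' @param caval_index_fraction Fractional collapse in \code{[0, 1]}.
#' @return Data frame with columns \code{class} (1 low, 2 intermediate,
#'   3 high), \code{rap_low} and \code{rap_high} (mmHg range bounds).
#' @export
guidelines_classify <- function(ivc_diameter_cm, caval_index_fraction) {
  d <- as.numeric(ivc_diameter_cm)
  ci <- as.numeric(caval_index_fraction)
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameter must be positive")
  if (any(!is.finite(ci)) || any(ci < 0 | ci > 1)) {
    stop("caval index must lie in [0, 1]")
  }
  cls <- ifelse(d < 2.1 & ci > 0.5, 1L, ifelse(d > 2.1 & ci < 0.5, 3L, 2L))
  data.frame(class = cls,
             rap_low = c(0, 5, 10)[cls],
             rap_high = c(5, 10, 20)[cls])
}

#' Convert continuous RAP to the three pressure classes
#'
#' Thresholds at 5 and 10 mmHg: low (<= 5), intermediate (> 5 and <= 10),
#' high (> 10).
#'
#' @param rap_mmHg Nonnegative pressures in mmHg (vectorized).
#' @return Integer classes in \code{1:3}.
#' @export
rap_to_class <- function(rap_mmHg) {
  r <- as.numeric(rap_mmHg)
  if (any(!is.finite(r)) || any(r < 0)) {
    stop("RAP must be nonnegative and finite")
  }
  ifelse(r <= 5, 1L, ifelse(r <= 10, 2L, 3L))
}

#' Inverse-shifted pulsatility transform
#'
#' RAP rises as the vessel stiffens and stops pulsating, so the caval index
#' enters the linear model through \code{1 / (CCI + a)} with offset
#' \code{a = 0.3}, the transform found maximally correlated with RAP.
#'
#' @param cci_fraction CCI as a fraction in \code{[0, 1)}.
#' @param offset Shift \code{a}, default 0.3.
#' @return \code{1 / (cci + offset)}.
#' @export
transform_cci <- function(cci_fraction, offset = 0.3) {
  x <- as.numeric(cci_fraction)
  if (any(!is.finite(x)) || any(x < 0 | x >= 1)) {
    stop("CCI must be a fraction in [0, 1)")
  }
  1 / (x + offset)
}

#' Linear model specification for RAP
#'
#' A normalized linear form: \code{RAP = intercept + sum(coef_i * g_i(x_i)
#' / denom_i)} where \code{g} is the identity for ordinary features and the
#' inverse-shifted transform for CCI.  Dividing each term by its maximum
#' value makes the multiplicative weights directly comparable across
#' features of different units.
#'
#' @param intercept Intercept in mmHg.
#' @param terms Data frame with columns \code{feature}, \code{coefficient},
#'   \code{denominator} and \code{transform} (\code{"identity"} or
#'   \code{"inv_cci"}).
#' @param cci_offset Offset of the CCI transform, default 0.3.
#' @return Object of class \code{linear_model_spec}.
#' @export
linear_model_spec <- function(intercept, terms, cci_offset = 0.3) {
  stopifnot(is.data.frame(terms),
            all(c("feature", "coefficient", "denominator", "transform")
                %in% names(terms)))
  if (any(terms$denominator <= 0)) stop("denominators must be positive")
  if (!all(terms$transform %in% c("identity", "inv_cci"))) {
    stop("unknown transform in model terms")
  }
  structure(list(intercept = as.numeric(intercept), terms = terms,
                 cci_offset = cci_offset),
            class = "linear_model_spec")
}

#' @export
print.linear_model_spec <- function(x, ...) {
  cat(sprintf("<linear_model_spec: intercept %.4g mmHg, %d terms>\n",
              x$intercept, nrow(x$terms)))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' The published six-feature linear model for RAP
#'
#' The selected model: \code{RAP = 0.26 + 11.59 PAWP/33.7 + 3.89 TAPSE/35
#' - 8.28 (E/E')/30 - 2.3 TRd/4 + 3.693 / (CCI + 0.3) + 2.82 D/34}, with
#' PAWP in mmHg, TAPSE in mm, TRd as a 0--4 grade, CCI as a fraction and
#' the IVC diameter D in mm.  Each identity term is divided by the maximum
#' value of its feature so the weights are comparable.
#'
#' The typeset source of the CCI term is ambiguous: the default
#' (\code{cci_parse = "unit"}) reads 3.693 as the full weight of
#' \code{1/(CCI + 0.3)} with unit denominator, consistent with how every
#' other term flattens.  The alternative (\code{"max"}) reads 3.69 divided
#' by the maximum attainable transformed value \code{1/0.3}.
#'
#' @param cci_parse \code{"unit"} (default) or \code{"max"}.
#' @return A [linear_model_spec()].
#' @export
published_lm_spec <- function(cci_parse = c("unit", "max")) {
  cci_parse <- match.arg(cci_parse)
  cci_den <- if (cci_parse == "unit") 1 else 1 / 0.3
  terms <- data.frame(
    feature = c("PAWP", "TAPSE", "EoverEprime", "TRd", "CCI", "IVCd"),
    coefficient = c(11.59, 3.89, -8.28, -2.3, 3.693, 2.82),
    denominator = c(33.7, 35, 30, 4, cci_den, 34),
    transform = c("identity", "identity", "identity", "identity",
                  "inv_cci", "identity"),
    stringsAsFactors = FALSE
  )
  linear_model_spec(0.26, terms)
}

lm_design <- function(table, spec) {
  X <- matrix(NA_real_, nrow = nrow(table), ncol = nrow(spec$terms))
  colnames(X) <- spec$terms$feature
  for (i in seq_len(nrow(spec$terms))) {
    f <- spec$terms$feature[i]
    if (!f %in% names(table)) stop("missing feature: ", f)
    v <- table[[f]]
    if (spec$terms$transform[i] == "inv_cci") {
      v <- ifelse(is.na(v), NA_real_, 1 / (v + spec$cci_offset))
    }
    X[, i] <- v / spec$terms$denominator[i]
  }
  X
}

#' Predict continuous RAP with a linear model specification
#'
#' @param newdata Data frame of patient records with the model's feature
#'   columns (already imputed; a missing value is an error naming the
#'   feature).
#' @param spec A [linear_model_spec()], e.g. [published_lm_spec()].
#' @return Numeric vector of RAP estimates in mmHg.
#' @export
lm_predict <- function(newdata, spec) {
  stopifnot(inherits(spec, "linear_model_spec"))
  X <- lm_design(newdata, spec)
  bad <- colnames(X)[colSums(is.na(X)) > 0]
  if (length(bad) > 0L) {
    stop("missing value in feature(s): ", paste(bad, collapse = ", "),
         " (impute before prediction)")
  }
  as.numeric(spec$intercept + X %*% spec$terms$coefficient)
}

#' Fit the normalized linear RAP model by ordinary least squares
#'
#' Regressors are the (transformed) features divided by their
#' denominators: either supplied (e.g. the published maxima) or derived
#' from the data as the maximum absolute transformed value.  Rows with a
#' missing feature or RAP are dropped.  CCI always enters through the
#' inverse-shifted transform.
#'
#' @param table Patient feature table with an \code{RAP} column (mmHg).
#' @param features Feature names to include.
#' @param denominators Optional named vector of denominators; unnamed
#'   features get data-derived maxima.
#' @param cci_offset Offset of the CCI transform.
#' @return A fitted [linear_model_spec()] with attribute \code{"n_used"}.
#' @export
lm_fit <- function(table, features, denominators = NULL, cci_offset = 0.3) {
  if (!"RAP" %in% names(table)) stop("table must contain an RAP column")
  missing_feat <- setdiff(features, names(table))
  if (length(missing_feat) > 0L) {
    stop("missing feature: ", paste(missing_feat, collapse = ", "))
  }
  transform <- ifelse(features == "CCI", "inv_cci", "identity")
  raw <- matrix(NA_real_, nrow = nrow(table), ncol = length(features),
                dimnames = list(NULL, features))
  for (i in seq_along(features)) {
    v <- table[[features[i]]]
    if (transform[i] == "inv_cci") {
      v <- ifelse(is.na(v), NA_real_, 1 / (v + cci_offset))
    }
    raw[, i] <- v
  }
  keep <- complete.cases(raw) & !is.na(table$RAP)
  raw <- raw[keep, , drop = FALSE]
  y <- table$RAP[keep]
  if (nrow(raw) < length(features) + 2L) {
    stop("need at least n_features + 2 complete rows to fit")
  }
  den <- vapply(seq_along(features), function(i) {
    nm <- features[i]
    if (!is.null(denominators) && nm %in% names(denominators)) {
      denominators[[nm]]
    } else {
      max(abs(raw[, i]))
    }
  }, numeric(1))
  if (any(den <= 0)) stop("constant-zero feature: cannot normalize")
  X <- sweep(raw, 2, den, "/")
  fit <- lm(y ~ X)
  b <- coef(fit)
  if (any(is.na(b))) {
    collinear <- features[is.na(b[-1])]
    stop("rank-deficient design; collinear feature(s): ",
         paste(collinear, collapse = ", "))
  }
  spec <- linear_model_spec(
    unname(b[1]),
    data.frame(feature = features, coefficient = unname(b[-1]),
               denominator = den, transform = transform,
               stringsAsFactors = FALSE),
    cci_offset = cci_offset
  )
  attr(spec, "n_used") <- nrow(raw)
  spec
}

#' Fit a one-vs-all radial-basis SVM for the three RAP classes
#'
#' Features are z-scored with the training-set centre and scale (a radial
#' kernel on raw mixed-unit clinical features is degenerate), then one
#' binary radial-basis machine is trained per class against the other two.
#' Prediction takes the argmax of the three decision values, ties broken
#' toward the lower class label.
#'
#' @param table Patient feature table with an \code{RAP} column.
#' @param features Feature names (numeric columns).
#' @param cost SVM cost parameter C, default 1.
#' @param gamma Radial-kernel width; default \code{1 / n_features} on the
#'   standardized features.
#' @return Object of class \code{svm_spec} holding the three machines and
#'   the standardization parameters.
#' @export
svm_fit <- function(table, features, cost = 1, gamma = NULL) {
  if (!"RAP" %in% names(table)) stop("table must contain an RAP column")
  raw <- as.matrix(table[, features, drop = FALSE])
  keep <- complete.cases(raw) & !is.na(table$RAP)
  raw <- raw[keep, , drop = FALSE]
  cls <- rap_to_class(table$RAP[keep])
  if (length(unique(cls)) < 3L) {
    stop("all three RAP classes must be present in the training data")
  }
  center <- colMeans(raw)
  scale_ <- apply(raw, 2, sd)
  scale_[scale_ == 0] <- 1
  Z <- scale(raw, center = center, scale = scale_)
  if (is.null(gamma)) gamma <- 1 / length(features)
  machines <- lapply(1:3, function(k) {
    yk <- factor(ifelse(cls == k, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x = Z, y = yk, kernel = "radial", cost = cost,
               gamma = gamma, scale = FALSE)
  })
  structure(list(machines = machines, center = center, scale = scale_,
                 features = features, cost = cost, gamma = gamma),
            class = "svm_spec")
}

#' Predict RAP classes with a fitted one-vs-all SVM
#'
#' @param newdata Data frame with the model's feature columns (imputed).
#' @param spec An \code{svm_spec} from [svm_fit()].
#' @return Integer classes in \code{1:3}.
#' @export
svm_predict <- function(newdata, spec) {
  stopifnot(inherits(spec, "svm_spec"))
  raw <- as.matrix(newdata[, spec$features, drop = FALSE])
  if (any(is.na(raw))) {
    bad <- spec$features[colSums(is.na(raw)) > 0]
    stop("missing value in feature(s): ", paste(bad, collapse = ", "))
  }
  Z <- scale(raw, center = spec$center, scale = spec$scale)
  dv <- vapply(1:3, function(k) {
    p <- predict(spec$machines[[k]], Z, decision.values = TRUE)
    d <- as.numeric(attr(p, "decision.values"))
    # orient so that positive means "this class"
    if (grepl("^neg/", colnames(attr(p, "decision.values"))[1])) -d else d
  }, numeric(nrow(Z)))
  dv <- matrix(dv, ncol = 3L)
  apply(dv, 1, which.max)  # first max -> tie toward lower class
}

#' Median imputation of missing values
#'
#' Each missing numeric entry is replaced by the median of the observed
#' values of its column; the categorical rhythm column is imputed with its
#' mode.  By default statistics come from the table itself (whole-table
#' mode); pass \code{stats} computed on a training fold for leakage-safe
#' imputation of held-out rows.
#'
#' @param table Patient feature table.
#' @param stats Optional statistics from [imputation_stats()].
#' @param columns Columns to impute (default: canonical feature columns
#'   present in the table).
#' @return The imputed table, with the statistics used attached as
#'   attribute \code{"imputation_stats"}.
#' @export
impute_missing <- function(table, stats = NULL, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(ivc_feature_columns(), names(table))
  }
  if (is.null(stats)) stats <- imputation_stats(table, columns)
  for (nm in intersect(columns, names(table))) {
    miss <- is.na(table[[nm]])
    if (!any(miss)) next
    if (nm == "Rhythm") {
      table[[nm]][miss] <- stats$rhythm_mode
    } else {
      if (!nm %in% names(stats$medians) || is.na(stats$medians[[nm]])) {
        stop("cannot impute column '", nm, "': no observed values")
      }
      table[[nm]][miss] <- stats$medians[[nm]]
    }
  }
  attr(table, "imputation_stats") <- stats
  table
}

#' @rdname impute_missing
#' @export
imputation_stats <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- intersect(ivc_feature_columns(), names(table))
  }
  num_cols <- setdiff(intersect(columns, names(table)), "Rhythm")
  medians <- vapply(num_cols, function(nm) {
    v <- table[[nm]][!is.na(table[[nm]])]
    if (length(v) == 0L) NA_real_ else median(v)
  }, numeric(1))
  rhythm_mode <- NA_character_
  if ("Rhythm" %in% names(table)) {
    obs <- table$Rhythm[!is.na(table$Rhythm)]
    if (length(obs) > 0L) {
      tab <- table(factor(obs, levels = rhythm_levels()))
      rhythm_mode <- names(tab)[which.max(tab)]
    }
  }
  list(medians = medians, rhythm_mode = rhythm_mode)
}

#' Serialize / restore a linear model specification as JSON
#'
#' @param spec A [linear_model_spec()].
#' @param path JSON path.
#' @return The path / the restored spec.
#' @export
save_lm_spec <- function(spec, path) {
  stopifnot(inherits(spec, "linear_model_spec"))
  jsonlite::write_json(
    list(intercept = spec$intercept, terms = spec$terms,
         cci_offset = spec$cci_offset),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_lm_spec
#' @export
load_lm_spec <- function(path) {
  x <- jsonlite::fromJSON(path)
  linear_model_spec(x$intercept, as.data.frame(x$terms), x$cci_offset)
}
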