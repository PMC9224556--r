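test_that("the guidelines rule reproduces the size/collapse truth table", {
  # four quadrants
  q <- guidelines_classify(c(1.8, 2.5, 1.8, 2.5), c(0.60, 0.30, 0.30, 0.60))
  expect_identical(q$class, c(1L, 3L, 2L, 2L))
  expect_equal(q$rap_low, c(0, 10, 5, 5))
  expect_equal(q$rap_high, c(5, 20, 10, 10))
  # boundary lines fall in "the other cases" (strict inequalities)
  b <- guidelines_classify(c(2.1, 2.1, 1.8, 2.5, 2.1),
                           c(0.50, 0.60, 0.50, 0.50, 0.30))
  expect_identical(b$class, rep(2L, 5))
  expect_error(guidelines_classify(-1, 0.5), "positive")
  expect_error(guidelines_classify(2, 1.5), "\\[0, 1\\]")
})

test_that("RAP thresholds at 5 and 10 mmHg define the three classes", {
  expect_identical(rap_to_class(c(0, 5, 5.01, 10, 10.01, 24)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(rap_to_class(-0.1), "nonnegative")
})

test_that("the inverse-shifted CCI transform matches hand values", {
  expect_equal(transform_cci(0), 1 / 0.3, tolerance = 1e-12)
  expect_equal(transform_cci(0.7), 1.0, tolerance = 1e-12)
  expect_equal(transform_cci(0.42), 1 / 0.72, tolerance = 1e-12)
  expect_error(transform_cci(1.2), "fraction")
})

test_that("lm_predict evaluates the published equation exactly", {
  spec <- published_lm_spec()
  # intercept-only behaviour with the CCI term removed
  no_cci <- linear_model_spec(0.26, spec$terms[spec$terms$feature != "CCI", ])
  zeros <- data.frame(PAWP = 0, TAPSE = 0, EoverEprime = 0, TRd = 0, IVCd = 0)
  expect_equal(lm_predict(zeros, no_cci), 0.26, tolerance = 1e-12)
  # a feature at its printed maximum contributes exactly its weight
  pawp_only <- zeros; pawp_only$PAWP <- 33.7
  expect_equal(lm_predict(pawp_only, no_cci), 0.26 + 11.59, tolerance = 1e-12)
  # central patient against the independent hand evaluation
  central <- data.frame(PAWP = 15, TAPSE = 19, EoverEprime = 12, TRd = 2,
                        CCI = 0.42, IVCd = 19)
  expect_equal(lm_predict(central, spec),
               hand_lm(15, 19, 12, 2, 0.42, 19), tolerance = 1e-9)
  # missing features are reported by name
  expect_error(lm_predict(zeros, spec), "CCI")
  na_row <- central; na_row$TAPSE <- NA
  expect_error(lm_predict(na_row, spec), "TAPSE")
})

test_that("lm_predict matches hand evaluation on several feature vectors", {
  spec <- published_lm_spec()
  cases <- data.frame(
    PAWP = c(15, 33.7, 5, 28, 10),
    TAPSE = c(19, 35, 12, 25, 8),
    EoverEprime = c(12, 30, 6, 20, 15),
    TRd = c(2, 4, 0, 3, 1),
    CCI = c(0.42, 0, 0.7, 0.15, 0.55),
    IVCd = c(19, 34, 12, 28, 22))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], expect_equal(
      lm_predict(cases[i, ], spec),
      hand_lm(PAWP, TAPSE, EoverEprime, TRd, CCI, IVCd),
      tolerance = 1e-9))
  }
})

test_that("both parses of the CCI term are available", {
  unit <- published_lm_spec("unit")
  mx <- published_lm_spec("max")
  expect_equal(unit$terms$denominator[unit$terms$feature == "CCI"], 1)
  expect_equal(mx$terms$denominator[mx$terms$feature == "CCI"], 1 / 0.3)
})

test_that("OLS refit recovers a generating linear model exactly on noiseless data", {
  sim <- simulate_cohort(n = 170, seed = 11, noise_sd = 0)
  spec <- sim$generating_spec
  den <- setNames(spec$terms$denominator, spec$terms$feature)
  fit <- lm_fit(sim$table, spec$terms$feature, denominators = den)
  expect_equal(fit$terms$coefficient, spec$terms$coefficient,
               tolerance = 1e-6)
  expect_equal(fit$intercept, spec$intercept, tolerance = 1e-6)
})

test_that("degenerate designs are diagnosed", {
  withr::with_seed(2, {
    tab <- data.frame(PAWP = rnorm(30, 15, 7), TAPSE = rnorm(30, 19, 6))
    tab$RAP <- rep(7, 30)
  })
  # constant outcome: zero slopes, intercept at the constant
  fit <- lm_fit(tab, c("PAWP", "TAPSE"))
  expect_equal(fit$terms$coefficient, c(0, 0), tolerance = 1e-10)
  expect_equal(fit$intercept, 7, tolerance = 1e-10)
  # duplicated column: rank deficiency named
  tab$PAWP2 <- tab$PAWP
  tab$RAP <- tab$PAWP / 2
  expect_error(lm_fit(tab, c("PAWP", "PAWP2")), "collinear.*PAWP2")
})

test_that("the one-vs-all radial SVM separates well-separated classes", {
  withr::with_seed(42, {
    n <- 20
    tab <- data.frame(
      PAWP = c(rnorm(n, -4, .5), rnorm(n, 0, .5), rnorm(n, 4, .5)),
      TAPSE = c(rnorm(n, 4, .5), rnorm(n, -4, .5), rnorm(n, 0, .5)),
      RAP = rep(c(2, 8, 15), each = n))
    m <- svm_fit(tab, c("PAWP", "TAPSE"))
    pred <- svm_predict(tab, m)
    expect_equal(mean(pred == rap_to_class(tab$RAP)), 1.0)
    # permutation invariance of the fitted decision rule
    perm <- sample(nrow(tab))
    m2 <- svm_fit(tab[perm, , drop = FALSE], c("PAWP", "TAPSE"))
    expect_identical(svm_predict(tab, m2), pred)
  })
  # memorizing one point per class
  tiny <- data.frame(PAWP = c(0, 5, 10), TAPSE = c(0, 5, 0),
                     RAP = c(2, 8, 15))
  mt <- svm_fit(tiny, c("PAWP", "TAPSE"), cost = 10)
  expect_identical(svm_predict(tiny, mt), c(1L, 2L, 3L))
  # a class missing from training is an error
  two <- data.frame(PAWP = rnorm(10), TAPSE = rnorm(10),
                    RAP = rep(c(2, 8), 5))
  expect_error(svm_fit(two, c("PAWP", "TAPSE")), "three RAP classes")
})

test_that("median imputation fills exactly the missing cells", {
  tab <- data.frame(TAPSE = c(1, 2, NA, 4), PAWP = c(10, NA, 14, 18),
                    Rhythm = c("sinus", "sinus", NA, "afib"))
  imp <- impute_missing(tab)
  expect_equal(imp$TAPSE[3], 2)          # median of {1, 2, 4}
  expect_equal(imp$PAWP[2], 14)
  expect_identical(imp$Rhythm[3], "sinus")
  # no missing values: identity
  full <- data.frame(TAPSE = 1:4, PAWP = 5:8)
  expect_identical(impute_missing(full)[names(full)], full)
  # fully missing column is an error
  gone <- data.frame(TAPSE = c(NA_real_, NA_real_, NA_real_))
  expect_error(impute_missing(gone), "TAPSE")
  # training statistics applied to held-out rows (leakage-safe path)
  st <- imputation_stats(tab)
  held <- data.frame(TAPSE = NA_real_, PAWP = 99, Rhythm = "pacing")
  imp2 <- impute_missing(held, stats = st)
  expect_equal(imp2$TAPSE, 2)
  expect_equal(imp2$PAWP, 99)
})

test_that("thresholded predictions are consistent with the class definition", {
  spec <- published_lm_spec()
  withr::with_seed(7, {
    tab <- draw <- simulate_cohort(n = 60, seed = 7, missing_rates = NULL)$table
  })
  rap <- lm_predict(tab, spec)
  cls <- rap_to_class(pmax(rap, 0))
  expect_true(all(cls[rap <= 5] == 1L))
  expect_true(all(cls[rap > 5 & rap <= 10] == 2L))
  expect_true(all(cls[rap > 10] == 3L))
})

test_that("linear model specs survive JSON serialization", {
  spec <- published_lm_spec()
  path <- withr::local_tempfile(fileext = ".json")
  save_lm_spec(spec, path)
  spec2 <- load_lm_spec(path)
  expect_equal(spec2$intercept, spec$intercept)
  expect_equal(spec2$terms$coefficient, spec$terms$coefficient)
  expect_equal(spec2$terms$denominator, spec$terms$denominator)
  central <- data.frame(PAWP = 15, TAPSE = 19, EoverEprime = 12, TRd = 2,
                        CCI = 0.42, IVCd = 19)
  expect_equal(lm_predict(central, spec2), lm_predict(central, spec),
               tolerance = 1e-12)
})
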