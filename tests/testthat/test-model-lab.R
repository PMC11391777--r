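# Small linear regression problem shared across the model tests.
make_linear_data <- function(n, p = 6, sd = 0, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(paste0("r", seq_len(n)),
                              paste0("x", seq_len(p))))
  y <- 5 + 2 * x[, 1] - 1.5 * x[, 2] + stats::rnorm(n, 0, sd)
  list(x = x, y = y)
}

# A learner that always predicts the training mean; used as a hand-checkable
# oracle inside nested CV.
constant_mean_learner <- function() {
  phoptima:::new_learner(
    "const", "constant mean",
    fit = function(x, y, params) mean(y),
    predict = function(model, x) rep(model, nrow(x)),
    defaults = list(dummy = 1),
    grid = data.frame(dummy = 1))
}

test_that("rmse matches its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_equal(rmse(4, 1), 3)
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  set.seed(2)
  y <- rnorm(20)
  yh <- rnorm(20)
  expect_gte(rmse(y, yh), 0)
  expect_equal(rmse(y, y), 0)
})

test_that("the screening rule is a pure function of the RMSE pairs", {
  sel <- apply_screen_rule(rmse_train = c(0.5, 0.2, 1.2),
                           rmse_val = c(0.7, 2.0, 1.29))
  expect_equal(sel, c(TRUE, FALSE, TRUE))
  # boundary: val exactly at the cutoff passes; gap exactly 0.30 passes
  expect_true(apply_screen_rule(1.0, 1.30))
  expect_true(apply_screen_rule(1.0, 1.299))
  expect_false(apply_screen_rule(1.0, 1.301))
  expect_true(apply_screen_rule(1.0, 1.30, screen_cutoffs(1.30, 0.30)))
  expect_false(apply_screen_rule(0.5, 0.81))
  expect_false(apply_screen_rule(NA, 1.0))
})

test_that("screening fits the roster and reports failures", {
  dat <- make_linear_data(60, sd = 0.3)
  report <- screen_learners(dat$x[1:45, ], dat$y[1:45],
                            dat$x[46:60, ], dat$y[46:60], seed = 3)
  expect_s3_class(report, "screen_report")
  expect_equal(nrow(report), 5L)
  expect_true(any(report$selected))
  expect_true(all(!report$failed))
  expect_equal(report$selected,
               apply_screen_rule(report$rmse_train, report$rmse_val))

  # a learner that errors is captured as failed, never selected
  broken <- list(bad = phoptima:::new_learner(
    "bad", "always errors",
    fit = function(x, y, params) stop("boom"),
    predict = function(model, x) rep(0, nrow(x)),
    defaults = list(), grid = data.frame(a = 1)))
  expect_warning(rep2 <- screen_learners(dat$x[1:45, ], dat$y[1:45],
                                         dat$x[46:60, ], dat$y[46:60],
                                         roster = broken),
                 "no learner passed")
  expect_true(rep2$failed)
  expect_false(rep2$selected)
})

test_that("nested CV returns the configured outer fold count and is
           reproducible", {
  dat <- make_linear_data(48, sd = 0.5)
  tm <- nested_cv("glmnet", dat$x, dat$y, seed = 7)
  expect_s3_class(tm, "tuned_model")
  expect_length(tm$outer_rmse, 3L)
  expect_equal(tm$mean_outer_rmse, mean(tm$outer_rmse))
  tm2 <- nested_cv("glmnet", dat$x, dat$y, seed = 7)
  expect_identical(tm$outer_rmse, tm2$outer_rmse)
  expect_identical(tm$best_params, tm2$best_params)
  expect_identical(predict(tm, dat$x), predict(tm2, dat$x))

  tm5 <- nested_cv(constant_mean_learner(), dat$x, dat$y,
                   outer_folds = 5L, seed = 7)
  expect_length(tm5$outer_rmse, 5L)
})

test_that("a realizable linear hypothesis is fit to near-zero error", {
  dat <- make_linear_data(60, sd = 0)
  ols <- phoptima:::new_learner(
    "ols", "ordinary least squares",
    fit = function(x, y, params) stats::lm.fit(cbind(1, x), y)$coefficients,
    predict = function(model, x) as.numeric(cbind(1, x) %*% model),
    defaults = list(dummy = 1), grid = data.frame(dummy = 1))
  tm <- nested_cv(ols, dat$x, dat$y, seed = 5)
  expect_lt(tm$mean_outer_rmse, 1e-6)
  expect_lt(rmse(dat$y, predict(tm, dat$x)), 1e-6)
})

test_that("outer-fold scores of a constant-mean learner match hand
           computation", {
  dat <- make_linear_data(30, sd = 1, seed = 9)
  seed <- 13
  tm <- nested_cv(constant_mean_learner(), dat$x, dat$y, seed = seed)
  # reproduce the fold partition and the per-fold arithmetic by hand
  folds <- phoptima:::cv_folds(30, 3, phoptima:::derive_seed(seed,
                                                             "outer"))
  expected <- vapply(folds, function(test_idx) {
    mu <- mean(dat$y[-test_idx])
    sqrt(mean((dat$y[test_idx] - mu)^2))
  }, 0.0)
  expect_equal(tm$outer_rmse, unname(expected), tolerance = 1e-12)
})

test_that("nested CV validates its inputs", {
  dat <- make_linear_data(30)
  expect_error(nested_cv("glmnet", dat$x[1:5, ], dat$y[1:5]),
               "2 rows per outer fold")
  expect_error(nested_cv("glmnet", dat$x, dat$y,
                         grid = data.frame(alpha = numeric(0))[0, ,
                                                               drop = FALSE]),
               "empty search space")
  expect_warning(nested_cv(constant_mean_learner(), dat$x,
                           rep(1, 30), seed = 1), "constant target")
})

test_that("learning curves span the default 41-point grid", {
  dat <- make_linear_data(60, sd = 0.5)
  expect_length(seq(0.20, 1.00, by = 0.02), 41L)
  curve <- learning_curve("glmnet", NULL, dat$x[1:45, ], dat$y[1:45],
                          dat$x[46:60, ], dat$y[46:60],
                          fractions = c(0.2, 0.6, 1.0), seed = 2)
  expect_equal(nrow(curve), 3L)
  expect_equal(curve$n, c(9, 27, 45))
  # fraction 1 reproduces the full-data fit
  lrn <- make_learner("glmnet")
  set.seed(phoptima:::derive_seed(2, "curve-fit:45"))
  full <- lrn$fit(dat$x[1:45, ], dat$y[1:45], lrn$defaults)
  expect_equal(curve$rmse_train[3],
               rmse(dat$y[1:45], lrn$predict(full, dat$x[1:45, ])))
  expect_error(learning_curve("glmnet", NULL, dat$x[1:45, ],
                              dat$y[1:45], dat$x[46:60, ],
                              dat$y[46:60], fractions = 0.02),
               "< 2 rows")
})

test_that("learning-curve subsets are nested across fractions", {
  dat <- make_linear_data(40)
  seen <- list()
  recorder <- phoptima:::new_learner(
    "rec", "records training rows",
    fit = function(x, y, params) {
      seen[[length(seen) + 1]] <<- sort(rownames(x))
      mean(y)
    },
    predict = function(model, x) rep(model, nrow(x)),
    defaults = list(), grid = data.frame(a = 1))
  learning_curve(recorder, NULL, dat$x, dat$y, dat$x, dat$y,
                 fractions = c(0.2, 0.4, 0.8), seed = 4)
  expect_true(all(seen[[1]] %in% seen[[2]]))
  expect_true(all(seen[[2]] %in% seen[[3]]))
})

test_that("batch prediction enforces the schema and flags outliers", {
  dat <- make_linear_data(10)
  const <- phoptima:::new_learner(
    "c", "constant",
    fit = function(x, y, params) params$value,
    predict = function(model, x) rep(model, nrow(x)),
    defaults = list(value = 15.2), grid = data.frame(value = 15.2))
  m1 <- nested_cv(const, dat$x, dat$y, seed = 1)
  m2 <- nested_cv(const, dat$x, dat$y,
                  grid = data.frame(value = 6.5), seed = 1)
  models <- list(a = m1, b = m2)
  preds <- predict_batch(models, dat$x)
  expect_equal(dim(preds), c(10L, 2L))
  expect_true(all(preds[, "a"] == 15.2))
  expect_true(all(preds[, "b"] == 6.5))
  # out-of-range predictions are preserved and flagged, never clipped
  oor <- attr(preds, "out_of_range")
  expect_true(all(oor[, "a"]))
  expect_false(any(oor[, "b"]))

  xbad <- dat$x[, rev(colnames(dat$x))]
  expect_error(predict_batch(models, xbad), "schema")
})
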