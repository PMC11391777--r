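# Metric, learner screening, nested cross-validated tuning, learning curves
# and batch prediction. `nested_cv()` is the package's central fitting
# routine; it returns a classed `tuned_model` with the usual print /
# summary / predict methods.

#' Root mean squared error
#'
#' \eqn{\sqrt{\frac{1}{n}\sum_i (y_i - \hat y_i)^2}} — the screening and
#' tuning metric throughout.
#'
#' @param y Observed values.
#' @param yhat Predicted values (same length).
#' @return Non-negative scalar.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0) stop("empty vectors", call. = FALSE)
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y - yhat)^2))
}

#' Screening cutoffs for native learner selection
#'
#' A learner is retained when its validation RMSE is at most
#' \code{max_val_rmse} and the absolute train/validation RMSE gap is at
#' most \code{max_train_val_gap} (guards against over- and under-fitting).
#'
#' @param max_val_rmse Maximum validation RMSE; default 1.30.
#' @param max_train_val_gap Maximum |RMSE_train - RMSE_val|; default 0.30.
#' @return A \code{screen_cutoffs} list.
#' @export
screen_cutoffs <- function(max_val_rmse = 1.30, max_train_val_gap = 0.30) {
  stopifnot(max_val_rmse > 0, max_train_val_gap > 0)
  structure(list(max_val_rmse = max_val_rmse,
                 max_train_val_gap = max_train_val_gap),
            class = "screen_cutoffs")
}

#' Apply the screening rule to train/validation RMSE pairs
#'
#' Pure rule: selected iff \code{rmse_val <= max_val_rmse} and
#' \code{|rmse_train - rmse_val| <= max_train_val_gap}.
#'
#' @param rmse_train,rmse_val Numeric vectors of per-learner RMSE values.
#' @param cutoffs A \code{screen_cutoffs}.
#' @return Logical vector of verdicts.
#' @export
apply_screen_rule <- function(rmse_train, rmse_val,
                              cutoffs = screen_cutoffs()) {
  eps <- 1e-9  # keep the inclusive boundaries robust to rounding
  !is.na(rmse_val) & !is.na(rmse_train) &
    rmse_val <= cutoffs$max_val_rmse + eps &
    abs(rmse_train - rmse_val) <= cutoffs$max_train_val_gap + eps
}

#' Screen a learner roster at default hyperparameters
#'
#' Fits every roster learner with its defaults on the training set and
#' applies the screening rule to its train/validation RMSE. Learners that
#' fail to fit are reported as failed, never selected.
#'
#' @param x_train,y_train Training features (matrix) and targets.
#' @param x_val,y_val Validation features and targets (disjoint rows).
#' @param roster Named list of \code{phop_learner}s;
#'   default [default_roster()].
#' @param cutoffs A \code{screen_cutoffs}.
#' @param seed Integer seed controlling any fit randomness.
#' @return A \code{screen_report} data.frame with columns \code{learner},
#'   \code{rmse_train}, \code{rmse_val}, \code{selected}, \code{failed}.
#' @export
screen_learners <- function(x_train, y_train, x_val, y_val,
                            roster = default_roster(),
                            cutoffs = screen_cutoffs(), seed = 1L) {
  stopifnot(length(roster) > 0)
  rows <- lapply(names(roster), function(nm) {
    lrn <- roster[[nm]]
    res <- tryCatch({
      set.seed(derive_seed(seed, paste0("screen:", nm)))
      model <- lrn$fit(x_train, y_train, lrn$defaults)
      c(rmse(y_train, lrn$predict(model, x_train)),
        rmse(y_val, lrn$predict(model, x_val)))
    }, error = function(e) c(NA_real_, NA_real_))
    data.frame(learner = nm, rmse_train = res[1], rmse_val = res[2],
               failed = anyNA(res), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  report$selected <- apply_screen_rule(report$rmse_train, report$rmse_val,
                                       cutoffs)
  if (!any(report$selected)) {
    warning("no learner passed the screening cutoffs", call. = FALSE)
  }
  attr(report, "cutoffs") <- cutoffs
  class(report) <- c("screen_report", "data.frame")
  report
}

#' @export
print.screen_report <- function(x, ...) {
  co <- attr(x, "cutoffs")
  cat(sprintf(
    "learner screening (val RMSE <= %.2f, |train-val| <= %.2f):\n",
    co$max_val_rmse, co$max_train_val_gap))
  df <- as.data.frame(x)
  df$rmse_train <- round(df$rmse_train, 3)
  df$rmse_val <- round(df$rmse_val, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

derive_seed <- function(master, tag) {
  as.integer((as.numeric(master) %% 65521 * 31013 +
                sum(utf8ToInt(tag)) * 97) %% 2147483647)
}

cv_folds <- function(n, k, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) sort(perm[fold_of == f]))
}

# Inner-loop grid search: mean CV RMSE per grid row; returns the index of
# the best row (ties broken by declaration order).
grid_search_cv <- function(learner, x, y, grid, folds, seed) {
  scores <- rep(NA_real_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- utils::modifyList(learner$defaults,
                                as.list(grid[g, , drop = FALSE]))
    fold_rmse <- rep(NA_real_, length(folds))
    for (f in seq_along(folds)) {
      test_idx <- folds[[f]]
      ok <- tryCatch({
        set.seed(derive_seed(seed, sprintf("inner:%d:%d", g, f)))
        model <- learner$fit(x[-test_idx, , drop = FALSE], y[-test_idx],
                             params)
        fold_rmse[f] <- rmse(y[test_idx],
                             learner$predict(model,
                                             x[test_idx, , drop = FALSE]))
        TRUE
      }, error = function(e) FALSE)
      if (!ok) break
    }
    scores[g] <- mean(fold_rmse)
  }
  if (all(is.na(scores))) stop("every grid point failed", call. = FALSE)
  list(best = which.min(scores), scores = scores)
}

#' Nested cross-validated hyperparameter tuning
#'
#' For each outer fold, an exhaustive grid search scored by inner-CV mean
#' RMSE selects hyperparameters, and the held-out fold yields an unbiased
#' outer RMSE. The final hyperparameters are those minimizing the inner-CV
#' score on the full data, and the final predictor is refit on all rows.
#' When the grid exceeds \code{max_grid} points a seeded random subset of
#' \code{max_grid} rows is searched instead.
#'
#' @param learner A \code{phop_learner} (or learner name).
#' @param x Feature matrix.
#' @param y Numeric target vector.
#' @param grid Hyperparameter grid (data.frame); defaults to the learner's.
#' @param inner_folds Inner CV folds; default 5.
#' @param outer_folds Outer CV folds; default 3.
#' @param seed Integer seed controlling all fold assignment and fit
#'   randomness.
#' @param max_grid Grid budget before switching to seeded random search.
#' @return A \code{tuned_model} with elements \code{learner},
#'   \code{best_params}, \code{outer_rmse}, \code{mean_outer_rmse},
#'   \code{outer_params}, \code{model} (final fit on all rows) and
#'   \code{feature_names}.
#' @export
nested_cv <- function(learner, x, y, grid = NULL, inner_folds = 5L,
                      outer_folds = 3L, seed = 1L, max_grid = 200L) {
  if (is.character(learner)) learner <- make_learner(learner)
  x <- as.matrix(x)
  if (nrow(x) < outer_folds * 2) {
    stop("need at least 2 rows per outer fold", call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    warning("constant target values", call. = FALSE)
  }
  if (is.null(grid)) grid <- learner$grid
  if (nrow(grid) == 0) stop("empty search space", call. = FALSE)
  if (nrow(grid) > max_grid) {
    set.seed(derive_seed(seed, "grid-subsample"))
    grid <- grid[sample.int(nrow(grid), max_grid), , drop = FALSE]
  }
  outer <- cv_folds(nrow(x), outer_folds, derive_seed(seed, "outer"))
  outer_rmse <- rep(NA_real_, outer_folds)
  outer_params <- vector("list", outer_folds)
  for (o in seq_len(outer_folds)) {
    test_idx <- outer[[o]]
    x_tr <- x[-test_idx, , drop = FALSE]
    y_tr <- y[-test_idx]
    inner <- cv_folds(nrow(x_tr), inner_folds,
                      derive_seed(seed, paste0("inner-folds:", o)))
    gs <- grid_search_cv(learner, x_tr, y_tr, grid, inner,
                         derive_seed(seed, paste0("gs:", o)))
    params <- utils::modifyList(learner$defaults,
                                as.list(grid[gs$best, , drop = FALSE]))
    outer_params[[o]] <- params
    set.seed(derive_seed(seed, paste0("outer-fit:", o)))
    model <- learner$fit(x_tr, y_tr, params)
    outer_rmse[o] <- rmse(y[test_idx],
                          learner$predict(model,
                                          x[test_idx, , drop = FALSE]))
  }
  inner_full <- cv_folds(nrow(x), inner_folds,
                         derive_seed(seed, "inner-folds:full"))
  gs_full <- grid_search_cv(learner, x, y, grid, inner_full,
                            derive_seed(seed, "gs:full"))
  best_params <- utils::modifyList(learner$defaults,
                                   as.list(grid[gs_full$best, ,
                                                drop = FALSE]))
  set.seed(derive_seed(seed, "final-fit"))
  final <- learner$fit(x, y, best_params)
  structure(list(learner = learner, best_params = best_params,
                 outer_rmse = outer_rmse,
                 mean_outer_rmse = mean(outer_rmse),
                 outer_params = outer_params, model = final,
                 feature_names = colnames(x), seed = seed),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  cat(sprintf("tuned '%s' model; mean outer-CV RMSE %.3f over %d folds\n",
              x$learner$name, x$mean_outer_rmse, length(x$outer_rmse)))
  invisible(x)
}

#' @export
summary.tuned_model <- function(object, ...) {
  cat(sprintf("learner:         %s (%s)\n", object$learner$name,
              object$learner$label))
  cat(sprintf("outer-fold RMSE: %s\n",
              paste(sprintf("%.3f", object$outer_rmse), collapse = ", ")))
  cat(sprintf("mean outer RMSE: %.3f\n", object$mean_outer_rmse))
  cat("final hyperparameters:\n")
  for (nm in names(object$best_params)) {
    cat(sprintf("  %s = %s\n", nm,
                format(object$best_params[[nm]])))
  }
  invisible(object)
}

#' @export
predict.tuned_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!identical(colnames(newdata), object$feature_names)) {
    stop("feature columns do not match the training schema ",
         "(names and order must be identical)", call. = FALSE)
  }
  object$learner$predict(object$model, newdata)
}

#' Learning curve over nested training subsets
#'
#' Refits a learner at fixed hyperparameters on nested random subsets of
#' the training set (default 20\% to 100\% in 2\% steps; subsets are
#' monotone by construction, so each larger fraction contains the smaller
#' ones) and records training-subset and validation RMSE.
#'
#' @param learner A \code{phop_learner} or learner name.
#' @param params Hyperparameter list (e.g. a tuned model's
#'   \code{best_params}); \code{NULL} = learner defaults.
#' @param x_train,y_train Training features and targets.
#' @param x_val,y_val Validation features and targets.
#' @param fractions Subset fractions in (0, 1].
#' @param seed Integer seed for the subset draw.
#' @return Data.frame with \code{fraction}, \code{n}, \code{rmse_train},
#'   \code{rmse_val}.
#' @export
learning_curve <- function(learner, params = NULL, x_train, y_train,
                           x_val, y_val,
                           fractions = seq(0.20, 1.00, by = 0.02),
                           seed = 1L) {
  if (is.character(learner)) learner <- make_learner(learner)
  if (is.null(params)) params <- learner$defaults
  stopifnot(all(fractions > 0), all(fractions <= 1))
  n <- nrow(x_train)
  set.seed(derive_seed(seed, "curve"))
  perm <- sample.int(n)
  rows <- lapply(fractions, function(f) {
    m <- round(f * n)
    if (m < 2) stop(sprintf("fraction %.2f yields < 2 rows", f),
                    call. = FALSE)
    idx <- perm[seq_len(m)]
    set.seed(derive_seed(seed, sprintf("curve-fit:%d", m)))
    model <- learner$fit(x_train[idx, , drop = FALSE], y_train[idx], params)
    data.frame(
      fraction = f, n = m,
      rmse_train = rmse(y_train[idx],
                        learner$predict(model,
                                        x_train[idx, , drop = FALSE])),
      rmse_val = rmse(y_val, learner$predict(model, x_val)))
  })
  do.call(rbind, rows)
}

#' Batch prediction across several tuned models
#'
#' @param models Named list of \code{tuned_model}s sharing one feature
#'   schema.
#' @param x Feature matrix whose columns match that schema exactly.
#' @return Numeric matrix (rows x models) with an \code{out_of_range}
#'   attribute flagging predictions outside \[0, 14\] (kept unclipped).
#' @export
predict_batch <- function(models, x) {
  stopifnot(length(models) > 0)
  x <- as.matrix(x)
  preds <- vapply(models, function(m) predict(m, x),
                  numeric(nrow(x)))
  preds <- matrix(preds, nrow = nrow(x),
                  dimnames = list(rownames(x), names(models)))
  attr(preds, "out_of_range") <- preds < 0 | preds > 14
  preds
}
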