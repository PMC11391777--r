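# Learner roster for pH-optimum regression. Each learner is a small object
# bundling a fit function, a predict function, default hyperparameters and
# a tuning grid, so screening / nested CV / curves treat all learners
# uniformly. The roster mirrors the usual small-data regression suspects:
# random forest, gradient-boosted trees, k-nearest neighbours, a penalized
# linear model, and a piecewise-linear hinge-basis regressor.

new_learner <- function(name, label, fit, predict, defaults, grid) {
  structure(list(name = name, label = label, fit = fit, predict = predict,
                 defaults = defaults, grid = grid),
            class = "phop_learner")
}

#' @export
print.phop_learner <- function(x, ...) {
  cat(sprintf("learner '%s' (%s); %d-point tuning grid\n", x$name, x$label,
              nrow(x$grid)))
  invisible(x)
}

#' Construct a roster learner by name
#'
#' Available learners: \code{"rf"} (random forest), \code{"gbt"}
#' (gradient-boosted trees), \code{"knn"} (k-nearest-neighbour regression),
#' \code{"glmnet"} (penalized linear model) and \code{"hinge"} (forward
#' stepwise piecewise-linear hinge-basis regression).
#'
#' @param name Learner name.
#' @return A \code{phop_learner} object.
#' @export
make_learner <- function(name) {
  switch(
    name,
    rf = new_learner(
      "rf", "random forest",
      fit = function(x, y, params) {
        mtry <- max(1L, round(params$mtry_frac * ncol(x)))
        randomForest::randomForest(
          x = x, y = y, ntree = params$ntree, mtry = mtry,
          nodesize = params$nodesize)
      },
      predict = function(model, x) unname(stats::predict(model, x)),
      defaults = list(ntree = 500L, mtry_frac = 1 / 3, nodesize = 5L),
      grid = expand.grid(ntree = 500L, mtry_frac = c(0.2, 1 / 3, 0.6),
                         nodesize = c(3L, 5L, 10L))),
    gbt = new_learner(
      "gbt", "gradient-boosted trees",
      fit = function(x, y, params) {
        dtrain <- xgboost::xgb.DMatrix(x, label = y)
        xgboost::xgb.train(
          params = list(max_depth = params$max_depth, eta = params$eta,
                        objective = "reg:squarederror", nthread = 1L),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
      },
      predict = function(model, x) {
        unname(stats::predict(model, xgboost::xgb.DMatrix(x)))
      },
      defaults = list(nrounds = 100L, max_depth = 3L, eta = 0.1),
      grid = expand.grid(nrounds = c(50L, 100L, 200L),
                         max_depth = c(2L, 3L, 4L), eta = c(0.05, 0.1, 0.3))),
    knn = new_learner(
      "knn", "k-nearest-neighbour regression",
      fit = function(x, y, params) {
        k <- min(params$k, nrow(x))
        caret::knnreg(x, y, k = k)
      },
      predict = function(model, x) unname(stats::predict(model, x)),
      defaults = list(k = 5L),
      grid = expand.grid(k = c(3L, 5L, 7L, 9L, 11L))),
    glmnet = new_learner(
      "glmnet", "penalized linear model",
      fit = function(x, y, params) {
        path <- glmnet::glmnet(x, y, alpha = params$alpha)
        # freeze the coefficient vector at the requested penalty so
        # prediction is a single affine map
        cf <- as.numeric(stats::predict(path, type = "coefficients",
                                        s = params$lambda))
        list(coefficients = cf)
      },
      predict = function(model, x) {
        as.numeric(cbind(1, x) %*% model$coefficients)
      },
      defaults = list(alpha = 1, lambda = 0.01),
      grid = expand.grid(alpha = c(0, 0.5, 1),
                         lambda = c(0.001, 0.01, 0.1, 1))),
    hinge = new_learner(
      "hinge", "piecewise-linear hinge-basis regression",
      fit = function(x, y, params) fit_hinge(x, y, params$max_terms),
      predict = function(model, x) predict_hinge(model, x),
      defaults = list(max_terms = 10L),
      grid = expand.grid(max_terms = c(5L, 10L, 15L, 20L))),
    stop("unknown learner: ", name, call. = FALSE))
}

#' Default learner roster
#'
#' @return Named list of the five roster \code{phop_learner}s.
#' @export
default_roster <- function() {
  names <- c("rf", "gbt", "knn", "glmnet", "hinge")
  stats::setNames(lapply(names, make_learner), names)
}

# Forward stepwise regression on hinge (rectified linear) basis functions:
# candidate knots at feature quantiles, greedy RSS-minimizing selection of
# mirrored hinge terms up to max_terms basis columns. A small stand-in for
# multivariate adaptive regression splines.
fit_hinge <- function(x, y, max_terms = 10L, n_knots = 7L) {
  x <- as.matrix(x)
  n <- nrow(x)
  cand <- list()
  for (j in seq_len(ncol(x))) {
    xs <- unique(stats::quantile(x[, j], probs = seq_len(n_knots) /
                                   (n_knots + 1), names = FALSE))
    for (t in xs) {
      if (min(x[, j]) < t && t < max(x[, j])) {
        cand[[length(cand) + 1]] <- list(j = j, t = t, sign = 1)
        cand[[length(cand) + 1]] <- list(j = j, t = t, sign = -1)
      }
    }
  }
  hinge_col <- function(term, xm) {
    if (term$sign > 0) pmax(xm[, term$j] - term$t, 0)
    else pmax(term$t - xm[, term$j], 0)
  }
  basis <- matrix(1, n, 1)
  terms <- list()
  rss <- sum((y - mean(y))^2)
  while (length(terms) < max_terms && length(cand) > 0) {
    best <- NULL
    best_rss <- rss - 1e-10
    for (ci in seq_along(cand)) {
      b <- cbind(basis, hinge_col(cand[[ci]], x))
      fit <- stats::lm.fit(b, y)
      r <- sum(fit$residuals^2)
      if (is.finite(r) && r < best_rss) {
        best <- ci
        best_rss <- r
      }
    }
    if (is.null(best)) break
    terms[[length(terms) + 1]] <- cand[[best]]
    basis <- cbind(basis, hinge_col(cand[[best]], x))
    cand[[best]] <- NULL
    rss <- best_rss
  }
  fit <- stats::lm.fit(basis, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  structure(list(terms = terms, coefficients = coefs),
            class = "hinge_model")
}

predict_hinge <- function(model, x) {
  x <- as.matrix(x)
  basis <- matrix(1, nrow(x), 1)
  for (term in model$terms) {
    col <- if (term$sign > 0) pmax(x[, term$j] - term$t, 0)
           else pmax(term$t - x[, term$j], 0)
    basis <- cbind(basis, col)
  }
  as.numeric(basis %*% model$coefficients)
}
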