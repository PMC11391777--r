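# Model interpretation: permutation feature importance (shuffle one column,
# compare metric to baseline), Monte-Carlo Shapley attributions, their
# global mean-|value| summary, and feature-type weights of the top-ranked
# features.

model_predict <- function(model, x) {
  if (inherits(model, "tuned_model")) {
    predict(model, x)
  } else if (is.function(model)) {
    model(x)
  } else {
    stop("model must be a tuned_model or a prediction function",
         call. = FALSE)
  }
}

#' Permutation feature importance
#'
#' In each repetition every feature column is independently shuffled and
#' the importance recorded as shuffled-metric / baseline-metric (ratio
#' mode, the default) or shuffled - baseline (difference mode). The report
#' carries the median, 5\% and 95\% quantiles over repetitions per feature.
#' A perfect model (zero baseline metric) falls back to difference mode
#' with a message, since the ratio is undefined.
#'
#' @param model A \code{tuned_model} or a function \code{f(x) -> yhat}.
#' @param x Feature matrix (>= 2 rows) with column names.
#' @param y Target vector.
#' @param metric Error metric \code{metric(y, yhat)}; default [rmse()].
#' @param repetitions Number of shuffle repetitions; default 100.
#' @param seed Integer seed; fixed seed gives bit-identical reports.
#' @param mode \code{"ratio"} or \code{"difference"}.
#' @param feature_type Optional per-column type tags (e.g. from a
#'   \code{feature_table}) carried into the report.
#' @return An \code{importance_report} data.frame with \code{feature},
#'   \code{feature_type}, \code{median}, \code{q05}, \code{q95}.
#' @export
permutation_importance <- function(model, x, y, metric = rmse,
                                   repetitions = 100L, seed = 1L,
                                   mode = c("ratio", "difference"),
                                   feature_type = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need >= 2 rows", call. = FALSE)
  baseline <- metric(y, model_predict(model, x))
  if (baseline == 0 && mode == "ratio") {
    message("zero baseline metric; importance reported as difference")
    mode <- "difference"
  }
  p <- ncol(x)
  n <- nrow(x)
  imp <- matrix(NA_real_, repetitions, p, dimnames = list(NULL,
                                                          colnames(x)))
  set.seed(derive_seed(seed, "perm-importance"))
  for (r in seq_len(repetitions)) {
    # one stacked prediction per repetition: block j holds the data with
    # only feature j shuffled
    big <- x[rep(seq_len(n), p), , drop = FALSE]
    for (j in seq_len(p)) {
      big[((j - 1) * n + 1):(j * n), j] <- x[sample.int(n), j]
    }
    preds <- model_predict(model, big)
    for (j in seq_len(p)) {
      m <- metric(y, preds[((j - 1) * n + 1):(j * n)])
      imp[r, j] <- if (mode == "ratio") m / baseline else m - baseline
    }
  }
  report <- data.frame(
    feature = colnames(x),
    feature_type = if (is.null(feature_type)) NA_character_ else
      feature_type,
    median = apply(imp, 2, stats::median),
    q05 = apply(imp, 2, stats::quantile, probs = 0.05, names = FALSE),
    q95 = apply(imp, 2, stats::quantile, probs = 0.95, names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "mode") <- mode
  attr(report, "baseline") <- baseline
  class(report) <- c("importance_report", "data.frame")
  report
}

#' Monte-Carlo Shapley values for one instance
#'
#' Sampling estimator of Shapley attributions: for each of
#' \code{sample_size} draws, a random feature permutation and a random
#' background row are taken and the features of the instance are switched
#' in one at a time along the permutation; the prediction increments are
#' the marginal contributions. By the telescoping construction the
#' contributions of each draw sum exactly to f(instance) - f(background
#' row), so local accuracy holds up to Monte-Carlo error in the background
#' expectation.
#'
#' @param model A \code{tuned_model} or prediction function.
#' @param instance Single row (vector or 1 x p matrix) on the model schema.
#' @param background Background feature matrix (non-empty).
#' @param sample_size Number of permutation/background draws; default 50.
#' @param seed Integer seed.
#' @return Named numeric vector of per-feature contributions, with
#'   attribute \code{se} (per-feature Monte-Carlo standard errors).
#' @export
shapley_values <- function(model, instance, background, sample_size = 50L,
                           seed = 1L) {
  background <- as.matrix(background)
  if (nrow(background) == 0) stop("empty background", call. = FALSE)
  instance <- matrix(as.numeric(instance), 1,
                     dimnames = list(NULL, colnames(background)))
  p <- ncol(background)
  contrib <- matrix(0, sample_size, p,
                    dimnames = list(NULL, colnames(background)))
  set.seed(derive_seed(seed, "shapley"))
  for (s in seq_len(sample_size)) {
    perm <- sample.int(p)
    z <- background[sample.int(nrow(background), 1), ]
    walk <- matrix(rep(z, p + 1), p + 1, p, byrow = TRUE,
                   dimnames = list(NULL, colnames(background)))
    for (k in seq_len(p)) {
      walk[(k + 1):(p + 1), perm[k]] <- instance[1, perm[k]]
    }
    preds <- model_predict(model, walk)
    contrib[s, perm] <- diff(preds)
  }
  out <- colMeans(contrib)
  attr(out, "se") <- apply(contrib, 2, stats::sd) / sqrt(sample_size)
  out
}

#' Global mean absolute Shapley importance
#'
#' Averages |Shapley value| per feature over a set of instances (a seeded
#' subsample of at most \code{n_instances} rows of \code{x}).
#'
#' @param model A \code{tuned_model} or prediction function.
#' @param x Feature matrix whose rows are explained.
#' @param background Background matrix; defaults to \code{x}.
#' @param sample_size Permutation draws per instance; default 50.
#' @param n_instances Maximum number of instances explained; default 50.
#' @param seed Integer seed.
#' @param feature_type Optional per-column type tags.
#' @return A \code{shap_report} data.frame with \code{feature},
#'   \code{feature_type}, \code{mean_abs_shap}.
#' @export
mean_abs_shap <- function(model, x, background = x, sample_size = 50L,
                          n_instances = 50L, seed = 1L,
                          feature_type = NULL) {
  x <- as.matrix(x)
  set.seed(derive_seed(seed, "shap-instances"))
  idx <- if (nrow(x) > n_instances) {
    sample.int(nrow(x), n_instances)
  } else {
    seq_len(nrow(x))
  }
  abs_sum <- rep(0, ncol(x))
  for (k in seq_along(idx)) {
    sv <- shapley_values(model, x[idx[k], , drop = FALSE], background,
                         sample_size = sample_size,
                         seed = derive_seed(seed, paste0("shap:", k)))
    abs_sum <- abs_sum + abs(sv)
  }
  report <- data.frame(
    feature = colnames(x),
    feature_type = if (is.null(feature_type)) NA_character_ else
      feature_type,
    mean_abs_shap = abs_sum / length(idx),
    stringsAsFactors = FALSE, row.names = NULL)
  class(report) <- c("shap_report", "data.frame")
  report
}

#' Feature-type weights among the top-ranked features
#'
#' Among the \code{top_k} features of an importance or SHAP report (ranked
#' by the report's own score), the fraction belonging to each feature type.
#' Weights sum to 1.
#'
#' @param report An \code{importance_report} (ranked by \code{median}) or
#'   \code{shap_report} (ranked by \code{mean_abs_shap}), with
#'   \code{feature_type} tags filled in.
#' @param top_k Number of top features considered; default 20.
#' @return Named numeric vector of weights per feature type.
#' @export
feature_type_weights <- function(report, top_k = 20L) {
  if (nrow(report) < top_k) {
    stop("report has fewer than top_k features", call. = FALSE)
  }
  if (anyNA(report$feature_type)) {
    stop("report lacks feature_type tags", call. = FALSE)
  }
  score <- if ("mean_abs_shap" %in% names(report)) {
    report$mean_abs_shap
  } else {
    report$median
  }
  top <- report$feature_type[order(-score)][seq_len(top_k)]
  tab <- table(top) / top_k
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}
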