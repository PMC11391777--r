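# Turning per-model pH predictions into a vetted candidate list: alkaline
# threshold, multi-learner consensus, cophenetic-distance window against
# reference laccase sets, and per-candidate verdict summaries.

#' Candidate filter configuration
#'
#' @param ph_threshold Predicted pH optimum threshold (inclusive, pH >=);
#'   default 7.0.
#' @param min_learners Minimum number of models that must predict at or
#'   above the threshold; default 3.
#' @param cd_lower,cd_upper Strict cophenetic-distance window to the
#'   alkaline reference set; defaults 1.1 and 1.5.
#' @param require_closer_than_neutral When TRUE (default) a candidate must
#'   additionally lie closer (in minimum cophenetic distance) to the
#'   alkaline references than to the neutral ones.
#' @return A \code{candidate_filter_config} list.
#' @export
candidate_filter_config <- function(ph_threshold = 7.0, min_learners = 3L,
                                    cd_lower = 1.1, cd_upper = 1.5,
                                    require_closer_than_neutral = TRUE) {
  stopifnot(cd_lower > 0, cd_lower < cd_upper, min_learners >= 1)
  structure(list(ph_threshold = ph_threshold,
                 min_learners = as.integer(min_learners),
                 cd_lower = cd_lower, cd_upper = cd_upper,
                 require_closer_than_neutral = require_closer_than_neutral),
            class = "candidate_filter_config")
}

#' Consensus candidates across learners
#'
#' A row passes when at least \code{min_learners} model columns predict a
#' pH optimum at or above \code{ph_threshold}. Out-of-range predictions
#' count toward the comparison as-is.
#'
#' @param predictions Numeric matrix (rows = sequences, columns = models)
#'   with row names as sequence ids.
#' @param config A \code{candidate_filter_config}.
#' @return Data.frame with \code{id}, \code{pass_count}, \code{consensus}.
#' @export
consensus_candidates <- function(predictions,
                                 config = candidate_filter_config()) {
  predictions <- as.matrix(predictions)
  stopifnot(ncol(predictions) >= 1)
  counts <- rowSums(predictions >= config$ph_threshold)
  data.frame(id = rownames(predictions), pass_count = as.integer(counts),
             consensus = counts >= config$min_learners,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cophenetic-distance filter against reference laccases
#'
#' A candidate passes when its minimum cophenetic distance to the alkaline
#' reference set lies strictly inside (\code{cd_lower}, \code{cd_upper})
#' and — unless disabled or the neutral set is empty — its minimum distance
#' to the neutral references exceeds that to the alkaline ones.
#'
#' @param candidate_ids Character vector of candidate leaf ids.
#' @param cd Cophenetic distance matrix over tree leaves (e.g. from
#'   [cophenetic_distances()]).
#' @param alkaline_ids,neutral_ids Reference leaf id sets (disjoint from
#'   the candidates).
#' @param config A \code{candidate_filter_config}.
#' @return Data.frame with per-candidate \code{min_cd_alkaline},
#'   \code{min_cd_neutral}, \code{cd_window_pass}, \code{closer_pass},
#'   \code{pass}.
#' @export
cophenetic_filter <- function(candidate_ids, cd, alkaline_ids,
                              neutral_ids = character(0),
                              config = candidate_filter_config()) {
  all_ids <- c(candidate_ids, alkaline_ids, neutral_ids)
  missing <- setdiff(all_ids, rownames(cd))
  if (length(missing) > 0) {
    stop("id(s) absent from the cophenetic matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(intersect(candidate_ids, c(alkaline_ids, neutral_ids))) > 0) {
    stop("reference sets must be disjoint from the candidates",
         call. = FALSE)
  }
  min_alk <- apply(cd[candidate_ids, alkaline_ids, drop = FALSE], 1, min)
  min_neu <- if (length(neutral_ids) > 0) {
    apply(cd[candidate_ids, neutral_ids, drop = FALSE], 1, min)
  } else {
    rep(NA_real_, length(candidate_ids))
  }
  window_pass <- min_alk > config$cd_lower & min_alk < config$cd_upper
  closer_pass <- if (config$require_closer_than_neutral &&
                     length(neutral_ids) > 0) {
    min_neu > min_alk
  } else {
    rep(TRUE, length(candidate_ids))
  }
  data.frame(id = candidate_ids, min_cd_alkaline = unname(min_alk),
             min_cd_neutral = unname(min_neu),
             cd_window_pass = unname(window_pass),
             closer_pass = unname(closer_pass),
             pass = unname(window_pass & closer_pass),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-candidate distribution of model predictions
#'
#' @param predictions Numeric matrix (rows = candidates, columns = models).
#' @param config A \code{candidate_filter_config} (for the unanimity
#'   threshold).
#' @return Data.frame with \code{id}, \code{min}, \code{median},
#'   \code{max}, \code{unanimous} (all models at or above the threshold)
#'   and \code{out_of_range} (any prediction outside \[0, 14\]).
#' @export
verdict_distribution <- function(predictions,
                                 config = candidate_filter_config()) {
  predictions <- as.matrix(predictions)
  stopifnot(ncol(predictions) >= 1)
  data.frame(
    id = rownames(predictions),
    min = apply(predictions, 1, min),
    median = apply(predictions, 1, stats::median),
    max = apply(predictions, 1, max),
    unanimous = apply(predictions >= config$ph_threshold, 1, all),
    out_of_range = apply(predictions < 0 | predictions > 14, 1, any),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' End-to-end candidate selection
#'
#' Applies the consensus rule to the prediction matrix, then the
#' cophenetic-distance filter to the consensus survivors, and reports one
#' verdict row per input sequence with all stage flags.
#'
#' @param predictions Numeric prediction matrix (rows = sequences,
#'   columns = models) with row names.
#' @param cd Cophenetic distance matrix over the tree leaves.
#' @param alkaline_ids,neutral_ids Reference leaf id sets.
#' @param config A \code{candidate_filter_config}.
#' @return A \code{candidate_verdicts} data.frame; \code{final} is TRUE
#'   only when every stage flag is TRUE.
#' @export
select_candidates <- function(predictions, cd, alkaline_ids,
                              neutral_ids = character(0),
                              config = candidate_filter_config()) {
  cons <- consensus_candidates(predictions, config)
  dist <- verdict_distribution(predictions, config)
  out <- merge(cons, dist, by = "id", sort = FALSE)
  out$min_cd_alkaline <- NA_real_
  out$min_cd_neutral <- NA_real_
  out$cd_window_pass <- FALSE
  out$closer_pass <- FALSE
  surv <- out$id[out$consensus]
  if (length(surv) > 0) {
    cf <- cophenetic_filter(surv, cd, alkaline_ids, neutral_ids, config)
    j <- match(cf$id, out$id)
    out$min_cd_alkaline[j] <- cf$min_cd_alkaline
    out$min_cd_neutral[j] <- cf$min_cd_neutral
    out$cd_window_pass[j] <- cf$cd_window_pass
    out$closer_pass[j] <- cf$closer_pass
  }
  out$final <- out$consensus & out$cd_window_pass & out$closer_pass
  class(out) <- c("candidate_verdicts", "data.frame")
  out
}

#' @export
print.candidate_verdicts <- function(x, ...) {
  cat(sprintf("candidate selection: %d/%d sequences pass all filters\n",
              sum(x$final), nrow(x)))
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
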