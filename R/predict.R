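#' Posterior-averaged response predictions
#'
#' Predicts a subject's response probabilities for novel trials by averaging
#' the ideal-observer response probabilities over all retained posterior
#' draws. The trials may come from a different task than the one the
#' posterior was fitted on: the subjective distribution (and the fitted
#' observer parameters with it) transfers, which is what makes across-task
#' prediction possible at all.
#'
#' @param object A `cogtomo_fit`.
#' @param trials A single-task trial tibble.
#' @param ... Unused.
#' @return A prediction tibble: `trial_id`, `task`, `source_task`, and
#'   response probabilities `p1`, `p2` (`p3` for odd-one-out); probability
#'   columns sum to one per row.
#' @export
predict.cogtomo_fit <- function(object, trials, ...) {
  if (n_draws(object) < 1) stop("fit has no draws", call. = FALSE)
  trials <- validate_trials(trials)
  task <- single_task(trials)
  S <- stim_matrix(trials, task)
  nd <- n_draws(object)
  K <- object$prior$K
  log_u <- log(uniform_density(object$space))
  acc <- 0
  for (i in seq_len(nd)) {
    acc <- acc + cpp_response_prob(
      S, n_alternatives(task),
      object$draws$weights[i, ], matrix(object$draws$means[i, ], K),
      matrix(object$draws$covs[i, ], K),
      object$draws$sigma_p[i], object$draws$temperature[i],
      object$draws$lapse[i], log_u
    )
  }
  finish_prediction(acc / nd, trials, task, source_task = object$task)
}

#' @keywords internal
finish_prediction <- function(p, trials, task, source_task) {
  p <- unname(as.matrix(p))
  out <- tibble::tibble(
    trial_id = trials$trial_id, task = task, source_task = source_task,
    p1 = p[, 1], p2 = p[, 2]
  )
  if (ncol(p) == 3) out$p3 <- p[, 3]
  out
}

#' @keywords internal
prediction_matrix <- function(pred) {
  cols <- intersect(c("p1", "p2", "p3"), names(pred))
  p <- as.matrix(pred[, cols])
  p[, colSums(is.na(p)) < nrow(p), drop = FALSE]
}

#' Predictive performance on observed responses
#'
#' Scores a prediction table against the subject's actual choices. The
#' default metric is the mean probability assigned to the chosen
#' alternative (threshold-free); `"accuracy"` scores the fraction of trials
#' whose argmax prediction matches the choice, the natural companion of the
#' consistency-derived upper bound. Chance is `1/2` for familiarity and
#' `1/3` for odd-one-out under either metric.
#'
#' @param pred A prediction tibble (see [predict.cogtomo_fit()]).
#' @param responses The matching response tibble (same trials, same order by
#'   `trial_id`).
#' @param metric `"prob"` or `"accuracy"`.
#' @return A scalar in `[0, 1]`.
#' @export
predictive_performance <- function(pred, responses,
                                   metric = c("prob", "accuracy")) {
  metric <- match.arg(metric)
  responses <- validate_trials(responses, responses = TRUE)
  if (nrow(pred) != nrow(responses) ||
    !all(pred$trial_id == responses$trial_id)) {
    stop("prediction and response tables are misaligned", call. = FALSE)
  }
  if (unique(pred$task) != single_task(responses)) {
    stop("prediction task does not match response task", call. = FALSE)
  }
  p <- prediction_matrix(pred)
  idx <- cbind(seq_len(nrow(p)), responses$choice + 1L)
  if (metric == "prob") {
    mean(p[idx])
  } else {
    mean(max.col(p, ties.method = "first") == responses$choice + 1L)
  }
}

#' Model-free response consistency from repeated trials
#'
#' Over all unordered pairs of presentations within each repeat group, the
#' fraction that received the identical choice, pooled across groups. A
#' model-free measure of a subject's reliability: it upper-bounds how well
#' any predictor can do (see [consistency_upper_bound()]).
#'
#' @param responses A response tibble with `repeat_group` set on at least
#'   one group of >= 2 presentations.
#' @return A scalar in `[0, 1]`.
#' @export
consistency_score <- function(responses) {
  responses <- validate_trials(responses, responses = TRUE)
  grp <- responses |>
    dplyr::filter(!is.na(.data$repeat_group)) |>
    dplyr::group_by(.data$repeat_group) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      pairs = dplyr::n() * (dplyr::n() - 1) / 2,
      same = sum(choose(table(.data$choice), 2)),
      .groups = "drop"
    )
  if (nrow(grp) == 0) {
    stop("no repeat_group with >= 2 presentations", call. = FALSE)
  }
  sum(grp$same) / sum(grp$pairs)
}

#' Consistency-derived upper bound on predictive performance
#'
#' Under a symmetric response model in which the subject picks one
#' (majority) option with probability `p` and splits the rest equally, the
#' probability of giving the same answer twice is `c = p^2 + (1-p)^2` for
#' two alternatives and `c = p^2 + (1-p)^2 / 2` for three. Inverting gives
#' the majority probability `p = (1 + sqrt(2c - 1)) / 2` (n = 2) or
#' `p = (1 + sqrt(6c - 2)) / 3` (n = 3), which is the best expected
#' per-trial accuracy of any predictor that knows the subject's response
#' distribution. The bound is strictly increasing in `c`.
#'
#' @param c Consistency score, at least the chance level `1/n_alternatives`.
#' @param n_alternatives 2 (familiarity) or 3 (odd-one-out).
#' @return The bound, a scalar in `[1/n_alternatives, 1]`.
#' @export
consistency_upper_bound <- function(c, n_alternatives) {
  stopifnot(n_alternatives %in% c(2, 3), length(c) == 1)
  chance_c <- 1 / n_alternatives
  if (c < chance_c - 1e-12) {
    stop("consistency ", c, " below chance level ", chance_c, call. = FALSE)
  }
  c <- max(c, chance_c)
  if (n_alternatives == 2) {
    (1 + sqrt(2 * c - 1)) / 2
  } else {
    (1 + sqrt(6 * c - 2)) / 3
  }
}

#' Chance performance level for a task
#' @param task `"familiarity"` or `"odd_one_out"`.
#' @return `1/2` or `1/3`.
#' @export
chance_level <- function(task) 1 / n_alternatives(task)

#' Evaluate predictions against responses in one report
#'
#' Bundles [predictive_performance()] (both metrics), the standard error of
#' the per-trial assigned probability, chance level, and — when repeats are
#' present — [consistency_score()] and [consistency_upper_bound()].
#'
#' @inheritParams predictive_performance
#' @return A one-row tibble.
#' @export
evaluate_predictions <- function(pred, responses) {
  task <- unique(pred$task)
  p <- prediction_matrix(pred)
  responses <- validate_trials(responses, responses = TRUE)
  per_trial <- p[cbind(seq_len(nrow(p)), responses$choice + 1L)]
  has_rep <- any(!is.na(responses$repeat_group) &
    duplicated(responses$repeat_group) |
    duplicated(responses$repeat_group, fromLast = TRUE) &
      !is.na(responses$repeat_group))
  cons <- if (has_rep) consistency_score(responses) else NA_real_
  tibble::tibble(
    task = task,
    source_task = unique(pred$source_task),
    n_trials = nrow(pred),
    performance = mean(per_trial),
    performance_se = stats::sd(per_trial) / sqrt(length(per_trial)),
    accuracy = predictive_performance(pred, responses, "accuracy"),
    chance = chance_level(task),
    consistency = cons,
    upper_bound = if (has_rep) {
      consistency_upper_bound(max(cons, 1 / n_alternatives(task)),
        n_alternatives(task)
      )
    } else {
      NA_real_
    }
  )
}
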