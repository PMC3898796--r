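# Reusable validation experiments on synthetic observers. These drive the
# package's own evidence that the inversion works: parameter recovery,
# in-silico task invariance and transfer, the consistency bound, and the
# baseline comparisons. The vignette describes the reasoning behind the
# default problem sizes.

#' Parameter-recovery experiment on a bimodal ground truth
#'
#' Simulates familiarity responses from a known two-component ground truth
#' (modes a fixed distance apart), runs the full inversion, and measures the
#' Jensen-Shannon divergence between the truth and the posterior-mean grid,
#' alongside the divergence between the truth and its own moment-matched
#' Gaussian. Successful recovery of multimodal structure means the first is
#' smaller than the second.
#'
#' @param seed Integer seed (stimuli, responses, sampler; the truth is
#'   fixed).
#' @param n_trials Simulated familiarity trials.
#' @param n_steps Sampler steps.
#' @param mode_distance Distance between the two ground-truth modes (SD).
#' @param params Generating [observer_params()].
#' @param resolution Grid resolution for the JS comparison.
#' @return A list: `js_posterior` (truth vs posterior mean, bits),
#'   `js_moment_matched` (truth vs its moment match, bits), `truth`, `fit`.
#' @export
experiment_recovery <- function(seed = 1, n_trials = 1000, n_steps = 20000,
                                mode_distance = 3,
                                params = observer_params(),
                                resolution = 100) {
  # a genuinely bimodal truth: near-equal weights, well-separated modes
  u <- mode_distance / (2 * sqrt(2))
  truth <- subjective_dist(
    weights = c(0.55, 0.45),
    means = rbind(c(-u, -u), c(u, u)),
    covariances = list(
      matrix(c(0.5, 0.1, 0.1, 0.35), 2),
      matrix(c(0.3, -0.05, -0.05, 0.55), 2)
    )
  )
  trials <- make_stimuli("familiarity", n_trials,
    repeat_fraction = 0,
    seed = seed + 1
  )
  resp <- simulate_responses(trials, truth, params, seed = seed + 2)
  fit <- fit_cogtomo(resp,
    prior = prior_config(K = 3), n_steps = n_steps,
    seed = seed + 3
  )
  tg <- to_grid(truth, resolution)
  list(
    js_posterior = js_divergence(tg, posterior_mean_grid(fit, resolution)),
    js_moment_matched = js_divergence(tg, to_grid(moment_match(truth),
      resolution
    )),
    truth = truth, fit = fit
  )
}

#' In-silico task-invariance and transfer experiment
#'
#' The package's analogue of the human study design: several synthetic
#' subjects, each with their own multimodal ground-truth prior shared across
#' both tasks, perform the familiarity and odd-one-out tasks; each task is
#' inverted independently. Returns the within- versus between-subject
#' divergence test, an MDS-ready distance matrix of all recovered priors,
#' and the across-task prediction table (fit on familiarity, predict
#' odd-one-out).
#'
#' @param seed Integer seed.
#' @param n_subjects Number of synthetic subjects.
#' @param n_trials Distinct trials per task and subject.
#' @param n_steps Sampler steps per fit (reduced relative to
#'   [experiment_recovery()]; 20 fits are run).
#' @param n_test_trials Held-out odd-one-out trials for transfer prediction.
#' @param params Generating [observer_params()].
#' @param resolution Grid resolution.
#' @return A list: `grids` (tibble subject x task with grid list-column),
#'   `invariance` (the [within_between_test()] table on JS bits),
#'   `distance_js` / `distance_sqrt` (the two `cogtomo_dist` objects),
#'   `transfer` (per-subject tibble: performance, se, chance), `truths`.
#' @export
experiment_task_invariance <- function(seed = 1, n_subjects = 10,
                                       n_trials = 500, n_steps = 4000,
                                       n_test_trials = 300,
                                       params = observer_params(),
                                       resolution = 100) {
  truths <- list()
  rows <- list()
  transfer <- list()
  for (s in seq_len(n_subjects)) {
    sseed <- seed + 100 * s
    world <- simulate_subject(sseed,
      n_trials = n_trials, K = 3,
      separation = 2.5, params = params, repeat_fraction = 0
    )
    truths[[s]] <- world$truth
    fits <- list()
    for (task in c("familiarity", "odd_one_out")) {
      fits[[task]] <- fit_cogtomo(world[[task]],
        prior = prior_config(K = 3),
        n_steps = n_steps, seed = sseed + 7
      )
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = s, task = task,
        grid = list(posterior_mean_grid(fits[[task]], resolution))
      )
    }
    test_trials <- make_stimuli("odd_one_out", n_test_trials,
      repeat_fraction = 0, seed = sseed + 11
    )
    test_resp <- simulate_responses(test_trials, world$truth, params,
      seed = sseed + 13
    )
    pred <- predict(fits$familiarity, test_trials)
    ev <- evaluate_predictions(pred, test_resp)
    ev$subject <- s
    transfer[[s]] <- ev
  }
  grids <- dplyr::bind_rows(rows)
  dm_js <- distance_matrix(grids, metric = "js_bits")
  dm_sqrt <- distance_matrix(grids, metric = "sqrt_js")
  list(
    grids = grids,
    invariance = within_between_test(dm_js),
    distance_js = dm_js,
    distance_sqrt = dm_sqrt,
    transfer = dplyr::bind_rows(transfer),
    truths = truths
  )
}

#' Consistency-bound compliance experiment
#'
#' For each seed, simulates a subject with repeated trials, scores the
#' generating model itself as a predictor (hard accuracy), and compares it
#' against the upper bound derived from the subject's measured consistency.
#' No predictor — not even the generating model — should beat the bound by
#' more than binomial sampling error.
#'
#' @param seeds Integer vector of seeds (one simulated subject each).
#' @param task Task to simulate.
#' @param n_trials Distinct trials per subject.
#' @param repeat_fraction Fraction of repeated trials.
#' @param params Generating [observer_params()].
#' @return A tibble per seed: `accuracy`, `consistency`, `bound`,
#'   `n_trials`, `excess` (accuracy minus bound), `excess_ci`
#'   (95% binomial CI half-width on the accuracy).
#' @export
experiment_bound <- function(seeds = 1:20, task = "odd_one_out",
                             n_trials = 600, repeat_fraction = 0.3,
                             params = observer_params()) {
  purrr::map_dfr(seeds, function(sd) {
    truth <- make_ground_truth(sd, K = 3, separation = 2.5)
    trials <- make_stimuli(task, n_trials,
      repeat_fraction = repeat_fraction,
      seed = sd + 1
    )
    resp <- simulate_responses(trials, truth, params, seed = sd + 2)
    p <- response_probabilities(resp, truth, params)
    pred <- finish_prediction(p, resp, task, source_task = task)
    acc <- predictive_performance(pred, resp, metric = "accuracy")
    cons <- consistency_score(resp)
    bound <- consistency_upper_bound(
      max(cons, chance_level(task)),
      n_alternatives(task)
    )
    tibble::tibble(
      seed = sd, accuracy = acc, consistency = cons, bound = bound,
      n_trials = nrow(resp), excess = acc - bound,
      excess_ci = 1.96 * sqrt(acc * (1 - acc) / nrow(resp))
    )
  })
}

#' Baseline-ordering experiment
#'
#' For each seed, simulates a multimodal subject on one task, fits the full
#' inversion on a training split, and scores three predictors on a held-out
#' split: the full posterior-averaged predictor, the moment-matched
#' Gaussian predictor, and the discriminative GP-classifier baseline. The
#' full model should win on both comparisons in the majority of seeds when
#' the ground truth has multimodal structure.
#'
#' @param seeds Integer vector of seeds.
#' @param task Task to simulate.
#' @param n_train Training trials.
#' @param n_test Held-out trials.
#' @param n_steps Sampler steps per fit.
#' @param params Generating [observer_params()].
#' @return A tibble per seed with `full`, `moment_matched`,
#'   `discriminative` mean-probability performances.
#' @export
experiment_baselines <- function(seeds = 1:20, task = "familiarity",
                                 n_train = 500, n_test = 300,
                                 n_steps = 3000,
                                 params = observer_params()) {
  purrr::map_dfr(seeds, function(sd) {
    truth <- make_ground_truth(sd, K = 3, separation = 3)
    train <- simulate_responses(
      make_stimuli(task, n_train, repeat_fraction = 0, seed = sd + 1),
      truth, params,
      seed = sd + 2
    )
    test <- simulate_responses(
      make_stimuli(task, n_test, repeat_fraction = 0, seed = sd + 3),
      truth, params,
      seed = sd + 4
    )
    fit <- fit_cogtomo(train,
      prior = prior_config(K = 3), n_steps = n_steps,
      seed = sd + 5
    )
    gp <- discriminative_fit(train,
      sigma_grid = c(0.05, 0.15, 0.4),
      n_folds = 3, seed = sd + 6
    )
    tibble::tibble(
      seed = sd,
      full = predictive_performance(predict(fit, test), test),
      moment_matched = predictive_performance(
        moment_matched_predict(fit, test), test
      ),
      discriminative = predictive_performance(
        discriminative_predict(gp, test), test
      )
    )
  })
}
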