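#' Draw a random ground-truth subjective distribution
#'
#' Generates a K-component Gaussian mixture emulating the multimodal,
#' subject-varying priors recovered from human choices: component means
#' sampled uniformly in the box subject to a minimum pairwise separation
#' (rejection sampling, capped retries), weights from a flat Dirichlet
#' simplex, and random covariances with eigen-scales drawn from
#' `eigen_range` (SD units) and a uniform rotation.
#'
#' @param seed Integer seed.
#' @param K Number of components (>= 1).
#' @param separation Minimum pairwise distance between component means
#'   (SD units).
#' @param space A [feature_space()].
#' @param eigen_range Length-2 range of covariance eigen-scales (SDs).
#' @param mean_margin Means are kept `mean_margin` SD inside the box edge so
#'   most of each component's mass stays in the box.
#' @param max_retries Cap on rejection rounds for the separation constraint.
#' @return A [subjective_dist()].
#' @export
make_ground_truth <- function(seed, K = 3, separation = 2.5,
                              space = feature_space(),
                              eigen_range = c(0.3, 1.0),
                              mean_margin = 1, max_retries = 1000) {
  stopifnot(K >= 1, separation >= 0)
  set.seed(seed)
  h <- space$half_width - mean_margin
  means <- NULL
  for (try in seq_len(max_retries)) {
    cand <- matrix(stats::runif(K * space$n_dims, -h, h), K)
    if (K == 1 || min(stats::dist(cand)) >= separation) {
      means <- cand
      break
    }
  }
  if (is.null(means)) {
    stop("could not place ", K, " means with separation ", separation,
      " in the box after ", max_retries, " tries",
      call. = FALSE
    )
  }
  w <- stats::rgamma(K, 1) # flat Dirichlet
  w <- w / sum(w)
  covs <- lapply(seq_len(K), function(k) {
    s <- stats::runif(2, eigen_range[1], eigen_range[2])
    th <- stats::runif(1, 0, pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    R %*% diag(s^2) %*% t(R)
  })
  subjective_dist(w, means, covs, space)
}

#' Generate stimulus designs for either task
#'
#' Familiarity trials pair two independent uniform draws from the box.
#' Odd-one-out trials are, for an `equidistant_fraction` of trials,
#' equilateral triads with uniform random center, orientation and side
#' length (rejection-sampled so all vertices stay in the box); the remaining
#' trials are three independent uniform draws. A `repeat_fraction` of trials
#' is presented twice with identical coordinates and a shared
#' `repeat_group`, which is what makes model-free consistency measurable.
#'
#' @param task `"familiarity"` or `"odd_one_out"`.
#' @param n_trials Number of distinct stimulus configurations.
#' @param repeat_fraction Fraction of trials duplicated (default 0.1).
#' @param equidistant_fraction Fraction of odd-one-out trials that are
#'   equilateral (default 0.9).
#' @param seed Integer seed.
#' @param space A [feature_space()].
#' @param side_range Side-length range for equilateral triads (SD units);
#'   small triads probe perceptual noise, large triads probe prior shape.
#' @param max_retries Rejection cap per triad.
#' @return A trial tibble (see [validate_trials()]) with
#'   `n_trials * (1 + repeat_fraction)` rows (rounded down).
#' @export
make_stimuli <- function(task = c("familiarity", "odd_one_out"),
                         n_trials = 1000, repeat_fraction = 0.1,
                         equidistant_fraction = 0.9, seed = 1,
                         space = feature_space(), side_range = c(1, 4),
                         max_retries = 1000) {
  task <- match.arg(task)
  stopifnot(
    repeat_fraction >= 0, repeat_fraction <= 1,
    equidistant_fraction >= 0, equidistant_fraction <= 1
  )
  set.seed(seed)
  h <- space$half_width
  if (task == "familiarity") {
    S <- matrix(stats::runif(n_trials * 4, -h, h), n_trials)
    trials <- tibble::tibble(
      trial_id = seq_len(n_trials), task = task,
      s1_x = S[, 1], s1_y = S[, 2], s2_x = S[, 3], s2_y = S[, 4],
      s3_x = NA_real_, s3_y = NA_real_, repeat_group = NA_integer_
    )
  } else {
    n_eq <- round(equidistant_fraction * n_trials)
    S <- matrix(NA_real_, n_trials, 6)
    for (i in seq_len(n_eq)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        side <- stats::runif(1, side_range[1], side_range[2])
        r <- side / sqrt(3) # circumradius of an equilateral triangle
        ctr <- stats::runif(2, -h, h)
        phi <- stats::runif(1, 0, 2 * pi)
        ang <- phi + c(0, 2, 4) * pi / 3
        v <- cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
        if (all(abs(v) <= h)) {
          S[i, ] <- as.vector(t(v))
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place an equilateral triad in the box", call. = FALSE)
      }
    }
    if (n_eq < n_trials) {
      S[(n_eq + 1):n_trials, ] <-
        matrix(stats::runif((n_trials - n_eq) * 6, -h, h), n_trials - n_eq)
    }
    S <- S[sample.int(n_trials), , drop = FALSE]
    trials <- tibble::tibble(
      trial_id = seq_len(n_trials), task = task,
      s1_x = S[, 1], s1_y = S[, 2], s2_x = S[, 3], s2_y = S[, 4],
      s3_x = S[, 5], s3_y = S[, 6], repeat_group = NA_integer_
    )
  }
  n_rep <- floor(repeat_fraction * n_trials)
  if (n_rep > 0) {
    idx <- sort(sample.int(n_trials, n_rep))
    trials$repeat_group[idx] <- seq_len(n_rep)
    dup <- trials[idx, ]
    dup$trial_id <- n_trials + seq_len(n_rep)
    trials <- dplyr::bind_rows(trials, dup)
  }
  validate_trials(trials)
}

#' Simulate a synthetic observer's responses
#'
#' For each trial, draws a choice from the ideal-observer response
#' probabilities under the given ground-truth subjective distribution and
#' observer parameters. Repeated presentations are resampled independently,
#' which is what makes a simulated subject's consistency fall below one.
#'
#' @param trials A single-task trial tibble.
#' @param P Ground-truth [subjective_dist()].
#' @param params [observer_params()].
#' @param seed Integer seed.
#' @return The trial tibble with a 0-based `choice` column appended.
#' @export
simulate_responses <- function(trials, P, params, seed) {
  trials <- validate_trials(trials)
  single_task(trials)
  p <- response_probabilities(trials, P, params)
  set.seed(seed)
  u <- stats::runif(nrow(p))
  cum <- t(apply(p, 1, cumsum))
  choice <- pmin(rowSums(u > cum), ncol(p) - 1L) # 0-based index
  trials$choice <- as.integer(choice)
  validate_trials(trials, responses = TRUE)
}

#' Simulate a full synthetic subject across both tasks
#'
#' Convenience wrapper producing a ground truth and seeded trial/response
#' tables for the familiarity and odd-one-out tasks, the substrate for
#' recovery and transfer experiments.
#'
#' @param seed Integer seed (also drives the ground truth).
#' @param n_trials Distinct trials per task.
#' @param K,separation Passed to [make_ground_truth()].
#' @param params [observer_params()].
#' @param repeat_fraction Passed to [make_stimuli()].
#' @param space A [feature_space()].
#' @return A list with `truth`, `params`, and per-task response tibbles
#'   `familiarity` and `odd_one_out`.
#' @export
simulate_subject <- function(seed, n_trials = 1000, K = 3, separation = 2.5,
                             params = observer_params(),
                             repeat_fraction = 0.1,
                             space = feature_space()) {
  truth <- make_ground_truth(seed, K = K, separation = separation,
    space = space
  )
  out <- list(truth = truth, params = params)
  for (task in c("familiarity", "odd_one_out")) {
    tr <- make_stimuli(task, n_trials,
      repeat_fraction = repeat_fraction,
      seed = seed + 1000 + (task == "odd_one_out"), space = space
    )
    out[[task]] <- simulate_responses(tr, truth, params,
      seed = seed + 2000 + (task == "odd_one_out")
    )
  }
  out
}
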