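#' Moment-matched Gaussian predictions
#'
#' The "structure-free" comparison predictor: every posterior draw's
#' subjective distribution is replaced by its moment-matched single Gaussian
#' (same mean and covariance, no multimodal detail; observer parameters
#' kept), then response probabilities are posterior-averaged exactly as in
#' [predict.cogtomo_fit()]. If the recovered fine structure were
#' behaviorally irrelevant, this predictor would do as well as the full one.
#'
#' @inheritParams predict.cogtomo_fit
#' @param object A `cogtomo_fit`.
#' @return A prediction tibble like [predict.cogtomo_fit()]'s.
#' @export
moment_matched_predict <- function(object, trials) {
  if (n_draws(object) < 1) stop("fit has no draws", call. = FALSE)
  trials <- validate_trials(trials)
  task <- single_task(trials)
  S <- stim_matrix(trials, task)
  nd <- n_draws(object)
  K <- object$prior$K
  log_u <- log(uniform_density(object$space))
  acc <- 0
  for (i in seq_len(nd)) {
    w <- object$draws$weights[i, ]
    m <- matrix(object$draws$means[i, ], K)
    cf <- matrix(object$draws$covs[i, ], K) # var_x, cov_xy, var_y
    mu <- colSums(m * w)
    vx <- sum(w * (cf[, 1] + m[, 1]^2)) - mu[1]^2
    vy <- sum(w * (cf[, 3] + m[, 2]^2)) - mu[2]^2
    cxy <- sum(w * (cf[, 2] + m[, 1] * m[, 2])) - mu[1] * mu[2]
    acc <- acc + cpp_response_prob(
      S, n_alternatives(task), 1, matrix(mu, 1),
      matrix(c(vx, cxy, vy), 1),
      object$draws$sigma_p[i], object$draws$temperature[i],
      object$draws$lapse[i], log_u
    )
  }
  finish_prediction(acc / nd, trials, task, source_task = object$task)
}

#' @keywords internal
gp_features <- function(trials, task) {
  stim_matrix(trials, task)
}

# Symmetry augmentation: familiarity trials also enter with stimuli swapped
# and the label flipped; odd-one-out trials enter under all three cyclic
# stimulus rotations with rotated labels.
#' @keywords internal
gp_augment <- function(x, y, task) {
  if (task == "familiarity") {
    xs <- x[, c(3, 4, 1, 2), drop = FALSE]
    list(x = rbind(x, xs), y = c(y, 1L - y))
  } else {
    x2 <- x[, c(3, 4, 5, 6, 1, 2), drop = FALSE] # (s2, s3, s1)
    x3 <- x[, c(5, 6, 1, 2, 3, 4), drop = FALSE] # (s3, s1, s2)
    list(x = rbind(x, x2, x3), y = c(y, (y - 1L) %% 3L, (y - 2L) %% 3L))
  }
}

#' Fit the discriminative (Gaussian-process-classifier) baseline
#'
#' A predictor with no notion of subjective distributions: a Gaussian
#' process classifier (squared-exponential kernel, via
#' [kernlab::gausspr()]) fitted directly on the trial's concatenated
#' stimulus coordinates. Training data are symmetry-augmented (stimulus
#' swap / cyclic rotations with matching label changes) so the learned
#' mapping respects the task's permutation structure. The kernel width is
#' chosen by a seeded k-fold cross-validated grid. Because it fits the
#' stimulus-to-response mapping of one task directly, it structurally
#' cannot predict the other task.
#'
#' @param responses A single-task response tibble with >= 20 rows.
#' @param sigma_grid Candidate inverse squared kernel widths for
#'   [kernlab::rbfdot()]; a single value skips cross-validation.
#' @param n_folds Cross-validation folds.
#' @param seed Integer seed (fold assignment).
#' @return An object of class `cogtomo_gp`.
#' @export
discriminative_fit <- function(responses,
                               sigma_grid = c(0.02, 0.05, 0.1, 0.2, 0.5),
                               n_folds = 5, seed = 1) {
  responses <- validate_trials(responses, responses = TRUE)
  task <- single_task(responses)
  if (nrow(responses) < 20) {
    stop("need >= 20 trials to fit the discriminative baseline",
      call. = FALSE
    )
  }
  x <- gp_features(responses, task)
  y <- responses$choice
  levs <- as.character(seq_len(n_alternatives(task)) - 1L)
  set.seed(seed)
  sigma <- sigma_grid[1]
  if (length(sigma_grid) > 1) {
    fold <- sample(rep_len(seq_len(n_folds), nrow(x)))
    score <- vapply(sigma_grid, function(sg) {
      ll <- 0
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        aug <- gp_augment(x[tr, , drop = FALSE], y[tr], task)
        m <- kernlab::gausspr(aug$x, factor(aug$y, levels = levs),
          kernel = "rbfdot", kpar = list(sigma = sg)
        )
        p <- kernlab::predict(m, x[!tr, , drop = FALSE],
          type = "probabilities"
        )
        pc <- p[cbind(seq_len(sum(!tr)), y[!tr] + 1L)]
        ll <- ll + sum(log(pmax(pc, 1e-12)))
      }
      ll
    }, numeric(1))
    sigma <- sigma_grid[which.max(score)]
  }
  aug <- gp_augment(x, y, task)
  set.seed(seed)
  model <- kernlab::gausspr(aug$x, factor(aug$y, levels = levs),
    kernel = "rbfdot", kpar = list(sigma = sigma)
  )
  structure(
    list(model = model, task = task, sigma = sigma, seed = seed),
    class = "cogtomo_gp"
  )
}

#' @export
print.cogtomo_gp <- function(x, ...) {
  cat(sprintf(
    "<cogtomo_gp> discriminative baseline, %s task, kernel sigma %g\n",
    x$task, x$sigma
  ))
  invisible(x)
}

#' Predict with the discriminative baseline
#'
#' Per-trial class probabilities, averaged over the same symmetry
#' augmentation group used in training so that, e.g., swapping the two
#' faces of a familiarity trial exactly mirrors the prediction. Trials must
#' come from the task the model was trained on; supplying the other task is
#' an error, reflecting the baseline's structural inability to generalize
#' across tasks.
#'
#' @param model A `cogtomo_gp`.
#' @param trials A trial tibble from the training task.
#' @return A prediction tibble like [predict.cogtomo_fit()]'s.
#' @export
discriminative_predict <- function(model, trials) {
  stopifnot(inherits(model, "cogtomo_gp"))
  trials <- validate_trials(trials)
  task <- single_task(trials)
  if (task != model$task) {
    stop(
      "discriminative baseline was trained on the ", model$task,
      " task and cannot predict ", task,
      " trials: it fits a stimulus-to-response mapping, not a prior",
      call. = FALSE
    )
  }
  x <- gp_features(trials, task)
  prob <- function(xx) {
    kernlab::predict(model$model, xx, type = "probabilities")
  }
  if (task == "familiarity") {
    p1 <- prob(x)
    p2 <- prob(x[, c(3, 4, 1, 2), drop = FALSE])[, c(2, 1), drop = FALSE]
    p <- (p1 + p2) / 2
  } else {
    p1 <- prob(x)
    # rotation (s2,s3,s1): its class 0 is original stimulus 2, etc.
    p2 <- prob(x[, c(3, 4, 5, 6, 1, 2), drop = FALSE])[, c(3, 1, 2),
      drop = FALSE
    ]
    p3 <- prob(x[, c(5, 6, 1, 2, 3, 4), drop = FALSE])[, c(2, 3, 1),
      drop = FALSE
    ]
    p <- (p1 + p2 + p3) / 3
  }
  p <- p / rowSums(p)
  finish_prediction(p, trials, task, source_task = task)
}
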