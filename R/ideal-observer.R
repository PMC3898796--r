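#' Observer nuisance parameters
#'
#' The non-prior parameters of the ideal observer: isotropic perceptual noise
#' (stimuli are perceived as Gaussian corruptions of the presented points,
#' covariance `perceptual_sigma^2 * I`), a decision softmax temperature (how
#' sharply hypothesis probabilities map to choices), and a lapse rate (the
#' probability of a uniformly random response).
#'
#' @param perceptual_sigma Positive perceptual noise SD, in feature-space SD
#'   units.
#' @param temperature Positive softmax sharpness applied to log hypothesis
#'   likelihoods.
#' @param lapse Lapse probability in `[0, 1]`.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(perceptual_sigma = 0.5, temperature = 3,
                            lapse = 0.05) {
  stopifnot(
    perceptual_sigma > 0, temperature > 0,
    lapse >= 0, lapse <= 1
  )
  structure(
    list(
      perceptual_sigma = perceptual_sigma,
      temperature = temperature,
      lapse = lapse
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "<observer_params> sigma_p = %g, temperature = %g, lapse = %g\n",
    x$perceptual_sigma, x$temperature, x$lapse
  ))
  invisible(x)
}

# Floor on log hypothesis likelihoods; prevents -Inf for far-outlying
# stimuli while keeping log-ratios informative over the feature box.
LOG_FLOOR <- -745

#' Familiarity-task hypothesis likelihoods
#'
#' For a two-stimulus familiarity trial, hypothesis k states that stimulus k
#' is the familiar one — a perceptual-noise-corrupted sample from the
#' subjective distribution — while the other stimulus is drawn uniformly from
#' the feature box. Integrating the latent face out analytically (a Gaussian
#' convolution) gives, for hypothesis k,
#' `u * sum_m w_m N(s_k; mu_m, Sigma_m + sigma_p^2 I)` with `u` the uniform
#' box density.
#'
#' @param trials A familiarity trial table (see [validate_trials()]).
#' @param P A [subjective_dist()].
#' @param params An [observer_params()].
#' @return An `n x 2` matrix of strictly positive hypothesis likelihoods.
#' @export
familiarity_likelihoods <- function(trials, P, params) {
  trials <- validate_trials(trials)
  if (single_task(trials) != "familiarity") {
    stop("trials must be familiarity trials", call. = FALSE)
  }
  exp(log_familiarity_likelihoods(trials, P, params))
}

#' @keywords internal
log_familiarity_likelihoods <- function(trials, P, params) {
  s2 <- params$perceptual_sigma^2
  lu <- log(uniform_density(P$space))
  l1 <- log_density_at(P, as.matrix(trials[, c("s1_x", "s1_y")]), inflate = s2)
  l2 <- log_density_at(P, as.matrix(trials[, c("s2_x", "s2_y")]), inflate = s2)
  pmax(cbind(lu + l1, lu + l2), LOG_FLOOR)
}

#' Odd-one-out hypothesis likelihoods
#'
#' For a three-stimulus odd-one-out trial, hypothesis k states that the other
#' two stimuli `{i, j}` are noisy realizations of one face sampled from the
#' subjective distribution while stimulus k is a noisy realization of an
#' independent second sample. Both latent faces integrate out analytically:
#' the pair contributes `N(s_i; s_j, 2 sigma_p^2 I) *
#' sum_m w_m N((s_i + s_j)/2; mu_m, Sigma_m + sigma_p^2/2 I)` and the
#' singleton contributes `sum_m w_m N(s_k; mu_m, Sigma_m + sigma_p^2 I)`.
#' Because all three hypotheses share the same pairwise geometry on
#' equidistant triads, choices there are driven purely by the subjective
#' distribution — stimuli near high-probability regions are easier to
#' discriminate.
#'
#' @param trials An odd-one-out trial table.
#' @inheritParams familiarity_likelihoods
#' @return An `n x 3` matrix of strictly positive hypothesis likelihoods.
#' @export
ooo_likelihoods <- function(trials, P, params) {
  trials <- validate_trials(trials)
  if (single_task(trials) != "odd_one_out") {
    stop("trials must be odd-one-out trials", call. = FALSE)
  }
  exp(log_ooo_likelihoods(trials, P, params))
}

#' @keywords internal
log_ooo_likelihoods <- function(trials, P, params) {
  s2 <- params$perceptual_sigma^2
  S <- lapply(1:3, function(i) {
    as.matrix(trials[, paste0("s", i, c("_x", "_y"))])
  })
  n <- nrow(trials)
  single <- vapply(
    S, function(x) log_density_at(P, x, inflate = s2),
    numeric(n)
  )
  single <- rbind(single) # keep matrix when n == 1
  logv <- matrix(NA_real_, n, 3)
  pairs <- list(c(2, 3), c(1, 3), c(1, 2))
  for (k in 1:3) {
    i <- pairs[[k]][1]
    j <- pairs[[k]][2]
    d <- S[[i]] - S[[j]]
    # N(s_i; s_j, 2 sigma^2 I) in 2-D
    lpair_noise <- -log(2 * pi) - log(2 * s2) -
      rowSums(d * d) / (4 * s2)
    mid <- (S[[i]] + S[[j]]) / 2
    lpair_prior <- log_density_at(P, mid, inflate = s2 / 2)
    logv[, k] <- lpair_noise + lpair_prior + single[, k]
  }
  pmax(logv, LOG_FLOOR)
}

#' Map hypothesis likelihoods to choice probabilities
#'
#' The noisy decision rule: a softmax with temperature on the log hypothesis
#' likelihoods, mixed with a uniform lapse component,
#' `p = (1 - lapse) * softmax(temperature * log v) + lapse / n`.
#'
#' @param likelihoods An `n x m` matrix of positive hypothesis likelihood
#'   values (rows are trials).
#' @param params An [observer_params()].
#' @return An `n x m` matrix of choice probabilities; rows sum to one.
#' @export
choice_probabilities <- function(likelihoods, params) {
  likelihoods <- rbind(likelihoods)
  softmax_lapse(log(likelihoods), params$temperature, params$lapse)
}

#' @keywords internal
softmax_lapse <- function(logv, temperature, lapse) {
  logv <- rbind(logv)
  z <- temperature * logv
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  (1 - lapse) * p + lapse / ncol(p)
}

#' Ideal-observer response probabilities
#'
#' The full forward model: the probability of each possible response given
#' the presented stimuli, the subjective distribution, and the observer
#' parameters, with perceived stimuli integrated out analytically. Dispatches
#' on the trial table's task and composes the task-appropriate hypothesis
#' likelihoods with [choice_probabilities()].
#'
#' @param trials A single-task trial table.
#' @param P A [subjective_dist()].
#' @param params An [observer_params()].
#' @return An `n x n_alternatives` matrix of response probabilities.
#' @export
response_probabilities <- function(trials, P, params) {
  trials <- validate_trials(trials)
  task <- single_task(trials)
  logv <- switch(task,
    familiarity = log_familiarity_likelihoods(trials, P, params),
    odd_one_out = log_ooo_likelihoods(trials, P, params)
  )
  softmax_lapse(logv, params$temperature, params$lapse)
}

#' Familiarity-based decision rules for the odd-one-out task
#'
#' Alternative (deliberately wrong-headed) decision models that reuse the
#' familiarity computation in the odd-one-out task: score each stimulus by
#' its smoothed subjective density
#' `f_k = sum_m w_m N(s_k; mu_m, Sigma_m + sigma_p^2 I)` and pick the most
#' familiar (`mode = "most"`) or least familiar (`mode = "least"`) stimulus
#' as the odd one out, through the same softmax-plus-lapse decision noise.
#' Used to test whether subjects truly use a different decision rule per
#' task.
#'
#' @param trials An odd-one-out trial table.
#' @param P A [subjective_dist()].
#' @param params An [observer_params()].
#' @param mode `"most"` or `"least"`.
#' @return An `n x 3` matrix of response probabilities.
#' @export
ooo_by_familiarity <- function(trials, P, params,
                               mode = c("most", "least")) {
  mode <- match.arg(mode)
  trials <- validate_trials(trials)
  if (single_task(trials) != "odd_one_out") {
    stop("trials must be odd-one-out trials", call. = FALSE)
  }
  s2 <- params$perceptual_sigma^2
  n <- nrow(trials)
  logf <- vapply(
    1:3,
    function(i) {
      log_density_at(P, as.matrix(trials[, paste0("s", i, c("_x", "_y"))]),
        inflate = s2
      )
    },
    numeric(n)
  )
  logf <- pmax(rbind(logf), LOG_FLOOR)
  if (mode == "least") logf <- -logf
  softmax_lapse(logf, params$temperature, params$lapse)
}
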