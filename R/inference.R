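#' Priors for cognitive-tomography inversion
#'
#' Hyperparameters of the flexible priors placed over the subjective
#' distribution (a K-component Gaussian mixture) and the observer parameters.
#' Component weights get a symmetric Dirichlet, means an isotropic Gaussian
#' centered at the origin, covariance eigen-scales (SD units) a log-normal,
#' and the covariance orientation a uniform angle. Perceptual noise and
#' decision temperature get log-normals; the lapse rate a Beta.
#'
#' @param K Number of mixture components fitted (fixed per fit; model
#'   selection across K is left to cross-validated prediction).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the weights.
#' @param mean_prior_sd SD of the Gaussian prior on component means.
#' @param logscale_prior `c(location, scale)` of the log-normal prior on
#'   covariance eigen-scales (SDs).
#' @param sigma_p_prior `c(location, scale)` of the log-normal prior on the
#'   perceptual noise SD.
#' @param temperature_prior `c(location, scale)` of the log-normal prior on
#'   the decision temperature.
#' @param lapse_prior `c(shape1, shape2)` of the Beta prior on the lapse
#'   rate.
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(K = 3, dirichlet_alpha = 2, mean_prior_sd = 2,
                         logscale_prior = c(log(0.6), 0.5),
                         sigma_p_prior = c(log(0.5), 0.5),
                         temperature_prior = c(log(2), 0.7),
                         lapse_prior = c(1, 1)) {
  stopifnot(
    K >= 1, dirichlet_alpha > 0, mean_prior_sd > 0,
    logscale_prior[2] > 0, sigma_p_prior[2] > 0,
    temperature_prior[2] > 0, all(lapse_prior > 0)
  )
  structure(
    list(
      K = as.integer(K), dirichlet_alpha = dirichlet_alpha,
      mean_prior_sd = mean_prior_sd, logscale_prior = logscale_prior,
      sigma_p_prior = sigma_p_prior,
      temperature_prior = temperature_prior, lapse_prior = lapse_prior
    ),
    class = "prior_config"
  )
}

# ---- internal parameterization -------------------------------------------
# Unconstrained state:
#   y     : K-1 softmax coordinates for the weights (first fixed at 0)
#   m     : K x 2 component means
#   l     : K x 2 log eigen-scales (Sigma_k = R diag(exp(2 l)) R')
#   th    : K rotation angles in [0, pi)
#   lsig  : log perceptual sigma
#   ltmp  : log temperature
#   llap  : logit lapse

#' @keywords internal
state_weights <- function(y) {
  z <- c(0, y)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' @keywords internal
state_covs_flat <- function(l, th) {
  K <- nrow(l)
  out <- matrix(NA_real_, K, 3) # var_x, cov_xy, var_y
  for (k in seq_len(K)) {
    c1 <- cos(th[k])
    s1 <- sin(th[k])
    e <- exp(2 * l[k, ])
    out[k, 1] <- c1 * c1 * e[1] + s1 * s1 * e[2]
    out[k, 3] <- s1 * s1 * e[1] + c1 * c1 * e[2]
    out[k, 2] <- c1 * s1 * (e[1] - e[2])
  }
  out
}

#' @keywords internal
state_to_dist <- function(st, space) {
  covs_flat <- state_covs_flat(st$l, st$th)
  covs <- lapply(seq_len(nrow(covs_flat)), function(k) {
    matrix(
      c(
        covs_flat[k, 1], covs_flat[k, 2],
        covs_flat[k, 2], covs_flat[k, 3]
      ), 2
    )
  })
  subjective_dist(state_weights(st$y), st$m, covs, space)
}

#' @keywords internal
state_to_params <- function(st) {
  observer_params(
    perceptual_sigma = exp(st$lsig),
    temperature = exp(st$ltmp),
    lapse = stats::plogis(st$llap)
  )
}

# Log prior density in the unconstrained space (constrained priors plus the
# softmax and logit Jacobians; the angle is uniform and contributes nothing).
#' @keywords internal
state_log_prior <- function(st, prior) {
  w <- state_weights(st$y)
  lp <- sum((prior$dirichlet_alpha - 1) * log(w)) # Dirichlet kernel
  lp <- lp + sum(log(w)) # softmax Jacobian
  lp <- lp + sum(stats::dnorm(st$m, 0, prior$mean_prior_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(st$l, prior$logscale_prior[1],
    prior$logscale_prior[2],
    log = TRUE
  ))
  lp <- lp + stats::dnorm(st$lsig, prior$sigma_p_prior[1],
    prior$sigma_p_prior[2],
    log = TRUE
  )
  lp <- lp + stats::dnorm(st$ltmp, prior$temperature_prior[1],
    prior$temperature_prior[2],
    log = TRUE
  )
  lap <- stats::plogis(st$llap)
  lp <- lp + stats::dbeta(lap, prior$lapse_prior[1], prior$lapse_prior[2],
    log = TRUE
  ) + log(lap) + log1p(-lap)
  lp
}

#' @keywords internal
prepare_data <- function(responses, space) {
  responses <- validate_trials(responses, responses = TRUE)
  task <- single_task(responses)
  list(
    S = stim_matrix(responses, task),
    choice = as.integer(responses$choice),
    task_code = n_alternatives(task),
    task = task,
    log_u = log(uniform_density(space))
  )
}

#' @keywords internal
state_loglik <- function(st, dat) {
  cpp_loglik(
    dat$S, dat$choice, dat$task_code,
    state_weights(st$y), st$m, state_covs_flat(st$l, st$th),
    exp(st$lsig), exp(st$ltmp), stats::plogis(st$llap), dat$log_u
  )
}

#' Log posterior density of the cognitive-tomography model
#'
#' `log P(P) + log P(Omega) + sum_t log P(choice_t | trial_t, P, Omega)`:
#' the (unnormalized) posterior over subjective distributions and observer
#' parameters given a subject's responses. Priors are evaluated on the
#' natural (constrained) parameters; the covariance prior scores the
#' log-normal density of each covariance's eigen-scales (square roots of its
#' eigenvalues) with a uniform orientation. Parameters outside the prior
#' support give `-Inf` rather than an error.
#'
#' @param P A [subjective_dist()].
#' @param params An [observer_params()] (or a list with the same fields;
#'   out-of-support values allowed and mapped to `-Inf`).
#' @param responses A single-task response tibble; may have zero rows, in
#'   which case the log prior alone is returned.
#' @param prior A [prior_config()] with `K = n_components(P)`.
#' @return A finite scalar, or `-Inf` outside the prior support.
#' @export
log_posterior <- function(P, params, responses, prior = prior_config()) {
  stopifnot(inherits(P, "subjective_dist"))
  if (n_components(P) != prior$K) {
    stop("prior$K must match the number of components of P", call. = FALSE)
  }
  if (params$lapse < 0 || params$lapse > 1 || params$perceptual_sigma <= 0 ||
    params$temperature <= 0) {
    return(-Inf)
  }
  lp <- sum((prior$dirichlet_alpha - 1) * log(P$weights)) +
    sum(stats::dnorm(P$means, 0, prior$mean_prior_sd, log = TRUE))
  for (S in P$covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    lp <- lp + sum(stats::dlnorm(sqrt(ev), prior$logscale_prior[1],
      prior$logscale_prior[2],
      log = TRUE
    ))
  }
  lp <- lp + stats::dlnorm(params$perceptual_sigma, prior$sigma_p_prior[1],
    prior$sigma_p_prior[2],
    log = TRUE
  ) + stats::dlnorm(params$temperature, prior$temperature_prior[1],
    prior$temperature_prior[2],
    log = TRUE
  ) + stats::dbeta(params$lapse, prior$lapse_prior[1], prior$lapse_prior[2],
    log = TRUE
  )
  if (!is.finite(lp)) {
    return(-Inf)
  }
  if (nrow(responses) == 0) {
    return(lp)
  }
  dat <- prepare_data(responses, P$space)
  op <- observer_params(params$perceptual_sigma, params$temperature,
    lapse = params$lapse
  )
  p <- response_probabilities(responses, P, op)
  lp + sum(log(p[cbind(seq_len(nrow(p)), dat$choice + 1L)]))
}

#' Invert the ideal observer: posterior sampling over (P, Omega)
#'
#' The cognitive-tomography inversion. Runs a random-walk
#' Metropolis-within-Gibbs sampler over parameter blocks — weights (softmax
#' coordinates), each component's mean, each component's covariance (log
#' eigen-scales plus rotation), log perceptual sigma, log temperature, logit
#' lapse — with proposal scales adapted toward 0.25 acceptance during
#' burn-in only (then frozen, preserving detailed balance). Identical seed
#' and settings give bit-identical draws.
#'
#' @param responses A single-task response tibble (>= 1 row).
#' @param prior A [prior_config()].
#' @param n_steps Total sampler steps (default 20000).
#' @param burn_in Steps discarded (default 25% of `n_steps`).
#' @param thin Keep every `thin`-th post-burn-in step (default: thinned so at
#'   most 2000 draws are retained).
#' @param seed Integer seed.
#' @param likelihood_weight Multiplier on the log-likelihood term; 0 turns
#'   the sampler into a prior sampler (used for prior-recovery checks).
#' @param space A [feature_space()].
#' @param init_retries Re-initialization attempts if the starting log
#'   posterior is not finite.
#' @param verbose Print progress every 1000 steps.
#' @return An object of class `cogtomo_fit` with elements `draws` (matrices
#'   of retained parameter draws), `log_posterior_trace`,
#'   `acceptance_rates`, `task`, `seed`, `prior`, `space`, and the settings.
#' @export
fit_cogtomo <- function(responses, prior = prior_config(), n_steps = 20000,
                        burn_in = NULL, thin = NULL, seed = 1,
                        likelihood_weight = 1, space = feature_space(),
                        init_retries = 100, verbose = FALSE) {
  if (nrow(responses) < 1) stop("need at least one response", call. = FALSE)
  dat <- prepare_data(responses, space)
  K <- prior$K
  if (is.null(burn_in)) burn_in <- floor(n_steps / 4)
  if (is.null(thin)) thin <- max(1L, ceiling((n_steps - burn_in) / 2000))
  set.seed(seed)

  lpost <- function(st) {
    lp <- state_log_prior(st, prior)
    if (!is.finite(lp)) {
      return(-Inf)
    }
    if (likelihood_weight == 0) {
      return(lp)
    }
    lp + likelihood_weight * state_loglik(st, dat)
  }

  # initialization: uniform weights, means from the prior, everything else
  # at the prior medians
  st <- NULL
  for (try in seq_len(init_retries)) {
    cand <- list(
      y = rep(0, K - 1),
      m = matrix(stats::rnorm(2 * K, 0, prior$mean_prior_sd), K),
      l = matrix(prior$logscale_prior[1], K, 2),
      th = rep(0, K),
      lsig = prior$sigma_p_prior[1],
      ltmp = prior$temperature_prior[1],
      llap = stats::qlogis(
        stats::qbeta(0.5, prior$lapse_prior[1], prior$lapse_prior[2])
      )
    )
    if (is.finite(lpost(cand))) {
      st <- cand
      break
    }
  }
  if (is.null(st)) {
    stop("no finite starting point after ", init_retries, " attempts",
      call. = FALSE
    )
  }
  cur_lp <- lpost(st)

  # blocks: weights | mean_k x K | cov_k x K | lsig | ltmp | llap
  blocks <- c(
    if (K > 1) "y",
    paste0("m", seq_len(K)), paste0("c", seq_len(K)),
    "lsig", "ltmp", "llap"
  )
  scales <- stats::setNames(rep(0.3, length(blocks)), blocks)
  acc <- stats::setNames(numeric(length(blocks)), blocks)
  n_prop <- stats::setNames(numeric(length(blocks)), blocks)

  propose <- function(st, b, s) {
    if (b == "y") {
      st$y <- st$y + stats::rnorm(K - 1, 0, s)
    } else if (startsWith(b, "m")) {
      k <- as.integer(substring(b, 2))
      st$m[k, ] <- st$m[k, ] + stats::rnorm(2, 0, s)
    } else if (startsWith(b, "c")) {
      k <- as.integer(substring(b, 2))
      st$l[k, ] <- st$l[k, ] + stats::rnorm(2, 0, s)
      st$th[k] <- (st$th[k] + stats::rnorm(1, 0, s)) %% pi
    } else if (b == "lsig") {
      st$lsig <- st$lsig + stats::rnorm(1, 0, s)
    } else if (b == "ltmp") {
      st$ltmp <- st$ltmp + stats::rnorm(1, 0, s)
    } else {
      st$llap <- st$llap + stats::rnorm(1, 0, s)
    }
    st
  }

  n_keep <- length(seq(burn_in + thin, n_steps, by = thin))
  draws <- list(
    weights = matrix(NA_real_, n_keep, K),
    means = matrix(NA_real_, n_keep, 2 * K),
    covs = matrix(NA_real_, n_keep, 3 * K),
    sigma_p = numeric(n_keep), temperature = numeric(n_keep),
    lapse = numeric(n_keep)
  )
  trace <- numeric(n_keep)
  kept <- 0L

  for (step in seq_len(n_steps)) {
    for (b in blocks) {
      cand <- propose(st, b, scales[[b]])
      cand_lp <- lpost(cand)
      n_prop[[b]] <- n_prop[[b]] + 1
      a <- exp(min(0, cand_lp - cur_lp))
      if (is.finite(cand_lp) && stats::runif(1) < a) {
        st <- cand
        cur_lp <- cand_lp
        acc[[b]] <- acc[[b]] + 1
      }
      if (step <= burn_in) {
        gamma <- min(0.1, 3 / sqrt(step))
        scales[[b]] <- scales[[b]] * exp(gamma * (a - 0.25))
      }
    }
    if (step > burn_in && (step - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws$weights[kept, ] <- state_weights(st$y)
      draws$means[kept, ] <- as.vector(st$m)
      draws$covs[kept, ] <- as.vector(state_covs_flat(st$l, st$th))
      draws$sigma_p[kept] <- exp(st$lsig)
      draws$temperature[kept] <- exp(st$ltmp)
      draws$lapse[kept] <- stats::plogis(st$llap)
      trace[kept] <- cur_lp
    }
    if (verbose && step %% 1000 == 0) {
      message(sprintf("step %d / %d, log posterior %.2f", step, n_steps,
        cur_lp
      ))
    }
  }

  structure(
    list(
      draws = draws, log_posterior_trace = trace,
      acceptance_rates = acc / pmax(n_prop, 1),
      task = dat$task, seed = seed, prior = prior, space = space,
      settings = list(
        n_steps = n_steps, burn_in = burn_in, thin = thin,
        likelihood_weight = likelihood_weight
      ),
      n_responses = nrow(responses)
    ),
    class = "cogtomo_fit"
  )
}

#' @export
print.cogtomo_fit <- function(x, ...) {
  cat(sprintf(
    "<cogtomo_fit> %s task, %d responses, %d retained draws (K = %d)\n",
    x$task, x$n_responses, n_draws(x), x$prior$K
  ))
  invisible(x)
}

#' Number of retained posterior draws
#' @param fit A `cogtomo_fit`.
#' @return Integer.
#' @export
n_draws <- function(fit) length(fit$draws$sigma_p)

#' Extract one posterior draw as model objects
#'
#' @param fit A `cogtomo_fit`.
#' @param i Draw index.
#' @return A list with `P` (a [subjective_dist()]) and `params`
#'   (an [observer_params()]).
#' @export
get_draw <- function(fit, i) {
  stopifnot(i >= 1, i <= n_draws(fit))
  K <- fit$prior$K
  m <- matrix(fit$draws$means[i, ], K)
  cf <- matrix(fit$draws$covs[i, ], K)
  covs <- lapply(seq_len(K), function(k) {
    matrix(c(cf[k, 1], cf[k, 2], cf[k, 2], cf[k, 3]), 2)
  })
  list(
    P = subjective_dist(fit$draws$weights[i, ], m, covs, fit$space),
    params = observer_params(
      fit$draws$sigma_p[i], fit$draws$temperature[i], fit$draws$lapse[i]
    )
  )
}

#' Posterior-mean grid density (the recovered "tomogram")
#'
#' Averages the grid discretization of the subjective distribution over all
#' retained posterior draws and renormalizes: the package's per-subject
#' image of the recovered prior.
#'
#' @param fit A `cogtomo_fit`.
#' @param resolution Grid cells per dimension.
#' @return A `grid_density`.
#' @export
posterior_mean_grid <- function(fit, resolution = 100) {
  stopifnot(inherits(fit, "cogtomo_fit"), n_draws(fit) >= 1)
  acc <- 0
  for (i in seq_len(n_draws(fit))) {
    acc <- acc + to_grid(get_draw(fit, i)$P, resolution)$masses
  }
  grid_density(acc / n_draws(fit), fit$space)
}

#' Tidy posterior draws into a long table
#'
#' @param x A `cogtomo_fit`.
#' @param ... Unused.
#' @return A tibble with one row per draw: observer parameters, component
#'   weights, and the log posterior.
#' @export
tidy.cogtomo_fit <- function(x, ...) {
  K <- x$prior$K
  w <- tibble::as_tibble(x$draws$weights, .name_repair = ~ paste0(
    "weight_",
    seq_len(K)
  ))
  dplyr::bind_cols(
    tibble::tibble(
      draw = seq_len(n_draws(x)),
      sigma_p = x$draws$sigma_p,
      temperature = x$draws$temperature,
      lapse = x$draws$lapse,
      log_posterior = x$log_posterior_trace
    ),
    w
  )
}

#' One-row summary of a fit
#'
#' @param x A `cogtomo_fit`.
#' @param ... Unused.
#' @return A one-row tibble: task, draw count, posterior means of the
#'   observer parameters, mean block acceptance rate.
#' @export
glance.cogtomo_fit <- function(x, ...) {
  tibble::tibble(
    task = x$task,
    n_responses = x$n_responses,
    n_draws = n_draws(x),
    K = x$prior$K,
    sigma_p = mean(x$draws$sigma_p),
    temperature = mean(x$draws$temperature),
    lapse = mean(x$draws$lapse),
    mean_acceptance = mean(x$acceptance_rates)
  )
}

#' Plot the posterior-mean subjective distribution
#'
#' @param object A `cogtomo_fit`.
#' @param resolution Grid cells per dimension.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cogtomo_fit <- function(object, resolution = 100, ...) {
  autoplot.grid_density(posterior_mean_grid(object, resolution))
}
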