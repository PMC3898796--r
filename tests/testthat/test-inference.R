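test_that("log posterior decomposes into prior and per-trial likelihood terms", {
  su <- random_setup(71)
  prior <- prior_config(K = n_components(su$P))
  empty <- make_stimuli("familiarity", 5, seed = 1)[0, ]
  empty$choice <- integer(0)
  lp0 <- log_posterior(su$P, su$params, empty, prior)
  expect_true(is.finite(lp0))

  resp <- simulate_responses(
    make_stimuli("familiarity", 10, repeat_fraction = 0, seed = 2),
    su$P, su$params,
    seed = 3
  )
  lp1 <- log_posterior(su$P, su$params, resp, prior)

  # the likelihood term equals the response-probability entries
  p <- response_probabilities(resp, su$P, su$params)
  ll <- sum(log(p[cbind(seq_len(nrow(p)), resp$choice + 1L)]))
  expect_equal(lp1 - lp0, ll, tolerance = 1e-10)

  # duplicating every response doubles the likelihood term
  dup <- dplyr::bind_rows(resp, dplyr::mutate(resp, trial_id = trial_id + 100L))
  lp2 <- log_posterior(su$P, su$params, dup, prior)
  expect_equal(lp2 - lp0, 2 * (lp1 - lp0), tolerance = 1e-10)

  # out-of-support observer parameters yield -Inf, not an error
  bad <- su$params
  bad$lapse <- 1.5
  expect_identical(log_posterior(su$P, bad, resp, prior), -Inf)
})

test_that("label switching leaves the log posterior unchanged", {
  su <- random_setup(72)
  resp <- simulate_responses(
    make_stimuli("odd_one_out", 15, repeat_fraction = 0, seed = 4),
    su$P, su$params,
    seed = 5
  )
  prior <- prior_config(K = 3)
  perm <- c(3, 1, 2)
  P2 <- subjective_dist(
    su$P$weights[perm], su$P$means[perm, ],
    su$P$covariances[perm], su$P$space
  )
  expect_equal(
    log_posterior(su$P, su$params, resp, prior),
    log_posterior(P2, su$params, resp, prior),
    tolerance = 1e-10
  )
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  su <- random_setup(73)
  resp <- simulate_responses(
    make_stimuli("familiarity", 60, repeat_fraction = 0, seed = 6),
    su$P, su$params,
    seed = 7
  )
  f1 <- fit_cogtomo(resp, prior_config(K = 2), n_steps = 400, seed = 11)
  f2 <- fit_cogtomo(resp, prior_config(K = 2), n_steps = 400, seed = 11)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$log_posterior_trace, f2$log_posterior_trace)
  f3 <- fit_cogtomo(resp, prior_config(K = 2), n_steps = 400, seed = 12)
  expect_false(identical(f1$draws, f3$draws))
  expect_true(all(f1$acceptance_rates >= 0 & f1$acceptance_rates <= 1))
  expect_error(fit_cogtomo(resp[0, ], prior_config(K = 2)), "at least one")
})

test_that("posterior mean grids average draw grids", {
  su <- random_setup(74)
  P2 <- make_ground_truth(75, K = 2, separation = 2)
  d1 <- list(P = su$P, params = su$params)
  d2 <- list(P = moment_match(P2), params = su$params)
  # pad the single-Gaussian draw to K = 3 for a shared layout
  d2$P <- subjective_dist(
    c(1, 0, 0) + c(-2e-13, 1e-13, 1e-13),
    rbind(d2$P$means, c(0, 0), c(0, 0)),
    list(d2$P$covariances[[1]], diag(2), diag(2))
  )

  one <- manual_fit(list(d1))
  expect_equal(
    posterior_mean_grid(one, 50)$masses,
    to_grid(su$P, 50)$masses,
    tolerance = 1e-12
  )

  two <- manual_fit(list(d1, d2))
  expect_equal(
    posterior_mean_grid(two, 50)$masses,
    (to_grid(d1$P, 50)$masses + to_grid(d2$P, 50)$masses) / 2,
    tolerance = 1e-9
  )
  expect_equal(sum(posterior_mean_grid(two, 50)$masses), 1, tolerance = 1e-9)
})

test_that("with the likelihood switched off the sampler reproduces its priors", {
  resp <- simulate_responses(
    make_stimuli("familiarity", 10, repeat_fraction = 0, seed = 8),
    make_ground_truth(76, K = 2), observer_params(),
    seed = 9
  )
  prior <- prior_config(K = 2)
  fit <- fit_cogtomo(resp, prior,
    n_steps = 50000, burn_in = 10000, thin = 20,
    seed = 21, likelihood_weight = 0
  )
  expect_equal(n_draws(fit), 2000)
  ks1 <- suppressWarnings(stats::ks.test(
    fit$draws$sigma_p,
    function(x) stats::plnorm(x, prior$sigma_p_prior[1], prior$sigma_p_prior[2])
  ))
  expect_gt(ks1$p.value, 0.01)
  ks2 <- suppressWarnings(stats::ks.test(
    fit$draws$lapse,
    function(x) stats::pbeta(x, prior$lapse_prior[1], prior$lapse_prior[2])
  ))
  expect_gt(ks2$p.value, 0.01)
  ks3 <- suppressWarnings(stats::ks.test(
    fit$draws$means[, 1],
    function(x) stats::pnorm(x, 0, prior$mean_prior_sd)
  ))
  expect_gt(ks3$p.value, 0.01)
  # weights: each marginal of a flat-ish Dirichlet(2,2) is Beta(2, 2)
  ks4 <- suppressWarnings(stats::ks.test(
    fit$draws$weights[, 1],
    function(x) {
      stats::pbeta(x, prior$dirichlet_alpha, prior$dirichlet_alpha)
    }
  ))
  expect_gt(ks4$p.value, 0.01)
})

test_that("recovery sharpens monotonically with more trials", {
  sizes <- c(250, 1000, 4000)
  js <- matrix(NA_real_, 10, length(sizes))
  for (s in 1:10) {
    truth <- make_ground_truth(300 + s, K = 2, separation = 3)
    tg <- to_grid(truth, 50)
    big <- simulate_responses(
      make_stimuli("familiarity", max(sizes), repeat_fraction = 0,
        seed = 400 + s
      ),
      truth, observer_params(),
      seed = 500 + s
    )
    for (j in seq_along(sizes)) {
      fit <- fit_cogtomo(big[seq_len(sizes[j]), ], prior_config(K = 2),
        n_steps = 2000, burn_in = 1000, seed = 600 + s
      )
      js[s, j] <- js_divergence(tg, posterior_mean_grid(fit, 50))
    }
  }
  med <- apply(js, 2, stats::median)
  expect_lt(med[2], med[1])
  expect_lt(med[3], med[2])
})

test_that("a pure-lapse subject leaves the posterior at its prior", {
  truth <- make_ground_truth(81, K = 3, separation = 2.5)
  resp <- simulate_responses(
    make_stimuli("familiarity", 200, repeat_fraction = 0, seed = 82),
    truth, observer_params(lapse = 1),
    seed = 83
  )
  prior <- prior_config(K = 3)
  post <- fit_cogtomo(resp, prior, n_steps = 20000, seed = 84)
  prior_only <- fit_cogtomo(resp, prior,
    n_steps = 20000, seed = 85,
    likelihood_weight = 0
  )
  expect_lt(
    js_divergence(
      posterior_mean_grid(post, 60),
      posterior_mean_grid(prior_only, 60)
    ),
    0.05
  )
})
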