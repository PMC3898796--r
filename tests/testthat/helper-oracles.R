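# Independent numerical oracles for the analytic ideal-observer marginals.
# Everything here is built on mvtnorm + tensor Gauss-Legendre quadrature and
# never calls the package's own density or likelihood code paths.

# tensor-product Gauss-Legendre grid over [-lim, lim]^2
ql_grid <- function(n = 200, lim = 10) {
  gl <- pracma::gaussLegendre(n, -lim, lim)
  list(
    f1 = rep(gl$x, times = n),
    f2 = rep(gl$x, each = n),
    w = as.vector(outer(gl$w, gl$w))
  )
}

# mixture pdf at the quadrature nodes, via mvtnorm
oracle_mix_pdf <- function(P, f1, f2) {
  out <- 0
  for (k in seq_along(P$weights)) {
    out <- out + P$weights[k] *
      mvtnorm::dmvnorm(cbind(f1, f2), P$means[k, ], P$covariances[[k]])
  }
  out
}

# int N(s; f, sigma^2 I) p(f) df  — the singleton marginal
oracle_single <- function(s, sigma, pf, q) {
  noise <- stats::dnorm(s[1], q$f1, sigma) * stats::dnorm(s[2], q$f2, sigma)
  sum(q$w * pf * noise)
}

# int N(si; f, sigma^2 I) N(sj; f, sigma^2 I) p(f) df — the pair marginal
oracle_pair <- function(si, sj, sigma, pf, q) {
  noise <- stats::dnorm(si[1], q$f1, sigma) * stats::dnorm(si[2], q$f2, sigma) *
    stats::dnorm(sj[1], q$f1, sigma) * stats::dnorm(sj[2], q$f2, sigma)
  sum(q$w * pf * noise)
}

# quadrature version of the familiarity hypothesis likelihoods
oracle_familiarity <- function(trial_row, P, params, q = ql_grid()) {
  pf <- oracle_mix_pdf(P, q$f1, q$f2)
  u <- uniform_density(P$space)
  s1 <- c(trial_row$s1_x, trial_row$s1_y)
  s2 <- c(trial_row$s2_x, trial_row$s2_y)
  c(
    u * oracle_single(s1, params$perceptual_sigma, pf, q),
    u * oracle_single(s2, params$perceptual_sigma, pf, q)
  )
}

# quadrature version of the odd-one-out hypothesis likelihoods
oracle_ooo <- function(trial_row, P, params, q = ql_grid()) {
  pf <- oracle_mix_pdf(P, q$f1, q$f2)
  s <- list(
    c(trial_row$s1_x, trial_row$s1_y),
    c(trial_row$s2_x, trial_row$s2_y),
    c(trial_row$s3_x, trial_row$s3_y)
  )
  sg <- params$perceptual_sigma
  singles <- vapply(s, oracle_single, numeric(1), sigma = sg, pf = pf, q = q)
  pairs <- list(c(2, 3), c(1, 3), c(1, 2))
  vapply(1:3, function(k) {
    ij <- pairs[[k]]
    oracle_pair(s[[ij[1]]], s[[ij[2]]], sg, pf, q) * singles[k]
  }, numeric(1))
}

# a reproducible random mixture + observer setup for randomized checks
random_setup <- function(seed, K = 3) {
  set.seed(seed)
  P <- make_ground_truth(seed, K = K, separation = 0)
  params <- observer_params(
    perceptual_sigma = stats::runif(1, 0.3, 1),
    temperature = stats::runif(1, 1, 5),
    lapse = stats::runif(1, 0, 0.2)
  )
  list(P = P, params = params)
}

# single-row trial constructors
one_trial <- function(task, s, repeat_group = NA_integer_, id = 1L) {
  tibble::tibble(
    trial_id = id, task = task,
    s1_x = s[1], s1_y = s[2], s2_x = s[3], s2_y = s[4],
    s3_x = if (length(s) >= 6) s[5] else NA_real_,
    s3_y = if (length(s) >= 6) s[6] else NA_real_,
    repeat_group = repeat_group
  )
}

# equilateral triad vertices around a center (side length `side`)
equilateral <- function(center, side, phi = 0) {
  r <- side / sqrt(3)
  ang <- phi + c(0, 2, 4) * pi / 3
  as.vector(t(cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))))
}

prediction_unname <- function(pred) {
  unname(as.matrix(pred[, intersect(c("p1", "p2", "p3"), names(pred))]))
}

# build a cogtomo_fit by hand from explicit draws (for averaging contracts)
manual_fit <- function(draws_list, task = "familiarity",
                       space = feature_space(), K = NULL) {
  if (is.null(K)) K <- n_components(draws_list[[1]]$P)
  nd <- length(draws_list)
  d <- list(
    weights = matrix(NA_real_, nd, K),
    means = matrix(NA_real_, nd, 2 * K),
    covs = matrix(NA_real_, nd, 3 * K),
    sigma_p = numeric(nd), temperature = numeric(nd), lapse = numeric(nd)
  )
  for (i in seq_len(nd)) {
    P <- draws_list[[i]]$P
    pr <- draws_list[[i]]$params
    d$weights[i, ] <- P$weights
    d$means[i, ] <- as.vector(P$means)
    d$covs[i, ] <- as.vector(t(vapply(
      P$covariances,
      function(S) c(S[1, 1], S[1, 2], S[2, 2]), numeric(3)
    )))
    d$sigma_p[i] <- pr$perceptual_sigma
    d$temperature[i] <- pr$temperature
    d$lapse[i] <- pr$lapse
  }
  structure(
    list(
      draws = d, log_posterior_trace = rep(0, nd),
      acceptance_rates = c(all = 0.25), task = task, seed = 0,
      prior = prior_config(K = K), space = space,
      settings = list(), n_responses = 0
    ),
    class = "cogtomo_fit"
  )
}
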