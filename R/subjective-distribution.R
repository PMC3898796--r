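#' Construct a subjective distribution (Gaussian mixture over the feature space)
#'
#' A subjective distribution is a subject's prior probability density over the
#' stimulus feature space. It is parameterized as a finite mixture of
#' `K` bivariate Gaussians: weights summing to one, component means, and
#' symmetric positive-definite component covariances (in squared SD units).
#' A finite mixture is expressive enough to produce the multimodal, nonconvex
#' shapes seen in recovered human priors while keeping every ideal-observer
#' likelihood analytic. Components are not truncated to the box; grid
#' discretizations renormalize over the box instead.
#'
#' @param weights Numeric vector of K nonnegative mixture weights; normalized
#'   to sum to one (must already sum to 1 within 1e-8 before normalization).
#' @param means K x n_dims matrix (or length-n_dims vector when K = 1) of
#'   component means.
#' @param covariances List of K symmetric positive-definite matrices, or a
#'   single matrix when K = 1.
#' @param space A [feature_space()].
#'
#' @return An object of class `subjective_dist`.
#' @examples
#' P <- subjective_dist(
#'   weights = c(0.5, 0.5),
#'   means = rbind(c(-2, 0), c(2, 0)),
#'   covariances = list(diag(2), diag(2))
#' )
#' density_at(P, c(0, 0))
#' @export
subjective_dist <- function(weights, means, covariances,
                            space = feature_space()) {
  stopifnot(inherits(space, "feature_space"))
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  }
  weights <- weights / sum(weights)
  K <- length(weights)
  means <- rbind(means)
  dimnames(means) <- NULL
  if (nrow(means) != K || ncol(means) != space$n_dims) {
    stop("means must be a ", K, " x ", space$n_dims, " matrix", call. = FALSE)
  }
  if (is.matrix(covariances)) covariances <- list(covariances)
  if (length(covariances) != K) {
    stop("need one covariance per component", call. = FALSE)
  }
  covariances <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    dimnames(S) <- NULL
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10))) {
      stop("covariance must be symmetric", call. = FALSE)
    }
    S <- (S + t(S)) / 2
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) {
      stop("covariance must be positive definite", call. = FALSE)
    }
    S
  })
  structure(
    list(
      space = space, weights = weights, means = means,
      covariances = covariances
    ),
    class = "subjective_dist"
  )
}

#' @export
print.subjective_dist <- function(x, ...) {
  cat(sprintf(
    "<subjective_dist> %d-component Gaussian mixture on a ±%g SD box\n",
    length(x$weights), x$space$half_width
  ))
  cat("weights:", paste(signif(x$weights, 3), collapse = " "), "\n")
  invisible(x)
}

#' Number of mixture components
#' @param P A [subjective_dist()].
#' @return Integer count of components.
#' @export
n_components <- function(P) length(P$weights)

# Bivariate normal log-density at rows of x, closed-form 2x2 inverse.
#' @keywords internal
log_dmvn2 <- function(x, mu, sigma) {
  x <- rbind(x)
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b * b
  dx <- x[, 1] - mu[1]
  dy <- x[, 2] - mu[2]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Evaluate the subjective density
#'
#' Returns the mixture density `sum_k w_k N(x; mu_k, Sigma_k)` at each row of
#' `x`.
#'
#' @param P A [subjective_dist()].
#' @param x A point (length-n_dims vector) or a matrix of points (rows).
#' @param inflate Optional nonnegative scalar added to the diagonal of every
#'   component covariance before evaluation (i.e. `Sigma_k + inflate * I`).
#'   This is the convolution of the mixture with isotropic Gaussian noise of
#'   variance `inflate`, used by the ideal-observer marginals.
#' @return Numeric vector of densities, one per row of `x`.
#' @export
density_at <- function(P, x, inflate = 0) {
  stopifnot(inherits(P, "subjective_dist"), inflate >= 0)
  x <- check_points(x, P$space)
  K <- n_components(P)
  lp <- matrix(NA_real_, nrow(x), K)
  for (k in seq_len(K)) {
    S <- P$covariances[[k]] + diag(inflate, P$space$n_dims)
    lp[, k] <- log(P$weights[k]) + log_dmvn2(x, P$means[k, ], S)
  }
  rowSums(exp(lp))
}

#' Log of the (noise-convolved) subjective density
#'
#' Numerically stable log of [density_at()] via log-sum-exp over components.
#'
#' @inheritParams density_at
#' @return Numeric vector of log-densities.
#' @export
log_density_at <- function(P, x, inflate = 0) {
  stopifnot(inherits(P, "subjective_dist"), inflate >= 0)
  x <- check_points(x, P$space)
  K <- n_components(P)
  lp <- matrix(NA_real_, nrow(x), K)
  for (k in seq_len(K)) {
    S <- P$covariances[[k]] + diag(inflate, P$space$n_dims)
    lp[, k] <- log(P$weights[k]) + log_dmvn2(x, P$means[k, ], S)
  }
  m <- apply(lp, 1, max)
  m + log(rowSums(exp(lp - m)))
}

#' Draw samples from a subjective distribution
#'
#' Ancestral sampling: a component is drawn by weight, then a Gaussian draw
#' from that component. Fully determined by `seed`.
#'
#' @param P A [subjective_dist()].
#' @param n Number of points to draw (>= 1).
#' @param seed Integer seed.
#' @return An `n x n_dims` matrix of points.
#' @export
sample_points <- function(P, n, seed) {
  stopifnot(inherits(P, "subjective_dist"))
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  K <- n_components(P)
  comp <- sample.int(K, n, replace = TRUE, prob = P$weights)
  x <- matrix(NA_real_, n, P$space$n_dims)
  for (k in seq_len(K)) {
    idx <- which(comp == k)
    if (!length(idx)) next
    R <- chol(P$covariances[[k]])
    z <- matrix(stats::rnorm(length(idx) * P$space$n_dims),
      ncol = P$space$n_dims
    )
    x[idx, ] <- z %*% R + rep(P$means[k, ], each = length(idx))
  }
  attr(x, "component") <- comp
  x
}

#' Moment-match a subjective distribution with a single Gaussian
#'
#' Replaces a mixture by the single Gaussian with the same mean and
#' covariance (law of total covariance). Used as the "structure-free"
#' baseline: if fine multimodal detail in a recovered prior mattered for
#' behavior, predictions from the moment-matched version should degrade.
#'
#' @param P A [subjective_dist()].
#' @return A [subjective_dist()] with one component.
#' @export
moment_match <- function(P) {
  stopifnot(inherits(P, "subjective_dist"))
  w <- P$weights
  mu <- colSums(P$means * w)
  d <- P$space$n_dims
  S <- matrix(0, d, d)
  for (k in seq_along(w)) {
    S <- S + w[k] * (P$covariances[[k]] + tcrossprod(P$means[k, ]))
  }
  S <- S - tcrossprod(mu)
  subjective_dist(1, matrix(mu, 1), list((S + t(S)) / 2), P$space)
}

#' Tidy a subjective distribution into a component table
#'
#' @param x A [subjective_dist()].
#' @param ... Unused.
#' @return A tibble with one row per mixture component: `component`,
#'   `weight`, `mean_x`, `mean_y`, `var_x`, `var_y`, `cov_xy`.
#' @export
tidy.subjective_dist <- function(x, ...) {
  K <- n_components(x)
  tibble::tibble(
    component = seq_len(K),
    weight = x$weights,
    mean_x = x$means[, 1],
    mean_y = x$means[, 2],
    var_x = purrr::map_dbl(x$covariances, ~ .x[1, 1]),
    var_y = purrr::map_dbl(x$covariances, ~ .x[2, 2]),
    cov_xy = purrr::map_dbl(x$covariances, ~ .x[1, 2])
  )
}
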