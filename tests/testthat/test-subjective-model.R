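test_that("mixture density matches closed forms and component sums", {
  P1 <- subjective_dist(1, c(0, 0), diag(2))
  expect_equal(density_at(P1, c(0, 0)), 1 / (2 * pi), tolerance = 1e-12)

  # sum of independently evaluated component Gaussians (mvtnorm)
  P2 <- subjective_dist(
    c(0.5, 0.5), rbind(c(-2, 0), c(2, 0)),
    list(diag(2), diag(2))
  )
  x <- c(0, 0)
  direct <- 0.5 * mvtnorm::dmvnorm(x, c(-2, 0), diag(2)) +
    0.5 * mvtnorm::dmvnorm(x, c(2, 0), diag(2))
  expect_equal(density_at(P2, x), direct, tolerance = 1e-12)
  expect_equal(log_density_at(P2, x), log(direct), tolerance = 1e-12)

  expect_error(density_at(P1, c(0, 0, 0)), "columns")
  expect_error(
    subjective_dist(1, c(0, 0), matrix(c(1, 2, 2, 1), 2)),
    "positive definite"
  )
  expect_error(subjective_dist(c(0.6, 0.6), rbind(c(0, 0), c(1, 1)),
    list(diag(2), diag(2))
  ), "sum to 1")
})

test_that("density integrates to one by quadrature for random mixtures", {
  q <- ql_grid(150, 12)
  for (sd in 1:3) {
    P <- random_setup(sd)$P
    total <- sum(q$w * density_at(P, cbind(q$f1, q$f2)))
    expect_equal(total, 1, tolerance = 1e-6)
  }
})

test_that("grid discretization normalizes, flattens and localizes", {
  P <- random_setup(11)$P
  g <- to_grid(P, 100)
  expect_equal(sum(g$masses), 1, tolerance = 1e-9)
  expect_error(to_grid(P, 7), "resolution")

  flatP <- subjective_dist(1, c(0, 0), 1e6 * diag(2))
  gf <- to_grid(flatP, 50)
  expect_lt(max(gf$masses) / min(gf$masses), 1.001)

  narrow <- subjective_dist(1, c(0, 0), 0.25 * diag(2))
  mom <- grid_moments(to_grid(narrow, 200))
  expect_lt(max(abs(mom$mean)), 0.02)

  # discretization converges: refining the grid barely moves the density
  for (sd in 1:3) {
    P <- make_ground_truth(sd, K = 3, separation = 1, eigen_range = c(0.3, 1))
    g100 <- to_grid(P, 100)
    g200 <- to_grid(P, 200)
    idx <- rep(seq_len(100), each = 2)
    agg <- t(rowsum(t(rowsum(g200$masses, idx)), idx)) # 2x2 cell pooling
    expect_lt(js_divergence(g100, grid_density(agg, P$space)), 1e-3)
  }
})

test_that("sampling is seeded and reproduces mixture moments", {
  P <- subjective_dist(1, c(0.5, -0.5), diag(2))
  a <- sample_points(P, 500, seed = 42)
  b <- sample_points(P, 500, seed = 42)
  expect_identical(a, b)
  expect_error(sample_points(P, 0, seed = 1), "n must be")

  big <- sample_points(P, 1e5, seed = 7)
  expect_lt(max(abs(colMeans(big) - c(0.5, -0.5))), 0.02)

  P2 <- subjective_dist(
    c(0.7, 0.3), rbind(c(-2, 0), c(2, 0)),
    list(diag(2), diag(2))
  )
  comp <- attr(sample_points(P2, 1e5, seed = 8), "component")
  expect_lt(abs(mean(comp == 1) - 0.7), 0.01)
})

test_that("moment matching obeys the law of total covariance", {
  P1 <- subjective_dist(1, c(1, 2), matrix(c(2, 0.5, 0.5, 1), 2))
  mm1 <- moment_match(P1)
  expect_equal(mm1$means, P1$means)
  expect_equal(mm1$covariances[[1]], P1$covariances[[1]])

  d <- 2.5
  P2 <- subjective_dist(
    c(0.5, 0.5), rbind(c(-d, 0), c(d, 0)),
    list(diag(2), diag(2))
  )
  mm2 <- moment_match(P2)
  expect_equal(as.vector(mm2$means), c(0, 0), tolerance = 1e-12)
  expect_equal(mm2$covariances[[1]], diag(c(1 + d^2, 1)), tolerance = 1e-12)

  # Monte-Carlo oracle on a random 3-component mixture
  P3 <- random_setup(3)$P
  x <- sample_points(P3, 1e6, seed = 99)
  mm3 <- moment_match(P3)
  expect_equal(as.vector(mm3$means), colMeans(x), tolerance = 0.01)
  expect_equal(mm3$covariances[[1]], unname(stats::cov(x)), tolerance = 0.01)

  # idempotence, exactly
  expect_equal(moment_match(mm3), mm3)
})

test_that("JS divergence is a bounded, symmetric divergence whose sqrt is a metric", {
  P <- random_setup(5)$P
  g <- to_grid(P, 60)
  expect_identical(js_divergence(g, g), 0)

  # disjoint supports: all mass in opposite halves of the box
  m1 <- matrix(0, 40, 40); m1[1:20, ] <- 1
  m2 <- matrix(0, 40, 40); m2[21:40, ] <- 1
  expect_equal(
    js_divergence(grid_density(m1), grid_density(m2)), 1,
    tolerance = 1e-12
  )

  # independent cell-by-cell implementation, different summation order
  g2 <- to_grid(subjective_dist(1, c(1, 1), diag(2)), 60)
  a <- as.vector(g$masses); b <- as.vector(g2$masses)
  m <- (a + b) / 2
  ref <- 0
  for (i in rev(seq_along(a))) { # reverse-order scalar accumulation
    if (a[i] > 0) ref <- ref + 0.5 * a[i] * log2(a[i] / m[i])
    if (b[i] > 0) ref <- ref + 0.5 * b[i] * log2(b[i] / m[i])
  }
  expect_equal(js_divergence(g, g2), ref, tolerance = 1e-9)
  expect_equal(js_divergence(g2, g), js_divergence(g, g2))

  # sqrt-JS triangle inequality on random triples
  for (sd in 1:5) {
    gs <- lapply(1:3, function(i) to_grid(random_setup(10 * sd + i)$P, 40))
    dab <- sqrt(js_divergence(gs[[1]], gs[[2]]))
    dbc <- sqrt(js_divergence(gs[[2]], gs[[3]]))
    dac <- sqrt(js_divergence(gs[[1]], gs[[3]]))
    expect_lte(dac, dab + dbc + 1e-9)
  }

  expect_error(js_divergence(g, to_grid(P, 50)), "share")
})
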