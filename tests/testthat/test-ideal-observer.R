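test_that("familiarity hypothesis likelihoods respect symmetry and ordering", {
  su <- random_setup(21)
  s <- c(1.2, -0.7)
  tr_same <- one_trial("familiarity", c(s, s))
  v <- familiarity_likelihoods(tr_same, su$P, su$params)
  expect_identical(v[1, 1], v[1, 2])

  P <- subjective_dist(1, c(0, 0), diag(2))
  tr <- one_trial("familiarity", c(0, 0, 3, 0))
  v2 <- familiarity_likelihoods(tr, P, observer_params())
  expect_gt(v2[1, 1], v2[1, 2])

  expect_error(
    familiarity_likelihoods(
      one_trial("odd_one_out", rep(0.5, 6)), P, su$params
    ),
    "familiarity"
  )
})

test_that("analytic likelihoods match numerical quadrature", {
  q <- ql_grid(200, 10)
  for (sd in 31:35) {
    su <- random_setup(sd)
    set.seed(sd + 700)
    tf <- one_trial("familiarity", runif(4, -3, 3))
    expect_equal(
      as.vector(familiarity_likelihoods(tf, su$P, su$params)),
      oracle_familiarity(tf, su$P, su$params, q),
      tolerance = 1e-6
    )
    to <- one_trial("odd_one_out", runif(6, -3, 3))
    expect_equal(
      as.vector(ooo_likelihoods(to, su$P, su$params)),
      oracle_ooo(to, su$P, su$params, q),
      tolerance = 1e-6
    )
  }
})

test_that("odd-one-out likelihoods are symmetric for symmetric geometry and
           favor discrimination near high-density regions", {
  # equilateral triad centered on a rotationally symmetric prior
  P <- subjective_dist(1, c(0, 0), diag(2))
  tr <- one_trial("odd_one_out", equilateral(c(0, 0), 2))
  v <- ooo_likelihoods(tr, P, observer_params())
  expect_equal(v[1, 1], v[1, 2], tolerance = 1e-12)
  expect_equal(v[1, 2], v[1, 3], tolerance = 1e-12)

  # stimuli 1,2 near a high-density mode, stimulus 3 in a low-density region:
  # the hypotheses placing the odd one inside the dense pair beat hypothesis 3
  Pb <- subjective_dist(
    c(0.5, 0.5), rbind(c(-2, 0), c(2, 0)),
    list(0.25 * diag(2), 0.25 * diag(2))
  )
  # equilateral triad so the pairwise geometry is shared across hypotheses
  v1 <- equilateral(c(0, 0), 2, phi = pi / 7)
  # place vertex 3 in the low-density region, vertices 1,2 near the mode
  shift <- c(-2, 0) - (v1[1:2] + v1[3:4]) / 2
  tri <- v1 + rep(shift, 3)
  tr3 <- one_trial("odd_one_out", tri)
  v3 <- ooo_likelihoods(tr3, Pb, observer_params(perceptual_sigma = 0.3))
  expect_gt(max(v3[1, 1], v3[1, 2]), v3[1, 3])
})

test_that("the decision rule maps likelihoods to calibrated choice probabilities", {
  pars <- observer_params(temperature = 2.7, lapse = 0.13)
  p_eq <- choice_probabilities(matrix(c(0.4, 0.4, 0.4), 1), pars)
  expect_equal(as.vector(p_eq), rep(1 / 3, 3), tolerance = 1e-12)

  p_lapse <- choice_probabilities(
    matrix(c(10, 1e-4), 1),
    observer_params(lapse = 1)
  )
  expect_equal(as.vector(p_lapse), c(0.5, 0.5), tolerance = 1e-12)

  p_sharp <- choice_probabilities(
    matrix(c(2, 1, 0.5), 1),
    observer_params(temperature = 1000, lapse = 0)
  )
  expect_gt(p_sharp[1, 1], 0.999)

  expect_equal(rowSums(choice_probabilities(
    matrix(runif(30, 0.1, 2), 10), pars
  )), rep(1, 10), tolerance = 1e-12)
})

test_that("response probabilities compose the pieces and respect symmetries", {
  su <- random_setup(41)

  tr_same <- one_trial("familiarity", c(0.3, 0.3, 0.3, 0.3))
  expect_equal(
    as.vector(response_probabilities(tr_same, su$P, su$params)),
    c(0.5, 0.5),
    tolerance = 1e-12
  )

  P0 <- subjective_dist(1, c(0, 0), diag(2))
  tri <- one_trial("odd_one_out", equilateral(c(0, 0), 2.5))
  expect_equal(
    as.vector(response_probabilities(tri, P0, su$params)),
    rep(1 / 3, 3),
    tolerance = 1e-12
  )

  # composition identity
  set.seed(42)
  tro <- one_trial("odd_one_out", runif(6, -2, 2))
  expect_equal(
    response_probabilities(tro, su$P, su$params),
    choice_probabilities(ooo_likelihoods(tro, su$P, su$params), su$params)
  )

  # permutation equivariance
  perm <- one_trial("odd_one_out", c(
    tro$s3_x, tro$s3_y, tro$s1_x, tro$s1_y, tro$s2_x, tro$s2_y
  ))
  p <- response_probabilities(tro, su$P, su$params)
  pp <- response_probabilities(perm, su$P, su$params)
  expect_equal(as.vector(pp), as.vector(p)[c(3, 1, 2)], tolerance = 1e-12)

  # huge perceptual noise washes out the prior on equidistant triads
  pu <- response_probabilities(
    tri, su$P,
    observer_params(perceptual_sigma = 100, temperature = 3, lapse = 0)
  )
  expect_equal(as.vector(pu), rep(1 / 3, 3), tolerance = 1e-4)

  expect_equal(rowSums(response_probabilities(
    make_stimuli("odd_one_out", 20, seed = 5), su$P, su$params
  )), rep(1, 22), tolerance = 1e-12)
})

test_that("familiarity-based odd-one-out rules order and mirror correctly", {
  su <- random_setup(51)
  P0 <- subjective_dist(1, c(0, 0), diag(2))
  tri <- one_trial("odd_one_out", equilateral(c(0, 0), 2))
  for (mode in c("most", "least")) {
    expect_equal(
      as.vector(ooo_by_familiarity(tri, P0, su$params, mode)),
      rep(1 / 3, 3),
      tolerance = 1e-12
    )
  }

  # strictly ordered familiarity along a density gradient
  tr <- one_trial("odd_one_out", c(0, 0, 1.5, 0, 3, 0))
  sharp <- observer_params(perceptual_sigma = 0.5, temperature = 50, lapse = 0)
  p_most <- ooo_by_familiarity(tr, P0, sharp, "most")
  p_least <- ooo_by_familiarity(tr, P0, sharp, "least")
  expect_equal(which.max(p_most), 1) # densest stimulus
  expect_equal(which.max(p_least), 3) # sparsest stimulus

  # rank order reverses exactly between modes
  set.seed(9)
  tr2 <- one_trial("odd_one_out", runif(6, -3, 3))
  pm <- ooo_by_familiarity(tr2, su$P, su$params, "most")
  pl <- ooo_by_familiarity(tr2, su$P, su$params, "least")
  expect_identical(order(pm), rev(order(pl)))

  expect_error(
    ooo_by_familiarity(
      one_trial("familiarity", rep(0, 4)), su$P, su$params
    ),
    "odd-one-out"
  )
})

test_that("the compiled likelihood path agrees with the analytic R path", {
  for (sd in 61:63) {
    su <- random_setup(sd)
    cf <- t(vapply(
      su$P$covariances,
      function(S) c(S[1, 1], S[1, 2], S[2, 2]), numeric(3)
    ))
    lu <- log(uniform_density(su$P$space))
    fam <- make_stimuli("familiarity", 50, seed = sd)
    p_r <- response_probabilities(fam, su$P, su$params)
    p_c <- cogtomo:::cpp_response_prob(
      as.matrix(fam[, 3:6]), 2L, su$P$weights, su$P$means, cf,
      su$params$perceptual_sigma, su$params$temperature, su$params$lapse, lu
    )
    expect_equal(p_r, p_c, tolerance = 1e-10)

    ooo <- make_stimuli("odd_one_out", 50, seed = sd + 1)
    p_r2 <- response_probabilities(ooo, su$P, su$params)
    p_c2 <- cogtomo:::cpp_response_prob(
      as.matrix(ooo[, 3:8]), 3L, su$P$weights, su$P$means, cf,
      su$params$perceptual_sigma, su$params$temperature, su$params$lapse, lu
    )
    expect_equal(p_r2, p_c2, tolerance = 1e-10)
  }
})
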