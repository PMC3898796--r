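test_that("posterior-averaged prediction reduces to the right arithmetic", {
  su <- random_setup(91)
  other <- random_setup(92)
  trials <- make_stimuli("familiarity", 25, repeat_fraction = 0, seed = 10)

  one <- manual_fit(list(su))
  p1 <- predict(one, trials)
  expect_equal(
    prediction_unname(p1),
    response_probabilities(trials, su$P, su$params),
    tolerance = 1e-12
  )

  two <- manual_fit(list(su, other))
  p2 <- predict(two, trials)
  direct <- (response_probabilities(trials, su$P, su$params) +
    response_probabilities(trials, other$P, other$params)) / 2
  expect_equal(prediction_unname(p2), direct, tolerance = 1e-12)

  # symmetry survives averaging
  sym <- one_trial("familiarity", c(0.4, -1, 0.4, -1))
  ps <- predict(two, sym)
  expect_equal(c(ps$p1, ps$p2), c(0.5, 0.5), tolerance = 1e-12)

  # source task travels with the posterior
  fit <- manual_fit(list(su), task = "odd_one_out")
  expect_identical(unique(predict(fit, trials)$source_task), "odd_one_out")
})

test_that("predictive performance scores assigned probability and accuracy", {
  trials <- make_stimuli("familiarity", 2, repeat_fraction = 0, seed = 11)
  resp <- trials
  resp$choice <- c(0L, 1L)
  pred <- tibble::tibble(
    trial_id = trials$trial_id, task = "familiarity",
    source_task = "familiarity", p1 = c(0.8, 0.6), p2 = c(0.2, 0.4)
  )
  expect_equal(predictive_performance(pred, resp), 0.6)
  expect_equal(predictive_performance(pred, resp, "accuracy"), 0.5)

  # perfect and uniform predictors
  perfect <- pred
  perfect$p1 <- c(1, 0)
  perfect$p2 <- c(0, 1)
  expect_equal(predictive_performance(perfect, resp), 1)

  tri <- make_stimuli("odd_one_out", 10, repeat_fraction = 0, seed = 12)
  tri$choice <- rep(0L, 10)
  unif <- tibble::tibble(
    trial_id = tri$trial_id, task = "odd_one_out",
    source_task = "odd_one_out",
    p1 = 1 / 3, p2 = 1 / 3, p3 = 1 / 3
  )
  expect_equal(predictive_performance(unif, tri), 1 / 3)

  expect_error(
    predictive_performance(pred[2:1, ], resp),
    "misaligned"
  )
})

test_that("consistency pools matching response pairs across repeat groups", {
  base <- make_stimuli("familiarity", 6, repeat_fraction = 0, seed = 13)
  r <- dplyr::bind_rows(base, base, base[1:3, ])
  r$trial_id <- seq_len(nrow(r))
  r$repeat_group <- c(1:6, 1:6, 1:3)
  r$choice <- 0L
  expect_equal(consistency_score(r), 1)

  # one group of three presentations answered (0, 0, 1): one pair of three
  r3 <- dplyr::bind_rows(base[1, ], base[1, ], base[1, ])
  r3$trial_id <- 1:3
  r3$repeat_group <- 1L
  r3$choice <- c(0L, 0L, 1L)
  expect_equal(consistency_score(r3), 1 / 3)

  expect_error(consistency_score(base |> dplyr::mutate(choice = 0L)), "repeat")

  # simulated binomial responder: consistency -> p^2 + (1-p)^2
  set.seed(14)
  p <- 0.9
  n_pairs <- 10000
  choices <- matrix(stats::rbinom(2 * n_pairs, 1, 1 - p), ncol = 2)
  rr <- base[rep(1, 2 * n_pairs), ]
  rr$trial_id <- seq_len(2 * n_pairs)
  rr$repeat_group <- rep(seq_len(n_pairs), each = 2)
  rr$choice <- as.integer(t(choices))
  expect_equal(consistency_score(rr), p^2 + (1 - p)^2, tolerance = 0.01)
})

test_that("the consistency-derived bound inverts the symmetric response model", {
  expect_equal(consistency_upper_bound(1, 2), 1)
  expect_equal(consistency_upper_bound(1, 3), 1)
  expect_equal(consistency_upper_bound(0.5, 2), 0.5)
  expect_equal(consistency_upper_bound(1 / 3, 3), 1 / 3, tolerance = 1e-12)

  # closed-form round trip: c(p) then bound(c) returns p
  for (p in seq(0.5, 1, by = 0.1)) {
    expect_equal(consistency_upper_bound(p^2 + (1 - p)^2, 2), p,
      tolerance = 1e-12
    )
  }
  for (p in seq(1 / 3, 1, by = 0.1)) {
    expect_equal(consistency_upper_bound(p^2 + (1 - p)^2 / 2, 3), p,
      tolerance = 1e-12
    )
  }

  # strictly increasing in c
  for (n in c(2, 3)) {
    cs <- seq(1 / n + 0.01, 0.99, length.out = 20)
    bs <- vapply(cs, consistency_upper_bound, numeric(1), n_alternatives = n)
    expect_true(all(diff(bs) > 0))
  }

  expect_error(consistency_upper_bound(0.2, 2), "below chance")
})

test_that("evaluation reports bundle performance, chance, consistency and bound", {
  truth <- make_ground_truth(95, K = 2, separation = 3)
  params <- observer_params()
  resp <- simulate_responses(
    make_stimuli("odd_one_out", 200, repeat_fraction = 0.3, seed = 15),
    truth, params,
    seed = 16
  )
  pred <- predict(manual_fit(list(list(P = truth, params = params)),
    task = "odd_one_out"
  ), resp)
  ev <- evaluate_predictions(pred, resp)
  expect_equal(ev$chance, 1 / 3)
  expect_gt(ev$performance, ev$chance)
  expect_true(ev$consistency >= 0 && ev$consistency <= 1)
  expect_gte(ev$upper_bound, 1 / 3)
})
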