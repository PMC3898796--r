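#' Read and write trial and response tables
#'
#' CSV round-trip for trial/response tibbles. Columns are `trial_id, task,
#' s1_x, s1_y, s2_x, s2_y, s3_x, s3_y, repeat_group` plus `choice` for
#' responses; coordinates in SD units, choices 0-based, `s3_*` blank for
#' familiarity trials. Files are validated on read and full floating-point
#' precision is preserved.
#'
#' @param path File path.
#' @param trials,responses The tibble to write.
#' @return The validated tibble (readers) or the input, invisibly (writers).
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
read_trials <- function(path) {
  validate_trials(read_trial_csv(path, responses = FALSE))
}

#' @rdname trial_io
#' @export
read_responses <- function(path) {
  validate_trials(read_trial_csv(path, responses = TRUE), responses = TRUE)
}

#' @keywords internal
read_trial_csv <- function(path, responses) {
  cols <- readr::cols(
    trial_id = readr::col_integer(),
    task = readr::col_character(),
    s1_x = readr::col_double(), s1_y = readr::col_double(),
    s2_x = readr::col_double(), s2_y = readr::col_double(),
    s3_x = readr::col_double(), s3_y = readr::col_double(),
    repeat_group = readr::col_integer()
  )
  if (responses) cols$cols$choice <- readr::col_integer()
  readr::read_csv(path, col_types = cols)
}

#' @rdname trial_io
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(validate_trials(trials), path)
  invisible(trials)
}

#' @rdname trial_io
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(validate_trials(responses, responses = TRUE), path)
  invisible(responses)
}

#' Serialize a subjective distribution to JSON
#'
#' @param P A [subjective_dist()].
#' @param path File path.
#' @return `P`, invisibly (writer); a [subjective_dist()] (reader).
#' @export
write_subjective_json <- function(P, path) {
  stopifnot(inherits(P, "subjective_dist"))
  obj <- list(
    space = list(half_width = P$space$half_width, n_dims = P$space$n_dims),
    weights = P$weights,
    means = P$means,
    covariances = P$covariances
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(P)
}

#' @rdname write_subjective_json
#' @export
read_subjective_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  space <- feature_space(obj$space$half_width, obj$space$n_dims)
  covs <- obj$covariances
  if (is.array(covs) && length(dim(covs)) == 3) {
    covs <- lapply(seq_len(dim(covs)[1]), function(k) {
      matrix(covs[k, , ], dim(covs)[2])
    })
  }
  subjective_dist(obj$weights, rbind(obj$means), covs, space)
}

#' Serialize a fitted posterior to JSON
#'
#' Writes all retained draws, the log-posterior trace, acceptance rates,
#' seed, priors, sampler settings, and a provenance block so a fit is fully
#' reproducible from its file.
#'
#' @param fit A `cogtomo_fit`.
#' @param path File path.
#' @return `fit`, invisibly (writer); a `cogtomo_fit` (reader).
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cogtomo_fit"))
  obj <- list(
    task = fit$task, seed = fit$seed, n_responses = fit$n_responses,
    space = list(
      half_width = fit$space$half_width,
      n_dims = fit$space$n_dims
    ),
    prior = unclass(fit$prior), settings = fit$settings,
    draws = fit$draws,
    log_posterior_trace = fit$log_posterior_trace,
    acceptance_rates = as.list(fit$acceptance_rates),
    provenance = provenance_block(fit$seed, unclass(fit$prior))
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(fit)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prior <- do.call(prior_config, lapply(obj$prior, unlist))
  draws <- obj$draws
  draws$weights <- rbind(draws$weights)
  draws$means <- rbind(draws$means)
  draws$covs <- rbind(draws$covs)
  structure(
    list(
      draws = draws,
      log_posterior_trace = obj$log_posterior_trace,
      acceptance_rates = unlist(obj$acceptance_rates),
      task = obj$task, seed = obj$seed, prior = prior,
      space = feature_space(obj$space$half_width, obj$space$n_dims),
      settings = obj$settings, n_responses = obj$n_responses
    ),
    class = "cogtomo_fit"
  )
}

#' Grid density CSV export
#'
#' Long-format `(x, y, mass)` table of cell centers and masses, for
#' plotting outside R.
#'
#' @param g A `grid_density`.
#' @param path File path.
#' @return `g` invisibly (writer); a `grid_density` (reader).
#' @export
write_grid_csv <- function(g, path) {
  stopifnot(inherits(g, "grid_density"))
  readr::write_csv(tidy.grid_density(g), path)
  invisible(g)
}

#' @rdname write_grid_csv
#' @param space A [feature_space()] matching the file.
#' @export
read_grid_csv <- function(path, space = feature_space()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    x = readr::col_double(), y = readr::col_double(),
    mass = readr::col_double()
  ))
  res <- length(unique(df$x))
  df <- dplyr::arrange(df, .data$y, .data$x)
  grid_density(matrix(df$mass, res, res), space)
}

#' Distance matrix CSV round-trip (long pair format)
#'
#' @param dm A `cogtomo_dist`.
#' @param path File path.
#' @return `dm` invisibly (writer); a `cogtomo_dist` (reader).
#' @export
write_distance_csv <- function(dm, path) {
  stopifnot(inherits(dm, "cogtomo_dist"))
  out <- tidy.cogtomo_dist(dm)
  out$metric <- dm$metric
  readr::write_csv(out, path)
  invisible(dm)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  labels <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(subject = df$subject_a, task = df$task_a),
    tibble::tibble(subject = df$subject_b, task = df$task_b)
  ))
  n <- nrow(labels)
  key <- paste(labels$subject, labels$task)
  values <- matrix(0, n, n)
  ia <- match(paste(df$subject_a, df$task_a), key)
  ib <- match(paste(df$subject_b, df$task_b), key)
  values[cbind(ia, ib)] <- df$distance
  values[cbind(ib, ia)] <- df$distance
  structure(
    list(labels = labels, values = values, metric = unique(df$metric)),
    class = "cogtomo_dist"
  )
}

#' Prediction table CSV round-trip
#'
#' @param pred A prediction tibble.
#' @param path File path.
#' @return `pred` invisibly (writer); a prediction tibble (reader).
#' @export
write_predictions <- function(pred, path) {
  readr::write_csv(pred, path)
  invisible(pred)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial_id = readr::col_integer(),
    task = readr::col_character(),
    source_task = readr::col_character(),
    .default = readr::col_double()
  ))
}

#' Provenance block for pipeline outputs
#'
#' A small list stamped into JSON outputs (and written as a sidecar by the
#' command-line tool): package version, seed, and a hash of the
#' configuration, so identical inputs reproduce byte-identical payloads.
#'
#' @param seed Integer seed used.
#' @param config A list of settings to hash.
#' @return A named list.
#' @export
provenance_block <- function(seed, config = list()) {
  cfg <- jsonlite::toJSON(config, digits = I(17), auto_unbox = TRUE)
  list(
    package = "cogtomo",
    version = as.character(utils::packageVersion("cogtomo")),
    seed = seed,
    config_hash = rlang::hash(as.character(cfg))
  )
}
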