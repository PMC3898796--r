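#' Trial and response tables
#'
#' Trials and responses are plain tibbles so they pipe through dplyr verbs
#' and read/write as CSV. A trial table has one row per presentation with
#' columns:
#' \describe{
#'   \item{trial_id}{integer, unique per row}
#'   \item{task}{`"familiarity"` (two stimuli) or `"odd_one_out"` (three)}
#'   \item{s1_x, s1_y, s2_x, s2_y, s3_x, s3_y}{stimulus coordinates in SD
#'     units; `s3_*` are `NA` for familiarity trials}
#'   \item{repeat_group}{integer linking repeated presentations of identical
#'     stimuli, `NA` when the trial is not repeated}
#' }
#' A response table additionally has `choice`, the 0-based index of the
#' chosen stimulus.
#'
#' @param trials A data frame to validate.
#' @param responses Logical; if `TRUE`, also require and validate `choice`.
#' @return The validated tibble (invisibly coerced column types).
#' @export
validate_trials <- function(trials, responses = FALSE) {
  trials <- tibble::as_tibble(trials)
  need <- c(
    "trial_id", "task", "s1_x", "s1_y", "s2_x", "s2_y",
    "s3_x", "s3_y", "repeat_group"
  )
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  bad_task <- setdiff(unique(trials$task), c("familiarity", "odd_one_out"))
  if (length(bad_task)) {
    stop("unknown task string: ", paste(bad_task, collapse = ", "),
      call. = FALSE
    )
  }
  fam <- trials$task == "familiarity"
  if (any(fam & (is.na(trials$s1_x) | is.na(trials$s2_x)))) {
    stop("familiarity trials need s1 and s2 coordinates", call. = FALSE)
  }
  ooo <- trials$task == "odd_one_out"
  if (any(ooo & (is.na(trials$s1_x) | is.na(trials$s2_x) |
    is.na(trials$s3_x)))) {
    stop("odd-one-out trials need s1, s2 and s3 coordinates", call. = FALSE)
  }
  if (responses) {
    if (!"choice" %in% names(trials)) {
      stop("response table missing 'choice'", call. = FALSE)
    }
    n_alt <- ifelse(fam, 2L, 3L)
    ok <- !is.na(trials$choice) & trials$choice >= 0 & trials$choice < n_alt
    if (!all(ok)) {
      stop("choice out of range (0-based) on trial_id ",
        paste(utils::head(trials$trial_id[!ok], 5), collapse = ", "),
        call. = FALSE
      )
    }
    trials$choice <- as.integer(trials$choice)
  }
  trials$trial_id <- as.integer(trials$trial_id)
  trials$repeat_group <- as.integer(trials$repeat_group)
  trials
}

#' @keywords internal
single_task <- function(trials) {
  tk <- unique(trials$task)
  if (length(tk) != 1) {
    stop("expected trials from a single task, got: ",
      paste(tk, collapse = ", "),
      call. = FALSE
    )
  }
  tk
}

#' @keywords internal
stim_matrix <- function(trials, task) {
  if (task == "familiarity") {
    as.matrix(trials[, c("s1_x", "s1_y", "s2_x", "s2_y")])
  } else {
    as.matrix(trials[, c("s1_x", "s1_y", "s2_x", "s2_y", "s3_x", "s3_y")])
  }
}

#' @keywords internal
n_alternatives <- function(task) {
  switch(task,
    familiarity = 2L,
    odd_one_out = 3L,
    stop("unknown task: ", task, call. = FALSE)
  )
}
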