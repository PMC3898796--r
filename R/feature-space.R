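#' Define the bounded stimulus feature space
#'
#' The feature space is the box over which subjective distributions live:
#' stimuli are points whose coordinates are measured in standard-deviation
#' units along each axis (for face stimuli, the first principal components of
#' face structure). The box spans `±half_width` along each of `n_dims`
#' dimensions.
#'
#' @param half_width Positive half-extent of the box per dimension, in SD
#'   units. The default of 4 matches the usual plotting range of ±4 SD.
#' @param n_dims Number of dimensions. The package's tested configuration is
#'   2-D; the math is written generically but only `n_dims = 2` is exercised.
#'
#' @return An object of class `feature_space`.
#' @examples
#' sp <- feature_space()
#' uniform_density(sp) # (2 * 4)^-2
#' @export
feature_space <- function(half_width = 4, n_dims = 2) {
  stopifnot(is.numeric(half_width), length(half_width) == 1, half_width > 0)
  stopifnot(is.numeric(n_dims), length(n_dims) == 1, n_dims >= 1)
  structure(
    list(half_width = as.numeric(half_width), n_dims = as.integer(n_dims)),
    class = "feature_space"
  )
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf(
    "<feature_space> %d-D box, ±%g SD per dimension\n",
    x$n_dims, x$half_width
  ))
  invisible(x)
}

#' Uniform density over the feature box
#'
#' The density of the uniform distribution over the feature box,
#' `(2 * half_width)^(-n_dims)`. This is the marginal assigned to an
#' "unfamiliar" face in the familiarity-task ideal observer.
#'
#' @param space A [feature_space()].
#' @return A positive scalar.
#' @export
uniform_density <- function(space) {
  stopifnot(inherits(space, "feature_space"))
  (2 * space$half_width)^(-space$n_dims)
}

#' @keywords internal
same_space <- function(a, b, tol = 1e-12) {
  abs(a$half_width - b$half_width) < tol && a$n_dims == b$n_dims
}

#' @keywords internal
check_points <- function(x, space) {
  x <- rbind(x)
  if (ncol(x) != space$n_dims) {
    stop("points must have ", space$n_dims, " columns, got ", ncol(x),
      call. = FALSE
    )
  }
  x
}
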