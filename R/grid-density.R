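#' Discretize a subjective distribution on a regular grid
#'
#' Evaluates the density at the centers of a `resolution x resolution` grid of
#' cells tiling the feature box exactly, then renormalizes the cell masses to
#' sum to one. Grid densities are the common currency for Jensen-Shannon
#' divergences, posterior-mean "tomograms", and plotting.
#'
#' @param P A [subjective_dist()].
#' @param resolution Cells per dimension (>= 8; default 100).
#' @return An object of class `grid_density`: the space, the resolution, the
#'   vector of cell-center coordinates per axis, and the matrix of masses
#'   (rows index x, columns index y).
#' @export
to_grid <- function(P, resolution = 100) {
  stopifnot(inherits(P, "subjective_dist"))
  if (resolution < 8) stop("resolution must be >= 8", call. = FALSE)
  resolution <- as.integer(resolution)
  centers <- grid_centers(P$space, resolution)
  xy <- as.matrix(expand.grid(x = centers, y = centers))
  d <- density_at(P, xy)
  m <- matrix(d, resolution, resolution)
  new_grid_density(P$space, resolution, m / sum(m))
}

#' @keywords internal
grid_centers <- function(space, resolution) {
  h <- space$half_width
  step <- 2 * h / resolution
  seq(-h + step / 2, h - step / 2, length.out = resolution)
}

#' @keywords internal
new_grid_density <- function(space, resolution, masses) {
  stopifnot(all(masses >= 0), abs(sum(masses) - 1) < 1e-9)
  structure(
    list(
      space = space, resolution = as.integer(resolution),
      centers = grid_centers(space, resolution), masses = masses
    ),
    class = "grid_density"
  )
}

#' Construct a grid density from raw nonnegative masses
#'
#' @param masses A square matrix of nonnegative masses; renormalized to sum
#'   to one.
#' @param space A [feature_space()].
#' @return A `grid_density`.
#' @export
grid_density <- function(masses, space = feature_space()) {
  masses <- as.matrix(masses)
  stopifnot(nrow(masses) == ncol(masses), all(masses >= 0), sum(masses) > 0)
  new_grid_density(space, nrow(masses), masses / sum(masses))
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf(
    "<grid_density> %d x %d cells on a ±%g SD box\n",
    x$resolution, x$resolution, x$space$half_width
  ))
  invisible(x)
}

#' Grid mean and covariance
#'
#' First and second moments of a discretized density, taken over cell centers.
#'
#' @param g A `grid_density`.
#' @return A list with `mean` (length 2) and `cov` (2 x 2).
#' @export
grid_moments <- function(g) {
  stopifnot(inherits(g, "grid_density"))
  xy <- as.matrix(expand.grid(x = g$centers, y = g$centers))
  w <- as.vector(g$masses)
  mu <- colSums(xy * w)
  xc <- sweep(xy, 2, mu)
  S <- crossprod(xc * w, xc)
  list(mean = mu, cov = S)
}

#' @keywords internal
check_same_grid <- function(p, q) {
  if (!inherits(p, "grid_density") || !inherits(q, "grid_density")) {
    stop("inputs must be grid_density objects", call. = FALSE)
  }
  if (p$resolution != q$resolution || !same_space(p$space, q$space)) {
    stop("grids must share space and resolution", call. = FALSE)
  }
}

#' Jensen-Shannon divergence between two grid densities (bits)
#'
#' `JS(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2` and base-2
#' logarithms, so the result lies in `[0, 1]` bits: 0 for identical grids, 1
#' for disjoint support. `0 * log(0)` is treated as 0. The square root of the
#' JS divergence is a metric and is what feeds multidimensional scaling.
#'
#' @param p,q `grid_density` objects sharing space and resolution.
#' @return A scalar in `[0, 1]` (bits).
#' @export
js_divergence <- function(p, q) {
  check_same_grid(p, q)
  a <- as.vector(p$masses)
  b <- as.vector(q$masses)
  m <- (a + b) / 2
  kl <- function(u, v) {
    i <- u > 0
    sum(u[i] * (log2(u[i]) - log2(v[i])))
  }
  js <- kl(a, m) / 2 + kl(b, m) / 2
  min(max(js, 0), 1)
}

#' Tidy a grid density into a long table
#'
#' @param x A `grid_density`.
#' @param ... Unused.
#' @return A tibble with columns `x`, `y`, `mass` (one row per cell).
#' @export
tidy.grid_density <- function(x, ...) {
  xs <- rep(x$centers, times = x$resolution)
  ys <- rep(x$centers, each = x$resolution)
  ms <- as.vector(x$masses)
  tibble::tibble(x = xs, y = ys, mass = ms)
}

#' Plot a grid density as a heat map
#'
#' @param object A `grid_density`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grid_density <- function(object, ...) {
  df <- tidy.grid_density(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$mass)) +
    ggplot2::scale_fill_gradient(low = "white", high = "black") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "feature 1 (SD)", y = "feature 2 (SD)", fill = "mass"
    ) +
    ggplot2::theme_minimal()
}
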