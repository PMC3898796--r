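#' Pairwise Jensen-Shannon distance matrix between recovered priors
#'
#' Computes all pairwise JS divergences (or their square roots, a true
#' metric) between labeled grid densities — typically the posterior-mean
#' grids of several subjects fitted on each task. With 20 labeled grids the
#' strict upper triangle holds 190 distances.
#'
#' @param grids A tibble with columns `subject`, `task`, and a list-column
#'   `grid` of `grid_density` objects sharing space and resolution.
#' @param metric `"js_bits"` (raw JS, bits) or `"sqrt_js"` (its square
#'   root; use this for multidimensional scaling).
#' @return An object of class `cogtomo_dist`: `labels` (tibble), `values`
#'   (symmetric matrix, zero diagonal), `metric`.
#' @export
distance_matrix <- function(grids, metric = c("js_bits", "sqrt_js")) {
  metric <- match.arg(metric)
  stopifnot(
    is.data.frame(grids),
    all(c("subject", "task", "grid") %in% names(grids)),
    nrow(grids) >= 2
  )
  n <- nrow(grids)
  g <- grids$grid
  for (i in seq_len(n - 1)) check_same_grid(g[[i]], g[[i + 1]])
  values <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- js_divergence(g[[i]], g[[j]])
      if (metric == "sqrt_js") d <- sqrt(d)
      values[i, j] <- d
      values[j, i] <- d
    }
  }
  structure(
    list(
      labels = tibble::tibble(
        subject = grids$subject,
        task = grids$task
      ),
      values = values, metric = metric
    ),
    class = "cogtomo_dist"
  )
}

#' @export
print.cogtomo_dist <- function(x, ...) {
  cat(sprintf(
    "<cogtomo_dist> %d items, metric %s\n", nrow(x$labels), x$metric
  ))
  invisible(x)
}

#' Tidy a distance matrix into a long pair table
#'
#' @param x A `cogtomo_dist`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `subject_a`, `task_a`,
#'   `subject_b`, `task_b`, `distance`.
#' @export
tidy.cogtomo_dist <- function(x, ...) {
  n <- nrow(x$labels)
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble::tibble(
    subject_a = x$labels$subject[idx[, 1]],
    task_a = x$labels$task[idx[, 1]],
    subject_b = x$labels$subject[idx[, 2]],
    task_b = x$labels$task[idx[, 2]],
    distance = x$values[idx]
  )
}

#' Within-subject versus between-subject divergence test
#'
#' The task-invariance analysis: per task, compares same-subject,
#' different-task distances against different-subject, same-task distances
#' with a one-sided Wilcoxon rank-sum test (within < between). If priors
#' are subject-specific but task-invariant, within-subject cross-task
#' distances should be systematically smaller.
#'
#' @param dm A `cogtomo_dist` whose labels contain >= 2 subjects x 2 tasks.
#' @return A tibble with one row per task: `task`, `within_mean`,
#'   `between_mean`, `statistic`, `p_value`.
#' @export
within_between_test <- function(dm) {
  stopifnot(inherits(dm, "cogtomo_dist"))
  pairs <- tidy.cogtomo_dist(dm)
  tasks <- sort(unique(dm$labels$task))
  subjects <- unique(dm$labels$subject)
  if (length(tasks) < 2 || length(subjects) < 2) {
    stop("need >= 2 subjects and 2 tasks", call. = FALSE)
  }
  within <- pairs |>
    dplyr::filter(.data$subject_a == .data$subject_b,
      .data$task_a != .data$task_b
    ) |>
    dplyr::pull(.data$distance)
  purrr::map_dfr(tasks, function(tk) {
    between <- pairs |>
      dplyr::filter(.data$subject_a != .data$subject_b,
        .data$task_a == tk, .data$task_b == tk
      ) |>
      dplyr::pull(.data$distance)
    if (length(within) == 0 || length(between) == 0) {
      stop("degenerate label structure", call. = FALSE)
    }
    if (all(c(within, between) == c(within, between)[1])) {
      # all distances identical (e.g. all-zero): nothing to detect
      return(tibble::tibble(
        task = tk, within_mean = mean(within),
        between_mean = mean(between), statistic = NA_real_, p_value = 1
      ))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(within, between, alternative = "less", exact = FALSE)
    )
    tibble::tibble(
      task = tk, within_mean = mean(within), between_mean = mean(between),
      statistic = unname(wt$statistic), p_value = wt$p.value
    )
  })
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Torgerson MDS: double-centers the squared distances and embeds on the
#' top eigenvectors scaled by root eigenvalues (via [stats::cmdscale()]).
#' Requires the `sqrt_js` metric, which satisfies the triangle inequality;
#' raw JS in bits does not. Deterministic up to per-axis sign, which is
#' fixed by making the largest-magnitude coordinate on each axis positive.
#' If more than 10% of the eigenvalue mass is negative the input is flagged
#' as substantially non-Euclidean with a warning.
#'
#' @param dm A `cogtomo_dist` with `metric = "sqrt_js"`.
#' @param dim Embedding dimensionality (>= 1, default 2).
#' @return A tibble: `subject`, `task`, `dim1` ... `dim<dim>`, rows in the
#'   label order of `dm`.
#' @export
mds_embed <- function(dm, dim = 2) {
  stopifnot(inherits(dm, "cogtomo_dist"), dim >= 1)
  if (dm$metric != "sqrt_js") {
    stop("mds_embed requires the sqrt_js metric", call. = FALSE)
  }
  n <- nrow(dm$labels)
  fit <- suppressWarnings(
    stats::cmdscale(dm$values, k = min(dim, n - 1), eig = TRUE)
  )
  eig <- fit$eig
  neg_mass <- sum(abs(eig[eig < 0])) / max(sum(abs(eig)), .Machine$double.eps)
  if (neg_mass > 0.10) {
    warning(sprintf(
      "distance matrix is substantially non-Euclidean (%.0f%% negative eigenvalue mass)",
      100 * neg_mass
    ), call. = FALSE)
  }
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < dim) {
    pad <- matrix(0, n, dim - ifelse(is.null(pts), 0, ncol(pts)))
    pts <- cbind(pts, pad)
  }
  pts <- pts[, seq_len(dim), drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (length(i) && pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  out <- dm$labels
  colnames(pts) <- paste0("dim", seq_len(dim))
  dplyr::bind_cols(out, tibble::as_tibble(pts))
}

#' Plot an MDS embedding of recovered priors
#'
#' @param object A `cogtomo_dist` with `metric = "sqrt_js"`.
#' @param ... Unused.
#' @return A ggplot object: points colored by subject, shaped by task, with
#'   same-subject points connected.
#' @export
autoplot.cogtomo_dist <- function(object, ...) {
  emb <- mds_embed(object, 2)
  ggplot2::ggplot(emb, ggplot2::aes(
    x = .data$dim1, y = .data$dim2,
    colour = factor(.data$subject)
  )) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject),
      linewidth = 0.3
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$task), size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "MDS dimension 1", y = "MDS dimension 2",
      colour = "subject", shape = "task"
    ) +
    ggplot2::theme_minimal()
}
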