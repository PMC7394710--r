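#' Principal component analysis of a character matrix
#'
#' PCA on the covariance matrix of the mean-centered data (no rescaling
#' beyond centering), the classic ordination baseline for morphometric
#' tables. Components are ordered by descending eigenvalue; the explained
#' variance fractions over all components sum to 1.
#'
#' @param x A [character_matrix].
#' @param n_components Number of components to return (default: all).
#' @return Object of class `ordination_result`: list with `method`
#'   (`"pca"`), `coordinates` (N x m scores), `explained_variance_fraction`
#'   (per returned component), `all_variance_fractions` (all d components),
#'   and `stress` (`NA` for PCA).
#' @export
pca_ordination <- function(x, n_components = NULL) {
  .assert_character_matrix(x)
  d <- ncol(x$values)
  n_components <- as.integer(n_components %||% min(d, nrow(x$values)))
  if (n_components > d) {
    stop(sprintf("n_components = %d exceeds the %d characters", n_components,
                 d), call. = FALSE)
  }
  fit <- stats::prcomp(x$values, center = TRUE, scale. = FALSE)
  fracs <- fit$sdev^2 / sum(fit$sdev^2)
  m <- min(n_components, ncol(fit$x))
  structure(
    list(method = "pca",
         coordinates = fit$x[, seq_len(m), drop = FALSE],
         explained_variance_fraction = fracs[seq_len(m)],
         all_variance_fractions = fracs,
         stress = NA_real_),
    class = "ordination_result")
}

#' Gower distances between individuals
#'
#' Continuous-variable Gower dissimilarity: the mean over characters of the
#' absolute difference divided by that character's range, so every
#' character contributes on a common 0-1 scale irrespective of units.
#' Computed via [vegan::vegdist()].
#'
#' @param x A [character_matrix]; every character must have nonzero range.
#' @return A [stats::dist] object (symmetric, zero diagonal, nonnegative).
#' @export
gower_distance <- function(x) {
  .assert_character_matrix(x)
  rng <- apply(x$values, 2L, function(v) diff(range(v)))
  if (any(rng == 0)) {
    stop("character '", x$character_names[which(rng == 0)[1L]],
         "' has zero range; Gower distance undefined", call. = FALSE)
  }
  vegan::vegdist(x$values, method = "gower")
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style nMDS: iterative minimization of stress-1 with monotone
#' (isotonic) regression of configuration distances on dissimilarity ranks,
#' via [vegan::monoMDS()] (global model). Each of `n_starts` restarts
#' begins from a random configuration drawn from a stream seeded with
#' `seed + start`; because global nMDS depends on the dissimilarities only
#' through their ranks, the result is deterministic given `seed` and
#' invariant under strictly increasing transforms of the dissimilarities.
#' The best (lowest-stress) start is returned, centered.
#'
#' @param distances A [stats::dist] object or symmetric distance matrix.
#' @param dims Number of ordination dimensions (default 2); must be below
#'   N.
#' @param n_starts Number of seeded random starts.
#' @param max_iter Iteration cap per start.
#' @param seed Integer seed.
#' @return Object of class `ordination_result` with `method = "nmds"`,
#'   centered `coordinates` and the final `stress` (Kruskal stress-1; below
#'   0.2 is conventionally an acceptable representation).
#' @export
nmds_ordination <- function(distances, dims = 2L, n_starts = 20L,
                            max_iter = 300L, seed = 1L) {
  if (!inherits(distances, "dist")) {
    if (is.matrix(distances)) {
      if (max(abs(distances - t(distances))) > 1e-10 ||
          any(diag(distances) != 0) || any(distances < 0)) {
        stop("distance matrix must be symmetric, nonnegative, zero-diagonal",
             call. = FALSE)
      }
      distances <- stats::as.dist(distances)
    } else {
      stop("distances must be a dist object or matrix", call. = FALSE)
    }
  }
  n <- attr(distances, "Size")
  dims <- as.integer(dims)
  if (dims >= n) stop("dims must be smaller than N", call. = FALSE)
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  best <- NULL
  for (r in seq_len(n_starts)) {
    init <- with_seed(seed + r, matrix(stats::rnorm(n * dims), n, dims))
    fit <- vegan::monoMDS(distances, y = init, k = dims, model = "global",
                          maxit = max_iter)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- scale(best$points, center = TRUE, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  colnames(coords) <- paste0("MDS", seq_len(dims))
  structure(
    list(method = "nmds", coordinates = coords,
         explained_variance_fraction = NULL,
         all_variance_fractions = NULL,
         stress = best$stress),
    class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result (%s): %d points x %d dimensions\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  if (x$method == "pca") {
    cat("explained variance:",
        paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
              collapse = ", "), "\n")
  } else {
    cat(sprintf("stress: %.4f\n", x$stress))
  }
  invisible(x)
}

#' k-means on the first two ordination dimensions
#'
#' The traditional clustering arm of an ordination workflow: k-means
#' (same seeded-restart engine as the spectral pipeline) applied to the
#' first two dimensions of a PCA or nMDS result. `K` defaults to 10, a
#' cluster count of the order of the number of candidate taxa.
#'
#' @param result An `ordination_result` with at least 2 dimensions.
#' @param K Number of clusters (default 10).
#' @inheritParams kmeans_partition
#' @return A `cluster_assignment`.
#' @export
ordination_kmeans <- function(result, K = 10L, restarts = 100L, seed = 1L) {
  if (!inherits(result, "ordination_result")) {
    stop("result must be an ordination_result", call. = FALSE)
  }
  if (ncol(result$coordinates) < 2L) {
    stop("ordination must have at least 2 dimensions", call. = FALSE)
  }
  kmeans_partition(result$coordinates[, 1:2, drop = FALSE], K,
                   restarts = restarts, seed = seed)
}
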