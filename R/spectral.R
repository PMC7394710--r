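#' Radial basis function similarity matrix
#'
#' Pairwise similarity between individuals,
#' `S_ij = exp(-gamma * scale * ||x_i - x_j||^2)`, where the exponent scale
#' depends on `exponent_scale`: `"divide"` (default) uses `1/d` with `d` the
#' number of characters, so that `gamma` values of order one are sensible
#' regardless of how many standardized characters enter; `"multiply"` uses
#' `d`; `"none"` uses 1. Larger `gamma` sharpens the kernel: small
#' morphological differences are amplified and off-diagonal similarities
#' shrink.
#'
#' @param x A standardized [character_matrix]; a warning is issued if any
#'   column mean exceeds 1e-6 in magnitude.
#' @param gamma Positive kernel width parameter.
#' @param exponent_scale One of `"divide"`, `"multiply"`, `"none"`.
#' @return An object of class `similarity_matrix`: list with `values`
#'   (symmetric N x N matrix, unit diagonal, entries in (0, 1]), `gamma`,
#'   and `exponent_scale`.
#' @export
rbf_similarity <- function(x, gamma,
                           exponent_scale = c("divide", "multiply", "none")) {
  .assert_character_matrix(x)
  exponent_scale <- match.arg(exponent_scale)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("gamma must be a positive number", call. = FALSE)
  }
  if (max(abs(colMeans(x$values))) > 1e-6) {
    warning("input does not look standardized (column means differ from 0); ",
            "call standardize() first", call. = FALSE)
  }
  d <- ncol(x$values)
  scale <- switch(exponent_scale, divide = 1 / d, multiply = d, none = 1)
  d2 <- as.matrix(stats::dist(x$values))^2
  s <- exp(-gamma * scale * d2)
  diag(s) <- 1
  structure(list(values = s, gamma = gamma, exponent_scale = exponent_scale),
            class = "similarity_matrix")
}

#' Suggest a kernel width from the local data scale
#'
#' Bandwidth selection by the k-nearest-neighbour rule common in the
#' spectral clustering literature: the kernel should assign substantial
#' similarity within a point's local neighbourhood and little beyond it.
#' The returned `gamma` makes the kernel exponent (under the default
#' divide-by-d scaling) equal to 1/2 at the median squared distance to the
#' `k`-th nearest neighbour. Useful as a starting point or grid centre
#' when the default grid is poorly matched to the data's scale.
#'
#' @param x A [character_matrix].
#' @param k Neighbour rank defining the local scale (default 7, of the
#'   order of log N for moderate samples).
#' @return A positive `gamma` value for [rbf_similarity()] with
#'   `exponent_scale = "divide"`.
#' @export
suggest_gamma <- function(x, k = 7L) {
  .assert_character_matrix(x)
  n <- nrow(x$values)
  k <- min(as.integer(k), n - 1L)
  d2 <- as.matrix(stats::dist(x$values))^2
  diag(d2) <- Inf
  kd <- apply(d2, 1L, function(r) sort(r, partial = k)[k])
  ncol(x$values) / (2 * stats::median(kd))
}

.assert_similarity <- function(s) {
  if (!inherits(s, "similarity_matrix")) {
    if (is.matrix(s)) {
      s <- structure(list(values = s, gamma = NA_real_,
                          exponent_scale = "none"),
                     class = "similarity_matrix")
    } else {
      stop("expected a similarity_matrix", call. = FALSE)
    }
  }
  v <- s$values
  if (nrow(v) != ncol(v)) stop("similarity matrix must be square", call. = FALSE)
  if (max(abs(v - t(v))) > 1e-10) {
    stop("similarity matrix must be symmetric", call. = FALSE)
  }
  s
}

#' Normalized symmetric graph Laplacian
#'
#' `L = I - D^{-1/2} S D^{-1/2}` with `D_ii = sum_j S_ij`. Eigenvalues of
#' `L` lie in `[0, 2]`; the multiplicity of eigenvalue 0 counts the
#' connected components of the similarity graph.
#'
#' @param s A `similarity_matrix` (from [rbf_similarity()]) or a plain
#'   symmetric nonnegative matrix.
#' @return Object of class `laplacian_bundle`: list with `laplacian` (the
#'   symmetric N x N matrix `L`) and `degrees` (the diagonal of `D`).
#' @export
normalized_laplacian <- function(s) {
  s <- .assert_similarity(s)
  deg <- rowSums(s$values)
  if (any(deg <= 0)) {
    stop("zero row sum at individual ", which(deg <= 0)[1L],
         "; Laplacian normalization undefined", call. = FALSE)
  }
  dm <- 1 / sqrt(deg)
  w <- s$values * outer(dm, dm)
  l <- diag(nrow(w)) - w
  dimnames(l) <- dimnames(s$values)
  structure(list(laplacian = l, degrees = deg), class = "laplacian_bundle")
}

# Full symmetric eigendecomposition, returned in ascending order.
.laplacian_eigen <- function(bundle) {
  e <- eigen(bundle$laplacian, symmetric = TRUE)
  n <- length(e$values)
  list(values = rev(e$values), vectors = e$vectors[, n:1, drop = FALSE])
}

# Build the K-dimensional embedding from a precomputed ascending
# eigendecomposition; shared by spectral_embed() and spectral_sweep() so
# both produce bitwise-identical coordinates.
.embed_from_eigen <- function(eig, K) {
  vecs <- eig$vectors[, seq_len(K), drop = FALSE]
  norms <- sqrt(rowSums(vecs^2))
  zero <- norms < 1e-12
  if (any(zero)) {
    warning(sum(zero), " embedding row(s) have zero norm; left at zero",
            call. = FALSE)
    norms[zero] <- 1
  }
  structure(
    list(coordinates = vecs / norms,
         vectors = vecs,
         eigenvalues = eig$values[seq_len(K)],
         all_eigenvalues = eig$values),
    class = "spectral_embedding")
}

#' Spectral embedding from the Laplacian
#'
#' Eigenvectors of the `K` smallest Laplacian eigenvalues (ascending),
#' with each row renormalized to unit Euclidean norm before k-means
#' (Ng-Jordan-Weiss style). Rows with zero norm are left at zero with a
#' warning.
#'
#' @param bundle A `laplacian_bundle` from [normalized_laplacian()].
#' @param K Number of dimensions, `1 <= K <= N`.
#' @return Object of class `spectral_embedding`: list with `coordinates`
#'   (N x K, unit rows), `vectors` (the raw eigenvectors), `eigenvalues`
#'   (the K smallest) and `all_eigenvalues`.
#' @export
spectral_embed <- function(bundle, K) {
  if (!inherits(bundle, "laplacian_bundle")) {
    stop("expected a laplacian_bundle", call. = FALSE)
  }
  n <- nrow(bundle$laplacian)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K > n) {
    stop("K must lie in [1, N]", call. = FALSE)
  }
  .embed_from_eigen(.laplacian_eigen(bundle), as.integer(K))
}

# Greedy (kmeans++) seeding: first center uniform at random, each further
# center sampled with probability proportional to squared distance from the
# nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums(sweep(x, 2L, x[idx[1L], ], "-")^2)
    for (j in 2:k) {
      idx[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
      nd <- rowSums(sweep(x, 2L, x[idx[j], ], "-")^2)
      d2 <- pmin(d2, nd)
    }
  }
  x[idx, , drop = FALSE]
}

# Relabel so that the cluster of the first individual is 1, the next new
# cluster encountered is 2, and so on; identical partitions then compare
# equal as plain label vectors.
.canonicalize_labels <- function(labels) {
  match(labels, unique(labels))
}

#' k-means partition of an embedding with seeded restarts
#'
#' Runs k-means `restarts` times with kmeans++ seeding; restart `r` draws
#' from a stream seeded with `seed + r`, so the restart set is reproducible
#' and extending `restarts` never changes earlier restarts. The run with
#' the lowest within-cluster sum of squares wins. Labels are canonicalized
#' by first occurrence (the first individual is always in cluster 1).
#'
#' @param embedding A `spectral_embedding`, an `ordination_result`, or a
#'   plain numeric matrix of coordinates.
#' @param K Number of clusters; must not exceed the number of distinct
#'   embedding points.
#' @param restarts Number of seeded restarts (>= 1); default 100.
#' @param seed Integer seed.
#' @param gamma Optional kernel width recorded in the result.
#' @return Object of class `cluster_assignment`: list with `labels`
#'   (integers in 1..K, canonicalized), `K`, `gamma`, `seed`,
#'   `kmeans_objective` (within-cluster sum of squares of the selected
#'   run), and attribute-style element `restart_objectives` (objective of
#'   every restart).
#' @export
kmeans_partition <- function(embedding, K, restarts = 100L, seed = 1L,
                             gamma = NA_real_) {
  coords <- if (inherits(embedding, "spectral_embedding")) {
    embedding$coordinates
  } else if (inherits(embedding, "ordination_result")) {
    embedding$coordinates
  } else if (is.matrix(embedding)) {
    embedding
  } else {
    stop("embedding must be a spectral_embedding, ordination_result or matrix",
         call. = FALSE)
  }
  if (!is.numeric(restarts) || restarts < 1L) {
    stop("restarts must be >= 1", call. = FALSE)
  }
  K <- as.integer(K)
  n_distinct <- nrow(unique(coords))
  if (K > n_distinct) {
    stop(sprintf("K = %d exceeds the %d distinct embedding points", K,
                 n_distinct), call. = FALSE)
  }
  restarts <- as.integer(restarts)
  if (K == 1L) {
    # trivial partition; also covers embeddings collapsed to a single point
    obj <- sum(sweep(coords, 2L, colMeans(coords))^2)
    return(structure(
      list(labels = rep(1L, nrow(coords)), K = 1L, gamma = gamma,
           seed = as.integer(seed), kmeans_objective = obj,
           restart_objectives = rep(obj, restarts)),
      class = "cluster_assignment"))
  }
  objectives <- rep(Inf, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(seed + r, {
      centers <- .kmeanspp_centers(coords, K)
      tryCatch(
        suppressWarnings(stats::kmeans(coords, centers = centers,
                                       iter.max = 100L,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
    })
    if (is.null(fit)) next
    objectives[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("all k-means restarts failed", call. = FALSE)
  structure(
    list(labels = .canonicalize_labels(best$cluster),
         K = K,
         gamma = gamma,
         seed = as.integer(seed),
         kmeans_objective = best$tot.withinss,
         restart_objectives = objectives),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: N = %d, K = %d (gamma = %s, seed = %d)\n",
              length(x$labels), x$K,
              ifelse(is.na(x$gamma), "-", format(x$gamma)), x$seed))
  cat("cluster sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  cat("k-means objective:", format(x$kmeans_objective), "\n")
  invisible(x)
}

#' Spectral clustering of a character matrix
#'
#' The full clustering engine: RBF similarity -> normalized symmetric
#' Laplacian -> K-dimensional spectral embedding -> k-means with seeded
#' restarts. Deterministic given `seed`.
#'
#' @inheritParams rbf_similarity
#' @inheritParams kmeans_partition
#' @param K Number of clusters to discover.
#' @return A `cluster_assignment` recording `gamma`, `K`, `seed` and the
#'   selected k-means objective.
#' @export
#' @examples
#' sim <- simulate_species_complex(species_complex_config(
#'   n_taxa = 3, per_taxon_range = c(10, 10), n_characters = 4,
#'   n_informative = 4, centroid_separation = 10, seed = 7))
#' m <- standardize(sim$matrix)
#' a <- spectral_cluster(m, gamma = 0.4, K = 3, restarts = 10, seed = 1)
#' table(a$labels, sim$matrix$ground_truth)
spectral_cluster <- function(x, gamma, K, restarts = 100L, seed = 1L,
                             exponent_scale = c("divide", "multiply", "none")) {
  .assert_character_matrix(x)
  exponent_scale <- match.arg(exponent_scale)
  s <- rbf_similarity(x, gamma, exponent_scale)
  bundle <- normalized_laplacian(s)
  embedding <- spectral_embed(bundle, K)
  kmeans_partition(embedding, K, restarts = restarts, seed = seed,
                   gamma = gamma)
}
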