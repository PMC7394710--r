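test_that("the RBF kernel evaluates exactly on hand-computable inputs", {
  # two individuals at squared distance 16 in 16 characters, gamma 0.4,
  # divide-by-d scaling: exp(-0.4 * 16 / 16) = exp(-0.4)
  vals <- matrix(0, 2, 16)
  vals[1, 1] <- 2
  vals[2, 1] <- -2
  s <- rbf_similarity(character_matrix(vals), gamma = 0.4)
  expect_equal(s$values[1, 2], exp(-0.4), tolerance = 1e-12)
  expect_equal(s$values[1, 2], 0.670320, tolerance = 1e-6)
  expect_equal(diag(s$values), rep(1, 2), ignore_attr = TRUE)
})

test_that("identical individuals have similarity exactly 1", {
  vals <- rbind(c(0.5, -0.5), c(0.5, -0.5), c(-1, 1))
  s <- suppressWarnings(rbf_similarity(character_matrix(vals), gamma = 2))
  expect_equal(s$values[1, 2], 1)
})

test_that("doubling gamma squares every off-diagonal similarity", {
  set.seed(5)
  m <- standardize(character_matrix(matrix(rnorm(40), 10, 4)))
  s1 <- rbf_similarity(m, gamma = 0.3)
  s2 <- rbf_similarity(m, gamma = 0.6)
  off <- upper.tri(s1$values)
  expect_equal(s2$values[off], s1$values[off]^2, tolerance = 1e-12)
})

test_that("similarity decreases in gamma and in distance", {
  set.seed(11)
  m <- standardize(character_matrix(matrix(rnorm(60), 15, 4)))
  gammas <- c(0.1, 0.4, 0.8, 1.6)
  mats <- lapply(gammas, function(g) rbf_similarity(m, g)$values)
  off <- upper.tri(mats[[1]])
  for (i in seq_len(length(gammas) - 1)) {
    expect_true(all(mats[[i + 1]][off] < mats[[i]][off]))
  }
  # larger distance, smaller similarity at fixed gamma
  d2 <- as.matrix(dist(m$values))^2
  ord <- order(d2[off])
  expect_true(all(diff(mats[[2]][off][ord]) <= 1e-15))
})

test_that("the exponent scale switch matches its definition", {
  vals <- rbind(c(1, 0, 0, 0), c(-1, 0, 0, 0))
  m <- character_matrix(vals)  # squared distance 4, d = 4
  expect_equal(rbf_similarity(m, 1, "divide")$values[1, 2], exp(-1))
  expect_equal(rbf_similarity(m, 1, "none")$values[1, 2], exp(-4))
  expect_equal(rbf_similarity(m, 1, "multiply")$values[1, 2], exp(-16))
})

test_that("invalid gamma and unstandardized input are reported", {
  m <- character_matrix(matrix(rnorm(20), 10, 2))
  expect_error(rbf_similarity(m, 0), "gamma must be")
  expect_error(rbf_similarity(m, -1), "gamma must be")
  shifted <- character_matrix(matrix(rnorm(20) + 5, 10, 2))
  expect_warning(rbf_similarity(shifted, 1), "standardized")
})

test_that("the normalized Laplacian matches hand linear algebra", {
  s <- structure(list(values = matrix(1, 2, 2), gamma = 1,
                      exponent_scale = "none"), class = "similarity_matrix")
  b <- normalized_laplacian(s)
  expect_equal(b$laplacian, matrix(c(0.5, -0.5, -0.5, 0.5), 2),
               tolerance = 1e-15)
  expect_equal(b$degrees, c(2, 2))
  ev <- eigen(b$laplacian, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sort(ev), c(0, 1), tolerance = 1e-12)
})

test_that("block-diagonal similarity yields one zero eigenvalue per block", {
  for (sizes in list(c(3, 4), c(2, 3, 4), c(2, 2, 2, 3))) {
    bs <- block_similarity(sizes)
    b <- normalized_laplacian(bs$similarity)
    ev <- sort(eigen(b$laplacian, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(max(abs(ev[seq_along(sizes)])), 1e-8)
    expect_gt(ev[length(sizes) + 1], 1e-3)
  }
})

test_that("Laplacian eigenvalues stay within [0, 2] and L reconstructs", {
  set.seed(21)
  for (i in 1:10) {
    m <- standardize(character_matrix(matrix(rnorm(12 * 5), 12, 5)))
    s <- rbf_similarity(m, gamma = runif(1, 0.1, 3))
    b <- normalized_laplacian(s)
    ev <- eigen(b$laplacian, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    expect_lt(max(ev), 2 + 1e-10)
    dm <- 1 / sqrt(b$degrees)
    recon <- diag(nrow(s$values)) - s$values * outer(dm, dm)
    expect_lt(max(abs(recon - b$laplacian)), 1e-12)
    expect_lt(max(abs(b$laplacian - t(b$laplacian))), 1e-12)
  }
})

test_that("a zero row sum is rejected", {
  s <- diag(c(1, 1, 0))
  expect_error(normalized_laplacian(s), "zero row sum")
})

test_that("spectral embedding spans the full basis at K = N", {
  set.seed(3)
  m <- standardize(character_matrix(matrix(rnorm(24), 8, 3)))
  b <- normalized_laplacian(rbf_similarity(m, 0.5))
  e <- spectral_embed(b, 8)
  expect_equal(dim(e$coordinates), c(8, 8))
  expect_length(e$eigenvalues, 8)
  expect_false(is.unsorted(e$eigenvalues))
})

test_that("two disconnected blocks embed as two distinct points", {
  bs <- block_similarity(c(2, 2))
  e <- spectral_embed(normalized_laplacian(bs$similarity), 2)
  expect_lt(max(abs(e$coordinates[1, ] - e$coordinates[2, ])), 1e-8)
  expect_lt(max(abs(e$coordinates[3, ] - e$coordinates[4, ])), 1e-8)
  expect_gt(sum((e$coordinates[1, ] - e$coordinates[3, ])^2), 0.5)
})

test_that("embedding rows are renormalized to unit norm", {
  set.seed(8)
  m <- standardize(character_matrix(matrix(rnorm(40), 10, 4)))
  e <- spectral_embed(normalized_laplacian(rbf_similarity(m, 1)), 4)
  expect_equal(sqrt(rowSums(e$coordinates^2)), rep(1, 10),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(spectral_embed(normalized_laplacian(rbf_similarity(m, 1)), 11),
               "K must lie")
})

test_that("k-means finds the optimum found by exhaustive bipartition", {
  set.seed(13)
  pts <- rbind(matrix(rnorm(8, sd = 0.2), 4, 2),
               matrix(rnorm(8, mean = 6, sd = 0.2), 4, 2))
  a <- kmeans_partition(pts, K = 2, restarts = 20, seed = 7)
  # brute force over all 2^8 - 2 assignments
  best_obj <- Inf
  best_split <- NULL
  for (code in 1:(2^8 - 2)) {
    g <- as.integer(intToBits(code))[1:8]
    if (length(unique(g)) < 2) next
    obj <- sum(sapply(unique(g), function(k) {
      sub <- pts[g == k, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }))
    if (obj < best_obj) {
      best_obj <- obj
      best_split <- g
    }
  }
  expect_equal(a$kmeans_objective, best_obj, tolerance = 1e-10)
  expect_equal(nmi(a$labels, best_split), 1)
  expect_equal(a$labels, c(rep(1, 4), rep(2, 4)))
})

test_that("the selected restart has the minimal objective", {
  set.seed(2)
  pts <- matrix(rnorm(60), 20, 3)
  a <- kmeans_partition(pts, K = 4, restarts = 15, seed = 3)
  expect_true(all(a$kmeans_objective <= a$restart_objectives + 1e-12))
  # extending the restart budget never worsens the selection
  a2 <- kmeans_partition(pts, K = 4, restarts = 40, seed = 3)
  expect_lte(a2$kmeans_objective, a$kmeans_objective)
  expect_equal(a2$restart_objectives[1:15], a$restart_objectives)
})

test_that("degenerate k-means cases behave as specified", {
  set.seed(6)
  pts <- matrix(rnorm(12), 6, 2)
  one <- kmeans_partition(pts, K = 1, restarts = 3, seed = 1)
  expect_equal(one$labels, rep(1, 6))
  expect_equal(one$kmeans_objective,
               sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-10)
  sat <- kmeans_partition(pts, K = 6, restarts = 3, seed = 1)
  expect_equal(sort(unique(sat$labels)), 1:6)
  expect_equal(sat$kmeans_objective, 0, tolerance = 1e-12)
  dup <- rbind(pts[c(1, 1, 2, 2), ])
  expect_error(kmeans_partition(dup, K = 3, restarts = 3, seed = 1),
               "distinct embedding points")
})

test_that("labels are canonicalized by first occurrence", {
  set.seed(17)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
               matrix(rnorm(10, 5, 0.1), 5, 2))
  for (seed in 1:5) {
    a <- kmeans_partition(pts, K = 2, restarts = 5, seed = seed)
    expect_equal(a$labels[1], 1L)
  }
})

test_that("spectral clustering recovers well-separated planted taxa", {
  sim <- simulate_species_complex(species_complex_config(
    n_taxa = 3, per_taxon_range = c(10, 10), n_characters = 4,
    n_informative = 4, centroid_separation = 10, seed = 5))
  m <- standardize(sim$matrix)
  a <- spectral_cluster(m, gamma = 0.4, K = 3, restarts = 20, seed = 2)
  expect_equal(nmi(a$labels, sim$matrix$ground_truth), 1)
  one <- spectral_cluster(m, gamma = 0.4, K = 1, restarts = 5, seed = 2)
  expect_equal(one$labels, rep(1L, 30))
  again <- spectral_cluster(m, gamma = 0.4, K = 3, restarts = 20, seed = 2)
  expect_identical(a$labels, again$labels)
  expect_identical(a$kmeans_objective, again$kmeans_objective)
})

test_that("block-diagonal similarity is partitioned exactly into its blocks", {
  for (sizes in list(c(3, 5), c(2, 3, 4))) {
    bs <- block_similarity(sizes)
    e <- spectral_embed(normalized_laplacian(bs$similarity), length(sizes))
    a <- kmeans_partition(e, length(sizes), restarts = 10, seed = 4)
    expect_equal(nmi(a$labels, bs$blocks), 1)
  }
})

test_that("suggest_gamma tracks the local data scale", {
  set.seed(31)
  tight <- standardize(character_matrix(matrix(rnorm(100), 50, 2)))
  g1 <- suggest_gamma(tight)
  expect_gt(g1, 0)
  # shrinking all distances by 10 scales the suggestion by 100
  small <- character_matrix(tight$values / 10,
                            individual_ids = tight$individual_ids)
  expect_equal(suggest_gamma(small), 100 * g1, tolerance = 1e-10)
})
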