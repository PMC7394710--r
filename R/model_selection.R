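#' Sweep configuration
#'
#' Settings for the kernel-width / cluster-count grid search. Defaults
#' follow common practice for a species complex of moderate size: gamma
#' from 0.05 to 1.0 in steps of 0.05 (20 values), K from 2 to 20 (an upper
#' bound chosen to exceed any plausible number of species or populations),
#' 100 k-means restarts.
#'
#' @param gamma_grid Strictly ascending positive kernel widths.
#' @param k_min,k_max Cluster-count range; `k_min >= 2`.
#' @param restarts k-means restarts per grid cell.
#' @param seed Integer master seed; per-cell seeds are derived from it.
#' @return Object of class `sweep_config`.
#' @export
sweep_config <- function(gamma_grid = seq(0.05, 1, by = 0.05),
                         k_min = 2L, k_max = 20L, restarts = 100L,
                         seed = 1L) {
  if (length(gamma_grid) == 0L) stop("gamma grid is empty", call. = FALSE)
  if (any(gamma_grid <= 0)) stop("gamma values must be positive", call. = FALSE)
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("gamma grid must be strictly ascending", call. = FALSE)
  }
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 2L) stop("k_min must be >= 2", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  structure(list(gamma_grid = as.numeric(gamma_grid), k_min = k_min,
                 k_max = k_max, restarts = as.integer(restarts),
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Eigengap profile
#'
#' Differences of successive ascending Laplacian eigenvalues,
#' `gap(K) = lambda_{K+1} - lambda_K` (1-based), for K in
#' `[k_min, k_max]`. A large gap after the K-th eigenvalue signals K
#' cohesive clusters.
#'
#' @param eigenvalues Ascending eigenvalues (at least `k_max + 1` of them).
#' @param k_min,k_max Range of K.
#' @return Named numeric vector of gaps, names `k_min:k_max`.
#' @export
#' @examples
#' eigengap_profile(c(0, 0.05, 0.8, 0.9), 1, 3)
eigengap_profile <- function(eigenvalues, k_min, k_max) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_min < 1L || k_max < k_min) stop("invalid K range", call. = FALSE)
  if (length(eigenvalues) < k_max + 1L) {
    stop(sprintf("need at least %d eigenvalues for k_max = %d",
                 k_max + 1L, k_max), call. = FALSE)
  }
  ks <- k_min:k_max
  gaps <- eigenvalues[ks + 1L] - eigenvalues[ks]
  names(gaps) <- ks
  gaps
}

# Per-cell seed for grid cell (gamma index gi, cluster count K). Shared
# between spectral_sweep() and users who want to reproduce one cell with
# spectral_cluster(); every assignment records the value it was given.
.cell_seed <- function(seed, gi, K, k_max) {
  as.integer(seed) + (as.integer(gi) - 1L) * (as.integer(k_max) + 1L) +
    as.integer(K)
}

#' Sweep the gamma grid and K range
#'
#' For each kernel width the similarity matrix, Laplacian and full
#' eigendecomposition are computed once; the eigengap profile and (unless
#' `compute_assignments = FALSE`) a k-means partition for every K are
#' derived from it. Each grid cell uses a seed derived deterministically
#' from the master seed, recorded in the assignment, so a single cell can
#' be reproduced with [spectral_cluster()].
#'
#' @param x A standardized [character_matrix] with `N >= k_max` rows.
#' @param config A [sweep_config()].
#' @param exponent_scale Kernel exponent scaling; see [rbf_similarity()].
#' @param compute_assignments If `FALSE`, only spectra (eigenvalues and
#'   eigengaps) are computed — enough for eigengap model selection, and far
#'   cheaper.
#' @return Object of class `sweep_result`: list with `spectra` (one entry
#'   per gamma: `gamma`, `eigenvalues`, `eigengaps`, `k_min`, `k_max`),
#'   `assignments` (nested list `assignments[[gamma index]][[as.character(K)]]`
#'   of `cluster_assignment`s, or `NULL`), and `config`.
#' @export
spectral_sweep <- function(x, config = sweep_config(),
                           exponent_scale = c("divide", "multiply", "none"),
                           compute_assignments = TRUE) {
  .assert_character_matrix(x)
  exponent_scale <- match.arg(exponent_scale)
  if (!inherits(config, "sweep_config")) stop("config must be a sweep_config",
                                              call. = FALSE)
  n <- nrow(x$values)
  if (config$k_max > n) {
    stop(sprintf("k_max = %d exceeds N = %d", config$k_max, n), call. = FALSE)
  }
  spectra <- vector("list", length(config$gamma_grid))
  assignments <- if (compute_assignments) {
    vector("list", length(config$gamma_grid))
  }
  for (gi in seq_along(config$gamma_grid)) {
    gamma <- config$gamma_grid[gi]
    bundle <- normalized_laplacian(rbf_similarity(x, gamma, exponent_scale))
    eig <- .laplacian_eigen(bundle)
    spectra[[gi]] <- list(
      gamma = gamma,
      eigenvalues = eig$values,
      eigengaps = eigengap_profile(eig$values, config$k_min, config$k_max),
      k_min = config$k_min, k_max = config$k_max)
    if (compute_assignments) {
      cell <- list()
      for (K in config$k_min:config$k_max) {
        emb <- .embed_from_eigen(eig, K)
        cell[[as.character(K)]] <- kmeans_partition(
          emb, K, restarts = config$restarts,
          seed = .cell_seed(config$seed, gi, K, config$k_max),
          gamma = gamma)
      }
      assignments[[gi]] <- cell
    }
  }
  structure(list(spectra = spectra, assignments = assignments,
                 config = config, exponent_scale = exponent_scale),
            class = "sweep_result")
}

#' Flatten sweep eigengaps to a table
#'
#' @param sweep A `sweep_result` (or its `spectra` list).
#' @param peaks Optional `selection_report` from
#'   [detect_eigengap_peaks()]; adds an `is_peak` column.
#' @return Data frame with columns `gamma`, `K`, `gap` (and `is_peak`).
#' @export
eigengap_table <- function(sweep, peaks = NULL) {
  spectra <- if (inherits(sweep, "sweep_result")) sweep$spectra else sweep
  tab <- do.call(rbind, lapply(spectra, function(sp) {
    data.frame(gamma = sp$gamma, K = as.integer(names(sp$eigengaps)),
               gap = unname(sp$eigengaps))
  }))
  if (!is.null(peaks)) {
    key <- paste(peaks$per_gamma$gamma, peaks$per_gamma$K)
    tab$is_peak <- peaks$per_gamma$is_peak[match(paste(tab$gamma, tab$K), key)]
  }
  tab
}

#' Detect eigengap peaks and consensus cluster counts
#'
#' Within each gamma, K is a peak of the eigengap profile when its gap
#' exceeds the gap at K-1, is at least the gap at K+1, and is at least
#' `min_prominence` times the median gap over the K range (so that flat
#' profiles yield no peaks). Gamma values with no prominent peak at all
#' (typically overly smooth kernels) are reported as excluded and do not
#' vote; consensus cluster counts are those K that peak for at least
#' `consensus_fraction` of the remaining gamma values. Any veto of a
#' consensus K on biological grounds is left to the user.
#'
#' @param sweep A `sweep_result`, or a list of per-gamma spectra as stored
#'   in its `spectra` element.
#' @param min_prominence Multiple of the median gap a peak must reach;
#'   default 2.
#' @param consensus_fraction Fraction of gamma values that must agree;
#'   default 0.5.
#' @return Object of class `selection_report`: list with `per_gamma` (data
#'   frame `gamma`, `K`, `gap`, `is_peak`), `peaks_by_gamma` (list of peak
#'   K vectors), `top_peak_by_gamma` (data frame `gamma`, `K`, `gap`; ties
#'   in gap height resolved toward smaller K; `NA` when no peak),
#'   `consensus` (sorted integer vector) and `excluded` (data frame
#'   `gamma`, `reason`).
#' @export
detect_eigengap_peaks <- function(sweep, min_prominence = 2,
                                  consensus_fraction = 0.5) {
  spectra <- if (inherits(sweep, "sweep_result")) sweep$spectra else sweep
  if (length(spectra) == 0L) stop("no spectra to analyze", call. = FALSE)
  per_gamma <- list()
  peaks_by_gamma <- list()
  top_rows <- list()
  excluded <- list()
  for (sp in spectra) {
    ev <- sp$eigenvalues
    k_min <- sp$k_min; k_max <- sp$k_max
    gaps <- sp$eigengaps
    ks <- as.integer(names(gaps))
    med <- stats::median(gaps)
    left <- rep(-Inf, length(ks))
    has_left <- ks - 1L >= 1L
    left[has_left] <- ev[ks[has_left]] - ev[ks[has_left] - 1L]
    right <- rep(-Inf, length(ks))
    has_right <- ks + 2L <= length(ev)
    right[has_right] <- ev[ks[has_right] + 2L] - ev[ks[has_right] + 1L]
    is_peak <- gaps > left & gaps >= right & gaps >= min_prominence * med
    per_gamma[[length(per_gamma) + 1L]] <- data.frame(
      gamma = sp$gamma, K = ks, gap = unname(gaps), is_peak = unname(is_peak))
    pk <- ks[is_peak]
    peaks_by_gamma[[as.character(sp$gamma)]] <- pk
    if (length(pk)) {
      g <- gaps[is_peak]
      best <- pk[which(g == max(g))]     # ties toward smaller K
      top_rows[[length(top_rows) + 1L]] <- data.frame(
        gamma = sp$gamma, K = min(best), gap = max(g))
    } else {
      excluded[[length(excluded) + 1L]] <- data.frame(
        gamma = sp$gamma, reason = "no prominent eigengap peak")
      top_rows[[length(top_rows) + 1L]] <- data.frame(
        gamma = sp$gamma, K = NA_integer_, gap = NA_real_)
    }
  }
  per_gamma <- do.call(rbind, per_gamma)
  counts <- table(unlist(peaks_by_gamma))
  # kernel widths with no prominent peak are excluded (reported above) and
  # do not vote in the consensus
  n_voting <- sum(lengths(peaks_by_gamma) > 0L)
  consensus <- if (n_voting == 0L) integer(0) else
    sort(as.integer(names(counts[counts >= consensus_fraction * n_voting])))
  structure(
    list(per_gamma = per_gamma,
         peaks_by_gamma = peaks_by_gamma,
         top_peak_by_gamma = do.call(rbind, top_rows),
         consensus = consensus,
         excluded = if (length(excluded)) do.call(rbind, excluded) else
           data.frame(gamma = numeric(0), reason = character(0)),
         min_prominence = min_prominence,
         consensus_fraction = consensus_fraction),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("eigengap selection report\n")
  cat("consensus K:",
      if (length(x$consensus)) paste(x$consensus, collapse = ", ") else "none",
      "\n")
  cat(sprintf("%d/%d gamma values excluded (no prominent peak)\n",
              nrow(x$excluded), length(x$peaks_by_gamma)))
  invisible(x)
}
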