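# Ross-type k-nearest-neighbour estimator of the mutual information (nats)
# between a continuous variable and a discrete label. For each point, the
# distance to its k-th neighbour within the same label class sets a radius;
# the number of points of any class strictly inside that radius enters a
# digamma average. Ties are broken by a tiny seeded jitter so the estimator
# depends on the values only through their order at matching scales.
.mi_knn <- function(xv, labels, k = 3L) {
  n <- length(xv)
  scale <- stats::sd(xv)
  if (scale == 0) return(0)
  xv <- xv + stats::rnorm(n, sd = 1e-10 * scale)
  counts <- table(labels)
  n_lab <- as.numeric(counts[match(labels, names(counts))])
  dmat <- abs(outer(xv, xv, "-"))
  diag(dmat) <- Inf
  psi_k <- psi_m <- numeric(n)
  use <- rep(TRUE, n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]
    same[i] <- FALSE
    if (!any(same)) { use[i] <- FALSE; next }   # singleton class
    ki <- min(k, sum(same))
    radius <- sort(dmat[i, same], partial = ki)[ki]
    m_i <- sum(dmat[i, ] <= radius)   # all classes, kth neighbour included
    psi_k[i] <- digamma(ki)
    psi_m[i] <- digamma(max(m_i, 1L))
  }
  if (!any(use)) return(0)
  digamma(n) - mean(digamma(n_lab[use])) + mean(psi_k[use]) - mean(psi_m[use])
}

# Plug-in estimate after equal-frequency binning of the continuous variable
# into ceiling(sqrt(N)) bins; a coarse but estimator-independent cross-check
# for the kNN route.
.mi_binned <- function(xv, labels) {
  n <- length(xv)
  if (stats::sd(xv) == 0) return(0)
  nb <- ceiling(sqrt(n))
  bins <- if (length(unique(xv)) <= nb) {
    # effectively discrete character: its own values are the bins
    factor(xv)
  } else {
    brk <- unique(stats::quantile(xv, probs = seq(0, 1, length.out = nb + 1L)))
    cut(xv, breaks = brk, include.lowest = TRUE)
  }
  ct <- table(bins, labels)
  .entropy(rowSums(ct)) + .entropy(colSums(ct)) - .entropy(ct)
}

#' Mutual information between characters and cluster assignment
#'
#' Scores each morphological character by the estimated mutual information
#' (in nats) between its values and the cluster labels. A high score means
#' the character carries substantial information about cluster identity.
#' The default estimator is a nearest-neighbour estimator for mixed
#' continuous/discrete data (k = 3 neighbours, seeded tie-breaking);
#' `estimator = "binning"` switches to an equal-frequency histogram
#' plug-in. Negative estimates (possible for the neighbour estimator under
#' independence) are clipped to 0 and flagged; constant characters score 0.
#'
#' @param x A [character_matrix].
#' @param assignment A `cluster_assignment` (or a plain label vector)
#'   covering all individuals, with at least two occupied clusters.
#' @param k Neighbour count for the kNN estimator.
#' @param estimator `"knn"` (default) or `"binning"`.
#' @param seed Seed for the tie-breaking jitter.
#' @return Data frame sorted by descending score with columns `character`,
#'   `mi`, `rank`, `clipped` (TRUE where a negative estimate was clipped),
#'   `constant`.
#' @export
mi_character_cluster <- function(x, assignment, k = 3L,
                                 estimator = c("knn", "binning"),
                                 seed = 1L) {
  .assert_character_matrix(x)
  estimator <- match.arg(estimator)
  labels <- .partition_labels(assignment)
  if (length(labels) != nrow(x$values)) {
    stop("assignment must cover all individuals", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("mutual information needs at least 2 occupied clusters", call. = FALSE)
  }
  d <- ncol(x$values)
  mi_raw <- numeric(d)
  constant <- logical(d)
  for (j in seq_len(d)) {
    xv <- x$values[, j]
    constant[j] <- stats::sd(xv) == 0
    mi_raw[j] <- if (constant[j]) {
      0
    } else if (estimator == "knn") {
      with_seed(seed + j, .mi_knn(xv, labels, k = k))
    } else {
      .mi_binned(xv, labels)
    }
  }
  clipped <- mi_raw < 0
  scores <- pmax(mi_raw, 0)
  out <- data.frame(character = x$character_names, mi = scores,
                    clipped = clipped, constant = constant,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mi), ]
  out$rank <- seq_len(d)
  rownames(out) <- NULL
  out[, c("character", "mi", "rank", "clipped", "constant")]
}

#' Correlation between characters and Laplacian eigenvectors
#'
#' Pearson correlation (with two-sided p-value) between every character and
#' every eigenvector used in the spectral embedding. Because k-means
#' separates clusters along these eigenvectors, a character strongly
#' correlated with one of them (positively or negatively) helps
#' differentiate the clusters. Eigenvectors are ordered by ascending
#' eigenvalue, i.e. by decreasing importance for cluster formation. Pairs
#' with p-value above `alpha` are marked non-significant for display
#' suppression; zero-variance characters or eigenvector columns yield a
#' missing correlation with a recorded reason.
#'
#' @param x A [character_matrix].
#' @param embedding A `spectral_embedding` over the same individuals in the
#'   same order.
#' @param alpha Significance threshold used for the `significant` flag.
#' @return Data frame with columns `character`, `eigenvector` (1 = smallest
#'   eigenvalue), `r`, `p_value`, `significant`, `reason` (`NA` unless the
#'   correlation is undefined).
#' @export
eigenvector_correlation <- function(x, embedding, alpha = 0.05) {
  .assert_character_matrix(x)
  if (!inherits(embedding, "spectral_embedding")) {
    stop("embedding must be a spectral_embedding", call. = FALSE)
  }
  vecs <- embedding$vectors
  if (nrow(vecs) != nrow(x$values)) {
    stop("embedding and matrix cover different individuals", call. = FALSE)
  }
  rows <- list()
  for (j in seq_len(ncol(x$values))) {
    xv <- x$values[, j]
    for (e in seq_len(ncol(vecs))) {
      ev <- vecs[, e]
      if (stats::sd(xv) == 0 || stats::sd(ev) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          character = x$character_names[j], eigenvector = e,
          r = NA_real_, p_value = NA_real_, significant = NA,
          reason = if (stats::sd(xv) == 0) "zero-variance character" else
            "zero-variance eigenvector", stringsAsFactors = FALSE)
        next
      }
      ct <- suppressWarnings(stats::cor.test(xv, ev, method = "pearson"))
      rows[[length(rows) + 1L]] <- data.frame(
        character = x$character_names[j], eigenvector = e,
        r = unname(ct$estimate), p_value = ct$p.value,
        significant = ct$p.value <= alpha, reason = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Closed-form Welch statistic; shared by the public test and kept simple so
# degenerate inputs can be routed before stats::t.test (which refuses
# constant data).
.welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  md <- mean(a) - mean(b)
  if (va == 0 && vb == 0) {
    if (md == 0) return(list(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    return(list(t = sign(md) * Inf, df = NA_real_, p = 0, degenerate = TRUE))
  }
  se2 <- va / na + vb / nb
  t <- md / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Cluster-versus-rest t-tests per character
#'
#' For every (character, cluster) pair, a two-sided Welch t-test of the
#' character's values inside the cluster against the values of all other
#' individuals. A significant difference marks the character as defining
#' for that cluster. Clusters with fewer than 2 members or fewer than 2
#' non-members are skipped with a logged reason. When both groups are
#' constant the pair is reported as `t = 0, p = 1` (equal means) or flagged
#' degenerate with infinite separation (unequal means) rather than failing.
#'
#' @param x A [character_matrix].
#' @param assignment A `cluster_assignment` or label vector.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] across all pairs; `"none"` (default) mirrors the
#'   raw-significance reporting convention, `"BH"` is the usual
#'   alternative.
#' @return Data frame with columns `character`, `cluster`, `t`, `df`,
#'   `p_value`, `n_within`, `n_outside`, `mean_diff`, `degenerate`;
#'   attribute `skipped` records clusters not tested and why.
#' @export
#' @examples
#' m <- character_matrix(cbind(size = c(4, 6, 1, 3)))
#' cluster_vs_rest_ttest(m, c(1, 1, 2, 2))
cluster_vs_rest_ttest <- function(x, assignment, p_adjust = "none") {
  .assert_character_matrix(x)
  labels <- .partition_labels(assignment)
  if (length(labels) != nrow(x$values)) {
    stop("assignment must cover all individuals", call. = FALSE)
  }
  clusters <- sort(unique(labels))
  n <- length(labels)
  rows <- list()
  skipped <- list()
  for (cl in clusters) {
    inside <- labels == cl
    if (sum(inside) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cluster = cl, reason = sprintf("only %d member(s)", sum(inside)))
      next
    }
    if (sum(!inside) < 2L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        cluster = cl, reason = sprintf("only %d non-member(s)", sum(!inside)))
      next
    }
    for (j in seq_len(ncol(x$values))) {
      a <- x$values[inside, j]
      b <- x$values[!inside, j]
      w <- .welch(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        character = x$character_names[j], cluster = cl,
        t = w$t, df = w$df, p_value = w$p,
        n_within = sum(inside), n_outside = sum(!inside),
        mean_diff = mean(a) - mean(b), degenerate = w$degenerate,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    character = character(0), cluster = integer(0), t = numeric(0),
    df = numeric(0), p_value = numeric(0), n_within = integer(0),
    n_outside = integer(0), mean_diff = numeric(0), degenerate = logical(0))
  if (p_adjust != "none" && nrow(out)) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cluster = integer(0), reason = character(0))
  out
}
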