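.partition_labels <- function(x) {
  if (inherits(x, "cluster_assignment")) x$labels else x
}

.check_partition_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions must label the same individuals (length mismatch)",
         call. = FALSE)
  }
  if (length(a) < 2L) stop("partitions must cover at least 2 items", call. = FALSE)
}

.contingency <- function(a, b) {
  table(factor(a), factor(b))
}

.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Normalized mutual information between two partitions
#'
#' Mutual information of the joint label distribution, normalized by a
#' summary of the two partition entropies. Ranges over `[0, 1]`; 1 means
#' the partitions agree up to relabeling; invariant to label permutation.
#' The default normalization is the arithmetic mean of the entropies;
#' geometric-mean, max and min variants are available since conventions
#' differ between implementations.
#'
#' @param a,b Label vectors of equal length (or `cluster_assignment`s).
#' @param normalization One of `"arithmetic"`, `"geometric"`, `"max"`,
#'   `"min"`.
#' @return NMI in `[0, 1]`. When both partitions are trivial (zero
#'   entropy) they are identical up to relabeling and 1 is returned.
#' @export
#' @examples
#' nmi(c(0, 0, 1, 1), c(1, 1, 0, 0))   # 1: same split, relabeled
#' nmi(c(0, 0, 1, 1), c(0, 1, 0, 1))   # 0: independent splits
nmi <- function(a, b, normalization = c("arithmetic", "geometric", "max", "min")) {
  normalization <- match.arg(normalization)
  a <- .partition_labels(a); b <- .partition_labels(b)
  .check_partition_pair(a, b)
  ct <- .contingency(a, b)
  n <- sum(ct)
  ha <- .entropy(rowSums(ct))
  hb <- .entropy(colSums(ct))
  if (ha == 0 && hb == 0) return(1)
  mi <- 0
  pa <- rowSums(ct) / n
  pb <- colSums(ct) / n
  for (i in seq_len(nrow(ct))) {
    for (j in seq_len(ncol(ct))) {
      if (ct[i, j] > 0) {
        pij <- ct[i, j] / n
        mi <- mi + pij * log(pij / (pa[i] * pb[j]))
      }
    }
  }
  denom <- switch(normalization,
                  arithmetic = (ha + hb) / 2,
                  geometric = sqrt(ha * hb),
                  max = max(ha, hb),
                  min = min(ha, hb))
  if (denom == 0) return(0)
  # clamp tiny negative / >1 excursions from floating point
  min(max(mi / denom, 0), 1)
}

#' Rand and adjusted Rand indices
#'
#' Pair-counting agreement between two partitions from the contingency
#' table. The plain Rand index is the fraction of item pairs on which the
#' partitions agree (together in both, or apart in both), in `[0, 1]`. The
#' adjusted Rand index corrects for chance agreement and ranges over
#' `[-1, 1]`; it is the score usually quoted when clusterings are compared
#' against taxonomic ground truth.
#'
#' @inheritParams nmi
#' @return List with elements `rand` and `adjusted_rand`.
#' @export
#' @examples
#' rand_indices(c(0, 0, 1, 1), c(0, 1, 0, 1))  # rand 1/3, adjusted -0.5
rand_indices <- function(a, b) {
  a <- .partition_labels(a); b <- .partition_labels(b)
  .check_partition_pair(a, b)
  ct <- .contingency(a, b)
  n <- sum(ct)
  total <- choose(n, 2)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  rand <- (total + 2 * sum_ij - sum_a - sum_b) / total
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) {
    # both partitions trivial in the same way (all-singletons or
    # one-cluster): identical up to relabeling
    1
  } else {
    (sum_ij - expected) / (max_index - expected)
  }
  list(rand = rand, adjusted_rand = ari)
}

#' All external validation scores at once
#'
#' @inheritParams nmi
#' @return Object of class `validation_scores`: list with `nmi`, `rand`,
#'   `adjusted_rand` and the `contingency` table.
#' @export
validation_scores <- function(a, b,
                              normalization = c("arithmetic", "geometric",
                                                "max", "min")) {
  a <- .partition_labels(a); b <- .partition_labels(b)
  ri <- rand_indices(a, b)
  structure(list(nmi = nmi(a, b, normalization = match.arg(normalization)),
                 rand = ri$rand,
                 adjusted_rand = ri$adjusted_rand,
                 contingency = .contingency(a, b)),
            class = "validation_scores")
}

#' @export
print.validation_scores <- function(x, ...) {
  cat(sprintf("NMI = %.4f, Rand = %.4f, adjusted Rand = %.4f\n",
              x$nmi, x$rand, x$adjusted_rand))
  invisible(x)
}

#' Validate every sweep assignment against ground truth
#'
#' @param sweep A `sweep_result` with assignments.
#' @param ground_truth Taxon labels, one per individual.
#' @return Data frame with columns `gamma`, `K`, `nmi`, `rand`,
#'   `adjusted_rand`, the per-cell analogue of an NMI/Rand validation plot.
#' @export
validate_sweep <- function(sweep, ground_truth) {
  if (!inherits(sweep, "sweep_result") || is.null(sweep$assignments)) {
    stop("sweep must be a sweep_result with assignments", call. = FALSE)
  }
  rows <- list()
  for (cell in unlist(sweep$assignments, recursive = FALSE)) {
    ri <- rand_indices(cell$labels, ground_truth)
    rows[[length(rows) + 1L]] <- data.frame(
      gamma = cell$gamma, K = cell$K,
      nmi = nmi(cell$labels, ground_truth),
      rand = ri$rand, adjusted_rand = ri$adjusted_rand)
  }
  do.call(rbind, rows)
}
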