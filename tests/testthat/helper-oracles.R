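# Independent oracles and small fixture builders shared across tests.

# All set partitions of n items as label vectors (restricted growth strings).
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(labels, next_max) {
    if (length(labels) == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(next_max + 1L)) {
      grow(c(labels, v), max(next_max, v))
    }
  }
  grow(integer(0), 0L)
  out
}

# Pair-enumeration oracle: counts of item pairs together/apart in two
# partitions, by explicit loop over all unordered pairs.
pair_counts_oracle <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ta <- a[i] == a[j]
      tb <- b[i] == b[j]
      if (ta && tb) s11 <- s11 + 1L
      else if (ta && !tb) s10 <- s10 + 1L
      else if (!ta && tb) s01 <- s01 + 1L
      else s00 <- s00 + 1L
    }
  }
  c(s11 = s11, s10 = s10, s01 = s01, s00 = s00)
}

rand_oracle <- function(a, b) {
  s <- pair_counts_oracle(a, b)
  (s["s11"] + s["s00"]) / sum(s)
}

# Adjusted Rand from pair counts (Hubert & Arabie form written in terms of
# the four pair-agreement counts; independent of the contingency route).
ari_oracle <- function(a, b) {
  s <- as.numeric(pair_counts_oracle(a, b))
  s11 <- s[1]; s10 <- s[2]; s01 <- s[3]; s00 <- s[4]
  denom <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (denom == 0) return(1)
  2 * (s11 * s00 - s10 * s01) / denom
}

# NMI via the entropy identity I = H(A) + H(B) - H(A,B), entropies taken
# from plain table() counts.
entropy_oracle <- function(x) {
  p <- as.numeric(table(x)) / length(x)
  -sum(p * log(p))
}

nmi_oracle <- function(a, b) {
  ha <- entropy_oracle(a)
  hb <- entropy_oracle(b)
  if (ha == 0 && hb == 0) return(1)
  mi <- ha + hb - entropy_oracle(paste(a, b, sep = "\r"))
  denom <- (ha + hb) / 2
  if (denom == 0) return(0)
  min(max(mi / denom, 0), 1)
}

# Closed-form Welch statistic for two samples.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

make_cmat <- function(values, labels = NULL) {
  character_matrix(values, ground_truth = labels)
}

# Center each character without rescaling: the form in which planted
# cluster geometry enters the recovery benchmarks.
centered_matrix <- function(cm) {
  vals <- scale(cm$values, center = TRUE, scale = FALSE)
  attr(vals, "scaled:center") <- NULL
  character_matrix(vals, individual_ids = cm$individual_ids,
                   ground_truth = cm$ground_truth)
}

# A block-constant similarity matrix: 1 within blocks, `off` across.
block_similarity <- function(sizes, off = 0) {
  blocks <- rep(seq_along(sizes), sizes)
  s <- matrix(off, length(blocks), length(blocks))
  for (b in seq_along(sizes)) {
    s[blocks == b, blocks == b] <- 1
  }
  list(similarity = s, blocks = blocks)
}
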