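#' Configuration for the synthetic species-complex generator
#'
#' Describes a benchmark data set with the statistical structure of a
#' morphometric species-complex study: a handful of taxa with uneven,
#' small sample sizes, a subset of informative characters whose taxon
#' centroids are separated by a controlled multiple of the within-taxon
#' spread, uninformative noise characters, optional hybrid (intermediate)
#' individuals and optional cross-complex outliers.
#'
#' @param n_taxa Number of taxa (ground-truth clusters).
#' @param per_taxon_range Two integers: minimum and maximum individuals
#'   sampled per taxon.
#' @param n_individuals Optional total N; per-taxon counts are re-drawn
#'   until they sum to it (must be feasible under `per_taxon_range`).
#' @param n_characters Total number of continuous characters.
#' @param n_informative How many characters carry taxon signal; the rest
#'   are drawn from a common standard normal regardless of taxon.
#' @param centroid_separation Minimum distance between taxon centroids in
#'   the informative subspace, in multiples of `within_sd`; 0 removes all
#'   signal.
#' @param within_sd Within-taxon standard deviation of informative
#'   characters.
#' @param hybrid_fraction Fraction of individuals turned into
#'   intermediates: their informative centroid is a convex combination
#'   (uniform mixing weight) of their own taxon's and a second taxon's
#'   centroid. They keep their own label; parents are recorded in the
#'   metadata.
#' @param outlier_fraction Fraction of individuals whose informative
#'   values are drawn around a centroid from the other complex (or any
#'   other taxon when no complex structure is given), keeping their label.
#' @param complexes Optional list of integer vectors partitioning
#'   `1:n_taxa` into species complexes; complex centers are separated by
#'   twice the taxon separation.
#' @param hybrid_taxa Optional list of integer triples
#'   `c(child, parent_a, parent_b)`: the child taxon's centroid is a
#'   per-individual convex blend of the two parents (an intermediate form
#'   carried as its own taxon).
#' @param distribution Within-taxon noise for informative characters:
#'   `"normal"` (default) or `"lognormal"` (centered, matched SD) for
#'   ratio-like skew.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return Object of class `species_complex_config`.
#' @seealso [simulate_species_complex()], [two_complex_preset()]
#' @export
species_complex_config <- function(n_taxa = 10L,
                                   per_taxon_range = c(4L, 19L),
                                   n_individuals = NULL,
                                   n_characters = 16L,
                                   n_informative = 8L,
                                   centroid_separation = 4,
                                   within_sd = 1,
                                   hybrid_fraction = 0,
                                   outlier_fraction = 0,
                                   complexes = NULL,
                                   hybrid_taxa = NULL,
                                   distribution = c("normal", "lognormal"),
                                   seed = 1L) {
  distribution <- match.arg(distribution)
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 1L) stop("n_taxa must be >= 1", call. = FALSE)
  per_taxon_range <- as.integer(per_taxon_range)
  if (length(per_taxon_range) != 2L || per_taxon_range[1L] < 1L ||
      per_taxon_range[2L] < per_taxon_range[1L]) {
    stop("per_taxon_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  n_characters <- as.integer(n_characters)
  n_informative <- as.integer(n_informative)
  if (n_informative < 1L || n_informative > n_characters) {
    stop("n_informative must lie in [1, n_characters]", call. = FALSE)
  }
  if (!is.null(n_individuals)) {
    n_individuals <- as.integer(n_individuals)
    if (n_individuals < n_taxa * per_taxon_range[1L] ||
        n_individuals > n_taxa * per_taxon_range[2L]) {
      stop("n_individuals infeasible under per_taxon_range", call. = FALSE)
    }
  }
  if (centroid_separation < 0) stop("centroid_separation must be >= 0",
                                    call. = FALSE)
  if (within_sd <= 0) stop("within_sd must be positive", call. = FALSE)
  if (hybrid_fraction < 0 || hybrid_fraction >= 1 ||
      outlier_fraction < 0 || outlier_fraction >= 1) {
    stop("hybrid_fraction and outlier_fraction must lie in [0, 1)",
         call. = FALSE)
  }
  if (!is.null(complexes)) {
    flat <- sort(unlist(complexes))
    if (!identical(flat, seq_len(n_taxa))) {
      stop("complexes must partition 1:n_taxa", call. = FALSE)
    }
  }
  if (!is.null(hybrid_taxa)) {
    for (h in hybrid_taxa) {
      if (length(h) != 3L || any(h < 1L) || any(h > n_taxa) ||
          h[1L] %in% h[2:3] || h[2L] == h[3L]) {
        stop("each hybrid_taxa entry must be c(child, parent_a, parent_b) ",
             "with three distinct taxa", call. = FALSE)
      }
    }
  }
  structure(list(n_taxa = n_taxa, per_taxon_range = per_taxon_range,
                 n_individuals = n_individuals, n_characters = n_characters,
                 n_informative = n_informative,
                 centroid_separation = centroid_separation,
                 within_sd = within_sd, hybrid_fraction = hybrid_fraction,
                 outlier_fraction = outlier_fraction, complexes = complexes,
                 hybrid_taxa = hybrid_taxa, distribution = distribution,
                 seed = as.integer(seed)),
            class = "species_complex_config")
}

# Place k centroids in m dimensions pairwise separated by `target`.
# For k <= m + 1 this is exact: a regular simplex with edge `target`,
# randomly rotated so no character axis is privileged. For more taxa than
# the simplex allows, a random Gaussian cloud is rescaled so the minimum
# pairwise distance equals `target` (other pairs then sit farther apart).
# target 0 collapses everything onto the origin (no signal).
.place_centroids <- function(k, m, target) {
  if (target == 0 || k < 2L) return(matrix(0, k, m))
  if (k <= m + 1L) {
    x <- diag(k) / sqrt(2)            # pairwise distances exactly 1
    x <- sweep(x, 2L, colMeans(x))    # center; affine dimension k - 1
    sv <- svd(x)
    y <- (sv$u %*% diag(sv$d, k))[, seq_len(k - 1L), drop = FALSE]
    # random orthonormal embedding into the m characters, redrawn until no
    # character is starved of between-taxon signal (each row must hold at
    # least half its equal share of the rotation energy) so that every
    # informative character is actually informative
    floor_norm <- 0.5 * (k - 1L) / m
    q <- NULL
    for (try in 1:200) {
      cand <- qr.Q(qr(matrix(stats::rnorm(m * (k - 1L)), m)))[,
        seq_len(k - 1L), drop = FALSE]
      if (min(rowSums(cand^2)) >= floor_norm) {
        q <- cand
        break
      }
    }
    if (is.null(q)) q <- cand
    return(target * y %*% t(q))
  }
  centers <- matrix(stats::rnorm(k * m), k, m)
  delta <- min(stats::dist(centers))
  if (delta == 0) stop("degenerate centroid draw", call. = FALSE)
  centers * target / delta
}

# sample() that treats a length-1 vector as a set, not as 1:n
.resample <- function(x, size) x[sample.int(length(x), size)]

.centered_noise <- function(n, sd_target, distribution) {
  if (distribution == "normal") {
    stats::rnorm(n, sd = sd_target)
  } else {
    sdlog <- 0.5
    raw <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    raw_sd <- sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
    (raw - exp(sdlog^2 / 2)) * sd_target / raw_sd
  }
}

#' Simulate a morphometric species complex
#'
#' Draws a character matrix under the configuration built by
#' [species_complex_config()]. Informative characters are normal (or
#' centered log-normal) around taxon centroids placed at the requested
#' minimum separation; noise characters are standard normal for everyone.
#' Hybrid taxa and hybrid/outlier individuals perturb the clean mixture
#' the way intermediates and cross-complex strays do in real complexes.
#'
#' @param config A `species_complex_config`.
#' @return List with `matrix` (a [character_matrix] whose `ground_truth`
#'   holds the planted taxon labels), `metadata` (data frame: taxon,
#'   complex, hybrid flag and parents, mixing weight, outlier flag) and
#'   `centroids` (taxa x informative characters).
#' @export
simulate_species_complex <- function(config) {
  if (!inherits(config, "species_complex_config")) {
    stop("config must come from species_complex_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    nt <- config$n_taxa
    m <- config$n_informative
    sep <- config$centroid_separation * config$within_sd

    # per-taxon sample sizes
    size_pool <- seq(config$per_taxon_range[1L], config$per_taxon_range[2L])
    draw_sizes <- function() {
      size_pool[sample.int(length(size_pool), nt, replace = TRUE)]
    }
    sizes <- draw_sizes()
    if (!is.null(config$n_individuals)) {
      tries <- 1L
      while (sum(sizes) != config$n_individuals) {
        sizes <- draw_sizes()
        tries <- tries + 1L
        if (tries > 100000L) {
          stop("could not hit n_individuals under per_taxon_range",
               call. = FALSE)
        }
      }
    }

    # taxon centroids in the informative subspace
    if (is.null(config$complexes)) {
      centroids <- .place_centroids(nt, m, sep)
    } else {
      nc <- length(config$complexes)
      ccenters <- .place_centroids(nc, m, 2 * sep)
      centroids <- matrix(0, nt, m)
      for (ci in seq_len(nc)) {
        members <- config$complexes[[ci]]
        offs <- .place_centroids(length(members), m, sep)
        centroids[members, ] <- sweep(offs, 2L, ccenters[ci, ], "+")
      }
    }
    complex_of <- rep(1L, nt)
    if (!is.null(config$complexes)) {
      for (ci in seq_along(config$complexes)) {
        complex_of[config$complexes[[ci]]] <- ci
      }
    }

    n <- sum(sizes)
    taxon <- rep(seq_len(nt), times = sizes)
    hybrid_taxon_children <- vapply(config$hybrid_taxa %||% list(),
                                    `[`, integer(1L), 1L)

    base <- centroids[taxon, , drop = FALSE]
    parent_a <- taxon
    parent_b <- rep(NA_integer_, n)
    mix <- rep(NA_real_, n)

    # hybrid taxa: the whole child taxon is a per-individual blend
    for (h in config$hybrid_taxa %||% list()) {
      rows <- which(taxon == h[1L])
      u <- stats::runif(length(rows))
      base[rows, ] <- u * centroids[rep(h[2L], length(rows)), , drop = FALSE] +
        (1 - u) * centroids[rep(h[3L], length(rows)), , drop = FALSE]
      parent_a[rows] <- h[2L]; parent_b[rows] <- h[3L]; mix[rows] <- u
    }

    # hybrid individuals scattered across ordinary taxa
    eligible <- which(!taxon %in% hybrid_taxon_children)
    n_hyb <- floor(config$hybrid_fraction * n)
    hybrid_rows <- if (n_hyb > 0L)
      .resample(eligible, min(n_hyb, length(eligible))) else integer(0)
    for (i in hybrid_rows) {
      other <- .resample(setdiff(seq_len(nt), taxon[i]), 1L)
      u <- stats::runif(1L)
      base[i, ] <- u * centroids[taxon[i], ] + (1 - u) * centroids[other, ]
      parent_b[i] <- other; mix[i] <- u
    }

    # outliers: informative values borrowed from across the complex boundary
    n_out <- floor(config$outlier_fraction * n)
    out_pool <- setdiff(eligible, hybrid_rows)
    outlier_rows <- if (n_out > 0L && nt > 1L)
      .resample(out_pool, min(n_out, length(out_pool))) else integer(0)
    for (i in outlier_rows) {
      foreign <- setdiff(which(complex_of != complex_of[taxon[i]]), taxon[i])
      if (!length(foreign)) foreign <- setdiff(seq_len(nt), taxon[i])
      base[i, ] <- centroids[.resample(foreign, 1L), ]
    }

    values <- matrix(stats::rnorm(n * config$n_characters), n,
                     config$n_characters)
    noise <- matrix(.centered_noise(n * m, config$within_sd,
                                    config$distribution), n, m)
    values[, seq_len(m)] <- base + noise

    ids <- sprintf("ind_%03d", seq_len(n))
    char_names <- c(sprintf("inf_%02d", seq_len(m)),
                    if (m < config$n_characters)
                      sprintf("noise_%02d", seq_len(config$n_characters - m)))
    labels <- sprintf("taxon_%02d", taxon)
    metadata <- data.frame(
      individual_id = ids,
      taxon = labels,
      complex = sprintf("complex_%d", complex_of[taxon]),
      hybrid = seq_len(n) %in% hybrid_rows | taxon %in% hybrid_taxon_children,
      parent_a = sprintf("taxon_%02d", parent_a),
      parent_b = ifelse(is.na(parent_b), NA_character_,
                        sprintf("taxon_%02d", parent_b)),
      mixing_weight = mix,
      outlier = seq_len(n) %in% outlier_rows,
      stringsAsFactors = FALSE)

    list(matrix = character_matrix(values, individual_ids = ids,
                                   character_names = char_names,
                                   ground_truth = labels),
         metadata = metadata,
         centroids = centroids)
  })
}

#' Benchmark preset: two species complexes, 93 individuals, 10 taxa
#'
#' A ready-made configuration emulating a two-complex morphometric study:
#' 10 taxa split into complexes of 3 and 7, per-taxon sample sizes between
#' 4 and 19 conditioned to total 93 individuals, 16 continuous characters
#' of which 8 are informative, overlapping clusters (centroid separation 4
#' within-taxon SDs), and one intermediate taxon generated as a convex
#' blend of two same-complex parents.
#'
#' @param seed Integer seed.
#' @return A `species_complex_config`.
#' @export
#' @examples
#' sim <- simulate_species_complex(two_complex_preset(seed = 1))
#' nrow(sim$matrix$values)                 # 93
#' length(unique(sim$matrix$ground_truth)) # 10
two_complex_preset <- function(seed = 1L) {
  species_complex_config(
    n_taxa = 10L, per_taxon_range = c(4L, 19L), n_individuals = 93L,
    n_characters = 16L, n_informative = 8L,
    centroid_separation = 4, within_sd = 1,
    complexes = list(1:3, 4:10),
    hybrid_taxa = list(c(10L, 5L, 6L)),
    seed = seed)
}

#' Simulate a non-convex two-cluster benchmark
#'
#' Two interleaved half-moons in two characters (plus optional noise
#' characters), the canonical structure on which centroid-based clustering
#' after linear ordination fails while similarity-graph methods succeed.
#'
#' @param n Total number of individuals (split evenly between moons).
#' @param noise_sd Gaussian jitter around the arcs.
#' @param n_noise_characters Additional pure-noise characters appended.
#' @param seed Integer seed.
#' @return A [character_matrix] with `ground_truth` labels `"moon_1"`,
#'   `"moon_2"`.
#' @export
simulate_two_moons <- function(n = 100L, noise_sd = 0.1,
                               n_noise_characters = 0L, seed = 1L) {
  n <- as.integer(n)
  if (n < 4L) stop("n must be >= 4", call. = FALSE)
  with_seed(seed, {
    n1 <- n %/% 2L
    n2 <- n - n1
    t1 <- stats::runif(n1, 0, pi)
    t2 <- stats::runif(n2, 0, pi)
    xy <- rbind(cbind(cos(t1), sin(t1)),
                cbind(1 - cos(t2), 0.5 - sin(t2)))
    xy <- xy + matrix(stats::rnorm(2L * n, sd = noise_sd), n, 2L)
    vals <- cbind(xy,
                  if (n_noise_characters > 0L)
                    matrix(stats::rnorm(n * n_noise_characters), n,
                           n_noise_characters))
    colnames(vals) <- c("arc_x", "arc_y",
                        if (n_noise_characters > 0L)
                          sprintf("noise_%02d", seq_len(n_noise_characters)))
    character_matrix(vals,
                     individual_ids = sprintf("ind_%03d", seq_len(n)),
                     ground_truth = rep(c("moon_1", "moon_2"), c(n1, n2)))
  })
}
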