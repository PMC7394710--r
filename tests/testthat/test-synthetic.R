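test_that("the generator plants exactly the declared structure", {
  cfg <- species_complex_config(n_taxa = 3, per_taxon_range = c(10, 10),
                                n_characters = 10, n_informative = 4,
                                centroid_separation = 6, seed = 8)
  sim <- simulate_species_complex(cfg)
  expect_equal(dim(sim$matrix$values), c(30, 10))
  expect_equal(unname(table(sim$matrix$ground_truth)), rep(10, 3),
               ignore_attr = TRUE)
  # taxon signal sits exactly in the informative characters
  labels <- sim$matrix$ground_truth
  pvals <- apply(sim$matrix$values, 2, function(v) {
    anova(lm(v ~ labels))[["Pr(>F)"]][1]
  })
  expect_true(all(pvals[1:4] < 1e-4))
  expect_true(all(pvals[5:10] > 1e-2))
  # pairwise centroid separation honours the config
  expect_equal(as.numeric(dist(sim$centroids)), rep(6, 3), tolerance = 1e-10)
})

test_that("zero separation removes all planted signal", {
  cfg <- species_complex_config(n_taxa = 3, per_taxon_range = c(12, 12),
                                n_characters = 8, n_informative = 4,
                                centroid_separation = 0, seed = 9)
  sim <- simulate_species_complex(cfg)
  expect_equal(max(abs(sim$centroids)), 0)
  m <- standardize(sim$matrix)
  a <- spectral_cluster(m, 0.5, 3, restarts = 10, seed = 1)
  expect_lt(nmi(a$labels, sim$matrix$ground_truth), 0.25)
})

test_that("the two-complex preset reproduces the study dimensions", {
  sim <- simulate_species_complex(two_complex_preset(seed = 1))
  expect_equal(nrow(sim$matrix$values), 93)
  expect_equal(ncol(sim$matrix$values), 16)
  expect_length(unique(sim$matrix$ground_truth), 10)
  sizes <- table(sim$matrix$ground_truth)
  expect_true(all(sizes >= 4 & sizes <= 19))
  expect_equal(sort(unique(sim$metadata$complex)),
               c("complex_1", "complex_2"))
  # the hybrid taxon is flagged with both parents recorded
  hyb <- sim$metadata[sim$metadata$taxon == "taxon_10", ]
  expect_true(all(hyb$hybrid))
  expect_true(all(hyb$parent_a == "taxon_05" & hyb$parent_b == "taxon_06"))
  expect_true(all(hyb$mixing_weight >= 0 & hyb$mixing_weight <= 1))
})

test_that("generation is deterministic given the seed", {
  s1 <- simulate_species_complex(two_complex_preset(seed = 5))
  s2 <- simulate_species_complex(two_complex_preset(seed = 5))
  expect_identical(s1$matrix$values, s2$matrix$values)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_species_complex(two_complex_preset(seed = 6))
  expect_false(identical(s1$matrix$values, s3$matrix$values))
})

test_that("recovery improves monotonically with centroid separation", {
  seps <- c(0, 1, 2, 4, 8)
  mean_nmi <- sapply(seps, function(sep) {
    mean(sapply(1:20, function(seed) {
      cfg <- species_complex_config(n_taxa = 3, per_taxon_range = c(10, 10),
                                    n_characters = 8, n_informative = 4,
                                    centroid_separation = sep, seed = seed)
      sim <- simulate_species_complex(cfg)
      m <- centered_matrix(sim$matrix)
      a <- spectral_cluster(m, suggest_gamma(m), 3, restarts = 10, seed = 1)
      nmi(a$labels, sim$matrix$ground_truth)
    }))
  })
  expect_true(all(diff(mean_nmi) > -0.05))
  expect_lt(mean_nmi[1], 0.3)
  expect_gt(mean_nmi[5], 0.9)
})

test_that("extreme separation yields perfect recovery through the pipeline", {
  cfg <- species_complex_config(n_taxa = 3, per_taxon_range = c(10, 10),
                                n_characters = 6, n_informative = 6,
                                centroid_separation = 10, seed = 10)
  sim <- simulate_species_complex(cfg)
  a <- spectral_cluster(standardize(sim$matrix), 0.4, 3, restarts = 20,
                        seed = 1)
  expect_equal(nmi(a$labels, sim$matrix$ground_truth), 1)
})

test_that("noise characters score stochastically below informative ones", {
  inf_mi <- c()
  noise_mi <- c()
  for (seed in 1:10) {
    cfg <- species_complex_config(n_taxa = 3, per_taxon_range = c(15, 15),
                                  n_characters = 8, n_informative = 3,
                                  centroid_separation = 5, seed = seed)
    sim <- simulate_species_complex(cfg)
    mi <- mi_character_cluster(sim$matrix, sim$matrix$ground_truth,
                               seed = seed)
    inf_mi <- c(inf_mi, mi$mi[grepl("^inf_", mi$character)])
    noise_mi <- c(noise_mi, mi$mi[grepl("^noise_", mi$character)])
  }
  wt <- wilcox.test(inf_mi, noise_mi, alternative = "greater")
  expect_lt(wt$p.value, 1e-6)
})

test_that("hybrid and outlier individuals are injected and recorded", {
  cfg <- species_complex_config(n_taxa = 4, per_taxon_range = c(10, 10),
                                n_characters = 6, n_informative = 4,
                                centroid_separation = 6,
                                hybrid_fraction = 0.1, outlier_fraction = 0.05,
                                complexes = list(1:2, 3:4), seed = 11)
  sim <- simulate_species_complex(cfg)
  expect_equal(sum(sim$metadata$hybrid), 4)   # floor(0.1 * 40)
  expect_equal(sum(sim$metadata$outlier), 2)  # floor(0.05 * 40)
  hyb <- sim$metadata[sim$metadata$hybrid, ]
  expect_true(all(!is.na(hyb$parent_b)))
  expect_true(all(hyb$parent_a != hyb$parent_b))
})

test_that("infeasible configurations are rejected", {
  expect_error(species_complex_config(n_taxa = 0), "n_taxa")
  expect_error(species_complex_config(n_individuals = 3, n_taxa = 2,
                                      per_taxon_range = c(4, 5)),
               "infeasible")
  expect_error(species_complex_config(n_informative = 20, n_characters = 16),
               "n_informative")
  expect_error(species_complex_config(hybrid_taxa = list(c(1, 1, 2))),
               "distinct taxa")
  expect_error(species_complex_config(complexes = list(1:2, 4:10)),
               "partition")
})

test_that("the lognormal noise option keeps the centroid structure", {
  cfg <- species_complex_config(n_taxa = 2, per_taxon_range = c(30, 30),
                                n_characters = 4, n_informative = 2,
                                centroid_separation = 8,
                                distribution = "lognormal", seed = 12)
  sim <- simulate_species_complex(cfg)
  labels <- sim$matrix$ground_truth
  centers <- aggregate(sim$matrix$values[, 1:2], list(labels), mean)[, -1]
  expect_equal(sqrt(sum((centers[1, ] - centers[2, ])^2)), 8,
               tolerance = 0.8)
})

test_that("two-moons data has the declared labels and is deterministic", {
  mm <- simulate_two_moons(100, seed = 3, n_noise_characters = 2)
  expect_equal(dim(mm$values), c(100, 4))
  expect_equal(unname(table(mm$ground_truth)), rep(50, 2), ignore_attr = TRUE)
  mm2 <- simulate_two_moons(100, seed = 3, n_noise_characters = 2)
  expect_identical(mm$values, mm2$values)
})
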