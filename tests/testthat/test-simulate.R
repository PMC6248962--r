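test_that("the six-population survey preset encodes the emulated design", {
  cfg <- haloxylon_preset(seed = 1)
  expect_equal(unname(cfg$sizes), c(20, 20, 20, 25, 10, 13))
  expect_equal(sum(cfg$sizes), 108)
  expect_equal(sum(cfg$loci_per_primer), 195)
  expect_length(cfg$loci_per_primer, 16)
  expect_equal(cfg$n_fixed, 28)
  expect_equal(cfg$F, rep(0.25, 6))
  km <- geographic_distance(
    data.frame(sample = cfg$centroids$pop, lat = cfg$centroids$lat,
               lon = cfg$centroids$lon),
    setNames(cfg$centroids$pop, cfg$centroids$pop))
  expect_gt(max(km), 80)   # centroids span on the order of 100 km
  expect_lt(max(km), 250)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(c(A = 1, B = 5), 10), ">= 2")
  expect_error(sim_config(c(A = 5, B = 5), 10, F = 0), "\\(0, 1\\)")
  expect_error(sim_config(c(A = 5, B = 5), 10, F = c(0.2, 0.2, 0.2)), "scalar")
  expect_error(sim_config(c(A = 5, B = 5), 10, missing_rate = 1), "missing_rate")
  expect_error(sim_config(c(A = 5, B = 5), 10, n_fixed = 10), "n_fixed")
  expect_error(sim_config(c(A = 5, B = 5), 10,
                          admixture = matrix(1, 2, 2)), "row-stochastic")
})

test_that("draws are reproducible and structurally consistent with the truth record", {
  cfg <- sim_config(c(A = 6, B = 7), c(5, 5), F = 0.3, missing_rate = 0.1,
                    seed = 99)
  s1 <- simulate_markers(cfg)
  s2 <- simulate_markers(cfg)
  expect_identical(s1$matrix$bands, s2$matrix$bands)
  expect_equal(dim(s1$truth$pop_freq), c(2, 10))
  expect_equal(n_samples(s1$matrix), 13)
  expect_equal(unique(s1$matrix$primers), c("P01", "P02"))
  miss <- mean(is.na(s1$matrix$bands))
  expect_gt(miss, 0.02); expect_lt(miss, 0.25)
})

test_that("F limits drive differentiation from none to near-fixation", {
  lo <- simulate_markers(sim_config(c(A = 15, B = 15, C = 15), rep(20, 3),
                                    F = 1e-4, seed = 2))
  phi_lo <- amova(squared_distances(lo$matrix), lo$matrix$pops, n_perm = 0)$phi_st
  expect_lt(abs(phi_lo), 0.05)

  hi <- simulate_markers(sim_config(c(A = 15, B = 15, C = 15), rep(20, 3),
                                    F = 0.99, seed = 2))
  phi_hi <- amova(squared_distances(hi$matrix), hi$matrix$pops, n_perm = 0)$phi_st
  expect_gt(phi_hi, 0.6)
  expect_gt(hi$truth$realized_phist, 0.6)
})

test_that("across-population frequency variance rises monotonically with F", {
  grid <- c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5, 0.7)
  spread <- vapply(grid, function(Fv) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_markers(sim_config(c(A = 5, B = 5, C = 5, D = 5),
                                         rep(15, 2), F = Fv, seed = 1000 * s))
      mean(apply(sim$truth$pop_freq, 2, var))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cor(grid, spread, method = "spearman"), 0.95)
})

test_that("dominant-diploid emission raises band probability to 1-(1-p)^2", {
  cfg <- sim_config(c(A = 5, B = 5), c(6, 6), F = 0.2,
                    emission = "dominant_diploid", seed = 17)
  sim <- simulate_markers(cfg)
  expect_equal(sim$truth$band_prob, 1 - (1 - sim$truth$pop_freq)^2)
  expect_true(all(sim$truth$band_prob >= sim$truth$pop_freq))
})

test_that("admixture mixing pulls a population's profile toward its sources", {
  A <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.5, 0.5, 0))  # pop C = 50/50 A and B
  cfg <- sim_config(c(A = 40, B = 40, C = 40), rep(30, 4), F = 0.7,
                    admixture = A, seed = 23)
  sim <- simulate_markers(cfg)
  bf <- band_frequencies(sim$matrix, "per_population")$freq
  target <- 0.5 * sim$truth$band_prob["A", ] + 0.5 * sim$truth$band_prob["B", ]
  expect_lt(mean(abs(bf["C", ] - target)), 0.08)
})

test_that("GPS scatter stays near the configured centroids", {
  cen <- data.frame(pop = c("A", "B"), lat = c(29, 30), lon = c(47, 48))
  cfg <- sim_config(c(A = 30, B = 30), c(5, 5), F = 0.2, centroids = cen,
                    scatter_km = 2, seed = 3)
  sim <- simulate_markers(cfg)
  est <- mean(sim$geo$lat[sim$matrix$pops == "A"])
  expect_lt(abs(est - 29), 3 * 2 / 111.19 / sqrt(30) * 3)
  km <- geographic_distance(sim$geo, sim$matrix$pops)
  expect_gt(km["A", "B"], 100)
})
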