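test_that("squared distances count band mismatches, rescaled for missingness", {
  m <- marker_matrix(rbind(c(1L, 0L), c(1L, 1L)), pops = c("A", "A"))
  d <- squared_distances(m)
  expect_equal(d[1, 2], 1)
  expect_equal(diag(d), c(a = 0, b = 0), ignore_attr = TRUE)

  m2 <- marker_matrix(rbind(s1 = c(1L, 0L, NA), s2 = c(0L, 0L, 1L)),
                      pops = c("A", "A"))
  expect_equal(squared_distances(m2)["s1", "s2"], 1.5)  # 1 mismatch / 2 shared * 3

  m3 <- marker_matrix(rbind(c(1L, NA), c(NA, 1L)), pops = c("A", "A"))
  expect_error(squared_distances(m3), "no scored loci")
})

test_that("hand-worked decomposition: 4 samples, 2 pops, Phi_ST = 1/3", {
  bands <- rbind(c(1L, 0L), c(1L, 1L), c(0L, 0L), c(0L, 1L))
  m <- marker_matrix(bands, pops = c("A", "A", "B", "B"))
  res <- amova(squared_distances(m), m$pops, n_perm = 0)
  expect_equal(unname(res$SS["total"]), 2)
  expect_equal(unname(res$SS["within"]), 1)
  expect_equal(unname(res$sigma2["within"]), 0.5)
  expect_equal(res$n0, 2)
  expect_equal(unname(res$sigma2["among"]), 0.25)
  expect_equal(res$phi_st, 1 / 3)
  expect_equal(unname(res$df), c(1, 2, 3))
  expect_equal(unname(sum(res$pct[1:2])), 100)
})

test_that("fixed differences give Phi_ST = 1 with the smallest attainable p", {
  bands <- rbind(c(1L, 1L, 1L), c(1L, 1L, 1L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  m <- marker_matrix(bands, pops = c("A", "A", "B", "B"))
  res <- amova(squared_distances(m), m$pops, n_perm = 200, seed = 1)
  expect_equal(res$phi_st, 1)
  # permutations preserving the split also reach phi = 1, so p reflects the
  # 1/3 of balanced 4-sample relabellings that keep the two pairs intact
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 0.45)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration", {
  set.seed(42)
  bands <- matrix(rbinom(6 * 12, 1, 0.5), nrow = 6)
  bands[1:3, 1:6] <- 1L  # some real structure
  storage.mode(bands) <- "integer"
  pops <- rep(c("A", "B"), each = 3)
  m <- marker_matrix(bands, pops = pops)
  exact <- amova_exact_p(m$bands, pops)
  res <- amova(squared_distances(m), pops, n_perm = 4000, seed = 9)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$p_value - exact), 3 * se + 1 / 4000)
  # and the observed statistic agrees with the from-definitions oracle
  expect_equal(res$phi_st, amova_oracle_phi(m$bands, pops))
})

test_that("permutation p is seed-reproducible and amova equals pairwise entry", {
  set.seed(3)
  sim <- simulate_markers(sim_config(c(A = 8, B = 8, C = 8), rep(10, 3),
                                     F = 0.25, seed = 3))
  m <- sim$matrix
  d <- squared_distances(m)
  r1 <- amova(d, m$pops, n_perm = 500, seed = 77)
  r2 <- amova(d, m$pops, n_perm = 500, seed = 77)
  expect_identical(r1$p_value, r2$p_value)

  pw <- pairwise_fst(m)
  idx <- which(m$pops %in% c("A", "B"))
  two <- amova(d[idx, idx], m$pops[idx], n_perm = 0)
  expect_equal(pw$fst["A", "B"], two$phi_st)
  expect_equal(diag(pw$fst), c(A = 0, B = 0, C = 0), ignore_attr = TRUE)
})

test_that("equal-frequency populations give near-zero Phi_ST, divergent ones rank higher", {
  set.seed(21)
  freqs <- runif(40, 0.2, 0.8)
  draw <- function(p_shift = 0) {
    p <- pmin(pmax(freqs + p_shift, 0.02), 0.98)
    matrix(rbinom(12 * 40, 1, rep(p, each = 12)), nrow = 12)
  }
  m <- marker_matrix(rbind(draw(), draw(), draw(0.4)),
                     pops = rep(c("A", "B", "C"), each = 12))
  pw <- pairwise_fst(m)$fst
  expect_lt(abs(pw["A", "B"]), 0.08)
  expect_lt(pw["A", "B"], pw["A", "C"])
})

test_that("negative among-population variance is reported, not hidden", {
  set.seed(8)
  bands <- matrix(rbinom(12 * 30, 1, 0.5), nrow = 12)
  storage.mode(bands) <- "integer"
  pops <- rep(c("A", "B"), 6)  # interleaved: no structure
  d <- squared_distances(marker_matrix(bands, pops = pops))
  res <- amova(d, pops, n_perm = 0)
  if (res$sigma2[["among"]] < 0) {
    expect_true(res$negative_variance)
    clamped <- amova(d, pops, n_perm = 0, clamp_negative = TRUE)
    expect_equal(clamped$phi_st, 0)
  } else {
    succeed("draw produced non-negative component")
  }
})
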