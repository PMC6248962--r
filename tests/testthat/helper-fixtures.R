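# Small fixtures and independent oracles shared across tests.

# 4 samples x 3 loci, two populations, two primers
tiny_mm <- function() {
  bands <- rbind(
    a1 = c(1L, 0L, 1L),
    a2 = c(1L, 1L, 1L),
    b1 = c(0L, 0L, 0L),
    b2 = c(0L, 1L, 0L)
  )
  colnames(bands) <- c("L1", "L2", "L3")
  marker_matrix(bands, pops = c("A", "A", "B", "B"),
                primers = c("P1", "P1", "P2"))
}

# AMOVA oracle straight from the definitions: explicit pair loops, no shared
# code with the implementation.
amova_oracle_phi <- function(bands, pops) {
  n <- nrow(bands)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    d[i, j] <- d[j, i] <- sum(bands[i, ] != bands[j, ])
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) ss_tot <- ss_tot + d[i, j]
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(pops)) {
    idx <- which(pops == g)
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]
    ss_w <- ss_w + s / length(idx)
  }
  K <- length(unique(pops))
  sizes <- as.numeric(table(pops))
  sig_b <- ss_w / (n - K)
  n0 <- (n - sum(sizes^2) / n) / (K - 1)
  sig_a <- ((ss_tot - ss_w) / (K - 1) - sig_b) / n0
  sig_a / (sig_a + sig_b)
}

# Exact permutation p for AMOVA: enumerate every distinct equal-size
# two-group assignment (sizes fixed), tail includes the observed one.
amova_exact_p <- function(bands, pops) {
  n <- nrow(bands)
  sizes <- table(pops)
  stopifnot(length(sizes) == 2)
  obs <- amova_oracle_phi(bands, pops)
  combos <- utils::combn(n, sizes[[1]])
  phis <- apply(combos, 2, function(idx) {
    lab <- rep(names(sizes)[2], n)
    lab[idx] <- names(sizes)[1]
    amova_oracle_phi(bands, lab)
  })
  mean(phis >= obs - 1e-12)
}

# Modal-assignment accuracy maximised over cluster label permutations
best_accuracy <- function(Q, truth) {
  hard <- apply(Q, 1, which.max)
  K <- ncol(Q)
  perms <- gtools_permutations(K)
  max(apply(perms, 1, function(pm) mean(pm[hard] == truth)))
}

# all permutations of 1..k as rows (tiny k only)
gtools_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(pos, ifelse(sub >= pos, sub + 1, sub))
  }))
}

# random symmetric zero-diagonal "distance" matrix
rand_sym <- function(k) {
  m <- matrix(0, k, k)
  m[upper.tri(m)] <- runif(k * (k - 1) / 2)
  m + t(m)
}
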