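#' Squared Euclidean band-mismatch distances between samples
#'
#' For binary profiles the squared Euclidean distance is the count of loci at
#' which band states differ (the Arlequin RFLP/AFLP convention). With missing
#' scores the mismatch count over loci scored in both samples is rescaled by
#' n_loci / n_shared so all pairs live on a common scale.
#'
#' @param m a [marker_matrix].
#' @return symmetric numeric matrix with zero diagonal, labelled by sample id.
#' @export
squared_distances <- function(m) {
  b <- m$bands
  L <- ncol(b)
  if (nrow(b) < 2) stop("need at least 2 samples", call. = FALSE)
  if (!anyNA(b)) {
    bd <- matrix(as.numeric(b), nrow(b))
    cross <- tcrossprod(bd)
    ones <- rowSums(bd)
    d <- outer(ones, ones, "+") - 2 * cross
  } else {
    obs <- !is.na(b)
    bz <- b; bz[!obs] <- 0L
    bz <- matrix(as.numeric(bz), nrow(b))
    obsn <- matrix(as.numeric(obs), nrow(b))
    shared <- tcrossprod(obsn)
    if (any(shared[upper.tri(shared)] == 0))
      stop("a sample pair shares no scored loci", call. = FALSE)
    # mismatches over shared loci: sum x_i + x_j - 2 x_i x_j, restricted to shared
    xi_on_j <- tcrossprod(bz, obsn)   # sum over l of x_i * obs_j
    mism <- xi_on_j + t(xi_on_j) - 2 * tcrossprod(bz)
    d <- mism * L / shared
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(b), rownames(b))
  d
}

amova_components <- function(d, pop_f) {
  N <- nrow(d)
  K <- nlevels(pop_f)
  sizes <- tabulate(pop_f, K)
  ss_total <- sum(d) / (2 * N)          # zero diagonal: sum/2 = sum over i<j
  ss_within <- 0
  for (k in seq_len(K)) {
    idx <- which(as.integer(pop_f) == k)
    ss_within <- ss_within + sum(d[idx, idx]) / (2 * sizes[k])
  }
  ss_among <- ss_total - ss_within
  df_among <- K - 1
  df_within <- N - K
  sigma_b <- ss_within / df_within
  n0 <- (N - sum(sizes^2) / N) / df_among
  sigma_a <- (ss_among / df_among - sigma_b) / n0
  list(ss_total = ss_total, ss_within = ss_within, ss_among = ss_among,
       df_among = df_among, df_within = df_within, n0 = n0,
       sigma_a = sigma_a, sigma_b = sigma_b,
       phi_st = sigma_a / (sigma_a + sigma_b))
}

#' Analysis of molecular variance (one level: among/within populations)
#'
#' Excoffier-style decomposition of squared inter-individual distances into
#' among- and within-population variance components, with Phi-ST tested by
#' permuting individuals among populations (sizes held fixed). The observed
#' statistic is counted in the permutation tail, so p is never exactly 0.
#'
#' @param d square matrix from [squared_distances()] (or any symmetric
#'   squared-distance matrix with sample labels).
#' @param pops population label per row of `d`.
#' @param n_perm number of random label permutations (default 10100; 0 skips
#'   the test and returns `p = NA`).
#' @param seed optional integer seed for reproducible permutations.
#' @param clamp_negative zero out a negative among-population variance
#'   component instead of reporting it.
#' @return object of class `amova_result`: df, SS, variance components,
#'   percentages, `phi_st`, `p_value`, `n_perm`, `seed` and a
#'   `negative_variance` flag.
#' @export
amova <- function(d, pops, n_perm = 10100, seed = NULL, clamp_negative = FALSE) {
  d <- as.matrix(d)
  pop_f <- factor(pops, levels = unique(pops))
  if (nlevels(pop_f) < 2) stop("need at least 2 populations", call. = FALSE)
  if (any(tabulate(pop_f) < 2)) stop("every population needs >= 2 samples", call. = FALSE)
  obs <- amova_components(d, pop_f)
  negative <- obs$sigma_a < 0
  sigma_a <- if (clamp_negative) max(obs$sigma_a, 0) else obs$sigma_a
  phi <- sigma_a / (sigma_a + obs$sigma_b)
  p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    labs <- as.integer(pop_f)
    hits <- vapply(seq_len(n_perm), function(i) {
      amova_components(d, factor(sample(labs)))$phi_st >= obs$phi_st
    }, logical(1))
    p <- (sum(hits) + 1) / (n_perm + 1)
  }
  structure(list(
    df = c(among = obs$df_among, within = obs$df_within,
           total = obs$df_among + obs$df_within),
    SS = c(among = obs$ss_among, within = obs$ss_within, total = obs$ss_total),
    sigma2 = c(among = sigma_a, within = obs$sigma_b),
    pct = 100 * c(among = sigma_a, within = obs$sigma_b) / (sigma_a + obs$sigma_b),
    n0 = obs$n0, phi_st = phi, p_value = p, n_perm = n_perm,
    seed = seed, negative_variance = negative
  ), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (among/within populations)\n")
  tab <- data.frame(df = x$df,
                    SS = c(x$SS),
                    Est.Var = c(x$sigma2, sum(x$sigma2)),
                    Pct = c(x$pct, 100))
  print(round(tab, 3))
  cat(sprintf("Phi_ST = %.3f", x$phi_st))
  if (!is.na(x$p_value))
    cat(sprintf(", P = %.4g (%d permutations)", x$p_value, x$n_perm))
  cat("\n")
  if (x$negative_variance) cat("note: negative among-population variance component\n")
  invisible(x)
}

#' Pairwise Phi-ST between populations
#'
#' Each off-diagonal entry is the Phi-ST of the two-population AMOVA on the
#' corresponding sub-matrix; optional permutation p-values per pair.
#'
#' @param m a [marker_matrix].
#' @param n_perm permutations per pair (0 skips testing).
#' @param seed optional integer seed.
#' @return list with `fst` (K x K symmetric, zero diagonal) and `p`
#'   (K x K, `NA` diagonal; all-`NA` when `n_perm = 0`).
#' @export
pairwise_fst <- function(m, n_perm = 0, seed = NULL) {
  d <- squared_distances(m)
  pops <- unique(m$pops)
  K <- length(pops)
  fst <- matrix(0, K, K, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  if (!is.null(seed)) set.seed(seed)
  for (a in seq_len(K - 1)) for (b in seq(a + 1, K)) {
    idx <- which(m$pops %in% pops[c(a, b)])
    res <- amova(d[idx, idx], m$pops[idx], n_perm = n_perm, seed = NULL)
    fst[a, b] <- fst[b, a] <- res$phi_st
    pmat[a, b] <- pmat[b, a] <- res$p_value
  }
  list(fst = fst, p = pmat)
}
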