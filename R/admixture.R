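#' Bayesian admixture clustering of binary band profiles
#'
#' STRUCTURE-style unsupervised clustering of dominant-marker profiles.
#' Bands are modelled as haploid observations: each cell X_il has a latent
#' cluster of origin Z_il drawn from the individual's membership vector q_i
#' (Dirichlet(alpha) prior), and X_il | Z_il = k is Bernoulli with cluster
#' band frequency F_kl (Beta(lambda1, lambda2) prior). A Gibbs sampler with
#' fully conjugate updates runs `burn_in + reps` sweeps; population labels
#' are never used in inference. The model evidence is summarised as
#' lnP = mean(lnL) - var(lnL)/2 over the post-burn-in marginal
#' log-likelihood trace (the STRUCTURE estimator of ln P(X|K)).
#'
#' @param m a [marker_matrix].
#' @param K number of clusters (>= 1, <= n_samples).
#' @param alpha Dirichlet admixture parameter (> 0).
#' @param lambda length-2 Beta prior parameters for cluster band frequencies.
#' @param burn_in,reps burn-in and retained sweep counts.
#' @param seed optional integer seed (fixed seed gives bit-identical output).
#' @param sample_alpha update alpha by random-walk Metropolis instead of
#'   holding it fixed.
#' @return object of class `admixture_result`: `Q` (samples x K posterior
#'   mean memberships, rows sum to 1), `F` (K x loci posterior mean band
#'   frequencies), `lnP`, `lnL_mean`, `lnL_var`, `alpha`, and the config.
#' @export
fit_admixture <- function(m, K, alpha = 1, lambda = c(1, 1),
                          burn_in = 1000, reps = 100000,
                          seed = NULL, sample_alpha = FALSE) {
  stopifnot(K >= 1, burn_in > 0, reps > 0, alpha > 0, all(lambda > 0))
  if (K > n_samples(m)) stop("K exceeds the number of samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- admix_gibbs_cpp(m$bands, as.integer(K), alpha, lambda[1], lambda[2],
                         as.integer(burn_in), as.integer(reps), sample_alpha)
  lnL <- fit$lnL
  rownames(fit$Q) <- rownames(m$bands)
  colnames(fit$F) <- colnames(m$bands)
  structure(list(
    Q = fit$Q / rowSums(fit$Q), F = fit$F,
    lnP = mean(lnL) - stats::var(lnL) / 2,
    lnL_mean = mean(lnL), lnL_var = stats::var(lnL),
    alpha = fit$alpha,
    config = list(K = K, alpha = alpha, lambda = lambda, burn_in = burn_in,
                  reps = reps, seed = seed, sample_alpha = sample_alpha)
  ), class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat(sprintf("admixture fit: K = %d, lnP = %.2f (%d sweeps after %d burn-in)\n",
              x$config$K, x$lnP, x$config$reps, x$config$burn_in))
  invisible(x)
}

#' Closed-form single-cluster log-evidence
#'
#' For K = 1 the model marginal is a product of independent Beta-Bernoulli
#' terms: ln P(X) = sum over loci of ln B(lambda1 + n1, lambda2 + n0) -
#' ln B(lambda1, lambda2). Used as an exact oracle for the sampler's lnP.
#'
#' @param m a [marker_matrix].
#' @param lambda Beta prior parameters.
#' @export
lnP_single_cluster <- function(m, lambda = c(1, 1)) {
  n1 <- colSums(m$bands == 1L, na.rm = TRUE)
  n0 <- colSums(m$bands == 0L, na.rm = TRUE)
  sum(lbeta(lambda[1] + n1, lambda[2] + n0) - lbeta(lambda[1], lambda[2]))
}

#' Replicate admixture runs over a range of K
#'
#' Runs [fit_admixture()] `n_runs` times for every K in `K_range`, with
#' per-run seeds derived deterministically from `seed`, and collects the lnP
#' estimates in the runs x K layout consumed by [evanno()].
#'
#' @inheritParams fit_admixture
#' @param K_range integer vector of K values (consecutive for [evanno()]).
#' @param n_runs replicate runs per K (>= 2 for Evanno).
#' @return matrix of lnP values, `n_runs` rows, columns named by K.
#' @export
admixture_runs <- function(m, K_range = 1:10, n_runs = 10, alpha = 1,
                           lambda = c(1, 1), burn_in = 1000, reps = 100000,
                           seed = NULL) {
  out <- matrix(NA_real_, n_runs, length(K_range),
                dimnames = list(NULL, as.character(K_range)))
  counter <- 0L
  for (j in seq_along(K_range)) for (r in seq_len(n_runs)) {
    counter <- counter + 1L
    run_seed <- if (is.null(seed)) NULL else (seed + counter) %% .Machine$integer.max
    out[r, j] <- fit_admixture(m, K_range[j], alpha = alpha, lambda = lambda,
                               burn_in = burn_in, reps = reps,
                               seed = run_seed)$lnP
  }
  out
}

#' Evanno delta-K table for cluster-number selection
#'
#' From a runs x K table of lnP estimates: L'(K) = mean lnP(K) - mean
#' lnP(K-1); |L''(K)| = mean over runs of |lnP_r(K-1) - 2 lnP_r(K) +
#' lnP_r(K+1)|; delta-K = |L''(K)| / sd over runs of lnP(K). The suggested
#' cluster number is the interior K maximising delta-K.
#'
#' @param lnp_runs matrix, runs in rows, consecutive K values as columns
#'   (column names = K).
#' @return data.frame per K: `K`, `mean_lnP`, `sd_lnP`, `Lprime`, `Lsecond`,
#'   `deltaK`; attribute `optimal_K`.
#' @export
evanno <- function(lnp_runs) {
  lnp_runs <- as.matrix(lnp_runs)
  if (nrow(lnp_runs) < 2) stop("need >= 2 runs per K", call. = FALSE)
  if (ncol(lnp_runs) < 3) stop("need >= 3 consecutive K values", call. = FALSE)
  Ks <- as.integer(colnames(lnp_runs))
  if (any(diff(Ks) != 1)) stop("K values must be consecutive", call. = FALSE)
  mlnp <- colMeans(lnp_runs)
  sdlnp <- apply(lnp_runs, 2, stats::sd)
  nK <- length(Ks)
  Lp <- c(NA, diff(mlnp))
  Ls <- rep(NA_real_, nK)
  dK <- rep(NA_real_, nK)
  for (j in 2:(nK - 1)) {
    Ls[j] <- mean(abs(lnp_runs[, j - 1] - 2 * lnp_runs[, j] + lnp_runs[, j + 1]))
    if (sdlnp[j] > 0) dK[j] <- Ls[j] / sdlnp[j]
    else warning("sd of lnP is 0 at K = ", Ks[j], "; delta-K undefined there")
  }
  out <- data.frame(K = Ks, mean_lnP = mlnp, sd_lnP = sdlnp,
                    Lprime = Lp, Lsecond = Ls, deltaK = dK)
  rownames(out) <- NULL
  attr(out, "optimal_K") <- if (all(is.na(dK))) NA_integer_
                            else Ks[which.max(dK)]
  out
}

#' Mean cluster membership per predefined population
#'
#' @param res an `admixture_result`.
#' @param pops population label per sample (named by sample id or in row
#'   order of `res$Q`).
#' @return n_pops x K matrix of mean Q, rows named by population.
#' @export
pop_membership <- function(res, pops) {
  if (length(pops) != nrow(res$Q))
    stop("need one population label per sample", call. = FALSE)
  lv <- unique(as.character(pops))
  out <- t(vapply(lv, function(pp)
    colMeans(res$Q[pops == pp, , drop = FALSE]), numeric(ncol(res$Q))))
  rownames(out) <- lv
  colnames(out) <- paste0("Cluster", seq_len(ncol(res$Q)))
  out
}
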